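#' Export a run trace to plain-text files
#'
#' Writes three files under `path`: `raster.tsv` (one row per timestep,
#' one column per neuron, values `1` = active, `0` = inactive, `.` =
#' blank — the white/black raster convention), `events.jsonl` (one JSON
#' record per cycle: fired rule, equality and symbol-detection states,
#' decoded slots) and `config.yaml` (the run's configuration snapshot and
#' seed). The files round-trip through [read_trace()].
#'
#' @param trace A `dpaan_run`.
#' @param path Directory to write into (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dpaan_run"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  raster_file <- file.path(path, "raster.tsv")
  events_file <- file.path(path, "events.jsonl")
  config_file <- file.path(path, "config.yaml")
  enc <- encode_raster(trace$raster)
  utils::write.table(enc, raster_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  lines <- vapply(trace$events, function(ev) {
    jsonlite::toJSON(ev, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, events_file)
  yaml::write_yaml(c(trace$config, list(seed = trace$seed)), config_file)
  invisible(c(raster = raster_file, events = events_file,
              config = config_file))
}

# {-1, 0, 1} activations -> {"0", ".", "1"} raster characters.
encode_raster <- function(raster) {
  if (is.null(raster)) return(matrix(character(0), 0, 0))
  out <- matrix(".", nrow(raster), ncol(raster))
  out[raster > 0] <- "1"
  out[raster < 0] <- "0"
  out
}

decode_raster <- function(chars) {
  out <- matrix(0, nrow(chars), ncol(chars))
  out[chars == "1"] <- 1
  out[chars == "0"] <- -1
  out
}

#' Re-load an exported run trace
#'
#' @param path Directory written by [export_trace()].
#' @return A `dpaan_run` with `raster`, `events`, `config` and `seed`
#'   reconstructed from the files.
#' @export
read_trace <- function(path) {
  raster_file <- file.path(path, "raster.tsv")
  events_file <- file.path(path, "events.jsonl")
  config_file <- file.path(path, "config.yaml")
  chars <- if (file.size(raster_file) > 0) {
    m <- as.matrix(utils::read.table(raster_file, sep = "\t",
                                     colClasses = "character",
                                     header = FALSE))
    dimnames(m) <- NULL
    m
  } else {
    matrix(character(0), 0, 0)
  }
  lines <- readLines(events_file)
  events <- lapply(lines, function(l) {
    jsonlite::fromJSON(l, simplifyVector = FALSE)
  })
  cfg <- yaml::read_yaml(config_file)
  seed <- cfg$seed
  cfg$seed <- NULL
  fired <- vapply(events, function(ev) {
    f <- ev$fired
    if (is.null(f)) NA_character_ else as.character(f)
  }, character(1))
  decoded <- do.call(rbind, lapply(events, function(ev) {
    vapply(ev$decoded, function(d) {
      if (is.null(d)) NA_character_ else as.character(d)
    }, character(1))
  }))
  structure(list(
    raster = decode_raster(chars), events = events, fired = fired,
    decoded = decoded,
    halted = any(vapply(events, function(ev) isTRUE(ev$halt), logical(1))),
    cycles = length(events), config = cfg, seed = as.integer(seed)
  ), class = "dpaan_run")
}
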