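#' Serialize and parse production rules
#'
#' Rules are written to and read from plain lists suitable for YAML, so a
#' rule bank can live in a configuration file. Conditions are recorded as
#' `{eq: [k, kp], weight}` or `{sd: [k, symbol], weight}`; actions as
#' `{set: [k, symbol]}`, `{transfer: [from, to]}` or `{dm: [blank...]}`.
#' Parsing and serializing are exact inverses (bit-exact round-trip).
#'
#' @param r A [rule()].
#' @param x A list as produced by `rule_to_list()`.
#' @return `rule_to_list()`: a plain list; `rule_from_list()`: a
#'   `dpaan_rule`.
#' @export
rule_to_list <- function(r) {
  stopifnot(inherits(r, "dpaan_rule"))
  list(
    name = r$name,
    threshold = r$threshold,
    halt = r$halt,
    inputs = lapply(r$inputs, function(i) {
      if (i$type == "eq") list(eq = c(i$k, i$kp), weight = i$weight)
      else list(sd = list(i$k, i$symbol), weight = i$weight)
    }),
    actions = lapply(r$actions, function(a) {
      switch(a$type,
             set = list(set = list(a$k, a$symbol)),
             transfer = list(transfer = c(a$from, a$to)),
             dm = list(dm = as.list(a$blank)))
    })
  )
}

#' @rdname rule_to_list
#' @export
rule_from_list <- function(x) {
  inputs <- lapply(x$inputs, function(i) {
    w <- i$weight %||% 1
    if (!is.null(i$eq)) eq_input(i$eq[[1]], i$eq[[2]], weight = w)
    else if (!is.null(i$sd)) sd_input(i$sd[[1]], i$sd[[2]], weight = w)
    else stopf("rule input must be 'eq' or 'sd'")
  })
  actions <- lapply(x$actions, function(a) {
    if (!is.null(a$set)) action_set(a$set[[1]], a$set[[2]])
    else if (!is.null(a$transfer)) action_transfer(a$transfer[[1]],
                                                   a$transfer[[2]])
    else if (!is.null(a$dm)) action_dm(unlist(a$dm))
    else stopf("rule action must be 'set', 'transfer' or 'dm'")
  })
  rule(x$name, inputs, x$threshold, actions, halt = isTRUE(x$halt))
}

#' Write and read a network configuration file
#'
#' The configuration schema (YAML) covers everything needed to rebuild a
#' network and its control layer: `partition_sizes`, `symbols`,
#' `coding_level`, `seed`, an optional `schedule` (see
#' [cycle_schedule()]) and an optional `rules` list (see
#' [rule_to_list()]).
#'
#' @param config List with the fields above (e.g. from
#'   [read_dpaan_config()], or built by hand).
#' @param path File path.
#' @return `write_dpaan_config()` returns `path` invisibly;
#'   `read_dpaan_config()` returns the configuration with `rules` parsed
#'   into `dpaan_rule` objects and `schedule` into a [cycle_schedule()].
#' @export
write_dpaan_config <- function(config, path) {
  out <- config
  if (!is.null(out$rules)) {
    out$rules <- lapply(out$rules, function(r) {
      if (inherits(r, "dpaan_rule")) rule_to_list(r) else r
    })
  }
  if (!is.null(out$schedule)) out$schedule <- unclass(out$schedule)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_dpaan_config
#' @export
read_dpaan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$partition_sizes) || is.null(cfg$symbols)) {
    stopf("config must define 'partition_sizes' and 'symbols'")
  }
  cfg$partition_sizes <- as.integer(unlist(cfg$partition_sizes))
  cfg$symbols <- as.character(unlist(cfg$symbols))
  cfg$coding_level <- cfg$coding_level %||% 0.5
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (!is.null(cfg$rules)) {
    cfg$rules <- lapply(cfg$rules, rule_from_list)
  }
  if (!is.null(cfg$schedule)) {
    cfg$schedule <- do.call(cycle_schedule, cfg$schedule)
  }
  cfg
}
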