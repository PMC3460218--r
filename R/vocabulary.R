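#' Generate a random symbol vocabulary
#'
#' Each symbol of the vocabulary is a global pattern over all `N` neurons:
#' a random bipolar vector whose entries are +1 (active) with probability
#' `coding_level` and -1 (inactive) otherwise. The restriction of pattern
#' `l` to partition `k` is the "piece" the slot holds when it represents
#' symbol `l`.
#'
#' Patterns are drawn sequentially and a draw is rejected (and redrawn, a
#' bounded number of times, with full restarts when an accepted prefix
#' proves unextendable) if it collides with an earlier pattern on any
#' partition, or — with `ensure_stable = TRUE`, the default — if adding it
#' to the Hopfield-trained weight matrix would leave any symbol's piece
#' unstable on its isolated partition. The network's operating premise is
#' that every partition, cut off from the rest, retains every symbol as a
#' fixed point; at moderate loads (L approaching a tenth of the partition
#' size) an unconditioned random draw occasionally violates this through
#' crosstalk, so generation screens for it. The screen conditions the
#' random draw; it does not alter the learning rule or the dynamics.
#'
#' @param layout A [partition_layout()].
#' @param symbols Character vector of unique symbol names. May be empty.
#' @param coding_level Fraction of active units in each random pattern,
#'   strictly between 0 and 1. Default 0.5 (dense random patterns).
#' @param seed Integer seed; the same seed always yields the same
#'   vocabulary.
#' @param ensure_stable Reject draws that break piece stability (see
#'   above). `FALSE` gives unconditioned random patterns.
#' @param max_retries Maximum redraws per pattern before giving up.
#' @return An object of class `dpaan_vocab`: list with `layout`, `symbols`,
#'   `patterns` (an L x N matrix of +1/-1 values, rows named by symbol),
#'   `coding_level`, `stable` (was the stability screen applied?) and
#'   `seed`.
#' @examples
#' lay <- partition_layout(rep(100, 5))
#' voc <- build_vocabulary(lay, c("red", "blue", "square", "circle"), seed = 1)
#' dim(voc$patterns)
#' @export
build_vocabulary <- function(layout, symbols, coding_level = 0.5, seed = 1L,
                             ensure_stable = TRUE, max_retries = 200L) {
  stopifnot(inherits(layout, "dpaan_layout"))
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stopf("symbol names must be unique")
  if (!is.numeric(coding_level) || coding_level <= 0 || coding_level >= 1) {
    stopf("coding_level must lie strictly between 0 and 1")
  }
  L <- length(symbols)
  patterns <- with_seed(seed, {
    # Sequential rejection sampling with restart: draws are accepted one
    # by one; if some pattern exhausts its retry budget (the fixed prefix
    # can make a later draw arbitrarily unlikely), the whole prefix is
    # discarded and generation restarts on the same random stream.
    pat <- NULL
    for (restart in seq_len(max(1L, max_retries %/% 8L))) {
      pat <- matrix(0, nrow = 0L, ncol = layout$N)
      stuck <- FALSE
      for (l in seq_len(L)) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          cand <- ifelse(stats::runif(layout$N) < coding_level, 1, -1)
          distinct <- all(vapply(layout$index, function(idx) {
            !any(apply(pat[, idx, drop = FALSE], 1L,
                       function(p) all(p == cand[idx])))
          }, logical(1)))
          if (!distinct) next
          cand_pat <- rbind(pat, cand)
          if (!ensure_stable || pieces_stable(cand_pat, layout)) {
            pat <- cand_pat
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stuck <- TRUE
          break
        }
      }
      if (!stuck) break
      pat <- NULL
    }
    if (is.null(pat)) {
      stopf(paste("could not generate %d admissible patterns (distinct,",
                  "stable pieces) on every partition; increase partition",
                  "sizes or reduce the vocabulary"), L)
    }
    pat
  })
  dimnames(patterns) <- list(symbols, NULL)
  structure(
    list(layout = layout, symbols = symbols, patterns = patterns,
         coding_level = coding_level, stable = isTRUE(ensure_stable),
         seed = as.integer(seed)),
    class = "dpaan_vocab"
  )
}

# Is every pattern piece a fixed point of its isolated partition (and
# every full pattern a fixed point of the ungated network) under the
# Hopfield rule trained on `pat`? Zero local field keeps the previous
# value, so only a sign disagreement with a nonzero field is unstable.
pieces_stable <- function(pat, layout) {
  W <- crossprod(pat) / layout$N
  diag(W) <- 0
  for (idx in layout$index) {
    F <- pat[, idx, drop = FALSE] %*% W[idx, idx]
    if (any(F * pat[, idx, drop = FALSE] < 0)) return(FALSE)
  }
  Fg <- pat %*% W
  all(Fg * pat >= 0)
}

#' @export
print.dpaan_vocab <- function(x, ...) {
  cat(sprintf("Symbol vocabulary: L = %d symbols over %d neurons (seed %d%s)\n",
              length(x$symbols), x$layout$N, x$seed,
              if (x$stable) ", stability-screened" else ""))
  if (length(x$symbols)) {
    cat("  symbols:", paste(x$symbols, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the piece of a symbol's pattern on one partition
#'
#' @param vocab A `dpaan_vocab`.
#' @param symbol Symbol name.
#' @param k Partition id.
#' @return Numeric +1/-1 vector of length `N_k`.
#' @export
vocab_piece <- function(vocab, symbol, k) {
  stopifnot(inherits(vocab, "dpaan_vocab"))
  l <- match(symbol, vocab$symbols)
  if (is.na(l)) stopf("unknown symbol '%s'", symbol)
  vocab$patterns[l, slot_index(vocab$layout, k)]
}
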