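#' Build a dynamically partitionable autoassociative network
#'
#' Constructs the full network in one call: a seeded random symbol
#' vocabulary over the given partition layout, the Hopfield outer-product
#' weight matrix trained on those patterns, and (for two or more symbols)
#' calibrated thresholds for the energy-based slot-equality neurons. The
#' result is a single trained attractor network whose between-partition
#' synapse blocks can be gated off — partitioning it into K independent
#' symbol buffers — or back on, forcing joint attractor completion
#' (slot-to-slot transfer).
#'
#' @param partition_sizes Integer vector of neuron counts per slot, e.g.
#'   `rep(100, 5)`.
#' @param symbols Character vector of symbol names; one global attractor
#'   pattern is created per symbol.
#' @param coding_level Fraction of active units per random pattern
#'   (default 0.5).
#' @param seed Integer run seed; identical arguments and seed give an
#'   identical network.
#' @return Object of class `dpaan`: list with `layout`, `vocab`,
#'   `weights`, `eqcfg` (equality thresholds; `NULL` when fewer than two
#'   symbols) and `seed`.
#' @examples
#' net <- dpaan(rep(100, 5), c("red", "blue", "square", "circle"), seed = 1)
#' net
#' st <- new_state(net)
#' st <- set_slot(st, 1, "red", net)
#' st <- set_slot(st, 3, "red", net)
#' equality_readout(net, st)
#' @export
dpaan <- function(partition_sizes, symbols, coding_level = 0.5, seed = 1L) {
  layout <- partition_layout(partition_sizes)
  vocab <- build_vocabulary(layout, symbols, coding_level = coding_level,
                            seed = seed)
  weights <- hopfield_train(vocab)
  eqcfg <- if (length(symbols) >= 2L) calibrate_equality(vocab, weights)
  structure(
    list(layout = layout, vocab = vocab, weights = weights, eqcfg = eqcfg,
         seed = as.integer(seed)),
    class = "dpaan"
  )
}

#' @export
print.dpaan <- function(x, ...) {
  cat("Dynamically partitionable autoassociative network\n")
  cat(sprintf("  %d slots (%s), N = %d neurons, L = %d symbols, seed %d\n",
              x$layout$K, paste(x$layout$sizes, collapse = "+"),
              x$layout$N, length(x$vocab$symbols), x$seed))
  invisible(x)
}

#' @export
summary.dpaan <- function(object, ...) {
  stable <- count_stable_patterns(object)
  out <- list(
    K = object$layout$K, N = object$layout$N,
    sizes = object$layout$sizes,
    L = length(object$vocab$symbols),
    symbols = object$vocab$symbols,
    coding_level = object$vocab$coding_level,
    stable_patterns = stable,
    eq_margin = if (!is.null(object$eqcfg)) min(object$eqcfg$margin)
  )
  class(out) <- "summary.dpaan"
  out
}

#' @export
print.summary.dpaan <- function(x, ...) {
  cat("Dynamically partitionable autoassociative network\n")
  cat(sprintf("  slots:         K = %d (%s)\n", x$K,
              paste(x$sizes, collapse = ", ")))
  cat(sprintf("  neurons:       N = %d\n", x$N))
  cat(sprintf("  vocabulary:    L = %d (%s)\n", x$L,
              paste(x$symbols, collapse = ", ")))
  cat(sprintf("  coding level:  %.2f\n", x$coding_level))
  cat(sprintf("  stable attractors: %d of %d vocabulary patterns\n",
              x$stable_patterns, x$L))
  if (!is.null(x$eq_margin)) {
    cat(sprintf("  equality margin:   %.3f (worst slot pair)\n", x$eq_margin))
  }
  invisible(x)
}

#' @export
coef.dpaan <- function(object, ...) object$weights$W

#' Decode the slot contents of a state
#'
#' `predict` maps a network state to its symbolic interpretation: the
#' decoded symbol of every slot.
#'
#' @param object A `dpaan` network.
#' @param state A `dpaan_state` (defaults to an all-blank state).
#' @param min_overlap Decode acceptance threshold, see [decode_slot()].
#' @param ... Unused.
#' @return Named character vector of decoded symbols (`NA` = no decode).
#' @export
predict.dpaan <- function(object, state = new_state(object),
                          min_overlap = 0.8, ...) {
  decode_slots(state, object$vocab, min_overlap = min_overlap)
}

#' Simulate settles from random initial states
#'
#' Draws random bipolar initial states, runs the ungated dynamics to
#' convergence, and reports the decoded slot contents of each final state
#' — a quick check of what the trained attractor landscape does with
#' arbitrary input.
#'
#' @param object A `dpaan` network.
#' @param nsim Number of simulated settles.
#' @param seed Integer seed.
#' @param max_steps Settle budget per simulation.
#' @param ... Unused.
#' @return Data frame with one row per simulation: `converged`, `steps`,
#'   and one decoded-symbol column per slot.
#' @export
simulate.dpaan <- function(object, nsim = 1, seed = 1L, max_steps = 50L, ...) {
  rows <- with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      st <- new_state(object)
      st$x <- sample(c(-1, 1), object$layout$N, replace = TRUE)
      tr <- settle(object, st, gates = NULL, max_steps = max_steps)
      dec <- decode_slots(tr$state, object$vocab)
      c(list(sim = i, converged = tr$converged, steps = tr$steps),
        as.list(dec))
    })
  })
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Plot an activity raster
#'
#' Draws the timestep-by-neuron activity trace of a trajectory or run in
#' the white-active / black-inactive convention (blank units grey), with
#' slot boundaries marked.
#'
#' @param x A `dpaan` network.
#' @param trace A trajectory matrix (rows = timesteps, columns = neurons),
#'   e.g. `settle(..., trace = TRUE)$trace` or a run's `raster`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.dpaan <- function(x, trace, ...) {
  if (inherits(trace, "dpaan_trajectory")) trace <- trace$trace
  if (is.null(trace)) stopf("no trace to plot; call settle(trace = TRUE)")
  graphics::image(
    x = seq_len(nrow(trace)), y = seq_len(ncol(trace)),
    z = trace, zlim = c(-1, 1),
    col = c("black", "grey50", "white"),
    xlab = "timestep", ylab = "neuron", useRaster = TRUE, ...
  )
  for (k in utils::head(cumsum(x$layout$sizes), -1L)) {
    graphics::abline(h = k + 0.5, col = "red", lty = 2)
  }
  invisible(x)
}

#' Count the vocabulary patterns that are stable attractors
#'
#' Sets every slot to the same symbol's piece (the full global pattern),
#' runs one settle of the given dynamics, and counts the patterns that
#' come back unchanged — i.e. are fixed points.
#'
#' @param net A `dpaan` network.
#' @param gates Gate configuration; `NULL` (default) = all synapses on.
#' @return Integer count in `0:L`.
#' @export
count_stable_patterns <- function(net, gates = NULL) {
  sum(vapply(net$vocab$symbols, function(sym) {
    st <- new_state(net)
    for (k in seq_len(net$layout$K)) st <- set_slot(st, k, sym, net)
    tr <- settle(net, st, gates = gates, max_steps = 1L)
    tr$converged
  }, logical(1)))
}
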