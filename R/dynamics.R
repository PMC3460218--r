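#' Run the gated attractor dynamics
#'
#' Unclamped units are updated by thresholding their gated weighted input:
#' a unit becomes +1 for positive net input, -1 for negative, and keeps
#' its previous value (so blank stays blank) at exactly zero. Synchronous
#' mode updates all unclamped units at once per step; asynchronous mode
#' updates one unit at a time in a seeded random order (one "step" is a
#' full sweep over the unclamped units), which with any symmetric gate
#' configuration makes the gated energy non-increasing at every single
#' update.
#'
#' @param net A `dpaan` network (or `dpaan_weights`).
#' @param state Initial `dpaan_state`.
#' @param gates A `dpaan_gates` matrix, or `NULL` for all synapses on.
#' @param mode `"synchronous"` (default) or `"asynchronous"`.
#' @param max_steps Maximum number of steps (sweeps); the dynamics stop
#'   early at a fixed point.
#' @param seed Seed for the asynchronous update order.
#' @param trace Record the visited states? For synchronous mode one row
#'   per step; for asynchronous mode one row per single-unit update.
#' @return Object of class `dpaan_trajectory`: list with `state` (final
#'   `dpaan_state`), `converged`, `steps` (steps actually run) and, when
#'   `trace = TRUE`, `trace` (matrix of activation vectors, first row the
#'   initial state).
#' @export
settle <- function(net, state, gates = NULL,
                   mode = c("synchronous", "asynchronous"),
                   max_steps = 40L, seed = 1L, trace = FALSE) {
  mode <- match.arg(mode)
  if (max_steps < 1L) stopf("max_steps must be at least 1")
  W <- weight_matrix(net)
  Wg <- gated_weights(W, state$layout, gates)
  x <- state$x
  free <- which(!state$clamped)
  rows <- if (trace) list(x) else NULL
  converged <- FALSE
  steps <- 0L
  if (mode == "synchronous") {
    for (s in seq_len(max_steps)) {
      h <- as.numeric(Wg %*% x)
      xn <- x
      xn[free] <- ifelse(h[free] > 0, 1, ifelse(h[free] < 0, -1, x[free]))
      steps <- s
      if (trace) rows[[length(rows) + 1L]] <- xn
      if (identical(xn, x)) {
        converged <- TRUE
        x <- xn
        break
      }
      x <- xn
    }
  } else {
    with_seed(seed, {
      for (s in seq_len(max_steps)) {
        changed <- FALSE
        for (i in sample(free)) {
          h <- sum(Wg[i, ] * x)
          xi <- if (h > 0) 1 else if (h < 0) -1 else x[i]
          if (xi != x[i]) changed <- TRUE
          x[i] <- xi
          if (trace) rows[[length(rows) + 1L]] <- x
        }
        steps <- s
        if (!changed) {
          converged <- TRUE
          break
        }
      }
    })
  }
  state$x <- x
  out <- list(state = state, converged = converged, steps = steps)
  if (trace) out$trace <- do.call(rbind, rows)
  structure(out, class = "dpaan_trajectory")
}

#' @export
print.dpaan_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d step(s), %s\n", x$steps,
              if (x$converged) "converged to a fixed point"
              else "did not converge"))
  invisible(x)
}

#' Transfer the semantic contents of one slot to another
#'
#' Implements slot-to-slot symbol assignment: the target slot is blanked,
#' the source slot is clamped, and the directed synapse block from source
#' to target is gated on (together with the target's within-partition
#' synapses). Attractor completion then drives the target into the piece
#' of the same global pattern the source is in. Afterwards the
#' between-slot block is off again while the target's within-slot gate
#' stays on, holding the transferred piece. The caller's `gates` matrix is
#' never modified.
#'
#' @param net A `dpaan` network (or `dpaan_weights`).
#' @param state A `dpaan_state` whose source slot decodes to some symbol.
#' @param gates Gate configuration for the slots not involved in the
#'   transfer; `NULL` means all within-partition gates on, cross gates
#'   off.
#' @param from,to Distinct source and target partition ids.
#' @param steps Settle-step budget (default 40 synchronous steps).
#' @param vocab Vocabulary used for the source-decode precondition check
#'   (taken from `net` when available).
#' @param trace Record the settling trajectory?
#' @return A `dpaan_trajectory` (final state has the source unclamped and
#'   the target holding the transferred piece).
#' @export
transfer <- function(net, state, gates = NULL, from, to, steps = 40L,
                     vocab = NULL, trace = FALSE) {
  if (from == to) stopf("transfer needs distinct source and target slots")
  check_slot(state$layout, from)
  check_slot(state$layout, to)
  if (is.null(vocab) && inherits(net, "dpaan")) vocab <- net$vocab
  if (all(state$x[slot_index(state$layout, from)] == 0)) {
    stopf("source slot %d is blank: nothing to transfer", from)
  }
  if (!is.null(vocab) &&
      is.na(decode_slot(state, from, vocab))) {
    stopf("source slot %d does not decode to any vocabulary symbol", from)
  }
  if (is.null(gates)) gates <- gate_matrix(state$layout$K)
  g <- gates
  g[from, to] <- TRUE
  g[to, to] <- TRUE
  was_clamped <- state$clamped
  st <- blank_slot(state, to)
  st <- clamp_slot(st, from, TRUE)
  traj <- settle(net, st, gates = g, mode = "synchronous",
                 max_steps = steps, trace = trace)
  traj$state$clamped <- was_clamped
  traj
}
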