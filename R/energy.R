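#' Hopfield energy of the whole network
#'
#' \deqn{E = -\tfrac{1}{2} \sum_i \sum_{j \ne i} w_{ij} x_i x_j}
#' Blank units (activation 0) contribute nothing. When `gates` is given
#' the sum runs over the gated weights, which is the Lyapunov function of
#' the gated dynamics whenever the gate configuration is symmetric.
#'
#' @param net A `dpaan` network (or a `dpaan_weights`).
#' @param state A `dpaan_state`.
#' @param gates Optional `dpaan_gates`; `NULL` (default) uses the full
#'   stored weights.
#' @return Scalar energy.
#' @export
energy_total <- function(net, state, gates = NULL) {
  W <- weight_matrix(net)
  if (!is.null(gates)) W <- gated_weights(W, state$layout, gates)
  # diagonal is zero by construction, so the j != i restriction is free
  -0.5 * sum(state$x * (W %*% state$x))
}

#' Cross-partition energy between two slots
#'
#' The Hopfield energy restricted to the synapses running between
#' partitions `k` and `kp` (both directions):
#' \deqn{E_{kk'} = -\sum_{i \in k} \sum_{j \in k'} w_{ij} x_i x_j
#'               - \sum_{j \in k} \sum_{i \in k'} w_{ij} x_i x_j.}
#' It is low precisely when the two slots hold pieces of the same stored
#' global pattern, which is what the equality-detection neurons threshold.
#' Always computed on the stored weights, independent of any gating.
#'
#' @param net A `dpaan` network (or `dpaan_weights`).
#' @param state A `dpaan_state`.
#' @param k,kp Distinct partition ids.
#' @return Scalar energy; 0 whenever either slot is fully blank.
#' @export
energy_cross <- function(net, state, k, kp) {
  if (k == kp) stopf("energy_cross needs two distinct partitions")
  W <- weight_matrix(net)
  i <- slot_index(state$layout, k)
  j <- slot_index(state$layout, kp)
  # weights are symmetric, so both directed sums are equal
  -2 * as.numeric(state$x[i] %*% W[i, j, drop = FALSE] %*% state$x[j])
}

# All pairwise cross energies for the vocabulary pieces of one slot pair:
# returns the L x L matrix M[l, lp] = E_kkp with slot k holding symbol l
# and slot kp holding symbol lp.
pair_energy_table <- function(W, vocab, k, kp) {
  i <- vocab$layout$index[[k]]
  j <- vocab$layout$index[[kp]]
  Pk <- vocab$patterns[, i, drop = FALSE]
  Pkp <- vocab$patterns[, j, drop = FALSE]
  -2 * Pk %*% W[i, j, drop = FALSE] %*% t(Pkp)
}

#' Calibrate the slot-equality thresholds
#'
#' For every unordered slot pair the cross energy is computed with the two
#' slots holding pieces of the same symbol (matched) and of every pair of
#' different symbols (mismatched), sweeping the whole vocabulary. The
#' equality neuron's threshold for that pair is placed in the middle of
#' the gap between the two populations (midpoint of the largest matched
#' and the smallest mismatched energy), so the readout is exact on every
#' vocabulary state whenever the populations separate. Calibration fails
#' if any pair's populations overlap.
#'
#' @param net A `dpaan` network, or a `dpaan_vocab` when `weights` is
#'   supplied.
#' @param weights Optional `dpaan_weights` (ignored when `net` is a full
#'   network).
#' @return Object of class `dpaan_eqconfig`: list with `pairs` (two-column
#'   matrix of k < kp ids), `thresholds`, `matched_mean`,
#'   `mismatched_mean`, `margin` (worst-case gap: min mismatched - max
#'   matched energy per pair).
#' @export
calibrate_equality <- function(net, weights = NULL) {
  if (inherits(net, "dpaan")) {
    vocab <- net$vocab
    W <- net$weights$W
  } else {
    vocab <- net
    W <- weight_matrix(weights)
  }
  stopifnot(inherits(vocab, "dpaan_vocab"))
  L <- length(vocab$symbols)
  if (L < 2L) stopf("equality calibration needs at least two symbols")
  K <- vocab$layout$K
  pairs <- t(utils::combn(K, 2L))
  n <- nrow(pairs)
  thr <- mm <- mmm <- marg <- numeric(n)
  for (p in seq_len(n)) {
    M <- pair_energy_table(W, vocab, pairs[p, 1], pairs[p, 2])
    matched <- diag(M)
    mismatched <- M[row(M) != col(M)]
    mm[p] <- mean(matched)
    mmm[p] <- mean(mismatched)
    thr[p] <- (max(matched) + min(mismatched)) / 2
    marg[p] <- min(mismatched) - max(matched)
  }
  if (any(marg <= 0)) {
    stopf(paste("matched and mismatched cross-energy populations are not",
                "separable; use larger partitions or fewer symbols"))
  }
  structure(
    list(pairs = pairs, thresholds = thr, matched_mean = mm,
         mismatched_mean = mmm, margin = marg, K = K),
    class = "dpaan_eqconfig"
  )
}

#' @export
print.dpaan_eqconfig <- function(x, ...) {
  cat(sprintf("Equality config: %d slot pairs, worst-case margin %.3f\n",
              nrow(x$pairs), min(x$margin)))
  invisible(x)
}

#' Read out the equality-detection neurons
#'
#' One binary unit per unordered slot pair (K(K-1)/2 in total); the unit
#' for (k, kp) fires iff the cross energy `E_kkp` of the current state
#' falls below that pair's calibrated threshold. Blank partitions have
#' zero cross energy and therefore never compare equal to anything.
#'
#' @param net A `dpaan` network (or `dpaan_weights`).
#' @param state A `dpaan_state`.
#' @param eqcfg A [calibrate_equality()] result matching the layout
#'   (defaults to the one stored in `net`).
#' @return Named integer 0/1 vector; names are `"eq_k_kp"` with k < kp.
#' @export
equality_readout <- function(net, state, eqcfg = NULL) {
  if (is.null(eqcfg) && inherits(net, "dpaan")) eqcfg <- net$eqcfg
  if (is.null(eqcfg)) stopf("no equality configuration available")
  if (eqcfg$K != state$layout$K) {
    stopf("equality config was calibrated for K = %d, state has K = %d",
          eqcfg$K, state$layout$K)
  }
  e <- vapply(seq_len(nrow(eqcfg$pairs)), function(p) {
    energy_cross(net, state, eqcfg$pairs[p, 1], eqcfg$pairs[p, 2])
  }, numeric(1))
  out <- as.integer(e < eqcfg$thresholds)
  names(out) <- paste0("eq_", eqcfg$pairs[, 1], "_", eqcfg$pairs[, 2])
  out
}

# Look up an equality bit by (k, kp) in either order.
eq_bit <- function(eq, k, kp) {
  nm <- paste0("eq_", min(k, kp), "_", max(k, kp))
  if (!nm %in% names(eq)) stopf("no equality neuron for pair (%d, %d)", k, kp)
  unname(eq[[nm]])
}
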