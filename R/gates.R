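#' Create a block-gate matrix
#'
#' The network is "dynamically partitionable": whole blocks of synapses
#' between partitions can be switched off (set to contribute zero) and
#' back on without touching the stored weight values. The gate matrix is a
#' K x K logical matrix whose entry `[k, kp]` is the state of the transfer
#' control signal for synapses projecting *from* partition `k` (presynaptic)
#' *to* partition `kp` (postsynaptic); the diagonal holds the
#' within-partition gates.
#'
#' @param K Number of partitions (or a `dpaan_layout` / `dpaan` object).
#' @param within State of the within-partition (diagonal) gates.
#'   Default `TRUE`: during normal operation each slot keeps its own
#'   recurrent synapses on, so it holds its content.
#' @param cross State of all between-partition gates. Default `FALSE`
#'   (fully partitioned into independent buffers).
#' @return K x K logical matrix of class `dpaan_gates`.
#' @examples
#' g <- gate_matrix(5)                  # isolated slots
#' g <- open_gate(g, from = 1, to = 5)  # enable transfer block 1 -> 5
#' @export
gate_matrix <- function(K, within = TRUE, cross = FALSE) {
  if (inherits(K, "dpaan")) K <- K$layout$K
  if (inherits(K, "dpaan_layout")) K <- K$K
  K <- as.integer(K)
  g <- matrix(cross, K, K)
  diag(g) <- within
  class(g) <- c("dpaan_gates", class(g))
  g
}

#' Open or close a directed gate block
#'
#' @param gates A `dpaan_gates` matrix.
#' @param from Presynaptic partition id.
#' @param to Postsynaptic partition id.
#' @return The modified gate matrix.
#' @export
open_gate <- function(gates, from, to) {
  gates[from, to] <- TRUE
  gates
}

#' @rdname open_gate
#' @export
close_gate <- function(gates, from, to) {
  gates[from, to] <- FALSE
  gates
}

# Expand the K x K block gates to an N x N logical mask and apply it to the
# stored weights. W[i, j] gates the synapse from presynaptic j to
# postsynaptic i, so block (from = k, to = kp) covers rows kp, columns k.
gated_weights <- function(W, layout, gates) {
  if (is.null(gates)) return(W)
  stopifnot(nrow(gates) == layout$K, ncol(gates) == layout$K)
  Wg <- W
  for (k in seq_len(layout$K)) {
    for (kp in seq_len(layout$K)) {
      if (!gates[k, kp]) {
        Wg[layout$index[[kp]], layout$index[[k]]] <- 0
      }
    }
  }
  Wg
}
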