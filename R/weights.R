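#' Train the autoassociative weight matrix
#'
#' Builds the synaptic weight matrix by the Hopfield outer-product rule,
#' \deqn{w_{ij} = \frac{1}{N} \sum_l \xi_i^l \xi_j^l, \quad w_{ii} = 0,}
#' where the \eqn{\xi^l} are the bipolar vocabulary patterns. Every
#' vocabulary pattern then becomes a stable attractor of the ungated
#' network provided the load stays well below the classical Hopfield
#' capacity (~0.14 N for random patterns); a warning is issued when the
#' vocabulary exceeds a tenth of the smallest partition size, since
#' isolated partitions must also retain every piece as a fixed point.
#'
#' @param vocab A [build_vocabulary()] result with at least one symbol.
#' @return Object of class `dpaan_weights`: list with `W` (N x N symmetric
#'   zero-diagonal matrix; entry `[i, j]` is the weight to postsynaptic
#'   unit i from presynaptic unit j), `rule`, and `L`.
#' @export
hopfield_train <- function(vocab) {
  stopifnot(inherits(vocab, "dpaan_vocab"))
  L <- length(vocab$symbols)
  if (L < 1L) stopf("cannot train on an empty vocabulary")
  if (!isTRUE(vocab$stable) && L > 0.1 * min(vocab$layout$sizes)) {
    warning(sprintf(
      "vocabulary of %d symbols is large for the smallest partition (%d neurons); attractor retention may degrade",
      L, min(vocab$layout$sizes)), call. = FALSE)
  }
  W <- crossprod(vocab$patterns) / vocab$layout$N
  diag(W) <- 0
  structure(list(W = W, rule = "hopfield", L = L), class = "dpaan_weights")
}

#' @export
print.dpaan_weights <- function(x, ...) {
  cat(sprintf("Trained weights: %d x %d (%s rule, L = %d patterns)\n",
              nrow(x$W), ncol(x$W), x$rule, x$L))
  invisible(x)
}

# Accept either a dpaan network or a dpaan_weights and return the matrix.
weight_matrix <- function(x) {
  if (inherits(x, "dpaan")) return(x$weights$W)
  if (inherits(x, "dpaan_weights")) return(x$W)
  if (is.matrix(x)) return(x)
  stopf("cannot extract a weight matrix from class '%s'", class(x)[1])
}
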