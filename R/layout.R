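#' Define a partition layout
#'
#' A partitioned autoassociative network divides its `N` neurons into `K`
#' contiguous partitions ("slots"), each acting as one symbol buffer. The
#' layout records the per-partition neuron counts and the index ranges of
#' each partition within the concatenated activation vector.
#'
#' @param sizes Integer vector of neuron counts, one per partition. All
#'   entries must be positive.
#' @return An object of class `dpaan_layout` with elements `sizes`, `K`
#'   (number of partitions), `N` (total neuron count) and `index` (a list
#'   of integer index vectors, one per partition).
#' @examples
#' lay <- partition_layout(c(100, 100, 100, 100, 100))
#' lay$K
#' lay$N
#' @export
partition_layout <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L) stopf("a layout needs at least one partition")
  if (anyNA(sizes) || any(sizes < 1L)) {
    stopf("all partition sizes must be positive integers")
  }
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  index <- Map(seq.int, starts, ends)
  structure(
    list(sizes = sizes, K = length(sizes), N = sum(sizes), index = index),
    class = "dpaan_layout"
  )
}

#' @export
print.dpaan_layout <- function(x, ...) {
  cat(sprintf("Partition layout: K = %d slots, N = %d neurons\n", x$K, x$N))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Integer indices of a partition in the concatenated activation vector
#'
#' @param layout A `dpaan_layout` (or a `dpaan` object).
#' @param k Partition id.
#' @return Integer vector of neuron indices.
#' @export
slot_index <- function(layout, k) {
  if (inherits(layout, "dpaan")) layout <- layout$layout
  check_slot(layout, k)
  layout$index[[k]]
}

check_slot <- function(layout, k) {
  if (length(k) != 1L || is.na(k) || k < 1L || k > layout$K) {
    stopf("invalid partition id %s (layout has K = %d)",
          paste(k, collapse = ","), layout$K)
  }
  invisible(as.integer(k))
}
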