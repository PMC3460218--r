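#' Create a network state
#'
#' Activations take three values: +1 (active), -1 (inactive), and 0
#' (blank). Blank is distinct from inactive: a blank unit contributes zero
#' drive to every postsynaptic sum and zero to every energy term, so a
#' fully blank partition is invisible to the rest of the network. A
#' clamped unit is never updated by the dynamics.
#'
#' @param layout A [partition_layout()] (or a `dpaan` object).
#' @return Object of class `dpaan_state`: list with `x` (length-N numeric
#'   in {-1, 0, 1}), `clamped` (length-N logical) and `layout`.
#' @export
new_state <- function(layout) {
  if (inherits(layout, "dpaan")) layout <- layout$layout
  stopifnot(inherits(layout, "dpaan_layout"))
  structure(
    list(x = numeric(layout$N), clamped = logical(layout$N), layout = layout),
    class = "dpaan_state"
  )
}

#' @export
print.dpaan_state <- function(x, ...) {
  nb <- sum(x$x == 0)
  cat(sprintf("Network state: %d neurons (%d blank, %d clamped) over %d slots\n",
              x$layout$N, nb, sum(x$clamped), x$layout$K))
  invisible(x)
}

#' Write a symbol's piece into a slot
#'
#' Sets partition `k` to the restriction of `symbol`'s global pattern,
#' leaving every other partition untouched. This is the `Set` control
#' operation a production uses to overwrite a slot.
#'
#' @param state A `dpaan_state`.
#' @param k Partition id.
#' @param symbol Symbol name present in `vocab`.
#' @param vocab The network vocabulary (or a `dpaan` object).
#' @return The modified state.
#' @export
set_slot <- function(state, k, symbol, vocab) {
  if (inherits(vocab, "dpaan")) vocab <- vocab$vocab
  piece <- vocab_piece(vocab, symbol, k)
  state$x[slot_index(state$layout, k)] <- piece
  state
}

#' Blank a slot
#'
#' Sets every unit of partition `k` to the blank value 0. A blank slot
#' contributes no drive and decodes to no symbol.
#'
#' @param state A `dpaan_state`.
#' @param k Partition id.
#' @return The modified state.
#' @export
blank_slot <- function(state, k) {
  state$x[slot_index(state$layout, k)] <- 0
  state
}

#' Clamp or release a slot
#'
#' Clamped units keep their current activation throughout the dynamics;
#' a transfer clamps its source slot so completion runs one way.
#'
#' @param state A `dpaan_state`.
#' @param k Partition id.
#' @param clamped Logical.
#' @return The modified state.
#' @export
clamp_slot <- function(state, k, clamped = TRUE) {
  state$clamped[slot_index(state$layout, k)] <- clamped
  state
}

# Normalized overlap of a slot's activation with one symbol piece;
# in [-1, 1] for bipolar states, 0 against blanks.
slot_overlap <- function(state, k, piece) {
  idx <- slot_index(state$layout, k)
  sum(state$x[idx] * piece) / length(idx)
}

#' Decode the symbol held in a slot
#'
#' Returns the vocabulary symbol whose piece on partition `k` has the
#' highest normalized overlap with the slot's activation, provided that
#' overlap reaches `min_overlap`; otherwise `NA`. Ties break by vocabulary
#' order. This is a readout/logging device: the network itself never uses
#' it.
#'
#' @param state A `dpaan_state`.
#' @param k Partition id.
#' @param vocab The vocabulary (or a `dpaan` object).
#' @param min_overlap Minimum normalized overlap in (0, 1] to accept a
#'   decode. Default 0.8.
#' @return Symbol name, or `NA_character_` for no decode (e.g. a blank
#'   slot).
#' @export
decode_slot <- function(state, k, vocab, min_overlap = 0.8) {
  if (inherits(vocab, "dpaan")) vocab <- vocab$vocab
  if (min_overlap <= 0 || min_overlap > 1) {
    stopf("min_overlap must lie in (0, 1]")
  }
  if (length(vocab$symbols) == 0L) return(NA_character_)
  idx <- slot_index(state$layout, k)
  ov <- as.numeric(vocab$patterns[, idx, drop = FALSE] %*% state$x[idx]) /
    length(idx)
  best <- which.max(ov)  # first maximum: vocabulary-order tie-break
  if (ov[best] >= min_overlap) vocab$symbols[best] else NA_character_
}

#' Decode every slot
#'
#' @inheritParams decode_slot
#' @return Named character vector, one entry per partition (`NA` where no
#'   symbol reaches `min_overlap`).
#' @export
decode_slots <- function(state, vocab, min_overlap = 0.8) {
  if (inherits(vocab, "dpaan")) vocab <- vocab$vocab
  out <- vapply(seq_len(state$layout$K),
                function(k) decode_slot(state, k, vocab, min_overlap),
                character(1))
  names(out) <- paste0("X", seq_len(state$layout$K))
  out
}
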