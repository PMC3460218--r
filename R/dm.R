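#' Declarative-memory chunks
#'
#' A chunk is an association of one symbol per declarative-memory (DM)
#' slot, e.g. the count-order fact "4 comes after 3" as
#' `dm_chunk(IsA = "count-order", first = "three", second = "four")`.
#'
#' @param ... Named symbol assignments, one per DM slot.
#' @return Named character vector of class `dpaan_chunk`.
#' @export
dm_chunk <- function(...) {
  vals <- c(...)
  if (is.null(names(vals)) || any(names(vals) == "")) {
    stopf("every chunk entry must be named by its DM slot")
  }
  structure(as.character(vals), names = names(vals), class = "dpaan_chunk")
}

#' Build a declarative-memory store
#'
#' Stores each chunk as the concatenation of its symbols' pattern pieces
#' over the designated DM partitions — the memory vectors a retrieval is
#' matched against. Matching the reference simulations, the store is a
#' look-up table of these vectors rather than a second trained synaptic
#' matrix. Duplicate chunks are both kept; retrieval ties break by storage
#' order.
#'
#' @param net A `dpaan` network.
#' @param chunks Non-empty list of [dm_chunk()]s (or named character
#'   vectors), all covering the same DM slot names.
#' @param dm_slots Integer partition ids of the DM slots, in the order of
#'   the chunk entries.
#' @return Object of class `dpaan_dm`: list with `dm_slots`, `slot_names`,
#'   `chunks` (matrix of symbol names, one row per chunk) and `vectors`
#'   (list of per-slot piece matrices).
#' @export
dm_store <- function(net, chunks, dm_slots) {
  stopifnot(inherits(net, "dpaan"))
  if (length(chunks) < 1L) stopf("dm_store needs at least one chunk")
  dm_slots <- vapply(dm_slots, check_slot, integer(1), layout = net$layout)
  slot_names <- names(chunks[[1L]])
  if (length(slot_names) != length(dm_slots)) {
    stopf("chunks have %d slots but %d DM partitions were given",
          length(slot_names), length(dm_slots))
  }
  sym <- do.call(rbind, lapply(chunks, function(ch) {
    if (!identical(sort(names(ch)), sort(slot_names))) {
      stopf("all chunks must cover the same DM slot names")
    }
    unlist(ch)[slot_names]
  }))
  colnames(sym) <- slot_names
  bad <- setdiff(unique(as.vector(sym)), net$vocab$symbols)
  if (length(bad)) stopf("chunk symbols not in vocabulary: %s",
                         paste(bad, collapse = ", "))
  vectors <- lapply(seq_along(dm_slots), function(s) {
    t(vapply(sym[, s], function(symname) {
      vocab_piece(net$vocab, symname, dm_slots[s])
    }, numeric(net$layout$sizes[dm_slots[s]])))
  })
  structure(list(dm_slots = dm_slots, slot_names = slot_names,
                 chunks = sym, vectors = vectors),
            class = "dpaan_dm")
}

#' @export
print.dpaan_dm <- function(x, ...) {
  cat(sprintf("Declarative memory: %d chunk(s) over DM slots %s (%s)\n",
              nrow(x$chunks), paste(x$dm_slots, collapse = ", "),
              paste(x$slot_names, collapse = "/")))
  invisible(x)
}

#' Retrieve the closest declarative memory
#'
#' Completes the blanked DM slots from the non-blank ones: the stored
#' chunk with the highest mean per-slot normalized overlap against the
#' non-blank DM slots wins (ties by storage order), and its pieces
#' overwrite exactly the blank DM slots. Non-blank DM slots and all
#' non-DM partitions are left untouched.
#'
#' @param net A `dpaan` network.
#' @param state A `dpaan_state` with at least one non-blank DM slot.
#' @param store A [dm_store()].
#' @return List with `state` (completed), `chunk` (index of the recalled
#'   chunk) and `similarity` (its mean cue overlap).
#' @export
dm_retrieve <- function(net, state, store) {
  stopifnot(inherits(store, "dpaan_dm"))
  if (nrow(store$chunks) == 0L) stopf("declarative store is empty")
  blank <- vapply(store$dm_slots, function(k) {
    all(state$x[slot_index(state$layout, k)] == 0)
  }, logical(1))
  if (all(blank)) stopf("all DM slots are blank: no retrieval cue")
  cue <- which(!blank)
  simmat <- vapply(cue, function(s) {
    k <- store$dm_slots[s]
    idx <- slot_index(state$layout, k)
    as.numeric(store$vectors[[s]] %*% state$x[idx]) / length(idx)
  }, numeric(nrow(store$chunks)))
  sims <- rowMeans(matrix(simmat, nrow = nrow(store$chunks)))
  best <- which.max(sims)  # first maximum: storage-order tie-break
  for (s in which(blank)) {
    state$x[slot_index(state$layout, store$dm_slots[s])] <-
      store$vectors[[s]][best, ]
  }
  list(state = state, chunk = unname(best), similarity = unname(sims[best]))
}
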