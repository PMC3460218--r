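# Shared fixtures and independent brute-force oracles.

# Small trained network with single-letter symbol names.
tiny_net <- function(sizes, L, seed = 1, coding_level = 0.5, ...) {
  dpaan(sizes, letters[seq_len(L)], coding_level = coding_level,
        seed = seed, ...)
}

# A vocabulary object with prescribed patterns (rows = symbols), bypassing
# random generation; used to pin down closed-form cases.
manual_vocab <- function(sizes, patterns, symbols = letters[seq_len(nrow(patterns))]) {
  layout <- partition_layout(sizes)
  stopifnot(ncol(patterns) == layout$N)
  dimnames(patterns) <- list(symbols, NULL)
  structure(
    list(layout = layout, symbols = symbols, patterns = patterns,
         coding_level = 0.5, stable = FALSE, seed = NA_integer_),
    class = "dpaan_vocab"
  )
}

# Naive double-loop Hopfield outer-product training.
hopfield_oracle <- function(patterns) {
  N <- ncol(patterns)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      W[i, j] <- sum(patterns[, i] * patterns[, j]) / N
    }
  }
  W
}

# Naive double-loop total energy.
energy_oracle <- function(W, x) {
  N <- length(x)
  e <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) e <- e - 0.5 * W[i, j] * x[i] * x[j]
    }
  }
  e
}

# Naive double-loop cross-partition energy (both directed blocks).
energy_cross_oracle <- function(W, x, idx_k, idx_kp) {
  e <- 0
  for (i in idx_k) for (j in idx_kp) e <- e - W[i, j] * x[i] * x[j]
  for (j in idx_k) for (i in idx_kp) e <- e - W[i, j] * x[i] * x[j]
  e
}

# State with chosen symbols written into slots 1..length(syms); NA = blank.
state_with <- function(net, syms) {
  st <- new_state(net)
  for (k in seq_along(syms)) {
    if (!is.na(syms[k])) st <- set_slot(st, k, syms[k], net)
  }
  st
}
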