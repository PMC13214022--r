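# Brute-force oracles, independent of the package's implementation.

# Run one success/failure pattern through the ligation chemistry: digit k can
# ligate only when its parity matches the exposed acceptor parity (odd at the
# start, flipped by every success) and the pattern says the ligation worked.
oracle_run_pattern <- function(pattern) {
  last <- 0L
  set <- integer(0)
  for (k in seq_along(pattern)) {
    eligible <- (last + 1L) %% 2L == k %% 2L
    if (eligible && pattern[k]) {
      set <- c(set, k)
      last <- k
    }
  }
  set
}

# All digit sets producible over 2^N success/failure patterns.
oracle_reachable_sets <- function(N) {
  pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  sets <- unique(apply(pats, 1L, function(p) {
    paste(oracle_run_pattern(p), collapse = ",")
  }))
  sort(sets)
}

# Digit-set probabilities by enumerating all 2^N Bernoulli patterns.
oracle_digit_set_probs <- function(p) {
  N <- length(p)
  pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  keys <- apply(pats, 1L, function(pat) {
    paste(oracle_run_pattern(pat), collapse = ",")
  })
  probs <- apply(pats, 1L, function(pat) prod(ifelse(pat, p, 1 - p)))
  tapply(probs, keys, sum)
}

set_keys <- function(sets) {
  sort(vapply(sets, function(s) paste(s, collapse = ","), character(1)))
}

# Small shared fixtures (built once per test run).
tiny_dict <- build_dictionary(base = 2, digits = 4, seed = 42)
tiny_ref <- make_toy_reference(n_transcripts = 6, seed = 43)

# A 2-region map with a convenience assignment/plan for round-trip tests.
two_region_map <- function(nrow = 10, ncol = 20) {
  make_grid_regions(c(nrow, ncol), pitch = nrow)
}
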