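# Shared fixture builders; all randomness is locally seeded.

random_efficiency_matrix <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), nrow = n, ncol = m)
}

# brute-force longest aligned run of equal characters between two 01-strings
brute_match_length <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  agree <- av == bv
  best <- run <- 0L
  for (i in seq_along(agree)) {
    run <- if (agree[i]) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

random_bitstring <- function(n = 1) {
  vapply(seq_len(n), function(i) paste(sample(0:1, 16, replace = TRUE),
                                       collapse = ""), character(1))
}

small_gaussian_config <- function(...) {
  args <- utils::modifyList(
    list(model = "gaussian", N = 500L, mu = 1e-4, generations = 200L,
         seed = 1L, K = 0.1, cmax = 4.4e10, m = 3L, v = 7, delta = 0.016,
         thin = 50L),
    list(...))
  do.call(wf_config, args)
}

small_bitstring_config <- function(...) {
  args <- utils::modifyList(
    list(model = "bitstring", N = 500L, mu = 1e-4, generations = 200L,
         seed = 1L, K = 1, cmax = 1e12, m = 4L, npep = 2L, v = 7,
         thin = 50L),
    list(...))
  do.call(wf_config, args)
}
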