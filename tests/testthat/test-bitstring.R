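test_that("bit-string codes round-trip through the text form", {
  expect_equal(bitstring_to_code("1000000000000000"), 1L)
  expect_equal(code_to_bitstring(3L), "1100000000000000")
  set.seed(8)
  s <- random_bitstring(50)
  expect_equal(code_to_bitstring(bitstring_to_code(s)), s)
  expect_error(bitstring_to_code("0101"), "16-character")
  expect_error(code_to_bitstring(65536L), "\\[0, 65535\\]")
})

test_that("max match length is the longest aligned run of agreeing bits", {
  s <- "1010110011100011"
  expect_equal(max_match_length(s, s), 16L)
  comp <- chartr("01", "10", s)
  expect_equal(max_match_length(s, comp), 0L)
  expect_equal(max_match_length("1111000011110000", "1111111111110000"), 8L)
  set.seed(21)
  for (i in 1:500) {
    a <- random_bitstring(); b <- random_bitstring()
    expect_identical(max_match_length(a, b), brute_match_length(a, b))
  }
})

test_that("detection probability hits its logistic anchors", {
  for (v in c(5, 7, 9)) {
    expect_equal(detection_probability(v, v), 0.5)
    expect_equal(detection_probability(v - 1, v), 0.1)
    expect_equal(detection_probability(v + 1, v), 0.9)
  }
  L <- 0:16
  expect_true(all(diff(detection_probability(L, 7)) > 0))
  expect_error(detection_probability(7, 7, a = -1), "positive")
})

test_that("pathogen efficiency is one minus the product of per-peptide misses", {
  mhc <- "1111000011110000"
  pep <- random_bitstring(1)
  expect_equal(pathogen_efficiency(mhc, pep, v = 7),
               detection_probability(max_match_length(mhc, pep), 7))
  # two peptides with D = 0.5 each
  p50 <- "1111111000000000" # L = 7 vs mhc below
  mhc2 <- "1111111111111111"
  expect_equal(max_match_length(mhc2, p50), 7L)
  expect_equal(pathogen_efficiency(mhc2, c(p50, p50), v = 7), 0.75)
  expect_error(pathogen_efficiency(mhc, character(0), v = 7), "at least one")
  # independent oracle on random sets, and invariance to peptide order
  set.seed(33)
  for (i in 1:50) {
    peps <- random_bitstring(4)
    d <- sapply(peps, function(p) {
      plogis(log(9) * (brute_match_length(mhc, p) - 7))
    })
    expect_equal(pathogen_efficiency(mhc, peps, v = 7), 1 - prod(1 - d))
    expect_equal(pathogen_efficiency(mhc, sample(peps), v = 7),
                 pathogen_efficiency(mhc, peps, v = 7))
  }
})

test_that("pathogen efficiency never reaches exactly 0 or 1", {
  e_lo <- pathogen_efficiency("1111111111111111",
                              rep("0000000000000000", 3), v = 7)
  e_hi <- pathogen_efficiency("1111111111111111", "1111111111111111", v = 7)
  expect_gt(e_lo, 0)
  expect_lt(e_hi, 1)
})

test_that("bit-flip mutation flips exactly one uniformly chosen bit", {
  set.seed(14)
  mhc <- random_bitstring()
  code <- bitstring_to_code(mhc)
  hamming <- function(a, b) sum(bitwAnd(bitwShiftR(bitwXor(a, b), 0:15), 1L))
  n_draw <- 160000
  muts <- vapply(seq_len(n_draw), function(i) mutate_bitstring(code),
                 integer(1))
  expect_true(all(vapply(muts, hamming, integer(1), b = code) == 1L))
  flips <- tabulate(as.integer(log2(bitwXor(muts, code))) + 1L, nbins = 16)
  expect_true(all(abs(flips / n_draw - 1 / 16) < 0.01))
  # involution: re-flipping the same bit restores the original
  mut <- bitwXor(code, 32L)
  expect_identical(bitwXor(mut, 32L), code)
  # string representation preserved
  expect_type(mutate_bitstring(mhc), "character")
})

test_that("random pathogen sets have the right shape and uniform bits", {
  set.seed(6)
  pats <- random_pathogens(5, 3, v = 7)
  expect_equal(dim(pats$peptides), c(5, 3))
  set.seed(6)
  pats2 <- random_pathogens(5, 3, v = 7)
  expect_identical(pats, pats2)
  set.seed(99)
  big <- random_pathogens(100, 10, v = 7)
  bits <- sapply(0:15, function(b)
    mean(bitwAnd(bitwShiftR(as.integer(big$peptides), b), 1L)))
  expect_true(all(abs(bits - 0.5) < 3 * sqrt(0.25 / 1000)))
})

test_that("pathogen sets round-trip through the TSV format", {
  set.seed(2)
  pats <- random_pathogens(4, 2, v = 7)
  path <- tempfile(fileext = ".tsv")
  write_pathogens(pats, path)
  back <- read_pathogens(path, v = 7)
  expect_identical(back$peptides, pats$peptides)
  unlink(path)
})
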