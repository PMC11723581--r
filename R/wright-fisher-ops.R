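# Single-generation Wright-Fisher operations on genotype proportions.
# These pure-R functions define the generation cycle exactly; wf_simulate()
# runs the same cycle in compiled code for long simulations.

#' Hardy-Weinberg genotype proportions
#'
#' Deterministic genotype proportions before viability selection under random
#' mating: `P[i, j] = q_i * q_j` (ordered-pair convention, so the unordered
#' heterozygote (i, j) has total proportion `2 q_i q_j`).
#'
#' @param freqs Allele frequency vector (nonnegative, summing to 1).
#' @return Symmetric matrix of ordered genotype proportions summing to 1.
#' @export
hardy_weinberg_proportions <- function(freqs) {
  check_freqs(freqs)
  outer(freqs, freqs)
}

#' Viability selection on genotype proportions
#'
#' Reweights genotype proportions by survival and renormalises:
#' `P'[i, j] = P[i, j] * s[i, j] / mean survival`. Only relative survival
#' matters; scaling the whole table by a constant leaves the result
#' unchanged.
#'
#' @param P Genotype proportion matrix (ordered convention, sums to 1).
#' @param s Symmetric survival table matching `P`.
#' @return Post-selection genotype proportion matrix summing to 1.
#' @export
viability_selection <- function(P, s) {
  if (!all(dim(P) == dim(s))) stop("genotype and survival tables must match")
  if (abs(sum(P) - 1) > 1e-8) stop("genotype proportions must sum to 1")
  w <- P * s
  wbar <- sum(w)
  if (wbar <= 0) stop("population extinct: every genotype has zero survival")
  w / wbar
}

#' Multinomial resampling of the adult population
#'
#' Draws `N` surviving offspring multinomially over unordered genotype
#' categories and returns the resulting allele copy-counts (summing to
#' `2 N`); alleles that are lost get count zero.
#'
#' @param P_sel Post-selection genotype proportion matrix (ordered
#'   convention).
#' @param N Population size.
#' @return Integer vector of allele copy-counts.
#' @export
resample_population <- function(P_sel, N) {
  n <- nrow(P_sel)
  # unordered categories: upper triangle incl. diagonal
  idx <- which(upper.tri(P_sel, diag = TRUE), arr.ind = TRUE)
  prob <- ifelse(idx[, 1] == idx[, 2], P_sel[idx], 2 * P_sel[idx])
  draw <- stats::rmultinom(1, N, prob)[, 1]
  counts <- integer(n)
  for (g in seq_along(draw)) {
    i <- idx[g, 1]; j <- idx[g, 2]
    counts[i] <- counts[i] + draw[g]
    counts[j] <- counts[j] + draw[g]
  }
  counts
}

#' Per-copy mutation on allele counts
#'
#' The number of mutation events is `Binomial(2N, mu)`; each event picks one
#' allele copy uniformly at random and replaces it with `mutator(allele)`.
#' Total copy count is conserved.
#'
#' @param alleles List of allele representations (trait vectors or bit-string
#'   codes).
#' @param counts Integer copy-counts, one per allele.
#' @param mu Per-copy mutation probability in \[0, 1\].
#' @param mutator Function mapping an allele to its mutated form.
#' @return List with updated `alleles` and `counts` (new alleles appended;
#'   zero-count alleles pruned). For bit-string alleles a mutant identical to
#'   an existing allele is merged into that allele's class.
#' @export
apply_mutation <- function(alleles, counts, mu, mutator) {
  if (mu < 0 || mu > 1) stop("'mu' must be a probability")
  two_n <- sum(counts)
  n_events <- stats::rbinom(1, two_n, mu)
  copies <- sample.int(two_n, n_events) # distinct: a copy mutates at most once
  cum0 <- cumsum(counts)
  for (copy in copies) {
    donor <- findInterval(copy - 0.5, cum0) + 1L
    counts[donor] <- counts[donor] - 1L
    mut <- mutator(alleles[[donor]])
    hit <- if (length(mut) == 1L) {
      Position(function(a) length(a) == 1L && a == mut, alleles)
    } else NULL
    if (!is.null(hit) && !is.na(hit)) {
      counts[hit] <- counts[hit] + 1L
    } else {
      alleles[[length(alleles) + 1L]] <- mut
      counts <- c(counts, 1L)
    }
  }
  keep <- counts > 0L
  list(alleles = alleles[keep], counts = counts[keep])
}

#' Marginal (expected) allele fitness
#'
#' Expected survival of a copy of each allele under random mating:
#' `w_i = sum_j q_j s[i, j]`. Allelic diversification proceeds by increasing
#' this marginal fitness.
#'
#' @param freqs Allele frequency vector.
#' @param s Survival table.
#' @return Numeric vector of marginal fitnesses.
#' @export
marginal_allele_fitness <- function(freqs, s) {
  check_freqs(freqs)
  as.numeric(s %*% freqs)
}

check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || any(freqs < 0)) {
    stop("allele frequencies must be nonnegative")
  }
  if (abs(sum(freqs) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  invisible(freqs)
}
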