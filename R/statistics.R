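#' Effective number of alleles
#'
#' Inverse homozygosity, `ne = 1 / sum(q_i^2)`: a conservative measure of
#' allelic diversity that discounts rare alleles segregating at
#' mutation-drift balance. Equals the plain allele count iff all frequencies
#' are equal.
#'
#' @param freqs Allele frequency vector (nonnegative, summing to 1).
#' @return Effective number of alleles, >= 1.
#' @examples
#' effective_number_of_alleles(c(0.5, 0.25, 0.25))  # 2.667
#' @export
effective_number_of_alleles <- function(freqs) {
  if (length(freqs) == 0L) stop("empty frequency vector")
  check_freqs(freqs)
  1 / sum(freqs^2)
}

#' Count alleles above a frequency threshold
#'
#' @param freqs Allele frequency vector.
#' @param threshold Inclusive frequency threshold in (0, 1); default 1%,
#'   the conventional cutoff for "coexisting" alleles.
#' @return Integer count of alleles with frequency >= `threshold`.
#' @export
count_alleles_at_threshold <- function(freqs, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  sum(freqs >= threshold)
}

#' Mutation-drift equilibrium effective allele number
#'
#' Expected effective number of alleles at an infinite-alleles locus under
#' mutation-drift balance alone: `ne = 1 + 4 N mu` for a diploid population
#' of size `N` and per-copy mutation probability `mu`. This is the baseline
#' against which selection-driven diversity is judged.
#'
#' @param N Diploid population size (>= 1).
#' @param mu Per-copy mutation probability (>= 0).
#' @return Expected effective number of alleles.
#' @examples
#' mutation_drift_ne(1e5, 5e-7)  # 1.2
#' @export
mutation_drift_ne <- function(N, mu) {
  if (N < 1) stop("'N' must be >= 1")
  if (mu < 0) stop("'mu' must be nonnegative")
  1 + 4 * N * mu
}

#' Gene-conversion effective allele number baseline
#'
#' Effective number of alleles that gene conversion alone could theoretically
#' maintain: `ne = 1 + 4 r Ne` for per-copy gene-conversion probability `r`
#' and effective population size `Ne` (gene conversion is not simulated by
#' this package; only the closed-form baseline is provided, for comparison).
#'
#' @param r Per-copy gene-conversion probability (>= 0).
#' @param Ne Effective population size (>= 1).
#' @return Expected effective number of alleles.
#' @examples
#' gene_conversion_ne(1e-4, 1e6)  # 401
#' @export
gene_conversion_ne <- function(r, Ne) {
  if (r < 0) stop("'r' must be nonnegative")
  if (Ne < 1) stop("'Ne' must be >= 1")
  1 + 4 * r * Ne
}

#' Time-averaged effective number of alleles
#'
#' Mean of the per-snapshot effective allele number over the post-burn-in
#' part of a trajectory.
#'
#' @param trajectory Either the `summary` data frame of a [wf_simulate()] run (with
#'   columns `generation` and `ne`) or a numeric vector of per-snapshot ne
#'   values.
#' @param burn_in Fraction of snapshots to discard from the start, in
#'   \[0, 1).
#' @return Mean effective number of alleles.
#' @export
time_averaged_ne <- function(trajectory, burn_in = 0.5) {
  ne <- if (is.data.frame(trajectory)) trajectory$ne else as.numeric(trajectory)
  if (length(ne) == 0L) stop("empty trajectory")
  if (burn_in < 0 || burn_in >= 1) stop("'burn_in' must be in [0, 1)")
  keep <- ne[seq_along(ne) > floor(burn_in * length(ne))]
  if (length(keep) == 0L) stop("all snapshots fall inside the burn-in")
  mean(keep)
}

#' Condition histogram split by genotype class
#'
#' Bins the conditions of all genotypes of the current population into
#' log-spaced bins, weighting each genotype by its Hardy-Weinberg proportion
#' under the realised allele frequencies, and splitting homozygotes from
#' heterozygotes. Conditions at or below the lowest edge are absorbed into
#' the first bin; conditions at or above the highest edge into the last.
#'
#' @param freqs Allele frequency vector.
#' @param eff Matrix of per-allele efficiencies (rows = alleles, columns =
#'   pathogens).
#' @param cmax Condition of a perfectly defended host.
#' @param bin_edges Increasing vector of bin edges; the default spans 1e-4
#'   to 1e4 in decade steps, with absorbing end bins.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `hom_freq`,
#'   `het_freq`; the two frequency columns jointly sum to 1.
#' @export
condition_histogram <- function(freqs, eff, cmax,
                                bin_edges = 10^seq(-4, 4, by = 1)) {
  check_freqs(freqs)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("'bin_edges' must be strictly increasing")
  }
  eff <- as.matrix(eff)
  n <- length(freqs)
  if (nrow(eff) != n) stop("one efficiency row per allele required")
  nb <- length(bin_edges) + 1L
  hom <- het <- numeric(nb)
  for (i in seq_len(n)) {
    for (j in i:n) {
      cm <- host_condition(codominant_efficiency(eff[i, ], eff[j, ]), cmax)
      w <- if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j]
      b <- findInterval(cm, bin_edges, left.open = TRUE) + 1L
      if (i == j) hom[b] <- hom[b] + w else het[b] <- het[b] + w
    }
  }
  # absorb the open end intervals into the first / last proper bin
  hom[2] <- hom[1] + hom[2]; het[2] <- het[1] + het[2]
  hom[nb - 1L] <- hom[nb - 1L] + hom[nb]; het[nb - 1L] <- het[nb - 1L] + het[nb]
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1],
             hom_freq = hom[2:(nb - 1L)],
             het_freq = het[2:(nb - 1L)])
}

#' Diversity summary of an allele frequency vector
#'
#' @param freqs Allele frequency vector.
#' @param threshold Frequency threshold for the coexisting-allele count.
#' @return List with `n_alleles`, `n_above_threshold`, `ne`, and
#'   `homozygosity`.
#' @export
diversity_summary <- function(freqs, threshold = 0.01) {
  list(n_alleles = length(freqs),
       n_above_threshold = count_alleles_at_threshold(freqs, threshold),
       ne = effective_number_of_alleles(freqs),
       homozygosity = sum(freqs^2))
}
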