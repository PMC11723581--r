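#' Co-dominant genotype efficiency
#'
#' MHC alleles are co-dominantly expressed: a diploid genotype's efficiency
#' against pathogen k is the arithmetic mean of the per-allele efficiencies.
#' Co-dominance is the conservative choice; any degree of dominance would
#' only strengthen heterozygote advantage.
#'
#' @param e_i,e_j Numeric vectors of per-pathogen efficiencies, one entry per
#'   pathogen, each entry in \[0, 1\]. Both vectors must have the same length.
#' @return Numeric vector of the same length: the entrywise mean.
#' @examples
#' codominant_efficiency(c(1, 0), c(0, 1))  # (0.5, 0.5)
#' @export
codominant_efficiency <- function(e_i, e_j) {
  check_efficiency(e_i)
  check_efficiency(e_j)
  if (length(e_i) != length(e_j)) {
    stop("efficiency vectors must have the same length (one entry per pathogen)")
  }
  (e_i + e_j) / 2
}

#' Host condition from genotype efficiencies
#'
#' Condition is a latent proxy for the host's physiological state. Every
#' imperfectly countered pathogen reduces it by a proportional factor, so the
#' genotype's condition is `cmax` times the product of its mean efficiencies
#' over all pathogens: a single poor defence is enough to collapse condition,
#' making undefended pathogens effectively lethal.
#'
#' The product is accumulated in log space so that runs with many pathogens do
#' not underflow; the returned value is the plain product.
#'
#' @param e_mean Numeric vector of genotype (mean) efficiencies in \[0, 1\],
#'   one per pathogen.
#' @param cmax Condition of a hypothetical host with perfect defence against
#'   every pathogen (> 0).
#' @return Condition, a scalar in \[0, cmax\].
#' @examples
#' host_condition(c(0.5, 0.5), cmax = 1)  # 0.25
#' @export
host_condition <- function(e_mean, cmax) {
  check_efficiency(e_mean)
  if (length(e_mean) == 0L) stop("need at least one pathogen efficiency")
  if (!is.numeric(cmax) || length(cmax) != 1L || !is.finite(cmax) || cmax <= 0) {
    stop("'cmax' must be a single positive number")
  }
  if (any(e_mean == 0)) return(0)
  cmax * exp(sum(log(e_mean)))
}

#' Survival probability from condition
#'
#' Survival saturates with condition: `s = c / (K + c)`, where `K` is the
#' condition required for a 50% chance of survival. Because survival cannot
#' exceed one, a given loss of condition costs a host in poor condition far
#' more survival than a host in good condition (diminishing returns).
#'
#' @param c_value Host condition, a nonnegative scalar or vector.
#' @param K Survival half-saturation constant (> 0), in the same units as
#'   condition.
#' @return Survival probability in \[0, 1\], same shape as `c_value`.
#' @examples
#' survival_probability(3, K = 1)  # 0.75
#' @export
survival_probability <- function(c_value, K) {
  if (!is.numeric(c_value) || any(!is.finite(c_value)) || any(c_value < 0)) {
    stop("condition must be finite and nonnegative")
  }
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop("'K' must be a single positive number")
  }
  c_value / (K + c_value)
}

#' Genotype survival table
#'
#' Builds the symmetric matrix of survival probabilities `s(x_i, x_j)` over a
#' set of alleles from their per-pathogen efficiency vectors, combining
#' co-dominant expression, multiplicative condition and saturating survival.
#'
#' @param eff Numeric matrix of allele efficiencies: one row per allele, one
#'   column per pathogen, entries in \[0, 1\].
#' @param cmax Condition of a perfectly defended host (> 0).
#' @param K Survival half-saturation constant (> 0).
#' @return Symmetric `n x n` matrix of survival probabilities.
#' @export
survival_table <- function(eff, cmax, K) {
  eff <- as.matrix(eff)
  n <- nrow(eff)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      cm <- host_condition(codominant_efficiency(eff[i, ], eff[j, ]), cmax)
      s[i, j] <- s[j, i] <- survival_probability(cm, K)
    }
  }
  s
}

check_efficiency <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    stop("efficiencies must be numeric values in [0, 1]")
  }
  invisible(e)
}
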