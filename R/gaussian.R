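#' Regular-simplex pathogen optima
#'
#' Places `m` pathogen optima at the vertices of a regular simplex in
#' `R^(m-1)` with unit edge length and centroid at the origin. This is the
#' maximally symmetric pathogen community: every pair of pathogens is at
#' distance 1 and the generalist allele sits exactly at the origin.
#'
#' Construction: the `m` scaled coordinate vectors `e_i / sqrt(2)` in `R^m`
#' are pairwise at distance 1; they are centred and rotated onto their
#' `(m-1)`-dimensional span via an eigendecomposition.
#'
#' @param m Number of pathogens (>= 2).
#' @return Numeric `m x (m-1)` matrix; row k is the optimum of pathogen k.
#' @examples
#' simplex_optima(3)  # unit equilateral triangle centred at the origin
#' @export
simplex_optima <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 2) {
    stop("'m' must be an integer >= 2")
  }
  m <- as.integer(m)
  x <- diag(m) / sqrt(2)
  x <- sweep(x, 2, colMeans(x))
  # rows live in an (m-1)-dim subspace; re-express them in an orthonormal
  # basis of that subspace (eigenvectors of the Gram matrix)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  basis <- ev$vectors[, seq_len(m - 1L), drop = FALSE]
  opt <- x %*% basis
  dimnames(opt) <- NULL
  opt
}

#' Gaussian recognition efficiency (isotropic)
#'
#' Efficiency of an MHC allele `x` against a pathogen with optimum `p`, under
#' an isotropic Gaussian recognition kernel of inverse width `v` (the
#' "virulence"): `e = exp(-(v^2 / 2) * ||x - p||^2)`. High virulence means a
#' narrow kernel, so alleles that are not well matched to the pathogen have
#' very low efficiency.
#'
#' @param x Allele trait vector.
#' @param p Pathogen optimum, same length as `x`.
#' @param v Virulence (> 0), the inverse width of the Gaussian.
#' @return Efficiency in (0, 1\]; equals 1 iff `x == p`.
#' @examples
#' gaussian_efficiency(c(0, 0), c(1, 0), v = 7)  # exp(-24.5)
#' @export
gaussian_efficiency <- function(x, p, v) {
  if (length(x) != length(p)) stop("allele and pathogen optimum dimensions differ")
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
    stop("'v' must be a single positive number")
  }
  d <- x - p
  exp(-(v^2 / 2) * sum(d * d))
}

#' Gaussian recognition efficiency (general covariance)
#'
#' General form of the Gaussian recognition kernel with an arbitrary
#' symmetric positive-definite covariance matrix per pathogen:
#' `e = exp(-0.5 * (x - p)' Sigma^{-1} (x - p))`. With
#' `Sigma = v^-2 * I` this reduces to [gaussian_efficiency()].
#'
#' @param x Allele trait vector.
#' @param p Pathogen optimum.
#' @param Sigma Symmetric positive-definite covariance matrix of the kernel.
#' @return Efficiency in (0, 1\].
#' @export
gaussian_efficiency_general <- function(x, p, Sigma) {
  if (length(x) != length(p)) stop("allele and pathogen optimum dimensions differ")
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma) || nrow(Sigma) != length(x) ||
      !isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-8))) {
    stop("'Sigma' must be a symmetric matrix matching the trait dimension")
  }
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("'Sigma' must be positive definite")
  d <- x - p
  z <- backsolve(ch, d, transpose = TRUE)
  exp(-0.5 * sum(z * z))
}

#' Per-pathogen efficiency vector of a Gaussian allele
#'
#' @param x Allele trait vector of length `m - 1`.
#' @param optima `m x (m-1)` matrix of pathogen optima.
#' @param v Virulence (> 0).
#' @return Numeric vector of length `m`.
#' @export
gaussian_efficiency_vector <- function(x, optima, v) {
  optima <- as.matrix(optima)
  vapply(seq_len(nrow(optima)),
         function(k) gaussian_efficiency(x, optima[k, ], v),
         numeric(1))
}

#' Mutation-kernel scale for the Gaussian model
#'
#' Mutations displace an allele by an isotropic normal step in `h` dimensions
#' calibrated so that the *expected step length* equals `delta`. For
#' `z ~ N(0, sigma^2 I_h)`, `E||z|| = sigma * sqrt(2) *
#' Gamma((h+1)/2) / Gamma(h/2)`; this returns the per-axis `sigma` that
#' inverts that relation.
#'
#' @param delta Expected mutational step length (> 0).
#' @param h Trait-space dimension (>= 1).
#' @return Per-axis standard deviation.
#' @examples
#' gaussian_mutation_sd(0.016, h = 1)  # 0.016 * sqrt(pi / 2)
#' @export
gaussian_mutation_sd <- function(delta, h) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("'delta' must be a single positive number")
  }
  if (h < 1 || h != round(h)) stop("'h' must be a positive integer")
  # E||z||/sigma, via lgamma for numerical safety at large h
  enorm <- sqrt(2) * exp(lgamma((h + 1) / 2) - lgamma(h / 2))
  delta / enorm
}

#' Mutate a Gaussian allele
#'
#' Draws an isotropic normal step with expected length `delta` and adds it to
#' the allele's trait vector. Traits are continuous, so every mutation yields
#' a new, distinct allele; mutants are never clipped to the pathogen simplex
#' (alleles outside it are simply disfavoured by selection).
#'
#' @param x Allele trait vector.
#' @param delta Expected mutational step length (> 0).
#' @return Mutated trait vector of the same length.
#' @export
mutate_gaussian <- function(x, delta) {
  h <- length(x)
  x + stats::rnorm(h, sd = gaussian_mutation_sd(delta, h))
}
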