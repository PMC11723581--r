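# Adaptive-dynamics predictions for the Gaussian recognition model. Gradual
# allelic evolution converges on the generalist allele (the mean of the
# pathogen optima); whether that singular point is an endpoint or an
# evolutionary branching point is decided by the spread of the pathogen
# optima relative to the width of the recognition kernels.

#' Singular (generalist) allele
#'
#' The attractor of gradual allelic evolution: the componentwise arithmetic
#' mean of the pathogen optima. For the centred unit-edge simplex this is
#' the origin.
#'
#' @param optima Matrix of pathogen optima, one row per pathogen.
#' @return Numeric vector: the generalist trait value `x*`.
#' @export
singular_point <- function(optima) {
  optima <- as.matrix(optima)
  if (nrow(optima) < 2) stop("need at least two pathogen optima")
  colMeans(optima)
}

#' Population covariance of the pathogen optima
#'
#' Covariance of the `m` optima about their mean, normalised by `m`
#' (population form). For the unit-edge regular simplex every nonzero
#' eigenvalue equals `1 / (2 m)`.
#'
#' @param optima Matrix of pathogen optima, one row per pathogen.
#' @return Symmetric `h x h` covariance matrix.
#' @export
pathogen_covariance <- function(optima) {
  optima <- as.matrix(optima)
  if (nrow(optima) < 2) stop("need at least two pathogen optima")
  x <- sweep(optima, 2, colMeans(optima))
  crossprod(x) / nrow(optima)
}

#' Evolutionary branching condition (general covariances)
#'
#' Diversification at the generalist allele occurs when the pathogen optima
#' are spread widely relative to the recognition kernels:
#' `M = Sigma_p^2 - 2 Sigma_G^2 > 0`. The verdict reports the eigenvalues of
#' `M`; branching requires disruptive selection in at least one trait
#' direction (largest eigenvalue positive), and `positive_definite` flags
#' the stronger reading (all eigenvalues positive; the two coincide in the
#' fully symmetric case). The condition does not involve the number of
#' pathogens `m` directly, only the two covariance matrices.
#'
#' @param Sigma_p Covariance matrix of the pathogen optima (see
#'   [pathogen_covariance()]).
#' @param Sigma_G Covariance matrix of the Gaussian recognition kernel
#'   (isotropic case: `v^-2 * I`); must be symmetric positive definite.
#' @param singular Optional singular point to carry in the verdict.
#' @return A list of class `branching_verdict`: `singular_point`, `matrix`
#'   (`M`), `eigenvalues` (decreasing), `branching` (whether the largest
#'   eigenvalue is positive), `positive_definite`.
#' @export
branching_condition_general <- function(Sigma_p, Sigma_G, singular = NULL) {
  Sigma_p <- as.matrix(Sigma_p)
  Sigma_G <- as.matrix(Sigma_G)
  sym <- function(A) isTRUE(all.equal(A, t(A), tolerance = 1e-8))
  if (!sym(Sigma_p) || !sym(Sigma_G)) stop("covariance matrices must be symmetric")
  if (any(eigen(Sigma_G, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("'Sigma_G' must be positive definite")
  }
  M <- Sigma_p - 2 * Sigma_G
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  structure(list(singular_point = singular,
                 matrix = M,
                 eigenvalues = ev,
                 branching = ev[1] > 0,
                 positive_definite = ev[length(ev)] > 0),
            class = "branching_verdict")
}

#' @export
print.branching_verdict <- function(x, ...) {
  cat("Evolutionary branching verdict at the generalist allele\n")
  if (!is.null(x$singular_point)) {
    cat("  singular point x*: ",
        paste(signif(x$singular_point, 4), collapse = ", "), "\n", sep = "")
  }
  cat("  eigenvalues of Sigma_p^2 - 2 Sigma_G^2: ",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n", sep = "")
  cat(sprintf("  branching: %s (positive definite: %s)\n",
              x$branching, x$positive_definite))
  invisible(x)
}

#' Critical virulence for branching under full symmetry
#'
#' With `m` pathogens at the vertices of the unit-edge simplex and isotropic
#' recognition kernels of inverse width `v`, the optima variance per
#' direction is `1 / (2 m)` and the branching condition
#' `sigma_p^2 - 2 sigma_G^2 > 0` reduces to `v > v_c = 2 sqrt(m)`. More
#' pathogens therefore *raise* the bar for initial diversification.
#'
#' @param m Number of pathogens (>= 2).
#' @return Critical virulence `v_c`; branching iff `v > v_c`.
#' @examples
#' branching_threshold_symmetric(3)  # 2 * sqrt(3) = 3.46
#' @export
branching_threshold_symmetric <- function(m) {
  if (m < 2 || m != round(m)) stop("'m' must be an integer >= 2")
  2 * sqrt(m)
}

#' Full adaptive-dynamics prediction for a Gaussian configuration
#'
#' Convenience wrapper: computes the singular point, the branching verdict
#' (isotropic kernel `v^-2 I`), and, for simplex-arranged optima, the
#' symmetric critical virulence.
#'
#' @param config A Gaussian `wf_config`, or a list with `optima` and `v`.
#' @return A `branching_verdict` with an extra `v_critical` element (NA when
#'   the optima are not a unit-edge simplex).
#' @export
predict_branching <- function(config) {
  if (is.null(config$optima) || is.null(config$v)) {
    stop("need a Gaussian configuration with 'optima' and 'v'")
  }
  optima <- as.matrix(config$optima)
  h <- ncol(optima)
  verdict <- branching_condition_general(
    pathogen_covariance(optima),
    diag(config$v^-2, h),
    singular = singular_point(optima)
  )
  d <- as.matrix(stats::dist(optima))
  unit_simplex <- all(abs(d[upper.tri(d)] - 1) < 1e-8)
  verdict$v_critical <- if (unit_simplex) {
    branching_threshold_symmetric(nrow(optima))
  } else NA_real_
  verdict
}
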