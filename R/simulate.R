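#' Run a Wright-Fisher simulation
#'
#' Iterates the diploid generation cycle — deterministic Hardy-Weinberg
#' proportions, viability selection through the genotype survival table,
#' multinomial resampling of `N` surviving offspring, then per-copy mutation
#' — for the configured number of generations. Genotype survival emerges
#' from the configured host-pathogen recognition model (Gaussian or
#' bit-string) through multiplicative condition and saturating survival; the
#' `"neutral"` model runs the same cycle with flat survival.
#'
#' The run is fully reproducible from its configuration: the seed drives
#' pathogen drawing (bit-string model), the initial allele, and every
#' stochastic step of the cycle.
#'
#' @param config A `wf_config` object (see [wf_config()], [load_config()]).
#' @param record_alleles If `TRUE` (default), keep the full allele table at
#'   every recorded snapshot, not just summary statistics.
#' @return An object of class `wf_sim`: a list with elements
#'   \describe{
#'     \item{config}{the configuration as run (with pathogens resolved),}
#'     \item{summary}{data frame of per-snapshot statistics (`generation`,
#'       `n_alleles`, `ne`, `n_above_1pct`, `mean_survival`),}
#'     \item{snapshots}{list of per-snapshot allele tables (or `NULL`),}
#'     \item{final}{data frame of the final allele population (`id`,
#'       `count`, `frequency`, `marginal_fitness`, allele representation),}
#'     \item{final_eff}{matrix of final per-allele efficiencies (one column
#'       per pathogen),}
#'     \item{final_survival}{final genotype survival table.}
#'   }
#' @examples
#' cfg <- wf_config("gaussian", N = 1000, mu = 1e-4, generations = 200,
#'                  seed = 1, K = 0.1, cmax = 1e4, m = 3, v = 7,
#'                  delta = 0.016)
#' sim <- wf_simulate(cfg)
#' summary(sim)
#' @export
wf_simulate <- function(config, record_alleles = TRUE) {
  if (!inherits(config, "wf_config")) {
    stop("'config' must be a 'wf_config' object (see wf_config())")
  }
  set.seed(config$seed)
  model_code <- match(config$model, c("neutral", "gaussian", "bitstring")) - 1L

  optima <- matrix(0, 0, 0)
  peptides <- matrix(0L, 0, 0)
  sigma <- 0
  init_coords <- matrix(0, 0, 0)
  init_codes <- integer(0)

  if (config$model == "gaussian") {
    optima <- config$optima
    sigma <- gaussian_mutation_sd(config$delta, ncol(optima))
    if (is.null(config$init)) config$init <- colMeans(optima) # generalist
    init_coords <- matrix(config$init, nrow = 1)
  } else if (config$model == "bitstring") {
    if (is.null(config$pathogens)) {
      config$pathogens <- random_pathogens(config$m, config$npep,
                                           v = config$v, a = config$a)
    }
    peptides <- config$pathogens$peptides
    if (is.null(config$init)) {
      config$init <- code_to_bitstring(sample.int(65536L, 1L) - 1L)
    }
    init_codes <- as_bit_code(config$init)
  }

  # re-seed the generation loop separately from the setup draws, so a run
  # with pathogens and initial allele resolved (e.g. from a manifest)
  # reproduces the original trajectory exactly
  set.seed(derive_seed(config$seed, 1000003L))

  res <- cpp_wf_run(model_code, config$N, config$mu, config$generations,
                    config$thin, config$cmax, config$K,
                    optima, if (is.null(config$v)) 0 else config$v, sigma,
                    peptides, config$a,
                    init_coords, init_codes,
                    init_counts = rep(2L * config$N, length.out = 1L),
                    record_alleles = record_alleles)

  summ <- as.data.frame(res$summary)
  names(summ) <- c("generation", "n_alleles", "ne", "n_above_1pct",
                   "mean_survival")

  counts <- res$final_count
  freqs <- counts / (2 * config$N)
  final <- data.frame(id = res$final_id, count = counts, frequency = freqs)
  s_final <- NULL
  if (config$model != "neutral") {
    s_final <- survival_table(res$final_eff, config$cmax, config$K)
    final$marginal_fitness <- marginal_allele_fitness(freqs, s_final)
  } else {
    final$marginal_fitness <- rep(summ$mean_survival[nrow(summ)], nrow(final))
  }
  if (config$model == "gaussian") {
    final$trait <- apply(res$final_repr, 1, paste, collapse = ",")
  } else if (config$model == "bitstring") {
    final$allele <- code_to_bitstring(res$final_repr)
  }

  structure(list(config = config,
                 summary = summ,
                 snapshots = res$snapshots,
                 final = final,
                 final_repr = res$final_repr,
                 final_eff = if (config$model == "neutral") NULL else res$final_eff,
                 final_survival = s_final),
            class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  cfg <- x$config
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("Wright-Fisher MHC simulation (%s model)\n", cfg$model))
  cat(sprintf("  N = %d, mu = %g, %d generations, seed %d\n",
              cfg$N, cfg$mu, cfg$generations, cfg$seed))
  if (cfg$model == "gaussian") {
    cat(sprintf("  m = %d pathogens, v = %g, K = %g, cmax = %g, delta = %g\n",
                cfg$m, cfg$v, cfg$K, cfg$cmax, cfg$delta))
  } else if (cfg$model == "bitstring") {
    cat(sprintf("  m = %d pathogens x %d peptides, v = %g, a = %.3f, K = %g, cmax = %g\n",
                cfg$m, cfg$npep, cfg$v, cfg$a, cfg$K, cfg$cmax))
  }
  cat(sprintf("Final generation: %d alleles, %d at >= 1%% frequency, ne = %.2f\n",
              last$n_alleles, last$n_above_1pct, last$ne))
  invisible(x)
}

#' Diversity summary of a simulation
#'
#' @param object A `wf_sim` object.
#' @param burn_in Burn-in fraction for the time-averaged effective allele
#'   number.
#' @param ... Unused.
#' @return A list of class `summary.wf_sim` with the final-snapshot allele
#'   count, count of alleles at >= 1% frequency, effective number of alleles
#'   (and its time average), homozygosity, and mean survival.
#' @export
summary.wf_sim <- function(object, burn_in = 0.5, ...) {
  last <- object$summary[nrow(object$summary), ]
  freqs <- object$final$frequency
  out <- list(
    model = object$config$model,
    generations = object$config$generations,
    n_alleles = as.integer(last$n_alleles),
    n_above_threshold = as.integer(last$n_above_1pct),
    ne = effective_number_of_alleles(freqs),
    ne_time_averaged = time_averaged_ne(object$summary, burn_in = burn_in),
    homozygosity = sum(freqs^2),
    mean_survival = last$mean_survival
  )
  class(out) <- "summary.wf_sim"
  out
}

#' @export
print.summary.wf_sim <- function(x, ...) {
  cat(sprintf("%s model, %d generations\n", x$model, x$generations))
  cat(sprintf("  alleles: %d (%d at >= 1%% frequency)\n",
              x$n_alleles, x$n_above_threshold))
  cat(sprintf("  effective number of alleles: %.2f (time-averaged %.2f)\n",
              x$ne, x$ne_time_averaged))
  cat(sprintf("  homozygosity: %.4f, mean survival: %.3g\n",
              x$homozygosity, x$mean_survival))
  invisible(x)
}

#' Re-run a simulation with fresh seeds
#'
#' Replicates the run `nsim` times, deriving each replicate's seed
#' deterministically from `seed`.
#'
#' @param object A `wf_sim` object.
#' @param nsim Number of replicate runs.
#' @param seed Base seed; replicate r uses `derive_seed(seed, r)`.
#' @param ... Passed to [wf_simulate()].
#' @return A list of `wf_sim` objects.
#' @export
simulate.wf_sim <- function(object, nsim = 1, seed = object$config$seed, ...) {
  lapply(seq_len(nsim), function(r) {
    cfg <- object$config
    cfg$seed <- derive_seed(seed, r)
    if (cfg$model == "bitstring") { # redraw pathogens and the founder allele
      cfg$pathogens <- NULL
      cfg$init <- NULL
    }
    wf_simulate(cfg, ...)
  })
}

#' Plot a simulation
#'
#' Two diagnostic panels: the effective-number-of-alleles trajectory over
#' time, and the final condition histogram split into homozygotes and
#' heterozygotes (pathogen models only).
#'
#' @param x A `wf_sim` object.
#' @param which Panels to draw (`1` = ne trajectory, `2` = condition
#'   histogram).
#' @param ... Unused.
#' @export
plot.wf_sim <- function(x, which = if (x$config$model == "neutral") 1 else 1:2,
                        ...) {
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    d <- x$summary[x$summary$generation > 0, ]
    if (nrow(d) < 2) d <- x$summary
    graphics::plot(d$generation, d$ne, type = "l",
                   log = if (all(d$generation > 0)) "x" else "",
                   xlab = "generation", ylab = "effective number of alleles",
                   main = "allelic diversity")
  }
  if (2 %in% which && x$config$model != "neutral") {
    h <- condition_histogram(x$final$frequency, x$final_eff,
                             cmax = x$config$cmax)
    mids <- sqrt(h$bin_lo * pmin(h$bin_hi, max(h$bin_lo) * 10))
    graphics::barplot(rbind(h$hom_freq, h$het_freq), beside = FALSE,
                      names.arg = signif(mids, 1),
                      col = c("darkblue", "lightblue"), las = 2,
                      xlab = "condition", ylab = "genotype frequency",
                      main = "final conditions")
    graphics::legend("topleft", fill = c("darkblue", "lightblue"),
                     legend = c("homozygotes", "heterozygotes"), bty = "n")
  }
  invisible(x)
}

#' Deterministic seed derivation
#'
#' Derives a child seed from a base seed and one or more indices, so that
#' replicate runs and sweep cells are independent but exactly reproducible.
#' Uses a small multiplicative hash folded into the 31-bit integer range.
#'
#' @param seed Base integer seed.
#' @param ... Integer indices (replicate number, cell index, ...).
#' @return A positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) * 16807 + 1) %% 2147483647
  }
  as.integer(x) + 1L
}
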