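# Plain-text outputs: per-allele trajectory TSV, per-run JSON manifest and
# condition-histogram TSV. A run is exactly reproducible from its manifest.

#' Write the allele trajectory of a run as TSV
#'
#' One row per allele per recorded snapshot, columns `generation`,
#' `allele_id`, `allele_repr` (comma-joined trait coordinates or 16-bit
#' string), `count`, `frequency`, and (final snapshot only)
#' `marginal_fitness`.
#'
#' @param sim A `wf_sim` run with recorded allele snapshots.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  if (is.null(sim$snapshots)) {
    stop("run was executed with record_alleles = FALSE; no trajectory to write")
  }
  two_n <- 2 * sim$config$N
  rows <- lapply(sim$snapshots, function(sn) {
    repr <- if (sim$config$model == "gaussian") {
      apply(as.matrix(sn$repr), 1, function(r) paste(signif(r, 8), collapse = ","))
    } else if (sim$config$model == "bitstring") {
      code_to_bitstring(sn$repr)
    } else {
      as.character(sn$id)
    }
    data.frame(generation = sn$generation, allele_id = sn$id,
               allele_repr = repr, count = sn$count,
               frequency = sn$count / two_n)
  })
  out <- do.call(rbind, rows)
  fin <- sim$final[, c("id", "marginal_fitness")]
  out$marginal_fitness <- NA_real_
  last <- out$generation == max(out$generation)
  out$marginal_fitness[last] <-
    fin$marginal_fitness[match(out$allele_id[last], fin$id)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the complete configuration (including the realised pathogen set
#' for bit-string runs), the seed, the package version, and final-generation
#' summary statistics, so that the run can be reproduced exactly from the
#' manifest alone.
#'
#' @param sim A `wf_sim` run.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sim, path) {
  cfg <- sim$config
  cfg_out <- cfg[!vapply(cfg, is.null, logical(1))]
  class(cfg_out) <- NULL
  if (!is.null(cfg_out$optima)) {
    cfg_out$optima <- unclass(cfg_out$optima)
  }
  if (!is.null(cfg_out$pathogens)) {
    cfg_out$pathogens <- list(
      peptides = code_to_bitstring(as.integer(t(cfg_out$pathogens$peptides))),
      m = nrow(cfg$pathogens$peptides), npep = ncol(cfg$pathogens$peptides))
  }
  last <- sim$summary[nrow(sim$summary), ]
  manifest <- list(
    package = "mhcsim",
    version = as.character(utils::packageVersion("mhcsim")),
    config = cfg_out,
    final = list(generation = last$generation,
                 n_alleles = last$n_alleles,
                 n_above_1pct = last$n_above_1pct,
                 ne = last$ne,
                 mean_survival = last$mean_survival)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rebuild a configuration from a JSON manifest
#'
#' @param path Path to a manifest written by [write_manifest()].
#' @return A `wf_config` that reproduces the original run.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- man$config
  if (!is.null(cfg$optima)) cfg$optima <- as.matrix(cfg$optima)
  if (!is.null(cfg$pathogens)) {
    codes <- bitstring_to_code(cfg$pathogens$peptides)
    cfg$pathogens <- list(
      peptides = matrix(codes, nrow = cfg$pathogens$m,
                        ncol = cfg$pathogens$npep, byrow = TRUE),
      v = cfg$v, a = cfg$a)
  }
  do.call(wf_config, cfg[intersect(names(cfg), names(formals(wf_config)))])
}

#' Write the final condition histogram as TSV
#'
#' @param sim A `wf_sim` run under a pathogen model.
#' @param path Output file path.
#' @param ... Passed to [condition_histogram()].
#' @return `path`, invisibly.
#' @export
write_condition_histogram <- function(sim, path, ...) {
  if (is.null(sim$final_eff)) stop("neutral runs have no condition histogram")
  h <- condition_histogram(sim$final$frequency, sim$final_eff,
                           cmax = sim$config$cmax, ...)
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
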