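#' Run a parameter sweep
#'
#' Runs one simulation per grid cell and replicate over named parameter
#' axes, with a deterministic seed derived from the base config's seed, the
#' cell index and the replicate number. Failures in individual cells are
#' recorded and the sweep continues.
#'
#' @param base A `wf_config` used for all parameters not swept.
#' @param axes Named list of parameter value vectors (e.g.
#'   `list(v = c(2, 3, 5, 7))`); the full factorial grid is run.
#' @param replicates Replicate runs per cell (>= 1).
#' @param out_dir Optional directory; when given, each run's manifest is
#'   written there as `cell<i>_rep<r>.json`.
#' @return Long-format data frame: one row per cell x replicate with the
#'   swept parameter values, the derived seed, `ne`, `n_alleles`,
#'   `n_above_1pct`, elapsed seconds, and an `error` column (NA on
#'   success).
#' @export
run_sweep <- function(base, axes, replicates = 1L, out_dir = NULL) {
  if (!inherits(base, "wf_config")) stop("'base' must be a 'wf_config'")
  if (!is.list(axes) || length(axes) == 0L || is.null(names(axes)) ||
      any(!nzchar(names(axes)))) {
    stop("'axes' must be a nonempty named list of parameter grids")
  }
  if (replicates < 1) stop("'replicates' must be >= 1")
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    for (rep in seq_len(replicates)) {
      cfg <- unclass(base)
      for (p in names(grid)) cfg[[p]] <- grid[[p]][cell]
      cfg$seed <- derive_seed(base$seed, cell, rep)
      cfg$pathogens <- NULL
      row <- cbind(grid[cell, , drop = FALSE],
                   data.frame(cell = cell, replicate = rep, seed = cfg$seed,
                              ne = NA_real_, n_alleles = NA_integer_,
                              n_above_1pct = NA_integer_,
                              seconds = NA_real_, error = NA_character_))
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        cfg_v <- do.call(wf_config, cfg[intersect(names(cfg),
                                                  names(formals(wf_config)))])
        sim <- wf_simulate(cfg_v, record_alleles = FALSE)
        if (!is.null(out_dir)) {
          write_manifest(sim, file.path(out_dir,
                                        sprintf("cell%d_rep%d.json", cell, rep)))
        }
        s <- sim$summary[nrow(sim$summary), ]
        row$ne <- s$ne
        row$n_alleles <- as.integer(s$n_alleles)
        row$n_above_1pct <- as.integer(s$n_above_1pct)
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      res$seconds <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
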