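#' Build a validated simulation configuration
#'
#' Assembles and validates the full parameter set of a Wright-Fisher run.
#' `cmax` has no default: it must be stated explicitly (the bundled presets
#' use `cmax = 1e4`).
#'
#' @param model `"gaussian"`, `"bitstring"`, or `"neutral"` (flat survival;
#'   pure mutation-drift dynamics through the identical generation cycle).
#' @param N Diploid population size (>= 1).
#' @param mu Per-copy mutation probability in \[0, 1\].
#' @param generations Number of generations to iterate (>= 1).
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @param K Survival half-saturation constant (> 0).
#' @param cmax Condition of a perfectly defended host (> 0). Required for
#'   the pathogen models.
#' @param m Number of pathogens.
#' @param v Virulence (Gaussian: inverse kernel width; bit-string: match
#'   length for 50% detection).
#' @param delta Gaussian model: expected mutational step length.
#' @param npep Bit-string model: peptides per pathogen.
#' @param a Bit-string model: logistic steepness (default `log(9)`).
#' @param optima Optional `m x (m-1)` matrix of pathogen optima (Gaussian);
#'   default is the unit-edge regular simplex.
#' @param pathogens Optional bit-string pathogen set (see
#'   [random_pathogens()]); default is drawn at run start from the run seed.
#' @param init Optional initial allele: trait vector (Gaussian; default the
#'   generalist allele, the mean of the optima) or a 16-bit string / code
#'   (bit-string; default a random string drawn from the run seed).
#' @param thin Record a snapshot every `thin` generations (plus the final
#'   one).
#' @return A list of class `wf_config`.
#' @export
wf_config <- function(model = c("gaussian", "bitstring", "neutral"),
                      N, mu, generations, seed = 1L,
                      K = 1, cmax = NULL,
                      m = NULL, v = NULL, delta = NULL,
                      npep = NULL, a = log(9),
                      optima = NULL, pathogens = NULL, init = NULL,
                      thin = 100L) {
  model <- match.arg(model)
  stop_if <- function(bad, msg) if (bad) stop("config error: ", msg, call. = FALSE)
  chk_num <- function(x, nm, lo = -Inf, hi = Inf, int = FALSE) {
    stop_if(is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x),
            sprintf("'%s' must be a single finite number", nm))
    stop_if(x < lo || x > hi, sprintf("'%s' out of range [%g, %g]", nm, lo, hi))
    stop_if(int && x != round(x), sprintf("'%s' must be an integer", nm))
  }
  chk_num(N, "N", lo = 1, int = TRUE)
  chk_num(mu, "mu", lo = 0, hi = 1)
  chk_num(generations, "generations", lo = 1, int = TRUE)
  chk_num(seed, "seed", int = TRUE)
  chk_num(thin, "thin", lo = 1, int = TRUE)
  chk_num(K, "K", lo = .Machine$double.xmin)
  if (model %in% c("gaussian", "bitstring")) {
    stop_if(is.null(cmax), "'cmax' is required (no default)")
    chk_num(cmax, "cmax", lo = .Machine$double.xmin)
    chk_num(v, "v", lo = .Machine$double.xmin)
    chk_num(m, "m", lo = 2, int = TRUE)
  } else {
    if (is.null(cmax)) cmax <- 1
  }
  if (model == "gaussian") {
    chk_num(delta, "delta", lo = .Machine$double.xmin)
    if (is.null(optima)) optima <- simplex_optima(m)
    optima <- as.matrix(optima)
    stop_if(nrow(optima) != m, "'optima' must have one row per pathogen")
    if (!is.null(init)) {
      stop_if(length(init) != ncol(optima),
              "'init' must match the trait dimension of the optima")
    }
  }
  if (model == "bitstring") {
    chk_num(npep, "npep", lo = 1, int = TRUE)
    chk_num(a, "a", lo = .Machine$double.xmin)
    if (!is.null(pathogens)) {
      stop_if(!is.list(pathogens) || is.null(pathogens$peptides) ||
                nrow(pathogens$peptides) != m || ncol(pathogens$peptides) != npep,
              "'pathogens' must be an m x npep pathogen set")
    }
  }
  structure(list(model = model, N = as.integer(N), mu = mu,
                 generations = as.integer(generations),
                 seed = as.integer(seed), thin = as.integer(thin),
                 K = K, cmax = cmax, m = if (is.null(m)) NULL else as.integer(m),
                 v = v, delta = delta,
                 npep = if (is.null(npep)) NULL else as.integer(npep), a = a,
                 optima = if (model == "gaussian") optima else NULL,
                 pathogens = pathogens, init = init),
            class = "wf_config")
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a flat YAML mapping (with an optional nested `model_params`
#' section), validates it through [wf_config()] and rejects unknown keys.
#' Pathogen optima / peptide sets may be given inline or as a path to a TSV
#' file (resolved relative to the config file).
#'
#' @param path Path to a YAML config file, or the name of a bundled preset
#'   (see [preset_names()]).
#' @return A `wf_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    preset <- system.file("presets", paste0(path, ".yaml"), package = "mhcsim")
    if (nzchar(preset)) path <- preset else stop("config file not found: ", path)
  }
  raw <- read_yaml_keyfixed(path)
  if (!is.null(raw$model_params)) {
    raw <- c(raw[setdiff(names(raw), "model_params")], raw$model_params)
  }
  known <- setdiff(names(formals(wf_config)), c("optima", "pathogens"))
  extra <- c("optima_file", "peptides_file")
  unknown <- setdiff(names(raw), c(known, extra))
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  dir <- dirname(path)
  optima <- NULL
  pathogens <- NULL
  if (!is.null(raw$optima_file)) {
    optima <- as.matrix(utils::read.table(file.path(dir, raw$optima_file),
                                          sep = "\t"))
    dimnames(optima) <- NULL
  }
  if (!is.null(raw$peptides_file)) {
    pathogens <- read_pathogens(file.path(dir, raw$peptides_file),
                                v = raw$v, a = if (is.null(raw$a)) log(9) else raw$a)
  }
  args <- raw[intersect(names(raw), known)]
  args$optima <- optima
  args$pathogens <- pathogens
  do.call(wf_config, args)
}

# YAML 1.1 resolves a bare key `N` to boolean FALSE; map it back at any depth
read_yaml_keyfixed <- function(path) {
  fix <- function(x) {
    if (is.list(x)) {
      names(x)[names(x) == "FALSE"] <- "N"
      lapply(x, fix)
    } else x
  }
  fix(yaml::read_yaml(path))
}

#' Names of the bundled preset configurations
#'
#' Presets mirror published simulation designs: `fig3A`-`fig3D` (Gaussian,
#' m = 3, v = 7, K = 10 / 1 / 0.1 / 0.01), `fig4-slice` and `fig5-slice`
#' (one-dimensional sweep slices), `fig6` (bit-string, m = 12, npep = 3),
#' `borghans-comparison` (bit-string, m = 50, npep = 20, near-step
#' detection) and `neutral` (flat survival).
#'
#' @return Character vector of preset names usable with [load_config()].
#' @export
preset_names <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("presets", package = "mhcsim"), "\\.yaml$"))
}

#' Bit-string configuration matching a classic bit-string study
#'
#' Returns the configuration used to contrast this package's fitness map
#' with earlier bit-string work: m = 50 pathogens with npep = 20 peptides
#' each, virulence v = 7, and a near-step detection function (steepness `a`
#' chosen so that detection is below 1e-3 one match short of `v` and above
#' 0.999 one match beyond it). Under the multiplicative-condition /
#' saturating-survival fitness map this setting evolves over 100 coexisting
#' alleles rather than a handful.
#'
#' @param N,mu,generations,seed,K,cmax Overridable run parameters.
#' @return A `wf_config` object.
#' @export
borghans_comparison_preset <- function(N = 1e5, mu = 5e-6, generations = 2e6,
                                       seed = 1L, K = 1, cmax = 1e4) {
  a_step <- log(999^2) # D(v - 1) approx 1e-6 ... guarantees < 1e-3
  wf_config(model = "bitstring", N = N, mu = mu, generations = generations,
            seed = seed, K = K, cmax = cmax,
            m = 50L, npep = 20L, v = 7, a = a_step)
}
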