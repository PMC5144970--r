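#' Quadratic reaction-norm shape constructor
#'
#' Builds a smooth mean-growth-rate function of an environmental setting:
#' a downward parabola `height - curvature * (x - peak)^2`, optionally on a
#' log10-transformed setting axis (used for sucrose, whose grid spans three
#' orders of magnitude), truncated below at zero.
#'
#' @param peak setting (on the possibly transformed axis) of maximal growth.
#' @param height growth rate at the peak (mm/hr).
#' @param curvature non-negative curvature of the parabola.
#' @param log10_axis evaluate the parabola in log10(setting)?
#' @return A function `f(setting) -> mean rate (mm/hr)`.
#' @export
quadratic_shape <- function(peak, height, curvature, log10_axis = FALSE) {
  stopifnot(curvature >= 0, height >= 0)
  function(setting) {
    x <- if (log10_axis) log10(setting) else setting
    pmax(0, height - curvature * (x - peak)^2)
  }
}

# Control-like base shapes for the four environments. Peaks follow the
# optima reported for the wild type (temperature ~33.7, salt 0 M, pH near
# 5.8); heights are anchored so growth at the control environment
# (25 C, 0 M, 1.5% sucrose, pH 5.8) is close to 3.29 mm/hr.
base_norm_shapes <- function() {
  list(
    temperature = quadratic_shape(33.7, 3.9, 0.008),
    salt        = function(setting) pmax(0, 3.29 - 2.2 * setting + 0.45 * setting^2),
    sucrose     = quadratic_shape(0.7, 3.45, 0.28, log10_axis = TRUE),
    pH          = quadratic_shape(5.8, 3.29, 0.09)
  )
}

#' Simulation configuration for growth-rate tables
#'
#' Bundles the generative model of the factorial experiment: per-genotype
#' reaction-norm elevation shifts, per-(genotype, parameter) mean shape
#' functions, per-genotype residual standard deviations, a
#' missing-completely-at-random rate, explicit zero-growth cells, and a
#' master seed.
#'
#' @param genotype_effects named numeric vector of elevation shifts (mm/hr),
#'   one entry per genotype.
#' @param norm_shapes either a function `(genotype, env_param, setting) ->
#'   mean rate`, or a named list `norm_shapes[[env_param]]` of functions of
#'   the setting shared by all genotypes.
#' @param sigma_by_genotype named numeric vector of residual SDs (> 0).
#' @param missing_rate probability in \[0, 1\] that an assay is missing.
#' @param zero_growth_cells data.frame with columns `genotype`, `env_param`,
#'   `setting` listing cells forced to zero growth, or NULL.
#' @param seed master integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genotype_effects, norm_shapes, sigma_by_genotype,
                       missing_rate = 0, zero_growth_cells = NULL,
                       seed = 1L) {
  if (any(sigma_by_genotype <= 0)) stop("sigma_by_genotype must be > 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (is.null(names(genotype_effects)) || is.null(names(sigma_by_genotype)))
    stop("genotype_effects and sigma_by_genotype must be named by genotype")
  if (!is.null(zero_growth_cells))
    stopifnot(all(c("genotype", "env_param", "setting") %in%
                    names(zero_growth_cells)))
  structure(list(genotype_effects = genotype_effects,
                 norm_shapes = norm_shapes,
                 sigma_by_genotype = sigma_by_genotype,
                 missing_rate = missing_rate,
                 zero_growth_cells = zero_growth_cells,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration
#'
#' The stated world of the synthetic experiment: 26 genotypes with
#' control-like nonlinear base norms, mostly small elevation shifts with
#' three severely growth-impaired strains, genotype-specific shape changes
#' for the strains known to shift their environmental optima (e.g. a
#' temperature optimum moved from 33.7 to 25.3 for the H3K36 methylation
#' mutant, pH optima moved to 4.0-5.0 for two sirtuin mutants), per-genotype
#' residual SDs spread over 0.15--0.30 mm/hr (replicate SD around 0.2),
#' missingness 19/3120, and zero-growth cells for the poorest growers in
#' their worst environments. The shape overrides give the genotype x
#' setting variance component a genuinely nonzero truth.
#'
#' @param genotypes data.frame as from [default_genotypes()].
#' @param seed master seed.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(genotypes = default_genotypes(), seed = 1L) {
  gl <- genotypes$genotype
  n <- length(gl)
  elev <- stats::setNames(rep(0, n), gl)
  mut <- setdiff(gl, "4200")
  elev[mut] <- seq(-0.45, 0.05, length.out = length(mut))
  # severe growth defects reported for these strains
  for (g in intersect(c("dim-5", "ngf-1"), gl)) elev[g] <- -1.8
  if ("npf" %in% gl) elev["npf"] <- -1.2
  sigma <- stats::setNames(seq(0.15, 0.30, length.out = n), gl)
  sigma["4200"] <- 0.2
  zg <- data.frame(
    genotype  = c("npf", "npf", "dim-5"),
    env_param = c("salt", "salt", "temperature"),
    setting   = c(1.2, 1.6, 15),
    stringsAsFactors = FALSE
  )
  zg <- zg[zg$genotype %in% gl, , drop = FALSE]
  base <- base_norm_shapes()
  overrides <- list(
    "set-2"  = list(temperature = quadratic_shape(25.3, 3.4, 0.008)),
    "qde-2"  = list(temperature = quadratic_shape(31.9, 3.8, 0.008),
                    salt = function(s) pmax(0, 3.29 - 1.7 * s + 0.3 * s^2)),
    "lid2"   = list(temperature = quadratic_shape(32.0, 3.8, 0.008)),
    "nst-6"  = list(pH = quadratic_shape(4.0, 3.1, 0.09)),
    "nst-7"  = list(pH = quadratic_shape(4.5, 3.1, 0.09)),
    "dmm-2"  = list(pH = quadratic_shape(5.0, 3.2, 0.09)),
    "elp3"   = list(pH = quadratic_shape(4.9, 3.2, 0.09)),
    "dim-5"  = list(salt = function(s) rep(0.5, length(s)))
  )
  overrides <- overrides[intersect(names(overrides), gl)]
  shapes <- function(genotype, env_param, setting) {
    f <- overrides[[genotype]][[env_param]]
    if (is.null(f)) f <- base[[env_param]]
    if (is.null(f)) stop("no norm shape for env_param '", env_param, "'")
    f(setting)
  }
  sim_config(genotype_effects = elev,
             norm_shapes = shapes,
             sigma_by_genotype = sigma,
             missing_rate = 19 / 3120,
             zero_growth_cells = if (nrow(zg)) zg else NULL,
             seed = seed)
}

#' Tabulated reaction norm with an exact spline-space optimum
#'
#' Builds a mean-rate function for parameter-recovery simulations. Starting
#' from a left-skewed thermal-performance-style curve (shallow rise below
#' the optimum, steep decline above, the canonical asymmetry of temperature
#' tolerance curves), its six tabulated grid values are projected onto the
#' natural-spline basis used by [fit_natural_spline()], and the underlying
#' peak is calibrated so that the spline-space norm has its argmax exactly
#' at `peak`. Because the resulting truth lies in the estimator's function
#' space, a noise-free fit recovers the optimum with zero bias, so recovery
#' error under noise reflects sampling variance only.
#'
#' @param peak target optimum setting.
#' @param settings the setting grid (default temperature grid).
#' @param height rate at the underlying peak (mm/hr).
#' @param c_low,c_high curvature below/above the peak.
#' @param df spline degrees of freedom (total parameters, default 5).
#' @param env_param parameter label (controls the axis transform).
#' @return list with `mean_rates` (at `settings`), `fn` (the spline-space
#'   norm as a function of setting), and `peak` (achieved argmax).
#' @export
spline_peak_norm <- function(peak, settings = default_env_params()$temperature,
                             height = 3.9, c_low = 0.008, c_high = 0.04,
                             df = 5, env_param = "temperature") {
  tpc <- function(x, p) pmax(0, height - ifelse(x < p, c_low * (p - x)^2,
                                                c_high * (x - p)^2))
  argmax_for <- function(p) {
    tab <- data.frame(genotype = "g", env_param = env_param,
                      setting = settings, replicate = 1L,
                      rate = tpc(settings, p))
    fit <- fit_natural_spline(build_norm(tab, "g", env_param), df = df)
    estimate_optimum(fit, grid_step = diff(range(settings)) / 5000)
  }
  f <- function(p) argmax_for(p)$optimum_setting - peak
  lo <- peak - 4; hi <- peak + 4
  root <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root,
                   error = function(e)
                     stop("could not calibrate a spline-space norm with its ",
                          "optimum at ", peak))
  tab <- data.frame(genotype = "g", env_param = env_param,
                    setting = settings, replicate = 1L,
                    rate = tpc(settings, root))
  fit <- fit_natural_spline(build_norm(tab, "g", env_param), df = df)
  fn <- function(s) predict(fit, s)
  list(mean_rates = fn(settings), fn = fn,
       peak = argmax_for(root)$optimum_setting)
}

resolve_shape <- function(norm_shapes, genotype, env_param, setting) {
  if (is.function(norm_shapes)) return(norm_shapes(genotype, env_param, setting))
  f <- norm_shapes[[env_param]]
  if (is.null(f)) stop("no norm shape for env_param '", env_param, "'")
  f(setting)
}

# Deterministic per-row RNG substreams: the master seed draws one 31-bit
# seed per design row, so regenerating any subset of rows reproduces them.
row_substreams <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n, replace = FALSE)
}

#' Simulate a growth-rate table over a design
#'
#' Draws one growth rate per design row: shape(genotype, parameter, setting)
#' plus the genotype's elevation shift plus Normal(0, sigma_genotype^2)
#' noise, truncated at zero. Cells listed in `zero_growth_cells` emit exactly
#' zero; each row is independently missing with `missing_rate`. The same
#' seed always reproduces the same table.
#'
#' @param config a [sim_config()].
#' @param design a design table from [enumerate_design()].
#' @return A data.frame (class `growth_rate_table`) with the design columns
#'   plus `rate` (mm/hr, NA when missing) and `missing` (logical).
#' @export
simulate_growth_rates <- function(config, design) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(design))
  unknown <- setdiff(unique(design$genotype), names(config$genotype_effects))
  if (length(unknown))
    stop("design contains genotypes absent from config: ",
         paste(unknown, collapse = ", "))
  unknown_s <- setdiff(unique(design$genotype), names(config$sigma_by_genotype))
  if (length(unknown_s))
    stop("no residual sigma for genotypes: ", paste(unknown_s, collapse = ", "))

  n <- nrow(design)
  seeds <- row_substreams(config$seed, n)
  mu <- numeric(n); rate <- numeric(n); missing <- logical(n)
  zg <- config$zero_growth_cells
  is_zero <- rep(FALSE, n)
  if (!is.null(zg) && nrow(zg)) {
    key_d <- paste(design$genotype, design$env_param, design$setting, sep = "\r")
    key_z <- paste(zg$genotype, zg$env_param, zg$setting, sep = "\r")
    is_zero <- key_d %in% key_z
  }
  for (i in seq_len(n)) {
    g <- design$genotype[i]
    mu[i] <- resolve_shape(config$norm_shapes, g, design$env_param[i],
                           design$setting[i]) + config$genotype_effects[[g]]
    set.seed(seeds[i])
    u <- stats::runif(1)
    e <- stats::rnorm(1)
    missing[i] <- u < config$missing_rate
    rate[i] <- max(0, mu[i] + config$sigma_by_genotype[[g]] * e)
  }
  rate[is_zero] <- 0
  rate[missing] <- NA_real_
  out <- design
  class(out) <- "data.frame"
  out$rate <- rate
  out$missing <- missing
  class(out) <- c("growth_rate_table", "data.frame")
  out
}

#' Simulate one race-tube position series
#'
#' Front positions are marked on an alternating 8 h / 16 h schedule (twice a
#' day) starting at inoculation. The expected position is
#' `max(0, true_rate * (t - lag))`; Gaussian marking noise is added, the
#' series is floored at zero and made non-decreasing by a cumulative
#' maximum. `first_visible_index` is the first mark at which the front is
#' genuinely visible (expected position positive; NA for a no-growth tube).
#'
#' @param true_rate linear front extension rate, mm/hr (>= 0).
#' @param lag hours before visible growth starts.
#' @param duration observation window in hours (<= 152; assays typically ran
#'   104 h, up to 152 h under osmotic stress).
#' @param noise_sd SD of the mark-position noise (mm).
#' @param seed integer seed.
#' @param assay_id label for the tube.
#' @return A list of class `race_tube_series` with `assay_id`, `mark_times`,
#'   `positions`, `first_visible_index`.
#' @export
simulate_race_tube <- function(true_rate, lag = 8, duration = 104,
                               noise_sd = 0.25, seed = 1L,
                               assay_id = "tube1") {
  if (true_rate < 0) stop("true_rate must be >= 0")
  if (duration < 0) stop("duration must be non-negative")
  if (duration > 152) stop("duration must be <= 152 hours")
  gaps <- rep(c(8, 16), length.out = 2 * ceiling(duration / 24) + 2)
  times <- c(0, cumsum(gaps))
  times <- times[times <= duration]
  mu <- pmax(0, true_rate * (times - lag))
  set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
  positions <- cummax(pmax(mu + eps, 0))
  # the front is "clearly visible" once its expected position is positive;
  # marking noise alone does not make an empty tube look inoculated
  fvi <- which(mu > 0)[1]
  structure(list(assay_id = assay_id,
                 mark_times = times,
                 positions = positions,
                 first_visible_index = if (is.na(fvi)) NA_integer_ else fvi),
            class = "race_tube_series")
}
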