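#' Build a reaction norm for one genotype and environmental parameter
#'
#' Aggregates the non-missing replicate growth rates (zero-growth assays
#' count as rate 0) into per-setting means and standard errors, keeping the
#' replicate-level data for spline fitting.
#'
#' @param table a growth-rate table (long format with `genotype`,
#'   `env_param`, `setting`, `rate`).
#' @param genotype genotype label.
#' @param env_param environmental parameter label.
#' @param min_settings minimum number of settings with data (default 4).
#' @return A list of class `reaction_norm`: `genotype`, `env_param`,
#'   `settings`, `mean_rates`, `se_rates`, `data` (replicate-level
#'   data.frame with `setting`, `rate`).
#' @export
build_norm <- function(table, genotype, env_param, min_settings = 4) {
  d <- table[table$genotype == genotype & table$env_param == env_param &
               !is.na(table$rate), c("setting", "rate")]
  full_grid <- sort(unique(
    table$setting[table$genotype == genotype & table$env_param == env_param]))
  settings <- sort(unique(d$setting))
  if (length(settings) < min_settings)
    stop("genotype '", genotype, "' has data at only ", length(settings),
         " settings of ", env_param, " (need >= ", min_settings, ")")
  if (length(settings) < length(full_grid))
    warning("genotype '", genotype, "': no data at ", env_param, " setting(s) ",
            paste(setdiff(full_grid, settings), collapse = ", "))
  means <- tapply(d$rate, factor(d$setting, levels = settings), mean)
  sds   <- tapply(d$rate, factor(d$setting, levels = settings), stats::sd)
  ns    <- tapply(d$rate, factor(d$setting, levels = settings), length)
  se <- as.numeric(sds) / sqrt(as.numeric(ns))
  se[is.na(se)] <- 0  # single replicate
  structure(list(genotype = genotype, env_param = env_param,
                 settings = settings,
                 mean_rates = as.numeric(means),
                 se_rates = se,
                 data = d[order(d$setting), , drop = FALSE]),
            class = "reaction_norm")
}

# settings axis transform: sucrose spans 3+ orders of magnitude, so its
# spline is fitted on log10(setting); other parameters stay linear.
norm_axis <- function(env_param, setting) {
  if (identical(env_param, "sucrose")) log10(setting) else setting
}
norm_axis_inverse <- function(env_param, x) {
  if (identical(env_param, "sucrose")) 10^x else x
}

ns_basis <- function(x, df, boundary, interior) {
  splines::ns(x, knots = interior, Boundary.knots = boundary)
}

#' Fit a natural cubic spline to a reaction norm
#'
#' Least-squares fit of the replicate-level rates on a natural cubic spline
#' basis with `df` free parameters in total (intercept plus `df - 1` basis
#' functions, so `df = 2` is a straight line). Interior knots sit at
#' quantiles of the distinct settings; boundary knots at the extreme
#' settings. The fit is only defined within the observed setting range:
#' natural splines do not allow extrapolation.
#'
#' @param norm a `reaction_norm` from [build_norm()].
#' @param df total degrees of freedom (>= 2, <= number of distinct
#'   settings). Default 5 (equivalently, a 4-df ns() basis plus intercept):
#'   flexible enough for curved norms while leaving residual df on a
#'   six-setting grid when fit to per-setting means.
#' @param use_replicates fit replicate-level rates (default) or the
#'   per-setting means.
#' @return A list of class `spline_fit` with the basis description,
#'   coefficients and fitting metadata. Evaluate with `predict()`.
#' @export
fit_natural_spline <- function(norm, df = 5, use_replicates = TRUE) {
  stopifnot(inherits(norm, "reaction_norm"))
  sx <- norm_axis(norm$env_param, norm$settings)
  if (df < 2) stop("df must be >= 2")
  if (df > length(sx))
    stop("df (", df, ") exceeds the number of distinct settings (",
         length(sx), ")")
  n_interior <- df - 2
  interior <- if (n_interior > 0)
    stats::quantile(sx, probs = seq_len(n_interior) / (n_interior + 1),
                    type = 7, names = FALSE)
  else
    numeric(0)
  boundary <- range(sx)
  if (use_replicates) {
    x <- norm_axis(norm$env_param, norm$data$setting)
    y <- norm$data$rate
  } else {
    x <- sx
    y <- norm$mean_rates
  }
  B <- cbind(1, ns_basis(x, df, boundary, interior))
  fit <- stats::lm.fit(B, y)
  structure(list(genotype = norm$genotype, env_param = norm$env_param,
                 coefficients = fit$coefficients,
                 interior_knots = interior, boundary_knots = boundary,
                 settings = norm$settings,
                 range = range(norm$settings),
                 df = df,
                 fitted = fit$fitted.values, residuals = fit$residuals,
                 x = x, y = y),
            class = "spline_fit")
}

#' Evaluate a fitted reaction-norm spline
#'
#' @param object a `spline_fit`.
#' @param newdata numeric settings (original units) at which to evaluate;
#'   values outside the observed setting range are an error because natural
#'   splines are not extrapolated.
#' @param ... unused.
#' @return Fitted growth rates (mm/hr).
#' @export
predict.spline_fit <- function(object, newdata, ...) {
  tol <- 1e-8 * max(1, abs(object$range))
  if (any(newdata < object$range[1] - tol | newdata > object$range[2] + tol))
    stop("no extrapolation outside the observed setting range [",
         object$range[1], ", ", object$range[2], "]")
  x <- norm_axis(object$env_param, newdata)
  B <- cbind(1, ns_basis(x, object$df, object$boundary_knots,
                         object$interior_knots))
  drop(B %*% object$coefficients)
}

#' Estimate the environmental optimum of a fitted reaction norm
#'
#' Dense grid search for the setting (original units) that maximises the
#' fitted growth rate within the observed range. Grid search is robust to
#' flat or multi-modal fits; ties break toward the lower setting.
#'
#' @param fit a `spline_fit`.
#' @param grid_step grid spacing on the (possibly log-transformed) fitting
#'   axis; default range/1000.
#' @return A list of class `optimum_estimate`: `optimum_setting`,
#'   `optimum_rate`, `at_boundary`.
#' @export
estimate_optimum <- function(fit, grid_step = NULL) {
  ax <- norm_axis(fit$env_param, fit$range)
  width <- diff(ax)
  if (is.null(grid_step)) grid_step <- width / 1000
  if (grid_step <= 0 || grid_step >= width)
    stop("grid_step must be positive and smaller than the setting range")
  grid_x <- seq(ax[1], ax[2], by = grid_step)
  if (grid_x[length(grid_x)] < ax[2]) grid_x <- c(grid_x, ax[2])
  grid_settings <- norm_axis_inverse(fit$env_param, grid_x)
  # clamp float fuzz so predict() never sees an out-of-range value
  grid_settings <- pmin(pmax(grid_settings, fit$range[1]), fit$range[2])
  yhat <- predict(fit, grid_settings)
  i <- which.max(yhat)
  structure(list(optimum_setting = grid_settings[i],
                 optimum_rate = yhat[i],
                 at_boundary = i == 1L || i == length(grid_x)),
            class = "optimum_estimate")
}

#' Elevation and shape differences between two reaction norms
#'
#' Decomposes the per-setting difference (mutant minus control) into an
#' elevation shift (the mean difference across settings, the genotypic main
#' effect) and a shape profile (the per-setting deviation from that shift,
#' the genotype-by-environment component, which sums to zero).
#'
#' @param norm mutant `reaction_norm`.
#' @param control control `reaction_norm` on the same settings grid.
#' @return list with `elevation_diff` (mm/hr) and `shape_profile` (named
#'   numeric, one entry per setting).
#' @export
elevation_and_shape <- function(norm, control) {
  stopifnot(inherits(norm, "reaction_norm"), inherits(control, "reaction_norm"))
  if (length(norm$settings) != length(control$settings) ||
      any(norm$settings != control$settings))
    stop("reaction norms are on different settings grids")
  diff <- norm$mean_rates - control$mean_rates
  elev <- mean(diff)
  shape <- diff - elev
  names(shape) <- as.character(norm$settings)
  list(elevation_diff = elev, shape_profile = shape)
}

#' Optimum table for every genotype in one environment
#'
#' Convenience wrapper: builds each genotype's norm, fits the spline and
#' locates the optimum.
#'
#' @param table growth-rate table.
#' @param env_param environmental parameter label.
#' @param df spline degrees of freedom.
#' @param grid_step passed to [estimate_optimum()].
#' @return data.frame with `genotype`, `env_param`, `optimum_setting`,
#'   `optimum_rate`, `at_boundary`.
#' @export
optimum_table <- function(table, env_param, df = 5, grid_step = NULL) {
  gens <- unique(table$genotype)
  rows <- lapply(gens, function(g) {
    opt <- estimate_optimum(
      fit_natural_spline(build_norm(table, g, env_param), df = df),
      grid_step = grid_step)
    data.frame(genotype = g, env_param = env_param,
               optimum_setting = opt$optimum_setting,
               optimum_rate = opt$optimum_rate,
               at_boundary = opt$at_boundary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
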