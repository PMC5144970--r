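#' Write a growth-rate table to CSV
#'
#' Columns: genotype, mechanism, env_param, setting, replicate,
#' rate_mm_per_hr, missing_flag.
#'
#' @param table growth-rate table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_growth_table <- function(table, path) {
  out <- data.frame(
    genotype = table$genotype, mechanism = table$mechanism,
    env_param = table$env_param, setting = table$setting,
    replicate = table$replicate,
    rate_mm_per_hr = table$rate,
    missing_flag = if ("missing" %in% names(table)) table$missing
                   else is.na(table$rate),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write race-tube series to CSV
#'
#' Long format: assay_id, time_hr, position_mm.
#'
#' @param tubes list of `race_tube_series`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_race_tubes <- function(tubes, path) {
  rows <- lapply(tubes, function(s)
    data.frame(assay_id = s$assay_id, time_hr = s$mark_times,
               position_mm = s$positions, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a phenotype table
#'
#' Reads either a long-format growth-rate CSV (`schema = "rates"`, columns
#' genotype, mechanism, env_param, setting, replicate, rate_mm_per_hr,
#' optional missing_flag) or a race-tube mark CSV (`schema = "racetube"`,
#' columns assay_id, time_hr, position_mm). Malformed rows are collected
#' into an attached error report rather than silently dropped; settings
#' outside the published grids trigger a warning.
#'
#' @param path CSV file.
#' @param schema `"rates"` or `"racetube"`.
#' @param column_map optional named character vector mapping required column
#'   names to the names actually used in the file, e.g.
#'   `c(rate_mm_per_hr = "growth_rate")`.
#' @return For `"rates"`, a `growth_rate_table` with attribute `"errors"`
#'   (data.frame of rejected rows). For `"racetube"`, a named list of
#'   `race_tube_series`.
#' @export
read_phenotype_table <- function(path, schema = c("rates", "racetube"),
                                 column_map = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(column_map))
    for (std in names(column_map)) {
      i <- match(column_map[[std]], names(raw))
      if (!is.na(i)) names(raw)[i] <- std
    }
  required <- if (schema == "rates")
    c("genotype", "mechanism", "env_param", "setting", "replicate",
      "rate_mm_per_hr")
  else
    c("assay_id", "time_hr", "position_mm")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  if (schema == "rates") {
    setting <- suppressWarnings(as.numeric(raw$setting))
    replicate <- suppressWarnings(as.integer(raw$replicate))
    rate_chr <- raw$rate_mm_per_hr
    rate <- suppressWarnings(as.numeric(rate_chr))
    missing_flag <- if ("missing_flag" %in% names(raw))
      tolower(raw$missing_flag) %in% c("true", "1", "t") else is.na(rate) & !nzchar(rate_chr)
    bad_rate <- !is.na(rate_chr) & nzchar(rate_chr) & is.na(rate)
    bad <- is.na(setting) | is.na(replicate) | bad_rate |
      (is.na(rate) & !missing_flag & nzchar(rate_chr))
    errors <- cbind(row = which(bad), raw[bad, , drop = FALSE])
    ok <- !bad
    out <- data.frame(genotype = raw$genotype[ok],
                      mechanism = raw$mechanism[ok],
                      env_param = raw$env_param[ok],
                      setting = setting[ok],
                      replicate = replicate[ok],
                      rate = rate[ok],
                      missing = missing_flag[ok] | is.na(rate[ok]),
                      stringsAsFactors = FALSE)
    grids <- default_env_params()
    for (p in intersect(unique(out$env_param), names(grids))) {
      s <- unique(out$setting[out$env_param == p])
      off <- setdiff(s, grids[[p]])
      if (length(off))
        warning("settings outside the published ", p, " grid: ",
                paste(off, collapse = ", "))
    }
    class(out) <- c("growth_rate_table", "data.frame")
    attr(out, "errors") <- errors
    return(out)
  }

  time_hr <- suppressWarnings(as.numeric(raw$time_hr))
  pos <- suppressWarnings(as.numeric(raw$position_mm))
  bad <- is.na(time_hr) | is.na(pos)
  errors <- cbind(row = which(bad), raw[bad, , drop = FALSE])
  ok <- which(!bad)
  tubes <- lapply(split(ok, raw$assay_id[ok]), function(i) {
    o <- i[order(time_hr[i])]
    structure(list(assay_id = raw$assay_id[o[1]],
                   mark_times = time_hr[o], positions = pos[o],
                   first_visible_index = NA_integer_),
              class = "race_tube_series")
  })
  attr(tubes, "errors") <- errors
  tubes
}

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param control control genotype label.
#' @param input optional CSV path of an existing growth-rate table; when
#'   NULL the synthetic generator supplies the data.
#' @param stages character subset of `c("norms", "anova", "contrasts")`.
#' @param spline_df spline degrees of freedom.
#' @param contrast_cells data.frame of (env_param, setting) cells for the
#'   Bayesian stage; defaults to 0.8 M NaCl and 40 degrees.
#' @param mcmc an [mcmc_config()]; chains/iterations can be reduced for
#'   quick runs.
#' @param alpha significance level.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, control = "4200",
                            input = NULL,
                            stages = c("norms", "anova", "contrasts"),
                            spline_df = 5,
                            contrast_cells = data.frame(
                              env_param = c("salt", "temperature"),
                              setting = c(0.8, 40)),
                            mcmc = mcmc_config(n_chains = 3, burn_in = 2000,
                                               n_saved = 1000, thin = 2,
                                               seed = seed),
                            alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 control = control, input = input, stages = stages,
                 spline_df = spline_df, contrast_cells = contrast_cells,
                 mcmc = mcmc, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> reaction-norm optima -> mixed-model ANOVA ->
#' Bayesian contrasts, writing every intermediate artifact under
#' `config$out_dir` and returning a run report. A fixed seed yields an
#' identical report.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  report <- list(seed = config$seed,
                 version = as.character(utils::packageVersion("plastinorm")))
  res <- try({
    table <- if (is.null(config$input)) {
      design <- enumerate_design()
      simulate_growth_rates(default_sim_config(seed = config$seed), design)
    } else {
      read_phenotype_table(config$input, "rates")
    }
    write_growth_table(table, file.path(config$out_dir, "growth_rates.csv"))
    report$n_rows <- nrow(table)
    report$qc <- qc_summary(table)

    if ("norms" %in% config$stages) {
      stage <- "norms"
      opts <- do.call(rbind, lapply(unique(table$env_param), function(p)
        optimum_table(table, p, df = config$spline_df)))
      utils::write.csv(opts, file.path(config$out_dir, "optima.csv"),
                       row.names = FALSE)
      report$optima <- opts
    }

    if ("anova" %in% config$stages) {
      stage <- "anova"
      fit <- fit_mixed_model(table, "eq1")
      fixed <- type3_tests(fit)
      rand <- random_effects_tests(fit)
      utils::write.csv(fixed, file.path(config$out_dir, "anova_fixed.csv"),
                       row.names = FALSE)
      utils::write.csv(rand, file.path(config$out_dir, "anova_random.csv"),
                       row.names = FALSE)
      pw <- do.call(rbind, lapply(unique(table$env_param), function(p) {
        t <- pairwise_control_tests(table, config$control, p, config$alpha)
        cbind(env_param = p, as.data.frame(t))
      }))
      utils::write.csv(pw, file.path(config$out_dir, "pairwise.csv"),
                       row.names = FALSE)
      report$anova_fixed <- fixed
      report$anova_random <- rand
      report$n_significant_pairwise <- sum(pw$significant)
    }

    if ("contrasts" %in% config$stages) {
      stage <- "contrasts"
      ct <- do.call(rbind, lapply(seq_len(nrow(config$contrast_cells)),
        function(i) {
          p <- config$contrast_cells$env_param[i]
          s <- config$contrast_cells$setting[i]
          dr <- sample_posterior(table, p, s, cfg = config$mcmc)
          cbind(env_param = p, setting = s,
                contrast_table(dr, config$control))
        }))
      utils::write.csv(ct, file.path(config$out_dir, "contrasts.csv"),
                       row.names = FALSE)
      report$contrasts <- ct
      report$n_significant_contrasts <- sum(ct$significant)
    }
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed in stage '", stage, "': ",
         attr(res, "condition")$message)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("plastinorm run report (seed", x$seed, ", version", x$version, ")\n")
  cat("  input rows:", x$n_rows, "\n")
  cat("  missing assays:", x$qc$n_missing,
      " zero-growth:", x$qc$n_zero_growth, "\n")
  if (!is.null(x$optima))
    cat("  optima estimated for", nrow(x$optima), "genotype x parameter norms\n")
  if (!is.null(x$n_significant_pairwise))
    cat("  significant pairwise interaction tests:",
        x$n_significant_pairwise, "\n")
  if (!is.null(x$n_significant_contrasts))
    cat("  significant Bayesian contrasts:", x$n_significant_contrasts, "\n")
  invisible(x)
}
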