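#' Estimate a growth rate from one race-tube series
#'
#' Ordinary least-squares regression of front position (mm) on time (hr),
#' using marks from the first clearly visible front onward; the slope is the
#' mycelial growth rate in mm/hr. Growth before the front is visible is
#' discarded, which corrects for differences in initial growth due to
#' inoculum size. A tube whose positions are all zero is assigned rate zero
#' (`zero_growth = TRUE`, R^2 undefined). A tube with fewer than two usable
#' marks that is not all-zero is flagged invalid.
#'
#' @param series a `race_tube_series` (list with `mark_times`, `positions`,
#'   and optionally `first_visible_index`).
#' @param visibility_threshold when `first_visible_index` is absent/NA, the
#'   first mark with position strictly above this many mm starts the fit
#'   window (default 1 mm).
#' @return A one-row data.frame (class `growth_rate_record`): `assay_id`,
#'   `rate`, `intercept`, `r_squared`, `n_marks_used`, `zero_growth`,
#'   `valid`.
#' @export
estimate_growth_rate <- function(series, visibility_threshold = 1) {
  t <- series$mark_times
  p <- series$positions
  stopifnot(length(t) == length(p))
  id <- if (!is.null(series$assay_id)) series$assay_id else NA_character_
  rec <- function(rate, intercept, r2, n_used, zero, valid) {
    structure(data.frame(assay_id = id, rate = rate, intercept = intercept,
                         r_squared = r2, n_marks_used = n_used,
                         zero_growth = zero, valid = valid,
                         stringsAsFactors = FALSE),
              class = c("growth_rate_record", "data.frame"))
  }
  if (all(p == 0))
    return(rec(0, 0, NA_real_, 0L, TRUE, TRUE))

  fvi <- series$first_visible_index
  if (is.null(fvi) || is.na(fvi))
    fvi <- which(p > visibility_threshold)[1]
  if (is.na(fvi)) fvi <- 1L
  use <- seq(fvi, length(t))
  if (length(use) < 2L)
    return(rec(NA_real_, NA_real_, NA_real_, length(use), FALSE, FALSE))

  tt <- t[use]; pp <- p[use]
  fit <- stats::lm.fit(cbind(1, tt), pp)
  slope <- fit$coefficients[2]
  rss <- sum(fit$residuals^2)
  tss <- sum((pp - mean(pp))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  rec(unname(slope), unname(fit$coefficients[1]), r2, length(use),
      FALSE, TRUE)
}

#' Estimate growth rates for a collection of race tubes
#'
#' @param tubes list of `race_tube_series`.
#' @param design optional design table whose rows (in order) correspond to
#'   the tubes; its key columns are bound to the rate records.
#' @param visibility_threshold passed to [estimate_growth_rate()].
#' @return data.frame of stacked growth-rate records (plus design keys).
#' @export
estimate_growth_rates <- function(tubes, design = NULL,
                                  visibility_threshold = 1) {
  recs <- do.call(rbind, lapply(tubes, estimate_growth_rate,
                                visibility_threshold = visibility_threshold))
  if (!is.null(design)) {
    stopifnot(nrow(design) == nrow(recs))
    recs <- cbind(as.data.frame(design), recs)
  }
  recs
}

#' Quality-control summary of a growth-rate table
#'
#' Reports the 2.5%, 50% and 97.5% quantiles of the per-assay R^2 of the
#' linear fits (over records where R^2 is defined), plus counts of
#' zero-growth and missing assays.
#'
#' @param table data.frame with at least a `rate` column; `r_squared`,
#'   `zero_growth` and `missing` columns are used when present.
#' @return list with `r2_quantiles` (named numeric length 3),
#'   `n_zero_growth`, `n_missing`.
#' @export
qc_summary <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("qc_summary needs a non-empty table")
  r2 <- if ("r_squared" %in% names(table)) table$r_squared else numeric(0)
  r2 <- r2[!is.na(r2)]
  q <- if (length(r2))
    stats::quantile(r2, c(0.025, 0.5, 0.975), type = 7)
  else
    stats::setNames(rep(NA_real_, 3), c("2.5%", "50%", "97.5%"))
  n_zero <- if ("zero_growth" %in% names(table))
    sum(table$zero_growth, na.rm = TRUE)
  else
    sum(table$rate == 0, na.rm = TRUE)
  n_missing <- if ("missing" %in% names(table))
    sum(table$missing, na.rm = TRUE)
  else
    sum(is.na(table$rate))
  list(r2_quantiles = q, n_zero_growth = n_zero, n_missing = n_missing)
}
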