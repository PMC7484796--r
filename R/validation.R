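#' Coefficient of variation and accuracy helpers
#'
#' `cv_percent()` is `100 * sd / mean` (sample SD convention, n-1
#' denominator when computed from raw replicates); `accuracy_percent()` is
#' `100 * mean / nominal`. Both accept printed summary statistics, so the
#' cells of a published validation table can be recomputed directly.
#'
#' @param sd,mean,nominal Numeric scalars.
#' @return Numeric scalar in percent.
#' @examples
#' cv_percent(0.1378, 9.880)        # 1.395 (3 dp)
#' accuracy_percent(10.016, 10)     # 100.160
#' @export
cv_percent <- function(sd, mean) {
  check_that(is_number(sd) && sd >= 0, "'sd' must be non-negative")
  check_that(is_number(mean) && mean != 0, "'mean' must be non-zero")
  100 * sd / mean
}

#' @rdname cv_percent
#' @export
accuracy_percent <- function(mean, nominal) {
  check_that(is_number(mean), "'mean' must be a number")
  check_that(is_number(nominal) && nominal > 0, "'nominal' must be positive")
  100 * mean / nominal
}

#' Accuracy and precision of a replicate set
#'
#' Mean, sample standard deviation, precision as CV% and accuracy as
#' percent of nominal for a set of replicate measurements of one QC level.
#'
#' @param values Measured concentrations (ng/ml), at least 2 replicates.
#' @param nominal Nominal (spiked) concentration, > 0.
#' @return List with `mean`, `sd`, `cv_pct`, `accuracy_pct`, `n`.
#' @examples
#' accuracy_precision(c(9.9, 10.1, 10.0, 9.8, 10.2), nominal = 10)
#' @export
accuracy_precision <- function(values, nominal) {
  check_that(is.numeric(values) && length(values) >= 2 && all(is.finite(values)),
             "'values' must be >= 2 finite replicates")
  check_that(is_number(nominal) && nominal > 0, "'nominal' must be positive")
  m <- mean(values)
  check_that(m != 0, "zero mean: CV undefined")
  s <- stats::sd(values)
  list(mean = m, sd = s, cv_pct = cv_percent(s, m),
       accuracy_pct = accuracy_percent(m, nominal), n = length(values))
}

#' Analytical recovery
#'
#' Percent recovery of analyte response in matrix (plasma) relative to the
#' same concentration in neat solvent/mobile phase, `100 * matrix / ref`.
#' With replicate vectors of paired responses, `recovery_summary()` returns
#' the mean recovery with its CV.
#'
#' @param matrix_response,reference_response Peak responses (or response
#'   ratios); the reference must be positive.
#' @return `recovery()`: numeric recovery in percent (vectorized).
#'   `recovery_summary()`: list with `mean_recovery_pct`, `cv_pct`, `n`.
#' @examples
#' recovery(0.95, 1)  # 95
#' @export
recovery <- function(matrix_response, reference_response) {
  check_that(is.numeric(matrix_response) && is.numeric(reference_response),
             "responses must be numeric")
  check_that(all(reference_response > 0), "reference response must be positive")
  100 * matrix_response / reference_response
}

#' @rdname recovery
#' @export
recovery_summary <- function(matrix_response, reference_response) {
  check_that(length(matrix_response) == length(reference_response) &&
               length(matrix_response) >= 2,
             "need >= 2 paired responses")
  r <- recovery(matrix_response, reference_response)
  list(mean_recovery_pct = mean(r), cv_pct = cv_percent(stats::sd(r), mean(r)),
       n = length(r))
}

#' Calibration linearity by least squares
#'
#' Ordinary least-squares line of detector response on concentration with
#' the coefficient of determination, for calibration-curve assessment over
#' the validated range.
#'
#' @param concs Concentrations (>= 3 distinct values).
#' @param responses Detector responses, same length.
#' @return List with `slope`, `intercept`, `r2`, `n`.
#' @export
linearity <- function(concs, responses) {
  check_that(is.numeric(concs) && is.numeric(responses) &&
               length(concs) == length(responses),
             "'concs' and 'responses' must be numeric of equal length")
  check_that(length(unique(concs)) >= 3,
             "need at least 3 distinct concentrations")
  fit <- stats::lm(responses ~ concs)
  co <- stats::coef(fit)
  tss <- sum((responses - mean(responses))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
       n = length(concs))
}

#' Flag concentrations outside the validated calibration range
#'
#' @param conc Concentrations to check (ng/ml).
#' @param lower,upper Validated range bounds; defaults 10--200 ng/ml.
#' @return Logical vector, `TRUE` when inside the range (inclusive).
#' @export
in_calibration_range <- function(conc, lower = 10, upper = 200) {
  check_that(is.numeric(conc), "'conc' must be numeric")
  conc >= lower & conc <= upper
}

#' Signal-to-noise quantification and detection limits
#'
#' A response is satisfactory for the lower limit of quantification when
#' signal/noise >= 7, and acceptable for the lower limit of detection when
#' signal/noise >= 3.
#'
#' @param signal,noise Peak signal and baseline noise; noise must be
#'   positive.
#' @return List with `snr`, `meets_lloq`, `meets_llod`.
#' @examples
#' snr_limits(7, 1)  # LLOQ pass
#' @export
snr_limits <- function(signal, noise) {
  check_that(is_number(signal) && signal >= 0, "'signal' must be non-negative")
  check_that(is_number(noise) && noise > 0, "'noise' must be positive")
  snr <- signal / noise
  list(snr = snr, meets_lloq = snr >= 7, meets_llod = snr >= 3)
}

#' Mean degradation between stability and baseline
#'
#' Percent loss of the stored-sample mean relative to the baseline mean,
#' `100 * (baseline - stability) / baseline`. Apparent gains are reported
#' as negative values, not clipped.
#'
#' @param stability_mean Mean measured concentration after storage.
#' @param baseline_mean Baseline (time-zero) mean, > 0.
#' @return Degradation in percent.
#' @export
degradation <- function(stability_mean, baseline_mean) {
  check_that(is_number(stability_mean), "'stability_mean' must be a number")
  check_that(is_number(baseline_mean) && baseline_mean > 0,
             "'baseline_mean' must be positive")
  100 * (baseline_mean - stability_mean) / baseline_mean
}

#' Shelf-life from a stability regression
#'
#' Single-batch shelf-life estimate in the ICH Q1E mean-response style:
#' ordinary least squares of assay (% label claim) on storage time, with
#' shelf life the earliest time at which the one-sided lower `confidence`
#' bound on the mean response crosses the acceptance limit (default 90% of
#' label claim). The crossing is located numerically to 0.01-month
#' resolution. With zero residual noise the bound degenerates to the
#' fitted line and the crossing has the closed form
#' `(intercept - limit) / |slope|`. Flat or improving trends whose bound
#' never crosses within `horizon` are reported as censored
#' (`> horizon`).
#'
#' @param times_months Storage times in months (>= 3 points).
#' @param assay_pct Assay values in percent of label claim.
#' @param acceptance_limit Lower acceptance limit, default 90.
#' @param confidence One-sided confidence level for the bound, default 0.95.
#' @param horizon Largest shelf life searched, in months (default 120).
#' @return Object of class `shelf_life`: list with `shelf_life_months`
#'   (NA when censored), `censored`, `slope`, `intercept`, `horizon`.
#' @examples
#' shelf_life(c(0, 3, 6), c(100, 99.4, 98.8))
#' @export
shelf_life <- function(times_months, assay_pct, acceptance_limit = 90,
                       confidence = 0.95, horizon = 120) {
  check_that(is.numeric(times_months) && is.numeric(assay_pct) &&
               length(times_months) == length(assay_pct),
             "'times_months' and 'assay_pct' must be numeric of equal length")
  check_that(length(times_months) >= 3,
             "need at least 3 stability time points")
  check_that(all(diff(sort(times_months)) >= 0) && all(times_months >= 0),
             "times must be non-negative")
  check_that(is_number(acceptance_limit) && acceptance_limit > 0,
             "'acceptance_limit' must be positive")
  fit <- stats::lm(assay_pct ~ times_months)
  co <- stats::coef(fit)
  df <- fit$df.residual
  s2 <- if (df > 0) sum(stats::residuals(fit)^2) / df else 0
  n <- length(times_months)
  tbar <- mean(times_months)
  sxx <- sum((times_months - tbar)^2)
  tcrit <- if (df > 0 && s2 > 0) stats::qt(confidence, df) else 0
  lower_bound <- function(t) {
    pred <- co[1] + co[2] * t
    se <- if (s2 > 0) sqrt(s2 * (1 / n + (t - tbar)^2 / sxx)) else 0
    pred - tcrit * se
  }
  grid <- seq(0, horizon, by = 0.01)
  lb <- lower_bound(grid)
  below <- which(lb <= acceptance_limit)
  if (!length(below)) {
    return(structure(list(shelf_life_months = NA_real_, censored = TRUE,
                          slope = unname(co[2]), intercept = unname(co[1]),
                          horizon = horizon), class = "shelf_life"))
  }
  i <- below[1]
  sl <- if (i == 1) 0 else {
    root <- stats::uniroot(function(t) lower_bound(t) - acceptance_limit,
                           interval = c(grid[i - 1], grid[i]),
                           tol = 1e-6)$root
    round(root, 2)
  }
  structure(list(shelf_life_months = sl, censored = FALSE,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 horizon = horizon), class = "shelf_life")
}

#' @export
print.shelf_life <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Shelf life > %g months (bound never crosses limit)\n",
                x$horizon))
  } else {
    cat(sprintf("Shelf life: %.2f months (slope %.4g %%/month)\n",
                x$shelf_life_months, x$slope))
  }
  invisible(x)
}
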