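check_crossover <- function(data) {
  need <- c("subject", "sequence", "period", "treatment", "value")
  check_that(is.data.frame(data) && all(need %in% names(data)),
             paste("crossover data needs columns:", paste(need, collapse = ", ")))
  check_that(all(data$value > 0),
             "all parameter values must be strictly positive (log is taken)")
  check_that(all(data$treatment %in% c("R", "T")),
             "treatment must be coded 'R' (reference) / 'T' (test)")
  tab <- table(data$subject, data$treatment)
  bad <- rownames(tab)[rowSums(tab != 1) > 0]
  if (length(bad)) {
    stop("each subject must appear exactly once per treatment; offenders: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq_per_subj <- tapply(as.character(data$sequence), data$subject,
                         function(s) length(unique(s)))
  check_that(all(seq_per_subj == 1), "a subject cannot change sequence")
  invisible(data)
}

#' Crossover ANOVA on log-transformed PK parameters
#'
#' Two-way fixed-effects analysis of variance for a two-treatment,
#' two-sequence crossover on `ln(value)`: effects for sequence, subject
#' nested in sequence, period and treatment, with sums of squares from the
#' sequential least-squares decomposition (orthogonal for balanced data).
#' Sequence is tested against the subject-within-sequence mean square;
#' period and treatment against the residual mean square.
#'
#' @param data Data frame with columns `subject`, `sequence`, `period`,
#'   `treatment` (`"R"`/`"T"`), `value` (> 0); one row per
#'   subject-treatment.
#' @return Object of class `crossover_anova`: list with `table` (effect,
#'   df, ss, ms, f, p), `mse`, `df_residual`, `delta` (adjusted ln(T)-ln(R)
#'   contrast), `se_delta`, `n_subjects`.
#' @export
crossover_anova <- function(data) {
  data <- check_crossover(data)
  d <- data.frame(
    lny = log(data$value),
    sequence = factor(data$sequence),
    subject = factor(data$subject),
    period = factor(data$period),
    treatment = factor(data$treatment, levels = c("R", "T"))
  )
  fit <- stats::lm(lny ~ sequence + subject + period + treatment, data = d)
  # zero-residual (degenerate) data are legitimate here and flagged below;
  # silence the perfect-fit caveat stats::anova attaches to them
  a <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ss <- a$`Sum Sq`
  df <- a$Df
  names(ss) <- names(df) <- rownames(a)
  n_sub <- nlevels(d$subject)
  df_res <- df[["Residuals"]]
  mse <- if (df_res > 0) ss[["Residuals"]] / df_res else 0
  ms_subj <- ss[["subject"]] / df[["subject"]]
  eff <- c("sequence", "subject", "period", "treatment")
  ms <- ss[eff] / df[eff]
  # a zero-variance numerator is a zero F even on degenerate zero-MSE data;
  # "zero" is judged relative to the total variation to absorb round-off
  tol_ss <- 1e-10 * max(sum(ss), .Machine$double.xmin)
  fratio <- function(num, den) {
    if (num <= tol_ss) 0 else if (den > tol_ss) num / den else Inf
  }
  f <- c(sequence = fratio(ms[["sequence"]], ms_subj),
         subject = fratio(ms[["subject"]], mse),
         period = fratio(ms[["period"]], mse),
         treatment = fratio(ms[["treatment"]], mse))
  fdf2 <- c(sequence = df[["subject"]], subject = df_res, period = df_res,
            treatment = df_res)
  p <- vapply(eff, function(e) {
    if (is.na(f[[e]]) || !is.finite(f[[e]])) NA_real_ else
      stats::pf(f[[e]], df[[e]], fdf2[[e]], lower.tail = FALSE)
  }, numeric(1))
  tab <- data.frame(effect = c(eff, "residual"),
                    df = c(df[eff], df_res),
                    ss = c(ss[eff], ss[["Residuals"]]),
                    ms = c(ms, mse),
                    f = c(f, NA_real_),
                    p = c(p, NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  cf <- stats::coef(fit)
  delta <- unname(cf[["treatmentT"]])
  # SE from the unscaled covariance of the pivoted QR (avoids summary.lm's
  # perfect-fit warning on degenerate zero-residual data)
  p_rank <- fit$rank
  piv <- fit$qr$pivot[seq_len(p_rank)]
  rmat <- qr.R(fit$qr)[seq_len(p_rank), seq_len(p_rank), drop = FALSE]
  xtx_inv <- chol2inv(rmat)
  idx <- which(names(cf)[piv] == "treatmentT")
  se_delta <- sqrt(max(mse, 0) * xtx_inv[idx, idx])
  structure(list(table = tab, mse = unname(mse), df_residual = unname(df_res),
                 delta = delta, se_delta = se_delta, n_subjects = n_sub,
                 degenerate = unname(mse) <= tol_ss),
            class = "crossover_anova")
}

#' @export
print.crossover_anova <- function(x, ...) {
  cat("Crossover ANOVA on ln(value):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("residual MSE = %.6g on %d df; treatment contrast = %.5f\n",
              x$mse, x$df_residual, x$delta))
  invisible(x)
}

#' Bioequivalence decision from a 90% confidence interval
#'
#' Average bioequivalence passes when the whole 90% CI of the geometric
#' mean ratio lies inside the acceptance limits (closed interval: touching
#' a boundary counts as a pass).
#'
#' @param ci90 Numeric length-2 vector `(lower, upper)`.
#' @param limits Acceptance limits, default `c(0.8, 1.25)`.
#' @return List with logical `pass` and a one-line `narrative`.
#' @examples
#' be_decision(c(0.95, 1.05))$pass
#' @export
be_decision <- function(ci90, limits = c(0.8, 1.25)) {
  check_that(is.numeric(ci90) && length(ci90) == 2 && ci90[1] <= ci90[2],
             "'ci90' must be (lower, upper) with lower <= upper")
  check_that(is.numeric(limits) && length(limits) == 2 && limits[1] < limits[2],
             "'limits' must be (lower, upper)")
  pass <- ci90[1] >= limits[1] && ci90[2] <= limits[2]
  narrative <- sprintf(
    "90%% CI %.4f-%.4f %s the %.3f-%.3f acceptance range: %s",
    ci90[1], ci90[2], if (pass) "lies within" else "falls outside",
    limits[1], limits[2],
    if (pass) "average bioequivalence concluded" else "bioequivalence not shown")
  list(pass = pass, narrative = narrative)
}

#' Geometric mean ratio with 90% confidence interval
#'
#' GMR of test over reference from the adjusted treatment contrast of the
#' crossover ANOVA, `exp(delta)`, with
#' `CI = exp(delta +/- t(0.05, df_res) * SE(delta))`; for a balanced 2x2
#' design `SE = sqrt(2 * MSE / n)`. Degenerate zero-residual data yield a
#' point interval with a warning rather than an error.
#'
#' @inheritParams crossover_anova
#' @param parameter Label of the analysed PK parameter.
#' @param limits Acceptance limits for the TOST decision.
#' @return Object of class `be_result`: `parameter`, `gmr`, `ci90`,
#'   `anova` (the `crossover_anova` object), `tost_pass`, `limits`,
#'   `n_subjects`.
#' @export
gmr_ci <- function(data, parameter = "parameter", limits = c(0.8, 1.25)) {
  an <- crossover_anova(data)
  if (an$degenerate) {
    warning("zero residual variance: degenerate point confidence interval",
            call. = FALSE)
  }
  tcrit <- if (an$df_residual > 0) stats::qt(0.95, an$df_residual) else 0
  lo <- exp(an$delta - tcrit * an$se_delta)
  hi <- exp(an$delta + tcrit * an$se_delta)
  dec <- be_decision(c(lo, hi), limits)
  structure(list(parameter = parameter, gmr = exp(an$delta),
                 ci90 = c(lo, hi), anova = an, tost_pass = dec$pass,
                 limits = limits, n_subjects = an$n_subjects),
            class = "be_result")
}

#' @export
print.be_result <- function(x, ...) {
  cat(sprintf("%s: GMR %.4f, 90%% CI %.4f-%.4f -> %s\n", x$parameter,
              x$gmr, x$ci90[1], x$ci90[2],
              if (x$tost_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Bioequivalence report across PK parameters
#'
#' Runs [gmr_ci()] for every parameter of one (or two) crossover datasets
#' and assembles a wide report: one row per parameter per study part with
#' GMR, 90% CI and the TOST outcome.
#'
#' @param part1_data Data frame with columns `subject`, `sequence`,
#'   `period`, `treatment`, `parameter`, `value` (long over parameters).
#' @param part2_data Optional second dataset of the same shape (e.g. a
#'   fed/fasted comparison).
#' @param limits Acceptance limits.
#' @return Object of class `be_report`: data frame with columns `part`,
#'   `parameter`, `gmr`, `ci90_low`, `ci90_high`, `pass`, plus attribute
#'   `results` holding the full `be_result` objects.
#' @export
be_report <- function(part1_data, part2_data = NULL, limits = c(0.8, 1.25)) {
  one_part <- function(data, part) {
    check_that("parameter" %in% names(data),
               "long dataset needs a 'parameter' column")
    pars <- unique(data$parameter)
    res <- lapply(pars, function(p) {
      gmr_ci(data[data$parameter == p, ], parameter = p, limits = limits)
    })
    names(res) <- pars
    tab <- data.frame(part = part, parameter = pars,
                      gmr = vapply(res, function(r) r$gmr, numeric(1)),
                      ci90_low = vapply(res, function(r) r$ci90[1], numeric(1)),
                      ci90_high = vapply(res, function(r) r$ci90[2], numeric(1)),
                      pass = vapply(res, function(r) r$tost_pass, logical(1)),
                      row.names = NULL, stringsAsFactors = FALSE)
    list(tab = tab, res = res)
  }
  p1 <- one_part(part1_data, 1L)
  out <- p1$tab
  results <- list(part1 = p1$res)
  if (!is.null(part2_data)) {
    p2 <- one_part(part2_data, 2L)
    out <- rbind(out, p2$tab)
    results$part2 <- p2$res
  }
  structure(out, results = results, class = c("be_report", "data.frame"))
}

#' @export
print.be_report <- function(x, ...) {
  cat("Average bioequivalence report (GMR with 90% CI):\n")
  print(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}

#' Summary-level mean-ratio point estimates
#'
#' Ratios of published arithmetic means, test over reference, per
#' parameter. This is a summary-level reconstruction: without
#' subject-level data it reproduces only the point estimates of a
#' bioequivalence table, not the confidence intervals, and is labelled
#' accordingly. It is not a substitute for the subject-level geometric
#' mean ratio of [gmr_ci()].
#'
#' @param reference_means,test_means Named numeric vectors of arithmetic
#'   means with identical names (the PK parameters).
#' @return Data frame with columns `parameter`, `reference_mean`,
#'   `test_mean`, `ratio`; attribute `level` is `"summary"`.
#' @examples
#' mean_ratio_be(c(cmax = 98.0512), c(cmax = 84.0517))
#' @export
mean_ratio_be <- function(reference_means, test_means) {
  check_that(is.numeric(reference_means) && is.numeric(test_means) &&
               length(reference_means) == length(test_means),
             "mean vectors must be numeric and of equal length")
  check_that(!is.null(names(reference_means)) &&
               identical(names(reference_means), names(test_means)),
             "mean vectors must carry identical parameter names")
  check_that(all(reference_means > 0), "reference means must be positive")
  out <- data.frame(parameter = names(reference_means),
                    reference_mean = unname(reference_means),
                    test_mean = unname(test_means),
                    ratio = unname(test_means / reference_means),
                    stringsAsFactors = FALSE)
  attr(out, "level") <- "summary"
  out
}
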