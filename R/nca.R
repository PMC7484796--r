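#' Area under a concentration-time curve
#'
#' Trapezoidal AUC from time 0 to `t_end`. The default `"linear"` method
#' applies the linear trapezoidal rule on every segment; `"linuplogdown"`
#' uses the log-trapezoidal rule on segments where concentration declines
#' between two positive values. `aumc_trapezoid()` computes the first
#' moment (ordinates `t * C(t)`; for log-down segments the matching
#' closed-form moment integral is used).
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param conc Concentrations (ng/ml), non-negative.
#' @param t_end Upper limit; defaults to the last sampling time, must lie
#'   within the sampled range. A non-sampled `t_end` is handled by linear
#'   interpolation of the ordinate.
#' @param method `"linear"` (default) or `"linuplogdown"`.
#' @return AUC in ng/ml*h (or AUMC in ng/ml*h^2).
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 10, 0))  # 10
#' @export
auc_trapezoid <- function(times, conc, t_end = max(times), method = "linear") {
  check_ct(times, conc)
  method <- match.arg(method, c("linear", "linuplogdown"))
  check_that(is_number(t_end) && t_end >= times[1] && t_end <= max(times),
             "'t_end' must lie within the sampled range")
  tt <- times[times < t_end]
  cc <- conc[times < t_end]
  tt <- c(tt, t_end)
  cc <- c(cc, stats::approx(times, conc, xout = t_end)$y)
  total <- 0
  for (i in seq_len(length(tt) - 1)) {
    dt <- tt[i + 1] - tt[i]
    c1 <- cc[i]; c2 <- cc[i + 1]
    seg <- if (method == "linuplogdown" && c1 > c2 && c2 > 0) {
      dt * (c1 - c2) / log(c1 / c2)
    } else {
      dt * (c1 + c2) / 2
    }
    total <- total + seg
  }
  total
}

#' @rdname auc_trapezoid
#' @export
aumc_trapezoid <- function(times, conc, t_end = max(times), method = "linear") {
  check_ct(times, conc)
  method <- match.arg(method, c("linear", "linuplogdown"))
  check_that(is_number(t_end) && t_end >= times[1] && t_end <= max(times),
             "'t_end' must lie within the sampled range")
  tt <- times[times < t_end]
  cc <- conc[times < t_end]
  tt <- c(tt, t_end)
  cc <- c(cc, stats::approx(times, conc, xout = t_end)$y)
  total <- 0
  for (i in seq_len(length(tt) - 1)) {
    t1 <- tt[i]; t2 <- tt[i + 1]
    c1 <- cc[i]; c2 <- cc[i + 1]
    dt <- t2 - t1
    seg <- if (method == "linuplogdown" && c1 > c2 && c2 > 0) {
      k <- log(c1 / c2) / dt
      (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      dt * (t1 * c1 + t2 * c2) / 2
    }
    total <- total + seg
  }
  total
}

check_ct <- function(times, conc) {
  check_that(is.numeric(times) && is.numeric(conc) &&
               length(times) == length(conc) && length(times) >= 2,
             "'times' and 'conc' must be numeric vectors of equal length >= 2")
  check_that(all(is.finite(times)) && all(is.finite(conc)),
             "non-finite values in concentration-time data")
  check_that(all(diff(times) > 0), "'times' must be strictly increasing")
  check_that(all(conc >= 0), "concentrations must be non-negative")
  invisible(TRUE)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression on a terminal subset of the profile. Candidate
#' subsets are the contiguous terminal windows of the last 3..m positive
#' concentrations strictly after Tmax (the Cmax point itself is excluded);
#' the window maximizing adjusted R-squared is selected, preferring more
#' points when within 1e-4. Windows with non-negative slope are discarded.
#'
#' @inheritParams auc_trapezoid
#' @return List with `kel` (1/h), `t_half` (h), `points_used` (indices into
#'   the input vectors), `r2adj`, `intercept` (log scale), and logical
#'   `ok`. On failure `ok = FALSE` and the estimates are `NA`.
#' @examples
#' t <- seq(2, 24, 2); lambda_z(t, 50 * exp(-0.1 * t))$kel
#' @export
lambda_z <- function(times, conc) {
  check_ct(times, conc)
  failed <- list(kel = NA_real_, t_half = NA_real_,
                 points_used = integer(0), r2adj = NA_real_,
                 intercept = NA_real_, ok = FALSE)
  i_max <- which.max(conc)
  elig <- which(seq_along(times) > i_max & conc > 0)
  if (length(elig) < 3) return(failed)
  best <- NULL
  for (k in 3:length(elig)) {
    idx <- utils::tail(elig, k)
    x <- times[idx]
    y <- log(conc[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    r2adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2adj > best$r2adj + 1e-4 ||
        (abs(r2adj - best$r2adj) <= 1e-4 && k > length(best$points_used))) {
      best <- list(kel = unname(-slope), t_half = unname(log(2) / -slope),
                   points_used = idx, r2adj = r2adj,
                   intercept = unname(fit$coefficients[1]), ok = TRUE)
    }
  }
  if (is.null(best)) failed else best
}

#' Non-compartmental analysis of one plasma profile
#'
#' Standard single-dose NCA: Cmax/Tmax read from the observed points (first
#' occurrence on ties), AUC and AUMC by the trapezoidal rule to the last
#' positive concentration, extrapolation to infinity through the terminal
#' rate constant from [lambda_z()]:
#' `AUC_inf = AUC_t + C_last/kel`,
#' `AUMC_inf = AUMC_t + C_last*t_last/kel + C_last/kel^2`,
#' `MRT = AUMC/AUC`, apparent clearance `Cl/F = dose/AUC_inf` and terminal
#' volume `Vz/F = Cl/F / kel`. When the terminal fit fails, the
#' extrapolated quantities are `NA` but all 0-t quantities are returned.
#'
#' @inheritParams auc_trapezoid
#' @param dose_mg Administered dose in mg (concentrations in ng/ml; the
#'   mg -> ng and ml -> l unit changes are handled internally so Cl/F is in
#'   l/h and Vz/F in l).
#' @param method Trapezoidal rule, as in [auc_trapezoid()].
#' @return Object of class `nca_result` with fields `cmax`, `tmax`,
#'   `auc_0_t`, `auc_0_inf`, `aumc_0_t`, `aumc_0_inf`, `mrt_0_t`,
#'   `mrt_0_inf`, `cl_f`, `vz_f`, `kel`, `t_half`, `lambda_z_points`,
#'   `lambda_z_r2adj`, `dose_mg`.
#' @export
nca <- function(times, conc, dose_mg, method = "linear") {
  check_ct(times, conc)
  check_that(is_number(dose_mg) && dose_mg > 0, "'dose_mg' must be positive")
  check_that(times[1] == 0, "profile must start at t = 0 (pre-dose sample)")
  conc[1] <- 0  # pre-dose baseline forced to zero for single-dose analysis
  i_max <- which.max(conc)
  cmax <- conc[i_max]
  tmax <- times[i_max]
  pos <- which(conc > 0)
  check_that(length(pos) >= 1, "profile has no positive concentration")
  i_last <- max(pos)
  t_last <- times[i_last]
  c_last <- conc[i_last]
  auc_t <- auc_trapezoid(times, conc, t_end = t_last, method = method)
  aumc_t <- aumc_trapezoid(times, conc, t_end = t_last, method = method)
  lz <- lambda_z(times, conc)
  if (lz$ok) {
    auc_inf <- auc_t + c_last / lz$kel
    aumc_inf <- aumc_t + c_last * t_last / lz$kel + c_last / lz$kel^2
    cl_f <- dose_mg * 1000 / auc_inf   # mg/(ng/ml*h) -> l/h
    vz_f <- cl_f / lz$kel
  } else {
    auc_inf <- aumc_inf <- cl_f <- vz_f <- NA_real_
  }
  structure(list(cmax = cmax, tmax = tmax,
                 auc_0_t = auc_t, auc_0_inf = auc_inf,
                 aumc_0_t = aumc_t, aumc_0_inf = aumc_inf,
                 mrt_0_t = aumc_t / auc_t,
                 mrt_0_inf = if (is.na(auc_inf)) NA_real_ else aumc_inf / auc_inf,
                 cl_f = cl_f, vz_f = vz_f,
                 kel = lz$kel, t_half = lz$t_half,
                 lambda_z_points = lz$points_used,
                 lambda_z_r2adj = lz$r2adj,
                 dose_mg = dose_mg),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Non-compartmental analysis:\n")
  cat(sprintf("  Cmax %.3f ng/ml at Tmax %.3f h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC0-t %.2f, AUC0-inf %.2f ng/ml*h; MRT0-inf %.2f h\n",
              x$auc_0_t, x$auc_0_inf, x$mrt_0_inf))
  cat(sprintf("  kel %.4f 1/h (t1/2 %.2f h, %d points, adj r2 %.4f)\n",
              x$kel, x$t_half, length(x$lambda_z_points), x$lambda_z_r2adj))
  cat(sprintf("  Cl/F %.2f l/h, Vz/F %.1f l\n", x$cl_f, x$vz_f))
  invisible(x)
}

#' NCA for every subject-period in a plasma table
#'
#' Applies [nca()] to each (subject, period) profile of a long plasma
#' table, carrying the treatment/sequence labels through so the output
#' feeds the bioequivalence analysis directly.
#'
#' @param plasma Data frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `time_h`, `conc_ng_ml`, `dose_mg` (one row per sample).
#' @param method Trapezoidal rule, see [auc_trapezoid()].
#' @return Data frame, one row per subject-period, with the NCA parameter
#'   set as columns (`cmax`, `tmax`, `auc_0_t`, `auc_0_inf`, `mrt_0_t`,
#'   `mrt_0_inf`, `cl_f`, `vz_f`, `kel`, `t_half`).
#' @export
nca_table <- function(plasma, method = "linear") {
  need <- c("subject", "sequence", "period", "treatment", "time_h",
            "conc_ng_ml", "dose_mg")
  check_that(is.data.frame(plasma) && all(need %in% names(plasma)),
             paste("plasma table needs columns:", paste(need, collapse = ", ")))
  keys <- unique(plasma[c("subject", "period")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- plasma[plasma$subject == keys$subject[i] &
                    plasma$period == keys$period[i], ]
    sub <- sub[order(sub$time_h), ]
    r <- nca(sub$time_h, sub$conc_ng_ml, sub$dose_mg[1], method = method)
    data.frame(subject = keys$subject[i], sequence = sub$sequence[1],
               period = keys$period[i], treatment = sub$treatment[1],
               cmax = r$cmax, tmax = r$tmax, auc_0_t = r$auc_0_t,
               auc_0_inf = r$auc_0_inf, mrt_0_t = r$mrt_0_t,
               mrt_0_inf = r$mrt_0_inf, cl_f = r$cl_f, vz_f = r$vz_f,
               kel = r$kel, t_half = r$t_half, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
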