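#' Mean dissolution time
#'
#' Discrete midpoint-weighted mean release time:
#' `MDT = sum(t_hat_j * dM_j) / sum(dM_j)`, where `t_hat_j` is the midpoint
#' of the j-th sampling interval and `dM_j` the additional amount dissolved
#' in it. The first interval runs from t = 0 with release 0%.
#'
#' @inheritParams fit_release_model
#' @return Mean dissolution time in hours.
#' @examples
#' mdt(dissolution_profile(c(1, 3), c(50, 100)))  # 1.25 h
#' @export
mdt <- function(profile) {
  profile <- as_profile(profile)
  t <- profile$times
  q <- profile$released
  if (t[1] > 0) {
    t <- c(0, t)
    q <- c(0, q)
  }
  dm <- diff(q)
  check_that(sum(dm) > 0, "zero total release: MDT undefined")
  t_mid <- (t[-1] + t[-length(t)]) / 2
  sum(t_mid * dm) / sum(dm)
}

#' Dissolution efficiency
#'
#' Area under the cumulative release curve from 0 to `t_end` (trapezoidal
#' rule, release 0% at t = 0 unless the profile starts at t = 0), expressed
#' as a percentage of the area of instantaneous complete release
#' (`100% * t_end`).
#'
#' @inheritParams fit_release_model
#' @param t_end End of the integration window in hours; must lie within the
#'   profile span. Release at a non-sampled `t_end` is linearly
#'   interpolated.
#' @return Dissolution efficiency in percent.
#' @examples
#' de <- dissolution_efficiency(dissolution_profile(c(1, 2), c(40, 80)), 2)
#' @export
dissolution_efficiency <- function(profile, t_end) {
  profile <- as_profile(profile)
  check_that(is_number(t_end) && t_end > 0, "'t_end' must be a positive number")
  t <- profile$times
  q <- profile$released
  if (t[1] > 0) {
    t <- c(0, t)
    q <- c(0, q)
  }
  check_that(t_end <= max(t), "'t_end' lies beyond the profile span")
  keep <- t < t_end
  tt <- c(t[keep], t_end)
  qq <- c(q[keep], stats::approx(t, q, xout = t_end)$y)
  auc <- sum(diff(tt) * (qq[-1] + qq[-length(qq)]) / 2)
  100 * auc / (100 * t_end)
}

#' Time to 90% cumulative release
#'
#' Linear interpolation between the observed points bracketing the
#' `threshold` (default 90%). Returns `NA` when the threshold is never
#' reached within the profile, i.e. "T90 > t_last"; the last sampling time
#' is attached as attribute `t_last` so reports can render the censored
#' form.
#'
#' @inheritParams fit_release_model
#' @param threshold Release level in percent (default 90).
#' @return Time in hours, or `NA_real_` (censored) with attribute `t_last`.
#' @examples
#' t90(dissolution_profile(c(8, 9), c(88, 92)))  # 8.5 h
#' @export
t90 <- function(profile, threshold = 90) {
  profile <- as_profile(profile)
  t <- profile$times
  q <- profile$released
  if (t[1] > 0) {
    t <- c(0, t)
    q <- c(0, q)
  }
  if (max(q) < threshold) {
    return(structure(NA_real_, t_last = max(t)))
  }
  i <- which(q >= threshold)[1]
  if (q[i] == threshold || i == 1L) {
    return(t[i])
  }
  t[i - 1] + (threshold - q[i - 1]) / (q[i] - q[i - 1]) * (t[i] - t[i - 1])
}

#' f2 similarity factor between two dissolution profiles
#'
#' `f2 = 50 * log10(100 / sqrt(1 + mean((R_t - T_t)^2)))`, computed over the
#' shared time points of the reference and test profiles. Profiles are
#' considered similar when `f2 >= 50`; identical profiles give `f2 = 100`.
#' The time grids must match exactly -- no silent interpolation.
#'
#' @param reference,test [dissolution_profile()] objects (or data frames)
#'   on identical time grids with at least 3 points.
#' @param truncate_85 If `TRUE`, drop points after the first at which both
#'   profiles exceed 85% release (regulatory convention). Default `FALSE`:
#'   all shared points are used.
#' @return Object of class `f2_result`: list with `f2`, `similar`, `n`.
#' @examples
#' r <- dissolution_profile(1:6, c(20, 35, 50, 65, 80, 90))
#' s <- dissolution_profile(1:6, c(22, 37, 52, 67, 82, 92))
#' f2_similarity(r, s)
#' @export
f2_similarity <- function(reference, test, truncate_85 = FALSE) {
  reference <- as_profile(reference)
  test <- as_profile(test)
  check_that(length(reference$times) == length(test$times) &&
               all(reference$times == test$times),
             "reference and test profiles must share identical time points")
  r <- reference$released
  s <- test$released
  if (isTRUE(truncate_85)) {
    over <- which(r > 85 & s > 85)
    if (length(over)) {
      keep <- seq_len(min(over))
      r <- r[keep]
      s <- s[keep]
    }
  }
  n <- length(r)
  check_that(n >= 3L, "f2 requires at least 3 shared time points")
  f2 <- 50 * log10(100 / sqrt(1 + mean((r - s)^2)))
  structure(list(f2 = f2, similar = f2 >= 50, n = n), class = "f2_result")
}

#' @export
print.f2_result <- function(x, ...) {
  cat(sprintf("f2 = %.2f over %d points: profiles %s\n", x$f2, x$n,
              if (x$similar) "similar (f2 >= 50)" else "different (f2 < 50)"))
  invisible(x)
}

#' Model-independent summary of a dissolution profile
#'
#' Convenience wrapper returning mean dissolution time, dissolution
#' efficiency over the profile span, and T90.
#'
#' @inheritParams fit_release_model
#' @param t_end Window for dissolution efficiency; defaults to the last
#'   sampling time.
#' @return List with `mdt_h`, `de_pct`, `t90_h` (NA when censored),
#'   `t90_censored`.
#' @export
profile_summary <- function(profile, t_end = NULL) {
  profile <- as_profile(profile)
  if (is.null(t_end)) t_end <- max(profile$times)
  t90v <- t90(profile)
  list(mdt_h = mdt(profile),
       de_pct = dissolution_efficiency(profile, t_end),
       t90_h = as.numeric(t90v),
       t90_censored = is.na(t90v))
}
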