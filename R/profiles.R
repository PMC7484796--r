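#' Cumulative dissolution profile
#'
#' Container for a single in vitro release curve: cumulative percent of label
#' claim released versus time for one formulation in one medium. Validation
#' enforces the physical constraints of a cumulative curve: strictly
#' increasing sampling times, releases within 0--110% (a small analytical
#' overage is tolerated), and non-decreasing release (decreases larger than
#' `tol` are rejected; simulated curves are monotonized at generation time).
#'
#' @param times Sampling times in hours, strictly increasing. The first time
#'   may be greater than zero; release is taken as 0% at t = 0.
#' @param released Cumulative percent released at `times`.
#' @param formulation_id Optional label for the formulation.
#' @param medium Optional label for the dissolution medium
#'   (e.g. `"0.01 N HCl"`, `"pH 6.8"`).
#' @param tol Tolerance for small numerical decreases between consecutive
#'   points.
#' @return An object of class `dissolution_profile`: a list with elements
#'   `times`, `released`, `formulation_id`, `medium`.
#' @examples
#' dissolution_profile(1:12, pmin(100, 30 * sqrt(1:12)), "FC12")
#' @export
dissolution_profile <- function(times, released, formulation_id = NA_character_,
                                medium = NA_character_, tol = 1e-9) {
  check_that(is.numeric(times) && is.numeric(released),
             "'times' and 'released' must be numeric")
  check_that(length(times) == length(released) && length(times) >= 2L,
             "'times' and 'released' must have equal length >= 2")
  check_that(all(is.finite(times)) && all(is.finite(released)),
             "non-finite values in dissolution profile")
  check_that(all(times >= 0), "sampling times must be non-negative")
  check_that(all(diff(times) > 0), "sampling times must be strictly increasing")
  check_that(all(released >= -tol & released <= 110),
             "released values must lie in [0, 110] percent")
  if (any(diff(released) < -tol)) {
    stop("cumulative release must be non-decreasing (tolerance ", tol, ")",
         call. = FALSE)
  }
  structure(
    list(times = as.numeric(times),
         released = pmax(as.numeric(released), 0),
         formulation_id = formulation_id,
         medium = medium),
    class = "dissolution_profile"
  )
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat("Dissolution profile", if (!is.na(x$formulation_id)) x$formulation_id,
      if (!is.na(x$medium)) paste0("(", x$medium, ")"), "\n")
  cat(sprintf("  %d points, t = %g..%g h, release %.1f..%.1f %%\n",
              length(x$times), min(x$times), max(x$times),
              min(x$released), max(x$released)))
  invisible(x)
}

as_profile <- function(x) {
  if (inherits(x, "dissolution_profile")) return(x)
  if (is.data.frame(x) && all(c("time_h", "released_pct") %in% names(x))) {
    return(dissolution_profile(x$time_h, x$released_pct,
                               formulation_id = if ("formulation_id" %in% names(x))
                                 as.character(x$formulation_id[1]) else NA_character_,
                               medium = if ("medium" %in% names(x))
                                 as.character(x$medium[1]) else NA_character_))
  }
  stop("expected a 'dissolution_profile' or a data frame with time_h/released_pct",
       call. = FALSE)
}
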