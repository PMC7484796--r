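#' Coded/actual factor-level conversion
#'
#' Central-composite designs are fitted on coded levels; the mapping to
#' actual units is `actual = center + coded * step`. Both directions are
#' exact round-trips.
#'
#' @param coded,actual Numeric level(s).
#' @param center Factor level at coded 0, in actual units.
#' @param step Actual units per coded unit (> 0).
#' @return Numeric vector of converted levels.
#' @examples
#' coded_to_actual(1.6818, center = 7, step = 1)     # 8.6818
#' actual_to_coded(0.750, center = 0.875, step = 0.125)  # -1
#' @export
coded_to_actual <- function(coded, center, step) {
  check_that(is.numeric(step) && all(step > 0), "'step' must be positive")
  center + coded * step
}

#' @rdname coded_to_actual
#' @export
actual_to_coded <- function(actual, center, step) {
  check_that(is.numeric(step) && all(step > 0), "'step' must be positive")
  (actual - center) / step
}

#' Coating-factor table for the reference pellet study
#'
#' Centers and steps (actual grams per coded unit) of the three coating
#' factors -- polymer (Eudragit RL100/RS100), plasticizer (TEC) and
#' anti-tacking agent (talc) -- implied by the factorial and center runs of
#' the published 20-run design.
#'
#' @return Data frame with columns `name`, `center`, `step`.
#' @export
ccrd_reference_factors <- function() {
  path <- system.file("extdata", "ccrd_factors.csv", package = "pelletpk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Central composite rotatable design
#'
#' Generates the 2^k factorial corners at coded +/-1, 2k axial points at
#' +/- alpha with the rotatability value alpha = (2^k)^(1/4), and `n_center`
#' replicated center points. Run order is fixed (factorial in standard
#' order, then axial, then center) -- no randomization -- so designs are
#' reproducible.
#'
#' @param factors Data frame with columns `name`, `center`, `step`
#'   (see [ccrd_reference_factors()] for the built-in example), 2--6 rows.
#' @param n_center Number of center replicates (>= 1).
#' @return Object of class `ccrd_design`: list with `factors`,
#'   `axial_alpha`, and `runs` (data frame with `run_id`, `space_type`,
#'   coded and actual columns per factor).
#' @examples
#' d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
#' nrow(d$runs)  # 20
#' @export
ccrd_design <- function(factors, n_center = 6) {
  check_that(is.data.frame(factors) &&
               all(c("name", "center", "step") %in% names(factors)),
             "'factors' needs columns name, center, step")
  k <- nrow(factors)
  check_that(k >= 2, "need at least 2 factors")
  check_that(k <= 6, "designs with more than 6 factors are unsupported")
  check_that(is_number(n_center) && n_center >= 1, "'n_center' must be >= 1")
  alpha <- (2^k)^(1 / 4)
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -alpha
    axial[2 * j, j] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k)
  coded <- rbind(fact, axial, center)
  colnames(coded) <- factors$name
  space <- c(rep("factorial", nrow(fact)), rep("axial", nrow(axial)),
             rep("center", n_center))
  actual <- sweep(sweep(coded, 2, factors$step, `*`), 2, factors$center, `+`)
  runs <- data.frame(run_id = sprintf("run%02d", seq_len(nrow(coded))),
                     space_type = space, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    runs[[paste0("coded_", factors$name[j])]] <- coded[, j]
    runs[[paste0("actual_", factors$name[j])]] <- actual[, j]
  }
  structure(list(factors = factors, axial_alpha = alpha, runs = runs),
            class = "ccrd_design")
}

#' @export
print.ccrd_design <- function(x, ...) {
  k <- nrow(x$factors)
  tab <- table(x$runs$space_type)
  cat(sprintf("CCRD: %d factors, %d runs (%d factorial + %d axial + %d center), alpha = %.4f\n",
              k, nrow(x$runs), tab[["factorial"]], tab[["axial"]],
              tab[["center"]], x$axial_alpha))
  invisible(x)
}

design_coded_matrix <- function(design) {
  nm <- design$factors$name
  m <- as.matrix(design$runs[paste0("coded_", nm)])
  colnames(m) <- nm
  m
}

# polynomial terms of a response-surface model order, as a named model
# matrix on coded levels
rsm_model_matrix <- function(coded, order) {
  order <- match.arg(order, c("linear", "2FI", "quadratic", "cubic"))
  k <- ncol(coded)
  nm <- colnames(coded)
  cols <- list("(Intercept)" = rep(1, nrow(coded)))
  for (j in seq_len(k)) cols[[nm[j]]] <- coded[, j]
  if (order %in% c("2FI", "quadratic", "cubic")) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      cols[[paste0(nm[i], ":", nm[j])]] <- coded[, i] * coded[, j]
    }
  }
  if (order %in% c("quadratic", "cubic")) {
    for (j in seq_len(k)) cols[[paste0(nm[j], "^2")]] <- coded[, j]^2
  }
  if (order == "cubic") {
    for (j in seq_len(k)) cols[[paste0(nm[j], "^3")]] <- coded[, j]^3
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) cols[[paste0(nm[i], "^2:", nm[j])]] <- coded[, i]^2 * coded[, j]
    }
    if (k >= 3) {
      idx <- utils::combn(k, 3)
      for (c3 in seq_len(ncol(idx))) {
        trip <- idx[, c3]
        cols[[paste(nm[trip], collapse = ":")]] <-
          coded[, trip[1]] * coded[, trip[2]] * coded[, trip[3]]
      }
    }
  }
  do.call(cbind, cols)
}

#' Fit a polynomial response-surface model
#'
#' Ordinary least squares of one response on the coded design matrix of the
#' requested model order (`linear` = main effects; `2FI` adds pairwise
#' interactions; `quadratic` adds squared terms; `cubic` adds all
#' third-degree monomials). Aliased (rank-deficient) terms are dropped by
#' pivoting and reported. Fit-summary statistics follow response-surface
#' software conventions: `sd` is the root mean squared error, PRESS is the
#' leave-one-out prediction error sum of squares computed through the hat
#' matrix, `predicted_r2 = 1 - PRESS/TSS` (negative values flag an
#' overfitted model). When a dropped observation has leverage 1 its
#' leave-one-out prediction is undefined and PRESS is reported as `Inf`.
#'
#' @param design A [ccrd_design()].
#' @param response Numeric response vector, one value per run, no missing
#'   values (censored responses cannot be fitted).
#' @param order Model order: `"linear"`, `"2FI"`, `"quadratic"`, `"cubic"`.
#' @return Object of class `rsm_fit`: coefficients on the coded scale,
#'   `anova` (model mean square, F, p against residual), `sd`, `r2`,
#'   `adjusted_r2`, `predicted_r2`, `press`, `rss`, `df_residual`,
#'   `aliased` (dropped term names), `fitted`, `residuals`, `leverage`.
#' @export
fit_rsm <- function(design, response, order = "quadratic") {
  check_that(inherits(design, "ccrd_design"), "'design' must be a ccrd_design")
  y <- as.numeric(response)
  check_that(length(y) == nrow(design$runs),
             "'response' must have one value per run")
  check_that(!anyNA(y),
             "response contains missing/censored values; exclude it from RSM fitting")
  x_full <- rsm_model_matrix(design_coded_matrix(design), order)
  check_that(nrow(x_full) >= 2, "too few runs")
  qr_x <- qr(x_full)
  rank <- qr_x$rank
  keep <- qr_x$pivot[seq_len(rank)]
  aliased <- setdiff(colnames(x_full), colnames(x_full)[keep])
  x <- x_full[, keep, drop = FALSE]
  n <- length(y)
  p <- ncol(x)  # including intercept
  check_that(n >= p + 1, "fewer runs than model terms + 1")
  fit <- stats::lm.fit(x, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - p
  mse <- rss / df_res
  h <- rowSums(qr.Q(qr(x))^2)
  loo_ok <- (1 - h) > 1e-10
  press <- if (all(loo_ok)) sum((res / (1 - h))^2) else Inf
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (tss > 0 && df_res > 0) 1 - (rss / df_res) / (tss / (n - 1)) else NA_real_
  pred <- if (tss > 0) 1 - press / tss else NA_real_
  df_model <- p - 1
  msm <- if (df_model > 0) (tss - rss) / df_model else NA_real_
  f <- if (df_model > 0 && mse > 0) msm / mse else NA_real_
  pval <- if (is.finite(f)) stats::pf(f, df_model, df_res, lower.tail = FALSE)
          else NA_real_
  structure(list(order = order, coefficients = coefs,
                 anova = list(model_ms = msm, f = f, p = pval,
                              df_model = df_model, df_residual = df_res),
                 sd = sqrt(mse), r2 = r2, adjusted_r2 = adj,
                 predicted_r2 = pred, press = press, rss = rss,
                 df_residual = df_res, aliased = aliased,
                 fitted = as.numeric(x %*% coefs), residuals = res,
                 leverage = h, n = n),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("RSM fit (%s): sd = %.4g, r2 = %.4f, adj = %.4f, pred = %.4f, PRESS = %.4g\n",
              x$order, x$sd, x$r2, x$adjusted_r2, x$predicted_r2, x$press))
  if (length(x$aliased)) {
    cat("  aliased terms dropped:", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit summary across model orders
#'
#' Fits the linear, two-factor-interaction, quadratic and cubic models to
#' one response and assembles the sequential model comparison used for
#' model selection: for each order, the sequential (Type-I) F statistic of
#' the terms it adds over the previous order, tested against that order's
#' residual mean square, together with each fit's SD, adjusted and
#' predicted R-squared and PRESS. The recommended model is the
#' highest-order non-aliased model with sequential p < 0.05 (ties broken by
#' lower PRESS, then lower SD); when no order is significant the
#' recommendation is the mean model.
#'
#' @inheritParams fit_rsm
#' @return Object of class `rsm_fit_summary`: list with `table` (one row
#'   per order), `fits` (the `rsm_fit` objects) and `recommended`.
#' @export
rsm_fit_summary <- function(design, response) {
  orders <- c("linear", "2FI", "quadratic", "cubic")
  y <- as.numeric(response)
  if (anyNA(y)) {
    tab <- data.frame(order = orders, seq_ms = NA_real_, seq_f = NA_real_,
                      seq_p = NA_real_, sd = NA_real_, adjusted_r2 = NA_real_,
                      predicted_r2 = NA_real_, press = NA_real_,
                      aliased = NA, stringsAsFactors = FALSE)
    return(structure(list(table = tab, fits = NULL, recommended = "none",
                          note = "response censored/missing; not fitted"),
                     class = "rsm_fit_summary"))
  }
  fits <- lapply(orders, function(o) fit_rsm(design, y, o))
  names(fits) <- orders
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss <= 1e-10 * max(1, sum(y^2))) {
    # constant response: nothing to model
    tab <- data.frame(order = orders, seq_ms = NA_real_, seq_f = NA_real_,
                      seq_p = NA_real_, sd = 0, adjusted_r2 = NA_real_,
                      predicted_r2 = NA_real_, press = NA_real_,
                      aliased = NA, stringsAsFactors = FALSE)
    return(structure(list(table = tab, fits = fits, recommended = "mean"),
                     class = "rsm_fit_summary"))
  }
  prev_rss <- tss
  prev_p <- 1L
  rows <- lapply(seq_along(orders), function(i) {
    f <- fits[[i]]
    p_cur <- n - f$df_residual
    df_seq <- p_cur - prev_p
    ss_seq <- prev_rss - f$rss
    mse <- f$rss / f$df_residual
    seq_ms <- if (df_seq > 0) ss_seq / df_seq else NA_real_
    seq_f <- if (df_seq > 0 && mse > 0) seq_ms / mse else NA_real_
    seq_p <- if (!is.na(seq_f) && is.finite(seq_f)) {
      stats::pf(seq_f, df_seq, f$df_residual, lower.tail = FALSE)
    } else {
      NA_real_
    }
    prev_rss <<- f$rss
    prev_p <<- p_cur
    data.frame(order = orders[i], seq_ms = seq_ms, seq_f = seq_f,
               seq_p = seq_p, sd = f$sd, adjusted_r2 = f$adjusted_r2,
               predicted_r2 = f$predicted_r2, press = f$press,
               aliased = length(f$aliased) > 0, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cand <- which(!tab$aliased & !is.na(tab$seq_p) & tab$seq_p < 0.05)
  recommended <- if (!length(cand)) {
    "mean"
  } else {
    best <- cand[order(-cand, tab$press[cand], tab$sd[cand])][1]
    tab$order[best]
  }
  structure(list(table = tab, fits = fits, recommended = recommended),
            class = "rsm_fit_summary")
}

#' @export
print.rsm_fit_summary <- function(x, ...) {
  cat("Response-surface fit summary:\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Recommended model:", x$recommended, "\n")
  invisible(x)
}

#' Constraint-based selection of formulation runs
#'
#' Filters a run table on per-response bounds and, among the passing runs,
#' ranks by a tie-break column (ascending) so that the formulation using
#' the least material is preferred. Typical target profile: release at
#' 12 h >= 90%, aspect ratio <= 1.1, shape factor eR >= 0.6.
#'
#' @param runs Data frame of runs with response columns.
#' @param criteria Named list, one entry per response column, each a list
#'   with optional `min` and/or `max` bounds, e.g.
#'   `list(release_12h_pct = list(min = 90), aspect_ratio = list(max = 1.1))`.
#' @param tie_break Optional column name; passing runs are ordered by it
#'   increasingly and the first row is flagged as `selected`.
#' @return Data frame of passing runs (possibly empty) with attribute
#'   `selected` holding the chosen `run` row (or `NULL`).
#' @export
select_optimal <- function(runs, criteria, tie_break = NULL) {
  check_that(is.data.frame(runs), "'runs' must be a data frame")
  check_that(is.list(criteria) && length(criteria) > 0 &&
               !is.null(names(criteria)),
             "'criteria' must be a non-empty named list of bounds")
  ok <- rep(TRUE, nrow(runs))
  for (col in names(criteria)) {
    check_that(col %in% names(runs), paste0("no column '", col, "' in runs"))
    b <- criteria[[col]]
    v <- runs[[col]]
    if (!is.null(b$min)) ok <- ok & !is.na(v) & v >= b$min
    if (!is.null(b$max)) ok <- ok & !is.na(v) & v <= b$max
  }
  out <- runs[ok, , drop = FALSE]
  sel <- NULL
  if (nrow(out) > 0) {
    if (!is.null(tie_break)) {
      check_that(tie_break %in% names(out),
                 paste0("no tie-break column '", tie_break, "'"))
      out <- out[order(out[[tie_break]]), , drop = FALSE]
    }
    sel <- out[1, , drop = FALSE]
  }
  attr(out, "selected") <- sel
  out
}
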