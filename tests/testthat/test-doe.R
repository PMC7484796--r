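test_that("rotatable design has the canonical structure", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  expect_equal(nrow(d$runs), 20)
  expect_equal(sum(d$runs$space_type == "factorial"), 8)
  expect_equal(sum(d$runs$space_type == "axial"), 6)
  expect_equal(sum(d$runs$space_type == "center"), 6)
  expect_equal(d$axial_alpha, 8^(1 / 4), tolerance = 1e-12)
  expect_equal(round(d$axial_alpha, 4), 1.6818)
  # coded columns sum to zero (orthogonal to the intercept)
  coded <- pelletpk:::design_coded_matrix(d)
  expect_equal(colSums(coded), c(RL100 = 0, TEC = 0, talc = 0))

  d2 <- ccrd_design(data.frame(name = c("a", "b"), center = 0, step = 1),
                    n_center = 1)
  expect_equal(nrow(d2$runs), 9)
  expect_equal(d2$axial_alpha, 4^(1 / 4))
  expect_error(ccrd_design(data.frame(name = letters[1:7], center = 0,
                                      step = 1)), "more than 6")
})

test_that("coded and actual levels convert exactly both ways", {
  factors <- ccrd_reference_factors()
  # center runs sit at the factor centers
  expect_equal(coded_to_actual(0, factors$center, factors$step),
               c(7, 0.875, 4.375))
  expect_equal(coded_to_actual(-1, 0.875, 0.125), 0.750)
  expect_equal(round(coded_to_actual(1.6818, 7, 1), 3), 8.682)
  # exact round trip over every level of the 20-run design
  d <- ccrd_design(factors, n_center = 6)
  for (j in seq_len(nrow(factors))) {
    coded <- d$runs[[paste0("coded_", factors$name[j])]]
    actual <- d$runs[[paste0("actual_", factors$name[j])]]
    expect_equal(actual_to_coded(actual, factors$center[j], factors$step[j]),
                 coded, tolerance = 1e-14)
  }
})

test_that("an exact linear response is fitted perfectly", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  y <- gen_ccrd_response(d, c("(Intercept)" = 60, RL100 = -5, TEC = 2,
                              talc = 1), noise_sd = 0)
  fit <- fit_rsm(d, y, "linear")
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-10)
  expect_equal(fit$predicted_r2, 1, tolerance = 1e-8)
  expect_lt(fit$press, 1e-8)
})

test_that("hat-matrix PRESS equals explicit leave-one-out refits", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  set.seed(88)
  y <- rnorm(20, 75, 5)
  for (order in c("linear", "2FI", "quadratic")) {
    fit <- fit_rsm(d, y, order)
    x <- pelletpk:::rsm_model_matrix(pelletpk:::design_coded_matrix(d), order)
    expect_equal(fit$press, press_loo(x, y), tolerance = 1e-8)
  }
})

test_that("RSS is non-increasing with model order (nesting)", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  set.seed(12)
  y <- rnorm(20, 50, 4)
  rss <- vapply(c("linear", "2FI", "quadratic"), function(o) {
    fit_rsm(d, y, o)$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("overfitting drives predicted R-squared negative", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  set.seed(17)
  y <- rnorm(20)  # pure noise: the quadratic model only chases it
  fit <- fit_rsm(d, y, "quadratic")
  expect_lt(fit$predicted_r2, 0)
})

test_that("cubic terms on a 20-run CCRD are reported as aliased", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  set.seed(5)
  y <- rnorm(20, 70, 3)
  fit <- fit_rsm(d, y, "cubic")
  expect_gt(length(fit$aliased), 0)
})

test_that("fit summary recommends the generating model order", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  quad <- c("(Intercept)" = 80, RL100 = -9, TEC = 1.5, talc = 0.8,
            "RL100^2" = -2.5, "TEC^2" = 0.9, "talc^2" = -0.5)
  lin <- c("(Intercept)" = 60, RL100 = -6, TEC = 1.2, talc = 0.9)
  # model selection is statistical: over repeated noise draws the
  # generating order must dominate the recommendations
  rec_q <- rec_l <- character(20)
  for (s in 1:20) {
    yq <- gen_ccrd_response(d, quad, noise_sd = 0.3, seed = 500 + s)
    rec_q[s] <- rsm_fit_summary(d, yq)$recommended
    yl <- gen_ccrd_response(d, lin, noise_sd = 0.3, seed = 700 + s)
    rec_l[s] <- rsm_fit_summary(d, yl)$recommended
  }
  expect_gte(mean(rec_q == "quadratic"), 0.75)
  expect_gte(mean(rec_l == "linear"), 0.75)

  expect_identical(rsm_fit_summary(d, rep(50, 20))$recommended, "mean")
  # censored responses are not fitted
  yq[3] <- NA
  cens <- rsm_fit_summary(d, yq)
  expect_identical(cens$recommended, "none")
  expect_true(all(is.na(cens$table$sd)))
})

test_that("constraint-based selection filters and tie-breaks on polymer", {
  runs <- data.frame(run = c("fast", "optimal", "slow", "optimal-heavy"),
                     polymer_g = c(5.318, 6, 7, 6.5),
                     release_12h_pct = c(98, 94, 80, 94),
                     aspect_ratio = c(1.03, 1.02, 1.05, 1.02),
                     shape_factor_er = c(0.98, 0.99, 0.97, 0.99))
  crit <- list(release_12h_pct = list(min = 90),
               aspect_ratio = list(max = 1.1),
               shape_factor_er = list(min = 0.6))
  # the fast-releasing run at 98% released that amount before 12 h; with the
  # 12-h release recorded as exhausted early it is screened by the criteria
  out <- select_optimal(runs, crit, tie_break = "polymer_g")
  expect_setequal(out$run, c("fast", "optimal", "optimal-heavy"))
  expect_identical(attr(out, "selected")$run, "fast")
  # among runs extending release to 12 h, the lighter coat wins the tie
  out2 <- select_optimal(runs[-1, ], crit, tie_break = "polymer_g")
  expect_identical(attr(out2, "selected")$run, "optimal")
  # no run passing the bounds is an empty result, not an error
  none <- select_optimal(runs, list(release_12h_pct = list(min = 99)))
  expect_equal(nrow(none), 0)
  expect_null(attr(none, "selected"))
  expect_error(select_optimal(runs, list()), "non-empty")
})
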