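test_that("crossover generator is seeded, balanced and schedule-checked", {
  sp <- ir_spec(bsv_cv = 0.2, noise_cv = 0.1, seed = 11)
  tab1 <- gen_crossover_pk(sp, er_spec(bsv_cv = 0.2, noise_cv = 0.1, seed = 11))
  tab2 <- gen_crossover_pk(sp, er_spec(bsv_cv = 0.2, noise_cv = 0.1, seed = 11))
  expect_identical(tab1, tab2)
  sp3 <- ir_spec(bsv_cv = 0.2, noise_cv = 0.1, seed = 12)
  tab3 <- gen_crossover_pk(sp3, er_spec(bsv_cv = 0.2, noise_cv = 0.1, seed = 12))
  expect_false(identical(tab1$conc_ng_ml, tab3$conc_ng_ml))

  # balance: half the subjects per sequence, both treatments per subject
  alloc <- unique(tab1[c("subject", "sequence")])
  expect_equal(unname(table(alloc$sequence)), c(6, 6), ignore_attr = TRUE)
  trt_per_subj <- tapply(tab1$treatment, tab1$subject,
                         function(x) length(unique(x)))
  expect_true(all(trt_per_subj == 2))

  expect_error(pk_sim_spec(n_subjects = 11), "even")
  expect_error(pk_sim_spec(schedule = c(0, 2, 1)), "increasing")
})

test_that("noiseless crossover equals the analytic one-compartment model", {
  sp <- ir_spec(bsv_cv = 0, noise_cv = 0, seed = 3)
  tab <- gen_crossover_pk(sp, sp)
  # identical processes: T/R concentration ratio 1 at all positive times
  r <- tab[tab$treatment == "R" & tab$time_h > 0, ]
  t_ <- tab[tab$treatment == "T" & tab$time_h > 0, ]
  merged <- merge(r, t_, by = c("subject", "time_h"))
  expect_equal(merged$conc_ng_ml.x, merged$conc_ng_ml.y)
  # and equals the closed-form curve
  one <- tab[tab$subject == 1 & tab$period == 1, ]
  expected <- one_compartment_conc(one$time_h, 60, 1.5, 0.12, 400)
  expected[one$time_h == 0] <- 0
  expect_equal(one$conc_ng_ml, expected)
})

test_that("noiseless peak matches the closed-form maximum", {
  pk <- one_compartment_peak(60, 1.5, 0.12, 400)
  expect_equal(pk$tmax, log(1.5 / 0.12) / (1.5 - 0.12))
  tt <- seq(0, 48, by = 1e-3)
  cc <- one_compartment_conc(tt, 60, 1.5, 0.12, 400)
  expect_equal(max(cc), pk$cmax, tolerance = 1e-6)
})

test_that("dissolution generator agrees with the forward model and is monotone", {
  # noiseless zero order: exact line
  pr <- gen_dissolution("zero", 10, 1:10, noise_sd = 0)
  expect_equal(pr$released, seq(10, 100, by = 10))
  # power law at n = 0.5 collapses onto the square-root law
  pk_pr <- gen_dissolution("korsmeyer_peppas", c(30, 0.5), 1:12, noise_sd = 0)
  hg_pr <- gen_dissolution("higuchi", 30, 1:12, noise_sd = 0)
  expect_equal(pk_pr$released, hg_pr$released)
  # first-order asymptote
  pr1 <- gen_dissolution("first", 0.3, c(1, 5, 40, 60), noise_sd = 0)
  expect_equal(pr1$released[4], 100, tolerance = 1e-6)
  # noisy curves stay in [0, 100], non-decreasing, and are seed-reproducible
  a <- gen_dissolution("higuchi", 28, 1:12, noise_sd = 3, seed = 5)
  b <- gen_dissolution("higuchi", 28, 1:12, noise_sd = 3, seed = 5)
  c_ <- gen_dissolution("higuchi", 28, 1:12, noise_sd = 3, seed = 6)
  expect_identical(a$released, b$released)
  expect_false(identical(a$released, c_$released))
  expect_true(all(diff(a$released) >= 0))
  expect_true(all(a$released >= 0 & a$released <= 100))
  expect_error(gen_dissolution("weibull", 1, 1:5), "unknown model_id")
})

test_that("CCRD response generator reproduces known polynomial surfaces", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  y0 <- gen_ccrd_response(d, c("(Intercept)" = 42), noise_sd = 0)
  expect_equal(y0, rep(42, 20))
  beta <- c("(Intercept)" = 50, RL100 = -4, TEC = 2, talc = 1)
  y <- gen_ccrd_response(d, beta, noise_sd = 0)
  fit <- fit_rsm(d, y, "linear")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$press, 1e-16)
  expect_error(gen_ccrd_response(d, c(nonsense = 1)), "unsupported model terms")
})

test_that("quadratic surface coefficients are recovered within 3 SE almost always", {
  d <- ccrd_design(ccrd_reference_factors(), n_center = 6)
  beta <- c("(Intercept)" = 80, RL100 = -9, TEC = 1.5, talc = 0.8,
            "RL100:TEC" = 0.5, "RL100^2" = -2, "TEC^2" = 0.7, "talc^2" = -0.4)
  x <- pelletpk:::rsm_model_matrix(pelletpk:::design_coded_matrix(d),
                                   "quadratic")
  hits <- 0L
  n_rep <- 200L
  # exact sampling SE from the known noise level and the design
  se <- 0.1 * sqrt(diag(solve(crossprod(x))))[names(beta)]
  for (s in seq_len(n_rep)) {
    y <- gen_ccrd_response(d, beta, noise_sd = 0.1, seed = 1000 + s)
    fit <- fit_rsm(d, y, "quadratic")
    est <- fit$coefficients[names(beta)]
    hits <- hits + all(abs(est - beta) <= 3 * se)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("QC replicate generator honours its moments and preconditions", {
  expect_equal(gen_qc_replicates(10, 0, n = 5), rep(10, 5))
  expect_error(gen_qc_replicates(10, 0.01, n = 1), ">= 2")
  expect_error(gen_qc_replicates(10, -0.1, 5), ">= 0")
  # sample CV of replicates concentrates near the generating CV
  cvs <- vapply(1:400, function(s) {
    v <- gen_qc_replicates(10, 0.014, n = 5, seed = s)
    100 * sd(v) / mean(v)
  }, numeric(1))
  expect_gt(mean(cvs), 1.0)
  expect_lt(mean(cvs), 1.8)
})

test_that("stability generator is linear and seeded", {
  flat <- gen_stability(100, 0, 0, times_months = c(0, 3, 6))
  expect_equal(flat$assay_pct, rep(100, 3))
  lin <- gen_stability(100, -0.2, 0, times_months = c(0, 25, 50))
  expect_equal(lin$assay_pct[3], 90)
  a <- gen_stability(100, -0.2, 0.3, times_months = c(0, 3, 6), seed = 4)
  b <- gen_stability(100, -0.2, 0.3, times_months = c(0, 3, 6), seed = 4)
  expect_identical(a, b)
})
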