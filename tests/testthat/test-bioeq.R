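make_crossover <- function(values_r, values_t) {
  n <- length(values_r)
  seqs <- ifelse(seq_len(n) <= n / 2, "RT", "TR")
  rbind(
    data.frame(subject = seq_len(n), sequence = seqs,
               period = ifelse(seqs == "RT", 1, 2), treatment = "R",
               value = values_r, stringsAsFactors = FALSE),
    data.frame(subject = seq_len(n), sequence = seqs,
               period = ifelse(seqs == "RT", 2, 1), treatment = "T",
               value = values_t, stringsAsFactors = FALSE)
  )
}

test_that("identical arms give zero treatment effect and GMR 1", {
  set.seed(314)
  v <- exp(rnorm(12, log(100), 0.2))
  d <- make_crossover(v, v)
  an <- crossover_anova(d)
  trt <- an$table[an$table$effect == "treatment", ]
  expect_equal(trt$ss, 0, tolerance = 1e-20)
  expect_equal(trt$f, 0, tolerance = 1e-10)
  r <- suppressWarnings(gmr_ci(d, "cmax"))
  expect_equal(r$gmr, 1)
  expect_true(r$ci90[1] <= 1 && 1 <= r$ci90[2])
  expect_true(r$tost_pass)
})

test_that("an injected log-scale treatment effect is recovered exactly", {
  set.seed(99)
  delta <- 0.11
  subj <- exp(rnorm(12, log(90), 0.25))
  d <- make_crossover(subj, subj * exp(delta))
  an <- crossover_anova(d)
  expect_equal(an$delta, delta, tolerance = 1e-12)
  expect_equal(an$mse, 0, tolerance = 1e-20)
  # constant subject-wise ratio: degenerate point interval at the ratio
  d2 <- make_crossover(subj, subj * 0.8572)
  r <- suppressWarnings(gmr_ci(d2, "cmax"))
  expect_equal(r$gmr, 0.8572, tolerance = 1e-12)
  expect_equal(r$ci90[1], r$ci90[2], tolerance = 1e-12)
})

test_that("ANOVA sums of squares match the sequential projection oracle", {
  for (s in 1:5) {
    d <- gen_be_dataset(12, gmr = 0.9, cv_w = 0.2, cv_b = 0.35, seed = 100 + s,
                        seq_effect = 1.05, period_effect = 0.97)
    an <- crossover_anova(d)
    oracle <- sequential_ss(crossover_blocks(d), log(d$value))
    got <- an$table$ss
    names(got) <- an$table$effect
    expect_equal(got[["sequence"]], oracle[["sequence"]], tolerance = 1e-8)
    expect_equal(got[["subject"]], oracle[["subject"]], tolerance = 1e-8)
    expect_equal(got[["period"]], oracle[["period"]], tolerance = 1e-8)
    expect_equal(got[["treatment"]], oracle[["treatment"]], tolerance = 1e-8)
    expect_equal(got[["residual"]], oracle[["residual"]], tolerance = 1e-8)
  }
})

test_that("GMR inverts when treatments swap and scales with the test arm", {
  d <- gen_be_dataset(12, gmr = 0.92, cv_w = 0.15, cv_b = 0.3, seed = 61)
  r1 <- gmr_ci(d, "cmax")
  swapped <- d
  swapped$treatment <- ifelse(d$treatment == "R", "T", "R")
  r2 <- gmr_ci(swapped, "cmax")
  expect_equal(r1$gmr * r2$gmr, 1, tolerance = 1e-12)
  scaled <- d
  c_ <- 1.17
  scaled$value <- ifelse(d$treatment == "T", d$value * c_, d$value)
  r3 <- gmr_ci(scaled, "cmax")
  expect_equal(r3$gmr, c_ * r1$gmr, tolerance = 1e-12)
  expect_equal(r3$ci90, c_ * r1$ci90, tolerance = 1e-12)
})

test_that("bioequivalence decision uses closed acceptance limits", {
  expect_true(be_decision(c(0.95, 1.05))$pass)
  expect_false(be_decision(c(0.78, 0.95))$pass)
  expect_true(be_decision(c(0.800, 1.250))$pass)
  expect_false(be_decision(c(0.799, 1.1))$pass)
  expect_error(be_decision(c(1.1, 0.9)), "lower <= upper")
})

test_that("malformed crossover data are rejected with diagnostics", {
  d <- gen_be_dataset(8, seed = 2)
  expect_error(crossover_anova(d[-1, ]), "offenders")
  neg <- d
  neg$value[3] <- 0
  expect_error(crossover_anova(neg), "positive")
})

test_that("TOST size at the upper acceptance boundary stays near 5%", {
  n_rep <- 2000
  passes <- 0L
  for (s in seq_len(n_rep)) {
    d <- gen_be_dataset(12, gmr = 1.25, cv_w = 0.15, cv_b = 0.3,
                        seed = 40000 + s)
    passes <- passes + gmr_ci(d)$tost_pass
  }
  # nominal size 0.05; allow 3 binomial SDs of Monte-Carlo error
  expect_lte(passes / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("report covers both parts and the simulated ER/IR pattern", {
  sp_r <- ir_spec(bsv_cv = 0.25, noise_cv = 0.05, seed = 77)
  sp_t <- er_spec(bsv_cv = 0.25, noise_cv = 0.05, seed = 77)
  tab <- gen_crossover_pk(sp_r, sp_t)
  long <- nca_long_dataset(nca_table(tab))
  rep1 <- be_report(long, long)
  expect_s3_class(rep1, "be_report")
  expect_equal(nrow(rep1), 8)
  expect_setequal(unique(rep1$part), c(1, 2))
  res <- as.data.frame(rep1[rep1$part == 1, ])
  gmr_of <- function(p) res$gmr[res$parameter == p]
  # slower absorption: lower Cmax, later Tmax, exposure preserved
  expect_lt(gmr_of("cmax"), 1)
  expect_gt(gmr_of("tmax"), 1)
  expect_lt(gmr_of("cmax"), gmr_of("auc_0_t"))
  expect_lt(gmr_of("auc_0_t"), gmr_of("tmax"))
})

test_that("summary-level mean ratios are labelled and computed directly", {
  out <- mean_ratio_be(c(cmax = 98.0512, tmax = 3.0295),
                       c(cmax = 84.0517, tmax = 5.1163))
  expect_identical(attr(out, "level"), "summary")
  expect_equal(out$ratio, c(84.0517 / 98.0512, 5.1163 / 3.0295))
  expect_error(mean_ratio_be(c(a = 1), c(b = 2)), "identical parameter names")
})
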