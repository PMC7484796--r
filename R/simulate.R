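#' Default blood-sampling schedule
#'
#' The 14-point single-dose sampling schedule used throughout: pre-dose at
#' 0 h, then 0.5, 1, 2, 3, 4, 5, 7, 9, 12, 18, 24, 36 and 48 h.
#'
#' @return Numeric vector of times in hours.
#' @export
default_pk_schedule <- function() {
  c(0, 0.5, 1, 2, 3, 4, 5, 7, 9, 12, 18, 24, 36, 48)
}

#' Simulation specification for one treatment arm
#'
#' Parameters of the one-compartment, first-order-absorption generative
#' model used for crossover plasma profiles:
#' `C(t) = D*ka / (V*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))`.
#' Between-subject variability is log-normal with coefficient of variation
#' `bsv_cv` applied to `ka`, `ke` and `v_over_f`; assay error is
#' multiplicative log-normal with CV `noise_cv`. The default immediate-
#' release absorption rate is 1.5/h; an extended-release arm is emulated
#' by lowering `ka` (default 0.45/h) at unchanged `ke` and `v_over_f`,
#' which delays Tmax and lowers Cmax without changing total exposure.
#'
#' @param dose_mg Dose in mg (default 60).
#' @param ka Absorption rate constant, 1/h.
#' @param ke Elimination rate constant, 1/h (default 0.12).
#' @param v_over_f Apparent volume of distribution V/F in litres
#'   (default 400, so Cl/F = V/F * ke = 48 l/h).
#' @param bsv_cv Between-subject CV (fraction) on ka, ke, V/F.
#' @param noise_cv Proportional assay-error CV (fraction).
#' @param schedule Sampling times, strictly increasing, starting at 0.
#' @param n_subjects Even number of subjects (1:1 sequence allocation).
#' @param seed Integer seed.
#' @return List of class `pk_sim_spec`.
#' @export
pk_sim_spec <- function(dose_mg = 60, ka = 1.5, ke = 0.12, v_over_f = 400,
                        bsv_cv = 0.25, noise_cv = 0.10,
                        schedule = default_pk_schedule(),
                        n_subjects = 12, seed = 1) {
  for (v in list(dose_mg, ka, ke, v_over_f)) {
    check_that(is_number(v) && v > 0, "PK parameters must be positive")
  }
  check_that(is_number(bsv_cv) && bsv_cv >= 0, "'bsv_cv' must be >= 0")
  check_that(is_number(noise_cv) && noise_cv >= 0, "'noise_cv' must be >= 0")
  check_that(is.numeric(schedule) && length(schedule) >= 4 &&
               schedule[1] == 0 && all(diff(schedule) > 0),
             "'schedule' must start at 0 and be strictly increasing")
  check_that(is_number(n_subjects) && n_subjects >= 4 &&
               n_subjects %% 2 == 0,
             "'n_subjects' must be an even number >= 4")
  structure(list(dose_mg = dose_mg, ka = ka, ke = ke, v_over_f = v_over_f,
                 bsv_cv = bsv_cv, noise_cv = noise_cv, schedule = schedule,
                 n_subjects = n_subjects, seed = as.integer(seed)),
            class = "pk_sim_spec")
}

#' One-compartment oral concentration curve
#'
#' Noiseless forward model for a single first-order absorption /
#' first-order elimination profile; concentrations in ng/ml for dose in
#' mg and volume in litres.
#'
#' @param t Times in hours.
#' @param dose_mg,ka,ke,v_over_f Model parameters as in [pk_sim_spec()];
#'   `ka` must differ from `ke`.
#' @return Concentrations (ng/ml).
#' @export
one_compartment_conc <- function(t, dose_mg, ka, ke, v_over_f) {
  check_that(abs(ka - ke) > 1e-12, "'ka' must differ from 'ke'")
  dose_ng <- dose_mg * 1e6
  v_ml <- v_over_f * 1e3
  dose_ng * ka / (v_ml * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Closed-form peak of the one-compartment curve
#'
#' `tmax = ln(ka/ke) / (ka - ke)`; `cmax` is the curve evaluated there.
#'
#' @inheritParams one_compartment_conc
#' @return List with `tmax` (h) and `cmax` (ng/ml).
#' @export
one_compartment_peak <- function(dose_mg, ka, ke, v_over_f) {
  check_that(abs(ka - ke) > 1e-12, "'ka' must differ from 'ke'")
  tmax <- log(ka / ke) / (ka - ke)
  list(tmax = tmax,
       cmax = one_compartment_conc(tmax, dose_mg, ka, ke, v_over_f))
}

lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a 2x2 crossover plasma study
#'
#' Generates the full subject-by-period plasma table of a two-treatment,
#' two-sequence crossover: subjects are allocated 1:1 to sequences RT and
#' TR; each subject receives the reference arm (from `spec`) and the test
#' arm (from `test_spec`) in the period dictated by its sequence. Subject
#' random effects (log-normal, CV `bsv_cv`) on ka, ke and V/F are drawn
#' once per subject and shared across both periods, which induces the
#' within-subject correlation a crossover design exploits; assay noise is
#' multiplicative log-normal per sample. If a subject's perturbed ka
#' collides with its ke, ka is nudged by 0.1% to keep the model defined.
#' Identical specs and seed reproduce the table bit-for-bit.
#'
#' @param spec Reference-arm [pk_sim_spec()]; its `seed`, `schedule`,
#'   `n_subjects`, `bsv_cv` and `noise_cv` drive the whole study.
#' @param test_spec Test-arm [pk_sim_spec()]; must share schedule and
#'   subject count with `spec`.
#' @return Data frame with columns `subject`, `sequence`, `period`,
#'   `treatment` (`"R"`/`"T"`), `time_h`, `conc_ng_ml`, `dose_mg`.
#' @export
gen_crossover_pk <- function(spec, test_spec = spec) {
  check_that(inherits(spec, "pk_sim_spec") && inherits(test_spec, "pk_sim_spec"),
             "specs must be built with pk_sim_spec()")
  check_that(identical(spec$schedule, test_spec$schedule),
             "reference and test specs must share the sampling schedule")
  check_that(spec$n_subjects == test_spec$n_subjects,
             "reference and test specs must share n_subjects")
  n <- spec$n_subjects
  sched <- spec$schedule
  with_seed(spec$seed, {
    sdlog <- lognormal_sdlog(spec$bsv_cv)
    eta <- matrix(stats::rnorm(3 * n, 0, sdlog), ncol = 3)
    noise_sdlog <- lognormal_sdlog(spec$noise_cv)
    rows <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      sequence <- if (i <= n / 2) "RT" else "TR"
      for (period in 1:2) {
        trt <- substr(sequence, period, period)
        arm <- if (trt == "R") spec else test_spec
        ka_i <- arm$ka * exp(eta[i, 1])
        ke_i <- arm$ke * exp(eta[i, 2])
        v_i <- arm$v_over_f * exp(eta[i, 3])
        if (abs(ka_i - ke_i) < 1e-8) ka_i <- ka_i * 1.001
        conc <- one_compartment_conc(sched, arm$dose_mg, ka_i, ke_i, v_i)
        if (spec$noise_cv > 0) {
          conc <- conc * exp(stats::rnorm(length(sched), 0, noise_sdlog))
        }
        conc[sched == 0] <- 0
        rows[[2 * (i - 1) + period]] <- data.frame(
          subject = i, sequence = sequence, period = period,
          treatment = trt, time_h = sched, conc_ng_ml = conc,
          dose_mg = arm$dose_mg, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a noisy dissolution profile
#'
#' Adds Gaussian noise (`noise_sd` percentage points) to the prediction of
#' one release-kinetics model, clips to [0, 100] and then monotonizes with
#' a running maximum -- a cumulative release curve cannot decrease. With
#' `noise_sd = 0` the output equals [predict_release()] exactly.
#'
#' @param model_id,params Release model and parameters, see
#'   [predict_release()].
#' @param times Sampling times (h), strictly increasing.
#' @param noise_sd Measurement noise SD in percentage points.
#' @param seed Integer seed.
#' @param formulation_id,medium Labels passed to the profile.
#' @return A [dissolution_profile()].
#' @export
gen_dissolution <- function(model_id, params, times, noise_sd = 0, seed = 1,
                            formulation_id = NA_character_,
                            medium = NA_character_) {
  check_that(is_number(noise_sd) && noise_sd >= 0, "'noise_sd' must be >= 0")
  clean <- predict_release(model_id, params, times)
  q <- if (noise_sd > 0) {
    with_seed(seed, clean + stats::rnorm(length(times), 0, noise_sd))
  } else {
    clean
  }
  q <- cummax(pmin(pmax(q, 0), 100))
  dissolution_profile(times, q, formulation_id = formulation_id,
                      medium = medium)
}

#' Simulate responses on a CCRD
#'
#' Evaluates a known polynomial surface on the coded design matrix and adds
#' Gaussian noise: `y = X beta + e`. `beta` is a named vector over
#' supported model terms (`"(Intercept)"`, main effects by factor name,
#' interactions like `"RL100:TEC"`, squares like `"RL100^2"`, and cubic
#' monomials); names outside the cubic term set are rejected.
#'
#' @param design A [ccrd_design()].
#' @param beta Named numeric coefficient vector on the coded scale.
#' @param noise_sd Response noise SD (response units).
#' @param seed Integer seed.
#' @return Numeric response vector, one value per run.
#' @export
gen_ccrd_response <- function(design, beta, noise_sd = 0, seed = 1) {
  check_that(inherits(design, "ccrd_design"), "'design' must be a ccrd_design")
  check_that(is.numeric(beta) && !is.null(names(beta)),
             "'beta' must be a named numeric vector")
  check_that(is_number(noise_sd) && noise_sd >= 0, "'noise_sd' must be >= 0")
  x <- rsm_model_matrix(design_coded_matrix(design), "cubic")
  unknown <- setdiff(names(beta), colnames(x))
  check_that(length(unknown) == 0,
             paste("unsupported model terms in beta:",
                   paste(unknown, collapse = ", ")))
  y <- as.numeric(x[, names(beta), drop = FALSE] %*% beta)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  y
}

#' Simulate QC replicate measurements
#'
#' `n` replicates drawn from `Normal(nominal, (cv * nominal)^2)`.
#'
#' @param nominal Nominal concentration (ng/ml), > 0.
#' @param cv Coefficient of variation as a fraction, >= 0.
#' @param n Number of replicates, >= 2.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_qc_replicates <- function(nominal, cv, n = 5, seed = 1) {
  check_that(is_number(nominal) && nominal > 0, "'nominal' must be positive")
  check_that(is_number(cv) && cv >= 0, "'cv' must be >= 0")
  check_that(is_number(n) && n >= 2, "'n' must be >= 2")
  with_seed(seed, stats::rnorm(n, nominal, cv * nominal))
}

#' Simulate a linear stability batch
#'
#' `assay(t) = assay0 + slope * t + e` with Gaussian noise, evaluated at
#' the given storage times.
#'
#' @param assay0 Assay at time zero, percent of label claim.
#' @param slope Degradation slope, percent per month (negative for loss).
#' @param noise_sd Assay noise SD in percentage points.
#' @param times_months Storage times, non-negative and increasing.
#' @param seed Integer seed.
#' @return Data frame with `time_months` and `assay_pct`.
#' @export
gen_stability <- function(assay0 = 100, slope = -0.2, noise_sd = 0,
                          times_months = c(0, 3, 6), seed = 1) {
  check_that(is_number(assay0) && assay0 > 0, "'assay0' must be positive")
  check_that(is_number(slope), "'slope' must be a number")
  check_that(is_number(noise_sd) && noise_sd >= 0, "'noise_sd' must be >= 0")
  check_that(is.numeric(times_months) && all(times_months >= 0) &&
               all(diff(times_months) > 0),
             "'times_months' must be non-negative and increasing")
  assay <- assay0 + slope * times_months
  if (noise_sd > 0) {
    assay <- with_seed(seed,
                       assay + stats::rnorm(length(times_months), 0, noise_sd))
  }
  data.frame(time_months = times_months, assay_pct = assay)
}

#' Simulate subject-level crossover PK parameter values
#'
#' Direct generator for bioequivalence simulations: log-normal PK
#' parameter values for a balanced 2x2 crossover with subject random
#' effects (between-subject CV `cv_b`), within-subject error (CV `cv_w`),
#' a true test/reference ratio `gmr`, and optional multiplicative
#' log-scale sequence and period effects.
#'
#' @param n_subjects Even subject count.
#' @param gmr True geometric mean ratio test/reference.
#' @param cv_w Within-subject CV (fraction).
#' @param cv_b Between-subject CV (fraction).
#' @param mu Log-scale grand mean.
#' @param seq_effect,period_effect Multiplicative effects applied to
#'   sequence 2 and period 2 (default 1 = none).
#' @param parameter Parameter label.
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `parameter`, `value`.
#' @export
gen_be_dataset <- function(n_subjects = 12, gmr = 1, cv_w = 0.15,
                           cv_b = 0.3, mu = log(100), seq_effect = 1,
                           period_effect = 1, parameter = "cmax", seed = 1) {
  check_that(is_number(n_subjects) && n_subjects >= 4 && n_subjects %% 2 == 0,
             "'n_subjects' must be even and >= 4")
  check_that(is_number(gmr) && gmr > 0, "'gmr' must be positive")
  sd_w <- lognormal_sdlog(cv_w)
  sd_b <- lognormal_sdlog(cv_b)
  with_seed(seed, {
    subj_eff <- stats::rnorm(n_subjects, 0, sd_b)
    subject <- rep(seq_len(n_subjects), each = 2)
    period <- rep(1:2, times = n_subjects)
    sequence <- ifelse(subject <= n_subjects / 2, "RT", "TR")
    treatment <- substr(sequence, period, period)
    lny <- mu + subj_eff[subject] +
      ifelse(treatment == "T", log(gmr), 0) +
      ifelse(sequence == "TR", log(seq_effect), 0) +
      ifelse(period == 2, log(period_effect), 0) +
      stats::rnorm(2 * n_subjects, 0, sd_w)
    data.frame(subject = subject, sequence = sequence, period = period,
               treatment = treatment, parameter = parameter,
               value = exp(lny), stringsAsFactors = FALSE)
  })
}
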