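#' Pipeline configuration
#'
#' Bundles the seeds and analysis options of the end-to-end synthetic
#' study run by [run_pipeline()]. Stage-level seeds are derived
#' deterministically from the master seed with small fixed offsets.
#'
#' @param seed Master integer seed.
#' @param be_limits Bioequivalence acceptance limits; must straddle 1.
#' @param f2_truncate Truncate f2 profiles after both exceed 85%?
#' @param auc_method Trapezoidal rule for NCA (see [auc_trapezoid()]).
#' @param n_subjects Subjects per crossover part (even).
#' @param stages Which stages to run; subset of
#'   `c("dissolution", "doe", "pk", "validation")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, be_limits = c(0.8, 1.25),
                            f2_truncate = FALSE, auc_method = "linear",
                            n_subjects = 12,
                            stages = c("dissolution", "doe", "pk",
                                       "validation")) {
  check_that(is_number(seed) && abs(seed) < 2^31 - 100,
             "'seed' must be a 32-bit integer")
  check_that(is.numeric(be_limits) && length(be_limits) == 2 &&
               be_limits[1] < 1 && be_limits[2] > 1,
             "'be_limits' must straddle 1")
  stages <- match.arg(stages, c("dissolution", "doe", "pk", "validation"),
                      several.ok = TRUE)
  structure(list(seed = as.integer(seed), be_limits = be_limits,
                 f2_truncate = isTRUE(f2_truncate),
                 auc_method = match.arg(auc_method,
                                        c("linear", "linuplogdown")),
                 n_subjects = n_subjects, stages = stages),
            class = "pipeline_config")
}

#' Run the synthetic end-to-end study
#'
#' Executes the full analysis chain on synthetic data in dependency
#' order: dissolution simulation, kinetic model ranking and profile
#' comparison; CCRD generation, response simulation and response-surface
#' fit summary; crossover plasma simulation, per-subject NCA and average
#' bioequivalence; QC and stability simulation with validation metrics
#' and shelf life. Deterministic: the same configuration reproduces the
#' identical result bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the stage tables are
#'   written there as schema-validated CSV files.
#' @return List of class `pellet_pipeline` with one element per executed
#'   stage plus the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  check_that(inherits(config, "pipeline_config"),
             "'config' must be a pipeline_config")
  seed <- config$seed
  out <- list(config = config)

  if ("dissolution" %in% config$stages) {
    times <- 1:12
    ref <- gen_dissolution("zero", 7.9, times, noise_sd = 1.2,
                           seed = seed + 1, formulation_id = "ER-ref",
                           medium = "0.01 N HCl")
    test <- gen_dissolution("zero", 7.6, times, noise_sd = 1.2,
                            seed = seed + 2, formulation_id = "ER-test",
                            medium = "0.01 N HCl")
    out$dissolution <- list(
      reference = ref, test = test,
      ranking = rank_release_models(ref),
      summary = profile_summary(ref),
      f2 = f2_similarity(ref, test, truncate_85 = config$f2_truncate))
  }

  if ("doe" %in% config$stages) {
    design <- ccrd_design(ccrd_reference_factors(), n_center = 6)
    beta <- c("(Intercept)" = 80, RL100 = -9, TEC = 1.2, talc = 0.8,
              "RL100^2" = -2.5)
    y <- gen_ccrd_response(design, beta, noise_sd = 1, seed = seed + 3)
    runs <- design$runs
    runs$release_12h_pct <- y
    out$doe <- list(design = design, response = y,
                    fit_summary = rsm_fit_summary(design, y),
                    selected = select_optimal(
                      runs, list(release_12h_pct = list(min = 90)),
                      tie_break = "actual_RL100"))
  }

  if ("pk" %in% config$stages) {
    ref_spec <- pk_sim_spec(ka = 1.5, n_subjects = config$n_subjects,
                            seed = seed + 4)
    test_spec <- pk_sim_spec(ka = 0.45, n_subjects = config$n_subjects,
                             seed = seed + 4)
    plasma <- gen_crossover_pk(ref_spec, test_spec)
    nca_tab <- nca_table(plasma, method = config$auc_method)
    long <- do.call(rbind, lapply(
      c("cmax", "tmax", "auc_0_t", "auc_0_inf"), function(p) {
        data.frame(subject = nca_tab$subject, sequence = nca_tab$sequence,
                   period = nca_tab$period, treatment = nca_tab$treatment,
                   parameter = p, value = nca_tab[[p]],
                   stringsAsFactors = FALSE)
      }))
    out$pk <- list(plasma = plasma, nca = nca_tab,
                   be = be_report(long, limits = config$be_limits))
  }

  if ("validation" %in% config$stages) {
    qc_low <- gen_qc_replicates(10, 0.014, n = 5, seed = seed + 5)
    qc_high <- gen_qc_replicates(200, 0.009, n = 5, seed = seed + 6)
    stab <- gen_stability(100, -0.2, noise_sd = 0.15,
                          times_months = c(0, 3, 6), seed = seed + 7)
    out$validation <- list(
      qc_low = accuracy_precision(qc_low, 10),
      qc_high = accuracy_precision(qc_high, 200),
      stability = stab,
      shelf_life = shelf_life(stab$time_months, stab$assay_pct))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$dissolution)) {
      pr <- out$dissolution$reference
      write_study_table(
        data.frame(formulation_id = pr$formulation_id, medium = pr$medium,
                   time_h = pr$times, released_pct = pr$released),
        file.path(out_dir, "dissolution.csv"), "dissolution")
    }
    if (!is.null(out$pk)) {
      write_study_table(out$pk$plasma, file.path(out_dir, "plasma.csv"),
                        "plasma")
      utils::write.csv(out$pk$nca, file.path(out_dir, "nca.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(out$pk$be),
                       file.path(out_dir, "be_report.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$validation)) {
      write_study_table(out$validation$stability,
                        file.path(out_dir, "stability.csv"), "stability")
    }
  }
  structure(out, class = "pellet_pipeline")
}

#' @export
print.pellet_pipeline <- function(x, ...) {
  cat("Synthetic pellet study pipeline (seed", x$config$seed, ")\n")
  if (!is.null(x$dissolution)) {
    cat(sprintf("  dissolution: best model %s, f2 = %.1f\n",
                x$dissolution$ranking[[1]]$model_id, x$dissolution$f2$f2))
  }
  if (!is.null(x$doe)) {
    cat(sprintf("  doe: recommended %s model\n",
                x$doe$fit_summary$recommended))
  }
  if (!is.null(x$pk)) {
    cmax_row <- as.data.frame(x$pk$be)
    cmax_row <- cmax_row[cmax_row$parameter == "cmax", ]
    cat(sprintf("  pk: Cmax GMR %.3f (90%% CI %.3f-%.3f)\n",
                cmax_row$gmr, cmax_row$ci90_low, cmax_row$ci90_high))
  }
  if (!is.null(x$validation)) {
    cat(sprintf("  validation: QC low CV %.2f %%; shelf life %s months\n",
                x$validation$qc_low$cv_pct,
                if (x$validation$shelf_life$censored) paste0("> ", x$validation$shelf_life$horizon)
                else sprintf("%.2f", x$validation$shelf_life$shelf_life_months)))
  }
  invisible(x)
}
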