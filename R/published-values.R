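#' Published summary PK means of the reference pellet study
#'
#' Arithmetic-mean pharmacokinetic parameters reported for the reference
#' bioavailability study of 60 mg meclizine HCl pellets: part 1 compared
#' immediate-release (IR) against extended-release (ER) pellets under
#' fasting; part 2 compared the ER pellets fed against fasted. Subject-
#' level data were not published, so these means support only the
#' summary-level mean-ratio reconstruction of [mean_ratio_be()]. The fed
#' Tmax follows the narrative value (5.5798 h), which is the one
#' consistent with the reported Tmax ratio; the tabulated fed Tmax
#' (5.117 h) is not.
#'
#' @return Data frame with columns `parameter`, `part1_ir`, `part1_er`,
#'   `part2_fasted`, `part2_fed`.
#' @export
meclizine_pk_means <- function() {
  path <- system.file("extdata", "pk_summary_means.csv", package = "pelletpk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published QC stability summary of the bioanalytical method
#'
#' Printed mean and sample-SD cells of the stability/recovery validation
#' table of the reference HPLC-fluorescence method (freeze-thaw,
#' long-term, stock-solution, benchtop and autosampler conditions at the
#' low and high QC levels). Used to recompute the self-consistent
#' precision (CV%) and accuracy cells with [cv_percent()] and
#' [accuracy_percent()].
#'
#' @return Data frame with columns `condition`, `conc_level`,
#'   `nominal_ng_ml`, `mean_ng_ml`, `sd_ng_ml`.
#' @export
qc_stability_summary <- function() {
  path <- system.file("extdata", "qc_stability_summary.csv",
                      package = "pelletpk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
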