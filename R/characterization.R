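#' Micromeritic flow properties of a pellet sample
#'
#' Bulk and tapped densities, Carr compressibility index, Hausner ratio and
#' (when heap dimensions are supplied) the angle of repose, with the flow
#' grade read off the compendial bands: CI <= 10% with HR <= 1.11 is
#' "excellent", CI 11--15% with HR <= 1.18 is "good", anything worse is
#' "other". The angle of repose is graded separately (25--30 degrees
#' excellent, 31--35 good).
#'
#' @param mass_g Sample mass in grams.
#' @param bulk_ml Bulk (poured) volume in ml.
#' @param tapped_ml Tapped volume in ml; must not exceed `bulk_ml`.
#' @param heap_height_mm,heap_base_mm Optional heap height and base diameter
#'   for the angle of repose, `atan(height / (0.5 * base))`.
#' @return Object of class `flow_properties`: bulk/tapped density (g/ml),
#'   `compressibility_index` (%), `hausner_ratio`, `angle_of_repose_deg`
#'   (NA if no heap data), `flow_grade`, `angle_grade`.
#' @examples
#' flow_properties(10, 12, 10)
#' @export
flow_properties <- function(mass_g, bulk_ml, tapped_ml,
                            heap_height_mm = NULL, heap_base_mm = NULL) {
  check_that(is_number(mass_g) && mass_g > 0, "'mass_g' must be positive")
  check_that(is_number(bulk_ml) && is_number(tapped_ml) && tapped_ml > 0,
             "volumes must be positive numbers")
  check_that(bulk_ml >= tapped_ml,
             "tapped volume cannot exceed bulk volume")
  bulk <- mass_g / bulk_ml
  tapped <- mass_g / tapped_ml
  ci <- (bulk_ml - tapped_ml) / bulk_ml * 100
  hr <- bulk_ml / tapped_ml
  angle <- NA_real_
  if (!is.null(heap_height_mm) && !is.null(heap_base_mm)) {
    check_that(is_number(heap_height_mm) && heap_height_mm >= 0 &&
                 is_number(heap_base_mm) && heap_base_mm > 0,
               "heap dimensions must be positive numbers")
    angle <- atan(heap_height_mm / (0.5 * heap_base_mm)) * 180 / pi
  }
  flow_grade <- if (ci <= 10 && hr <= 1.11) "excellent"
    else if (ci <= 15 && hr <= 1.18) "good"
    else "other"
  angle_grade <- if (is.na(angle)) NA_character_
    else if (angle >= 25 && angle <= 30) "excellent"
    else if (angle > 30 && angle <= 35) "good"
    else "other"
  structure(list(bulk_density = bulk, tapped_density = tapped,
                 compressibility_index = ci, hausner_ratio = hr,
                 angle_of_repose_deg = angle, flow_grade = flow_grade,
                 angle_grade = angle_grade),
            class = "flow_properties")
}

#' @export
print.flow_properties <- function(x, ...) {
  cat(sprintf("Flow: bulk %.3f g/ml, tapped %.3f g/ml, CI %.2f %%, HR %.3f -> %s\n",
              x$bulk_density, x$tapped_density, x$compressibility_index,
              x$hausner_ratio, x$flow_grade))
  if (!is.na(x$angle_of_repose_deg)) {
    cat(sprintf("  angle of repose %.2f deg -> %s\n",
                x$angle_of_repose_deg, x$angle_grade))
  }
  invisible(x)
}

#' Friability of a pellet sample
#'
#' Percent weight loss after mechanical stress,
#' `100 * (initial - final) / initial`; less than 1% is acceptable.
#'
#' @param initial_weight_g,final_weight_g Weights in grams before and after
#'   the friability test; `0 < final <= initial`.
#' @return List with `friability_pct` and logical `acceptable`.
#' @examples
#' friability(10, 9.95)
#' @export
friability <- function(initial_weight_g, final_weight_g) {
  check_that(is_number(initial_weight_g) && is_number(final_weight_g) &&
               final_weight_g > 0, "weights must be positive numbers")
  check_that(final_weight_g <= initial_weight_g,
             "final weight cannot exceed initial weight")
  pct <- 100 * (initial_weight_g - final_weight_g) / initial_weight_g
  list(friability_pct = pct, acceptable = pct < 1)
}

#' Capsule fill weight from tapped density
#'
#' Estimated fill weight of a capsule shell: tapped bulk density of the
#' pellets multiplied by the body volume of the shell.
#'
#' @param tapped_density_g_ml Tapped bulk density in g/ml.
#' @param body_volume_ml Capsule body volume in ml.
#' @return Fill weight in grams.
#' @examples
#' capsule_fill_weight(0.890, 0.37)
#' @export
capsule_fill_weight <- function(tapped_density_g_ml, body_volume_ml) {
  check_that(is_number(tapped_density_g_ml) && tapped_density_g_ml > 0,
             "'tapped_density_g_ml' must be positive")
  check_that(is_number(body_volume_ml) && body_volume_ml >= 0,
             "'body_volume_ml' must be non-negative")
  tapped_density_g_ml * body_volume_ml
}

#' Two-dimensional shape descriptors of a pellet
#'
#' Morphometric shape factors from image-analysis measurements of a single
#' pellet projection:
#'
#' * circularity `C = 4*pi*A / P^2`
#' * projection sphericity `PS = 4*A / (pi * dL^2)` with `dL` the longest
#'   Feret diameter
#' * aspect ratio `AR = dmax / dmin`
#' * circle-equivalent diameter `dce = sqrt(4*A/pi)`
#' * elongation correction factor `f = 1.008 - 0.231 * (1 - b/l)`
#' * two-dimensional shape factor
#'   `eR = (2*pi/P) * (re/f) - sqrt(1 - (b/l)^2)`, with the mean radius
#'   `re` taken as `dce/2` (radius of the area-equivalent circle), so a
#'   perfect circle scores `eR = 1/1.008 ~ 0.992`
#' * elongation ratio `width/height` when both are supplied
#'
#' All descriptors are dimensionless except `dce`; any consistent length
#' unit may be used (the factors are scale-invariant).
#'
#' @param area Projected area.
#' @param perimeter Projection perimeter.
#' @param feret_max,feret_min Longest and shortest Feret diameters.
#' @param breadth,length Pellet breadth `b` and length `l` (`b <= l`).
#' @param width,height Optional width and height for the elongation ratio.
#' @return Object of class `shape_factors` with fields `circularity`,
#'   `projection_sphericity`, `aspect_ratio`, `d_ce`, `correction_factor`,
#'   `shape_factor_er`, `mean_radius`, `elongation_ratio`.
#' @examples
#' r <- 1
#' shape_factors(pi * r^2, 2 * pi * r, 2 * r, 2 * r, 2 * r, 2 * r)
#' @export
shape_factors <- function(area, perimeter, feret_max, feret_min,
                          breadth, length, width = NULL, height = NULL) {
  for (v in list(area, perimeter, feret_max, feret_min, breadth, length)) {
    check_that(is_number(v) && v > 0, "all shape measurements must be positive")
  }
  check_that(feret_max >= feret_min, "'feret_max' must be >= 'feret_min'")
  check_that(length >= breadth, "'length' must be >= 'breadth'")
  circ <- 4 * pi * area / perimeter^2
  ps <- 4 * area / (pi * feret_max^2)
  ar <- feret_max / feret_min
  d_ce <- sqrt(4 * area / pi)
  r_e <- d_ce / 2
  bl <- breadth / length
  f <- 1.008 - 0.231 * (1 - bl)
  er <- (2 * pi / perimeter) * (r_e / f) - sqrt(1 - bl^2)
  elong <- NA_real_
  if (!is.null(width) && !is.null(height)) {
    check_that(is_number(width) && width > 0 && is_number(height) && height > 0,
               "width and height must be positive")
    elong <- width / height
  }
  structure(list(circularity = circ, projection_sphericity = ps,
                 aspect_ratio = ar, d_ce = d_ce, correction_factor = f,
                 shape_factor_er = er, mean_radius = r_e,
                 elongation_ratio = elong),
            class = "shape_factors")
}

#' @export
print.shape_factors <- function(x, ...) {
  cat(sprintf("Shape: C = %.3f, PS = %.3f, AR = %.3f, dce = %.3f, eR = %.3f (f = %.4f)\n",
              x$circularity, x$projection_sphericity, x$aspect_ratio,
              x$d_ce, x$shape_factor_er, x$correction_factor))
  invisible(x)
}

#' Sphericity acceptance of a pellet
#'
#' A pellet is acceptably spherical when its two-dimensional shape factor
#' is at least `er_min` (default 0.6, the literature limiting value) and
#' its aspect ratio at most `ar_max` (default 1.1).
#'
#' @param sf A `shape_factors` object, or a list with `shape_factor_er`
#'   and `aspect_ratio`.
#' @param er_min Minimum acceptable shape factor.
#' @param ar_max Maximum acceptable aspect ratio.
#' @return List with logical `acceptable` and character vector `reasons`
#'   naming each failed bound (empty when acceptable).
#' @export
classify_sphericity <- function(sf, er_min = 0.6, ar_max = 1.1) {
  check_that(!is.null(sf$shape_factor_er) && !is.null(sf$aspect_ratio),
             "'sf' must carry shape_factor_er and aspect_ratio")
  reasons <- character(0)
  if (sf$shape_factor_er < er_min) {
    reasons <- c(reasons,
                 sprintf("shape factor eR %.3f below limit %.2f",
                         sf$shape_factor_er, er_min))
  }
  if (sf$aspect_ratio > ar_max) {
    reasons <- c(reasons,
                 sprintf("aspect ratio %.3f above limit %.2f",
                         sf$aspect_ratio, ar_max))
  }
  list(acceptable = length(reasons) == 0L, reasons = reasons)
}
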