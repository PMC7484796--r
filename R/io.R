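# column schemas for the flat study tables; unit-suffixed column names are
# part of the contract (_h, _ng_ml, _pct, _g, _ml, _months)
study_schemas <- function() {
  list(
    dissolution = list(
      required = c(formulation_id = "character", medium = "character",
                   time_h = "numeric", released_pct = "numeric"),
      optional = character(0),
      key = c("formulation_id", "medium", "time_h"),
      bounds = list(time_h = c(0, Inf), released_pct = c(0, 110))
    ),
    plasma = list(
      required = c(subject = "character", sequence = "character",
                   period = "numeric", treatment = "character",
                   time_h = "numeric", conc_ng_ml = "numeric",
                   dose_mg = "numeric"),
      optional = c(condition = "character"),
      key = c("subject", "period", "time_h"),
      bounds = list(time_h = c(0, Inf), conc_ng_ml = c(0, Inf),
                    dose_mg = c(1e-12, Inf))
    ),
    flow = list(
      required = c(sample_id = "character", mass_g = "numeric",
                   bulk_ml = "numeric", tapped_ml = "numeric"),
      optional = c(heap_height_mm = "numeric", heap_base_mm = "numeric"),
      key = "sample_id",
      bounds = list(mass_g = c(1e-12, Inf), bulk_ml = c(1e-12, Inf),
                    tapped_ml = c(1e-12, Inf))
    ),
    shapes = list(
      required = c(pellet_id = "character", area = "numeric",
                   perimeter = "numeric", feret_max = "numeric",
                   feret_min = "numeric", breadth = "numeric",
                   length = "numeric"),
      optional = c(width = "numeric", height = "numeric"),
      key = "pellet_id",
      bounds = list(area = c(1e-12, Inf), perimeter = c(1e-12, Inf),
                    feret_max = c(1e-12, Inf), feret_min = c(1e-12, Inf),
                    breadth = c(1e-12, Inf), length = c(1e-12, Inf))
    ),
    qc = list(
      required = c(condition = "character", nominal_ng_ml = "numeric",
                   value_ng_ml = "numeric"),
      optional = character(0),
      key = NULL,
      bounds = list(nominal_ng_ml = c(1e-12, Inf), value_ng_ml = c(0, Inf))
    ),
    stability = list(
      required = c(time_months = "numeric", assay_pct = "numeric"),
      optional = character(0),
      key = "time_months",
      bounds = list(time_months = c(0, Inf), assay_pct = c(0, Inf))
    )
  )
}

convert_numeric_checked <- function(x, col) {
  x <- trimws(x)
  if (any(grepl(",", x, fixed = TRUE))) {
    stop("column '", col, "' contains decimal commas; ",
         "use '.' as the decimal separator", call. = FALSE)
  }
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "")
  if (length(bad)) {
    stop("column '", col, "' has a non-numeric value in row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  v
}

#' Read a validated study table
#'
#' CSV reader with schema validation for the flat tables the pipeline
#' exchanges: `dissolution` (formulation_id, medium, time_h,
#' released_pct), `plasma` (subject, sequence, period, treatment, time_h,
#' conc_ng_ml, dose_mg), `flow`, `shapes`, `qc` and `stability`. Missing
#' or misnamed columns abort with the column name; numeric columns reject
#' decimal commas and out-of-domain values (e.g. negative concentrations);
#' duplicate key rows are rejected.
#'
#' @param path CSV file path (header row required).
#' @param schema One of `"dissolution"`, `"plasma"`, `"flow"`,
#'   `"shapes"`, `"qc"`, `"stability"`.
#' @return Validated data frame with typed columns.
#' @export
read_study_table <- function(path, schema) {
  schemas <- study_schemas()
  schema <- match.arg(schema, names(schemas))
  sc <- schemas[[schema]]
  check_that(file.exists(path), paste0("file not found: ", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(sc$required), names(raw))
  if (length(missing)) {
    stop("table '", schema, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  types <- c(sc$required, sc$optional[names(sc$optional) %in% names(raw)])
  out <- raw[names(types)]
  for (col in names(types)) {
    if (types[[col]] == "numeric") {
      out[[col]] <- convert_numeric_checked(out[[col]], col)
      b <- sc$bounds[[col]]
      if (!is.null(b)) {
        bad <- which(!is.na(out[[col]]) &
                       (out[[col]] < b[1] | out[[col]] > b[2]))
        if (length(bad)) {
          stop("column '", col, "' out of range [", b[1], ", ", b[2],
               "] in row ", bad[1], call. = FALSE)
        }
      }
    }
  }
  if (!is.null(sc$key)) {
    keys <- do.call(paste, c(out[sc$key], sep = "\r"))
    if (anyDuplicated(keys)) {
      stop("duplicate key (", paste(sc$key, collapse = ", "),
           ") in table '", schema, "'", call. = FALSE)
    }
  }
  out
}

#' Write a study table
#'
#' Validates a data frame against a schema (see [read_study_table()]) by
#' a write-read round trip contract and writes it as CSV.
#'
#' @param data Data frame to write.
#' @param path Destination CSV path.
#' @param schema Schema name, as in [read_study_table()].
#' @return Invisibly, the path.
#' @export
write_study_table <- function(data, path, schema) {
  schemas <- study_schemas()
  schema <- match.arg(schema, names(schemas))
  sc <- schemas[[schema]]
  missing <- setdiff(names(sc$required), names(data))
  if (length(missing)) {
    stop("cannot write '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
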