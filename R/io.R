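# Tabular IO for subject and item tables (CSV natively, Parquet when the
# arrow package is available). Tables are read column-wise as text and
# converted explicitly so that schema and parse errors can name the
# offending column and row.

subject_enums <- function() {
  list(
    sex = c("male", "female"),
    ethnicity = c("Mexican American", "Other Hispanic", "NH White",
                  "NH Black", "Other"),
    pir_level = c("<1.35", "1.35-1.85", ">1.85"),
    physical_activity = c("sedentary", "moderate", "vigorous"),
    weight_status = c("under", "normal", "over", "obese")
  )
}

subject_columns <- function() {
  c("subject_id", "age_years", "sex", "ethnicity", "pir_level",
    "physical_activity", "weight_status", "pregnant_or_lactating",
    "recall_reliable", "day1_weight", "stratum_id", "psu_id")
}

item_columns <- function() {
  c("subject_id", "food_code", "wweia_code", "occasion_code", "grams",
    nutrient_names())
}

read_table_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package", call. = FALSE)
    }
    return(as.data.frame(arrow::read_parquet(path)))
  }
  as.data.frame(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE))
}

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(what, " table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

parse_numeric <- function(x, column) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop("non-numeric value in column '", column, "' at row ",
         bad[1], ": \"", x[bad[1]], "\"", call. = FALSE)
  }
  out
}

parse_flag <- function(x, column) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop("column '", column, "' has non-flag value at row ", bad[1],
         call. = FALSE)
  }
  out
}

check_enum <- function(x, column, levels) {
  bad <- which(!(x %in% levels))
  if (length(bad) > 0) {
    stop("column '", column, "' has unknown category \"", x[bad[1]],
         "\" at row ", bad[1], " (expected one of: ",
         paste(levels, collapse = ", "), ")", call. = FALSE)
  }
  x
}

#' Read a subject table
#'
#' One row per child: demographics, eligibility flags, and the survey
#' design variables (day-1 dietary weight, stratum, PSU). Categorical
#' fields are validated against the package's enumerations; see
#' `milksub:::subject_enums()` for the accepted labels.
#'
#' @param path CSV (or Parquet, with the arrow package) file path.
#' @return A tibble with one validated row per subject.
#' @export
read_subjects <- function(path) {
  raw <- read_table_raw(path)
  check_columns(raw, subject_columns(), "subject")
  enums <- subject_enums()
  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    age_years = parse_numeric(raw$age_years, "age_years"),
    sex = check_enum(as.character(raw$sex), "sex", enums$sex),
    ethnicity = check_enum(as.character(raw$ethnicity), "ethnicity",
                           enums$ethnicity),
    pir_level = check_enum(as.character(raw$pir_level), "pir_level",
                           enums$pir_level),
    physical_activity = check_enum(as.character(raw$physical_activity),
                                   "physical_activity",
                                   enums$physical_activity),
    weight_status = check_enum(as.character(raw$weight_status),
                               "weight_status", enums$weight_status),
    pregnant_or_lactating = parse_flag(raw$pregnant_or_lactating,
                                       "pregnant_or_lactating"),
    recall_reliable = parse_flag(raw$recall_reliable, "recall_reliable"),
    day1_weight = parse_numeric(raw$day1_weight, "day1_weight"),
    stratum_id = as.character(raw$stratum_id),
    psu_id = as.character(raw$psu_id)
  )
  if (any(out$day1_weight < 0)) {
    stop("negative day1_weight at row ", which(out$day1_weight < 0)[1],
         call. = FALSE)
  }
  out
}

#' Read a food-item table
#'
#' One row per reported food or beverage item: subject key, USDA food code,
#' 4-digit WWEIA category code, meal-occasion code, grams consumed, and the
#' 18-nutrient panel. Negative nutrient values are rejected, as are items
#' reporting zero grams with nonzero nutrients.
#'
#' @inheritParams read_subjects
#' @return A tibble with one validated row per item.
#' @export
read_items <- function(path) {
  raw <- read_table_raw(path)
  check_columns(raw, item_columns(), "item")
  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    food_code = parse_numeric(raw$food_code, "food_code"),
    wweia_code = parse_numeric(raw$wweia_code, "wweia_code"),
    occasion_code = parse_numeric(raw$occasion_code, "occasion_code"),
    grams = parse_numeric(raw$grams, "grams")
  )
  for (nm in nutrient_names()) out[[nm]] <- parse_numeric(raw[[nm]], nm)
  if (nrow(out) == 0) return(out)
  if (any(out$grams < 0)) {
    stop("negative grams at row ", which(out$grams < 0)[1], call. = FALSE)
  }
  validate_nutrients(out)
  nut <- as.matrix(out[nutrient_names()])
  bad <- which(out$grams == 0 & rowSums(nut) > 0)
  if (length(bad) > 0) {
    stop("item with grams = 0 but nonzero nutrients at row ", bad[1],
         call. = FALSE)
  }
  out
}

#' Write subject or item tables
#'
#' CSV writers that round-trip numeric values at full double precision
#' (Parquet is used instead when the path ends in `.parquet` and arrow is
#' available).
#'
#' @param x Table to write.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_table <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing Parquet requires the 'arrow' package", call. = FALSE)
    }
    arrow::write_parquet(x, path)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
write_subjects <- function(x, path) write_table(x, path)

#' @rdname write_table
#' @export
write_items <- function(x, path) write_table(x, path)

#' Write an estimate table
#'
#' Serializes point estimates with linearized SEs (columns `quantity`,
#' `age_group`, `estimate`, `se`, `n`, plus any trend columns present) as
#' CSV.
#'
#' @param x An estimate table tibble.
#' @param path Destination CSV path.
#' @export
write_estimates <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
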