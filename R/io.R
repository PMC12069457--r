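# CSV readers/writers with schema validation. Outputs are byte-stable
# under a fixed seed: rows sorted by stable keys, written with
# data.table::fwrite at full precision so a write/read round trip
# reproduces the table.

.write_table <- function(df, path, key = NULL) {
  dt <- as.data.table(df)
  key <- intersect(key %||% character(0), names(dt))
  if (length(key)) setorderv(dt, key)
  fwrite(dt, path)
  invisible(path)
}

.schema_error <- function(file, msg) {
  stop(sprintf("%s: %s", file, msg), call. = FALSE)
}

#' Validate a cell table
#'
#' Requires `sample_id`, `patient_id`, `x_um`, `y_um`; coordinates must be
#' numeric and non-missing. Violations are reported naming the column.
#'
#' @param cells data.frame to validate.
#' @param file Label used in error messages.
#' @return The validated table, invisibly usable.
#' @export
validate_cells <- function(cells, file = "cells") {
  req <- c("sample_id", "patient_id", "x_um", "y_um")
  missing <- setdiff(req, names(cells))
  if (length(missing)) {
    .schema_error(file, paste0("missing required column(s): ",
                               paste(missing, collapse = ", ")))
  }
  for (col in c("x_um", "y_um")) {
    if (!is.numeric(cells[[col]])) {
      .schema_error(file, sprintf("column %s must be numeric", col))
    }
    if (anyNA(cells[[col]])) {
      .schema_error(file, sprintf("column %s has missing values (row %d)",
                                  col, which(is.na(cells[[col]]))[1L]))
    }
  }
  cells
}

#' Validate a clinical table
#'
#' Requires `patient_id`, `time_months` (positive numeric) and `event`
#' (0/1).
#'
#' @inheritParams validate_cells
#' @param clinical data.frame to validate.
#' @export
validate_clinical <- function(clinical, file = "clinical") {
  req <- c("patient_id", "time_months", "event")
  missing <- setdiff(req, names(clinical))
  if (length(missing)) {
    .schema_error(file, paste0("missing required column(s): ",
                               paste(missing, collapse = ", ")))
  }
  if (!is.numeric(clinical$time_months) || any(is.na(clinical$time_months)) ||
        any(clinical$time_months <= 0)) {
    .schema_error(file, "column time_months must be positive numeric")
  }
  if (!all(clinical$event %in% c(0, 1))) {
    bad <- which(!clinical$event %in% c(0, 1))[1L]
    .schema_error(file, sprintf("column event must be 0/1 (row %d)", bad))
  }
  clinical
}

#' Read and write cell tables
#'
#' `write_cells()` sorts rows by `sample_id`/`cell_id` and writes CSV;
#' `read_cells()` reads and validates the schema.
#'
#' @param path CSV path.
#' @param cells Cell table.
#' @return `read_cells()`: validated data.frame. `write_cells()`: the path,
#'   invisibly.
#' @export
read_cells <- function(path) {
  df <- setDF(fread(path))
  validate_cells(df, file = path)
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  validate_cells(cells)
  .write_table(cells, path, key = c("sample_id", "cell_id"))
}

#' Read and write clinical tables
#'
#' @param path CSV path.
#' @param clinical Clinical table.
#' @export
read_clinical <- function(path) {
  df <- setDF(fread(path))
  # all-missing character columns (e.g. site in a single-site cohort) are
  # read as logical NA; restore the schema type
  for (col in intersect(c("stage", "site", "sex"), names(df))) {
    if (is.logical(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  validate_clinical(df, file = path)
}

#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  .write_table(clinical, path, key = "patient_id")
}

#' Read and write generic result tables
#'
#' Rows are sorted by the given key columns (those present) before
#' writing, keeping outputs byte-stable across runs.
#'
#' @param path CSV path.
#' @param results data.frame.
#' @param key Candidate key columns for the stable sort.
#' @export
read_results <- function(path) {
  setDF(fread(path))
}

#' @rdname read_results
#' @export
write_results <- function(results, path,
                          key = c("stratum", "family", "sample_id",
                                  "feature", "neighborhood", "type")) {
  .write_table(results, path, key = key)
}
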