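.pk_dataset_schema <- c(
  subject_id = "character", species = "character", group = "character",
  dose_group = "numeric", scan = "integer", time_min = "numeric",
  obs_type = "character", region = "character", value = "numeric",
  body_weight_g = "numeric", injected_kBq = "numeric",
  inj_dur_min = "numeric", tq_start_min = "numeric", tq_dur_min = "numeric"
)

#' Validate a long-format PK dataset
#'
#' Checks the long-format observation table against the dataset schema:
#' mandatory columns, numeric values, uniqueness of
#' (subject, scan, time, observation type), and that every subject has at
#' least one plasma and one brain record per scan. Violations raise an error
#' naming the offending column or rows.
#'
#' @param data a data frame.
#' @return The data invisibly (with class `pk_dataset`), for piping.
#' @export
validate_pk_dataset <- function(data) {
  missing_cols <- setdiff(names(.pk_dataset_schema), names(data))
  if (length(missing_cols)) {
    abort(paste0("Dataset is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("time_min", "value", "body_weight_g", "injected_kBq")) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("Column `%s` must be numeric.", col))
    }
  }
  if (any(!is.finite(data$value))) {
    abort(paste0("Non-finite `value` at row(s): ",
                 paste(head(which(!is.finite(data$value)), 5), collapse = ", ")))
  }
  key <- paste(data$subject_id, data$scan, data$time_min, data$obs_type)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (subject, scan, time, obs_type) at row(s): ",
                 paste(head(which(duplicated(key)), 5), collapse = ", ")))
  }
  cover <- dplyr::count(data, .data$subject_id, .data$scan, .data$obs_type)
  full <- tidyr::expand_grid(
    subject_id = unique(data$subject_id),
    scan = unique(data$scan), obs_type = c("plasma", "brain"))
  gap <- dplyr::anti_join(full, cover, by = c("subject_id", "scan", "obs_type"))
  if (nrow(gap)) {
    abort(paste0("Subject ", gap$subject_id[1], " scan ", gap$scan[1],
                 " has no ", gap$obs_type[1], " records."))
  }
  if (!inherits(data, "pk_dataset")) class(data) <- c("pk_dataset", class(data))
  invisible(data)
}

#' Read and write long-format PK datasets
#'
#' CSV serialization of the long-format observation table produced by
#' [simulate_dataset()]. Round trips are lossless to full double precision
#' (values are written with 15 significant digits).
#'
#' @param path file path.
#' @param data a `pk_dataset` tibble.
#' @return `read_pk_dataset()` returns a validated `pk_dataset` tibble;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            subject_id = "c", species = "c", group = "c",
                            obs_type = "c", region = "c", scan = "i",
                            .default = "d"))
  data <- validate_pk_dataset(data)
  data
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  validate_pk_dataset(data)
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double), ~ signif(.x, 15)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write time-activity curve CSV files
#'
#' TAC files have columns `label`, `time_min`, `value`, `unit`
#' (`kBq_per_ml` or `SUV`).
#'
#' @param path file path.
#' @param x a [tac()] tibble.
#' @return `read_tac()` returns a validated TAC tibble.
#' @export
read_tac <- function(path) {
  x <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(label = "c", unit = "c",
                                            .default = "d")))
  need <- c("label", "time_min", "value", "unit")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("TAC file missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$unit %in% c("kBq_per_ml", "SUV"))) {
    abort("TAC `unit` must be 'kBq_per_ml' or 'SUV'.")
  }
  x
}

#' @rdname read_tac
#' @export
write_tac <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
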