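#' Trial dataset container
#'
#' A tidy long-format record of one simulated trial: measurement rows
#' (patient, observable, time, value), dose rows (patient, time, dose) and the
#' cohort covariates table, plus run metadata (trial name, seed, configuration
#' hash, stopped patients).
#'
#' @param measurements Tibble with columns `patient_id`, `observable`
#'   (`"warfarin_conc_mg_per_L"` or `"INR"`), `time_h`, `value`.
#' @param doses Tibble with columns `patient_id`, `time_h`, `dose_mg`.
#' @param covariates Tibble with columns `patient_id`, `cyp2c9`, `vkorc1`,
#'   `age`.
#' @param metadata Named list; typically `trial`, `seed`, `config_hash`,
#'   `stopped`.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(measurements, doses, covariates, metadata = list()) {
  measurements <- tibble::as_tibble(measurements)
  doses <- tibble::as_tibble(doses)
  covariates <- tibble::as_tibble(covariates)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(measurements, c("patient_id", "observable", "time_h", "value"),
       "measurements")
  need(doses, c("patient_id", "time_h", "dose_mg"), "doses")
  need(covariates, c("patient_id", "cyp2c9", "vkorc1", "age"), "covariates")
  known <- unique(covariates$patient_id)
  if (!all(measurements$patient_id %in% known) ||
      !all(doses$patient_id %in% known))
    stop("every patient_id in rows must appear in the covariates table",
         call. = FALSE)
  if (nrow(measurements) && any(measurements$value <= 0))
    stop("measurement values must be positive", call. = FALSE)
  structure(list(measurements = measurements, doses = doses,
                 covariates = covariates, metadata = metadata),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset '%s': %d patients, %d measurements, %d doses>\n",
              x$metadata$trial %||% "?", nrow(x$covariates),
              nrow(x$measurements), nrow(x$doses)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trial dataset
#'
#' A dataset is stored as a directory of three CSV files with fixed column
#' order -- `measurements.csv` (ID, Observable, Time_h, Value), `doses.csv`
#' (ID, Time_h, Dose_mg), `covariates.csv` (ID, CYP2C9, VKORC1, Age) -- plus
#' `metadata.json`. Numeric columns are written with full round-trip
#' precision, so write/read is bit-exact. Unknown extra columns are accepted
#' with a warning and preserved on write.
#'
#' @param dataset A [trial_dataset()].
#' @param path Directory path (created if missing).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` a
#'   [trial_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rename <- function(df, map) {
    i <- match(names(map), names(df))
    names(df)[i[!is.na(i)]] <- unname(map[!is.na(i)])
    df[, c(unname(map), setdiff(names(df), unname(map))), drop = FALSE]
  }
  write_exact(rename(dataset$measurements,
                     c(patient_id = "ID", observable = "Observable",
                       time_h = "Time_h", value = "Value")),
              file.path(path, "measurements.csv"))
  write_exact(rename(dataset$doses,
                     c(patient_id = "ID", time_h = "Time_h",
                       dose_mg = "Dose_mg")),
              file.path(path, "doses.csv"))
  write_exact(rename(dataset$covariates,
                     c(patient_id = "ID", cyp2c9 = "CYP2C9",
                       vkorc1 = "VKORC1", age = "Age")),
              file.path(path, "covariates.csv"))
  jsonlite::write_json(dataset$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# CSV writer with shortest-round-trip numeric formatting (17 significant
# digits survive double -> text -> double exactly)
write_exact <- function(df, file) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) formatC(col, digits = 17, format = "g") else col
  })
  utils::write.csv(as.data.frame(fmt, check.names = FALSE), file,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  grab <- function(file, map, types) {
    f <- file.path(path, file)
    if (!file.exists(f))
      stop(sprintf("dataset is missing '%s'", file), call. = FALSE)
    df <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(names(map), names(df))
    if (length(miss))
      stop(sprintf("schema mismatch in '%s': missing column(s) %s", file,
                   paste(miss, collapse = ", ")), call. = FALSE)
    extra <- setdiff(names(df), names(map))
    if (length(extra))
      warning(sprintf("'%s' has unknown column(s) %s; preserved", file,
                      paste(extra, collapse = ", ")), call. = FALSE)
    for (i in seq_along(map)) {
      ty <- types[[i]]
      col <- names(map)[i]
      if (ty %in% c("numeric", "integer") && !is.numeric(df[[col]]))
        stop(sprintf("schema mismatch in '%s': column %s is not %s", file,
                     col, ty), call. = FALSE)
      if (ty == "character" && !is.character(df[[col]]))
        stop(sprintf("schema mismatch in '%s': column %s is not %s", file,
                     col, ty), call. = FALSE)
      # integers in CSV read back as integer; restore declared storage type
      if (ty == "numeric") df[[col]] <- as.numeric(df[[col]])
      if (ty == "integer") df[[col]] <- as.integer(df[[col]])
    }
    names(df)[match(names(map), names(df))] <- unname(map)
    tibble::as_tibble(df[, c(unname(map), extra), drop = FALSE])
  }
  meas <- grab("measurements.csv",
               c(ID = "patient_id", Observable = "observable",
                 Time_h = "time_h", Value = "value"),
               list("integer", "character", "numeric", "numeric"))
  doses <- grab("doses.csv",
                c(ID = "patient_id", Time_h = "time_h", Dose_mg = "dose_mg"),
                list("integer", "numeric", "numeric"))
  cov <- grab("covariates.csv",
              c(ID = "patient_id", CYP2C9 = "cyp2c9", VKORC1 = "vkorc1",
                Age = "age"),
              list("integer", "character", "character", "integer"))
  meta_file <- file.path(path, "metadata.json")
  meta <- if (file.exists(meta_file))
    jsonlite::read_json(meta_file, simplifyVector = TRUE) else list()
  trial_dataset(meas, doses, cov, meta)
}
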