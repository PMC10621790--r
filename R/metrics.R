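#' Therapeutic INR range
#'
#' The standard warfarin therapeutic window: INRs in `[low, high]` are
#' considered effective and safe, with `target` the individualisation target.
#'
#' @param low,high Range bounds (low < target < high).
#' @param target Target INR.
#' @return A `therapeutic_range` object.
#' @export
therapeutic_range <- function(low = 2, high = 3, target = 2.5) {
  stopifnot(low < target, target < high)
  structure(list(low = low, high = high, target = target),
            class = "therapeutic_range")
}

#' Time in therapeutic range
#'
#' Fraction of INR measurements inside the therapeutic range (bounds
#' inclusive). The denominator is the number of measurements in the series,
#' i.e. the scheduled daily measurements of the trial.
#'
#' @param inr_series Ordered numeric vector of INR measurements (non-empty).
#' @param range A [therapeutic_range()].
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' ttr(c(1.5, 2.2, 2.6, 3.4), therapeutic_range()) # 0.5
ttr <- function(inr_series, range = therapeutic_range()) {
  if (length(inr_series) == 0)
    stop("inr_series must be non-empty", call. = FALSE)
  stopifnot(inherits(range, "therapeutic_range"))
  mean(inr_series >= range$low & inr_series <= range$high)
}

#' Summarise a trial into per-patient outcomes and the cohort success rate
#'
#' For every patient with at least one INR row: the maintenance INR is the
#' measurement on the last monitoring day, the peak INR the largest
#' measurement recorded during the trial, the TTR the fraction of INR
#' measurements inside the range, and success means the maintenance INR lies
#' inside the range. Patients without INR rows are excluded with a warning.
#'
#' @param dataset A [trial_dataset()].
#' @param range A [therapeutic_range()].
#' @return A `trial_outcome`: list with `patients` (tibble: patient_id,
#'   maintenance_inr, peak_inr, ttr, success) and `success_rate`.
#' @export
summarise_trial <- function(dataset, range = therapeutic_range()) {
  stopifnot(inherits(dataset, "trial_dataset"))
  inr <- dataset$measurements[dataset$measurements$observable == "INR", ]
  ids <- unique(dataset$covariates$patient_id)
  missing <- setdiff(ids, unique(inr$patient_id))
  if (length(missing)) {
    warning(sprintf("%d patient(s) without INR rows excluded from outcomes",
                    length(missing)), call. = FALSE)
    ids <- setdiff(ids, missing)
  }
  if (length(ids) == 0)
    stop("dataset contains no INR measurements; outcomes are INR-based",
         call. = FALSE)
  rows <- lapply(ids, function(id) {
    s <- inr[inr$patient_id == id, ]
    s <- s[order(s$time_h), ]
    tibble::tibble(patient_id = id,
                   maintenance_inr = s$value[nrow(s)],
                   peak_inr = max(s$value),
                   ttr = ttr(s$value, range))
  })
  patients <- do.call(rbind, rows)
  patients$success <- patients$maintenance_inr >= range$low &
    patients$maintenance_inr <= range$high
  structure(list(patients = patients,
                 success_rate = mean(patients$success)),
            class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat(sprintf(paste0("<trial_outcome: %d patients, success rate %.1f%%, ",
                     "median TTR %.0f%%, max peak INR %.2f>\n"),
              nrow(x$patients), 100 * x$success_rate,
              100 * stats::median(x$patients$ttr), max(x$patients$peak_inr)))
  invisible(x)
}
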