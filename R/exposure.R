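#' Case/control window specification
#'
#' Offsets count whole days before the index date; day 0 (the index date
#' itself) is never part of any window, since same-day dispensing is
#' ambiguous between cause and consequence of the event. Both endpoints are
#' inclusive. The default compares days 1-7 (case period) with days 15-21
#' (control period), leaving a one-week wash-out in between; the extended
#' variant uses 1-14 against 29-42.
#'
#' @param case_range integer length-2, inclusive offset range of the case
#'   period (smaller offsets = closer to the event).
#' @param control_range integer length-2, inclusive offset range of the
#'   control period; must be equally long and strictly earlier in time
#'   (larger offsets).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(case_range = c(1L, 7L), control_range = c(15L, 21L)) {
  case_range <- as.integer(case_range)
  control_range <- as.integer(control_range)
  stopifnot(length(case_range) == 2L, length(control_range) == 2L)
  if (case_range[1] < 1L || case_range[2] < case_range[1])
    stop("case_range must be an increasing pair of offsets >= 1", call. = FALSE)
  if (control_range[2] < control_range[1])
    stop("control_range must be an increasing pair of offsets", call. = FALSE)
  if (diff(case_range) != diff(control_range))
    stop("case and control periods must have equal length", call. = FALSE)
  if (control_range[1] <= case_range[2])
    stop("control period must lie strictly earlier than the case period ",
         "(larger offsets)", call. = FALSE)
  structure(list(case_range = case_range, control_range = control_range),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("case period %d-%d days, control period %d-%d days before index (wash-out %d-%d)\n",
              x$case_range[1], x$case_range[2],
              x$control_range[1], x$control_range[2],
              x$case_range[2] + 1L, x$control_range[1] - 1L))
  invisible(x)
}

#' Patient eligibility filters
#'
#' Filters compose conjunctively. `require_prior_year_rx` keeps only
#' patients with at least one dispensing 1-365 days (inclusive) before the
#' index date, mirroring registries where institutionalized patients cannot
#' be identified directly. `hospital_only` drops index events ascertained
#' from a cause-of-death register. `age_split_at` with `age_side` restricts
#' to one side of an age cut ("below" keeps age < cut, "above" keeps
#' age >= cut).
#'
#' @param hospital_only logical.
#' @param require_prior_year_rx logical.
#' @param age_split_at optional integer age cut (e.g. 80), or `NULL`.
#' @param age_side which side of the cut to keep; ignored when
#'   `age_split_at` is `NULL`.
#' @return object of class `eligibility_filters`.
#' @export
eligibility_filters <- function(hospital_only = FALSE,
                                require_prior_year_rx = FALSE,
                                age_split_at = NULL,
                                age_side = c("below", "above")) {
  age_side <- match.arg(age_side)
  if (!is.null(age_split_at)) age_split_at <- as.integer(age_split_at)
  structure(list(hospital_only = isTRUE(hospital_only),
                 require_prior_year_rx = isTRUE(require_prior_year_rx),
                 age_split_at = age_split_at,
                 age_side = age_side),
            class = "eligibility_filters")
}

#' Build per-patient case/control exposure indicators
#'
#' For every retained patient and every drug, the case (control) bit is 1
#' iff at least one dispensing falls in the case (control) window, where a
#' dispensing at offset `o = index_date - dispense_date` is in a window when
#' `o` lies inside its inclusive range. Exposure is binary per window: the
#' number and quantity of dispensings are deliberately ignored.
#'
#' Patients are retained only if they pass all eligibility filters and have
#' at least one dispensing in the case or control period; drug columns are
#' restricted to drugs with at least one exposed period in either window.
#' Dispensings of patients absent from the event table are dropped (their
#' count is recorded in the result).
#'
#' @param dispensings data.frame with columns `patient_id`, `drug_code`,
#'   `dispense_date`.
#' @param events data.frame with columns `patient_id`, `index_date`,
#'   `source`, `age_years`, `sex`; one row per patient (first events only).
#' @param window a [window_spec()].
#' @param filters an [eligibility_filters()].
#' @return object of class `exposure_matrix`: list with `case_bits` and
#'   `control_bits` (patient x drug 0/1 matrices), `patients`, `drugs`, and
#'   bookkeeping counts (`n_events_in`, `n_retained`,
#'   `n_unmatched_dispensings`, `n_drugs_dispensed`).
#' @export
build_exposures <- function(dispensings, events, window = window_spec(),
                            filters = eligibility_filters()) {
  stopifnot(all(c("patient_id", "drug_code", "dispense_date") %in% names(dispensings)),
            all(c("patient_id", "index_date") %in% names(events)))
  if (anyDuplicated(events$patient_id))
    stop("duplicate patient_id in events: index events must be first ",
         "episodes, one row per patient", call. = FALSE)
  n_events_in <- nrow(events)

  keep <- rep(TRUE, nrow(events))
  if (filters$hospital_only && "source" %in% names(events))
    keep <- keep & events$source == "hospital"
  if (!is.null(filters$age_split_at) && "age_years" %in% names(events)) {
    keep <- keep & if (filters$age_side == "below")
      events$age_years < filters$age_split_at
    else events$age_years >= filters$age_split_at
  }
  events <- events[keep, , drop = FALSE]

  idx <- match(dispensings$patient_id, events$patient_id)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched)
    message(n_unmatched,
            " dispensing rows for patients without an index event were ignored")
  dispensings <- dispensings[!is.na(idx), , drop = FALSE]
  offset <- events$index_date[idx[!is.na(idx)]] - dispensings$dispense_date

  if (filters$require_prior_year_rx) {
    has_rx <- unique(dispensings$patient_id[offset >= 1L & offset <= 365L])
    events <- events[events$patient_id %in% has_rx, , drop = FALSE]
    still <- dispensings$patient_id %in% events$patient_id
    dispensings <- dispensings[still, , drop = FALSE]
    offset <- offset[still]
  }

  n_drugs_dispensed <- length(unique(dispensings$drug_code))

  in_case <- offset >= window$case_range[1] & offset <= window$case_range[2]
  in_ctrl <- offset >= window$control_range[1] & offset <= window$control_range[2]
  hit <- in_case | in_ctrl
  dh <- dispensings[hit, , drop = FALSE]
  if (nrow(dh) == 0L) {
    warning("no dispensings fall in the case or control window; ",
            "empty analysis", call. = FALSE)
  }
  patients <- sort(unique(dh$patient_id))
  drugs <- sort(unique(dh$drug_code))
  case_bits <- control_bits <- matrix(
    0L, nrow = length(patients), ncol = length(drugs),
    dimnames = list(as.character(patients), drugs))
  pi_ <- match(dh$patient_id, patients)
  di_ <- match(dh$drug_code, drugs)
  case_bits[cbind(pi_[in_case[hit]], di_[in_case[hit]])] <- 1L
  control_bits[cbind(pi_[in_ctrl[hit]], di_[in_ctrl[hit]])] <- 1L

  ev_retained <- events[match(patients, events$patient_id), , drop = FALSE]
  structure(list(
    case_bits = case_bits,
    control_bits = control_bits,
    patients = patients,
    drugs = drugs,
    events = ev_retained,
    window = window,
    filters = filters,
    n_events_in = n_events_in,
    n_retained = length(patients),
    n_unmatched_dispensings = n_unmatched,
    n_drugs_dispensed = n_drugs_dispensed
  ), class = "exposure_matrix")
}

#' @export
print.exposure_matrix <- function(x, ...) {
  cat("Case-crossover exposure matrix\n")
  print(x$window)
  cat("  events in:", x$n_events_in,
      "| patients retained (exposed in either window):", x$n_retained, "\n")
  cat("  drugs dispensed:", x$n_drugs_dispensed,
      "| drugs with either-window exposure:", length(x$drugs), "\n")
  invisible(x)
}

#' @export
summary.exposure_matrix <- function(object, ...) {
  dc <- discordant_counts(object)
  cat("Discordant-pair summary over", nrow(dc), "drugs:\n")
  print(summary(dc[c("n10", "n01")]))
  invisible(dc)
}

#' Pair-difference matrix of a case-crossover analysis
#'
#' Reduces the exposure matrix to the sufficient data of the 1:1 conditional
#' likelihood: per patient, `d = case_bits - control_bits`; rows that are
#' all zero (concordant in every drug) carry no information and are removed.
#'
#' @param exposures an [build_exposures()] result.
#' @return integer matrix of class `pair_diff` (entries -1/0/1), rows named
#'   by patient id, columns by drug code. Zero informative pairs triggers a
#'   warning and a 0-row matrix.
#' @export
difference_matrix <- function(exposures) {
  stopifnot(inherits(exposures, "exposure_matrix"))
  d <- exposures$case_bits - exposures$control_bits
  informative <- rowSums(d != 0L) > 0L
  d <- d[informative, , drop = FALSE]
  if (nrow(d) == 0L)
    warning("no informative pairs: every patient is concordant in every drug",
            call. = FALSE)
  class(d) <- c("pair_diff", class(d))
  d
}

#' Discordant-pair counts per drug
#'
#' @param exposures an [build_exposures()] result.
#' @return data.frame with one row per drug: `drug_code`, `n10` (exposed in
#'   the case period only), `n01` (control period only), `n11`, `n00`.
#' @export
discordant_counts <- function(exposures) {
  stopifnot(inherits(exposures, "exposure_matrix"))
  cb <- exposures$case_bits; kb <- exposures$control_bits
  data.frame(
    drug_code = exposures$drugs,
    n10 = colSums(cb == 1L & kb == 0L),
    n01 = colSums(cb == 0L & kb == 1L),
    n11 = colSums(cb == 1L & kb == 1L),
    n00 = colSums(cb == 0L & kb == 0L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write the per-drug exposure summary as tab-separated text
#'
#' @param exposures an [build_exposures()] result.
#' @param path output file.
#' @export
write_exposure_summary <- function(exposures, path) {
  write.table(discordant_counts(exposures), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
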