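#' Label left-ventricular systolic dysfunction from ejection fraction
#'
#' LVSD is defined as an echocardiographic ejection fraction strictly below
#' 40%. Missing EF yields `NA` (the pair is later excluded from the cohort).
#'
#' @param ejection_fraction Numeric vector of EF percentages in (0, 100),
#'   possibly `NA`.
#' @return Integer vector: 1 (EF < 40), 0 (EF >= 40) or `NA`.
#' @export
label_lvsd <- function(ejection_fraction) {
  ef <- as.numeric(ejection_fraction)
  bad <- !is.na(ef) & (ef <= 0 | ef >= 100)
  if (any(bad)) {
    stop("ejection fraction out of (0, 100): ",
         paste(utils::head(ef[bad], 3), collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(ef), NA_integer_, as.integer(ef < 40))
}

#' Pair echocardiography exams with their closest ECG
#'
#' One-to-one pairing of echo exams with ECGs of the same patient recorded
#' within 28 days. Echoes are processed in chronological order; each echo
#' takes the still-unconsumed ECG of its patient minimizing the absolute day
#' gap, ties broken toward the earlier ECG. A consumed ECG is unavailable to
#' later echoes. Echoes with missing ejection fraction, or with no eligible
#' ECG, produce no row.
#'
#' @param ecgs Data frame of ECG metadata with columns `record_id`,
#'   `patient_id`, `acquisition_date` (`Date` or ISO-8601 string).
#' @param echoes Data frame with columns `exam_id`, `patient_id`,
#'   `exam_date`, `ejection_fraction` (percent, `NA` allowed).
#' @param max_days Maximum allowed absolute gap in days (default 28).
#' @return A cohort tibble with columns `record_id`, `exam_id`,
#'   `patient_id`, `days_between` (ECG date minus echo date, integer days),
#'   `ejection_fraction`, `lvsd_label`. Each ECG and each echo appears at
#'   most once.
#' @export
pair_exams <- function(ecgs, echoes, max_days = 28L) {
  ecgs <- tibble::as_tibble(ecgs)
  echoes <- tibble::as_tibble(echoes)
  if (anyDuplicated(ecgs$record_id)) {
    stop("duplicate ECG record_ids", call. = FALSE)
  }
  if (anyDuplicated(echoes$exam_id)) {
    stop("duplicate echo exam_ids", call. = FALSE)
  }
  ecgs$acquisition_date <- as.Date(ecgs$acquisition_date)
  echoes$exam_date <- as.Date(echoes$exam_date)
  if (anyNA(ecgs$acquisition_date) || anyNA(echoes$exam_date)) {
    stop("exam dates must all be present", call. = FALSE)
  }
  echoes <- dplyr::arrange(echoes, .data$exam_date, .data$exam_id)
  consumed <- character(0)
  rows <- vector("list", nrow(echoes))
  for (i in seq_len(nrow(echoes))) {
    eh <- echoes[i, ]
    if (is.na(eh$ejection_fraction)) next
    cand <- ecgs[ecgs$patient_id == eh$patient_id &
                   !(ecgs$record_id %in% consumed), , drop = FALSE]
    if (nrow(cand) == 0L) next
    gap <- as.integer(cand$acquisition_date - eh$exam_date)
    ok <- abs(gap) <= max_days
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    gap <- gap[ok]
    # minimal |gap|; ties toward the earlier ECG (more negative gap)
    ord <- order(abs(gap), gap)
    pick <- ord[[1]]
    consumed <- c(consumed, cand$record_id[[pick]])
    rows[[i]] <- tibble::tibble(
      record_id = cand$record_id[[pick]],
      exam_id = eh$exam_id,
      patient_id = eh$patient_id,
      days_between = gap[[pick]],
      ejection_fraction = eh$ejection_fraction,
      lvsd_label = label_lvsd(eh$ejection_fraction)
    )
  }
  dplyr::bind_rows(rows)
}

#' Assign patient-level train/validation/test splits
#'
#' Splits a cohort 7 : 1.5 : 1.5 (by default) at the patient level: unique
#' patient ids are shuffled by a seeded generator and partitioned at the
#' cumulative-ratio cut points, and every row of a patient receives that
#' patient's split. This guarantees no patient appears in two splits
#' (no leakage), and is deterministic for a fixed seed.
#'
#' @param cohort A cohort data frame with a `patient_id` column.
#' @param ratios Length-3 positive vector summing to 1 (train, val, test).
#' @param seed Integer seed for the shuffle.
#' @return The cohort tibble with a `split` factor column
#'   (`train`/`val`/`test`).
#' @export
split_cohort <- function(cohort, ratios = c(0.7, 0.15, 0.15), seed = 1L) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be 3 non-negative fractions summing to 1",
         call. = FALSE)
  }
  pts <- unique(cohort$patient_id)
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  pts <- sample(pts)
  n <- length(pts)
  cuts <- round(cumsum(ratios) * n)
  split_of <- rep(c("train", "val", "test"),
                  times = c(cuts[1], cuts[2] - cuts[1], n - cuts[2]))
  names(split_of) <- pts
  cohort$split <- factor(unname(split_of[cohort$patient_id]),
                         levels = c("train", "val", "test"))
  cohort
}

# RNG bookkeeping: seeded operations must not clobber the caller's stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Check cohort invariants
#'
#' Verifies that every row has `|days_between| <= 28` and a non-missing
#' ejection fraction, that no ECG or echo is reused, and (if a `split`
#' column is present) that no patient id occurs in more than one split.
#'
#' @param cohort A cohort tibble as produced by [pair_exams()] /
#'   [split_cohort()].
#' @param max_days Pairing window used (default 28).
#' @return `cohort`, invisibly, or an error.
#' @export
validate_cohort <- function(cohort, max_days = 28L) {
  stopifnot(all(abs(cohort$days_between) <= max_days))
  stopifnot(!anyNA(cohort$ejection_fraction))
  stopifnot(!anyDuplicated(cohort$record_id),
            !anyDuplicated(cohort$exam_id))
  if ("split" %in% names(cohort)) {
    per_pt <- tapply(as.character(cohort$split), cohort$patient_id,
                     function(s) length(unique(s)))
    stopifnot(all(per_pt == 1L))
  }
  invisible(cohort)
}
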