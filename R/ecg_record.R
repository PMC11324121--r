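#' Standard 12-lead order
#'
#' Canonical ordering of the 12 conventional ECG leads used throughout the
#' package: limb leads, augmented limb leads, then precordial leads. All
#' signal matrices are stored with rows in this order.
#'
#' @format Character vector of length 12.
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead ECG record
#'
#' An `ecg_record` holds one 10-second, 12-lead voltage trace as a
#' 12 x 5000 matrix (rows = leads in [ECG_LEADS] order, columns = time at
#' 500 Hz, values in millivolts) plus record/patient metadata.
#'
#' @param signal Numeric 12 x (10 * sampling_rate) matrix, millivolts.
#' @param record_id,patient_id Opaque identifier strings.
#' @param acquisition_date A `Date` (or ISO-8601 string) for the recording.
#' @param sampling_rate Sampling rate in Hz; the pipeline operates at 500.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, record_id = "ecg", patient_id = "pt",
                       acquisition_date = as.Date("2020-01-01"),
                       sampling_rate = 500) {
  signal <- as.matrix(signal)
  rec <- structure(
    list(
      record_id = as.character(record_id),
      patient_id = as.character(patient_id),
      acquisition_date = as.Date(acquisition_date),
      sampling_rate = as.integer(sampling_rate),
      signal = signal,
      lead_names = ECG_LEADS
    ),
    class = "ecg_record"
  )
  validate_ecg_record(rec)
}

#' Validate an ECG record
#'
#' Checks the record invariants: exactly 12 leads, exactly
#' `10 * sampling_rate` samples per lead, and all-finite voltages.
#'
#' @param rec An `ecg_record`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_ecg_record <- function(rec) {
  if (!inherits(rec, "ecg_record")) {
    stop("not an ecg_record", call. = FALSE)
  }
  sig <- rec$signal
  if (!is.matrix(sig) || nrow(sig) != 12L) {
    stop("ECG signal must have exactly 12 leads (rows)", call. = FALSE)
  }
  expected <- 10L * rec$sampling_rate
  if (ncol(sig) != expected) {
    stop(sprintf("ECG signal must have %d samples per lead at %d Hz, got %d",
                 expected, rec$sampling_rate, ncol(sig)), call. = FALSE)
  }
  if (!all(is.finite(sig))) {
    stop("ECG signal contains non-finite values", call. = FALSE)
  }
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> patient %s, %s, 12 x %d @ %d Hz\n",
              x$record_id, x$patient_id, format(x$acquisition_date),
              ncol(x$signal), x$sampling_rate))
  invisible(x)
}

#' Per-lead z-score normalization
#'
#' Centers and scales each lead independently to zero mean and unit standard
#' deviation, the preprocessing applied before MAE pretraining and
#' fine-tuning. No band-pass filtering or baseline-wander removal is applied.
#' A lead whose standard deviation is degenerate (below
#' `max(1e-8, 1e-8 * max(|lead|))`) is returned as all zeros.
#'
#' The operation is idempotent: `normalize_ecg(normalize_ecg(x))` equals
#' `normalize_ecg(x)` up to floating-point noise.
#'
#' @param rec An `ecg_record`.
#' @return The record with normalized signal.
#' @export
normalize_ecg <- function(rec) {
  validate_ecg_record(rec)
  sig <- rec$signal
  for (i in seq_len(nrow(sig))) {
    x <- sig[i, ]
    s <- stats::sd(x)
    tol <- max(1e-8, 1e-8 * max(abs(x)))
    if (!is.finite(s) || s < tol) {
      sig[i, ] <- 0
    } else {
      sig[i, ] <- (x - mean(x)) / s
    }
  }
  rec$signal <- sig
  rec
}

# ---- delimited-text record container -----------------------------------

#' Read / write an ECG record as delimited text
#'
#' A plain-text container for single records: a `#`-prefixed JSON header line
#' with the metadata, then one comma-separated row of 5000 voltages per lead,
#' in [ECG_LEADS] order. Used for hand-made fixtures and CLI artifacts.
#'
#' @param rec An `ecg_record`.
#' @param path File path.
#' @return `write_ecg_csv` returns `path` invisibly; `read_ecg_csv` returns
#'   an `ecg_record`.
#' @export
write_ecg_csv <- function(rec, path) {
  validate_ecg_record(rec)
  hdr <- jsonlite::toJSON(
    list(record_id = rec$record_id, patient_id = rec$patient_id,
         acquisition_date = format(rec$acquisition_date),
         sampling_rate = rec$sampling_rate),
    auto_unbox = TRUE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(rec$signal, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) {
    stop("not an ECG csv container: missing header line", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  sig <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                     colClasses = "numeric"))
  dimnames(sig) <- NULL
  ecg_record(sig,
             record_id = meta$record_id, patient_id = meta$patient_id,
             acquisition_date = meta$acquisition_date,
             sampling_rate = meta$sampling_rate)
}

# ---- WFDB (header + signal) --------------------------------------------

#' Read a WFDB record as a 12-lead ECG
#'
#' Minimal reader for the WFDB header/signal pair used by public ECG
#' distributions (PTB-XL layout): a text `.hea` header and an interleaved
#' 16-bit little-endian signal file (WFDB format 16). Channels are remapped
#' to the canonical [ECG_LEADS] order by their header description names, and
#' ADC units are converted to millivolts via each channel's gain and
#' baseline.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param resample If `TRUE`, records at rates other than 500 Hz are linearly
#'   resampled to 500 Hz; if `FALSE` (default) such records are an error.
#' @return An `ecg_record` at 500 Hz.
#' @export
read_wfdb <- function(path, resample = FALSE) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rec_name <- top[[1]]
  n_sig <- as.integer(top[[2]])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[[3]])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[[4]]) else NA_integer_
  sig_lines <- lines[seq(2L, 1L + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- f[[3]]
    baseline <- 0
    if (grepl("\\(", gain_spec)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    }
    gain <- as.numeric(sub("[(/].*", "", gain_spec))
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[[1]], format = sub("x.*|:.*|\\+.*", "", f[[2]]),
         gain = gain, baseline = baseline,
         desc = f[[length(f)]])
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmt <- unique(vapply(sigs, `[[`, "", "format"))
  if (!identical(fmt, "16")) {
    stop("unsupported WFDB signal format: ", paste(fmt, collapse = ","),
         " (only format 16 is supported)", call. = FALSE)
  }
  if (n_sig != 12L) {
    stop(sprintf("expected 12 channels, found %d", n_sig), call. = FALSE)
  }
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  raw <- readBin(dat, what = "integer", n = file.size(dat) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
  if (is.na(n_samp)) n_samp <- length(raw) %/% n_sig
  adc <- matrix(raw[seq_len(n_sig * n_samp)], nrow = n_sig)  # interleaved
  mv <- matrix(0, n_sig, n_samp)
  for (i in seq_len(n_sig)) {
    mv[i, ] <- (adc[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  }
  descs <- vapply(sigs, `[[`, "", "desc")
  idx <- match(toupper(ECG_LEADS), toupper(descs))
  if (anyNA(idx)) {
    stop("WFDB channels do not cover the standard 12 leads; missing: ",
         paste(ECG_LEADS[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mv <- mv[idx, , drop = FALSE]
  if (fs != 500) {
    if (!resample) {
      stop(sprintf("record sampled at %g Hz; pipeline requires 500 Hz (set resample = TRUE)",
                   fs), call. = FALSE)
    }
    out <- matrix(0, 12L, 5000L)
    t_in <- seq(0, by = 1 / fs, length.out = ncol(mv))
    t_out <- seq(0, by = 1 / 500, length.out = 5000L)
    for (i in 1:12) {
      out[i, ] <- stats::approx(t_in, mv[i, ], xout = t_out, rule = 2)$y
    }
    mv <- out
  }
  ecg_record(mv, record_id = rec_name, patient_id = rec_name,
             sampling_rate = 500)
}

#' Write an ECG record as a WFDB format-16 pair
#'
#' Emits a `.hea` header and an interleaved 16-bit `.dat` signal file with a
#' fixed gain of 1000 ADC units per millivolt. Primarily used to build
#' WFDB-layout fixtures for tests and the PTB-XL-style fixture generator.
#'
#' @param rec An `ecg_record`.
#' @param path Record path without extension.
#' @param lead_order Optional permutation of [ECG_LEADS] controlling the
#'   channel order on disk (the reader must undo it).
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(rec, path, lead_order = ECG_LEADS) {
  validate_ecg_record(rec)
  stopifnot(setequal(lead_order, ECG_LEADS))
  gain <- 1000
  perm <- match(lead_order, ECG_LEADS)
  sig <- rec$signal[perm, , drop = FALSE]
  adc <- round(sig * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  n_samp <- ncol(adc)
  base <- basename(path)
  hdr <- c(
    sprintf("%s 12 %d %d", base, rec$sampling_rate, n_samp),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
            base, gain, adc[seq_len(12)], lead_order)
  )
  writeLines(hdr, paste0(path, ".hea"))
  writeBin(as.integer(adc), paste0(path, ".dat"), size = 2L,
           endian = "little")
  invisible(path)
}
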