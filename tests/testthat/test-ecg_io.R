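test_that("record invariants are enforced", {
  rec <- test_record(1)
  expect_s3_class(rec, "ecg_record")
  expect_identical(dim(rec$signal), c(12L, 5000L))
  expect_identical(rec$lead_names, ECG_LEADS)
  expect_error(ecg_record(matrix(0, 8, 5000)), "12 leads")
  expect_error(ecg_record(matrix(0, 12, 4999)), "5000 samples")
  bad <- matrix(0, 12, 5000); bad[3, 7] <- NA
  expect_error(ecg_record(bad), "non-finite")
})

test_that("per-lead normalization z-scores, zeroes degenerate leads, and is idempotent", {
  rec <- test_record(2)
  rec$signal[5, ] <- 3.0                      # constant lead
  rec$signal[7, ] <- rep(c(-1, 1), 2500)      # known two-point lead
  nz <- normalize_ecg(rec)
  for (i in setdiff(1:12, 5)) {
    expect_equal(mean(nz$signal[i, ]), 0, tolerance = 1e-12)
    expect_equal(sd(nz$signal[i, ]), 1, tolerance = 1e-12)
  }
  expect_true(all(nz$signal[5, ] == 0))
  expect_true(all(abs(nz$signal[7, ]) < 1.001))
  # idempotence
  nz2 <- normalize_ecg(nz)
  expect_equal(nz2$signal, nz$signal, tolerance = 1e-12)
  expect_true(all(is.finite(nz$signal)))
})

test_that("delimited-text record container round-trips", {
  rec <- test_record(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(rec, path)
  back <- read_ecg_csv(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-10)
  expect_identical(back$record_id, rec$record_id)
  expect_identical(back$patient_id, rec$patient_id)
  expect_identical(back$acquisition_date, rec$acquisition_date)
})

test_that("WFDB reader round-trips, remaps shuffled channels, rejects bad layouts", {
  rec <- test_record(4)
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "rec004")
  write_wfdb(rec, stem)
  back <- read_wfdb(stem)
  expect_identical(dim(back$signal), c(12L, 5000L))
  # 16-bit quantization at gain 1000: half an ADC unit = 0.0005 mV
  expect_lt(max(abs(back$signal - rec$signal)), 6e-4)

  # channels stored in shuffled order come back in canonical lead order
  shuffled <- ECG_LEADS[c(7:12, 1:6)]
  stem2 <- file.path(dir, "shuf")
  write_wfdb(rec, stem2, lead_order = shuffled)
  back2 <- read_wfdb(stem2)
  expect_lt(max(abs(back2$signal - rec$signal)), 6e-4)

  # 8-channel header is a format error
  hea <- readLines(paste0(stem, ".hea"))
  hea[1] <- sub(" 12 ", " 8 ", hea[1])
  writeLines(hea[1:9], paste0(stem, ".hea"))
  expect_error(read_wfdb(stem), "12 channels")
})

test_that("WFDB reader enforces the 500 Hz contract unless resampling", {
  rec <- test_record(5)
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "slow")
  write_wfdb(rec, stem)
  hea <- readLines(paste0(stem, ".hea"))
  hea[1] <- sub(" 500 ", " 250 ", hea[1])
  writeLines(hea, paste0(stem, ".hea"))
  expect_error(read_wfdb(stem), "500 Hz")
  back <- read_wfdb(stem, resample = TRUE)
  expect_identical(dim(back$signal), c(12L, 5000L))
  expect_identical(back$sampling_rate, 500L)
})

test_that("LVSD labeling uses the strict EF < 40 rule and propagates missingness", {
  expect_identical(label_lvsd(39.9), 1L)
  expect_identical(label_lvsd(40.0), 0L)
  expect_identical(label_lvsd(NA), NA_integer_)
  expect_identical(label_lvsd(c(25, 40, NA, 65)), c(1L, 0L, NA, 0L))
  expect_error(label_lvsd(0), "out of")
  expect_error(label_lvsd(100), "out of")
  expect_error(label_lvsd(-5), "out of")
})

test_that("pairing picks the closest ECG within 28 days, one-to-one, earlier on ties", {
  d0 <- as.Date("2021-03-01")
  echoes <- tibble::tibble(exam_id = "e1", patient_id = "p1",
                           exam_date = d0, ejection_fraction = 55)
  ecgs <- tibble::tibble(record_id = c("a", "b"), patient_id = "p1",
                         acquisition_date = d0 + c(-3, 2))
  expect_identical(pair_exams(ecgs, echoes)$record_id, "b")   # |2| < |-3|

  # 29 days away -> excluded
  far <- tibble::tibble(record_id = "a", patient_id = "p1",
                        acquisition_date = d0 + 29)
  expect_identical(nrow(pair_exams(far, echoes)), 0L)

  # equidistant -> earlier ECG wins
  tie <- tibble::tibble(record_id = c("early", "late"), patient_id = "p1",
                        acquisition_date = d0 + c(-2, 2))
  expect_identical(pair_exams(tie, echoes)$record_id, "early")

  # missing EF -> no row
  e_na <- echoes; e_na$ejection_fraction <- NA
  expect_identical(nrow(pair_exams(ecgs, e_na)), 0L)

  expect_error(pair_exams(tibble::tibble(record_id = c("a", "a"),
                                         patient_id = "p1",
                                         acquisition_date = d0),
                          echoes), "duplicate")
})

test_that("chronological one-to-one consumption: an ECG is used at most once", {
  d0 <- as.Date("2021-03-01")
  echoes <- tibble::tibble(exam_id = c("e1", "e2"), patient_id = "p1",
                           exam_date = d0 + c(0, 10),
                           ejection_fraction = c(55, 30))
  ecgs <- tibble::tibble(record_id = c("a", "b"), patient_id = "p1",
                         acquisition_date = d0 + c(1, 9))
  tab <- pair_exams(ecgs, echoes)
  # e1 (earlier) takes its nearest (a); e2 gets the remaining b
  expect_identical(tab$record_id[tab$exam_id == "e1"], "a")
  expect_identical(tab$record_id[tab$exam_id == "e2"], "b")
  expect_false(anyDuplicated(tab$record_id) > 0)
  expect_identical(tab$lvsd_label[tab$exam_id == "e2"], 1L)
  validate_cohort(tab)
})

test_that("patient-level split has exact cut points, no leakage, and is deterministic", {
  cohort <- tibble::tibble(
    record_id = paste0("r", 1:2000),
    exam_id = paste0("e", 1:2000),
    patient_id = rep(paste0("p", 1:1000), each = 2),
    days_between = 0L, ejection_fraction = 60, lvsd_label = 0L
  )
  sp <- split_cohort(cohort, c(0.7, 0.15, 0.15), seed = 42)
  per_split <- tapply(sp$patient_id, sp$split, function(x) length(unique(x)))
  expect_identical(as.integer(per_split), c(700L, 150L, 150L))
  # leakage: patient ids of different splits are disjoint
  ids <- split(sp$patient_id, sp$split)
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  # determinism
  sp2 <- split_cohort(cohort, c(0.7, 0.15, 0.15), seed = 42)
  expect_identical(sp$split, sp2$split)
  sp3 <- split_cohort(cohort, c(0.7, 0.15, 0.15), seed = 43)
  expect_false(identical(sp$split, sp3$split))
  expect_error(split_cohort(cohort[0, ]), "empty")
  expect_error(split_cohort(cohort, c(0.5, 0.2)), "ratios")
})
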