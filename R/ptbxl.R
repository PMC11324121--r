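PTBXL_TASKS <- c("all", "diagnostic", "form", "rhythm")

parse_scp_codes <- function(s) {
  # statement field is a python-dict literal: {'NORM': 100.0, 'SR': 0.0}
  s <- gsub("'", "\"", s)
  out <- jsonlite::fromJSON(s)
  vapply(out, as.numeric, numeric(1))
}

#' Load a PTB-XL-style directory as a multi-label task
#'
#' Reads the benchmark layout: a metadata table (`ptbxl_database.csv`) with
#' one row per record (statement codes, stratified fold, signal filename),
#' a statement-ontology table (`scp_statements.csv`) with per-code
#' diagnostic/form/rhythm category flags, and WFDB signal files. Statement
#' codes are mapped to the selected task's class set; a record's label for
#' a class is positive when its statement likelihood exceeds
#' `min_likelihood` (default 0: any nonzero likelihood counts). Records
#' with no positive statement in the task are retained as all-negative.
#' Folds follow the dataset convention: 1-8 train, 9 validation, 10 test.
#'
#' @param root Directory containing the metadata tables and signal files.
#' @param task One of `"all"`, `"diagnostic"`, `"form"`, `"rhythm"`.
#' @param sampling_rate 500 (the `filename_hr` pathway) or 100 (resampled
#'   on load).
#' @param min_likelihood Positive-label threshold on the statement
#'   likelihood.
#' @param load_signals If `FALSE`, skip reading WFDB files (metadata only).
#' @return List with `records` (list of [ecg_record()], unless
#'   `load_signals = FALSE`), `labels` (binary record x class matrix),
#'   `folds` (integer 1-10), `splits` (`train`/`val`/`test` factor),
#'   `classes`, `task`, and `meta` (the metadata tibble).
#' @export
load_ptbxl <- function(root, task = c("all", "diagnostic", "form", "rhythm"),
                       sampling_rate = 500, min_likelihood = 0,
                       load_signals = TRUE) {
  task <- match.arg(task)
  db_path <- file.path(root, "ptbxl_database.csv")
  scp_path <- file.path(root, "scp_statements.csv")
  if (!file.exists(db_path) || !file.exists(scp_path)) {
    stop("not a PTB-XL layout: need ptbxl_database.csv and scp_statements.csv under ",
         root, call. = FALSE)
  }
  meta <- utils::read.csv(db_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  scp <- utils::read.csv(scp_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  codes <- scp[[1]]
  flag <- function(col) {
    if (col %in% names(scp)) {
      v <- suppressWarnings(as.numeric(scp[[col]]))
      !is.na(v) & v == 1
    } else {
      rep(FALSE, nrow(scp))
    }
  }
  classes <- switch(task,
    all = codes,
    diagnostic = codes[flag("diagnostic")],
    form = codes[flag("form")],
    rhythm = codes[flag("rhythm")]
  )
  if (length(classes) == 0L) {
    stop("ontology table defines no classes for task ", task, call. = FALSE)
  }
  n <- nrow(meta)
  labels <- matrix(0L, n, length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    lik <- parse_scp_codes(meta$scp_codes[[i]])
    pos <- names(lik)[lik > min_likelihood]
    hit <- intersect(pos, classes)
    if (length(hit)) labels[i, hit] <- 1L
  }
  folds <- as.integer(meta$strat_fold)
  splits <- factor(ifelse(folds <= 8L, "train",
                          ifelse(folds == 9L, "val", "test")),
                   levels = c("train", "val", "test"))
  records <- NULL
  if (load_signals) {
    fn_col <- if (sampling_rate == 500) "filename_hr" else "filename_lr"
    records <- lapply(seq_len(n), function(i) {
      rec <- read_wfdb(file.path(root, meta[[fn_col]][[i]]),
                       resample = sampling_rate != 500)
      rec$record_id <- as.character(meta$ecg_id[[i]])
      rec$patient_id <- as.character(meta$patient_id[[i]])
      rec
    })
  }
  list(records = records, labels = labels, folds = folds, splits = splits,
       classes = classes, task = task, meta = tibble::as_tibble(meta))
}

#' Write a synthetic PTB-XL-style mini-fixture
#'
#' Emits a small, fully synthetic directory in the benchmark layout
#' (metadata table, statement ontology, WFDB format-16 signal files) for
#' exercising [load_ptbxl()] and [run_benchmark()] without the real
#' dataset. Statement classes and label assignments are fabricated;
#' signals come from the package's synthetic beat model, with a small
#' class-linked morphology shift so labels are learnable in smoke tests.
#'
#' @param dir Output directory (created).
#' @param n_records Number of records (spread over the 10 folds).
#' @param seed Seed for reproducibility.
#' @return Invisibly, the ground-truth label matrix (records x classes),
#'   for round-trip tests against [load_ptbxl()].
#' @export
write_ptbxl_fixture <- function(dir, n_records = 20L, seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  dir.create(file.path(dir, "records500", "00000"), recursive = TRUE,
             showWarnings = FALSE)
  ontology <- data.frame(
    code = c("NORM", "IMI", "LVH", "ABQRS", "SR", "AFIB"),
    description = c("normal ECG", "inferior myocardial infarction",
                    "left ventricular hypertrophy", "abnormal QRS",
                    "sinus rhythm", "atrial fibrillation"),
    diagnostic = c(1, 1, 1, 0, 0, 0),
    form = c(0, 0, 0, 1, 0, 0),
    rhythm = c(0, 0, 0, 0, 1, 1)
  )
  classes <- ontology$code
  labels <- matrix(0L, n_records, length(classes),
                   dimnames = list(NULL, classes))
  rows <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    normal <- stats::runif(1) < 0.5
    if (normal) {
      pos <- c("NORM", "SR")
    } else {
      pos <- c(sample(c("IMI", "LVH"), 1),
               if (stats::runif(1) < 0.5) "ABQRS",
               sample(c("SR", "AFIB"), 1))
    }
    labels[i, pos] <- 1L
    bp <- beat_params(heart_rate = stats::rnorm(1, 72, 6))
    if (!normal) {  # crude class-linked morphology shift
      bp$amplitude[["R"]] <- bp$amplitude[["R"]] * 0.7
      bp$width[c("Q", "R", "S")] <- bp$width[c("Q", "R", "S")] * 1.4
    }
    state <- list(beat = bp, projection = LEAD_PROJECTION,
                  noise_sd = 0.04, wander_amp = 0.08, wander_freq = 0.3)
    rec <- synth_record(state, seed = seed * 1000L + i,
                        record_id = as.character(i), patient_id = sprintf("pt%03d", i))
    stem <- sprintf("records500/00000/%05d_hr", i)
    write_wfdb(rec, file.path(dir, stem))
    lik <- stats::setNames(rep(100.0, length(pos)), pos)
    scp_str <- paste0("{", paste(sprintf("'%s': %.1f", names(lik), lik),
                                 collapse = ", "), "}")
    rows[[i]] <- data.frame(
      ecg_id = i, patient_id = 10000 + i, scp_codes = scp_str,
      strat_fold = ((i - 1L) %% 10L) + 1L,
      filename_lr = sprintf("records100/00000/%05d_lr", i),
      filename_hr = stem
    )
  }
  db <- do.call(rbind, rows)
  utils::write.csv(db, file.path(dir, "ptbxl_database.csv"),
                   row.names = FALSE)
  utils::write.csv(ontology, file.path(dir, "scp_statements.csv"),
                   row.names = FALSE)
  invisible(labels)
}

#' Fine-tune repeatedly on a multi-label task and summarize macro-AUC
#'
#' Runs the downstream fine-tuning protocol `repeats` times with distinct
#' head/shuffle seeds on a loaded statement task, evaluates macro-AUC on
#' the test fold each time, and reports the mean and standard deviation in
#' the compact run-summary notation (e.g. `"0.960 (02)"`).
#'
#' @param model A pretrained `mae_model` (its encoder is fine-tuned).
#' @param data A task as returned by [load_ptbxl()] (with signals).
#' @param cfg A [finetune_config()].
#' @param repeats Number of fine-tuning runs (benchmark convention: 10).
#' @return A `benchmark_result`: per-run macro-AUCs, the last run's
#'   `multilabel_result`, and the formatted `summary` string.
#' @export
run_benchmark <- function(model, data, cfg = finetune_config(),
                          repeats = 10L) {
  stopifnot(!is.null(data$records))
  tr <- data$splits == "train"
  va <- data$splits == "val"
  te <- data$splits == "test"
  macros <- numeric(repeats)
  last <- NULL
  for (r in seq_len(repeats)) {
    clf <- attach_head(model, n_outputs = ncol(data$labels), seed = r)
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + r - 1L
    fit <- finetune(clf, data$records[tr], data$labels[tr, , drop = FALSE],
                    data$records[va], data$labels[va, , drop = FALSE],
                    run_cfg)
    scores <- predict(fit$classifier, data$records[te])
    scores <- matrix(scores, ncol = ncol(data$labels),
                     dimnames = list(NULL, colnames(data$labels)))
    last <- macro_auc(scores, data$labels[te, , drop = FALSE])
    macros[r] <- last$macro
  }
  structure(list(macro_aucs = macros, result = last,
                 summary = format_run_summary(macros),
                 task = data$task, repeats = repeats),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark task '%s': macro-AUC %s over %d runs\n",
              x$task, x$summary, x$repeats))
  invisible(x)
}
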