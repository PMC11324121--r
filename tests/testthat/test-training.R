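test_that("plateau scheduler reproduces the halve-at-3 / stop-at-10 rule", {
  run <- function(losses, lr0 = 1) {
    st <- scheduler_init(lr0)
    trace <- list()
    for (l in losses) {
      st <- scheduler_step(st, l)
      trace[[length(trace) + 1]] <- tidy(st)
      if (st$stop) break
    }
    dplyr::bind_rows(trace)
  }

  # 1.0, 0.9, 0.95, 0.96, 0.97: one halving, after the 5th value
  tr <- run(c(1.0, 0.9, 0.95, 0.96, 0.97))
  expect_identical(tr$lr, c(1, 1, 1, 1, 0.5))
  expect_false(any(tr$stop))
  expect_equal(tr$best[5], 0.9)

  # strictly decreasing: never halves, never stops
  tr2 <- run(seq(1, 0.01, length.out = 100))
  expect_true(all(tr2$lr == 1))
  expect_false(any(tr2$stop))
  expect_true(all(tr2$improved))

  # 0.9 then ten non-improving values: halve at 3, 6, 9; stop at the 10th
  tr3 <- run(c(0.9, rep(0.95, 12)))
  expect_identical(nrow(tr3), 11L)           # stopped after 10 bad epochs
  expect_true(tr3$stop[11])
  expect_equal(tr3$best[11], 0.9)
  expect_equal(tr3$lr[11], 1 * 0.5^3)        # halved at counters 3, 6, 9

  # ties are non-improvements under strict <
  tr4 <- run(c(0.5, rep(0.5, 10)))
  expect_true(tr4$stop[11])
  expect_equal(tr4$best[11], 0.5)
  expect_false(any(tr4$improved[-1]))

  # improvement after a plateau resets the counter and keeps the halved lr
  tr5 <- run(c(1.0, 1.1, 1.1, 1.1, 0.8, 1.1, 1.1, 1.1))
  expect_equal(tr5$lr[4], 0.5)               # halved once during plateau
  expect_identical(tr5$since_improve[5], 0L) # reset on improvement
  expect_equal(tr5$lr[8], 0.25)              # next plateau halves again
  expect_error(scheduler_init(1, plateau_patience = 5, stop_patience = 3))
})

test_that("head attachment produces sigmoid outputs of the right shape", {
  m <- tiny_model(1)
  clf1 <- attach_head(m, n_outputs = 1L, seed = 2)
  recs <- lapply(1:3, test_record)
  pr <- predict(clf1, recs)
  expect_length(pr, 3)
  expect_true(all(pr > 0 & pr < 1))

  # multi-label shape (benchmark all-statements task)
  clf71 <- attach_head(m, n_outputs = 71L, seed = 2)
  pr71 <- predict(clf71, recs)
  expect_identical(dim(pr71), c(3L, 71L))
  expect_true(all(is.finite(pr71)))

  expect_error(attach_head(m, n_outputs = 0L), "n_outputs")
})

test_that("pretraining is reproducible and a zero-epoch run is a no-op", {
  m <- micro_model(3)
  recs <- lapply(1:6, test_record)
  cfg <- pretrain_config(epochs = 2L, batch_size = 3L, base_lr = 4e-3,
                         warmup_epochs = 1L, seed = 11)
  a <- pretrain(m, recs, cfg)
  b <- pretrain(m, recs, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_identical(nrow(a$history), 2L)

  z <- pretrain(m, recs, pretrain_config(epochs = 0L))
  expect_identical(z$model$params, m$params)
  expect_identical(nrow(z$history), 0L)
})

test_that("fine-tuning monitors validation loss and restores best weights", {
  m <- micro_model(4)
  ch <- synth_cohort(synth_config(n_patients = 24, lvsd_prevalence = 0.4,
                                  seed = 8, ecgs_per_patient = c(`1` = 1)))
  y <- ch$patients$lvsd
  recs <- unname(ch$records)
  tr_i <- 1:16; va_i <- 17:24
  clf <- attach_head(m, 1L, seed = 5)
  cfg <- finetune_config(batch_size = 8L, lr = 1e-3, max_epochs = 4L,
                         seed = 5)
  fit <- finetune(clf, recs[tr_i], y[tr_i], recs[va_i], y[va_i], cfg)
  expect_identical(nrow(fit$history), fit$epochs_run)
  expect_lte(fit$best_val_loss, min(fit$history$val_loss) + 1e-12)
  expect_true(any(fit$history$improved))

  # reproducibility
  fit2 <- finetune(clf, recs[tr_i], y[tr_i], recs[va_i], y[va_i], cfg)
  expect_identical(fit$history, fit2$history)

  # zero-epoch run returns the initial weights
  fit0 <- finetune(clf, recs[tr_i], y[tr_i], recs[va_i], y[va_i],
                   finetune_config(max_epochs = 0L))
  expect_identical(fit0$classifier$params, clf$params)

  # single-class training labels warn but proceed
  expect_warning(
    finetune(clf, recs[tr_i], rep(0, 16), recs[va_i], y[va_i],
             finetune_config(batch_size = 8L, max_epochs = 1L)),
    "single class")
  expect_error(finetune(clf, list(), numeric(0), recs[va_i], y[va_i], cfg),
               "empty")
})

test_that("grid selection returns the lowest-validation-loss cell", {
  m <- micro_model(5)
  ch <- synth_cohort(synth_config(n_patients = 16, lvsd_prevalence = 0.4,
                                  seed = 9, ecgs_per_patient = c(`1` = 1)))
  recs <- unname(ch$records); y <- ch$patients$lvsd
  out <- finetune_grid(attach_head(m, 1L, seed = 1),
                       recs[1:10], y[1:10], recs[11:16], y[11:16],
                       batch_sizes = c(5L, 10L), lrs = c(1e-3, 1e-4),
                       cfg = finetune_config(max_epochs = 2L, seed = 3))
  expect_identical(nrow(out$grid), 4L)
  expect_equal(out$best$best_val_loss, min(out$grid$best_val_loss))
  expect_true(out$best_batch_size %in% c(5L, 10L))
  expect_true(out$best_lr %in% c(1e-3, 1e-4))
})

test_that("frozen-encoder fine-tuning trains the head only, with whitening", {
  m <- micro_model(7)
  ch <- synth_cohort(synth_config(n_patients = 30, lvsd_prevalence = 0.4,
                                  seed = 12, ecgs_per_patient = c(`1` = 1)))
  y <- ch$patients$lvsd
  recs <- unname(ch$records)
  clf <- attach_head(m, 1L, seed = 2)
  fit <- finetune(clf, recs[1:20], y[1:20], recs[21:30], y[21:30],
                  finetune_config(batch_size = 10L, lr = 1e-3,
                                  max_epochs = 5L, freeze_encoder = TRUE,
                                  seed = 2))
  # encoder untouched, head moved, whitening fitted
  expect_identical(fit$classifier$params$enc, clf$params$enc)
  expect_false(identical(fit$classifier$params$head, clf$params$head))
  expect_identical(dim(fit$classifier$feat_whiten),
                   rep(m$enc_cfg$embed_dim, 2))
  expect_identical(nrow(fit$history), fit$epochs_run)
  # predictions flow through the stored whitening
  pr <- predict(fit$classifier, recs[1:3])
  expect_true(all(pr > 0 & pr < 1))
  # reproducible
  fit2 <- finetune(clf, recs[1:20], y[1:20], recs[21:30], y[21:30],
                   finetune_config(batch_size = 10L, lr = 1e-3,
                                   max_epochs = 5L, freeze_encoder = TRUE,
                                   seed = 2))
  expect_equal(fit$history, fit2$history)
})
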