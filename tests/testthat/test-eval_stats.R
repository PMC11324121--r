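test_that("rank AUROC equals brute-force concordance on random instances", {
  set.seed(314)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- if (i %% 3 == 0) {
      sample(round(rnorm(n), 1))   # heavy ties
    } else {
      rnorm(n) + labels * runif(1, 0, 2)
    }
    expect_equal(auroc(scores, labels), naive_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC handles its reference cases and rejects one-class input", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 20), rep(c(0, 1), 10)), 0.5)   # all ties
  expect_error(auroc(1:5, rep(1, 5)), "both classes")
  # invariance under strictly increasing transforms
  set.seed(2)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5); l[1:2] <- c(0, 1)
  expect_equal(auroc(exp(s), l), auroc(s, l))
  expect_equal(auroc(qlogis(plogis(s)), l), auroc(s, l))
})

test_that("DeLong interval matches pROC and brackets the bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(7)
  n <- 200
  labels <- rep(c(0, 1), each = n / 2)
  scores <- rnorm(n) + labels * 1.2
  res <- auroc_ci(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(res$auroc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(res$ci_low, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(res$ci_high, as.numeric(ref[3]), tolerance = 1e-6)

  # bootstrap oracle: 2000 resamples; point estimate inside our interval,
  # half-widths within 20% relative
  set.seed(8)
  boot <- replicate(2000, {
    idx <- sample(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) NA else auroc(scores[idx], labels[idx])
  })
  boot <- boot[!is.na(boot)]
  expect_gt(mean(boot), res$ci_low)
  expect_lt(mean(boot), res$ci_high)
  bw <- diff(quantile(boot, c(0.025, 0.975))) / 2
  dw <- (res$ci_high - res$ci_low) / 2
  expect_lt(abs(bw - dw) / dw, 0.2)

  # larger n narrows the interval
  set.seed(9)
  n2 <- 2000
  l2 <- rep(c(0, 1), each = n2 / 2)
  s2 <- rnorm(n2) + l2 * 1.2
  res2 <- auroc_ci(s2, l2)
  expect_lt(res2$ci_high - res2$ci_low, res$ci_high - res$ci_low)

  # perfect separation: degenerate point interval, flagged
  resp <- auroc_ci(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_identical(resp$auroc, 1)
  expect_identical(c(resp$ci_low, resp$ci_high), c(1, 1))
  expect_true(resp$degenerate)
})

test_that("structural components match the O(mn) oracle", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    l <- rbinom(n, 1, 0.5); l[1:2] <- c(0, 1)
    s <- round(rnorm(n), 1)
    fast <- ecgmae:::delong_components(s, l)
    slow <- naive_delong_components(s, l)
    expect_equal(fast$theta, slow$theta, tolerance = 1e-12)
    expect_equal(fast$v10, slow$v10, tolerance = 1e-12)
    expect_equal(fast$v01, slow$v01, tolerance = 1e-12)
  }
})

test_that("paired DeLong test agrees with pROC and obeys its symmetries", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 300
  labels <- rep(c(0, 1), each = n / 2)
  base <- rnorm(n) + labels
  a <- base + rnorm(n, 0, 0.6)
  b <- 0.7 * base + rnorm(n, 0, 0.8)
  res <- delong_test(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(res$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)

  # identical scores: delta 0, p = 1 by the degenerate rule
  same <- delong_test(a, a, labels)
  expect_identical(same$delta, 0)
  expect_identical(same$p, 1)
  expect_identical(same$z, 0)

  # swapping a and b negates z, leaves p unchanged
  swp <- delong_test(b, a, labels)
  expect_equal(swp$z, -res$z, tolerance = 1e-12)
  expect_equal(swp$p, res$p, tolerance = 1e-12)

  expect_error(delong_test(a[-1], b, labels), "equal length")
})

test_that("DeLong null rejection rate is close to nominal", {
  # two independent noisy readouts of the same signal, n = 500:
  # the paired test at p < 0.05 should reject about 5% of the time
  set.seed(42)
  n <- 500
  labels <- rep(c(0, 1), each = n / 2)
  reject <- logical(1000)
  for (r in seq_len(1000)) {
    base <- rnorm(n) + labels
    a <- base + rnorm(n)
    b <- base + rnorm(n)
    reject[r] <- delong_test(a, b, labels)$p < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("macro-AUC averages retained classes and reports skips", {
  # two perfectly separated classes
  l <- cbind(rep(c(0, 1), each = 10), rep(c(1, 0), each = 10))
  s <- cbind(seq_len(20), rev(seq_len(20)))
  res <- macro_auc(s, l)
  expect_equal(res$macro, 1)
  expect_length(res$skipped, 0)

  # an all-negative column is skipped, macro over the valid two
  l3 <- cbind(l, 0)
  s3 <- cbind(s, rnorm(20))
  colnames(l3) <- colnames(s3) <- c("a", "b", "c")
  res3 <- macro_auc(s3, l3)
  expect_identical(res3$skipped, "c")
  expect_equal(res3$macro, 1)
  expect_identical(sum(res3$per_class$skipped), 1L)

  # null: random scores, balanced labels, 10 classes, n = 2000
  set.seed(31)
  L <- matrix(rbinom(2000 * 10, 1, 0.5), 2000, 10)
  S <- matrix(rnorm(2000 * 10), 2000, 10)
  expect_lt(abs(macro_auc(S, L)$macro - 0.5), 0.03)

  expect_error(macro_auc(S[, 1, drop = FALSE] ,
                         matrix(0, 2000, 1)), "every class")
})

test_that("run-summary notation reproduces the printed convention", {
  expect_identical(format_run_summary(c(0.958, 0.960, 0.962)), "0.960 (02)")
  expect_identical(format_run_summary(rep(0.875, 4)), "0.875 (00)")
  expect_identical(format_run_summary(c(0.96, 0.96)), "0.960 (00)")
  # mean 0.8333, sd 0.0101 -> "0.833 (10)"
  v <- c(0.8333 - 0.0101 / sqrt(2) * 1, 0.8333 + 0.0101 / sqrt(2) * 1)
  expect_identical(format_run_summary(v), "0.833 (10)")
  expect_identical(format_run_summary(0.5), "0.500 (00)")
})

test_that("tidy and glance methods return one-row summaries", {
  set.seed(3)
  s <- rnorm(60); l <- rep(c(0, 1), 30)
  res <- auroc_ci(s + l, l)
  expect_s3_class(tidy(res), "tbl_df")
  expect_identical(nrow(glance(res)), 1L)
  dl <- delong_test(s + l, s + 0.5 * l, l)
  td <- tidy(dl)
  expect_true(all(c("statistic", "p.value") %in% names(td)))
  ml <- macro_auc(cbind(s + l, s), cbind(l, rev(l)))
  expect_identical(nrow(tidy(ml)), 2L)
  expect_identical(glance(ml)$n_classes, 2L)
})
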