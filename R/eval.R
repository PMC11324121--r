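#' Rank-based AUROC
#'
#' Area under the receiver operating characteristic curve, computed with the
#' Mann-Whitney rank estimator: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, ties counting one half.
#' Uses midranks, so it runs in O(n log n) and equals the brute-force
#' all-pairs concordance count exactly.
#'
#' @param scores Numeric vector of predicted scores (any strictly increasing
#'   transform of scores leaves the result unchanged).
#' @param labels Binary vector (0/1 or logical) of the same length, with at
#'   least one positive and one negative.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m == 0L || n == 0L) {
    stop("AUROC undefined: labels must contain both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: V10 (per positive) and V01 (per negative),
# computed from midranks within/across classes.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  if (m == 0L || n == 0L) {
    stop("AUROC undefined: labels must contain both classes", call. = FALSE)
  }
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(theta = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01, m = m, n = n)
}

#' AUROC with a DeLong confidence interval
#'
#' Point estimate from the rank estimator and a normal-approximation
#' interval using the DeLong structural-components variance, clipped to
#' \[0, 1\]. Perfect separation gives zero estimated variance; the interval
#' then degenerates to the point estimate and is flagged.
#'
#' @inheritParams auroc
#' @param level Confidence level (default 0.95).
#' @return A `roc_result` with fields `auroc`, `ci_low`, `ci_high`, `se`,
#'   `level`, `n_pos`, `n_neg`, `degenerate`.
#' @export
auroc_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  cmp <- delong_components(scores, labels)
  v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
  se <- sqrt(max(v, 0))
  degenerate <- !is.finite(se) || se == 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- if (degenerate) cmp$theta else max(0, cmp$theta - z * se)
  hi <- if (degenerate) cmp$theta else min(1, cmp$theta + z * se)
  structure(list(auroc = cmp$theta, ci_low = lo, ci_high = hi, se = se,
                 level = level, n_pos = cmp$m, n_neg = cmp$n,
                 degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%.0f%% CI: %.3f-%.3f), %d pos / %d neg%s\n",
              x$auroc, 100 * x$level, x$ci_low, x$ci_high, x$n_pos, x$n_neg,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Paired DeLong comparison of two AUROCs
#'
#' Compares two models scored on the same cases with the DeLong paired
#' test: the difference in rank AUROCs divided by its structural-components
#' standard error, referred to a standard normal (two-sided). Identical
#' paired scores give a zero difference with zero standard error; this
#' degenerate case is defined as z = 0, p = 1.
#'
#' @param scores_a,scores_b Score vectors from the two models on the same
#'   cases, in the same case order.
#' @param labels Shared binary labels; at least two positives and two
#'   negatives are required for the covariance estimate.
#' @return A `delong_result` with `auroc_a`, `auroc_b`, `delta`, `se`, `z`
#'   and two-sided `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("paired scores and labels must have equal length", call. = FALSE)
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / ca$m + s01 / ca$n
  delta <- ca$theta - cb$theta
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  se <- sqrt(max(v, 0))
  if (se == 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / se
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(auroc_a = ca$theta, auroc_b = cb$theta, delta = delta,
                 se = se, z = z, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUROC %.3f vs %.3f, delta %+0.4f, z = %.3f, p = %.4g\n",
              x$auroc_a, x$auroc_b, x$delta, x$z, x$p))
  invisible(x)
}

#' Macro-averaged AUROC for multi-label tasks
#'
#' Computes the per-class rank AUROC over the columns of a score matrix and
#' averages them (macro-AUC). Classes lacking a positive or a negative in
#' the evaluation set have no defined AUROC; they are skipped and reported,
#' and the macro mean averages only the retained classes.
#'
#' @param scores Numeric n x K matrix of per-class scores.
#' @param labels Binary n x K matrix of per-class targets.
#' @return A `multilabel_result`: tibble `per_class` (class, auroc,
#'   skipped), `macro` mean over retained classes, `skipped` class names.
#' @export
macro_auc <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(identical(dim(scores), dim(labels)))
  K <- ncol(scores)
  cls <- colnames(scores) %||% paste0("class", seq_len(K))
  auc <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    lk <- as.integer(labels[, k])
    if (length(unique(lk)) == 2L) auc[k] <- auroc(scores[, k], lk)
  }
  keep <- !is.na(auc)
  if (!any(keep)) {
    stop("macro-AUC undefined: every class lacks a positive or a negative",
         call. = FALSE)
  }
  structure(list(
    per_class = tibble::tibble(class = cls, auroc = auc, skipped = !keep),
    macro = mean(auc[keep]),
    skipped = cls[!keep]
  ), class = "multilabel_result")
}

#' @export
print.multilabel_result <- function(x, ...) {
  cat(sprintf("macro-AUC %.3f over %d classes (%d skipped)\n",
              x$macro, sum(!x$per_class$skipped), length(x$skipped)))
  invisible(x)
}

#' Run-summary notation for repeated fine-tuning runs
#'
#' Formats the mean and standard deviation over repeated runs in the
#' compact convention used for benchmark macro-AUC tables: the mean to
#' three decimals, followed by the last two of the SD's three decimals in
#' parentheses. A macro-AUC of 0.960 with SD 0.002 prints as
#' `"0.960 (02)"`.
#'
#' @param values Numeric vector of per-run metric values (length >= 2, or
#'   length 1 which reports an SD of zero).
#' @return A string such as `"0.960 (02)"`.
#' @export
format_run_summary <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  m <- mean(values)
  s <- if (length(values) >= 2) stats::sd(values) else 0
  s3 <- sprintf("%.3f", s)
  sprintf("%.3f (%s)", m, substr(s3, nchar(s3) - 1L, nchar(s3)))
}

# ---- broom-style methods ------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high,
                 se = x$se, level = x$level)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high,
                 se = x$se, level = x$level, n_pos = x$n_pos,
                 n_neg = x$n_neg, degenerate = x$degenerate)
}

#' @export
tidy.delong_result <- function(x, ...) {
  tibble::tibble(auroc_a = x$auroc_a, auroc_b = x$auroc_b, delta = x$delta,
                 se = x$se, statistic = x$z, p.value = x$p)
}

#' @export
tidy.multilabel_result <- function(x, ...) {
  x$per_class
}

#' @export
glance.multilabel_result <- function(x, ...) {
  tibble::tibble(macro_auc = x$macro,
                 n_classes = nrow(x$per_class),
                 n_skipped = length(x$skipped))
}

#' ROC curve points for plotting
#'
#' Empirical ROC curve (false positive rate, true positive rate) swept over
#' all score thresholds.
#'
#' @inheritParams auroc
#' @return Tibble with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  tibble::tibble(
    fpr = c(0, fp[keep] / sum(1 - l)),
    tpr = c(0, tp[keep] / sum(l)),
    threshold = c(Inf, s[keep])
  )
}
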