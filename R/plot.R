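#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

signal_long <- function(sig, leads, value_name = "mv") {
  keep <- match(leads, ECG_LEADS)
  df <- lapply(seq_along(keep), function(i) {
    tibble::tibble(lead = leads[[i]],
                   time = (seq_len(ncol(sig)) - 1) / 500,
                   value = sig[keep[[i]], ])
  })
  out <- dplyr::bind_rows(df)
  out$lead <- factor(out$lead, levels = ECG_LEADS)
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Plot a 12-lead record
#'
#' Voltage traces against time, one facet per selected lead.
#'
#' @param object An [ecg_record()].
#' @param leads Leads to draw (default all 12).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecg_record <- function(object, leads = ECG_LEADS, ...) {
  df <- signal_long(object$signal, leads)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)",
                  title = object$record_id) +
    ggplot2::theme_minimal()
}

#' Plot an MAE reconstruction
#'
#' Three panels per selected lead, mirroring the qualitative
#' reconstruction view: the original trace, the masked input (visible
#' patches only, masked spans blank) and the reconstruction.
#'
#' @param object An `mae_reconstruction` from [reconstruct()].
#' @param leads Leads to draw (default II and V5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mae_reconstruction <- function(object, leads = c("II", "V5"), ...) {
  panels <- dplyr::bind_rows(
    dplyr::mutate(signal_long(object$original, leads), panel = "original"),
    dplyr::mutate(signal_long(object$masked_sig, leads), panel = "masked"),
    dplyr::mutate(signal_long(object$pred, leads), panel = "reconstructed")
  )
  panels$panel <- factor(panels$panel,
                         levels = c("original", "masked", "reconstructed"))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$time, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(lead ~ panel) +
    ggplot2::labs(x = "time (s)", y = "normalized voltage",
                  title = sprintf("masked-autoencoder reconstruction (%s, %.0f%% masked)",
                                  object$record_id, 100 * object$mask$ratio)) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' Empirical ROC curve with the AUROC and its confidence interval in the
#' subtitle.
#'
#' @inheritParams auroc
#' @param level Confidence level for the annotation.
#' @return A ggplot.
#' @export
plot_roc <- function(scores, labels, level = 0.95) {
  pts <- roc_points(scores, labels)
  res <- auroc_ci(scores, labels, level)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "receiver operating characteristic",
                  subtitle = sprintf("AUROC %.3f (%.0f%% CI %.3f-%.3f)",
                                     res$auroc, 100 * level, res$ci_low,
                                     res$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss trajectories from [pretrain()] or [finetune()] histories.
#'
#' @param history A history tibble with an `epoch` column and one or more
#'   loss columns.
#' @return A ggplot.
#' @export
plot_history <- function(history) {
  loss_cols <- intersect(c("loss", "train_loss", "val_loss"),
                         names(history))
  df <- tidyr::pivot_longer(history[, c("epoch", loss_cols)],
                            -"epoch", names_to = "series",
                            values_to = "loss_value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss_value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
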