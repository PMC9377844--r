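#' @describeIn evaluate_predictions Tidy per-label metrics: one row per label
#'   with confusion counts and metric values.
#' @param x A `metric_report`.
#' @param ... Unused.
#' @export
tidy.metric_report <- function(x, ...) {
  x$per_label
}

#' @describeIn evaluate_predictions One-row summary: macro metrics, macro
#'   AUC, example-based F1 and F_max.
#' @export
glance.metric_report <- function(x, ...) {
  macro <- x$summary[x$summary$averaging == "macro", ]
  eb <- x$summary[x$summary$averaging == "example_based", ]
  tibble(macro_accuracy = macro$accuracy, macro_precision = macro$precision,
         macro_recall = macro$recall, macro_f1 = macro$f1,
         macro_auc = x$macro_auc, example_f1 = eb$f1, f_max = x$f_max,
         f_max_threshold = x$f_max_threshold, threshold = x$threshold)
}

#' @describeIn train_mrf Tidy training history (one row per epoch).
#' @param x A trained `mrf_model`.
#' @param ... Unused.
#' @export
tidy.mrf_model <- function(x, ...) {
  if (is.null(x$history)) abort("Model has no training history yet.")
  x$history
}

#' @describeIn train_mrf One-row fit summary: epochs run, best epoch, best
#'   validation loss and AUC, parameter count.
#' @export
glance.mrf_model <- function(x, ...) {
  p <- count_params(x$config)
  if (is.null(x$history)) {
    return(tibble(epochs = 0L, best_epoch = NA_integer_,
                  val_loss = NA_real_, val_auc = NA_real_,
                  n_parameters = p$total))
  }
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         val_loss = best$val_loss, val_auc = best$val_auc,
         n_parameters = p$total)
}

#' Plot a 12-lead ECG record
#'
#' Facets the leads on a shared time axis.
#'
#' @param object An [ecg_record()].
#' @param leads Optional subset of lead names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, leads = NULL, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(
      as_tibble(t(object$signal), .name_repair = "minimal"),
      time = (seq_len(ncol(object$signal)) - 1) / object$rate
    ),
    -"time", names_to = "lead", values_to = "mV"
  )
  if (!is.null(leads)) df <- dplyr::filter(df, .data$lead %in% leads)
  df$lead <- factor(df$lead, levels = rownames(object$signal))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead), scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (mV)",
      title = sprintf("%s  [%s]", object$id,
                      paste(object$labels, collapse = ", "))
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot training history
#'
#' Loss and macro-AUC curves for train and validation, with the best epoch
#' marked.
#'
#' @param object A trained `mrf_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrf_model <- function(object, ...) {
  if (is.null(object$history)) abort("Model has no training history yet.")
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = c("split", "metric"), names_sep = "_",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-label metrics of a report
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_label[, c("label", "precision", "recall", "f1", "auc")],
    -"label", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
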