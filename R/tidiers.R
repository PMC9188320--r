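# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# experiment results.

#' @export
tidy.seq_model <- function(x, ...) {
  x$log
}

#' @export
glance.seq_model <- function(x, ...) {
  tibble(encoder = x$spec$encoder,
         use_structured = x$spec$use_structured,
         best_epoch = x$best_epoch,
         best_val_loss = min(x$log$val_loss),
         n_parameters = sum(vapply(x$params, length, 0L)),
         epochs = nrow(x$log))
}

#' @export
tidy.bow_model <- function(x, ...) {
  tibble(classifier = x$clf,
         parameter = names(x$params) %||% character(0),
         value = unlist(x$params) %||% numeric(0))
}

#' @export
glance.bow_model <- function(x, ...) {
  tibble(classifier = x$clf, scaled = !is.null(x$scaling),
         n_classes = length(x$classes), seed = x$seed)
}

#' @export
tidy.experiment_result <- function(x, ...) {
  x$results
}

#' @export
glance.experiment_result <- function(x, ...) {
  tibble(matrix = x$matrix, n_cells = nrow(x$results),
         n_comparisons = if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
         seed = x$seed)
}

#' @export
autoplot.seq_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = paste0("Training curves (", object$spec$encoder, ")"),
                  x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  xvar <- switch(object$matrix, models = "model",
                 prep_methods = "prep_method", train_sizes = "train_size")
  p <- ggplot2::ggplot(object$results,
                       ggplot2::aes(x = .data[[xvar]], y = .data$auroc,
                                    colour = .data$class,
                                    group = .data$class))
  p <- if (object$matrix == "train_sizes") {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(size = 2) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$auroc_lo,
                                          ymax = .data$auroc_hi),
                             width = 0.2)
  }
  p + ggplot2::labs(y = "AUROC", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ROC curve points for a score vector
#'
#' Emits the (false positive rate, true positive rate) points of the
#' empirical ROC curve, ready for plotting or export.
#'
#' @param scores Numeric scores.
#' @param truth Binary truth.
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth) {
  truth <- as.logical(truth)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord]); fp <- cumsum(!truth[ord])
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  pts <- tibble(threshold = scores[ord][keep],
                fpr = fp[keep] / sum(!truth),
                tpr = tp[keep] / sum(truth))
  dplyr::bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), pts) %>%
    arrange(.data$fpr, .data$tpr)
}

#' Plot ROC curves for each class of a score matrix
#'
#' @param cands Labelled candidate tibble.
#' @param scores Aligned score matrix.
#' @return A ggplot object.
#' @export
plot_roc <- function(cands, scores) {
  df <- dplyr::bind_rows(lapply(c("AHI", "SaO2"), function(cl) {
    roc_points(scores[, cl], cands$label == cl) %>% mutate(class = cl)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
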