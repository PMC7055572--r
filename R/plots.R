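# ggplot2 graphics for scores, evaluations and phantom images.

#' ROC curve of risk scores
#'
#' @param scores Numeric risk scores (or a [loco_cv()] tibble).
#' @param labels Binary labels (ignored when `scores` is a tibble).
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$risk_score
  }
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(labels[ord] == 1L) / sum(labels == 1L))
  fpr <- c(0, cumsum(labels[ord] == 0L) / sum(labels == 0L))
  df <- tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)",
                                  roc_auc(scores, labels)$auc)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a subgroup odds-ratio table
#'
#' @param or_table Tibble from [odds_ratio_table()].
#' @return A ggplot object.
#' @export
plot_or_table <- function(or_table) {
  df <- or_table
  df$subgroup <- factor(df$subgroup)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subgroup, y = .data$odds_ratio)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Score subgroup", y = "Odds ratio (log scale)",
                  title = "Subgroup odds ratios vs baseline") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.risk_evaluation <- function(object, type = c("roc", "or"), ...) {
  type <- match.arg(type)
  switch(type,
         roc = plot_roc(object$scores),
         or = plot_or_table(object$or_table))
}

#' Raster plot of a 2D image or one slice of a volume
#'
#' @param image Numeric matrix, or 3D array with `slice` given.
#' @param slice Slice index along the third axis for 3D input.
#' @return A ggplot object.
#' @export
plot_slice <- function(image, slice = NULL) {
  if (length(dim(image)) == 3L) {
    slice <- slice %||% ceiling(dim(image)[3] / 2)
    image <- image[, , slice]
  }
  df <- tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    value = as.vector(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Intensity") +
    ggplot2::theme_minimal()
}
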