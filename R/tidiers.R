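# broom-style accessors and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy a detection evaluation
#'
#' @param x A `grain_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return Per-class tibble: label, n_gt, TP, FP, FN, precision, recall, AP.
#' @method tidy grain_eval
#' @export
tidy.grain_eval <- function(x, ...) x$per_class

#' @rdname tidy.grain_eval
#' @return For `glance()`: one-row tibble with mAP, iou_thresh, n_gt.
#' @method glance grain_eval
#' @export
glance.grain_eval <- function(x, ...) {
  tibble(mAP = x$mAP, iou_thresh = x$iou_thresh, n_gt = x$n_gt)
}

#' Tidy a trained detector's loss history
#'
#' @param x A `grain_detector`.
#' @param ... Unused.
#' @return Tibble: epoch, rpn_cls, rpn_loc, roi_cls, roi_loc, total.
#' @method tidy grain_detector
#' @export
tidy.grain_detector <- function(x, ...) x$history

#' @rdname tidy.grain_detector
#' @return For `glance()`: one-row tibble with final losses, parameter count
#'   and class count.
#' @method glance grain_detector
#' @export
glance.grain_detector <- function(x, ...) {
  last <- x$history[nrow(x$history), , drop = FALSE]
  tibble(
    epochs = nrow(x$history), final_loss = last$total,
    n_parameters = sum(purrr::map_int(x$params, length)),
    n_classes = length(x$classes), arch = x$backbone$arch
  )
}

#' Tidy a cross-validation run
#'
#' @param x A `grain_cv` from [cross_validate()].
#' @param ... Unused.
#' @return Per-fold metric tibble.
#' @method tidy grain_cv
#' @export
tidy.grain_cv <- function(x, ...) x$per_fold

#' @rdname tidy.grain_cv
#' @return For `glance()`: the mean +/- sd summary table.
#' @method glance grain_cv
#' @export
glance.grain_cv <- function(x, ...) x$summary

#' Tidy a confusion matrix
#'
#' @param x A `grain_confusion`.
#' @param ... Unused.
#' @return Long tibble: actual, predicted, n, percent.
#' @method tidy grain_confusion
#' @export
tidy.grain_confusion <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n")
  pc <- as.data.frame.table(x$percent, responseName = "percent")
  tibble(
    actual = as.character(df$actual), predicted = as.character(df$predicted),
    n = df$n, percent = pc$percent
  )
}

#' Plot a scene with its annotations (and optional detections)
#'
#' @param object A `grain_record`.
#' @param detections Optional detection tibble to overlay (dashed boxes).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grain_record
#' @export
autoplot.grain_record <- function(object, detections = NULL, ...) {
  px <- object$pixels
  df <- expand.grid(y = seq_len(dim(px)[1]), x = seq_len(dim(px)[2]))
  df$col <- grDevices::rgb(as.vector(px[, , 1]), as.vector(px[, , 2]),
                           as.vector(px[, , 3]))
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = df,
      ggplot2::aes(x = .data$x - 0.5, y = .data$y - 0.5, fill = .data$col)
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, title = object$id)
  if (nrow(object$annotations)) {
    p <- p + ggplot2::geom_rect(
      data = object$annotations,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$label),
      fill = NA, linewidth = 0.4
    )
  }
  if (!is.null(detections) && nrow(detections)) {
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$label),
      fill = NA, linetype = 2, linewidth = 0.4
    )
  }
  p
}

#' Plot per-class AP and the training-loss curve
#'
#' @param object A `grain_eval` or `grain_detector`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grain_eval
#' @export
autoplot.grain_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_class,
                  ggplot2::aes(x = .data$label, y = .data$AP)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = object$mAP, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Average precision",
                  subtitle = sprintf("mAP = %.3f at IoU >= %.2f",
                                     object$mAP, object$iou_thresh))
}

#' @rdname autoplot.grain_eval
#' @method autoplot grain_detector
#' @export
autoplot.grain_detector <- function(object, ...) {
  long <- tidyr_pivot(object$history)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL)
}

# small local reshape to avoid a tidyr dependency for one call
tidyr_pivot <- function(history) {
  comps <- c("rpn_cls", "rpn_loc", "roi_cls", "roi_loc")
  purrr::map_dfr(comps, function(cc) {
    tibble(epoch = history$epoch, component = cc, loss = history[[cc]])
  })
}
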