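# Detection evaluation: greedy score-ordered matching against ground truth,
# precision / recall, all-point average precision (area under the precision
# envelope of the PR curve), mAP over classes, a localization-first
# confusion matrix, and the ten-fold cross-validation harness.

#' Match detections to ground truths in one image/class slice
#'
#' Detections are processed in descending score order (ties by input order);
#' each matches the highest-IoU not-yet-matched ground truth at or above
#' `iou_thresh`. A detection whose only match is a difficult annotation is
#' neither TP nor FP; unmatched non-difficult ground truths are FN.
#'
#' @param dets Detection tibble (xmin..ymax, score) for one image and class.
#' @param gts Ground-truth tibble (xmin..ymax, difficult) for the same slice.
#' @param iou_thresh Matching threshold, default 0.5.
#' @return List: `det` tibble (score, outcome TP/FP/ignored, matched_gt),
#'   `n_fn` unmatched non-difficult ground-truth count.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  d <- as_tibble(dets)
  g <- as_tibble(gts)
  if (!"difficult" %in% names(g)) g$difficult <- FALSE
  nd <- nrow(d)
  ng <- nrow(g)
  ord <- if (nd) order(d$score, decreasing = TRUE) else integer(0)
  outcome <- character(nd)
  matched_gt <- rep(NA_integer_, nd)
  gt_taken <- rep(FALSE, ng)
  M <- if (nd && ng) iou_matrix(d, g) else matrix(0, nd, ng)
  for (i in ord) {
    if (ng == 0L) { outcome[i] <- "FP"; next }
    cand <- which(M[i, ] >= iou_thresh & !gt_taken)
    if (length(cand) == 0L) { outcome[i] <- "FP"; next }
    best <- cand[which.max(M[i, cand])]
    if (g$difficult[best]) {
      outcome[i] <- "ignored" # difficult targets are not counted either way
      gt_taken[best] <- TRUE
    } else {
      outcome[i] <- "TP"
      matched_gt[i] <- best
      gt_taken[best] <- TRUE
    }
  }
  list(
    det = dplyr::bind_cols(d, tibble(outcome = outcome,
                                     matched_gt = matched_gt)),
    n_fn = sum(!gt_taken & !g$difficult)
  )
}

#' All-point average precision
#'
#' Precision/recall are accumulated over the score-ranked outcomes; AP is
#' the area under the precision envelope (each precision replaced by the
#' maximum at equal-or-higher recall) over recall in \[0, 1\].
#'
#' @param tp Logical vector of per-detection outcomes, ranked by descending
#'   score across the whole test set.
#' @param n_gt Number of (non-difficult) ground truths of the class.
#' @return AP in \[0, 1\] (0 when `n_gt > 0` and there is no TP).
#' @export
average_precision <- function(tp, n_gt) {
  if (n_gt <= 0) return(NA_real_)
  if (length(tp) == 0L || !any(tp)) return(0)
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Mean average precision
#'
#' @param aps Named per-class AP vector; NA entries (classes with no ground
#'   truth) are dropped with a warning.
#' @return Mean of the remaining APs.
#' @export
mean_ap <- function(aps) {
  if (any(is.na(aps))) {
    warning("classes without ground truth excluded from mAP: ",
            paste(names(aps)[is.na(aps)], collapse = ", "))
    aps <- aps[!is.na(aps)]
  }
  mean(aps)
}

#' Evaluate detections against ground truth
#'
#' Pools detections over all images, ranks per class by descending score
#' (ties by image id then input order), matches greedily per image at
#' `iou_thresh`, and reports per-class precision, recall, AP and counts plus
#' the overall mAP. Difficult ground truths are excluded from denominators.
#'
#' @param dets Detection tibble: image_id, label, score, xmin..ymax.
#' @param gts Ground-truth tibble: image_id, label, xmin..ymax, difficult
#'   (e.g. from [flatten_annotations()]).
#' @param iou_thresh IoU threshold, default 0.5.
#' @return A `grain_eval` object.
#' @export
evaluate_detections <- function(dets, gts, iou_thresh = 0.5) {
  d <- as_tibble(dets)
  g <- as_tibble(gts)
  if (!"difficult" %in% names(g)) g$difficult <- FALSE
  classes <- sort(unique(g$label[!g$difficult]))
  per_class <- purrr::map_dfr(classes, function(cl) {
    gc <- g[g$label == cl, , drop = FALSE]
    dc <- d[d$label == cl, , drop = FALSE]
    n_gt <- sum(!gc$difficult)
    if (nrow(dc)) {
      dc <- dc[order(-dc$score, dc$image_id), , drop = FALSE]
    }
    flags <- logical(0)
    n_fp <- 0L
    if (nrow(dc)) {
      res <- purrr::map(split(seq_len(nrow(dc)), dc$image_id), function(ix) {
        m <- match_detections(dc[ix, , drop = FALSE],
                              gc[gc$image_id == dc$image_id[ix[1]], ,
                                 drop = FALSE],
                              iou_thresh)
        tibble(row = ix, outcome = m$det$outcome)
      })
      res <- dplyr::bind_rows(res)
      res <- res[order(res$row), , drop = FALSE]
      keep <- res$outcome != "ignored"
      flags <- res$outcome[keep] == "TP"
      n_fp <- sum(res$outcome == "FP")
    }
    n_tp <- sum(flags)
    tibble(
      label = cl, n_gt = n_gt, TP = n_tp, FP = n_fp, FN = n_gt - n_tp,
      precision = if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else NA_real_,
      recall = if (n_gt > 0) n_tp / n_gt else NA_real_,
      AP = average_precision(flags, n_gt)
    )
  })
  structure(
    list(per_class = per_class,
         mAP = mean_ap(setNames(per_class$AP, per_class$label)),
         iou_thresh = iou_thresh,
         n_gt = sum(!g$difficult)),
    class = "grain_eval"
  )
}

#' @export
print.grain_eval <- function(x, ...) {
  cat(sprintf("<grain_eval> IoU >= %.2f, %d ground truths\n",
              x$iou_thresh, x$n_gt))
  df <- x$per_class
  df[c("precision", "recall", "AP")] <-
    lapply(df[c("precision", "recall", "AP")], function(v) round(100 * v, 2))
  names(df) <- c("Class", "GT", "TP", "FP", "FN",
                 "Precision", "Recall", "AveP")
  print(as.data.frame(df), row.names = FALSE)
  cat(sprintf("mAP: %.2f%%\n", 100 * x$mAP))
  invisible(x)
}

#' Confusion matrix over localized matches
#'
#' Boxes are matched class-agnostically first (localization), then labels
#' are compared: each matched (ground truth, detection) pair increments cell
#' (actual = gt label, predicted = detection label). Percentages are
#' relative to the total number of matched positives; unmatched detections
#' and ground truths are reported separately, not in the matrix.
#'
#' @param dets Detection tibble: image_id, label, score, xmin..ymax.
#' @param gts Ground-truth tibble: image_id, label, xmin..ymax, difficult.
#' @param iou_thresh Localization threshold, default 0.5.
#' @return A `grain_confusion`: counts (actual x predicted), percent,
#'   accuracy, n_unmatched_det, n_unmatched_gt.
#' @export
confusion_matrix <- function(dets, gts, iou_thresh = 0.5) {
  d <- as_tibble(dets)
  g <- as_tibble(gts)
  if (!"difficult" %in% names(g)) g$difficult <- FALSE
  g <- g[!g$difficult, , drop = FALSE]
  classes <- sort(unique(c(d$label, g$label)))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(actual = classes, predicted = classes))
  n_matched_det <- 0L
  for (img in unique(c(d$image_id, g$image_id))) {
    di <- d[d$image_id == img, , drop = FALSE]
    gi <- g[g$image_id == img, , drop = FALSE]
    m <- match_detections(di, gi, iou_thresh) # class-agnostic: all labels in
    ok <- !is.na(m$det$matched_gt)
    n_matched_det <- n_matched_det + sum(ok)
    if (any(ok)) {
      actual <- gi$label[m$det$matched_gt[ok]]
      pred <- m$det$label[ok]
      for (q in seq_along(actual)) {
        cm[actual[q], pred[q]] <- cm[actual[q], pred[q]] + 1L
      }
    }
  }
  total <- sum(cm)
  structure(
    list(counts = cm,
         percent = if (total > 0) 100 * cm / total else cm * 0,
         accuracy = if (total > 0) sum(diag(cm)) / total else NA_real_,
         n_unmatched_det = nrow(d) - n_matched_det,
         n_unmatched_gt = nrow(g) - total),
    class = "grain_confusion"
  )
}

#' @export
print.grain_confusion <- function(x, ...) {
  cat("<grain_confusion> rows = actual, columns = predicted\n")
  print(x$counts)
  cat(sprintf("accuracy: %.2f%%  (unmatched: %d detections, %d ground truths)\n",
              100 * x$accuracy, x$n_unmatched_det, x$n_unmatched_gt))
  invisible(x)
}

#' Split indices into k near-equal folds
#'
#' @param n Number of items.
#' @param k Number of folds (default 10).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return List of `k` disjoint integer vectors whose union is `1:n` and
#'   whose sizes differ by at most 1.
#' @export
fold_split <- function(n, k = 10, seed = 1L) {
  if (n < k) abort(sprintf("dataset of size %d cannot form %d folds", n, k))
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n)
    fold_of <- rep(seq_len(k), length.out = n)
    unname(split(idx, fold_of))
  })
}

#' Ten-fold cross-validation of the detector
#'
#' Builds a seeded fold split, trains on the out-of-fold images and
#' evaluates on the held-out fold, and summarizes AP/mAP/precision/recall
#' across folds as mean and sample (n-1) standard deviation.
#'
#' @param dataset List of `grain_record`s.
#' @param config A [train_config()] passed to the training function.
#' @param k Number of folds, default 10.
#' @param seed Seed for the fold split.
#' @param iou_thresh Evaluation IoU threshold.
#' @param train_fn Function `(dataset, config)` returning a model; defaults
#'   to [train_detector()].
#' @param detect_fn Function `(record, model)` returning a detection tibble;
#'   defaults to [detect()].
#' @return A `grain_cv`: per-fold tibble plus a mean/sd summary table.
#' @export
cross_validate <- function(dataset, config = train_config(), k = 10,
                           seed = 1L, iou_thresh = 0.5,
                           train_fn = train_detector, detect_fn = detect) {
  folds <- fold_split(length(dataset), k, seed)
  per_fold <- purrr::map_dfr(seq_along(folds), function(fi) {
    test_idx <- folds[[fi]]
    model <- train_fn(dataset[-test_idx], config)
    dets <- purrr::map_dfr(dataset[test_idx], detect_fn, model = model)
    ev <- evaluate_detections(dets, flatten_annotations(dataset[test_idx]),
                              iou_thresh)
    tibble(
      fold = fi,
      mAP = ev$mAP,
      precision = mean(ev$per_class$precision, na.rm = TRUE),
      recall = mean(ev$per_class$recall, na.rm = TRUE),
      AP_min = min(ev$per_class$AP, na.rm = TRUE)
    )
  })
  metrics <- c("mAP", "precision", "recall", "AP_min")
  summary <- purrr::map_dfr(metrics, function(mm) {
    tibble(metric = mm, mean = mean(per_fold[[mm]]), sd = sd(per_fold[[mm]]))
  })
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 seed = seed),
            class = "grain_cv")
}

#' @export
print.grain_cv <- function(x, ...) {
  cat(sprintf("<grain_cv> %d folds (seed %d)\n", length(x$folds), x$seed))
  df <- x$summary
  df$`mean +/- sd` <- sprintf("%.2f +/- %.2f", 100 * df$mean, 100 * df$sd)
  print(as.data.frame(df[, c("metric", "mean +/- sd")]), row.names = FALSE)
  invisible(x)
}

#' Anchor-scale ablation harness
#'
#' Trains and evaluates the detector once per candidate anchor-scale set
#' (fixed aspect ratios), mirroring the classical scale-ablation experiment:
#' more, smaller scales recover more small objects at some proposal-volume
#' cost.
#'
#' @param scale_sets List of numeric scale vectors.
#' @param train_data,test_data Lists of `grain_record`s.
#' @param config A [train_config()].
#' @param ratios Aspect ratios held fixed across runs.
#' @param iou_thresh Evaluation IoU threshold.
#' @param train_fn,detect_fn Injection points, as in [cross_validate()].
#' @return Tibble: one row per scale set with k, mAP, precision, recall.
#' @export
ablate_anchors <- function(scale_sets, train_data, test_data,
                           config = train_config(),
                           ratios = c(1, 0.5, 2), iou_thresh = 0.5,
                           train_fn = NULL, detect_fn = detect) {
  purrr::map_dfr(scale_sets, function(sc) {
    ac <- anchor_config(scales = sc, ratios = ratios)
    model <- if (is.null(train_fn)) {
      train_detector(train_data, config, anchors = ac)
    } else {
      train_fn(train_data, config, ac)
    }
    dets <- purrr::map_dfr(test_data, detect_fn, model = model)
    ev <- evaluate_detections(dets, flatten_annotations(test_data), iou_thresh)
    tibble(
      scales = paste(sc, collapse = ","), k = ac$k, mAP = ev$mAP,
      precision = mean(ev$per_class$precision, na.rm = TRUE),
      recall = mean(ev$per_class$recall, na.rm = TRUE)
    )
  })
}
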