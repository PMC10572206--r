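# Non-maximum suppression over scored detections. Hard NMS deletes
# neighbours of the running maximum outright; Soft-NMS decays their scores
# instead -- linearly (only above the overlap threshold Nt) or with a
# Gaussian penalty exp(-iou^2 / sigma) applied to every remaining box -- and
# prunes boxes only once their decayed score falls below a small floor.
# Decaying rather than deleting is what preserves recall when insects
# aggregate at a single grain kernel.

#' Suppression configuration
#'
#' @param mode `"hard"`, `"linear"` or `"gaussian"`.
#' @param Nt Overlap threshold (used by hard and linear modes), default 0.3.
#' @param sigma Gaussian decay coefficient, default 0.5.
#' @param score_floor Scores decayed below this are pruned, default 0.001.
#' @return A `suppression_config` list.
#' @export
suppression_config <- function(mode = c("gaussian", "linear", "hard"),
                               Nt = 0.3, sigma = 0.5, score_floor = 0.001) {
  mode <- match.arg(mode)
  stopifnot(Nt > 0, Nt < 1, sigma > 0, score_floor >= 0, score_floor < 1)
  structure(list(mode = mode, Nt = Nt, sigma = sigma,
                 score_floor = score_floor),
            class = "suppression_config")
}

det_table <- function(dets) {
  d <- as_tibble(dets)
  stopifnot(all(c("xmin", "ymin", "xmax", "ymax", "score") %in% names(d)))
  d
}

# shared iterative engine (compiled); ties in the running maximum go to the
# lowest input index
suppress_engine <- function(dets, mode, Nt, sigma, score_floor) {
  d <- det_table(dets)
  if (nrow(d) == 0L) return(d[0, ])
  mode_int <- match(mode, c("hard", "linear", "gaussian")) - 1L
  res <- nms_engine(box_matrix(d), d$score, mode_int, Nt, sigma, score_floor)
  out <- d[res$picked, , drop = FALSE]
  out$score <- res$scores
  out
}

#' Hard non-maximum suppression (single class)
#'
#' Iteratively keeps the highest-scoring box and removes every remaining box
#' whose IoU with it exceeds `Nt`. Equal scores are broken by input order.
#'
#' @param dets Detection tibble with columns xmin, ymin, xmax, ymax, score.
#' @param Nt Overlap threshold, default 0.3.
#' @return The surviving detections, in selection order.
#' @export
hard_nms <- function(dets, Nt = 0.3) {
  suppress_engine(dets, "hard", Nt, sigma = 1, score_floor = 0)
}

#' Soft non-maximum suppression (single class)
#'
#' Linear mode rescales a remaining score s to `s * (1 - iou)` when its IoU
#' with the current maximum is at least `Nt` (otherwise unchanged); Gaussian
#' mode rescales every remaining score by `exp(-iou^2 / sigma)`. Boxes whose
#' decayed score drops below `config$score_floor` are pruned; all surviving
#' boxes are returned with their final scores, in selection order.
#'
#' @param dets Detection tibble with columns xmin, ymin, xmax, ymax, score.
#' @param config A [suppression_config()] with mode `"linear"` or
#'   `"gaussian"` (mode `"hard"` dispatches to [hard_nms()]).
#' @return Surviving detections with decayed scores.
#' @export
soft_nms <- function(dets, config = suppression_config()) {
  stopifnot(inherits(config, "suppression_config"))
  if (!config$mode %in% c("hard", "linear", "gaussian")) {
    abort(sprintf("unknown suppression mode '%s'", config$mode))
  }
  if (config$mode == "hard") return(hard_nms(dets, config$Nt))
  suppress_engine(dets, config$mode, config$Nt, config$sigma,
                  config$score_floor)
}

#' Class-wise suppression over a multi-class detection table
#'
#' Partitions detections by `label`, applies the configured suppression
#' within each class, and concatenates; boxes of different classes never
#' suppress each other.
#'
#' @param dets Detection tibble with columns label, xmin, ymin, xmax, ymax,
#'   score (extra columns such as image_id pass through).
#' @param config A [suppression_config()].
#' @return The suppressed detections, ordered by score within class groups.
#' @export
suppress_per_class <- function(dets, config = suppression_config()) {
  d <- det_table(dets)
  stopifnot("label" %in% names(d))
  if (nrow(d) == 0L) return(d)
  parts <- split(d, d$label)
  dplyr::bind_rows(purrr::map(parts, function(p) {
    if (config$mode == "hard") hard_nms(p, config$Nt) else soft_nms(p, config)
  }))
}
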