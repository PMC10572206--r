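# YAML configuration surface for the command-line tool. Keys mirror the
# constructor arguments: anchors.scales/ratios/stride, suppress.mode/Nt/
# sigma/floor, pspm.k, train.*, scene.*.

#' Default pipeline configuration
#'
#' @return Nested list of [anchor_config()], [suppression_config()],
#'   [train_config()], [scene_config()] and `pspm = list(k = 3)`.
#' @export
default_config <- function() {
  list(
    anchors = anchor_config(),
    suppress = suppression_config(),
    pspm = list(k = 3L),
    train = train_config(),
    scene = scene_config(),
    arch = "tiny"
  )
}

#' Read a YAML pipeline configuration
#'
#' Any key left out falls back to the package default; recognized sections
#' are `anchors` (scales, ratios, stride), `suppress` (mode, Nt, sigma,
#' floor), `pspm` (k), `train` (lr, epochs, ...), `scene` (width, height,
#' classes as name: weight pairs, ...) and `arch`.
#'
#' @param path YAML file path.
#' @return Config list as in [default_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(raw$anchors)) {
    a <- raw$anchors
    cfg$anchors <- anchor_config(
      scales = a$scales %||% cfg$anchors$scales,
      ratios = a$ratios %||% cfg$anchors$ratios,
      stride = a$stride %||% cfg$anchors$stride
    )
  }
  if (!is.null(raw$suppress)) {
    s <- raw$suppress
    cfg$suppress <- suppression_config(
      mode = s$mode %||% cfg$suppress$mode,
      Nt = s$Nt %||% cfg$suppress$Nt,
      sigma = s$sigma %||% cfg$suppress$sigma,
      score_floor = s$floor %||% cfg$suppress$score_floor
    )
  }
  if (!is.null(raw$pspm$k)) cfg$pspm$k <- as.integer(raw$pspm$k)
  if (!is.null(raw$train)) {
    t <- raw$train
    base <- cfg$train
    cfg$train <- train_config(
      lr = t$lr %||% base$lr,
      epochs = t$epochs %||% base$epochs,
      lr_decay = t$lr_decay %||% base$lr_decay,
      lr_decay_at = t$lr_decay_at %||% base$lr_decay_at,
      weight_decay = t$weight_decay %||% base$weight_decay,
      beta1 = t$beta1 %||% base$beta1,
      pre_nms = t$pre_nms %||% base$pre_nms,
      post_nms = t$post_nms %||% base$post_nms,
      roi_pos_iou = t$roi_pos_iou %||% base$roi_pos_iou,
      roi_batch = t$roi_batch %||% base$roi_batch,
      augment = t$augment %||% base$augment,
      seed = t$seed %||% base$seed
    )
  }
  if (!is.null(raw$scene)) {
    s <- raw$scene
    base <- cfg$scene
    classes <- if (!is.null(s$classes)) unlist(s$classes) else base$classes
    cfg$scene <- scene_config(
      width = s$width %||% base$width,
      height = s$height %||% base$height,
      classes = classes,
      count_range = s$count_range %||% base$count_range,
      size_range = s$size_range %||% base$size_range,
      aspect_range = s$aspect_range %||% base$aspect_range,
      cluster_prob = s$cluster_prob %||% base$cluster_prob,
      cluster_size_range = s$cluster_size_range %||% base$cluster_size_range,
      difficult_prob = s$difficult_prob %||% base$difficult_prob,
      seed = s$seed %||% base$seed
    )
  }
  if (!is.null(raw$arch)) cfg$arch <- raw$arch
  cfg
}
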