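small_cfg <- function(count_range = c(2, 4), ...) {
  scene_config(width = 96, height = 96, count_range = count_range,
               size_range = c(10, 24), difficult_prob = 0, ...)
}

small_anchors <- anchor_config(scales = c(8, 16, 24), ratios = c(1, 0.5, 2),
                               stride = 4)

quick_train <- function(scenes, epochs = 2, seed = 5, ...) {
  train_detector(scenes, train_config(epochs = epochs, seed = seed,
                                      pre_nms = 800, post_nms = 200),
                 anchors = small_anchors, ...)
}

# a hand-built detector with reflection-symmetric constant weights and zero
# regression heads: backbone and heads then commute with horizontal flips
toy_symmetric_model <- function(classes = c("Cfb", "Rfb")) {
  set.seed(1)
  bb <- build_backbone("tiny")
  k <- small_anchors$k
  params <- grainsight:::init_detector_params(bb, k, length(classes), 3L)
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] * 0
    if (grepl("_W$", nm)) params[[nm]][] <- 0.01
  }
  params$rpn_reg_W[] <- 0
  params$ps_reg_W[] <- 0
  # foreground channels slightly hotter than background ones
  fg_rows <- seq(2, 2 * k, by = 2)
  params$rpn_cls_W[fg_rows, ] <- 0.02
  # distinct per-class constants so softmax is non-degenerate
  params$ps_cls_W[seq_len(9), ] <- 0.015
  bb$params <- params[names(bb$params)]
  structure(
    list(params = params, backbone = bb, classes = classes,
         anchors = small_anchors, suppression = suppression_config("gaussian"),
         pspm_k = 3L, train_config = train_config(pre_nms = 400,
                                                  post_nms = 100),
         history = tibble::tibble()),
    class = "grain_detector"
  )
}

test_that("backbones have the documented strides, channels and layer counts", {
  set.seed(2)
  tiny <- build_backbone("tiny")
  f <- backbone_forward(tiny, array(0.5, c(64, 64, 3)))$feat
  expect_equal(dim(f), c(16, 16, 32))
  mcs <- build_backbone("mcs")
  n_conv <- sum(purrr::map_chr(mcs$layers, "op") == "conv")
  n_pool <- sum(purrr::map_chr(mcs$layers, "op") == "pool")
  expect_equal(n_conv, 12L)
  expect_equal(n_pool, 4L)
  fm <- backbone_forward(mcs, array(0.5, c(480, 640, 3)))$feat
  expect_equal(dim(fm), c(30, 40, 256)) # 640/16 x 480/16
  # fusion changes values, not shapes
  set.seed(2)
  mcs_nofuse <- build_backbone("mcs", fusion = FALSE)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  f1 <- backbone_forward(mcs, x)$feat
  f2 <- backbone_forward(mcs_nofuse, x)$feat
  expect_equal(dim(f1), dim(f2))
  expect_gt(max(abs(f1 - f2)), 0)
  expect_error(build_backbone("vgg19"), "arg")
})

test_that("loss components have their closed forms", {
  probs <- diag(3)[c(1, 2, 3), ] # one-hot correct
  losses <- compute_losses(
    rpn = list(probs = matrix(c(0.5, 0.5), 2, 2), deltas = matrix(0, 2, 4)),
    head = list(probs = probs, deltas = matrix(1, 3, 4)),
    rpn_match = list(labels = factor(c("positive", "negative"),
                                     c("positive", "negative", "ignore")),
                     targets = matrix(0, 2, 4)),
    rois = list(labels = c(1L, 2L, 3L), targets = matrix(1, 3, 4))
  )
  expect_equal(losses$roi_cls, 0)
  expect_equal(losses$roi_loc, 0) # predicted deltas equal targets
  expect_equal(losses$rpn_cls, log(2), tolerance = 1e-12)
  # uniform 3-way prediction: per-RoI classification loss is ln 3
  uni <- compute_losses(
    rpn = list(probs = matrix(c(0.5, 0.5), 1, 2), deltas = matrix(0, 1, 4)),
    head = list(probs = matrix(1 / 3, 5, 3), deltas = matrix(0, 5, 4)),
    rpn_match = list(labels = factor("negative",
                                     c("positive", "negative", "ignore")),
                     targets = matrix(0, 1, 4)),
    rois = list(labels = rep(2L, 5), targets = matrix(0, 5, 4))
  )
  expect_equal(uni$roi_cls, log(3), tolerance = 1e-12)
  expect_equal(uni$total, uni$rpn_cls + uni$roi_cls + uni$rpn_loc + uni$roi_loc)
  expect_error(compute_losses(
    rpn = list(probs = matrix(0.5, 1, 2), deltas = matrix(0, 1, 4)),
    head = list(probs = matrix(1, 1, 2), deltas = matrix(0, 1, 4)),
    rpn_match = list(labels = factor("ignore",
                                     c("positive", "negative", "ignore")),
                     targets = matrix(0, 1, 4)),
    rois = list(labels = 1L, targets = matrix(0, 1, 4))
  ), "no positive or negative")
})

test_that("proposal selection respects budgets, bounds and the tie rule", {
  cfg <- anchor_config(scales = c(8, 16), ratios = 1, stride = 8)
  ag <- generate_anchors(cfg, 6, 6, 48, 48, "test")
  n <- nrow(ag$anchors)
  # equal objectness, zero deltas: selection must follow input order among
  # survivors of suppression
  props <- propose_rois(rep(0.5, n), matrix(0, n, 4), ag$anchors, 48, 48, 8,
                        suppression_config("hard", Nt = 0.99),
                        pre_nms = n, post_nms = 10)
  expect_equal(nrow(props), 10L)
  first <- clip_boxes(ag$anchors[1, ], 48, 48)
  expect_equal(as.numeric(props[1, c("xmin", "ymin", "xmax", "ymax")]),
               as.numeric(first[1, 1:4]))
  # deltas pushing boxes outside: all outputs clipped into the image
  set.seed(3)
  big <- matrix(rnorm(n * 4, sd = 1), n, 4)
  props2 <- propose_rois(runif(n), big, ag$anchors, 48, 48, 8,
                         suppression_config("gaussian"), 400, 600)
  expect_true(all(props2$xmin >= 0 & props2$ymin >= 0 &
                    props2$xmax <= 48 & props2$ymax <= 48))
  expect_lte(nrow(props2), 600L)
  expect_true(all(props2$fw >= 1 & props2$fh >= 1))
  expect_true(all(diff(props2$score) <= 1e-12))
})

test_that("training errors on unusable datasets", {
  scenes <- lapply(1:2, function(i) generate_scene(small_cfg(), 40 + i))
  bad <- lapply(scenes, function(r) {
    r$annotations$difficult <- TRUE
    r
  })
  expect_error(quick_train(bad, epochs = 1), "non-difficult")
  expect_error(train_detector(list(), train_config(epochs = 1)), "length")
})

test_that("two epochs on ten scenes reduce the total loss", {
  scenes <- lapply(1:10, function(i) generate_scene(small_cfg(), 50 + i))
  m <- quick_train(scenes, epochs = 2, seed = 7)
  h <- tidy(m)
  expect_equal(nrow(h), 2L)
  expect_lt(h$total[2], h$total[1])
  expect_true(all(c("rpn_cls", "rpn_loc", "roi_cls", "roi_loc")
                  %in% names(h)))
  g <- glance(m)
  expect_equal(g$n_classes, 2L)
  expect_gt(g$n_parameters, 1000L)
})

test_that("all trainable parameters precede the RoI stage", {
  m <- toy_symmetric_model()
  inv <- parameter_inventory(m)
  expect_setequal(unique(inv$stage), c("backbone", "rpn", "head"))
  # the inventory covers every parameter: voting/suppression add none
  expect_setequal(inv$parameter, names(m$params))
})

test_that("detection output contract holds and save/load is bit-exact", {
  scenes <- lapply(1:4, function(i) generate_scene(small_cfg(), 70 + i))
  m <- quick_train(scenes, epochs = 1, seed = 9)
  # score threshold 1.0 can never be met by a softmax probability
  expect_equal(nrow(detect(scenes[[1]], m, score_thresh = 1.0)), 0L)
  d <- detect(scenes[[1]], m, score_thresh = 0.05)
  if (nrow(d)) {
    expect_true(all(d$score >= 0.05))
    expect_true(all(d$xmin >= 0 & d$ymin >= 0 & d$xmax <= 96 & d$ymax <= 96))
    expect_true(all(d$label %in% m$classes))
  }
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(m, path)
  m2 <- load_detector(path)
  expect_identical(detect(scenes[[2]], m2), detect(scenes[[2]], m))
  expect_error(detect(array(0.5, c(2, 2, 3)), m), "stride")
})

test_that("detections are covariant with horizontal flips for a symmetric model", {
  m <- toy_symmetric_model()
  rec <- generate_scene(small_cfg(), 81)
  d1 <- detect(rec, m, score_thresh = 0.01)
  d2 <- detect(augment_record(rec, "hflip"), m, score_thresh = 0.01)
  expect_gt(nrow(d1), 0L)
  expect_equal(nrow(d1), nrow(d2))
  # map the flipped detections back and compare as score-sorted sets
  back <- tibble::tibble(
    label = d2$label, score = d2$score,
    xmin = rec$width - d2$xmax, ymin = d2$ymin,
    xmax = rec$width - d2$xmin, ymax = d2$ymax
  )
  key <- function(d) {
    d <- d[order(-d$score, d$xmin, d$ymin), ]
    unname(cbind(d$score, d$xmin, d$ymin, d$xmax, d$ymax))
  }
  # compare the clearly score-separated head of the ranking exactly; deeper
  # ranks contain float-level score ties whose suppression order is not
  # mirror-stable
  expect_equal(key(back)[1:12, ], key(d1)[1:12, ], tolerance = 1e-6)
})

test_that("the detector can overfit a single scene and recover every object", {
  rec <- generate_scene(small_cfg(count_range = c(2, 3)), 90)
  # 100 epochs on one image = 200 optimizer steps
  m <- train_detector(
    list(rec),
    train_config(epochs = 100, seed = 11, pre_nms = 600, post_nms = 150,
                 augment = FALSE),
    anchors = small_anchors
  )
  d <- detect(rec, m, score_thresh = 0.2)
  gts <- flatten_annotations(rec)
  res <- match_detections(d, gts, 0.5)
  expect_equal(res$n_fn, 0L) # every ground truth matched at IoU >= 0.5
})
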