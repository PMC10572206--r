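# Synthetic grain-surface scenes with dense, small, optionally clustered
# "insects" and exact ground-truth boxes. The point is to emulate the
# *statistics* of stored-grain pest imagery (counts per image, 8-48 px body
# sizes, label aspect ratios, aggregation at single kernels, two visually
# similar classes) -- not to be photorealistic. Insects are parametric
# ellipse composites (elytra body + pronotum); the two classes differ in a
# deterministic hue shift and in pronotum corner sharpness (rounded vs
# pointed anterior angles, the field's classical distinguishing character),
# so they are separable in principle by a small convolutional model.

#' Scene generator configuration
#'
#' @param width,height Image dimensions in pixels.
#' @param classes Named numeric vector of class mixture weights (must sum
#'   to 1). Names are the class labels.
#' @param count_range Integer range (min, max) of insects per image.
#' @param size_range Range (min, max) of the longer side of an insect's
#'   bounding box, pixels.
#' @param aspect_range Allowed (lo, hi) range of box aspect ratio
#'   (width/height).
#' @param cluster_prob Probability that a placement starts an aggregation
#'   cluster instead of a lone insect.
#' @param cluster_size_range Integer range of insects per cluster.
#' @param grain_density Expected fraction of the background covered by grain
#'   kernels.
#' @param grain_size Range of kernel long-axis lengths, pixels.
#' @param color_jitter Per-kernel RGB jitter amplitude.
#' @param illum_gradient Amplitude of the linear illumination ramp (0 = flat).
#' @param noise_sd Per-pixel Gaussian noise standard deviation.
#' @param difficult_prob Probability that an insect is flagged difficult.
#' @param seed Default seed used when [generate_scene()] is called without one.
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(width = 640, height = 480,
                         classes = c(Rfb = 0.5, Cfb = 0.5),
                         count_range = c(1, 7),
                         size_range = c(8, 48),
                         aspect_range = c(0.3, 2.2),
                         cluster_prob = 0.25,
                         cluster_size_range = c(3, 5),
                         grain_density = 0.6,
                         grain_size = c(12, 24),
                         color_jitter = 0.05,
                         illum_gradient = 0.15,
                         noise_sd = 0.012,
                         difficult_prob = 0.02,
                         seed = 1L) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    classes = classes, count_range = as.integer(count_range),
    size_range = size_range, aspect_range = aspect_range,
    cluster_prob = cluster_prob, cluster_size_range = as.integer(cluster_size_range),
    grain_density = grain_density, grain_size = grain_size,
    color_jitter = color_jitter, illum_gradient = illum_gradient,
    noise_sd = noise_sd, difficult_prob = difficult_prob, seed = as.integer(seed)
  )
  stopifnot(
    cfg$width >= 16, cfg$height >= 16,
    length(cfg$classes) >= 1, !is.null(names(cfg$classes)),
    abs(sum(cfg$classes) - 1) < 1e-8,
    cfg$count_range[1] >= 0, cfg$count_range[2] >= cfg$count_range[1],
    cfg$size_range[1] > 0, cfg$size_range[2] >= cfg$size_range[1],
    cfg$size_range[2] <= min(cfg$width, cfg$height),
    cfg$aspect_range[1] <= cfg$aspect_range[2],
    cfg$cluster_prob >= 0, cfg$cluster_prob <= 1,
    cfg$cluster_size_range[1] >= 2
  )
  structure(cfg, class = "scene_config")
}

#' Lab-like default scene configuration (sparse: 1-7 insects per image)
#' @param ... Overrides passed to [scene_config()].
#' @export
lab_scene_config <- function(...) {
  scene_config(count_range = c(1, 7), ...)
}

#' Field-like default scene configuration (dense: 20-50 insects per tile)
#' @param ... Overrides passed to [scene_config()].
#' @export
field_scene_config <- function(...) {
  scene_config(count_range = c(20, 50), cluster_prob = 0.4, ...)
}

# ellipse/superellipse mask over pixel-center grids; p = 2 is an ellipse,
# larger p squares off the corners ("sharply pointed anterior angles")
superellipse_mask <- function(xg, yg, cx, cy, a, b, theta, p = 2) {
  ct <- cos(theta); st <- sin(theta)
  u <- (xg - cx) * ct + (yg - cy) * st
  v <- -(xg - cx) * st + (yg - cy) * ct
  abs(u / a)^p + abs(v / b)^p <= 1
}

paint_mask <- function(pixels, rows, cols, mask, color) {
  for (ch in 1:3) {
    plane <- pixels[rows, cols, ch]
    plane[mask] <- color[[ch]][mask]
    pixels[rows, cols, ch] <- plane
  }
  pixels
}

render_background <- function(cfg) {
  W <- cfg$width; H <- cfg$height
  base <- c(0.76, 0.66, 0.45)
  px <- array(0, c(H, W, 3))
  # linear illumination ramp in a random direction
  phi <- runif(1, 0, 2 * pi)
  xg <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  yg <- matrix(seq_len(H) - 0.5, H, W)
  t <- (xg * cos(phi) + yg * sin(phi))
  t <- (t - min(t)) / max(1e-9, diff(range(t)))
  shade <- 1 + cfg$illum_gradient * (t - 0.5)
  for (ch in 1:3) px[, , ch] <- base[ch] * 0.92 * shade
  # overlapping grain kernels
  mean_area <- pi * mean(cfg$grain_size / 2) * mean(cfg$grain_size / 2 * 0.65)
  n_grain <- max(1L, round(cfg$grain_density * W * H / mean_area))
  for (i in seq_len(n_grain)) {
    L <- runif(1, cfg$grain_size[1], cfg$grain_size[2])
    a <- L / 2
    b <- a * runif(1, 0.5, 0.8)
    cx <- runif(1, 0, W); cy <- runif(1, 0, H)
    theta <- runif(1, 0, pi)
    jit <- runif(3, -cfg$color_jitter, cfg$color_jitter)
    gshade <- runif(1, 0.85, 1.12)
    rows <- max(1, floor(cy - a)):min(H, ceiling(cy + a))
    cols <- max(1, floor(cx - a)):min(W, ceiling(cx + a))
    if (!length(rows) || !length(cols)) next
    lx <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
    ly <- matrix(rows - 0.5, length(rows), length(cols))
    m <- superellipse_mask(lx, ly, cx, cy, a, b, theta)
    if (!any(m)) next
    # simple top-lit shading inside the kernel
    ct <- cos(theta); st <- sin(theta)
    v <- (-(lx - cx) * st + (ly - cy) * ct) / b
    kern_shade <- gshade * (1 - 0.18 * pmin(1, pmax(-1, v)))
    col <- lapply(1:3, function(ch) {
      pmin(pmax((base[ch] + jit[ch]) * kern_shade * shade[rows, cols], 0), 1)
    })
    px <- paint_mask(px, rows, cols, m, col)
  }
  if (cfg$noise_sd > 0) {
    px <- px + array(rnorm(length(px), 0, cfg$noise_sd), dim(px))
  }
  pmin(pmax(px, 0), 1)
}

class_appearance <- function(label, classes) {
  idx <- match(label, names(classes))
  if ((idx %% 2L) == 1L) {
    list(color = c(0.37, 0.16, 0.08), pronotum_p = 2, width_frac = 0.45)
  } else {
    list(color = c(0.14, 0.13, 0.17), pronotum_p = 4, width_frac = 0.42)
  }
}

# Render one insect near (cx, cy); returns its pixel mask window and the
# tight bounding box of the rendered mask (0-based half-open), or NULL when
# the draw violates the size/aspect/bounds constraints.
draw_insect <- function(cfg, cx, cy, label) {
  L <- runif(1, min(cfg$size_range[1] * 1.1, cfg$size_range[2]),
             cfg$size_range[2])
  theta <- runif(1, 0, pi)
  ap <- class_appearance(label, cfg$classes)
  u <- c(cos(theta), sin(theta))
  # elytra/abdomen ellipse occupying the rear ~70% of the body
  c1 <- c(cx, cy) - 0.14 * L * u
  a1 <- 0.36 * L; b1 <- 0.5 * ap$width_frac * L * 0.93
  # pronotum at the front; class-specific corner sharpness
  c2 <- c(cx, cy) + 0.32 * L * u
  a2 <- 0.18 * L; b2 <- 0.5 * ap$width_frac * L * 0.84
  r0 <- floor(min(c1[2] - a1, c2[2] - a2)); r1 <- ceiling(max(c1[2] + a1, c2[2] + a2))
  k0 <- floor(min(c1[1] - a1, c2[1] - a2)); k1 <- ceiling(max(c1[1] + a1, c2[1] + a2))
  rows <- (r0 + 1):r1
  cols <- (k0 + 1):k1
  if (rows[1] < 1 || cols[1] < 1) return(NULL)
  lx <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
  ly <- matrix(rows - 0.5, length(rows), length(cols))
  m <- superellipse_mask(lx, ly, c1[1], c1[2], a1, b1, theta) |
    superellipse_mask(lx, ly, c2[1], c2[2], a2, b2, theta, p = ap$pronotum_p)
  if (!any(m)) return(NULL)
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  box <- c(
    xmin = cols[cc[1]] - 1, ymin = rows[rr[1]] - 1,
    xmax = cols[cc[2]], ymax = rows[rr[2]]
  )
  side <- max(box[3] - box[1], box[4] - box[2])
  aspect <- (box[3] - box[1]) / (box[4] - box[2])
  if (side < cfg$size_range[1] || side > cfg$size_range[2]) return(NULL)
  if (aspect < cfg$aspect_range[1] || aspect > cfg$aspect_range[2]) return(NULL)
  if (box[1] < 0 || box[2] < 0 || box[3] > cfg$width || box[4] > cfg$height) {
    return(NULL)
  }
  shade <- runif(1, 0.85, 1.15)
  list(rows = rows, cols = cols, mask = m, box = box,
       color = pmin(1, ap$color * shade), size = side)
}

sample_class <- function(classes) {
  names(classes)[sample.int(length(classes), 1L, prob = classes)]
}

#' Generate one synthetic grain scene
#'
#' Renders a textured grain background plus `count_range`-many insects (lone
#' or clustered), and returns the record with exact tight bounding boxes of
#' the rendered insects. Identical `(config, seed)` pairs give bit-identical
#' pixels and annotations.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param id Image id; defaults to `scene_<seed>`.
#' @return A `grain_record`.
#' @export
generate_scene <- function(config, seed = config$seed,
                           id = sprintf("scene_%d", seed)) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(as.integer(seed), {
    px <- render_background(config)
    n_target <- if (config$count_range[2] == config$count_range[1]) {
      config$count_range[1]
    } else {
      sample(config$count_range[1]:config$count_range[2], 1L)
    }
    ann <- empty_annotations()
    placed <- 0L
    margin <- min(config$size_range[2] / 2 + 2,
                  config$width / 2, config$height / 2)
    while (placed < n_target) {
      remaining <- n_target - placed
      in_cluster <- runif(1) < config$cluster_prob &&
        remaining >= config$cluster_size_range[1]
      group_n <- if (in_cluster) {
        min(remaining,
            sample(config$cluster_size_range[1]:config$cluster_size_range[2], 1L))
      } else 1L
      gx <- runif(1, margin, config$width - margin)
      gy <- runif(1, margin, config$height - margin)
      anchor_size <- NULL
      for (j in seq_len(group_n)) {
        label <- sample_class(config$classes)
        ins <- NULL
        for (try in 1:80) {
          if (j == 1L) {
            cx <- gx; cy <- gy
          } else {
            # clustered individuals pile up within ~half a body length
            rad <- 0.45 * anchor_size
            ang <- runif(1, 0, 2 * pi)
            rr <- sqrt(runif(1)) * rad
            cx <- gx + rr * cos(ang); cy <- gy + rr * sin(ang)
          }
          ins <- draw_insect(config, cx, cy, label)
          if (!is.null(ins)) break
          if (j == 1L) {
            gx <- runif(1, margin, config$width - margin)
            gy <- runif(1, margin, config$height - margin)
          }
        }
        if (is.null(ins)) {
          abort(paste0(
            "infeasible placement: could not fit an insect with size_range [",
            config$size_range[1], ", ", config$size_range[2],
            "] and aspect_range inside a ", config$width, "x", config$height,
            " image after 80 attempts"
          ))
        }
        if (j == 1L) anchor_size <- ins$size
        px <- paint_mask(px, ins$rows, ins$cols, ins$mask,
                         lapply(ins$color, function(v) {
                           matrix(v, length(ins$rows), length(ins$cols))
                         }))
        ann <- dplyr::bind_rows(ann, tibble(
          label = label,
          xmin = ins$box[[1]], ymin = ins$box[[2]],
          xmax = ins$box[[3]], ymax = ins$box[[4]],
          difficult = runif(1) < config$difficult_prob
        ))
        placed <- placed + 1L
      }
    }
    image_record(id, px, ann)
  })
}

#' Derive a per-image seed from a master seed
#'
#' The fixed derivation `(master + index * 9973) mod (2^31 - 1)` keeps every
#' seed a valid 32-bit integer and makes datasets of any size reproducible
#' from one master seed.
#'
#' @param master Master seed (integer).
#' @param index 1-based image index.
#' @return Integer seed.
#' @export
per_image_seed <- function(master, index) {
  as.integer((as.numeric(master) + as.numeric(index) * 9973) %% 2147483647)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_images` PNG + VOC XML pairs into `out_dir` via the package's
#' annotation writer, plus a tab-separated `manifest.tsv` listing them.
#'
#' @param n_images Number of images (>= 1).
#' @param config A [scene_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-image seeds come from [per_image_seed()].
#' @return The manifest tibble (image_id, image, xml, n_annotations), with the
#'   manifest path in attribute `"path"`.
#' @export
generate_dataset <- function(n_images, config, out_dir, seed = config$seed) {
  stopifnot(n_images >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  rows <- purrr::map_dfr(seq_len(n_images), function(i) {
    rec <- generate_scene(config, per_image_seed(seed, i),
                          id = sprintf("scene_%05d", i))
    img <- paste0(rec$id, ".png")
    xml <- paste0(rec$id, ".xml")
    write_image(rec$pixels, file.path(out_dir, img))
    write_voc_xml(rec, file.path(out_dir, xml), image_filename = img)
    tibble(image_id = rec$id, image = img, xml = xml,
           n_annotations = nrow(rec$annotations))
  })
  man_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(rows, man_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  attr(rows, "path") <- man_path
  rows
}

#' Generate a list of in-memory synthetic scenes
#'
#' Convenience wrapper around [generate_scene()] using the same per-image
#' seed derivation as [generate_dataset()], without touching disk.
#'
#' @inheritParams generate_dataset
#' @return List of `grain_record`s.
#' @export
generate_scenes <- function(n_images, config, seed = config$seed) {
  purrr::map(seq_len(n_images), function(i) {
    generate_scene(config, per_image_seed(seed, i),
                   id = sprintf("scene_%05d", i))
  })
}
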