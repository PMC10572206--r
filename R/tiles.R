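# Tiling of large frames into fixed-size training tiles, and the four
# label-preserving augmentations (quarter-turn rotations, horizontal and
# vertical flips). Boxes follow the pixels exactly: under the half-open
# convention a flip maps [xmin, xmax) to [W - xmax, W - xmin).

tile_origins <- function(full, tile) {
  # grid from the top-left; the final tile is shifted inward so it never
  # exceeds the image (overlap with its neighbour is allowed)
  o <- seq(0L, full - tile, by = tile)
  if (utils::tail(o, 1L) + tile < full) o <- c(o, full - tile)
  o
}

#' Crop a record into fixed-size tiles
#'
#' Tiles are laid on a grid from the top-left corner; the final row/column is
#' shifted inward so tiles never exceed the image. Annotations are clipped to
#' each tile, and a clipped box is kept only if it retains at least
#' `min_box_retention` of its original area (labels and difficult flags are
#' preserved).
#'
#' @param record A `grain_record`.
#' @param tile_w,tile_h Tile dimensions in pixels (must not exceed the image).
#' @param min_box_retention Minimum clipped/original area ratio for an
#'   annotation to be kept in a tile.
#' @return A list of `grain_record` tiles with ids `<id>_tile<i>`.
#' @export
crop_to_tiles <- function(record, tile_w = 640, tile_h = 480,
                          min_box_retention = 0.5) {
  stopifnot(inherits(record, "grain_record"))
  if (tile_w > record$width || tile_h > record$height) {
    abort("tile dimensions exceed image dimensions")
  }
  xs <- tile_origins(record$width, tile_w)
  ys <- tile_origins(record$height, tile_h)
  ann <- record$annotations
  orig_area <- if (nrow(ann)) box_area(ann) else numeric(0)
  tiles <- list()
  i <- 0L
  for (y0 in ys) {
    for (x0 in xs) {
      i <- i + 1L
      px <- record$pixels[(y0 + 1):(y0 + tile_h), (x0 + 1):(x0 + tile_w), ,
                          drop = FALSE]
      tile_ann <- empty_annotations()
      if (nrow(ann)) {
        cx1 <- pmax(ann$xmin, x0); cy1 <- pmax(ann$ymin, y0)
        cx2 <- pmin(ann$xmax, x0 + tile_w); cy2 <- pmin(ann$ymax, y0 + tile_h)
        clip_area <- pmax(0, cx2 - cx1) * pmax(0, cy2 - cy1)
        keep <- clip_area / orig_area >= min_box_retention
        if (any(keep)) {
          tile_ann <- tibble(
            label = ann$label[keep],
            xmin = cx1[keep] - x0, ymin = cy1[keep] - y0,
            xmax = cx2[keep] - x0, ymax = cy2[keep] - y0,
            difficult = ann$difficult[keep]
          )
        }
      }
      tiles[[i]] <- image_record(sprintf("%s_tile%d", record$id, i), px, tile_ann)
    }
  }
  tiles
}

augment_ops <- c("rot+90", "rot-90", "hflip", "vflip")

rotate_pixels_ccw <- function(px) {
  # (row r, col c) -> (row W + 1 - c, col r); output is W x H
  aperm(px, c(2L, 1L, 3L))[rev(seq_len(dim(px)[2])), , , drop = FALSE]
}

rotate_pixels_cw <- function(px) {
  # (row r, col c) -> (row c, col H + 1 - r); output is W x H
  aperm(px, c(2L, 1L, 3L))[, rev(seq_len(dim(px)[1])), , drop = FALSE]
}

#' Apply a label-preserving augmentation to a record
#'
#' Supported ops: `"rot+90"` (counter-clockwise quarter turn), `"rot-90"`
#' (clockwise), `"hflip"`, `"vflip"`. Pixels and all annotation boxes are
#' transformed consistently; labels and difficult flags are unchanged;
#' rotations swap width and height.
#'
#' @param record A `grain_record`.
#' @param op One of `"rot+90"`, `"rot-90"`, `"hflip"`, `"vflip"`.
#' @return The transformed `grain_record`.
#' @export
augment_record <- function(record, op) {
  stopifnot(inherits(record, "grain_record"))
  if (!op %in% augment_ops) {
    abort(sprintf("unknown augmentation op '%s' (use %s)",
                  op, paste(augment_ops, collapse = ", ")))
  }
  W <- record$width
  H <- record$height
  ann <- record$annotations
  px <- record$pixels
  new_ann <- ann
  if (op == "hflip") {
    px <- px[, rev(seq_len(W)), , drop = FALSE]
    new_ann$xmin <- W - ann$xmax
    new_ann$xmax <- W - ann$xmin
  } else if (op == "vflip") {
    px <- px[rev(seq_len(H)), , , drop = FALSE]
    new_ann$ymin <- H - ann$ymax
    new_ann$ymax <- H - ann$ymin
  } else if (op == "rot+90") {
    # CCW: (x, y) -> (y, W - x); new image is H wide, W tall
    px <- rotate_pixels_ccw(px)
    new_ann$xmin <- ann$ymin
    new_ann$xmax <- ann$ymax
    new_ann$ymin <- W - ann$xmax
    new_ann$ymax <- W - ann$xmin
  } else if (op == "rot-90") {
    # CW: (x, y) -> (H - y, x); new image is H wide, W tall
    px <- rotate_pixels_cw(px)
    new_ann$xmin <- H - ann$ymax
    new_ann$xmax <- H - ann$ymin
    new_ann$ymin <- ann$xmin
    new_ann$ymax <- ann$xmax
  }
  image_record(record$id, px, new_ann)
}
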