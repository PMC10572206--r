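# Fully convolutional feature extractors. "mcs" is the full-size backbone:
# four groups of three 3x3 convolutions (12 conv layers) each followed by
# 2x2 max pooling (total stride 16, 256 output channels), plus a feature
# fusion pathway that re-injects the shallow group-2 map (stride 4) into the
# final map to counter the loss of microstructural detail across poolings.
# "tiny" is a two-group, stride-4 variant of the same shape used for
# desk-scale training and unit tests.

mcs_channels <- c(32, 64, 128, 256)

build_layer_list <- function(group_channels, convs_per_group) {
  layers <- list()
  c_in <- 3L
  for (g in seq_along(group_channels)) {
    c_out <- group_channels[g]
    for (j in seq_len(convs_per_group)) {
      layers[[length(layers) + 1L]] <- list(
        op = "conv", name = sprintf("g%dc%d", g, j),
        c_in = c_in, c_out = c_out, kh = 3L, kw = 3L, pad = 1L
      )
      layers[[length(layers) + 1L]] <- list(op = "relu")
      c_in <- c_out
    }
    layers[[length(layers) + 1L]] <- list(op = "pool")
  }
  layers
}

#' Build a convolutional backbone
#'
#' @param arch `"mcs"` (4 groups / 12 conv layers / stride 16 / 256 channels,
#'   with a shallow-feature fusion pathway) or `"tiny"` (2 groups, stride 4,
#'   32 channels, for desk-scale training and tests).
#' @param fusion Enable the feature-fusion pathway (mcs only).
#' @return A `grain_backbone` with initialized parameters (uses the current
#'   RNG state; seed beforehand for reproducibility).
#' @export
build_backbone <- function(arch = c("tiny", "mcs"), fusion = TRUE) {
  arch <- match.arg(arch)
  if (identical(arch, "tiny")) {
    layers <- build_layer_list(c(16L, 32L), 1L)
    bb <- list(arch = arch, stride = 4L, out_channels = 32L,
               layers = layers, fusion = NULL)
  } else {
    layers <- build_layer_list(mcs_channels, 3L)
    fus <- NULL
    if (isTRUE(fusion)) {
      # tap the group-2 output (stride 4, 64 channels), subsample to the
      # final stride-16 grid, expand with a 1x1 conv, add to the final map
      tap_idx <- which(purrr::map_chr(layers, "op") == "pool")[2]
      fus <- list(tap = tap_idx, c_in = mcs_channels[2],
                  c_out = mcs_channels[4], factor = 4L)
    }
    bb <- list(arch = arch, stride = 16L, out_channels = 256L,
               layers = layers, fusion = fus)
  }
  bb$params <- init_backbone_params(bb)
  structure(bb, class = "grain_backbone")
}

init_backbone_params <- function(bb) {
  params <- list()
  for (ly in bb$layers) {
    if (ly$op == "conv") {
      p <- init_conv_params(ly$c_in, ly$c_out, ly$kh, ly$kw)
      params[[paste0(ly$name, "_W")]] <- p$W
      params[[paste0(ly$name, "_b")]] <- p$b
    }
  }
  if (!is.null(bb$fusion)) {
    p <- init_conv_params(bb$fusion$c_in, bb$fusion$c_out, 1L, 1L)
    params[["fuse_W"]] <- p$W
    params[["fuse_b"]] <- p$b
  }
  params
}

subsample_idx <- function(n_in, n_out, factor) {
  pmin(seq(1L, by = factor, length.out = n_out), n_in)
}

#' Run a backbone forward
#'
#' @param bb A `grain_backbone`.
#' @param x Image array `H x W x 3` in \[0, 1\].
#' @param params Parameter list (defaults to the backbone's own).
#' @return List with `feat` (array `ceil(H/stride) x ceil(W/stride) x
#'   out_channels`) and `cache` for [backbone_backward()].
#' @export
backbone_forward <- function(bb, x, params = bb$params) {
  caches <- vector("list", length(bb$layers))
  cur <- x
  tap_out <- NULL
  for (li in seq_along(bb$layers)) {
    ly <- bb$layers[[li]]
    if (ly$op == "conv") {
      cc <- conv_fwd(cur, params[[paste0(ly$name, "_W")]],
                     params[[paste0(ly$name, "_b")]], ly$kh, ly$kw, ly$pad)
      caches[[li]] <- list(x = cc$x)
      cur <- cc$out
    } else if (ly$op == "relu") {
      cc <- relu_fwd(cur)
      caches[[li]] <- list(mask = cc$mask)
      cur <- cc$out
    } else {
      cc <- pool_fwd(cur)
      caches[[li]] <- cc[c("argmax", "in_dim")]
      cur <- cc$out
    }
    if (!is.null(bb$fusion) && li == bb$fusion$tap) tap_out <- cur
  }
  fuse_cache <- NULL
  if (!is.null(bb$fusion)) {
    ri <- subsample_idx(dim(tap_out)[1], dim(cur)[1], bb$fusion$factor)
    ci <- subsample_idx(dim(tap_out)[2], dim(cur)[2], bb$fusion$factor)
    sub <- tap_out[ri, ci, , drop = FALSE]
    fc <- conv_fwd(sub, params[["fuse_W"]], params[["fuse_b"]], 1L, 1L, 0L)
    cur <- cur + fc$out
    fuse_cache <- list(sub = fc$x, ri = ri, ci = ci, tap_dim = dim(tap_out))
  }
  list(feat = cur, cache = list(layers = caches, fuse = fuse_cache))
}

#' Backpropagate through a backbone
#'
#' @param bb A `grain_backbone`.
#' @param cache Cache from [backbone_forward()].
#' @param dfeat Gradient w.r.t. the output feature map.
#' @param params Parameter list used in the forward pass.
#' @return List with `grads` (named like the parameters) and `dx`.
#' @export
backbone_backward <- function(bb, cache, dfeat, params = bb$params) {
  grads <- list()
  dtap <- NULL
  if (!is.null(bb$fusion)) {
    fc <- cache$fuse
    bw <- conv_bwd(fc$sub, params[["fuse_W"]], dfeat, 1L, 1L, 0L)
    grads[["fuse_W"]] <- bw$dW
    grads[["fuse_b"]] <- bw$db
    dtap <- array(0, fc$tap_dim)
    dtap[fc$ri, fc$ci, ] <- bw$dx
  }
  dcur <- dfeat
  for (li in rev(seq_along(bb$layers))) {
    if (!is.null(bb$fusion) && li == bb$fusion$tap && !is.null(dtap)) {
      dcur <- dcur + dtap
    }
    ly <- bb$layers[[li]]
    cc <- cache$layers[[li]]
    if (ly$op == "conv") {
      bw <- conv_bwd(cc$x, params[[paste0(ly$name, "_W")]], dcur,
                     ly$kh, ly$kw, ly$pad)
      grads[[paste0(ly$name, "_W")]] <- bw$dW
      grads[[paste0(ly$name, "_b")]] <- bw$db
      dcur <- bw$dx
    } else if (ly$op == "relu") {
      dcur <- relu_bwd(cc$mask, dcur)
    } else {
      dcur <- pool_bwd(cc, dcur)
    }
  }
  list(grads = grads, dx = dcur)
}
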