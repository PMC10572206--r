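# Layer-level plumbing over the compiled kernels: parameter init, forward /
# backward for conv / relu / maxpool stacks, softmax and robust-regression
# losses, and an Adam optimizer with L2 weight decay. Parameters live in a
# flat named list of matrices/vectors; layer geometry lives in the
# architecture spec, so a parameter set is trivially serializable.

init_conv_params <- function(c_in, c_out, kh = 3, kw = 3) {
  fan_in <- kh * kw * c_in
  list(
    W = matrix(rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)), nrow = c_out),
    b = numeric(c_out)
  )
}

conv_fwd <- function(x, W, b, kh, kw, pad, stride = 1L) {
  out <- conv2d_forward(x, W, b, kh, kw, pad, stride)$out
  list(out = out, x = x)
}

conv_bwd <- function(cache_x, W, dout, kh, kw, pad, stride = 1L) {
  conv2d_backward(cache_x, W, dout, kh, kw, pad, stride)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_bwd <- function(mask, dout) dout * mask

pool_fwd <- function(x) {
  r <- maxpool2_forward(x)
  list(out = r$out, argmax = r$argmax, in_dim = dim(x))
}

pool_bwd <- function(cache, dout) {
  maxpool2_backward(dout, cache$argmax,
                    cache$in_dim[1], cache$in_dim[2], cache$in_dim[3])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(probs, labels) {
  # labels: integer class per row
  p <- probs[cbind(seq_len(nrow(probs)), labels)]
  -mean(log(pmax(p, 1e-12)))
}

smooth_l1 <- function(d) {
  a <- abs(d)
  sum(ifelse(a < 1, 0.5 * d^2, a - 0.5))
}

smooth_l1_grad <- function(d) {
  ifelse(abs(d) < 1, d, sign(d))
}

adam_init <- function(params) {
  list(
    t = 0L,
    m = purrr::map(params, function(p) p * 0),
    v = purrr::map(params, function(p) p * 0)
  )
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
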