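# Minimal neural-network engine.
#
# Activations are (H, W, C, N) arrays; dense activations are N x F matrices.
# Convolutions are evaluated as im2col (C++) followed by one BLAS GEMM.
# Three passes are provided for sequential nets:
#   seq_forward   - primal evaluation with caches
#   seq_backward  - reverse mode: gradients w.r.t. parameters and/or input
#   seq_tangent   - forward mode (Jacobian-vector product) reusing the caches
# The pair (seq_tangent, seq_backward with tangent inputs) implements the
# forward-over-reverse computation required to differentiate the WGAN-GP
# gradient penalty with respect to the critic parameters: for piecewise-linear
# nets the input-gradient map is linear given the activation masks, so its
# parameter derivative reduces to a second reverse pass over the tangent
# activations (the measure-zero mask kinks carry no gradient).

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  sdv <- sqrt(2 / (k * k * in_ch))
  list(kind = "conv",
       W = array(rnorm(k * k * in_ch * out_ch, sd = sdv), c(k, k, in_ch, out_ch)),
       b = numeric(out_ch), stride = as.integer(stride), pad = as.integer(pad))
}

nn_dense <- function(in_f, out_f) {
  list(kind = "dense",
       W = matrix(rnorm(in_f * out_f, sd = sqrt(2 / in_f)), in_f, out_f),
       b = numeric(out_f))
}

nn_lrelu <- function(alpha = 0) list(kind = "lrelu", alpha = alpha)
nn_scale <- function(s) list(kind = "scale", s = s)
nn_sigmoid <- function() list(kind = "sigmoid")
nn_gap <- function() list(kind = "gap")
nn_flatten <- function() list(kind = "flatten")

nn_net <- function(layers, names = NULL) {
  net <- structure(list(layers = layers), class = "nn_net")
  if (!is.null(names)) names(net$layers) <- names
  net
}

# primitives ------------------------------------------------------------

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

conv_forward <- function(x, W, b = NULL, stride = 1L, pad = 1L) {
  conv_fw_rcpp(x, W, b, stride, pad)
}

# Returns dx and, when requested, dW/db. `x_w` overrides the activations used
# for the weight gradient (tangent activations in the double-backward pass).
conv_backward <- function(x, W, stride, pad, dout,
                          need_dx = TRUE, need_dw = TRUE, x_w = NULL,
                          bias_grad = TRUE) {
  conv_bw_rcpp(x, W, dout, stride, pad, need_dx, need_dw, bias_grad, x_w)
}

gap_forward <- function(x) t(colMeans(x, dims = 2L))

gap_backward <- function(d, dims) {
  hw <- dims[1] * dims[2]
  array(rep(t(d) / hw, each = hw), dims)
}

flatten_forward <- function(x) t(matrix(x, ncol = dim(x)[4]))

# sequential passes -----------------------------------------------------

seq_forward <- function(net, x, upto = length(net$layers)) {
  cache <- vector("list", upto)
  for (i in seq_len(upto)) {
    l <- net$layers[[i]]
    cache[[i]] <- switch(l$kind,
      conv = { cc <- list(input = x)
               x <- conv_forward(x, l$W, l$b, l$stride, l$pad); cc },
      dense = { cc <- list(input = x); x <- x %*% l$W + rep(l$b, each = nrow(x)); cc },
      lrelu = { m <- 1 + (l$alpha - 1) * (x <= 0); x <- x * m; list(mask = m) },
      scale = { x <- x * l$s; NULL },
      sigmoid = { x <- 1 / (1 + exp(-x)); list(out = x) },
      gap = { cc <- list(dims = dim(x)); x <- gap_forward(x); cc },
      flatten = { cc <- list(dims = dim(x)); x <- flatten_forward(x); cc },
      stop_fundus(paste("unknown layer kind", l$kind), "fundusgan_config_error"))
  }
  list(out = x, cache = cache)
}

# Reverse pass. `inputs` optionally replaces the cached layer inputs for the
# weight gradients (used by the tangent/double-backward pass, where bias
# gradients are structurally zero and `bias_grads = FALSE`).
seq_backward <- function(net, cache, dout, need_dx = TRUE,
                         need_param_grads = TRUE, inputs = NULL,
                         bias_grads = TRUE) {
  n <- length(cache)
  grads <- vector("list", n)
  d <- dout
  for (i in rev(seq_len(n))) {
    l <- net$layers[[i]]
    last_dx <- need_dx || i > 1L
    switch(l$kind,
      conv = {
        g <- conv_backward(cache[[i]]$input, l$W, l$stride, l$pad, d,
                           need_dx = last_dx, need_dw = need_param_grads,
                           x_w = if (!is.null(inputs)) inputs[[i]] else NULL,
                           bias_grad = bias_grads)
        if (need_param_grads) grads[[i]] <- list(dW = g$dW, db = g$db)
        if (last_dx) d <- g$dx
      },
      dense = {
        if (need_param_grads) {
          xs <- if (!is.null(inputs)) inputs[[i]] else cache[[i]]$input
          grads[[i]] <- list(dW = crossprod(xs, d),
                             db = if (bias_grads) colSums(d) else numeric(ncol(d)))
        }
        if (last_dx) d <- tcrossprod(d, l$W)
      },
      lrelu = d <- d * cache[[i]]$mask,
      scale = d <- d * l$s,
      sigmoid = d <- d * cache[[i]]$out * (1 - cache[[i]]$out),
      gap = d <- gap_backward(d, cache[[i]]$dims),
      flatten = d <- array(t(d), cache[[i]]$dims))
  }
  list(dx = if (need_dx) d else NULL, grads = grads)
}

# Forward-mode tangent propagation through the cached primal evaluation.
# Linear layers apply without bias; nonlinearities use the cached masks.
seq_tangent <- function(net, cache, tx) {
  n <- length(cache)
  tcache <- vector("list", n)
  t <- tx
  for (i in seq_len(n)) {
    l <- net$layers[[i]]
    switch(l$kind,
      conv = { tcache[[i]] <- t; t <- conv_forward(t, l$W, NULL, l$stride, l$pad) },
      dense = { tcache[[i]] <- t; t <- t %*% l$W },
      lrelu = t <- t * cache[[i]]$mask,
      scale = t <- t * l$s,
      sigmoid = t <- t * cache[[i]]$out * (1 - cache[[i]]$out),
      gap = t <- gap_forward(t),
      flatten = t <- flatten_forward(t))
  }
  list(tout = t, tcache = tcache)
}

# parameter utilities ---------------------------------------------------

has_params <- function(l) !is.null(l$W)

grads_scale <- function(grads, s) {
  lapply(grads, function(g) if (is.null(g)) NULL else list(dW = g$dW * s, db = g$db * s))
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  mapply(function(x, y) {
    if (is.null(x)) return(y)
    if (is.null(y)) return(x)
    list(dW = x$dW + y$dW, db = x$db + y$db)
  }, a, b, SIMPLIFY = FALSE)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!has_params(l)) return(NULL)
    list(mW = array(0, dim(l$W) %||% length(l$W)), vW = array(0, dim(l$W) %||% length(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)), t = 0L)
  })
}

adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (!has_params(layers[[i]]) || is.null(grads[[i]])) next
    s <- state[[i]]; g <- grads[[i]]
    s$t <- s$t + 1L
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    c1 <- 1 - beta1^s$t; c2 <- 1 - beta2^s$t
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
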