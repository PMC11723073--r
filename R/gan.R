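# Conditional WGAN-GP core: generator, critic, and the loss system.
#
# The generator G_theta(y, D(x), z) maps a condition stack (vessel mask +
# fine/coarse lesion maps) and a noise vector to an RGB image in [0,1]^3 via
# a conv encoder-decoder with skip connections; decoder upsampling applies
# the active resample_spec (so one kernel choice defines a method variant
# end to end), each step followed by a 3x3 convolution, with a final
# sigmoid. The critic D_gamma(x, y) scores an (image, mask) pair with
# strided convolutions and an unbounded linear output. The critic maximizes
# the Wasserstein objective under a two-sided gradient penalty at uniform
# interpolates; the generator minimizes the negative critic score plus
# weighted perceptual and severity terms.

#' Loss weights for the combined objective
#'
#' @param wp Weight of the perceptual loss (>= 0).
#' @param ws Weight of the severity loss (>= 0).
#' @param lambda_gp Gradient-penalty coefficient (>= 0); the conventional
#'   WGAN-GP value 10 is the default.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(wp = 1, ws = 1, lambda_gp = 10) {
  stopifnot(is.finite(wp), is.finite(ws), is.finite(lambda_gp),
            wp >= 0, ws >= 0, lambda_gp >= 0)
  structure(list(wp = wp, ws = ws, lambda_gp = lambda_gp),
            class = "loss_weights")
}

# generator -------------------------------------------------------------

#' Build an untrained conditional generator
#'
#' Encoder-decoder with four stride-2 encoder stages over the condition
#' stack (vessel mask + 2 lesion channels), noise injected at the bottleneck
#' by a linear projection, and four decoder stages of
#' resample-upsample + 3x3 conv with skip connections from the encoder.
#'
#' @param side Image side (divisible by 16).
#' @param z_dim Noise-vector length.
#' @param base Channel width of the first stage (doubling per stage).
#' @param resample [resample_spec()] used by every decoder upsampling layer.
#' @param seed Weight-initialization seed.
#' @return An object of class `gan_generator`.
#' @export
build_generator <- function(side = 64L, z_dim = 128L, base = 4L,
                            resample = resample_spec("nearest"), seed = 1L) {
  if (side %% 16 != 0)
    stop_fundus("generator side must be divisible by 16",
                "fundusgan_config_error")
  if (!inherits(resample, "resample_spec")) resample <- resample_spec(resample)
  w <- base * c(1L, 2L, 4L, 8L)
  bs <- side %/% 16L
  with_seed(seed, {
    layers <- list(
      e1 = nn_conv(3L, w[1], stride = 2L),
      e2 = nn_conv(w[1], w[2], stride = 2L),
      e3 = nn_conv(w[2], w[3], stride = 2L),
      e4 = nn_conv(w[3], w[4], stride = 2L),
      z = nn_dense(z_dim, bs * bs * w[4]),
      d1 = nn_conv(w[4] + w[3], w[3]),
      d2 = nn_conv(w[3] + w[2], w[2]),
      d3 = nn_conv(w[2] + w[1], w[1]),
      # the full-resolution stage mixes channels with 1x1 convolutions, so
      # spatial structure at the output scale comes from the resampling
      # kernel itself (keeping the method-variant axis visible) and full-res
      # compute stays affordable on a single CPU
      d4 = nn_conv(w[1] + 3L, w[1], k = 1L, pad = 0L),
      head = nn_conv(w[1], 3L, k = 1L, pad = 0L))
    ups <- lapply(c(bs, 2L * bs, 4L * bs, 8L * bs), function(n)
      resample_weights(n, 2L * n, resample))
    structure(list(layers = layers, side = as.integer(side),
                   z_dim = as.integer(z_dim), base = as.integer(base),
                   widths = w, bottleneck = bs, resample = resample,
                   up = ups, seed = as.integer(seed)),
              class = "gan_generator")
  })
}

relu_fw <- function(x) {
  m <- (x > 0) * 1
  list(a = x * m, m = m)
}

generator_forward <- function(gen, cond, z) {
  L <- gen$layers
  d <- dim(cond)
  if (d[1] != gen$side || d[2] != gen$side || d[3] != 3L)
    stop_fundus("condition stack must be side x side x 3", "fundusgan_shape_error")
  if (ncol(z) != gen$z_dim || nrow(z) != d[4])
    stop_fundus("z must be an N x z_dim matrix", "fundusgan_shape_error")
  cc <- list(cond = cond, z = z)
  cf <- function(x, l) conv_forward(x, l$W, l$b, l$stride, l$pad)
  e1 <- relu_fw(cf(cond, L$e1)); cc$m1 <- e1$m
  e2 <- relu_fw(cf(e1$a, L$e2)); cc$m2 <- e2$m
  e3 <- relu_fw(cf(e2$a, L$e3)); cc$m3 <- e3$m
  e4 <- relu_fw(cf(e3$a, L$e4)); cc$m4 <- e4$m
  cc$a1 <- e1$a; cc$a2 <- e2$a; cc$a3 <- e3$a
  zb <- z %*% L$z$W + rep(L$z$b, each = nrow(z))
  bs <- gen$bottleneck
  h <- e4$a + array(t(zb), c(bs, bs, gen$widths[4], d[4]))
  cc$h <- h
  dec_in <- h
  skips <- list(cc$a3, cc$a2, cc$a1, cond)
  dnames <- c("d1", "d2", "d3", "d4")
  for (k in 1:4) {
    up <- upsample_apply(dec_in, gen$up[[k]], gen$up[[k]])
    din <- concat_channels(up, skips[[k]])
    r <- relu_fw(cf(din, L[[dnames[k]]]))
    cc[[paste0("din", k)]] <- din
    cc[[paste0("md", k)]] <- r$m
    dec_in <- r$a
  }
  cc$u4 <- dec_in
  pre <- cf(dec_in, L$head)
  out <- 1 / (1 + exp(-pre))
  cc$out <- out
  list(out = out, cache = cc)
}

# Forward pass without caches or masks, for inference-only evaluations
# (identical numerics to generator_forward).
generator_infer <- function(gen, cond, z) {
  L <- gen$layers
  cf <- function(x, l) conv_forward(x, l$W, l$b, l$stride, l$pad)
  e1 <- pmax(cf(cond, L$e1), 0)
  e2 <- pmax(cf(e1, L$e2), 0)
  e3 <- pmax(cf(e2, L$e3), 0)
  e4 <- pmax(cf(e3, L$e4), 0)
  zb <- z %*% L$z$W + rep(L$z$b, each = nrow(z))
  bs <- gen$bottleneck
  dec_in <- e4 + array(t(zb), c(bs, bs, gen$widths[4], dim(cond)[4]))
  skips <- list(e3, e2, e1, cond)
  dnames <- c("d1", "d2", "d3", "d4")
  for (k in 1:4) {
    up <- upsample_apply(dec_in, gen$up[[k]], gen$up[[k]])
    dec_in <- pmax(cf(concat_channels(up, skips[[k]]), L[[dnames[k]]]), 0)
  }
  1 / (1 + exp(-cf(dec_in, L$head)))
}

generator_backward <- function(gen, cache, dout) {
  L <- gen$layers
  w <- gen$widths
  grads <- list()
  d <- dout * cache$out * (1 - cache$out)
  g <- conv_backward(cache$u4, L$head$W, L$head$stride, L$head$pad, d)
  grads$head <- list(dW = g$dW, db = g$db)
  d <- g$dx
  skip_ch <- c(w[3], w[2], w[1], 3L)
  up_ch <- c(w[4], w[3], w[2], w[1])
  dskip <- vector("list", 4)
  for (k in 4:1) {
    nm <- paste0("d", k)
    d <- d * cache[[paste0("md", k)]]
    g <- conv_backward(cache[[paste0("din", k)]], L[[nm]]$W,
                       L[[nm]]$stride, L[[nm]]$pad, d)
    grads[[nm]] <- list(dW = g$dW, db = g$db)
    dup <- g$dx[, , seq_len(up_ch[k]), , drop = FALSE]
    dskip[[k]] <- g$dx[, , up_ch[k] + seq_len(skip_ch[k]), , drop = FALSE]
    d <- upsample_apply(dup, gen$up[[k]], gen$up[[k]], transpose = TRUE)
  }
  # bottleneck: d is dL/dh; route through the z projection and encoder
  dzmat <- t(matrix(d, ncol = dim(d)[4]))
  grads$z <- list(dW = crossprod(cache$z, dzmat), db = colSums(dzmat))
  d <- d * cache$m4
  g <- conv_backward(cache$a3, L$e4$W, 2L, 1L, d)
  grads$e4 <- list(dW = g$dW, db = g$db)
  d <- (g$dx + dskip[[1]]) * cache$m3
  g <- conv_backward(cache$a2, L$e3$W, 2L, 1L, d)
  grads$e3 <- list(dW = g$dW, db = g$db)
  d <- (g$dx + dskip[[2]]) * cache$m2
  g <- conv_backward(cache$a1, L$e2$W, 2L, 1L, d)
  grads$e2 <- list(dW = g$dW, db = g$db)
  d <- (g$dx + dskip[[3]]) * cache$m1
  g <- conv_backward(cache$cond, L$e1$W, 2L, 1L, d, need_dx = FALSE)
  grads$e1 <- list(dW = g$dW, db = g$db)
  grads[names(gen$layers)]
}

# Build the (side, side, 3, N) condition stack from masks and descriptors.
condition_stack <- function(y, lesions) {
  if (inherits(lesions, "lesion_descriptor")) lesions <- list(lesions)
  if (!is.list(y)) y <- list(y)
  stacks <- mapply(function(m, l) {
    m <- if (is.matrix(m)) m else m[, , 1]
    array(c(m, l$fine, l$coarse), c(dim(m), 3L))
  }, y, lesions, SIMPLIFY = FALSE)
  as_batch(stacks)
}

#' Synthesize fundus images from a trained (or fresh) generator
#'
#' Evaluates `G(y, D(x), z)`: given a vessel mask and a two-scale lesion
#' descriptor, produces an RGB image in `[0, 1]`. With `z = NULL` a noise
#' vector is drawn from a seeded standard normal.
#'
#' @param gen A `gan_generator`.
#' @param y A binary vessel mask (`side x side`), or a list of masks.
#' @param lesions A `lesion_descriptor`, or a list of them (one per mask).
#' @param z Optional noise: an `N x z_dim` matrix.
#' @param seed Seed used when `z` is drawn internally.
#' @return A single `side x side x 3` image, or an `(side, side, 3, N)`
#'   batch when several masks are supplied.
#' @export
generate <- function(gen, y, lesions, z = NULL, seed = 1L) {
  stopifnot(inherits(gen, "gan_generator"))
  cond <- condition_stack(y, lesions)
  n <- dim(cond)[4]
  if (is.null(z))
    z <- with_seed(seed, matrix(rnorm(n * gen$z_dim), n, gen$z_dim))
  if (!is.matrix(z) || nrow(z) != n || ncol(z) != gen$z_dim)
    stop_fundus("z must be an N x z_dim matrix", "fundusgan_shape_error")
  out <- generator_forward(gen, cond, z)$out
  if (n == 1L) out[, , , 1] else out
}

# critic ----------------------------------------------------------------

#' Build an untrained Wasserstein critic
#'
#' Four stride-2 conv stages (leaky ReLU 0.2) over the channel-concatenated
#' (image, vessel mask) pair, flattened into a linear scalar score with no
#' output nonlinearity.
#'
#' @param side Input side length.
#' @param in_ch Input channels (3 image + 1 mask by default).
#' @param widths Channel widths of the four stages.
#' @param seed Weight-initialization seed.
#' @param init_gain Multiplier on the He-initialized weights. The default
#'   0.25 starts the critic as a conservative, nearly flat scorer whose
#'   input-gradient norm sits well below 1, so the gradient penalty
#'   calibrates it upward toward 1 as training proceeds (the canonical
#'   WGAN-GP behavior) instead of reining in an initially steep critic.
#' @return An object of class `gan_critic`.
#' @export
build_critic <- function(side = 64L, in_ch = 4L, widths = c(4L, 8L, 16L, 32L),
                         seed = 1L, init_gain = 0.25) {
  with_seed(seed, {
    layers <- list()
    ch <- in_ch
    s <- side
    for (wd in widths) {
      cv <- nn_conv(ch, wd, stride = 2L)
      cv$W <- cv$W * init_gain
      layers <- c(layers, list(cv, nn_lrelu(0.2)))
      ch <- wd
      s <- conv_out_dim(s, 3L, 2L, 1L)
    }
    dn <- nn_dense(s * s * ch, 1L)
    dn$W <- dn$W * init_gain
    layers <- c(layers, list(nn_flatten(), dn))
    structure(list(net = nn_net(layers), side = as.integer(side),
                   in_ch = as.integer(in_ch), seed = as.integer(seed)),
              class = "gan_critic")
  })
}

critic_input <- function(critic, x, y = NULL) {
  x <- as_batch(x)
  if (dim(x)[3] == critic$in_ch) return(x)
  if (is.null(y))
    stop_fundus("critic expects a vessel mask y", "fundusgan_shape_error")
  inp <- concat_channels(x, y)
  if (dim(inp)[3] != critic$in_ch)
    stop_fundus("image + mask channels do not match the critic input",
                "fundusgan_shape_error")
  inp
}

# Scores (length-N vector); with cache = TRUE also the forward caches.
# A plain function(x, y) may stand in for the critic in score-only contexts
# (loss stubs, user-plugged critics); it cannot provide input gradients.
critic_score <- function(critic, x, y = NULL, cache = FALSE) {
  if (is.function(critic)) {
    if (cache)
      stop_fundus("a function critic provides no input gradients",
                  "fundusgan_capability_error")
    return(critic(as_batch(x), y))
  }
  inp <- critic_input(critic, x, y)
  fw <- seq_forward(critic$net, inp)
  if (cache) list(score = drop(fw$out), cache = fw$cache, input = inp)
  else drop(fw$out)
}

# losses ----------------------------------------------------------------

#' Wasserstein loss of a critic on real and synthesized batches
#'
#' Batch mean of `D(x, y) - D(x_hat, y)`; the quantity the critic maximizes
#' and whose magnitude tracks how far apart the two distributions sit.
#'
#' @param critic A `gan_critic`.
#' @param x,x_hat Real and synthesized image batches (`(H, W, 3, N)` or
#'   single images).
#' @param y Conditioning vessel masks (same spatial size).
#' @return A scalar.
#' @export
wasserstein_loss <- function(critic, x, x_hat, y = NULL) {
  x <- as_batch(x); x_hat <- as_batch(x_hat)
  if (!identical(dim(x), dim(x_hat)))
    stop_fundus("x and x_hat must have identical shape", "fundusgan_shape_error")
  mean(critic_score(critic, x, y)) - mean(critic_score(critic, x_hat, y))
}

# Full gradient-penalty computation. Returns the penalty, the per-sample
# interpolate gradient norms, and (optionally, via the forward-over-reverse
# double-backward pass) its gradient w.r.t. the critic parameters.
gp_compute <- function(critic, x, x_hat, y = NULL, seed = 1L,
                       param_grads = FALSE) {
  x <- as_batch(x); x_hat <- as_batch(x_hat)
  if (!identical(dim(x), dim(x_hat)))
    stop_fundus("x and x_hat batch sizes/shapes must match",
                "fundusgan_shape_error")
  n <- dim(x)[4]
  u <- with_seed(seed, runif(n))
  xt <- x * rep(u, each = prod(dim(x)[1:3])) +
    x_hat * rep(1 - u, each = prod(dim(x)[1:3]))
  sc <- critic_score(critic, xt, y, cache = TRUE)
  img_ch <- dim(x)[3]
  bw <- seq_backward(critic$net, sc$cache, matrix(1, n, 1),
                     need_dx = TRUE, need_param_grads = FALSE)
  g_img <- bw$dx[, , seq_len(img_ch), , drop = FALSE]
  norms <- sqrt(colSums(matrix(g_img^2, ncol = n)))
  penalty <- mean((norms - 1)^2)
  out <- list(penalty = penalty, grad_norms = norms)
  if (param_grads) {
    scale <- ifelse(norms > 0, 2 * (norms - 1) / (n * norms), 0)
    v <- array(0, dim(sc$input))
    v[, , seq_len(img_ch), ] <- g_img *
      rep(scale, each = prod(dim(x)[1:3]))
    tg <- seq_tangent(critic$net, sc$cache, v)
    out$grads <- seq_backward(critic$net, sc$cache, matrix(1, n, 1),
                              need_dx = FALSE, inputs = tg$tcache,
                              bias_grads = FALSE)$grads
  }
  out
}

#' Gradient penalty at uniform interpolates
#'
#' Samples one `u ~ Uniform(0, 1)` per batch element (seeded), forms the
#' interpolates `u * x + (1 - u) * x_hat`, and returns the batch mean of
#' `(||grad of D at the interpolate||_2 - 1)^2` - the two-sided penalty that
#' holds the critic near 1-Lipschitz. The per-sample gradient norms are
#' attached as attribute `"grad_norms"`.
#'
#' @inheritParams wasserstein_loss
#' @param seed Seed for the interpolation weights.
#' @return A scalar penalty with attribute `grad_norms`.
#' @export
gradient_penalty <- function(critic, x, x_hat, y = NULL, seed = 1L) {
  gp <- gp_compute(critic, x, x_hat, y, seed)
  structure(gp$penalty, grad_norms = gp$grad_norms)
}

#' Severity loss: grade agreement between real and synthesized images
#'
#' Batch mean of `|DR(x) - DR(x_hat)|`, the absolute difference of the
#' grader's scalar severity estimates.
#'
#' @param grader A `dr_grader` or any function mapping an image batch to a
#'   numeric vector of grades.
#' @param x,x_hat Real and synthesized batches of equal shape.
#' @return A scalar.
#' @export
severity_loss <- function(grader, x, x_hat) {
  x <- as_batch(x); x_hat <- as_batch(x_hat)
  if (!identical(dim(x), dim(x_hat)))
    stop_fundus("x and x_hat must have identical shape", "fundusgan_shape_error")
  mean(abs(predict_grade(grader, x) - predict_grade(grader, x_hat)))
}

#' Perceptual loss in a feature network's activation space
#'
#' Mean squared difference of the layer-`layer` feature maps of `x` and
#' `x_hat` (squared L2 averaged over feature elements, then over the batch).
#' With `layer = "input"` the feature map is the image itself and the loss
#' equals pixel MSE.
#'
#' @param feature_net A `dr_grader` (its conv stages act as the feature
#'   extractor) or a function `f(batch, layer)` returning feature arrays.
#' @param x,x_hat Image batches of equal shape.
#' @param layer Feature layer name (see [grader_features()]).
#' @return A scalar.
#' @export
perceptual_loss <- function(feature_net, x, x_hat, layer = "stage2") {
  x <- as_batch(x); x_hat <- as_batch(x_hat)
  if (!identical(dim(x), dim(x_hat)))
    stop_fundus("x and x_hat must have identical shape", "fundusgan_shape_error")
  feats <- function(b) {
    if (is.function(feature_net)) feature_net(b, layer)
    else grader_features(feature_net, b, layer)
  }
  mean((feats(x) - feats(x_hat))^2)
}

#' Generator loss and its components
#'
#' Synthesizes `x_hat = G(y, D(x), z)` and evaluates the generator
#' objective: the negative mean critic score plus `wp` times the perceptual
#' loss and `ws` times the severity loss. All components are returned for
#' logging; the total equals `adversarial + wp * perceptual + ws * severity`
#' exactly.
#'
#' @param gen A `gan_generator`.
#' @param critic A `gan_critic`.
#' @param x Real image batch providing the style-transfer targets.
#' @param y Vessel-mask batch.
#' @param lesions Lesion descriptors of the real images (list or single).
#' @param z `N x z_dim` noise matrix.
#' @param weights A [loss_weights()].
#' @param grader Severity scorer (used when `ws > 0`).
#' @param feature_net Perceptual feature network (defaults to `grader`;
#'   used when `wp > 0`).
#' @param layer Perceptual feature layer.
#' @return A list with `total`, `adversarial`, `perceptual`, `severity` and
#'   the synthesized batch `x_hat`.
#' @export
generator_loss <- function(gen, critic, x, y, lesions, z,
                           weights = loss_weights(), grader = NULL,
                           feature_net = grader, layer = "stage2") {
  cond <- condition_stack(y, lesions)
  x <- as_batch(x)
  x_hat <- generator_forward(gen, cond, z)$out
  adv <- -mean(critic_score(critic, x_hat, y))
  lp <- if (weights$wp > 0 && !is.null(feature_net))
    perceptual_loss(feature_net, x, x_hat, layer) else 0
  ls <- if (weights$ws > 0 && !is.null(grader))
    severity_loss(grader, x, x_hat) else 0
  list(total = adv + weights$wp * lp + weights$ws * ls,
       adversarial = adv, perceptual = lp, severity = ls, x_hat = x_hat)
}

#' Critic loss: negative Wasserstein loss plus gradient penalty
#'
#' The minimization form of the critic's max objective:
#' `-(mean D(x, y) - mean D(x_hat, y)) + lambda_gp * penalty`.
#'
#' @inheritParams wasserstein_loss
#' @param weights A [loss_weights()] (only `lambda_gp` is used here).
#' @param seed Seed for the gradient-penalty interpolates.
#' @return A list with `total`, `wasserstein`, `penalty` and the mean
#'   interpolate gradient norm `grad_norm`.
#' @export
critic_loss <- function(critic, x, x_hat, y = NULL,
                        weights = loss_weights(), seed = 1L) {
  lw <- wasserstein_loss(critic, x, x_hat, y)
  gp <- gp_compute(critic, x, x_hat, y, seed)
  list(total = -lw + weights$lambda_gp * gp$penalty,
       wasserstein = lw, penalty = gp$penalty,
       grad_norm = mean(gp$grad_norms))
}

#' @export
print.gan_generator <- function(x, ...) {
  cat(sprintf("<gan_generator> side %d, z_dim %d, base %d, resample %s\n",
              x$side, x$z_dim, x$base, format(x$resample)))
  invisible(x)
}

#' @export
print.gan_critic <- function(x, ...) {
  cat(sprintf("<gan_critic> side %d, %d input channels\n", x$side, x$in_ch))
  invisible(x)
}
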