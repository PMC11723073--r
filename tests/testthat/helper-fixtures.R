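# Shared fixtures (memoised across test files) and independent oracles.

fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(fx[[key]])) fx[[key]] <- expr
  fx[[key]]
}

# The study-scale synthetic datasets and graders (500 samples, side 64,
# 30 epochs) shared by the grader-accuracy, lesion-localization and
# adversarial-training checks.
fx_dataset <- function(seed, n = 500L, side = 64L) {
  fx_memo(sprintf("ds_%d_%d_%d", seed, n, side),
          generate_dataset(synth_config(side = side, n_samples = n,
                                        seed = seed)))
}

fx_grader <- function(seed) {
  fx_memo(sprintf("grader_%d", seed),
          train_grader(fx_dataset(seed), epochs = 30L, seed = seed))
}

# Small, fast fixtures for unit tests.
fx_tiny_dataset <- function(seed = 5L, n = 60L, side = 32L) {
  fx_memo(sprintf("tinyds_%d_%d_%d", seed, n, side),
          generate_dataset(synth_config(side = side, n_samples = n,
                                        seed = seed)))
}

fx_tiny_grader <- function() {
  fx_memo("tiny_grader",
          train_grader(fx_tiny_dataset(), epochs = 2L, seed = 5L))
}

# ---------------------------------------------------------------------
# Independent resampling oracle: direct 2-D evaluation of the kernel
# definitions at every destination pixel (scalar loops, no shared code
# with the package implementation).

oracle_kernel_eval <- function(kernel, t) {
  at <- abs(t)
  switch(kernel,
    bilinear = if (at < 1) 1 - at else 0,
    bicubic = {
      a <- -0.5
      if (at <= 1) (a + 2) * at^3 - (a + 3) * at^2 + 1
      else if (at < 2) a * (at^3 - 5 * at^2 + 8 * at - 4)
      else 0
    },
    mitchell = {
      B <- 1 / 3; C <- 1 / 3
      if (at < 1)
        ((12 - 9 * B - 6 * C) * at^3 + (-18 + 12 * B + 6 * C) * at^2 +
           (6 - 2 * B)) / 6
      else if (at < 2)
        ((-B - 6 * C) * at^3 + (6 * B + 30 * C) * at^2 +
           (-12 * B - 48 * C) * at + (8 * B + 24 * C)) / 6
      else 0
    },
    lanczos5 = {
      if (at >= 5) 0
      else if (at == 0) 1
      else {
        s1 <- sin(pi * t) / (pi * t)
        s2 <- sin(pi * t / 5) / (pi * t / 5)
        s1 * s2
      }
    },
    stop("unknown oracle kernel"))
}

oracle_axis_weights <- function(n_in, dest, scale_io, kernel, antialias) {
  # dest is 0-based; returns a length-n_in weight vector
  s <- (dest + 0.5) * scale_io - 0.5
  w <- numeric(n_in)
  if (kernel == "nearest") {
    j <- min(max(floor(s + 0.5), 0), n_in - 1)
    w[j + 1] <- 1
    return(w)
  }
  base_support <- switch(kernel, bilinear = 1, bicubic = 2, mitchell = 2,
                         lanczos5 = 5)
  f <- if (antialias && scale_io > 1) scale_io else 1
  support <- base_support * f
  for (j in ceiling(s - support):floor(s + support)) {
    wj <- oracle_kernel_eval(kernel, (j - s) / f)
    if (wj == 0) next
    jj <- min(max(j, 0), n_in - 1)
    w[jj + 1] <- w[jj + 1] + wj
  }
  w / sum(w)
}

oracle_resize <- function(img, out_h, out_w, kernel, antialias = FALSE) {
  img <- if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
  d <- dim(img)
  out <- array(0, c(out_h, out_w, d[3]))
  for (i in seq_len(out_h)) {
    wy <- oracle_axis_weights(d[1], i - 1, d[1] / out_h, kernel, antialias)
    for (j in seq_len(out_w)) {
      wx <- oracle_axis_weights(d[2], j - 1, d[2] / out_w, kernel, antialias)
      for (ch in seq_len(d[3])) {
        acc <- 0
        for (m in seq_len(d[1]))
          for (nn in seq_len(d[2]))
            acc <- acc + wy[m] * wx[nn] * img[m, nn, ch]
        out[i, j, ch] <- acc
      }
    }
  }
  if (d[3] == 1L) out[, , 1] else out
}

# Central finite difference of f at x[idx].
fd_grad_at <- function(f, x, idx, eps = 1e-6) {
  xp <- x; xp[idx] <- xp[idx] + eps
  xm <- x; xm[idx] <- xm[idx] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# Linear critic D(x) = sum(w * x) + b as a gan_critic (flatten + dense).
linear_critic <- function(w, b = 0, side, channels = 3L) {
  net <- fundusgan:::nn_net(list(fundusgan:::nn_flatten(),
                                 fundusgan:::nn_dense(length(w), 1L)))
  net$layers[[2]]$W <- matrix(as.numeric(w), ncol = 1)
  net$layers[[2]]$b <- b
  structure(list(net = net, side = as.integer(side),
                 in_ch = as.integer(channels), seed = NA_integer_),
            class = "gan_critic")
}
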