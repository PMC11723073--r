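ns <- asNamespace("fundusgan")

rand_batch <- function(side, ch, n, seed = 1) {
  ns$with_seed(seed, array(runif(side * side * ch * n), c(side, side, ch, n)))
}

test_that("wasserstein loss reduces to the score difference", {
  x <- rand_batch(8, 3, 4, 1); xh <- rand_batch(8, 3, 4, 2)
  y <- rand_batch(8, 1, 4, 3)
  # constant critic: D = c for every input
  expect_equal(wasserstein_loss(function(x, y) rep(5, dim(x)[4]), x, xh, y), 0)
  # critic scoring real 1, fake 0 (stateful stub; real is scored first)
  stub <- local({
    k <- 0
    function(x, y) { k <<- k + 1; rep(2 - k, dim(x)[4]) }
  })
  expect_equal(wasserstein_loss(stub, x, xh, y), 1)
  # real critic, batch of 4: hand-computed mean of per-pair differences
  critic <- build_critic(side = 8, in_ch = 4, widths = c(2, 4, 4, 4), seed = 2)
  got <- wasserstein_loss(critic, x, xh, y)
  per_pair <- vapply(1:4, function(i)
    ns$critic_score(critic, x[, , , i, drop = FALSE],
                    y[, , , i, drop = FALSE]) -
      ns$critic_score(critic, xh[, , , i, drop = FALSE],
                      y[, , , i, drop = FALSE]),
    numeric(1))
  expect_equal(got, mean(per_pair), tolerance = 1e-6)
  expect_error(wasserstein_loss(critic, x, xh[, , , 1:2], y),
               class = "fundusgan_shape_error")
})

test_that("gradient penalty matches the analytic linear-critic cases", {
  side <- 6
  nf <- side * side * 3
  w <- rnorm(nf); w <- w / sqrt(sum(w^2))
  crit1 <- linear_critic(w, side = side)        # gradient norm exactly 1
  x <- rand_batch(side, 3, 3, 4); xh <- rand_batch(side, 3, 3, 5)
  expect_lt(abs(gradient_penalty(crit1, x, xh, seed = 1)), 1e-12)

  w2 <- numeric(nf); w2[1] <- 2                 # D = 2 * x[1,1,red]
  crit2 <- linear_critic(w2, side = side)
  gp <- gradient_penalty(crit2, x, xh, seed = 1)
  expect_equal(as.numeric(gp), 1)
  expect_equal(unname(attr(gp, "grad_norms")), rep(2, 3))
})

test_that("interpolate gradients match finite differences", {
  side <- 10
  critic <- build_critic(side = side, in_ch = 3, widths = c(3, 4, 6, 6),
                         seed = 4)
  x <- rand_batch(side, 3, 2, 6)
  fw <- ns$seq_forward(critic$net, x)
  g <- ns$seq_backward(critic$net, fw$cache, matrix(1, 2, 1),
                       need_param_grads = FALSE)$dx
  f <- function(xx) sum(ns$seq_forward(critic$net, xx)$out)
  for (i in sample(length(x), 10))
    expect_lt(abs(g[i] - fd_grad_at(f, x, i)), 1e-3)
})

test_that("the penalty's parameter gradient matches finite differences", {
  # forward-over-reverse double backprop, checked end to end
  side <- 8
  critic <- build_critic(side = side, in_ch = 3, widths = c(3, 4, 4, 4),
                         seed = 3)
  x <- rand_batch(side, 3, 2, 7); xh <- rand_batch(side, 3, 2, 8)
  gp <- ns$gp_compute(critic, x, xh, NULL, seed = 5, param_grads = TRUE)
  pen <- function(cr) ns$gp_compute(cr, x, xh, NULL, seed = 5)$penalty
  for (li in c(1L, 5L, 10L)) {
    if (is.null(critic$net$layers[[li]]$W)) next
    for (i in sample(length(critic$net$layers[[li]]$W), 4)) {
      fd <- fd_grad_at(function(w) {
        c2 <- critic; c2$net$layers[[li]]$W[i] <- w[i]; pen(c2)
      }, critic$net$layers[[li]]$W, i)
      expect_lt(abs(gp$grads[[li]]$dW[i] - fd), 1e-6)
    }
  }
  expect_error(gradient_penalty(function(x, y) rep(0, dim(x)[4]), x, xh),
               class = "fundusgan_capability_error")
})

test_that("severity loss is the mean absolute grade difference", {
  x <- rand_batch(8, 3, 3, 1); xh <- rand_batch(8, 3, 3, 2)
  expect_equal(severity_loss(function(b) rep(2, dim(b)[4]), x, x), 0)
  stub <- local({
    k <- 0
    function(b) { k <<- k + 1; if (k == 1) c(0, 2, 4) else c(1, 2, 0) }
  })
  expect_equal(severity_loss(stub, x, xh), 5 / 3)
  g <- fx_tiny_grader()
  expect_equal(severity_loss(g, x, x), 0)
})

test_that("perceptual loss with the identity layer equals pixel MSE", {
  g <- fx_tiny_grader()
  x <- rand_batch(32, 3, 2, 3); xh <- rand_batch(32, 3, 2, 4)
  expect_equal(perceptual_loss(g, x, xh, layer = "input"), mean((x - xh)^2))
  expect_equal(perceptual_loss(g, x, x), 0)
  # manual evaluation against grader_features
  lp <- perceptual_loss(g, x, xh, layer = "stage2")
  fx <- grader_features(g, x, "stage2"); fh <- grader_features(g, xh, "stage2")
  expect_equal(lp, mean((fx - fh)^2), tolerance = 1e-12)
  expect_error(perceptual_loss(g, x, xh, layer = "nope"),
               class = "fundusgan_config_error")
})

test_that("the generator objective decomposes exactly", {
  side <- 32
  gen <- build_generator(side = side, z_dim = 16, base = 4, seed = 1)
  critic <- build_critic(side = side, in_ch = 4, widths = c(3, 4, 6, 6),
                         seed = 2)
  g <- fx_tiny_grader()
  ds <- fx_tiny_dataset()[1:3]
  x <- ns$as_batch(lapply(ds, function(s) s$image))
  y <- lapply(ds, function(s) s$vessel_mask)
  lds <- lapply(ds, function(s) lesion_descriptor(s$lesion_mask_fine,
                                                  s$lesion_mask_coarse))
  z <- ns$with_seed(3, matrix(rnorm(3 * 16), 3, 16))

  l0 <- generator_loss(gen, critic, x, y, lds, z,
                       weights = loss_weights(wp = 0, ws = 0), grader = g)
  expect_equal(l0$total, l0$adversarial)
  expect_equal(l0$adversarial,
               -mean(ns$critic_score(critic, l0$x_hat, ns$as_batch(
                 lapply(y, function(m) array(m, c(side, side, 1)))))))

  w1 <- loss_weights(wp = 0.7, ws = 1.3)
  l1 <- generator_loss(gen, critic, x, y, lds, z, weights = w1, grader = g)
  expect_equal(l1$total,
               l1$adversarial + 0.7 * l1$perceptual + 1.3 * l1$severity)
  w2 <- loss_weights(wp = 1.4, ws = 1.3)
  l2 <- generator_loss(gen, critic, x, y, lds, z, weights = w2, grader = g)
  expect_equal(l2$perceptual, l1$perceptual)
  expect_equal(l2$total - l1$total, 0.7 * l1$perceptual, tolerance = 1e-12)
})

test_that("critic loss combines the Wasserstein term and the penalty", {
  side <- 8
  x <- rand_batch(side, 3, 3, 9); xh <- rand_batch(side, 3, 3, 10)
  w <- rnorm(side * side * 3); w <- w / sqrt(sum(w^2))
  crit <- linear_critic(w, side = side)
  cl <- critic_loss(crit, x, xh, weights = loss_weights(lambda_gp = 10),
                    seed = 2)
  expect_equal(cl$total, -cl$wasserstein)   # unit-slope critic: zero penalty
  expect_equal(cl$penalty, 0)
  cl2 <- critic_loss(crit, x, xh, weights = loss_weights(lambda_gp = 10),
                     seed = 2)
  expect_identical(cl, cl2)                 # seeded determinism
})

test_that("generation is seeded, conditioned and in range", {
  gen <- build_generator(side = 32, z_dim = 16, base = 4, seed = 6)
  s <- fx_tiny_dataset()[[2]]
  ld <- lesion_descriptor(s$lesion_mask_fine, s$lesion_mask_coarse)
  img1 <- generate(gen, s$vessel_mask, ld, seed = 4)
  img2 <- generate(gen, s$vessel_mask, ld, seed = 4)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(32L, 32L, 3L))
  expect_true(all(img1 >= 0 & img1 <= 1))
  # different z draws move the output
  imgs <- lapply(1:5, function(k) generate(gen, s$vessel_mask, ld, seed = 10 + k))
  expect_true(any(vapply(2:5, function(k) !identical(imgs[[1]], imgs[[k]]),
                         logical(1))))
  expect_error(generate(gen, s$vessel_mask, ld,
                        z = matrix(0, 2, 16)),
               class = "fundusgan_shape_error")
})
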