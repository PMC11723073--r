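test_that("FID matches its closed forms", {
  a <- gaussian_stats(c(0, 0), diag(2), 10)
  expect_lt(abs(fid(a, a)), 1e-8)
  b <- gaussian_stats(c(3, 4), diag(2), 10)
  expect_lt(abs(fid(a, b) - 25), 1e-8)
  # 1-D, equal means, variances 4 and 1: 4 + 1 - 2 * sqrt(4) = 1
  v4 <- gaussian_stats(0, matrix(4), 5)
  v1 <- gaussian_stats(0, matrix(1), 5)
  expect_lt(abs(fid(v4, v1) - 1), 1e-8)
})

test_that("FID is symmetric and non-negative on random Gaussian fits", {
  set.seed(3)
  for (d in c(2, 5, 8)) {
    A <- matrix(rnorm(d * d), d); B <- matrix(rnorm(d * d), d)
    sa <- gaussian_stats(rnorm(d), crossprod(A) / d, 20)
    sb <- gaussian_stats(rnorm(d), crossprod(B) / d, 20)
    f1 <- fid(sa, sb); f2 <- fid(sb, sa)
    expect_lt(abs(f1 - f2), 1e-8)
    expect_gt(f1, -1e-8)
  }
  bad <- gaussian_stats(c(0, 0), matrix(c(1, 0, 0, -1), 2), 5)
  good2 <- gaussian_stats(c(0, 0), diag(2), 5)
  expect_error(fid(bad, good2), class = "fundusgan_numeric_error")
  expect_error(fid(gaussian_stats(0, matrix(1), 5), good2),
               class = "fundusgan_shape_error")
})

test_that("feature statistics are fit with the n-1 denominator", {
  # two 1-pixel gray images with values 0 and 1, identity embedding
  imgs <- list(matrix(0, 1, 1), matrix(1, 1, 1))
  st <- embed_images(imgs, "identity")
  expect_equal(st$mu, 0.5)
  expect_equal(st$sigma[1, 1], 0.5)
  expect_error(embed_images(imgs[1], "identity"),
               class = "fundusgan_sample_error")

  # identical images: zero covariance, FID against itself 0
  same <- replicate(4, matrix(0.3, 2, 2), simplify = FALSE)
  st2 <- embed_images(same, "identity")
  expect_equal(max(abs(st2$sigma)), 0)
  expect_lt(abs(fid(st2, st2)), 1e-8)

  # order invariance
  set.seed(1)
  pool <- lapply(1:6, function(i) matrix(runif(9), 3, 3))
  s1 <- embed_images(pool, "identity")
  s2 <- embed_images(pool[c(4, 2, 6, 1, 5, 3)], "identity")
  expect_equal(s1$mu, s2$mu)
  expect_equal(s1$sigma, s2$sigma)
})

test_that("MSE matches a brute-force loop", {
  expect_equal(mse(matrix(c(0, 0), 1), matrix(c(1, 0), 1)), 0.5)
  set.seed(2)
  for (rep in 1:100) {
    x <- array(runif(48), c(4, 4, 3)); y <- array(runif(48), c(4, 4, 3))
    acc <- 0
    for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
    expect_lt(abs(mse(x, y) - acc / length(x)), 1e-12)
  }
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "fundusgan_shape_error")
})

test_that("SSIM identities hold in both modes", {
  set.seed(4)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(ssim(x, x), 1)
  expect_identical(ssim(x, x, mode = "global"), 1)
  y <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(ssim(x, y), ssim(y, x))
  expect_lte(ssim(x, y), 1)
  # constant images 0 vs 1 in global mode: (0 + C1) / (1 + C1), second
  # factor cancels because both variances vanish
  a <- matrix(0, 12, 12); b <- matrix(1, 12, 12)
  got <- ssim(a, b, constants = c(1e-4, 0.03^2), mode = "global")
  expect_lt(abs(got - 1e-4 / 1.0001), 1e-9)
  # for constant images every window sees the same statistics
  a2 <- matrix(0.2, 12, 12); b2 <- matrix(0.7, 12, 12)
  expect_equal(ssim(a2, b2), ssim(a2, b2, mode = "global"), tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8), window = c(11, 1.5)),
               class = "fundusgan_config_error")
})

test_that("evaluation reports collapse correctly on self-comparison", {
  ds <- fx_tiny_dataset()[1:8]
  imgs <- lapply(ds, function(s) s$image)
  g <- fx_tiny_grader()
  rep1 <- evaluate_synthesis(ds, generated = imgs, embedder = g)
  expect_equal(rep1$mse_mean, 0)
  expect_equal(rep1$ssim_mean, 1)
  expect_lt(abs(rep1$fid_mean), 1e-6)
  expect_equal(rep1$n_images, 8)
  expect_error(evaluate_synthesis(ds, generated = imgs[1:5], embedder = g),
               class = "fundusgan_pairing_error")
})
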