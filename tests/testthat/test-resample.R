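kernels <- c("nearest", "bilinear", "bicubic", "mitchell", "lanczos5")

test_that("spec parsing and validation", {
  sp <- resample_spec("bilinear+antialias")
  expect_equal(sp$kernel, "bilinear")
  expect_true(sp$antialias)
  expect_equal(format(resample_spec("mitchell")), "mitchell")
  expect_error(resample_spec("box"), class = "fundusgan_config_error")
  expect_error(resize(matrix(0, 4, 4), 0, 4), class = "fundusgan_config_error")
})

test_that("nearest-neighbor 2x upscale replicates blocks exactly", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  out <- resize(img, 4, 4, resample_spec("nearest"), clip = FALSE)
  expect_identical(out, matrix(c(1, 1, 3, 3, 1, 1, 3, 3,
                                 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))
})

test_that("every kernel preserves constant images (partition of unity)", {
  img <- matrix(0.37, 9, 7)
  for (k in kernels) for (aa in c(FALSE, TRUE)) {
    sp <- resample_spec(k, aa)
    expect_lt(max(abs(resize(img, 5, 3, sp) - 0.37)), 1e-9)
    expect_lt(max(abs(resize(img, 18, 14, sp) - 0.37)), 1e-9)
  }
})

test_that("renormalized weights sum to one for every destination pixel", {
  for (k in kernels) for (aa in c(FALSE, TRUE)) {
    sp <- resample_spec(k, aa)
    for (dims in list(c(16L, 7L), c(7L, 16L), c(9L, 9L))) {
      M <- fundusgan:::resample_weights(dims[1], dims[2], sp)
      expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    }
  }
})

test_that("identity-scale resizing reproduces the input for interpolating kernels", {
  set.seed(1)
  img <- matrix(runif(81), 9, 9)
  expect_identical(resize(img, 9, 9, resample_spec("nearest"), clip = FALSE),
                   img)
  # mitchell is excluded: with B = 1/3 it is a smoothing (non-interpolating)
  # reconstruction filter, so it does not fix the grid even at scale 1
  for (k in c("bilinear", "bicubic", "lanczos5"))
    expect_lt(max(abs(resize(img, 9, 9, resample_spec(k), clip = FALSE) - img)),
              1e-6)
})

test_that("separable implementation matches the direct-evaluation oracle", {
  set.seed(7)
  img <- matrix(runif(63), 9, 7)
  for (k in kernels) for (aa in c(FALSE, TRUE)) {
    for (scale in c(0.5, 1, 2)) {
      oh <- max(1L, as.integer(round(9 * scale)))
      ow <- max(1L, as.integer(round(7 * scale)))
      got <- resize(img, oh, ow, resample_spec(k, aa), clip = FALSE)
      want <- oracle_resize(img, oh, ow, k, aa)
      expect_lt(max(abs(got - want)), 1e-6,
                label = sprintf("kernel %s aa=%s scale=%s", k, aa, scale))
    }
  }
})

test_that("antialiased downsampling removes high-frequency energy", {
  checker <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)  # Nyquist rate
  lap_energy <- function(m) {
    n <- nrow(m)
    core <- m[2:(n - 1), 2:(n - 1)]
    mean(abs(4 * core - m[1:(n - 2), 2:(n - 1)] - m[3:n, 2:(n - 1)] -
               m[2:(n - 1), 1:(n - 2)] - m[2:(n - 1), 3:n]))
  }
  # a non-integer scale keeps the sampling phases varied; at an exact 2x
  # decimation every destination sits at half-integer phase and any
  # symmetric kernel averages the checkerboard to a constant
  plain <- preprocess(checker, 13, resample_spec("bicubic", FALSE))
  smooth <- preprocess(checker, 13, resample_spec("bicubic", TRUE))
  expect_lt(lap_energy(smooth), lap_energy(plain))
})

test_that("preprocess standardizes arbitrary shapes to side x side", {
  img <- array(runif(60 * 40 * 3), c(60, 40, 3))
  out <- preprocess(img, 32, resample_spec("mitchell"))
  expect_equal(dim(out), c(32L, 32L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(preprocess(img, 4), class = "fundusgan_config_error")
})

test_that("image files decode to [0,1] rasters and round-trip", {
  dir <- withr::local_tempdir()
  img <- array(sample(0:255, 24 * 16 * 3, replace = TRUE) / 255,
               c(24, 16, 3))
  p <- file.path(dir, "x.png")
  save_image(img, p)
  expect_equal(load_image(p), img)

  gray <- matrix(sample(0:255, 64, replace = TRUE) / 255, 8, 8)
  pg <- file.path(dir, "g.png")
  save_image(gray, pg)
  back <- load_image(pg)
  expect_equal(dim(back), c(8L, 8L, 1L))
  expect_equal(back[, , 1], gray)

  # a truncated file fails loudly, with no partial result
  raw <- readBin(p, "raw", file.info(p)$size)
  pt <- file.path(dir, "trunc.png")
  writeBin(raw[1:20], pt)
  expect_error(load_image(pt), class = "fundusgan_io_error")
  expect_error(load_image(file.path(dir, "missing.png")),
               class = "fundusgan_io_error")
})
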