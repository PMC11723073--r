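ns <- asNamespace("fundusgan")

# Grader whose output is the mean over pixel positions of the channel sums:
# pred = sum(x) / (H*W). Built by zeroing the trunk, threading one evidence
# channel through as sum_c x_c (bias shifts undo the input centering), and
# reading it out with the right head weight.
mean_grader <- function(side) {
  g <- build_grader(side = side, seed = 1)
  for (i in seq_along(g$trunk$layers))
    if (!is.null(g$trunk$layers[[i]]$W)) {
      g$trunk$layers[[i]]$W[] <- 0
      g$trunk$layers[[i]]$b[] <- 0
    }
  ev <- g$evid$layers
  ev[[1]]$W[] <- 0; ev[[1]]$b[] <- 0
  ev[[1]]$W[2, 2, , 1] <- 1          # center tap, summed over RGB
  ev[[1]]$b[1] <- 1.5                # + 3 * 0.5 undoes the centering
  ev[[3]]$W[] <- 0; ev[[3]]$b[] <- 0; ev[[3]]$W[1, 1, 1, 1] <- 1
  ev[[5]]$W[] <- 0; ev[[5]]$b[] <- 0; ev[[5]]$W[1, 1, 1, 1] <- 1
  g$evid$layers <- ev
  g$head$layers[[1]]$W[] <- 0
  g$head$layers[[1]]$b <- 0
  # area feature = sum(map) / area_scale; want pred = sum(x) / side^2
  g$head$layers[[1]]$W[g$widths[length(g$widths)] + 1, 1] <-
    g$area_scale / side^2
  g
}

test_that("saliency is the channel-summed absolute input gradient", {
  g <- build_grader(side = 12, seed = 6)
  set.seed(1)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  sal <- saliency_map(g, img)
  expect_true(all(sal >= 0))
  # finite-difference oracle on a sample of pixels
  fd_abs <- matrix(0, 12, 12)
  idx <- cbind(sample(12, 6, TRUE), sample(12, 6, TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    acc <- 0
    for (ch in 1:3) {
      k <- i + 12 * (j - 1) + 144 * (ch - 1)
      acc <- acc + abs(fd_grad_at(function(x) predict_grade(g, x), img, k))
    }
    fd_abs[i, j] <- acc
  }
  for (r in seq_len(nrow(idx)))
    expect_lt(abs(sal[idx[r, 1], idx[r, 2]] - fd_abs[idx[r, 1], idx[r, 2]]),
              1e-3)
})

test_that("a constant-output grader yields zero saliency and empty masks", {
  g <- build_grader(side = 16, seed = 2)
  for (nm in c("trunk", "evid", "head"))
    for (i in seq_along(g[[nm]]$layers))
      if (!is.null(g[[nm]]$layers[[i]]$W)) {
        g[[nm]]$layers[[i]]$W[] <- 0
        g[[nm]]$layers[[i]]$b[] <- 0
      }
  img <- array(runif(16 * 16 * 3, 0.1, 0.9), c(16, 16, 3))
  expect_equal(max(saliency_map(g, img)), 0)
  ld <- extract_lesions(g, img)
  expect_equal(sum(ld$fine), 0)
  expect_equal(sum(ld$coarse), 0)
})

test_that("the pixel-mean grader has uniform saliency 3/(H*W)", {
  side <- 16
  g <- mean_grader(side)
  set.seed(3)
  img <- array(runif(side * side * 3, 0.1, 0.9), c(side, side, 3))
  expect_equal(predict_grade(g, img), sum(img) / side^2, tolerance = 1e-10)
  sal <- saliency_map(g, img)
  expect_lt(max(abs(sal - 3 / side^2)), 1e-12)
})

test_that("Gaussian smoothing reproduces the discrete kernel on an impulse", {
  n <- 33
  x <- matrix(0, n, n); x[17, 17] <- 1
  for (sigma in c(1, 2.5)) {
    sm <- gaussian_blur(x, sigma)
    k <- ns$gaussian_kernel(sigma)
    r <- (length(k) - 1) / 2
    want <- outer(k, k)
    got <- sm[(17 - r):(17 + r), (17 - r):(17 + r)]
    expect_lt(max(abs(got - want)), 1e-9)
    expect_equal(sum(sm), 1, tolerance = 1e-9)  # kernel is normalized
  }
})

test_that("uniform saliency with tie-inclusive quantile masks everything", {
  side <- 16
  g <- mean_grader(side)
  img <- array(runif(side * side * 3, 0.2, 0.8), c(side, side, 3))
  ld <- extract_lesions(g, img, q = 0.02)
  expect_equal(sum(ld$fine), side^2)   # all pixels tie at the threshold
  expect_equal(sum(ld$coarse), side^2)
})

test_that("extraction parameters are validated and extraction is pure", {
  g <- fx_tiny_grader()
  img <- fx_tiny_dataset()[[1]]$image
  expect_error(extract_lesions(g, img, q = 0), class = "fundusgan_config_error")
  expect_error(extract_lesions(g, img, q = 1), class = "fundusgan_config_error")
  expect_error(extract_lesions(g, img, sigma_fine = 2, sigma_coarse = 1),
               class = "fundusgan_config_error")
  expect_identical(extract_lesions(g, img), extract_lesions(g, img))
  expect_error(saliency_map(function(x) 1, img),
               class = "fundusgan_capability_error")
})

test_that("coarse-scale components are larger than fine-scale components", {
  g <- fx_grader(7)
  ds <- Filter(function(s) s$grade >= 2, fx_dataset(7))[1:10]
  comp_mean_area <- function(mask) {
    if (sum(mask) == 0) return(NA_real_)
    lab <- ns$label_components(mask)
    mean(tabulate(lab[lab > 0]))
  }
  areas <- vapply(ds, function(s) {
    ld <- extract_lesions(g, s$image)
    c(fine = comp_mean_area(ld$fine), coarse = comp_mean_area(ld$coarse))
  }, numeric(2))
  ok <- stats::complete.cases(t(areas))
  expect_gt(mean(areas["coarse", ok]), mean(areas["fine", ok]))
})
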