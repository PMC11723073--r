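test_that("sample generation is seeded and bitwise reproducible", {
  cfg <- synth_config(side = 48, n_samples = 5, seed = 11)
  s1 <- generate_sample(cfg, 2)
  s2 <- generate_sample(cfg, 2)
  expect_identical(s1, s2)
  s3 <- generate_sample(synth_config(side = 48, n_samples = 5, seed = 12), 2)
  expect_false(identical(s1$image, s3$image))
})

test_that("configuration is validated", {
  expect_error(synth_config(side = 0), class = "fundusgan_config_error")
  expect_error(synth_config(n_samples = -1), class = "fundusgan_config_error")
  bad <- default_lesion_ranges()
  bad[["4"]] <- c(0, 1)   # maximum drops below grade 3's
  expect_error(synth_config(lesion_count_range = bad),
               class = "fundusgan_config_error")
  cfg <- synth_config(n_samples = 3)
  expect_error(generate_sample(cfg, 4), class = "fundusgan_config_error")
})

test_that("samples satisfy the structural invariants", {
  ds <- fx_tiny_dataset()
  fov <- fundusgan:::fov_disk(32)
  for (s in ds[1:25]) {
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$vessel_mask %in% c(0, 1)))
    expect_true(all(s$lesion_mask_fine %in% c(0, 1)))
    expect_true(all(s$lesion_mask_coarse %in% c(0, 1)))
    # masks vanish outside the field of view; fine and coarse are disjoint
    expect_equal(sum(s$vessel_mask[!fov]), 0)
    expect_equal(sum((s$lesion_mask_fine + s$lesion_mask_coarse)[!fov]), 0)
    expect_equal(max(s$lesion_mask_fine * s$lesion_mask_coarse), 0)
    expect_true(s$grade %in% 0:4)
    # grading rule: count uniform in [4g, 4g+3] makes g = floor(count / 4)
    expect_equal(s$grade, floor(s$n_lesions / 4))
  }
})

test_that("a zero count range gives grade-0 samples empty lesion masks", {
  rng <- default_lesion_ranges()
  rng[["0"]] <- c(0, 0)
  cfg <- synth_config(side = 32, n_samples = 40, lesion_count_range = rng,
                      seed = 3)
  ds <- generate_dataset(cfg)
  g0 <- Filter(function(s) s$grade == 0, ds)
  expect_gt(length(g0), 0)
  for (s in g0) {
    expect_equal(sum(s$lesion_mask_fine), 0)
    expect_equal(sum(s$lesion_mask_coarse), 0)
  }
})

test_that("mean lesion count increases strictly with grade", {
  ds <- generate_dataset(synth_config(side = 64, n_samples = 100, seed = 42))
  g <- vapply(ds, function(s) s$grade, numeric(1))
  cnt <- vapply(ds, function(s) s$n_lesions, numeric(1))
  expect_setequal(unique(g), 0:4)
  means <- tapply(cnt, g, mean)
  expect_true(all(diff(means) > 0))
})

test_that("the stored vessel mask matches the drawn vessel imprint", {
  ds <- fx_tiny_dataset()
  jac <- vapply(ds[1:20], function(s)
    fundusgan:::jaccard(fundusgan:::recover_vessels(s$image), s$vessel_mask),
    numeric(1))
  expect_true(all(jac >= 0.5))
})

test_that("datasets round-trip through PNG files and a CSV manifest", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(side = 32, n_samples = 6, seed = 9)
  manifest <- write_dataset(cfg, dir)
  expect_equal(nrow(manifest), 6)
  expect_named(manifest, c("id", "image_path", "mask_path",
                           "lesion_fine_path", "lesion_coarse_path", "grade"))
  for (p in unlist(manifest[, 2:5])) expect_true(file.exists(file.path(dir, p)))

  back <- read_dataset(dir)
  orig <- generate_dataset(cfg)
  for (i in seq_len(6)) {
    expect_lt(max(abs(back[[i]]$image - orig[[i]]$image)), 1 / 255)
    expect_equal(back[[i]]$vessel_mask, orig[[i]]$vessel_mask)
    expect_equal(back[[i]]$lesion_mask_fine, orig[[i]]$lesion_mask_fine)
    expect_equal(back[[i]]$grade, orig[[i]]$grade)
  }

  dir2 <- withr::local_tempdir()
  write_dataset(synth_config(side = 32, n_samples = 6, seed = 10), dir2)
  h1 <- tools::md5sum(file.path(dir, manifest$image_path))
  h2 <- tools::md5sum(file.path(dir2, manifest$image_path))
  expect_true(any(unname(h1) != unname(h2)))
})
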