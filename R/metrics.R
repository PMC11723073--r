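# Evaluation metrics: Frechet Inception Distance on an embedding network,
# pixel mean squared error, and the structural similarity index, plus the
# per-configuration comparison pipeline producing one report row per method.

#' Gaussian feature statistics
#'
#' Mean and covariance of embedded image features, the sufficient statistics
#' for FID.
#'
#' @param mu Mean vector.
#' @param sigma Covariance matrix (symmetric).
#' @param n Number of images the statistics were estimated from (>= 2).
#' @return An object of class `gaussian_stats`.
#' @export
gaussian_stats <- function(mu, sigma, n) {
  sigma <- as.matrix(sigma)
  if (n < 2) stop_fundus("need n >= 2", "fundusgan_sample_error")
  if (nrow(sigma) != length(mu) || ncol(sigma) != length(mu))
    stop_fundus("sigma must be square and match mu", "fundusgan_shape_error")
  structure(list(mu = as.numeric(mu), sigma = (sigma + t(sigma)) / 2,
                 n = as.integer(n)), class = "gaussian_stats")
}

# Principal square root of a symmetric PSD matrix by eigendecomposition;
# eigenvalues below -tol are a hard error, small negatives are clipped.
psd_sqrt <- function(S, tol = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  scale <- max(1, abs(e$values))
  if (any(e$values < -tol * scale))
    stop_fundus("matrix is not positive semi-definite within tolerance",
                "fundusgan_numeric_error")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet Inception Distance between two Gaussian feature fits
#'
#' `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, evaluated with
#' the principal matrix square root computed as
#' `sqrt(S_r)^{1/2}`-symmetrized product (eigendecomposition, negative
#' eigenvalues clipped at -1e-10), which keeps the result real and the
#' trace term symmetric in its arguments.
#'
#' @param stats_r,stats_g [gaussian_stats()] of the real and generated
#'   feature sets (matching dimension).
#' @return A non-negative scalar (up to ~1e-8 numerical tolerance).
#' @examples
#' a <- gaussian_stats(c(0, 0), diag(2), 10)
#' b <- gaussian_stats(c(3, 4), diag(2), 10)
#' fid(a, b)  # 25: the trace term vanishes for equal covariances
#' @export
fid <- function(stats_r, stats_g) {
  stopifnot(inherits(stats_r, "gaussian_stats"),
            inherits(stats_g, "gaussian_stats"))
  if (length(stats_r$mu) != length(stats_g$mu))
    stop_fundus("feature dimensions differ", "fundusgan_shape_error")
  sr <- stats_r$sigma; sg <- stats_g$sigma
  rs <- psd_sqrt(sr)
  inner <- rs %*% sg %*% rs
  ev <- eigen((inner + t(inner)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(1, abs(ev))
  if (any(ev < -1e-10 * scale))
    stop_fundus("covariance product has negative spectrum beyond tolerance",
                "fundusgan_numeric_error")
  sum((stats_r$mu - stats_g$mu)^2) +
    sum(diag(sr)) + sum(diag(sg)) - 2 * sum(sqrt(pmax(ev, 0)))
}

#' Embed images and fit Gaussian feature statistics
#'
#' Applies the configured embedding network to every image and returns the
#' sample mean and covariance (denominator `n - 1`). The default embedder -
#' the stand-in grader's perceptual-layer features, globally average-pooled
#' - replaces the externally trained Inception network; FID values are only
#' comparable within one embedder.
#'
#' @param images A list of `H x W (x C)` images, or an `(H, W, C, N)` batch.
#' @param embedder A `dr_grader` (pooled features at `layer`), a function
#'   mapping one image to a numeric vector, or `"identity"` (flattened
#'   pixels).
#' @param layer Feature layer when `embedder` is a grader.
#' @return A [gaussian_stats()] object.
#' @export
embed_images <- function(images, embedder, layer = "stage2") {
  batch <- as_batch(images)
  n <- dim(batch)[4]
  if (n < 2)
    stop_fundus("need at least 2 images to fit feature statistics",
                "fundusgan_sample_error")
  feats <- if (identical(embedder, "identity")) {
    t(matrix(batch, ncol = n))
  } else if (is.function(embedder)) {
    t(vapply(seq_len(n), function(i) as.numeric(embedder(batch[, , , i])),
             numeric(length(as.numeric(embedder(batch[, , , 1]))))))
  } else if (inherits(embedder, "dr_grader")) {
    gap_forward(grader_features(embedder, batch, layer))
  } else {
    stop_fundus("unsupported embedder", "fundusgan_config_error")
  }
  gaussian_stats(colMeans(feats), cov(feats), n)
}

#' Mean squared pixel error
#'
#' Mean over all pixels and channels of the squared difference between two
#' images on the `[0, 1]` float scale.
#'
#' @param x,x_hat Arrays of identical shape.
#' @return A non-negative scalar.
#' @export
mse <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)))
    stop_fundus("images must have identical shape", "fundusgan_shape_error")
  mean((x - x_hat)^2)
}

#' Structural similarity index
#'
#' Evaluates the luminance/contrast/structure similarity
#' `((2 mu_x mu_y + C1)(2 cov_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(var_x + var_y + C2))`.
#' RGB images are converted to grayscale (channel mean) first. In the
#' default `"windowed"` mode the statistics are local Gaussian-window
#' moments (11 x 11, sigma 1.5) and the index is averaged over all valid
#' window positions; `"global"` evaluates the formula once with whole-image
#' moments (useful for direct formula checks).
#'
#' @param x,x_hat Images of identical shape with values in `[0, 1]`.
#' @param window `c(size, sigma)` of the Gaussian window.
#' @param constants `c(C1, C2)`; defaults `(0.01 L)^2, (0.03 L)^2` with
#'   dynamic range `L = 1`.
#' @param mode `"windowed"` or `"global"`.
#' @return A scalar `<= 1`, equal to 1 exactly when the images are identical.
#' @export
ssim <- function(x, x_hat, window = c(11, 1.5),
                 constants = c(0.01^2, 0.03^2), mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  if (!identical(dim(x), dim(x_hat)))
    stop_fundus("images must have identical shape", "fundusgan_shape_error")
  gray <- function(img) {
    img <- as_raster_array(img)
    if (dim(img)[3] > 1) rowMeans(img, dims = 2L) else img[, , 1]
  }
  gx <- gray(x); gy <- gray(x_hat)
  C1 <- constants[1]; C2 <- constants[2]
  if (mode == "global") {
    mx <- mean(gx); my <- mean(gy)
    vx <- mean(gx^2) - mx^2; vy <- mean(gy^2) - my^2
    cxy <- mean(gx * gy) - mx * my
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  ws <- window[1]
  if (ws > nrow(gx) || ws > ncol(gx))
    stop_fundus("SSIM window larger than the image", "fundusgan_config_error")
  k <- exp(-0.5 * ((seq_len(ws) - (ws + 1) / 2) / window[2])^2)
  k <- k / sum(k)
  valid <- function(n) {
    M <- matrix(0, n - ws + 1L, n)
    for (i in seq_len(n - ws + 1L)) M[i, i:(i + ws - 1L)] <- k
    M
  }
  Mh <- valid(nrow(gx)); Mw <- valid(ncol(gx))
  f <- function(a) Mh %*% a %*% t(Mw)
  mx <- f(gx); my <- f(gy)
  vx <- f(gx^2) - mx^2; vy <- f(gy^2) - my^2
  cxy <- f(gx * gy) - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

#' Evaluate a synthesis method against a real dataset
#'
#' Reproduces one method row of the comparison tables: MSE and SSIM are
#' averaged over paired real/generated images (paired by sample), FID is
#' computed between the pooled real and generated feature statistics, and
#' the whole evaluation is repeated with fresh noise seeds when images are
#' generated from a model, reporting mean and standard deviation.
#'
#' @param real A list of `fundus_sample` objects or a manifest path.
#' @param generated Optional pre-generated images: a list (same length and
#'   order as `real`) or an `(H, W, 3, N)` batch. When omitted, `generator`
#'   must be given.
#' @param generator Optional `gan_generator` (or checkpoint state/path);
#'   images are synthesized from each real sample's vessel mask and lesion
#'   descriptor with per-repeat noise.
#' @param grader `dr_grader` used for the lesion descriptors (when
#'   generating) and as the default FID embedder.
#' @param embedder FID embedder; defaults to `grader`.
#' @param layer Feature layer for grader-based embedding.
#' @param repeats Number of noise repeats (model-based evaluation only).
#' @param seed Base seed for the noise repeats.
#' @param label Method label for the report row; defaults to the
#'   generator's resampling kernel.
#' @return A one-row data frame: `method, mse_mean, mse_sd, ssim_mean,
#'   ssim_sd, fid_mean, fid_sd, n_images, n_repeats, embedder`.
#' @export
evaluate_synthesis <- function(real, generated = NULL, generator = NULL,
                               grader = NULL, embedder = grader,
                               layer = "stage2", repeats = 1L, seed = 1L,
                               label = NULL) {
  samples <- resolve_samples(real)
  n <- length(samples)
  imgs_real <- lapply(samples, function(s) s$image)
  if (is.null(generated) && is.null(generator))
    stop_fundus("supply generated images or a generator", "fundusgan_config_error")
  if (is.null(embedder))
    stop_fundus("supply a grader or embedder for FID", "fundusgan_config_error")

  gen_model <- NULL
  if (!is.null(generator)) {
    if (is.character(generator)) generator <- load_checkpoint(generator)
    gen_model <- if (inherits(generator, "gan_generator")) generator
                 else generator$generator
    masks <- lapply(samples, function(s) s$vessel_mask)
    lds <- lapply(imgs_real, function(im) extract_lesions(grader, im))
    label <- label %||% paste0("WGAN-GP w/", format(gen_model$resample))
  } else {
    repeats <- 1L
    label <- label %||% "precomputed"
  }

  one_repeat <- function(r) {
    gen_imgs <- if (!is.null(gen_model)) {
      z <- with_seed(derive_seed(seed, r, 31L),
                     matrix(rnorm(n * gen_model$z_dim), n, gen_model$z_dim))
      batch <- generator_forward(gen_model, condition_stack(masks, lds), z)$out
      lapply(seq_len(n), function(i) batch[, , , i])
    } else if (is.list(generated)) generated
    else lapply(seq_len(dim(generated)[4]), function(i) generated[, , , i])
    if (length(gen_imgs) != n)
      stop_fundus("real and generated counts differ", "fundusgan_pairing_error")
    pair_mse <- mapply(mse, imgs_real, gen_imgs)
    pair_ssim <- mapply(ssim, imgs_real, gen_imgs)
    f <- fid(embed_images(imgs_real, embedder, layer),
             embed_images(gen_imgs, embedder, layer))
    c(mse = mean(pair_mse), ssim = mean(pair_ssim), fid = f)
  }
  res <- t(vapply(seq_len(repeats), one_repeat, numeric(3)))
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  data.frame(method = label,
             mse_mean = mean(res[, "mse"]), mse_sd = sd0(res[, "mse"]),
             ssim_mean = mean(res[, "ssim"]), ssim_sd = sd0(res[, "ssim"]),
             fid_mean = mean(res[, "fid"]), fid_sd = sd0(res[, "fid"]),
             n_images = n, n_repeats = repeats,
             embedder = if (identical(embedder, "identity")) "identity"
                        else if (is.function(embedder)) "custom"
                        else paste0("grader:", layer))
}
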