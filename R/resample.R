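#' Resampling specification
#'
#' Names one of the separable resampling kernels used for image resizing and
#' for the generator's decoder upsampling layers. The kernel definitions are
#' the conventional ones from the image-processing literature: `nearest`
#' (round-half-up toward the larger index), `bilinear` (tent, support 1),
#' `bicubic` (Keys cubic with a = -0.5, support 2), `mitchell`
#' (Mitchell-Netravali with B = C = 1/3, support 2) and `lanczos5`
#' (sinc windowed by sinc, support 5). Coordinates are mapped with half-pixel
#' centers (source s = (d + 0.5) * in/out - 0.5) and edges handled by
#' clamping source indices.
#'
#' When `antialias = TRUE` and the image is being downscaled, the kernel
#' support and argument are stretched by the inverse scale so frequencies
#' above the output Nyquist limit are suppressed; upsampling is unaffected by
#' the flag. The nearest kernel ignores the flag.
#'
#' @param kernel One of `"nearest"`, `"bilinear"`, `"bicubic"`, `"mitchell"`,
#'   `"lanczos5"`. A trailing `"+antialias"` (e.g. `"bilinear+antialias"`)
#'   may be used instead of the `antialias` argument.
#' @param antialias Logical; stretch the kernel when downscaling.
#' @return An object of class `resample_spec`.
#' @examples
#' resample_spec("bilinear", antialias = TRUE)
#' resample_spec("mitchell")
#' @export
resample_spec <- function(kernel = c("nearest", "bilinear", "bicubic",
                                     "mitchell", "lanczos5"),
                          antialias = FALSE) {
  if (length(kernel) == 1 && grepl("\\+antialias$", kernel)) {
    antialias <- TRUE
    kernel <- sub("\\+antialias$", "", kernel)
  }
  kernel <- tryCatch(match.arg(kernel),
                     error = function(e) stop_fundus(
                       paste0("unknown resampling kernel: ",
                              paste(kernel, collapse = "/")),
                       "fundusgan_config_error"))
  structure(list(kernel = kernel, antialias = isTRUE(antialias)),
            class = "resample_spec")
}

#' @export
format.resample_spec <- function(x, ...) {
  paste0(x$kernel, if (x$antialias) "+antialias" else "")
}

#' @export
print.resample_spec <- function(x, ...) {
  cat("<resample_spec>", format(x), "\n"); invisible(x)
}

# 1-D reconstruction kernels (radius = support for scale 1) --------------

kernel_fun <- function(name) {
  switch(name,
    bilinear = list(support = 1, f = function(t) pmax(0, 1 - abs(t))),
    bicubic = list(support = 2, f = function(t) {
      a <- -0.5; t <- abs(t)
      ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
             ifelse(t < 2, a * (t^3 - 5 * t^2 + 8 * t - 4), 0))
    }),
    mitchell = list(support = 2, f = function(t) {
      B <- 1 / 3; C <- 1 / 3; t <- abs(t)
      ifelse(t < 1,
             ((12 - 9 * B - 6 * C) * t^3 + (-18 + 12 * B + 6 * C) * t^2 +
                (6 - 2 * B)) / 6,
             ifelse(t < 2,
                    ((-B - 6 * C) * t^3 + (6 * B + 30 * C) * t^2 +
                       (-12 * B - 48 * C) * t + (8 * B + 24 * C)) / 6, 0))
    }),
    lanczos5 = list(support = 5, f = function(t) {
      out <- rep(0, length(t))
      inside <- abs(t) < 5
      ti <- t[inside]
      s <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))
      out[inside] <- s(ti) * s(ti / 5)
      out
    }),
    stop_fundus(paste("unknown kernel", name), "fundusgan_config_error"))
}

# Dense (n_out x n_in) weight matrix for one axis. Each row's weights are
# renormalized to sum to 1; clamped source indices accumulate at the edges.
resample_weights <- function(n_in, n_out, spec) {
  M <- matrix(0, n_out, n_in)
  scale_io <- n_in / n_out
  if (spec$kernel == "nearest") {
    for (d in seq_len(n_out)) {
      s <- (d - 0.5) * scale_io - 0.5               # 0-based source coordinate
      j <- min(max(floor(s + 0.5), 0), n_in - 1)    # half rounds up
      M[d, j + 1] <- 1
    }
    return(M)
  }
  kf <- kernel_fun(spec$kernel)
  stretch <- if (spec$antialias && scale_io > 1) scale_io else 1
  support <- kf$support * stretch
  for (d in seq_len(n_out)) {
    s <- (d - 0.5) * scale_io - 0.5
    js <- ceiling(s - support):floor(s + support)
    w <- kf$f((js - s) / stretch)
    keep <- w != 0
    js <- pmin(pmax(js[keep], 0), n_in - 1)
    w <- w[keep]
    if (sum(w) == 0) { js <- round(s); w <- 1 }
    for (k in seq_along(js)) M[d, js[k] + 1] <- M[d, js[k] + 1] + w[k]
    M[d, ] <- M[d, ] / sum(M[d, ])
  }
  M
}

#' Resize an image with a named resampling kernel
#'
#' Separable resampling with half-pixel-center coordinate mapping and
#' clamp-to-edge boundary handling. See [resample_spec()] for the kernel
#' definitions.
#'
#' @param img An `H x W` matrix or `H x W x C` array with values in `[0, 1]`.
#' @param out_h,out_w Output dimensions (positive integers).
#' @param spec A [resample_spec()] (or a kernel name coerced to one).
#' @param clip Clip the output to `[0, 1]` (cubic and Lanczos kernels can
#'   overshoot). Disable for signed data.
#' @return The resized image with the same number of channels.
#' @examples
#' img <- matrix(runif(35), 7, 5)
#' dim(resize(img, 14, 10, resample_spec("bicubic")))
#' @export
resize <- function(img, out_h, out_w, spec = resample_spec("bilinear"),
                   clip = TRUE) {
  if (!inherits(spec, "resample_spec")) spec <- resample_spec(spec)
  if (out_h < 1 || out_w < 1)
    stop_fundus("output dimensions must be >= 1", "fundusgan_config_error")
  was_matrix <- is.matrix(img)
  img <- as_raster_array(img)
  d <- dim(img)
  Mh <- resample_weights(d[1], out_h, spec)
  Mw <- resample_weights(d[2], out_w, spec)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Mh %*% img[, , c] %*% t(Mw)
  if (clip) out <- clip01(out)
  if (was_matrix && d[3] == 1L) out <- out[, , 1]
  out
}

# Apply/adjoint of a 2x upsampling step on an (H, W, C, N) batch; used by the
# generator decoder so one resample_spec selects the whole method variant.
upsample_apply <- function(x, Mh, Mw, transpose = FALSE) {
  if (transpose) { Mh <- t(Mh); Mw <- t(Mw) }
  upsample_rcpp(x, Mh, Mw)
}

#' Preprocess an image to a square side length
#'
#' Standardizes an image to `side x side` pixels with the configured
#' resampling kernel, clipping values to `[0, 1]` — the normalization applied
#' to every image before grading, lesion extraction, training or evaluation.
#'
#' @inheritParams resize
#' @param side Target side length in pixels (>= 8).
#' @return A `side x side` image with the input's channel count.
#' @export
preprocess <- function(img, side, spec = resample_spec("bilinear")) {
  if (side < 8) stop_fundus("side must be >= 8", "fundusgan_config_error")
  resize(img, side, side, spec, clip = TRUE)
}

#' Read an image file as a [0,1] raster
#'
#' Decodes an 8- or 16-bit PNG or JPEG into an `H x W x C` array scaled to
#' `[0, 1]`. An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `H x W x C` array (C = 1 for grayscale, 3 for RGB).
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop_fundus(paste0("cannot read image: ", path), "fundusgan_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = , jpeg = jpeg::readJPEG(path),
           stop_fundus(paste0("unsupported image format: ", path),
                       "fundusgan_io_error")),
    error = function(e) stop_fundus(
      paste0("failed to decode image ", path, ": ", conditionMessage(e)),
      "fundusgan_io_error"))
  img <- as_raster_array(img)
  if (dim(img)[3] %in% c(2L, 4L)) img <- img[, , -dim(img)[3], drop = FALSE]
  img
}

#' Write a [0,1] raster as an 8-bit PNG
#'
#' The inverse of [load_image()] for values on the 8-bit lattice; other
#' values are quantized to the nearest 8-bit level.
#'
#' @param img `H x W` matrix or `H x W x C` array in `[0, 1]`.
#' @param path Output path (`.png`).
#' @export
save_image <- function(img, path) {
  img <- clip01(as_raster_array(img))
  if (dim(img)[3] == 1L) img <- img[, , 1]
  ok <- tryCatch({ png::writePNG(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_fundus(paste0("cannot write image: ", path),
                       "fundusgan_io_error")
  invisible(path)
}
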