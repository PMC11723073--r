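# Saliency-based lesion extraction.
#
# The grader's scalar severity output is backpropagated to the input image;
# the channel-summed absolute gradient is the lesion saliency. Smoothing the
# saliency with two Gaussian filters of different widths and binarizing each
# at a per-image quantile yields a pair of binary maps describing lesions at
# a fine and a coarse scale - the pathological conditioning input D(x) of
# the generator.

#' Input-gradient saliency map of the grader
#'
#' Per-pixel saliency is the channel-summed absolute gradient of the scalar
#' grade estimate with respect to the input image.
#'
#' @param model A trained `dr_grader`.
#' @param img An `H x W x 3` image in `[0, 1]`.
#' @return A non-negative `H x W` matrix.
#' @export
saliency_map <- function(model, img) {
  if (is.function(model))
    stop_fundus("saliency needs a differentiable grader, not a plain function",
                "fundusgan_capability_error")
  stopifnot(inherits(model, "dr_grader"))
  g <- grader_input_grad(model, img)
  rowSums(abs(g), dims = 2L)
}

# Discrete Gaussian kernel truncated at 4 sigma and renormalized.
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# (n x n) matrix applying the 1-D kernel with reflect padding
# (scipy-style reflect: d c b a | a b c d | d c b a); memoised per (n, k).
reflect_cache <- new.env(parent = emptyenv())

reflect_filter_matrix <- function(n, k) {
  key <- paste0(n, ":", paste(signif(k, 12), collapse = ","))
  hit <- reflect_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      M[i, j] <- M[i, j] + k[o + r + 1L]
    }
  }
  reflect_cache[[key]] <- M
  M
}

#' Gaussian smoothing with reflect padding
#'
#' Separable convolution with a discrete Gaussian truncated at 4 sigma and
#' renormalized; boundaries are reflect-padded.
#'
#' @param x Numeric matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Smoothed matrix of the same size.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma > 0)
  k <- gaussian_kernel(sigma)
  Mh <- reflect_filter_matrix(nrow(x), k)
  Mw <- reflect_filter_matrix(ncol(x), k)
  Mh %*% x %*% t(Mw)
}

#' Extract two-scale lesion descriptor maps
#'
#' Computes the [saliency_map()], smooths it with Gaussian filters of
#' standard deviations `sigma_fine` and `sigma_coarse`, and binarizes each
#' smoothed map at its own empirical `1 - q` quantile taken over
#' field-of-view pixels (ties at the threshold are included). A saliency map
#' that is identically zero yields two all-zero masks.
#'
#' @inheritParams saliency_map
#' @param sigma_fine,sigma_coarse Gaussian widths in pixels;
#'   `0 < sigma_fine < sigma_coarse`.
#' @param q Mask quantile in (0, 1): each mask keeps the top fraction `q` of
#'   smoothed saliency inside the field of view.
#' @param fov Optional logical field-of-view matrix; by default pixels where
#'   any channel exceeds 0.01 (the region outside a fundus photograph's
#'   aperture is structurally black).
#' @return An object of class `lesion_descriptor` with binary `fine` and
#'   `coarse` masks, the raw `saliency`, and `params`.
#' @export
extract_lesions <- function(model, img, sigma_fine = 1, sigma_coarse = 4,
                            q = 0.02, fov = NULL) {
  if (q <= 0 || q >= 1)
    stop_fundus("q must lie in (0, 1)", "fundusgan_config_error")
  if (sigma_fine <= 0 || sigma_coarse <= sigma_fine)
    stop_fundus("need 0 < sigma_fine < sigma_coarse", "fundusgan_config_error")
  img <- as_raster_array(img)
  sal <- saliency_map(model, img)
  if (is.null(fov))
    fov <- (if (dim(img)[3] == 3L) pmax(img[, , 1], img[, , 2], img[, , 3])
            else img[, , 1]) > 0.01
  if (!any(fov)) fov <- matrix(TRUE, nrow(sal), ncol(sal))

  binarize_at_scale <- function(sigma) {
    if (max(sal) == 0) return(matrix(0, nrow(sal), ncol(sal)))
    sm <- gaussian_blur(sal, sigma)
    thr <- as.numeric(quantile(sm[fov], 1 - q, type = 7))
    # ties at the threshold are included, up to filtering round-off
    ((sm >= thr - 1e-9 * max(sm)) & fov) * 1
  }
  structure(list(fine = binarize_at_scale(sigma_fine),
                 coarse = binarize_at_scale(sigma_coarse),
                 saliency = sal,
                 params = list(sigma_fine = sigma_fine,
                               sigma_coarse = sigma_coarse, q = q)),
            class = "lesion_descriptor")
}

# 4-connected component labelling of a binary mask (iterative flood fill);
# used to reason about lesion component sizes in descriptors.
label_components <- function(mask) {
  mask <- mask > 0.5
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      i <- (p - 1L) %% H + 1L
      j <- (p - 1L) %/% H + 1L
      if (i > 1L) stack <- c(stack, p - 1L)
      if (i < H) stack <- c(stack, p + 1L)
      if (j > 1L) stack <- c(stack, p - H)
      if (j < W) stack <- c(stack, p + H)
    }
  }
  lab
}

#' Build a lesion descriptor directly from known masks
#'
#' Convenience constructor used when ground-truth lesion masks are available
#' (e.g. from the synthetic generator) and the saliency route is not needed.
#'
#' @param fine,coarse Binary `H x W` masks.
#' @return A `lesion_descriptor`.
#' @export
lesion_descriptor <- function(fine, coarse) {
  structure(list(fine = (fine > 0.5) * 1, coarse = (coarse > 0.5) * 1,
                 saliency = NULL, params = NULL),
            class = "lesion_descriptor")
}

#' @export
print.lesion_descriptor <- function(x, ...) {
  cat(sprintf("<lesion_descriptor> %dx%d fine %d px, coarse %d px\n",
              nrow(x$fine), ncol(x$fine), sum(x$fine > 0), sum(x$coarse > 0)))
  invisible(x)
}
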