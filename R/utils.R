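#' @useDynLib fundusgan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd cov
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# stream afterwards so seeded helpers never perturb global reproducibility.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic derivation of per-item seeds from a base seed; kept below
# .Machine$integer.max so the result is always a valid set.seed() argument.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 +
                as.double(salt) * 104729) %% 2147483629)
}

stop_fundus <- function(msg, class) {
  stop(structure(class = c(class, "fundusgan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# image helpers ---------------------------------------------------------

# Coerce to an H x W x C array (C in {1,3}); matrices become single-channel.
as_raster_array <- function(img) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) != 3L)
    stop_fundus("image must be an H x W or H x W x C array",
                "fundusgan_shape_error")
  img
}

# Stack a batch list of H x W x C arrays into (H, W, C, N).
as_batch <- function(x) {
  if (is.list(x)) {
    d <- dim(as_raster_array(x[[1]]))
    out <- array(0, c(d, length(x)))
    for (i in seq_along(x)) out[, , , i] <- as_raster_array(x[[i]])
    return(out)
  }
  x <- if (is.matrix(x)) array(x, c(dim(x), 1L, 1L)) else x
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Channel-wise concatenation of (H, W, C, N) batches.
concat_channels <- function(...) {
  parts <- lapply(list(...), as_batch)
  d1 <- dim(parts[[1]])
  if (length(parts) == 2L &&
      identical(dim(parts[[2]])[c(1, 2, 4)], d1[c(1, 2, 4)]))
    return(concat_ch_rcpp(parts[[1]], parts[[2]]))
  cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (p in parts) {
    dp <- dim(p)
    if (!identical(dp[c(1, 2, 4)], d1[c(1, 2, 4)]))
      stop_fundus("channel concat requires matching H, W and batch size",
                  "fundusgan_shape_error")
    out[, , at + seq_len(dp[3]), ] <- p
    at <- at + dp[3]
  }
  out
}

jaccard <- function(a, b) {
  a <- a > 0.5; b <- b > 0.5
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
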