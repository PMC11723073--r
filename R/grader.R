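# Stand-in diabetic-retinopathy severity grader.
#
# A small convolutional regressor mapping an RGB fundus image in [0,1] to a
# scalar grade estimate. It serves three roles behind one interface:
#   * the severity-loss scorer DR(.) (absolute grade difference),
#   * the backpropagation source for saliency-based lesion extraction,
#   * the fixed feature extractor for the perceptual loss and the default
#     embedding for FID.
# Any of the three roles also accepts a user-supplied network (a function);
# the stand-in exists so the full pipeline runs without external pretrained
# models or downloads.
#
# Architecture: a stride-2 conv trunk (the stage/lambda features) pooled
# into the regression head, plus a full-resolution lesion-evidence branch
# (3x3 context layer followed by 1x1 convs) whose pooled fine/coarse
# evidence areas enter the same head. During training the evidence branch
# receives auxiliary supervision from the dataset's lesion masks with
# positively-weighted squared error; grade supervision remains the primary
# objective. The evidence route mirrors how severity grading actually
# works - detect lesions, integrate their extent - and makes the grade
# head's job a near-linear calibration.

grader_layer_index <- function(model, layer) {
  idx <- match(layer, c("input", model$stage_names))
  if (is.na(idx))
    stop_fundus(paste0("unknown feature layer: ", layer,
                       " (valid: input, ",
                       paste(model$stage_names, collapse = ", "), ")"),
                "fundusgan_config_error")
  idx - 1L   # 0 = identity passthrough
}

#' Build an untrained grader network
#'
#' The grader has a conv trunk of stride-2 stages (3x3, ReLU) providing the
#' named feature layers, a full-resolution lesion-evidence branch (one 3x3
#' context layer, then 1x1 convs, ReLU) producing fine/coarse lesion
#' evidence maps, and a linear head regressing the scalar grade from the
#' pooled trunk features together with the summed evidence areas. Inputs
#' are `[0, 1]` RGB, centered internally by subtracting 0.5.
#'
#' @param side Expected input side length in pixels.
#' @param widths Channel widths of the trunk stages (>= 3 stages).
#' @param evidence_widths Hidden widths of the evidence branch.
#' @param seed Seed for the weight initialization.
#' @return An object of class `dr_grader`. Feature layers are named
#'   `"input"` (identity passthrough), `"stage1"`, `"stage2"`, ... with
#'   cumulative stride `2^k` at stage k; the default perceptual layer is
#'   `"stage2"`.
#' @export
build_grader <- function(side = 64L, widths = c(16L, 32L, 48L),
                         evidence_widths = c(16L, 8L), seed = 1L) {
  stopifnot(length(widths) >= 3)
  with_seed(seed, {
    trunk <- list()
    in_ch <- 3L
    for (w in widths) {
      trunk <- c(trunk, list(nn_conv(in_ch, w, stride = 2L), nn_lrelu(0)))
      in_ch <- w
    }
    # leaky hidden units and a nearly-one-sided output (slope 0.01 below
    # zero, bias started positive) keep every evidence channel trainable -
    # a hard terminal ReLU can permanently silence a channel - while still
    # clipping most negative noise out of the pooled area sums
    evid <- list(nn_conv(3L, evidence_widths[1], k = 3L), nn_lrelu(0.1))
    ein <- evidence_widths[1]
    for (w in evidence_widths[-1]) {
      evid <- c(evid, list(nn_conv(ein, w, k = 1L, pad = 0L), nn_lrelu(0.1)))
      ein <- w
    }
    out_conv <- nn_conv(ein, 2L, k = 1L, pad = 0L)
    out_conv$b <- rep(0.05, 2L)
    evid <- c(evid, list(out_conv, nn_lrelu(0.01)))
    structure(list(trunk = nn_net(trunk), evid = nn_net(evid),
                   head = nn_net(list(nn_dense(in_ch + 2L, 1L))),
                   side = as.integer(side), widths = as.integer(widths),
                   stage_names = paste0("stage", seq_along(widths)),
                   default_layer = "stage2",
                   area_scale = side^2 / 256,
                   seed = as.integer(seed), holdout = NULL),
              class = "dr_grader")
  })
}

# Full forward pass: scalar estimates (length-N) plus caches for backward.
grader_forward <- function(model, x, cache = FALSE) {
  x <- as_batch(x) - 0.5
  ft <- seq_forward(model$trunk, x)
  fe <- seq_forward(model$evid, x)
  feat <- cbind(gap_forward(ft$out),
                t(colSums(fe$out, dims = 2L)) / model$area_scale)
  fh <- seq_forward(model$head, feat)
  if (cache)
    list(pred = drop(fh$out), trunk = ft, evid = fe, head = fh,
         trunk_dims = dim(ft$out), evid_dims = dim(fe$out))
  else drop(fh$out)
}

# Input gradient of sum(dpred * DR(x_n)) given forward caches.
grader_backward_input <- function(model, fw, dpred) {
  dfeat <- seq_backward(model$head, fw$head$cache, dpred,
                        need_param_grads = FALSE)$dx
  n_t <- ncol(dfeat) - 2L
  dt <- gap_backward(dfeat[, seq_len(n_t), drop = FALSE], fw$trunk_dims)
  de <- array(rep(t(dfeat[, n_t + 1:2, drop = FALSE]) / model$area_scale,
                  each = prod(fw$evid_dims[1:2])), fw$evid_dims)
  seq_backward(model$trunk, fw$trunk$cache, dt, need_param_grads = FALSE)$dx +
    seq_backward(model$evid, fw$evid$cache, de, need_param_grads = FALSE)$dx
}

grader_input_grad <- function(model, x, weights = 1) {
  x <- as_batch(x)
  fw <- grader_forward(model, x, cache = TRUE)
  n <- dim(x)[4]
  grader_backward_input(model, fw, matrix(rep_len(weights, n), n, 1))
}

resolve_samples <- function(data) {
  if (is.character(data)) data <- read_dataset(data)
  if (is.data.frame(data))
    stop_fundus("pass a manifest path or a list of fundus_sample objects",
                "fundusgan_config_error")
  data
}

sample_images <- function(samples, side, spec = resample_spec("bilinear")) {
  imgs <- lapply(samples, function(s) {
    img <- s$image
    if (!identical(dim(img)[1:2], c(side, side))) img <- preprocess(img, side, spec)
    img
  })
  as_batch(imgs)
}

# Random orientation (flips/transpose) of an image batch and the matching
# lesion-mask targets; severity is orientation-invariant.
orient_batch <- function(xb, tb = NULL) {
  n <- dim(xb)[4]; H <- dim(xb)[1]
  for (i in seq_len(n)) {
    im <- xb[, , , i]
    tg <- if (!is.null(tb)) tb[, , , i] else NULL
    if (runif(1) < 0.5) { im <- im[rev(seq_len(H)), , ]
      if (!is.null(tg)) tg <- tg[rev(seq_len(H)), , ] }
    if (runif(1) < 0.5) { im <- im[, rev(seq_len(H)), ]
      if (!is.null(tg)) tg <- tg[, rev(seq_len(H)), ] }
    if (runif(1) < 0.5) { im <- aperm(im, c(2, 1, 3))
      if (!is.null(tg)) tg <- aperm(tg, c(2, 1, 3)) }
    xb[, , , i] <- im
    if (!is.null(tg)) tb[, , , i] <- tg
  }
  list(x = xb, t = tb)
}

#' Train the stand-in severity grader
#'
#' Minimizes squared error between predicted and true grade with Adam on
#' shuffled minibatches under random orientation augmentation. The lesion
#' masks bundled with the synthetic samples additionally supervise the
#' grader's lesion-evidence branch (squared error with lesion pixels
#' upweighted, weight `aux_weight * pos_weight`); samples without masks fall
#' back to grade-only supervision. A held-out subset (or an explicit
#' evaluation set) is scored with the *within-one accuracy*: the fraction of
#' held-out samples whose prediction is within one grade of the truth.
#'
#' @param data A list of `fundus_sample` objects or a manifest path. Must
#'   contain at least 50 samples spanning at least 3 grades.
#' @param epochs Training epochs (0 returns the initialized model).
#' @param seed Seed controlling initialization, the holdout split, batch
#'   order and augmentation; identical inputs give identical models and
#'   metrics.
#' @param holdout Fraction held out for evaluation (ignored when `eval_data`
#'   is given).
#' @param eval_data Optional explicit evaluation set (same format as `data`).
#' @param batch_size,lr Minibatch size and Adam learning rate.
#' @param widths Trunk stage widths, passed to [build_grader()].
#' @param aux_weight Weight of the lesion-evidence auxiliary loss (0
#'   disables it).
#' @param pos_weight Upweighting factor of lesion pixels in the auxiliary
#'   loss, countering the ~2% lesion-pixel class imbalance.
#' @param verbose Print the per-epoch training loss.
#' @return A trained `dr_grader`; `$holdout` holds `accuracy_within_one`,
#'   `n`, `predictions` and `grades` for the evaluation set.
#' @export
train_grader <- function(data, epochs = 30L, seed = 1L, holdout = 0.2,
                         eval_data = NULL, batch_size = 8L, lr = 5e-3,
                         widths = c(16L, 32L, 48L), aux_weight = 1,
                         pos_weight = 12, verbose = FALSE) {
  samples <- resolve_samples(data)
  grades <- vapply(samples, function(s) as.numeric(s$grade), numeric(1))
  if (length(unique(grades)) < 2)
    stop_fundus("degenerate labels: all samples share one grade",
                "fundusgan_degenerate_labels")
  if (length(samples) < 50 || length(unique(grades)) < 3)
    stop_fundus("need >= 50 samples spanning >= 3 grades",
                "fundusgan_config_error")
  side <- dim(samples[[1]]$image)[1]
  model <- build_grader(side = side, widths = widths, seed = seed)
  has_masks <- aux_weight > 0 &&
    !is.null(samples[[1]]$lesion_mask_fine) &&
    !is.null(samples[[1]]$lesion_mask_coarse)

  with_seed(derive_seed(seed, 1L, salt = 11L), {
    if (is.null(eval_data)) {
      n_eval <- max(1L, round(holdout * length(samples)))
      eval_idx <- sample(seq_along(samples), n_eval)
      eval_samples <- samples[eval_idx]
      train_samples <- samples[-eval_idx]
    } else {
      eval_samples <- resolve_samples(eval_data)
      train_samples <- samples
    }
    x_train <- sample_images(train_samples, side)
    y_train <- vapply(train_samples, function(s) as.numeric(s$grade), numeric(1))
    n <- length(y_train)
    masks <- NULL
    if (has_masks) {
      masks <- array(0, c(side, side, 2L, n))
      for (i in seq_len(n)) {
        masks[, , 1, i] <- train_samples[[i]]$lesion_mask_fine
        masks[, , 2, i] <- train_samples[[i]]$lesion_mask_coarse
      }
    }
    st_t <- adam_init(model$trunk$layers)
    st_e <- adam_init(model$evid$layers)
    st_h <- adam_init(model$head$layers)
    for (ep in seq_len(epochs)) {
      perm <- sample(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        nb <- length(idx)
        ob <- orient_batch(x_train[, , , idx, drop = FALSE],
                           if (has_masks) masks[, , , idx, drop = FALSE])
        fw <- grader_forward(model, ob$x, cache = TRUE)
        err <- fw$pred - y_train[idx]
        ep_loss <- ep_loss + sum(err^2)
        dfeat <- seq_backward(model$head, fw$head$cache,
                              matrix(2 * err / nb, ncol = 1))
        n_t <- model$widths[length(model$widths)]
        dt <- gap_backward(dfeat$dx[, seq_len(n_t), drop = FALSE],
                           fw$trunk_dims)
        # the evidence branch trains on its own mask supervision; the grade
        # loss reaches it only through the head (stop-gradient at the areas),
        # which keeps the detectors from being disrupted early in training.
        # Without masks the grade gradient is routed through instead.
        if (has_masks) {
          w <- 1 + (pos_weight - 1) * ob$t
          de <- aux_weight * 2 * w * (fw$evid$out - ob$t) / length(ob$t)
        } else {
          de <- array(rep(t(dfeat$dx[, n_t + 1:2, drop = FALSE]) /
                            model$area_scale,
                          each = prod(fw$evid_dims[1:2])), fw$evid_dims)
        }
        bt <- seq_backward(model$trunk, fw$trunk$cache, dt, need_dx = FALSE)
        be <- seq_backward(model$evid, fw$evid$cache, de, need_dx = FALSE)
        u <- adam_step(model$trunk$layers, bt$grads, st_t, lr)
        model$trunk$layers <- u$layers; st_t <- u$state
        u <- adam_step(model$evid$layers, be$grads, st_e, lr)
        model$evid$layers <- u$layers; st_e <- u$state
        u <- adam_step(model$head$layers, dfeat$grads, st_h, lr)
        model$head$layers <- u$layers; st_h <- u$state
      }
      if (verbose) message(sprintf("epoch %d: mse %.4f", ep, ep_loss / n))
    }
    x_eval <- sample_images(eval_samples, side)
    y_eval <- vapply(eval_samples, function(s) as.numeric(s$grade), numeric(1))
    pred <- grader_forward(model, x_eval)
    model$holdout <- list(
      accuracy_within_one = mean(abs(pred - y_eval) <= 1),
      n = length(y_eval), predictions = pred, grades = y_eval)
  })
  model
}

#' Predict the severity grade of a fundus image
#'
#' @param model A `dr_grader` (or any function mapping an image batch to a
#'   numeric vector, for user-plugged external detectors).
#' @param img An `H x W x 3` image or an `(H, W, 3, N)` batch; images whose
#'   side differs from the model's are resized (bilinear) first.
#' @return A numeric grade estimate per image (unbounded regression value).
#' @export
predict_grade <- function(model, img) {
  if (is.function(model)) return(model(img))
  stopifnot(inherits(model, "dr_grader"))
  x <- as_batch(img)
  d <- dim(x)
  if (d[3] != 3L)
    stop_fundus("grader expects 3-channel images", "fundusgan_shape_error")
  if (d[1] != model$side || d[2] != model$side) {
    imgs <- lapply(seq_len(d[4]), function(i)
      preprocess(x[, , , i], model$side))
    x <- as_batch(imgs)
  }
  grader_forward(model, x)
}

#' Extract an intermediate feature map from the grader
#'
#' @inheritParams predict_grade
#' @param layer `"input"` (identity passthrough, returned unchanged) or one
#'   of the named trunk stages (`"stage1"`, ...), whose post-activation map
#'   is returned. The spatial size of stage k is the input side divided by
#'   `2^k`.
#' @return The activation array `(h, w, channels, N)`.
#' @export
grader_features <- function(model, img, layer = model$default_layer) {
  stopifnot(inherits(model, "dr_grader"))
  x <- as_batch(img)
  idx <- grader_layer_index(model, layer)
  if (idx == 0L) return(x)
  seq_forward(model$trunk, x - 0.5, upto = 2L * idx)$out  # conv + relu per stage
}

#' @export
print.dr_grader <- function(x, ...) {
  cat("<dr_grader> side", x$side, "widths", paste(x$widths, collapse = "-"))
  if (!is.null(x$holdout))
    cat(sprintf(" | held-out within-one accuracy %.3f (n=%d)",
                x$holdout$accuracy_within_one, x$holdout$n))
  cat("\n"); invisible(x)
}
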