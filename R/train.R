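# Alternating adversarial optimization with seeded reproducibility.
#
# Each generator step performs n_critic critic updates (negative Wasserstein
# loss plus gradient penalty, the penalty differentiated with the
# forward-over-reverse double-backward pass) followed by one generator
# update (negative critic score plus weighted perceptual and severity
# terms). The grader and feature network stay frozen throughout. Every
# logged number is a deterministic function of (data, grader, config).

#' Training configuration
#'
#' @param steps Number of generator updates.
#' @param n_critic Critic updates per generator update.
#' @param batch_size Minibatch size.
#' @param lr,beta1,beta2 Adam hyperparameters; `lr` drives the generator.
#' @param lr_critic Critic learning rate; defaults to `lr / 4`. Training
#'   the critic slower than the generator keeps the two in balance over
#'   short desk-scale runs, letting the gradient penalty calibrate the
#'   critic toward 1-Lipschitz instead of chasing an ever-sharper score.
#' @param weights A [loss_weights()]. The training default raises the
#'   gradient-penalty coefficient to 100: the critic's stationary gradient
#'   norm balances the Wasserstein term's parameter gradient against the
#'   penalty's, and with a small desk-scale critic the former is large, so
#'   the canonical coefficient 10 lets the norm equilibrate far above 1
#'   instead of calibrating toward it.
#' @param resample [resample_spec()] applied to the generator's decoder
#'   upsampling (the method-variant axis).
#' @param side,z_dim,base Generator geometry (see [build_generator()]).
#' @param critic_widths Critic stage widths (see [build_critic()]).
#' @param perceptual_layer Grader layer used for the perceptual loss.
#' @param sigma_fine,sigma_coarse,q Lesion-extraction parameters used to
#'   compute the cached descriptors of the real images.
#' @param seed Master seed: initialization, batch order, noise and
#'   interpolates all derive from it.
#' @param checkpoint_every Write a checkpoint every so many generator steps
#'   (requires `out_dir`; `Inf` disables intermediate checkpoints).
#' @param log_every Record a history row every so many generator steps.
#' @return An object of class `train_config`.
#' @export
train_config <- function(steps = 500L, n_critic = 5L, batch_size = 16L,
                         lr = 2e-3, lr_critic = NULL, beta1 = 0, beta2 = 0.9,
                         weights = loss_weights(lambda_gp = 100),
                         resample = resample_spec("nearest"),
                         side = 64L, z_dim = 128L, base = 4L,
                         critic_widths = c(4L, 8L, 16L, 32L),
                         perceptual_layer = "stage2",
                         sigma_fine = 1, sigma_coarse = 4, q = 0.02,
                         seed = 1L, checkpoint_every = Inf, log_every = 1L) {
  if (steps < 1 || n_critic < 1 || batch_size < 1)
    stop_fundus("steps, n_critic and batch_size must be >= 1",
                "fundusgan_config_error")
  if (!inherits(resample, "resample_spec")) resample <- resample_spec(resample)
  structure(list(steps = as.integer(steps), n_critic = as.integer(n_critic),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_critic = lr_critic %||% (lr / 4),
                 beta1 = beta1, beta2 = beta2, weights = weights,
                 resample = resample, side = as.integer(side),
                 z_dim = as.integer(z_dim), base = as.integer(base),
                 critic_widths = as.integer(critic_widths),
                 perceptual_layer = perceptual_layer,
                 sigma_fine = sigma_fine, sigma_coarse = sigma_coarse, q = q,
                 seed = as.integer(seed), checkpoint_every = checkpoint_every,
                 log_every = as.integer(log_every)),
            class = "train_config")
}

CKPT_VERSION <- "fundusgan-checkpoint-1"

#' Save / load a training checkpoint
#'
#' A checkpoint bundles generator and critic parameters, both optimizer
#' states, the configuration, the step counter, the history so far and the
#' random-stream position, so a resumed run reproduces the unbroken run
#' exactly. `save -> load -> save` is byte-identical.
#'
#' @param state A checkpoint state (as found in the `$checkpoint` element of
#'   a [train_gan()] result).
#' @param path File path (`.rds`).
#' @return `load_checkpoint` returns the state.
#' @export
save_checkpoint <- function(state, path) {
  if (!identical(state$version, CKPT_VERSION))
    stop_fundus("not a fundusgan checkpoint state", "fundusgan_config_error")
  saveRDS(state, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- tryCatch(readRDS(path), error = function(e)
    stop_fundus(paste0("corrupt or unreadable checkpoint: ", path, " (",
                       conditionMessage(e), ")"), "fundusgan_io_error"))
  if (!is.list(state) || !identical(state$version, CKPT_VERSION))
    stop_fundus(paste0("incompatible checkpoint version in ", path),
                "fundusgan_version_error")
  state
}

# Condition stacks (vessel mask + fine/coarse lesion descriptors) for every
# image of a training pool. Equivalent to extract_lesions() per image, with
# the grader passes chunk-batched and the smoothing matrices shared.
condition_stack_cached <- function(grader, x_all, y_all,
                                   sigma_fine, sigma_coarse, q) {
  side <- dim(x_all)[1]
  n <- dim(x_all)[4]
  cond_all <- array(0, c(side, side, 3L, n))
  Mf <- reflect_filter_matrix(side, gaussian_kernel(sigma_fine))
  Mc <- reflect_filter_matrix(side, gaussian_kernel(sigma_coarse))
  for (at in seq(1L, n, by = 32L)) {
    ii <- at:min(at + 31L, n)
    xb <- x_all[, , , ii, drop = FALSE]
    fw <- grader_forward(grader, xb, cache = TRUE)
    gr <- grader_backward_input(grader, fw, matrix(1, length(ii), 1))
    for (j in seq_along(ii)) {
      i <- ii[j]
      sal <- abs(gr[, , 1, j]) + abs(gr[, , 2, j]) + abs(gr[, , 3, j])
      img <- xb[, , , j]
      fov <- pmax(img[, , 1], img[, , 2], img[, , 3]) > 0.01
      if (!any(fov)) fov <- matrix(TRUE, side, side)
      bin <- function(M) {
        if (max(sal) == 0) return(matrix(0, side, side))
        sm <- M %*% sal %*% t(M)
        thr <- as.numeric(quantile(sm[fov], 1 - q, type = 7))
        ((sm >= thr - 1e-9 * max(sm)) & fov) * 1
      }
      cond_all[, , , i] <- c(y_all[, , 1, i], bin(Mf), bin(Mc))
    }
  }
  cond_all
}

# Gradient of the perceptual + severity style losses with respect to x_hat
# against precomputed real-image targets, with a single grader forward on
# x_hat whose trunk caches serve both losses. The grader stays frozen.
style_grad_cached <- function(grader, p_idx, x_hat, dr_tgt, feat_tgt,
                              wp, ws) {
  n <- dim(x_hat)[4]
  dxh <- array(0, dim(x_hat))
  lp <- 0; ls <- 0
  fh <- grader_forward(grader, x_hat, cache = TRUE)
  if (wp > 0) {
    if (p_idx == 0L) {
      diff <- x_hat - feat_tgt
      lp <- mean(diff^2)
      dxh <- dxh + wp * 2 * diff / length(diff)
    } else {
      k <- 2L * p_idx
      fxh <- if (k < length(grader$trunk$layers))
        fh$trunk$cache[[k + 1L]]$input
      else seq_forward(grader$trunk, as_batch(x_hat) - 0.5)$out
      diff <- fxh - feat_tgt
      lp <- mean(diff^2)
      dF <- 2 * diff / length(diff)
      sub <- nn_net(grader$trunk$layers[seq_len(k)])
      dxh <- dxh + wp * seq_backward(sub, fh$trunk$cache[seq_len(k)], dF,
                                     need_param_grads = FALSE)$dx
    }
  }
  if (ws > 0) {
    ph <- fh$pred
    ls <- mean(abs(dr_tgt - ph))
    dpred <- matrix(-sign(dr_tgt - ph) / n, n, 1)
    dxh <- dxh + ws * grader_backward_input(grader, fh, dpred)
  }
  list(dxh = dxh, perceptual = lp, severity = ls)
}

#' Train the conditional WGAN-GP
#'
#' @param data A list of `fundus_sample` objects (images, vessel masks,
#'   grades) or a manifest path; needs at least `batch_size` samples.
#' @param grader A trained `dr_grader`; provides the lesion descriptors of
#'   the real images (computed once and cached), the severity scores and the
#'   perceptual features. Never updated.
#' @param config A [train_config()].
#' @param out_dir Optional directory for checkpoints and `history.csv`.
#' @param resume Optional checkpoint state (or path) to continue from; the
#'   run proceeds to `config$steps` total generator updates and reproduces
#'   the unbroken run's history exactly.
#' @param verbose Print progress every 25 generator steps.
#' @return A list with the trained `generator`, `critic`, the step-indexed
#'   `history` data frame (columns `step, LW, penalty, Lpercept, Lseverity,
#'   LG, grad_norm`), the final `checkpoint` state and `config`.
#'   If any loss turns non-finite the run aborts with an error of class
#'   `fundusgan_nan_error` carrying the last good checkpoint and history.
#' @export
train_gan <- function(data, grader, config, out_dir = NULL, resume = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), inherits(grader, "dr_grader"))
  samples <- resolve_samples(data)
  n <- length(samples)
  if (n < config$batch_size)
    stop_fundus("need at least batch_size samples", "fundusgan_config_error")
  side <- config$side
  x_all <- sample_images(samples, side)
  y_all <- as_batch(lapply(samples, function(s)
    array(if (all(dim(s$vessel_mask) == side)) s$vessel_mask
          else (resize(s$vessel_mask, side, side, "nearest") > 0.5) * 1,
          c(side, side, 1L))))
  # lesion descriptors of the real images: computed once, frozen
  cond_all <- condition_stack_cached(grader, x_all, y_all,
                                     config$sigma_fine, config$sigma_coarse,
                                     config$q)
  # style-transfer targets of the real images are likewise fixed: severity
  # scores and perceptual feature maps of a frozen grader (chunked batches
  # keep the conv workspace cache-sized)
  p_idx <- grader_layer_index(grader, config$perceptual_layer)
  dr_real <- numeric(n)
  feat_real <- NULL
  for (at in seq(1L, n, by = 32L)) {
    ii <- at:min(at + 31L, n)
    xb <- x_all[, , , ii, drop = FALSE]
    dr_real[ii] <- grader_forward(grader, xb)
    fb <- if (p_idx == 0L) xb
          else grader_features(grader, xb, config$perceptual_layer)
    if (is.null(feat_real)) {
      fd <- dim(fb)
      feat_real <- array(0, c(fd[1:3], n))
    }
    feat_real[, , , ii] <- fb
  }

  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old_seed, envir = globalenv())
  })

  if (is.null(resume)) {
    set.seed(config$seed)
    gen <- build_generator(side, config$z_dim, config$base, config$resample,
                           seed = derive_seed(config$seed, 1L, 21L))
    critic <- build_critic(side, 4L, config$critic_widths,
                           seed = derive_seed(config$seed, 2L, 21L))
    opt_g <- adam_init(gen$layers)
    opt_c <- adam_init(critic$net$layers)
    step0 <- 0L
    hist <- list()
    queue <- integer(0)
  } else {
    if (is.character(resume)) resume <- load_checkpoint(resume)
    gen <- resume$generator; critic <- resume$critic
    opt_g <- resume$opt_g; opt_c <- resume$opt_c
    step0 <- resume$step
    hist <- resume$history_rows
    queue <- resume$queue
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }

  npx <- prod(c(side, side, 3L))
  next_batch <- function() {
    while (length(queue) < config$batch_size)
      queue <<- c(queue, sample(n))
    idx <- queue[seq_len(config$batch_size)]
    queue <<- queue[-seq_len(config$batch_size)]
    idx
  }
  make_state <- function(step) {
    list(version = CKPT_VERSION, step = step, generator = gen,
         critic = critic, opt_g = opt_g, opt_c = opt_c, config = config,
         history_rows = hist, queue = queue,
         rng_state = get(".Random.seed", envir = globalenv()))
  }
  last_good <- make_state(step0)

  steps_todo <- if (step0 >= config$steps) integer(0)
                else (step0 + 1L):config$steps
  for (step in steps_todo) {
    lw_acc <- pen_acc <- gn_acc <- 0
    nb <- config$batch_size
    for (j in seq_len(config$n_critic)) {
      idx <- next_batch()
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[, , , idx, drop = FALSE]
      z <- matrix(rnorm(nb * config$z_dim), nb, config$z_dim)
      # fakes are held fixed during the critic update: no caches needed
      x_hat <- generator_infer(gen, cond_all[, , , idx, drop = FALSE], z)

      # one batched pass over [real; fake] for the Wasserstein term
      xin <- array(c(xb, x_hat), c(side, side, 3L, 2L * nb))
      yin <- array(c(yb, yb), c(side, side, 1L, 2L * nb))
      frf <- seq_forward(critic$net, critic_input(critic, xin, yin))
      g_rf <- seq_backward(critic$net, frf$cache,
                           matrix(c(rep(-1 / nb, nb), rep(1 / nb, nb)),
                                  ncol = 1),
                           need_dx = FALSE)$grads
      gp <- gp_compute(critic, xb, x_hat, yb,
                       seed = sample.int(2147483629L, 1L),
                       param_grads = TRUE)
      grads <- grads_add(g_rf,
                         grads_scale(gp$grads, config$weights$lambda_gp))
      lw <- mean(frf$out[seq_len(nb)]) - mean(frf$out[nb + seq_len(nb)])
      if (!all(is.finite(c(lw, gp$penalty))))
        stop(structure(class = c("fundusgan_nan_error", "fundusgan_error",
                                 "error", "condition"),
                       list(message = sprintf(
                         "non-finite critic loss at generator step %d", step),
                         call = NULL, checkpoint = last_good,
                         history = do.call(rbind, hist))))
      upd <- adam_step(critic$net$layers, grads, opt_c, config$lr_critic,
                       config$beta1, config$beta2)
      critic$net$layers <- upd$layers; opt_c <- upd$state
      lw_acc <- lw_acc + lw
      pen_acc <- pen_acc + gp$penalty
      gn_acc <- gn_acc + mean(gp$grad_norms)
    }

    idx <- next_batch()
    xb <- x_all[, , , idx, drop = FALSE]
    yb <- y_all[, , , idx, drop = FALSE]
    condb <- cond_all[, , , idx, drop = FALSE]
    nb <- config$batch_size
    z <- matrix(rnorm(nb * config$z_dim), nb, config$z_dim)
    gf <- generator_forward(gen, condb, z)
    x_hat <- gf$out
    fc <- seq_forward(critic$net, critic_input(critic, x_hat, yb))
    adv <- -mean(fc$out)
    dxh <- seq_backward(critic$net, fc$cache, matrix(-1 / nb, nb, 1),
                        need_param_grads = FALSE)$dx[, , 1:3, , drop = FALSE]
    st <- style_grad_cached(grader, p_idx, x_hat,
                            dr_real[idx], feat_real[, , , idx, drop = FALSE],
                            config$weights$wp, config$weights$ws)
    lg <- adv + config$weights$wp * st$perceptual +
      config$weights$ws * st$severity
    if (!is.finite(lg))
      stop(structure(class = c("fundusgan_nan_error", "fundusgan_error",
                               "error", "condition"),
                     list(message = sprintf(
                       "non-finite generator loss at step %d", step),
                       call = NULL, checkpoint = last_good,
                       history = do.call(rbind, hist))))
    ggrads <- generator_backward(gen, gf$cache, dxh + st$dxh)
    upd <- adam_step(gen$layers, ggrads, opt_g, config$lr,
                     config$beta1, config$beta2)
    gen$layers <- upd$layers; opt_g <- upd$state

    if (step %% config$log_every == 0L)
      hist[[length(hist) + 1L]] <- data.frame(
        step = step, LW = lw_acc / config$n_critic,
        penalty = pen_acc / config$n_critic,
        Lpercept = st$perceptual, Lseverity = st$severity, LG = lg,
        grad_norm = gn_acc / config$n_critic)
    last_good <- make_state(step)
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %d | LW %.4f | pen %.4f | LG %.4f | |grad| %.3f",
                      step, lw_acc / config$n_critic,
                      pen_acc / config$n_critic, lg, gn_acc / config$n_critic))
    if (!is.null(out_dir) && is.finite(config$checkpoint_every) &&
        step %% config$checkpoint_every == 0L)
      save_checkpoint(last_good, file.path(out_dir,
                                           sprintf("ckpt_%06d.rds", step)))
  }

  history <- do.call(rbind, hist)
  if (!is.null(out_dir)) {
    save_checkpoint(last_good, file.path(out_dir, "ckpt_final.rds"))
    write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  list(generator = gen, critic = critic, history = history,
       checkpoint = last_good, config = config)
}
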