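# Deterministic CPU training loop: Adam with weight decay, deep-supervised
# fused loss over the prediction pyramid, per-step metric logging and
# best-validation checkpointing.

#' Training configuration
#'
#' Defaults follow the reference optimisation settings: Adam, learning rate
#' 1e-4, weight decay 1e-4, batch size 16, 100 epochs.
#'
#' @param learning_rate Adam step size (constant unless `lr_schedule` given).
#' @param lr_schedule Optional `function(step) -> rate` overriding the
#'   constant rate, e.g. a piecewise drop for short overfitting runs where
#'   the rank-loss gradient noise sets a rate-proportional error floor.
#' @param weight_decay L2 penalty added to gradients.
#' @param batch_size Samples per optimisation step.
#' @param epochs Maximum epochs.
#' @param max_steps Optional cap on total optimisation steps.
#' @param seed Integer seed controlling initialisation and data order.
#' @param loss A [loss_config()].
#' @param model A [prt_model_config()].
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         batch_size = 16L, epochs = 100L, max_steps = Inf,
                         seed = 1L, loss = loss_config(),
                         model = prt_model_config(),
                         split_fractions = c(69, 22, 13) / 104,
                         lr_schedule = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1, epochs >= 1,
            abs(sum(split_fractions) - 1) < 1e-8,
            is.null(lr_schedule) || is.function(lr_schedule))
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_schedule = lr_schedule,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 max_steps = max_steps, seed = as.integer(seed), loss = loss,
                 model = model, split_fractions = split_fractions,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Split a cohort into train/validation/test
#'
#' Disjoint, exhaustive, seed-reproducible random split. Counts are
#' `round(f * n)` for the first two fractions with the remainder assigned to
#' the test set (104 cases at fractions 69/22/13 of 104 give exactly
#' 69/22/13).
#'
#' @param cases List (or vector) of cases.
#' @param fractions Three fractions summing to 1.
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
split_cohort <- function(cases, fractions = c(69, 22, 13) / 104, seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- length(cases)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1) stop("split produces an empty partition")
  set.seed(seed)
  perm <- sample.int(n)
  list(train = cases[perm[seq_len(n_train)]],
       val = cases[perm[n_train + seq_len(n_val)]],
       test = cases[perm[n_train + n_val + seq_len(n_test)]])
}

# Adam update over the model's parameter registry; state kept per parameter
adam_init <- function(params) {
  lapply(params, function(p) list(m = p$val * 0, v = p$val * 0))
}

adam_step <- function(params, state, t, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad + wd * p$val
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
    state[[nm]] <- st
  }
  state
}

sample_loss_node <- function(tp, model, sample, loss_cfg, training = TRUE) {
  batch_loss_node(tp, model, list(sample), loss_cfg, training = training)
}

# One stacked forward pass for a whole minibatch (batch-norm statistics are
# computed over the batch); losses are evaluated per sample on row slices of
# the pyramid (the rank loss sorts within samples) and averaged.
batch_loss_node <- function(tp, model, samples, loss_cfg, training = TRUE) {
  B <- length(samples)
  X <- do.call(rbind, lapply(samples, function(s) {
    t(matrix(s$input, nrow = dim(s$input)[1]))
  }))
  out <- model_forward(tp, model, X, training = training, B = B)
  terms <- vector("list", B)
  for (b in seq_len(B)) {
    pyr_b <- if (B == 1L) out$pyramid else lapply(1:4, function(i) {
      L <- model$head_sides[i]^2
      ad_gather_rows(tp, out$pyramid[[i]], (b - 1L) * L + seq_len(L))
    })
    terms[[b]] <- ad_deep_supervised_loss(tp, pyr_b, samples[[b]]$target,
                                          samples[[b]]$ptv_mask, loss_cfg)
  }
  if (B == 1L) terms[[1]] else ad_scale(tp, ad_addn(tp, terms), 1 / B)
}

#' Evaluate the deep-supervised loss of a model on samples (no training)
#'
#' @param model A [prt_net()].
#' @param samples List of `triplet_sample`s.
#' @param loss_cfg A [loss_config()].
#' @param training Normalisation mode passed to the forward pass (TRUE,
#'   `"batch"` or FALSE; see [prt_forward()]).
#' @return Mean loss over the samples.
#' @export
evaluate_loss <- function(model, samples, loss_cfg = loss_config(),
                          training = FALSE) {
  vals <- vapply(samples, function(s) {
    tp <- new_tape()
    nv(sample_loss_node(tp, model, s, loss_cfg, training = training))
  }, 1.0)
  mean(vals)
}

#' Train the network
#'
#' Runs seeded minibatch Adam over per-slice triplet samples. Each step
#' averages the deep-supervised fused loss over the batch and applies one
#' optimiser update. Training aborts with a diagnostic if the loss becomes
#' non-finite. When validation samples are given, the returned checkpoint is
#' the one with the best validation loss (evaluated once per epoch);
#' otherwise it is the final state.
#'
#' @param samples Training samples (list of `triplet_sample`).
#' @param config A [train_config()].
#' @param model Optional pre-built [prt_net()]; built from
#'   `config$model` and `config$seed` when NULL.
#' @param val_samples Optional validation samples.
#' @return List with `model`, `checkpoint`, `log` (data.frame of per-step
#'   train losses and per-epoch validation losses), `steps`.
#' @export
train_model <- function(samples, config = train_config(), model = NULL,
                        val_samples = NULL) {
  stopifnot(length(samples) >= 1L)
  if (is.null(model)) model <- prt_net(config$model, seed = config$seed)
  state <- adam_init(model$params)
  set.seed(config$seed + 1L)
  n <- length(samples)
  step <- 0L
  log_step <- integer(0); log_epoch <- integer(0); log_loss <- numeric(0)
  val_log <- data.frame(epoch = integer(0), val_loss = numeric(0))
  best_val <- Inf
  best_ckpt <- NULL
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      if (step >= config$max_steps) break
      tp <- new_tape()
      total <- batch_loss_node(tp, model, samples[b], config$loss, training = TRUE)
      lval <- nv(total)
      if (!is.finite(lval)) {
        stop(sprintf("training diverged: non-finite loss %g at step %d", lval, step + 1L))
      }
      ad_backward(tp, total)
      step <- step + 1L
      lr_now <- if (is.null(config$lr_schedule)) config$learning_rate else {
        config$lr_schedule(step)
      }
      state <- adam_step(model$params, state, step, lr_now,
                         config$weight_decay)
      log_step <- c(log_step, step)
      log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, lval)
    }
    if (!is.null(val_samples)) {
      vl <- evaluate_loss(model, val_samples, config$loss)
      val_log <- rbind(val_log, data.frame(epoch = epoch, val_loss = vl))
      if (vl < best_val) {
        best_val <- vl
        best_ckpt <- prt_checkpoint(model)
      }
    }
    if (config$verbose) {
      message(sprintf("epoch %d  step %d  train loss %.6f", epoch, step,
                      log_loss[length(log_loss)]))
    }
    if (step >= config$max_steps) break
  }
  if (is.null(best_ckpt)) best_ckpt <- prt_checkpoint(model)
  list(model = model, checkpoint = best_ckpt,
       log = data.frame(step = log_step, epoch = log_epoch, train_loss = log_loss),
       val_log = val_log, steps = step)
}

#' Predict a full 3D dose volume for a case
#'
#' Builds the per-slice triplets exactly as in training, runs the network in
#' deterministic inference mode, takes the full-resolution pyramid level,
#' removes padding, rescales by the recorded dose normalisation, clips at 0
#' and stacks the slices.
#'
#' @param model A trained [prt_net()] (or a checkpoint list).
#' @param case A `phantom_case`.
#' @param pad_size Padding used at preprocessing time (NULL for none); must
#'   match training.
#' @param stats Normalisation statistics: `"batch"` (default) normalises
#'   each slice by its own statistics, exactly as during optimisation;
#'   `"running"` uses the tracked running averages. Both are deterministic.
#' @return A [dose_grid()] on the case lattice.
#' @export
predict_volume <- function(model, case, pad_size = NULL,
                           stats = c("batch", "running")) {
  stats <- match.arg(stats)
  if (!inherits(model, "prt_net")) model <- prt_restore(model)
  samples <- build_triplets(case, pad_size = pad_size)
  d <- dim(case$dose$values)
  out <- array(0, dim = d)
  mode <- if (stats == "batch") "batch" else FALSE
  for (s in samples) {
    pyr <- prt_forward(model, s, training = mode)
    plane <- unpad_from_grid(pyr[[4]], s$orig_shape[1], s$orig_shape[2])
    out[, , s$slice] <- pmax(plane * s$dose_scale, 0)
  }
  dose_grid(out, spacing_mm = case$dose$spacing_mm)
}
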