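#' Training configuration
#'
#' Optimization protocol of the segmentation network: Adam with learning
#' rate 0.003, batch size 8, 150 epochs and seed 39 by default.
#'
#' @param lr Adam learning rate.
#' @param batch_size samples per optimizer step.
#' @param epochs passes over the training set.
#' @param max_steps optional cap on the total number of optimizer steps
#'   (useful for smoke tests and small-budget runs).
#' @param seed global seed covering weight initialization, data order and
#'   augmentation.
#' @param augmentation list with logical flags `random_crop`, `hflip`,
#'   `vflip`.
#' @param loss a [loss_config()].
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.003, batch_size = 8L, epochs = 150L,
                         max_steps = NULL, seed = 39L,
                         augmentation = list(random_crop = FALSE,
                                             hflip = FALSE, vflip = FALSE),
                         loss = loss_config(),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  if (lr <= 0) stop("invalid config: lr must be > 0")
  if (batch_size < 1) stop("invalid config: batch_size must be >= 1")
  if (epochs < 1) stop("invalid config: epochs must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 seed = as.integer(seed), augmentation = augmentation,
                 loss = loss, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps), class = "train_config")
}

# bilinear resize of a matrix to (out_h, out_w), align-corners style
.bilinear_resize <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ri <- if (out_h == 1) rep(1, 1) else seq(1, h, length.out = out_h)
  ci <- if (out_w == 1) rep(1, 1) else seq(1, w, length.out = out_w)
  r0 <- pmin(floor(ri), h - 1L); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), w - 1L); c1 <- c0 + 1; fc <- ci - c0
  if (h == 1) { r0 <- r1 <- rep(1, out_h); fr <- rep(0, out_h) }
  if (w == 1) { c0 <- c1 <- rep(1, out_w); fc <- rep(0, out_w) }
  a <- m[r0, c0, drop = FALSE]; b <- m[r1, c0, drop = FALSE]
  cc <- m[r0, c1, drop = FALSE]; dd <- m[r1, c1, drop = FALSE]
  fr <- matrix(fr, out_h, out_w); fc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + cc * (1 - fr) * fc + dd * fr * fc
}

#' Augment a stack/mask pair
#'
#' Applies the same spatial transform to every channel of the stack and to
#' the mask: optional horizontal/vertical flips (axis reversals, each with
#' probability 1/2) and an optional random crop of side fraction uniform in
#' [0.8, 1], bilinearly resized back (nearest-neighbor for the mask).
#' Draws from R's RNG; with all flags disabled the pair is returned
#' unchanged.
#'
#' @param stack `(n, H, W)` array.
#' @param mask `H x W` binary matrix.
#' @param aug list of flags `random_crop`, `hflip`, `vflip`.
#' @return List with transformed `stack` and `mask`.
#' @export
augment <- function(stack, mask,
                    aug = list(random_crop = TRUE, hflip = TRUE, vflip = TRUE)) {
  d <- dim(stack)
  if (isTRUE(aug$hflip) && runif(1) < 0.5) {
    stack <- stack[, , d[3]:1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (isTRUE(aug$vflip) && runif(1) < 0.5) {
    stack <- stack[, d[2]:1, , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  if (isTRUE(aug$random_crop)) {
    frac <- runif(1, 0.8, 1)
    ch <- max(2L, round(frac * d[2])); cw <- max(2L, round(frac * d[3]))
    oh <- sample.int(d[2] - ch + 1L, 1L) - 1L
    ow <- sample.int(d[3] - cw + 1L, 1L) - 1L
    ns <- array(0, d)
    for (k in seq_len(d[1]))
      ns[k, , ] <- .bilinear_resize(stack[k, oh + seq_len(ch), ow + seq_len(cw)],
                                    d[2], d[3])
    mcrop <- mask[oh + seq_len(ch), ow + seq_len(cw), drop = FALSE]
    mask <- (.bilinear_resize(mcrop, d[2], d[3]) >= 0.5) * 1
    stack <- ns
  }
  list(stack = stack, mask = mask)
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(P) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- new.env(parent = emptyenv())
  opt$v <- new.env(parent = emptyenv())
  for (nm in ls(P)) {
    opt$m[[nm]] <- P[[nm]] * 0   # clones shape and dim attributes exactly
    opt$v[[nm]] <- P[[nm]] * 0
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(P, G, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in ls(P)) {
    g <- G[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}

# stack a list of samples into an (H, W, C, N) input and (H, W, 1, N) target
.make_batch <- function(samples, aug = NULL) {
  n <- length(samples)
  s1 <- samples[[1]]$stack
  d <- dim(s1)
  x <- array(0, c(d[2], d[3], d[1], n))
  y <- array(0, c(d[2], d[3], 1, n))
  for (i in seq_len(n)) {
    st <- samples[[i]]$stack
    mk <- samples[[i]]$mask
    if (!is.null(aug)) {
      a <- augment(st, mk, aug)
      st <- a$stack; mk <- a$mask
    }
    x[, , , i] <- aperm(st, c(2, 3, 1))
    y[, , 1, i] <- mk
  }
  list(x = x, y = y)
}

# mean slice-wise DPC of a model over a list of samples (inference mode)
.val_dpc <- function(model, samples, batch_size = 8L, threshold = 0.5) {
  if (length(samples) == 0) return(NA_real_)
  scores <- numeric(length(samples))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batch_size - 1L, length(samples))
    b <- .make_batch(samples[i:j])
    prob <- .model_fw(model, b$x, training = FALSE)$prob
    for (k in seq_len(j - i + 1L)) {
      pred <- (prob[, , 1, k] >= threshold) * 1
      gt <- b$y[, , 1, k]
      scores[i + k - 1L] <- dpc(array(gt, c(dim(gt), 1)),
                                array(pred, c(dim(pred), 1)))
    }
    i <- j + 1L
  }
  mean(scores)
}

#' Train a Res-Inception-SE U-Net
#'
#' Optimizes the hybrid Dice+BCE objective with Adam over 2.5D samples
#' (output of [preprocess_case()], concatenated across cases). Training is
#' fully seeded: weight initialization (if the model was built with the same
#' seed), shuffling and augmentation all draw from R's RNG, so identical
#' configurations reproduce identical loss curves. Per-epoch training loss
#' and validation DPC are recorded; the weights with the best validation
#' DPC are retained alongside the final weights.
#'
#' @param model a [ris_unet()] model (modified in place and returned).
#' @param train_samples list of samples (`stack`, `mask`).
#' @param val_samples optional validation samples for DPC tracking.
#' @param cfg a [train_config()].
#' @param log_path optional CSV path for the per-epoch log.
#' @param verbose print per-epoch lines to stderr.
#' @return An object of class `risunet_fit` with elements `model`,
#'   `best_params` (weights at the best validation DPC), `history`
#'   (data frame: epoch, step, train_loss, val_dpc) and `config`.
#' @export
train_risunet <- function(model, train_samples, val_samples = list(),
                          cfg = train_config(), log_path = NULL,
                          verbose = FALSE) {
  if (length(train_samples) == 0) stop("empty training set")
  set.seed(cfg$seed)
  opt <- .adam_init(model$P)
  steps_per_epoch <- max(1L, ceiling(length(train_samples) / cfg$batch_size))
  total_cap <- cfg$max_steps %||% (cfg$epochs * steps_per_epoch)
  history <- NULL
  best <- list(dpc = -Inf, params = NULL, state = NULL)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train_samples))
    losses <- c()
    for (bi in seq_len(steps_per_epoch)) {
      if (step >= total_cap) break
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size,
                                                       length(ord))]
      aug <- if (any(unlist(cfg$augmentation))) cfg$augmentation else NULL
      b <- .make_batch(train_samples[idx], aug)
      fw <- .model_fw(model, b$x, training = TRUE)
      loss <- hybrid_loss(fw$prob, b$y, cfg$loss)
      if (!is.finite(loss))
        stop(sprintf("training diverged: non-finite loss at step %d", step + 1L))
      gprob <- hybrid_loss_grad(fw$prob, b$y, cfg$loss)
      G <- .model_bw(model, fw$cache, gprob)
      .adam_step(model$P, G, opt, cfg$lr, cfg$beta1, cfg$beta2, cfg$adam_eps)
      losses <- c(losses, loss)
      step <- step + 1L
    }
    vd <- .val_dpc(model, val_samples, cfg$batch_size)
    history <- rbind(history,
                     data.frame(epoch = epoch, step = step,
                                train_loss = mean(losses), val_dpc = vd))
    if (verbose)
      message(sprintf("epoch %d step %d loss %.4f val_dpc %s", epoch, step,
                      mean(losses), ifelse(is.na(vd), "NA", sprintf("%.3f", vd))))
    if (!is.na(vd) && vd > best$dpc)
      best <- list(dpc = vd, params = as.list(model$P), state = as.list(model$S))
    if (step >= total_cap) break
  }
  if (!is.null(log_path)) utils::write.csv(history, log_path, row.names = FALSE)
  fit <- structure(list(model = model, best_params = best$params,
                        best_state = best$state, best_val_dpc = best$dpc,
                        history = history, config = cfg),
                   class = "risunet_fit")
  fit
}

#' Read a training configuration from YAML
#'
#' Parses a YAML file with top-level `train_config` fields; a nested `loss`
#' block (`alpha`, `beta`, `smooth`, `clamp_eps`) becomes the
#' [loss_config()] and a nested `augmentation` block sets the flags. Absent
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return A [train_config()].
#' @export
read_train_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  loss <- do.call(loss_config, y$loss %||% list())
  aug <- utils::modifyList(list(random_crop = FALSE, hflip = FALSE,
                                vflip = FALSE), y$augmentation %||% list())
  args <- y[setdiff(names(y), c("loss", "augmentation"))]
  do.call(train_config, c(args, list(loss = loss, augmentation = aug)))
}

#' Restore the best-validation weights of a fit
#'
#' @param fit a `risunet_fit`.
#' @return The fitted `ris_unet` with its best-validation-DPC weights (the
#'   final weights if no validation set was used).
#' @export
best_model <- function(fit) {
  m <- fit$model
  if (!is.null(fit$best_params)) {
    m <- structure(list(config = m$config,
                        P = list2env(fit$best_params, parent = emptyenv()),
                        S = list2env(fit$best_state, parent = emptyenv())),
                   class = "ris_unet")
  }
  m
}

#' @export
print.risunet_fit <- function(x, ...) {
  h <- x$history
  cat("<risunet_fit>\n")
  cat(sprintf("  %d epochs, %d optimizer steps\n", max(h$epoch), max(h$step)))
  cat(sprintf("  final training loss: %.4f\n", tail(h$train_loss, 1)))
  if (any(!is.na(h$val_dpc)))
    cat(sprintf("  best validation DPC: %.3f\n", max(h$val_dpc, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.risunet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$train_loss, type = "l", xlab = "optimizer step",
                 ylab = "training loss", main = "Training curve", ...)
  invisible(x)
}

#' Segment a full CT volume
#'
#' Applies the training-time preprocessing to every slice (tumor-slice
#' filtering is a training-set operation and is disabled here), builds a
#' 2.5D stack per slice, thresholds the sigmoid output at 0.5 and
#' re-assembles a full-size 3-d mask, zero-padding the cropped border back
#' to the original in-plane size. Predictions are independent per slice, so
#' the result does not depend on how slices are batched.
#'
#' @param model a trained `ris_unet`.
#' @param vol a `ct_volume` in HU (raw, not preprocessed).
#' @param cfg a [preprocess_config()]; its `n_slices` must match the model.
#' @param batch_size slices per forward pass.
#' @param threshold binarization threshold (default 0.5).
#' @return Binary mask array with the volume's original dimensions.
#' @export
predict_volume <- function(model, vol, cfg = preprocess_config(),
                           batch_size = 8L, threshold = 0.5) {
  if (cfg$n_slices != model$config$n_slices)
    stop(sprintf("config n_slices = %d but model expects %d",
                 cfg$n_slices, model$config$n_slices))
  v <- .vol_data(vol)
  d <- dim(v)
  proc <- .preprocess_slices(v, cfg)
  out <- array(0, d)
  off <- (d[1:2] - cfg$crop_size) %/% 2L
  t <- 1L
  while (t <= d[3]) {
    te <- min(t + batch_size - 1L, d[3])
    stacks <- lapply(t:te, function(s) build_stack(proc, s, cfg$n_slices))
    xb <- .as_input_batch(stacks, cfg$n_slices)
    prob <- .model_fw(model, xb, training = FALSE)$prob
    for (k in seq_len(te - t + 1L)) {
      out[off[1] + seq_len(cfg$crop_size), off[2] + seq_len(cfg$crop_size),
          t + k - 1L] <- (prob[, , 1, k] >= threshold) * 1
    }
    t <- te + 1L
  }
  out
}

#' Slice-count experiment harness
#'
#' Trains one model per value of `n_slices` with identical settings and
#' seed, evaluates each on the shared test split, and returns one row of
#' metrics per `n` (the layout of a slice-count comparison table).
#'
#' @param n_values odd slice counts to compare (default `c(1, 3, 5, 7)`).
#' @param dataset output of [generate_dataset()].
#' @param model_base `model_config` template; `n_slices` is overridden
#'   per run.
#' @param pre_cfg `preprocess_config` template; `n_slices` overridden.
#' @param train_cfg a [train_config()].
#' @param path optional CSV output path.
#' @return Data frame with columns `n_slices`, `dpc`, `voe`, `ravd`,
#'   `assd`, `rmsd`.
#' @export
run_slice_grid <- function(n_values = c(1L, 3L, 5L, 7L), dataset,
                           model_base = model_config(base_channels = 8),
                           pre_cfg = preprocess_config(crop_size = 48),
                           train_cfg = train_config(max_steps = 50),
                           path = NULL) {
  if (any(n_values %% 2L == 0L)) stop("invalid config: slice counts must be odd")
  rows <- lapply(n_values, function(n) {
    mcfg <- model_config(n_slices = n, depth = model_base$depth,
                         channel_plan = model_base$channel_plan,
                         se_reduction = model_base$se_reduction)
    pcfg <- preprocess_config(hu_lo = pre_cfg$hu_lo, hu_hi = pre_cfg$hu_hi,
                              crop_size = pre_cfg$crop_size, n_slices = n,
                              equalize = pre_cfg$equalize,
                              keep_only_tumor_slices = pre_cfg$keep_only_tumor_slices)
    model <- ris_unet(mcfg, seed = train_cfg$seed)
    tr <- unlist(lapply(dataset$splits$train, function(i)
      preprocess_case(dataset$cases[[i]]$volume, dataset$cases[[i]]$tumor, pcfg)),
      recursive = FALSE)
    va <- unlist(lapply(dataset$splits$validation, function(i)
      preprocess_case(dataset$cases[[i]]$volume, dataset$cases[[i]]$tumor, pcfg)),
      recursive = FALSE)
    fit <- train_risunet(model, tr, va, train_cfg)
    m <- best_model(fit)
    reports <- lapply(dataset$splits$test, function(i) {
      pred <- predict_volume(m, dataset$cases[[i]]$volume, pcfg)
      evaluate_case(dataset$cases[[i]]$tumor, pred,
                    dataset$cases[[i]]$volume$spacing,
                    case_id = sprintf("case%03d", i))
    })
    df <- do.call(rbind, reports)
    data.frame(n_slices = n,
               dpc = mean(df$dpc, na.rm = TRUE),
               voe = mean(df$voe, na.rm = TRUE),
               ravd = mean(df$ravd, na.rm = TRUE),
               assd = mean(df$assd, na.rm = TRUE),
               rmsd = mean(df$rmsd, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
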