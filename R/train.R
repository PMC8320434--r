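#' Dice loss
#'
#' Soft dice loss between a reference segmentation and a predicted
#' probability map:
#' `1 - 2 * sum(s_true * s_pred) / (sum(s_true^2) + sum(s_pred^2))`.
#' For binary inputs this is exactly `1 - DSC` (see [dsc()]). An optional
#' additive smoothing constant in numerator and denominator guards the
#' degenerate case where both grids are empty (as happens for background
#' training patches); with `smooth = 0` that case is defined as 0 (a
#' perfect match of two empty segmentations).
#'
#' @param s_true,s_pred Arrays of identical shape with values in `[0, 1]`.
#' @param smooth Additive smoothing constant (default 0; training uses 1).
#' @return Scalar loss in `[0, 1]`.
#' @examples
#' a <- array(c(1, 1, 0, 0), c(1, 2, 2))
#' dice_loss(a, a)
#' @export
dice_loss <- function(s_true, s_pred, smooth = 0) {
  if (!identical(dim(s_true) %||% length(s_true),
                 dim(s_pred) %||% length(s_pred)))
    stop_raunet("dice_loss: shape mismatch", "raunet_shape_mismatch")
  num <- 2 * sum(s_true * s_pred) + smooth
  den <- sum(s_true^2) + sum(s_pred^2) + smooth
  if (den == 0) return(0)
  1 - num / den
}

# analytic gradient of dice_loss w.r.t. s_pred (used by the training loop)
dice_loss_grad <- function(s_true, s_pred, smooth = 1) {
  num <- 2 * sum(s_true * s_pred) + smooth
  den <- sum(s_true^2) + sum(s_pred^2) + smooth
  g <- -(2 * s_true * den - num * 2 * s_pred) / den^2
  dim(g) <- dim(s_pred)
  g
}

#' Training configuration
#'
#' Bundles the optimisation protocol: Adam with an initial learning rate of
#' 1e-4, up to 1500 epochs, early stopping after 500 epochs without
#' improvement, and learning-rate reduction to `lr_factor` of its value
#' when the monitored loss has not improved for `plateau_patience` epochs
#' (floor `lr_floor`). `lr_factor` defaults to 0.1; the printed protocol
#' ("by a factor of 10%") is ambiguous between x0.1 and x0.9, so the factor
#' is a configuration knob.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param max_epochs Maximum number of training epochs.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param plateau_patience Epochs without improvement before the learning
#'   rate is reduced.
#' @param lr_factor Multiplicative learning-rate reduction on plateau.
#' @param lr_floor Smallest learning rate the schedule may reach.
#' @param batch_size Samples per optimisation step (10 slices for the 2D
#'   model, 72 patches for the 3D models in the full-scale protocol).
#' @param val_fraction Fraction of samples held out to monitor the loss
#'   (0 monitors the training loss instead).
#' @param loss_smooth Dice-loss smoothing constant used during training.
#' @param seed Integer seed governing all training randomness.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 1500,
                         early_stop_patience = 500, plateau_patience = 20,
                         lr_factor = 0.1, lr_floor = 1e-6, batch_size = 10,
                         val_fraction = 0.1, loss_smooth = 1, seed = 42) {
  stopifnot(learning_rate > 0, max_epochs >= 1, early_stop_patience >= 1,
            plateau_patience >= 1, lr_factor > 0, lr_factor <= 1,
            batch_size >= 1, val_fraction >= 0, val_fraction < 1)
  structure(
    list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         plateau_patience = as.integer(plateau_patience),
         lr_factor = lr_factor, lr_floor = lr_floor,
         batch_size = as.integer(batch_size), val_fraction = val_fraction,
         loss_smooth = loss_smooth, seed = as.integer(seed)),
    class = "train_config"
  )
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a residual-attention U-Net
#'
#' Optimises the dice loss with Adam. Samples are `(input, target)` pairs
#' of identical spatial shape — 2D slices for the slice-wise liver model,
#' 3D patches for the lesion models. A fraction of samples can be held out
#' as a validation split whose loss is monitored for the plateau
#' learning-rate schedule and early stopping; otherwise the training loss
#' is monitored. All randomness (validation split, shuffling) derives from
#' `cfg$seed`, making runs bit-reproducible.
#'
#' @param model An `ra_unet_model` from [build_network()].
#' @param samples List of `list(input =, target =)` pairs, or a generator
#'   `function(epoch)` returning such a list (fresh patches per epoch).
#' @param cfg A [train_config()].
#' @param verbose Print a progress line every `verbose` epochs (0 = quiet).
#' @return The model with trained weights and a `history` data frame
#'   (epoch, train_loss, monitor_loss, lr) attached as `model$history`.
#' @export
train <- function(model, samples, cfg = train_config(), verbose = 0) {
  stopifnot(inherits(model, "ra_unet_model"), inherits(cfg, "train_config"))
  gen <- if (is.function(samples)) samples else function(epoch) samples
  set.seed(cfg$seed)

  fixed <- !is.function(samples)
  val <- list()
  trn <- NULL
  if (fixed) {
    if (length(samples) == 0)
      stop_raunet("no training samples provided", "raunet_no_samples")
    n <- length(samples)
    n_val <- if (cfg$val_fraction > 0) max(0L, floor(cfg$val_fraction * n))
             else 0L
    if (n_val > 0 && n - n_val >= 1) {
      vi <- sample.int(n, n_val)
      val <- samples[vi]
      trn <- samples[-vi]
    } else {
      trn <- samples
    }
  }

  opt <- adam_init(model$params)
  lr <- cfg$learning_rate
  best <- Inf
  since_best <- 0L
  since_plateau <- 0L
  hist <- vector("list", cfg$max_epochs)

  batch_loss_grad <- function(batch, update) {
    x <- stack_batch(lapply(batch, `[[`, "input"))
    y <- stack_batch(lapply(batch, `[[`, "target"))
    fwd <- forward_graph(model, x, training = TRUE, keep = update)
    if (update) model$state <<- fwd$state
    loss <- dice_loss(y, fwd$out, smooth = cfg$loss_smooth)
    if (!is.finite(loss))
      stop_raunet("non-finite training loss; aborting", "raunet_diverged")
    if (update) {
      dout <- dice_loss_grad(y, fwd$out, smooth = cfg$loss_smooth)
      grads <- backward_graph(model, fwd, dout)
      st <- adam_step(model$params, grads, opt, lr)
      model$params <<- st$params
      opt <<- st$opt
    }
    loss
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    if (!fixed) {
      trn <- gen(epoch)
      if (length(trn) == 0)
        stop_raunet("sample generator returned no samples",
                    "raunet_no_samples")
    }
    ord <- sample.int(length(trn))
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      losses <- c(losses, batch_loss_grad(trn[b], update = TRUE))
    }
    train_loss <- mean(losses)
    monitor <- if (length(val) > 0) {
      vl <- vapply(split(seq_along(val),
                         ceiling(seq_along(val) / cfg$batch_size)),
                   function(b) batch_loss_grad(val[b], update = FALSE),
                   numeric(1))
      mean(vl)
    } else train_loss

    if (monitor < best - 1e-6) {
      best <- monitor
      since_best <- 0L
      since_plateau <- 0L
    } else {
      since_best <- since_best + 1L
      since_plateau <- since_plateau + 1L
    }
    if (since_plateau >= cfg$plateau_patience) {
      lr <- max(lr * cfg$lr_factor, cfg$lr_floor)
      since_plateau <- 0L
    }
    # the recorded lr is the schedule state after this epoch's update, so an
    # unbroken plateau shows the reduction at epoch plateau_patience + 1
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                monitor_loss = monitor, lr = lr)
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %4d  loss %.4f  monitor %.4f  lr %.2g",
                      epoch, train_loss, monitor, lr))
    if (since_best >= cfg$early_stop_patience) break
  }

  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}

#' Initialise a model from a pre-trained base (transfer learning)
#'
#' Copies every weight and batchnorm statistic from `base_model` into
#' `model`, which must have an identical architecture specification. All
#' layers remain trainable, so subsequent [train()] calls fine-tune the
#' transferred weights rather than starting from random initialisation.
#'
#' @param model Target `ra_unet_model`.
#' @param base_model Source `ra_unet_model` with an identical spec.
#' @return `model` with the base model's weights.
#' @export
transfer_init <- function(model, base_model) {
  stopifnot(inherits(model, "ra_unet_model"),
            inherits(base_model, "ra_unet_model"))
  sa <- model$spec; sb <- base_model$spec
  same <- identical(sa[c("dimensionality", "levels", "channel_schedule",
                         "bottleneck_factor", "in_channels")],
                    sb[c("dimensionality", "levels", "channel_schedule",
                         "bottleneck_factor", "in_channels")])
  if (!same) {
    bad <- names(sa)[!mapply(identical, sa, sb)]
    stop_raunet(paste0("network specs differ (", paste(bad, collapse = ", "),
                       "); cannot transfer weights"),
                "raunet_spec_mismatch")
  }
  mism <- names(model$params)[!mapply(
    function(a, b) identical(dim(a) %||% length(a), dim(b) %||% length(b)),
    model$params, base_model$params[names(model$params)])]
  if (length(mism) > 0)
    stop_raunet(paste0("parameter shape mismatch in: ",
                       paste(head(mism, 10), collapse = ", ")),
                "raunet_spec_mismatch")
  model$params <- base_model$params
  model$state <- base_model$state
  model
}
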