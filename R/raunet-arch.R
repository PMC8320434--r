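#' Residual-attention U-Net architecture specification
#'
#' Declarative description of a 2D (slice-wise) or 3D (patch-wise)
#' residual-attention U-Net. The encoder applies one bottleneck residual
#' block per resolution level with 2x max-pooling between levels; the
#' decoder mirrors it with learned 2x transposed convolutions, attention
#' blocks gating each encoder skip connection, and one residual block after
#' each skip concatenation. A final 1x1 convolution with sigmoid activation
#' produces a one-channel probability map at input resolution.
#'
#' The default 2D specification (4 pooling levels, channel schedule
#' 32-64-128-256-512) has 9 residual blocks and 4 attention blocks and,
#' with the calibrated bottleneck factor of 4, a total of about 2.9 million
#' trainable parameters; its deepest encoder feature for a 512x512 input is
#' 32x32 with 512 channels. The 3D variant uses 3 pooling levels so the
#' small 3D patches survive the downsampling path.
#'
#' @param dimensionality 2 for the slice-wise model, 3 for patch models.
#' @param input_shape Spatial extents: length 2 (y, x) for 2D, length 3
#'   (z, y, x) for 3D. Every extent must be divisible by `2^levels`.
#' @param levels Number of pooling stages.
#' @param channel_schedule Channel widths per level, length `levels + 1`.
#' @param bottleneck_factor Ratio of residual-block output width to its
#'   internal width. The default of 4 is the calibrated value that makes
#'   the default 2D network match the 2.9 M-parameter budget.
#' @param in_channels Number of input channels (1 for CT intensity).
#' @return An object of class `network_spec`.
#' @examples
#' spec <- network_spec_2d(input_shape = c(64, 64),
#'                         channel_schedule = c(4, 8, 16, 32, 64))
#' spec$levels
#' @export
network_spec <- function(dimensionality, input_shape, levels,
                         channel_schedule, bottleneck_factor = 4,
                         in_channels = 1) {
  if (!dimensionality %in% c(2, 3))
    stop_raunet("dimensionality must be 2 or 3", "raunet_invalid_spec")
  if (length(input_shape) != dimensionality)
    stop_raunet("input_shape length must equal dimensionality",
                "raunet_invalid_spec")
  if (length(channel_schedule) != levels + 1)
    stop_raunet("channel_schedule must have levels + 1 entries",
                "raunet_invalid_spec")
  if (any(input_shape %% 2^levels != 0))
    stop_raunet(sprintf(
      "every input extent must be divisible by 2^levels = %d; pad first",
      2^levels), "raunet_invalid_spec")
  levels <- as.integer(levels)
  structure(
    list(dimensionality = as.integer(dimensionality),
         input_shape = as.integer(input_shape),
         levels = levels,
         channel_schedule = as.integer(channel_schedule),
         bottleneck_factor = bottleneck_factor,
         in_channels = as.integer(in_channels),
         n_residual_blocks = 2L * levels + 1L,
         n_attention_blocks = as.integer(levels)),
    class = "network_spec"
  )
}

#' @rdname network_spec
#' @export
network_spec_2d <- function(input_shape = c(512, 512), levels = 4,
                            channel_schedule = c(32, 64, 128, 256, 512),
                            bottleneck_factor = 4) {
  network_spec(2, input_shape, levels, channel_schedule, bottleneck_factor)
}

#' @rdname network_spec
#' @export
network_spec_3d <- function(input_shape = c(24, 32, 32), levels = 3,
                            channel_schedule = c(32, 64, 128, 256),
                            bottleneck_factor = 4) {
  network_spec(3, input_shape, levels, channel_schedule, bottleneck_factor)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %dD, input %s, %d levels, channels %s, bottleneck 1/%g\n",
    x$dimensionality, paste(x$input_shape, collapse = "x"), x$levels,
    paste(x$channel_schedule, collapse = "-"), x$bottleneck_factor))
  cat(sprintf("  %d residual blocks, %d attention blocks\n",
              x$n_residual_blocks, x$n_attention_blocks))
  invisible(x)
}

#' Build a residual-attention U-Net model
#'
#' Instantiates the computational graph and randomly initialised weights
#' (He initialisation for convolutions; unit-gain batchnorm) for a
#' [network_spec()]. Weight initialisation consumes the R random stream, so
#' call `set.seed()` beforehand for reproducible models.
#'
#' @param spec A [network_spec()].
#' @return An object of class `ra_unet_model`.
#' @examples
#' set.seed(1)
#' m <- build_network(network_spec_2d(c(32, 32), channel_schedule = c(2, 4, 6, 8, 10)))
#' count_parameters(m)
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  kernel <- if (spec$dimensionality == 2) c(1L, 3L, 3L) else c(3L, 3L, 3L)
  pool <- if (spec$dimensionality == 2) c(1L, 2L, 2L) else c(2L, 2L, 2L)
  ch <- spec$channel_schedule
  L <- spec$levels
  bf <- spec$bottleneck_factor

  g <- new_graph()
  params <- list()
  state <- list()
  inp <- add_node(g, "input")

  # encoder: residual block per level, pooling between levels
  skips <- integer(L)
  r <- gadd_residual_block(g, params, state, inp, spec$in_channels, ch[1],
                           kernel, bf, "enc1")
  params <- r$params; state <- r$state
  cur <- r$id
  for (l in seq_len(L)) {
    skips[l] <- cur
    p <- add_node(g, "maxpool", cur, cfg = list(factor = pool))
    r <- gadd_residual_block(g, params, state, p, ch[l], ch[l + 1],
                             kernel, bf, paste0("enc", l + 1))
    params <- r$params; state <- r$state
    cur <- r$id
  }

  # decoder: up-convolution, attention-gated skip, concatenation, residual
  for (l in rev(seq_len(L))) {
    cc <- node_channels(g, params, cur)
    r <- gadd_upconv(g, params, cur, pool, cc, cc, paste0("up", l))
    params <- r$params
    up <- r$id
    a <- gadd_attention_block(g, params, state, skips[l], ch[l], kernel,
                              pool, bf, paste0("att", l))
    params <- a$params; state <- a$state
    cat_id <- add_node(g, "concat", c(up, a$id))
    cin <- node_channels(g, params, up) + ch[l]
    r <- gadd_residual_block(g, params, state, cat_id, cin, ch[l], kernel,
                             bf, paste0("dec", l))
    params <- r$params; state <- r$state
    cur <- r$id
  }

  r <- gadd_conv(g, params, cur, rep(1L, 3), ch[1], 1L, "head")
  params <- r$params
  out <- add_node(g, "sigmoid", r$id)

  structure(
    list(spec = spec, nodes = g$nodes, params = params, state = state,
         output_id = out),
    class = "ra_unet_model"
  )
}

# channel bookkeeping during construction (walk back to the defining node)
node_channels <- function(g, params, id) {
  nd <- g$nodes[[id]]
  switch(nd$op,
    conv = nd$cfg$cout,
    upconv = nd$cfg$cout,
    bn = nd$cfg$c,
    input = NA_integer_,
    add = node_channels(g, params, nd$inputs[1]),
    concat = node_channels(g, params, nd$inputs[1]) +
      node_channels(g, params, nd$inputs[2]),
    node_channels(g, params, nd$inputs[1])
  )
}
chan_of <- node_channels

#' Count trainable parameters
#'
#' @param model An `ra_unet_model`.
#' @return Integer count of trainable parameters (convolution weights and
#'   biases plus batchnorm scale/shift; running statistics excluded).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ra_unet_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.ra_unet_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d nodes, %s trainable parameters\n", length(x$nodes),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# tensor plumbing -------------------------------------------------------------

# promote a bare spatial array (2D slice or 3D patch) to (D,H,W,1,1)
as_input_tensor <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_raunet("input must be an array", "raunet_invalid_input")
  if (length(d) == 2) d <- c(1L, d)
  array(x, dim = c(d, 1L, 1L))
}

stack_batch <- function(inputs) {
  ds <- lapply(inputs, function(x) {
    d <- dim(x)
    if (length(d) == 2) c(1L, d) else d
  })
  d0 <- ds[[1]]
  if (!all(vapply(ds, function(d) all(d == d0), logical(1))))
    stop_raunet("all samples in a batch must share a spatial shape",
                "raunet_invalid_input")
  array(unlist(inputs, use.names = FALSE), dim = c(d0, 1L, length(inputs)))
}

#' Pad a spatial grid up to extents divisible by a factor
#'
#' Patch extents quoted for the 3D models (20x30x30, 40x60x60) are not
#' divisible by the network's downsampling factor, so patches are
#' zero-padded at the trailing edge up to the next multiple of
#' `2^levels` and predictions are cropped back to the original extents.
#'
#' @param x Spatial array (2D or 3D).
#' @param multiple Per-axis divisibility requirement (scalar or vector).
#' @return List with `padded` array and the `original` extents.
#' @export
pad_to_multiple <- function(x, multiple) {
  d <- dim(x)
  mult <- rep_len(multiple, length(d))
  target <- as.integer(ceiling(d / mult) * mult)
  if (all(target == d)) return(list(padded = x, original = d))
  out <- array(0, dim = target)
  idx <- lapply(d, seq_len)
  out <- do.call(`[<-`, c(list(out), idx, list(value = x)))
  list(padded = out, original = d)
}

crop_to <- function(x, shape) {
  d <- dim(x)
  stopifnot(length(d) == length(shape), all(shape <= d))
  idx <- lapply(shape, seq_len)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Predict a probability map
#'
#' Runs a forward pass in inference mode (batchnorm uses running
#' statistics). The model is fully convolutional: any spatial shape whose
#' extents are divisible by `2^levels` is accepted.
#'
#' @param object An `ra_unet_model`.
#' @param x Spatial input array: (y, x) for 2D models, (z, y, x) for 3D.
#' @param ... Unused.
#' @return A `probability_map`: list with `voxels` in `[0, 1]` of the same
#'   spatial shape as the input.
#' @export
predict.ra_unet_model <- function(object, x, ...) {
  d <- dim(x)
  if (is.null(d) ||
      !length(d) %in% c(2, 3) ||
      (length(d) == 2 && object$spec$dimensionality != 2) ||
      (length(d) == 3 && object$spec$dimensionality != 3))
    stop_raunet("input dimensionality does not match the model",
                "raunet_shape_mismatch")
  spatial <- if (length(d) == 2) c(1L, d) else d
  div <- if (object$spec$dimensionality == 2)
    c(1L, rep(2L^object$spec$levels, 2)) else rep(2L^object$spec$levels, 3)
  if (any(spatial %% div != 0))
    stop_raunet(sprintf(
      "spatial extents must be divisible by %s; pad_to_multiple() first",
      paste(div, collapse = "x")), "raunet_shape_mismatch")
  xt <- as_input_tensor(x)
  out <- forward_graph(object, xt, training = FALSE, keep = FALSE)$out
  v <- array(out, dim = dim(xt)[1:3])
  if (length(d) == 2) v <- array(v, dim = d)
  structure(list(voxels = v), class = "probability_map")
}

#' Threshold a probability map into a binary mask
#'
#' @param p A `probability_map` (or bare numeric array in `[0, 1]`).
#' @param threshold Decision threshold; voxels with probability `>=`
#'   threshold map to 1.
#' @param spacing,label Metadata for the resulting [binary_mask()] when the
#'   input is 3D.
#' @return A [binary_mask()] for 3D input, otherwise a plain 0/1 array.
#' @export
binarize <- function(p, threshold = 0.5, spacing = c(1, 1, 1),
                     label = "liver") {
  v <- if (inherits(p, "probability_map")) p$voxels else p
  if (min(v) < 0 || max(v) > 1)
    stop_raunet("probabilities must lie in [0, 1]", "raunet_invalid_input")
  b <- array(as.numeric(v >= threshold), dim = dim(v))
  if (length(dim(b)) == 3) binary_mask(b, spacing, label = label) else b
}

# checkpointing ---------------------------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints are written as an RDS payload (weights, batchnorm state and
#' architecture spec) with a YAML sidecar carrying the spec and training
#' configuration for provenance.
#'
#' @param model An `ra_unet_model`.
#' @param path Checkpoint path (`.rds`).
#' @param train_config Optional [train_config()] recorded in the sidecar.
#' @return `load_checkpoint()` returns the model; `save_checkpoint()` the
#'   path, invisibly.
#' @export
save_checkpoint <- function(model, path, train_config = NULL) {
  stopifnot(inherits(model, "ra_unet_model"))
  saveRDS(model, path)
  side <- sub("\\.rds$", ".yaml", path)
  if (identical(side, path)) side <- paste0(path, ".yaml")
  meta <- list(spec = unclass(model$spec))
  if (!is.null(train_config)) meta$train_config <- unclass(train_config)
  yaml::write_yaml(meta, side)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop_raunet(sprintf("checkpoint not found: %s", path), "raunet_io_missing")
  model <- readRDS(path)
  if (!inherits(model, "ra_unet_model"))
    stop_raunet("file is not an ra_unet_model checkpoint", "raunet_io_malformed")
  model
}
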