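#' Encoder-decoder network configuration
#'
#' The network is a U-Net: `depth` encoder blocks (two 3x3 conv + ReLU
#' layers, then 2x2 max-pool), a two-conv bottleneck, and `depth`
#' decoder blocks (2x2 transpose-conv upsampling, skip concatenation,
#' two 3x3 conv + ReLU layers), closed by a 1-channel 1x1 sigmoid head
#' that produces a probability map the same size as the input.
#'
#' @param depth Number of down-sampling blocks (default 5).
#' @param base_channels Channels of the first block; later blocks double
#'   (capped at `8 * base_channels`, matching the VGG-style plateau).
#' @param channel_schedule Optional explicit per-block channel counts
#'   (length `depth`); overrides `base_channels`.
#' @param bottleneck_channels Bottleneck width; default twice the last
#'   encoder block.
#' @param input_size Nominal square input size; must be divisible by
#'   `2^depth`. The network itself is fully convolutional and accepts
#'   any input whose sides are divisible by `2^depth`.
#' @param use_pretrained_encoder Marker consumed by
#'   [load_encoder_weights()] workflows; no effect on construction.
#' @return A `unet_config` object.
#' @export
unet_config <- function(depth = 5L, base_channels = 64L,
                        channel_schedule = NULL, bottleneck_channels = NULL,
                        input_size = 384L, use_pretrained_encoder = FALSE) {
  depth <- as.integer(depth)
  if (is.null(channel_schedule)) {
    channel_schedule <- pmin(base_channels * 2^(seq_len(depth) - 1L),
                             8L * base_channels)
  }
  channel_schedule <- as.integer(channel_schedule)
  if (length(channel_schedule) != depth) {
    stop("channel_schedule must have one entry per block (", depth, ")")
  }
  if (is.null(bottleneck_channels)) {
    bottleneck_channels <- 2L * channel_schedule[depth]
  }
  if (input_size %% 2^depth != 0) {
    stop("input_size ", input_size, " not divisible by 2^depth = ", 2^depth)
  }
  structure(list(depth = depth, channel_schedule = channel_schedule,
                 bottleneck_channels = as.integer(bottleneck_channels),
                 input_size = as.integer(input_size),
                 use_pretrained_encoder = isTRUE(use_pretrained_encoder)),
            class = "unet_config")
}

#' Full-size preset: five blocks with VGG16-style encoder widths
#' (64, 128, 256, 512, 512), 384 px inputs.
#' @return A `unet_config`.
#' @export
unet_full <- function() {
  unet_config(depth = 5L, channel_schedule = c(64L, 128L, 256L, 512L, 512L),
              bottleneck_channels = 512L, input_size = 384L)
}

#' Tiny desk-scale preset: three blocks (8, 16, 32 channels), 96 px
#' inputs, under 200k parameters. All package tests and benchmarks run
#' at this scale.
#' @return A `unet_config`.
#' @export
unet_tiny <- function() {
  unet_config(depth = 3L, channel_schedule = c(8L, 16L, 32L),
              bottleneck_channels = 64L, input_size = 96L)
}

# Weight-list layout shared with the C++ kernels: encoder blocks
# (W1,b1,W2,b2), bottleneck (W1,b1,W2,b2), decoder blocks deepest-first
# (upW,upb,W1,b1,W2,b2), head (W,b). Conv W is (9*Cin x Cout),
# transpose-conv W is (Cin x 4*Cout).
unet_param_shapes <- function(cfg) {
  ch <- cfg$channel_schedule
  D <- cfg$depth
  bc <- cfg$bottleneck_channels
  shapes <- list()
  add <- function(name, d) shapes[[name]] <<- d
  cin <- 3L
  for (i in seq_len(D)) {
    add(paste0("enc", i, "_W1"), c(9L * cin, ch[i]))
    add(paste0("enc", i, "_b1"), ch[i])
    add(paste0("enc", i, "_W2"), c(9L * ch[i], ch[i]))
    add(paste0("enc", i, "_b2"), ch[i])
    cin <- ch[i]
  }
  add("bot_W1", c(9L * ch[D], bc)); add("bot_b1", bc)
  add("bot_W2", c(9L * bc, bc)); add("bot_b2", bc)
  prev <- bc
  for (i in rev(seq_len(D))) {
    add(paste0("dec", i, "_upW"), c(prev, 4L * ch[i]))
    add(paste0("dec", i, "_upb"), ch[i])
    add(paste0("dec", i, "_W1"), c(9L * 2L * ch[i], ch[i]))
    add(paste0("dec", i, "_b1"), ch[i])
    add(paste0("dec", i, "_W2"), c(9L * ch[i], ch[i]))
    add(paste0("dec", i, "_b2"), ch[i])
    prev <- ch[i]
  }
  add("head_W", c(ch[1], 1L)); add("head_b", 1L)
  shapes
}

#' Build a segmentation model with freshly initialized weights
#'
#' Weights use He-normal initialization (`sd = sqrt(2 / fan_in)`), zero
#' biases; the sigmoid head starts near probability 0.5 everywhere.
#' Initialization is driven by R's RNG, so `set.seed()` (or the `seed`
#' argument) makes it bit-reproducible.
#'
#' @param cfg A [unet_config()].
#' @param seed Optional integer seed applied before drawing weights.
#' @return An object of class `unet_model` with fields `config` and
#'   `weights`.
#' @export
build_model <- function(cfg = unet_tiny(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shapes <- unet_param_shapes(cfg)
  weights <- lapply(names(shapes), function(nm) {
    d <- shapes[[nm]]
    if (length(d) == 2L) {
      matrix(stats::rnorm(prod(d), sd = sqrt(2 / d[1])), d[1], d[2])
    } else {
      numeric(d)
    }
  })
  names(weights) <- names(shapes)
  structure(list(config = cfg, weights = weights), class = "unet_model")
}

#' Number of trainable parameters
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, 0L))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model depth %d, channels %s, %d parameters>\n",
              x$config$depth,
              paste(x$config$channel_schedule, collapse = "/"),
              n_parameters(x)))
  invisible(x)
}

#' Predict a probability map for one image
#'
#' Deterministic given weights and input; output values lie in `(0, 1)`.
#' Models returned by the training functions carry the per-channel
#' normalization statistics of their training set (`model$norm_stats`);
#' by default these are applied to `pixels` before the forward pass so
#' inference sees the same preprocessing as training.
#'
#' @param model A trained or freshly built `unet_model`.
#' @param pixels `H x W x 3` numeric array; `H` and `W` must be
#'   divisible by `2^depth`.
#' @param normalize Apply `model$norm_stats` when present. Pass `FALSE`
#'   when `pixels` are already normalized.
#' @return `H x W` numeric matrix of polyp probabilities.
#' @export
predict_prob <- function(model, pixels, normalize = TRUE) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (normalize && !is.null(model$norm_stats)) {
    cfg <- preprocess_config(target_size = dim(pixels)[1],
                             normalization = "dataset-stats",
                             dataset_mean = model$norm_stats$mean,
                             dataset_std = model$norm_stats$sd)
    pixels <- normalize_image(pixels, cfg)
  }
  d <- 2^model$config$depth
  if (dim(pixels)[1] %% d != 0 || dim(pixels)[2] %% d != 0) {
    stop("input sides must be divisible by 2^depth = ", d)
  }
  cpp_unet_forward(unname(model$weights), pixels,
                   model$config$channel_schedule)
}

# Batch masked loss + gradients (internal training step backend).
unet_loss_grad <- function(model, xs, ys, ms) {
  res <- cpp_unet_batch_grad(unname(model$weights), xs, ys, ms,
                             model$config$channel_schedule)
  # vector parameters come back as n x 1 matrices; restore their shape
  res$grads <- Map(function(g, w) if (is.matrix(w)) g else as.numeric(g),
                   res$grads, model$weights)
  names(res$grads) <- names(model$weights)
  res
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding the config and weight list.
#'
#' @param model A `unet_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, weights = model$weights,
               norm_stats = model$norm_stats), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(config = obj$config, weights = obj$weights,
                 norm_stats = obj$norm_stats),
            class = "unet_model")
}

#' Replace the encoder weights of a model
#'
#' `source = "random"` re-draws the encoder (seeded); `"checkpoint"`
#' copies encoder weights from another saved model of identical encoder
#' shape; `"vgg16-imagenet"` is an optional hook that loads
#' externally converted VGG16 convolution weights from a local RDS file
#' (a list of matrices in this package's layout) - it requires
#' `depth = 5` with the VGG16 channel schedule and never downloads
#' anything. Decoder and head weights are untouched.
#'
#' @param model A `unet_model`.
#' @param source One of `"random"`, `"vgg16-imagenet"`, `"checkpoint"`.
#' @param path Checkpoint / converted-weights file for the file-based
#'   sources.
#' @param seed Seed for `source = "random"`.
#' @return The model with encoder weights replaced.
#' @export
load_encoder_weights <- function(model,
                                 source = c("random", "vgg16-imagenet",
                                            "checkpoint"),
                                 path = NULL, seed = NULL) {
  source <- match.arg(source)
  enc_names <- grep("^(enc|bot)", names(model$weights), value = TRUE)
  if (source == "random") {
    fresh <- build_model(model$config, seed = seed)
    model$weights[enc_names] <- fresh$weights[enc_names]
    return(model)
  }
  if (is.null(path) || !file.exists(path)) {
    stop("source '", source, "' requires an existing weights file")
  }
  if (source == "vgg16-imagenet") {
    vgg_sched <- c(64L, 128L, 256L, 512L, 512L)
    if (model$config$depth != 5L ||
        !identical(model$config$channel_schedule, vgg_sched)) {
      stop("vgg16-imagenet encoder weights require depth 5 with ",
           "channel schedule 64/128/256/512/512")
    }
    donor <- readRDS(path)
  } else {
    donor <- load_checkpoint(path)$weights
  }
  for (nm in enc_names) {
    if (is.null(donor[[nm]])) stop("weights file lacks entry ", nm)
    if (!identical(dim2(donor[[nm]]), dim2(model$weights[[nm]]))) {
      stop("shape mismatch for ", nm)
    }
    model$weights[[nm]] <- donor[[nm]]
  }
  model
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)
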