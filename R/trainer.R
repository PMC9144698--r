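#' Training schedule
#'
#' The reference schedule trains with batch size 12 for 3 epochs per
#' iteration for the first 2 iterations, then 6 epochs for another 6
#' iterations, with Adam at an initial learning rate of 1e-4 and
#' inverse-time decay `lr / (1 + 5e-4 * e)` (epoch counter `e` starting
#' at the `decay_start_iteration`-th iteration), stopping early when the
#' validation loss fails to improve for two consecutive iterations.
#'
#' @param epochs_per_iteration Integer vector; refinement happens after
#'   each element.
#' @param batch_size Images per gradient step.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_decay Inverse-time decay coefficient per epoch.
#' @param decay_start_iteration Iteration (1-based) from which decay
#'   epochs are counted.
#' @param early_stop_patience Consecutive non-improving iterations after
#'   which training stops; 0 disables early stopping (then a validation
#'   set is optional).
#' @param seed Run seed; model initialization, shuffling and
#'   augmentation randomness all derive from it.
#' @return A `training_schedule` object.
#' @export
training_schedule <- function(epochs_per_iteration = c(3, 3, 6, 6, 6, 6, 6, 6),
                              batch_size = 12L, initial_lr = 1e-4,
                              lr_decay = 5e-4, decay_start_iteration = 3L,
                              early_stop_patience = 2L, seed = 0L) {
  stopifnot(length(epochs_per_iteration) >= 1,
            all(epochs_per_iteration > 0), batch_size >= 1)
  structure(list(epochs_per_iteration = as.integer(epochs_per_iteration),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 decay_start_iteration = as.integer(decay_start_iteration),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

#' Desk-scale schedule for the tiny network preset
#'
#' Four iterations of two epochs, batch 12, Adam at 3e-3 (a standard
#' rate for small networks trained from scratch; the reference 1e-4
#' belongs to large pretrained encoders), no early stopping.
#'
#' @param seed Run seed.
#' @param epochs_per_iteration Override the iteration plan.
#' @return A `training_schedule`.
#' @export
desk_schedule <- function(seed = 0L, epochs_per_iteration = c(2, 2, 2, 2)) {
  training_schedule(epochs_per_iteration = epochs_per_iteration,
                    batch_size = 12L, initial_lr = 3e-3, lr_decay = 5e-4,
                    decay_start_iteration = 3L, early_stop_patience = 0L,
                    seed = seed)
}

epoch_lr <- function(schedule, global_epoch, decay_epoch0) {
  if (global_epoch < decay_epoch0) return(schedule$initial_lr)
  e <- global_epoch - decay_epoch0 + 1
  schedule$initial_lr / (1 + schedule$lr_decay * e)
}

#' Mark a fraction of images as fixed-target (mixed supervision)
#'
#' Promotes a seeded random subset of mask-labelled images to
#' fixed-target status: their training target becomes the ground-truth
#' mask and is excluded from iterative refinement.
#'
#' @param images List of [annotated_image()] with `gt_mask`.
#' @param fraction Fraction to promote.
#' @param seed Selection seed.
#' @return The image list with `fixed_target`/`target` updated.
#' @export
mark_fixed <- function(images, fraction, seed = 0L) {
  has_gt <- which(vapply(images, function(im) !is.null(im$gt_mask), TRUE))
  set.seed(seed)
  chosen <- sample(has_gt, round(fraction * length(has_gt)))
  for (i in chosen) {
    images[[i]]$fixed_target <- TRUE
    images[[i]]$target <- images[[i]]$gt_mask
  }
  images
}

#' Refine training targets from model predictions
#'
#' For every refinable image the new target is the model's prediction,
#' thresholded and clipped to the bounding boxes; fixed-target images
#' are returned unchanged. The clipping invariant (no positive target
#' pixel outside the box union) is asserted on every output.
#'
#' @param model A `unet_model`.
#' @param images List of [annotated_image()].
#' @param threshold Probability threshold (default 0.5, shared with
#'   prediction initialization).
#' @param pixels_list Optional list of preprocessed `H x W x 3` arrays to
#'   predict on (defaults to each image's raw pixels; the trainer passes
#'   the normalized arrays it trains on).
#' @return The image list with refreshed targets.
#' @export
refine_targets <- function(model, images, threshold = 0.5,
                           pixels_list = NULL) {
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (img$fixed_target) next
    prob <- if (is.null(pixels_list)) {
      predict_prob(model, img$pixels)  # applies the model's norm_stats
    } else {
      predict_prob(model, pixels_list[[i]], normalize = FALSE)
    }
    pred <- matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
    target <- clip_mask_to_boxes(pred, img$boxes)
    inside <- box_union_mask(img$boxes, ncol(target), nrow(target))
    stopifnot(sum(target > inside) == 0)  # positives inside box union
    images[[i]]$target <- target
  }
  images
}

# Refresh targets, rejecting refreshes that fail the box-coverage
# sanity rule (the image keeps its current target instead).
refine_targets_guarded <- function(model, images, threshold, min_coverage,
                                   pixels_list = NULL) {
  refreshed <- refine_targets(model, images, threshold, pixels_list)
  if (min_coverage <= 0) return(refreshed)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (img$fixed_target || is.null(img$target)) next
    box_area <- sum(vapply(img$boxes, function(b) b$box_w * b$box_h, 0))
    if (sum(refreshed[[i]]$target) / box_area < min_coverage) {
      refreshed[[i]]$target <- img$target
    }
  }
  refreshed
}

normalize_set <- function(images, stats) {
  cfg <- preprocess_config(target_size = dim(images[[1]]$pixels)[1],
                           normalization = "dataset-stats",
                           dataset_mean = stats$mean, dataset_std = stats$sd)
  lapply(images, function(im) normalize_image(im$pixels, cfg))
}

# One epoch of minibatch Adam on (xs, ys, ms); returns updated model,
# optimizer state and the epoch's mean batch loss.
train_one_epoch <- function(model, opt, xs, ys, ms, batch_size, lr,
                            aug = NULL, boxes_list = NULL,
                            fixed_flags = NULL, loss_params = NULL) {
  n <- length(xs)
  order <- sample(n)
  losses <- c()
  for (start in seq(1, n, by = batch_size)) {
    idx <- order[start:min(start + batch_size - 1, n)]
    bx <- xs[idx]; by <- ys[idx]; bm <- ms[idx]
    if (!is.null(aug) && isTRUE(aug$enabled)) {
      for (k in seq_along(idx)) {
        i <- idx[k]
        res <- augment(xs[[i]], boxes_list[[i]], ys[[i]], aug)
        bx[[k]] <- res$image
        by[[k]] <- res$mask
        bm[[k]] <- if (fixed_flags[i] || length(res$boxes) == 0L) {
          matrix(1, nrow(res$mask), ncol(res$mask))
        } else {
          combine_loss_masks(lapply(res$boxes, build_loss_mask,
                                    width = ncol(res$mask),
                                    height = nrow(res$mask),
                                    params = loss_params))
        }
      }
    }
    res <- unet_loss_grad(model, bx, by, bm)
    step <- adam_step(model$weights, res$grads, opt, lr)
    model$weights <- step$weights
    opt <- step$state
    losses <- c(losses, res$loss)
  }
  list(model = model, opt = opt, loss = mean(losses))
}

set_loss <- function(model, xs, ys, ms) {
  num <- 0; den <- 0
  for (i in seq_along(xs)) {
    p <- predict_prob(model, xs[[i]], normalize = FALSE)
    num <- num + masked_loss(p, ys[[i]], ms[[i]]) * sum(ms[[i]])
    den <- den + sum(ms[[i]])
  }
  num / den
}

#' Iterative weakly supervised training
#'
#' Implements the refinement loop: build initial pseudo-targets with the
#' configured initializer, then alternate between (a) training the
#' network for `epochs_per_iteration[i]` epochs minimizing the masked
#' binary cross-entropy — with the oval-ring loss mask on box-supervised
#' images and unit weights on fixed-target images — and (b) replacing
#' every refinable image's target with the network's thresholded,
#' box-clipped prediction. Optionally stops early on the validation
#' masked loss (computed with the same loss masks as training, so no
#' ground truth is consumed during training). Validation targets are
#' refreshed alongside the training targets.
#'
#' All pixels are normalized with per-channel statistics computed once
#' from the training images.
#'
#' @param data A [dataset_split()]; every refinable training image needs
#'   at least one box. Validation may be empty when
#'   `schedule$early_stop_patience == 0`.
#' @param init_cfg An [initializer_config()].
#' @param schedule A [training_schedule()].
#' @param loss_params A [loss_mask_params()].
#' @param model_cfg A [unet_config()]; default tiny preset.
#' @param init_model Optional pre-trained model: required by the
#'   prediction/hybrid initializers, and also used as the starting
#'   weights of training when `warm_start = TRUE`.
#' @param warm_start Start from `init_model`'s weights instead of a
#'   fresh initialization.
#' @param augment_cfg Optional [augment_config()] applied per epoch.
#' @param refine_threshold Probability threshold for target refreshes.
#' @param refine_min_coverage Coverage sanity rule applied to every
#'   refresh: if a refinable image's new target covers less than this
#'   fraction of its box area, the refresh is rejected and the image
#'   keeps its current target (same 30% rule the hybrid initializer
#'   applies to pre-trained predictions). Early in training — before
#'   the network's probabilities are decisive — thresholding yields
#'   near-empty masks, and accepting them would erase the supervision
#'   signal and lock self-training into predicting background
#'   everywhere. Set to 0 to accept every refresh unconditionally.
#' @param snapshot_ids Image ids whose target evolution is recorded
#'   per iteration (default: first 4 training images).
#' @return A list of class `weak_training_run`: `model`, `history`
#'   (data frame: iteration, epoch, lr, train_loss, val_loss),
#'   `train_images` (final targets), `initial_targets`, `init_log`,
#'   `snapshots`, `stopped_early`, `norm_stats`.
#' @export
run_weakly_supervised_training <- function(data, init_cfg = initializer_config(),
                                           schedule = desk_schedule(),
                                           loss_params = loss_mask_params(),
                                           model_cfg = unet_tiny(),
                                           init_model = NULL,
                                           warm_start = FALSE,
                                           augment_cfg = NULL,
                                           refine_threshold = 0.5,
                                           refine_min_coverage = 0.3,
                                           snapshot_ids = NULL) {
  train <- data$train
  val <- data$validation
  if (length(train) == 0L) stop("empty training set")
  if (schedule$early_stop_patience > 0 && length(val) == 0L) {
    stop("early stopping requires a non-empty validation set")
  }
  for (im in train) {
    if (!im$fixed_target && length(im$boxes) == 0L) {
      stop("refinable image ", im$image_id, " has no boxes")
    }
  }
  set.seed(schedule$seed)
  model <- if (warm_start && !is.null(init_model)) init_model else
    build_model(model_cfg, seed = schedule$seed)

  stats <- dataset_stats(train)
  xs <- normalize_set(train, stats)
  xs_val <- if (length(val)) normalize_set(val, stats) else list()

  init <- build_initial_targets(train, init_cfg, init_model)
  train <- init$images
  initial_targets <- lapply(train, `[[`, "target")
  names(initial_targets) <- vapply(train, `[[`, "", "image_id")
  if (length(val)) val <- build_initial_targets(val, init_cfg, init_model)$images

  ms <- lapply(train, image_loss_mask, params = loss_params)
  ms_val <- lapply(val, image_loss_mask, params = loss_params)
  fixed_flags <- vapply(train, `[[`, TRUE, "fixed_target")
  boxes_list <- lapply(train, `[[`, "boxes")

  if (is.null(snapshot_ids)) {
    snapshot_ids <- vapply(train[seq_len(min(4, length(train)))], `[[`, "",
                           "image_id")
  }
  snapshots <- list()
  take_snapshot <- function(iter) {
    ids <- vapply(train, `[[`, "", "image_id")
    snapshots[[as.character(iter)]] <<-
      lapply(train[match(snapshot_ids, ids)], `[[`, "target")
  }
  take_snapshot(0L)

  opt <- adam_init(model$weights)
  history <- data.frame()
  n_iter <- length(schedule$epochs_per_iteration)
  decay_epoch0 <- if (schedule$decay_start_iteration <= n_iter) {
    sum(schedule$epochs_per_iteration[seq_len(schedule$decay_start_iteration - 1)]) + 1
  } else Inf
  global_epoch <- 0L
  best_val <- Inf
  bad_iters <- 0L
  stopped_early <- FALSE

  for (iter in seq_len(n_iter)) {
    ys <- lapply(train, `[[`, "target")
    for (ep in seq_len(schedule$epochs_per_iteration[iter])) {
      global_epoch <- global_epoch + 1L
      lr <- epoch_lr(schedule, global_epoch, decay_epoch0)
      res <- train_one_epoch(model, opt, xs, ys, ms, schedule$batch_size, lr,
                             aug = augment_cfg, boxes_list = boxes_list,
                             fixed_flags = fixed_flags,
                             loss_params = loss_params)
      model <- res$model; opt <- res$opt
      history <- rbind(history, data.frame(
        iteration = iter, epoch = global_epoch, lr = lr,
        train_loss = res$loss, val_loss = NA_real_))
    }
    val_loss <- NA_real_
    if (length(val)) {
      val_loss <- set_loss(model, xs_val, lapply(val, `[[`, "target"), ms_val)
      history$val_loss[nrow(history)] <- val_loss
    }
    train <- refine_targets_guarded(model, train, refine_threshold,
                                    refine_min_coverage, pixels_list = xs)
    if (length(val)) {
      val <- refine_targets_guarded(model, val, refine_threshold,
                                    refine_min_coverage,
                                    pixels_list = xs_val)
    }
    take_snapshot(iter)
    if (schedule$early_stop_patience > 0 && !is.na(val_loss)) {
      if (val_loss < best_val - 1e-5) {
        best_val <- val_loss
        bad_iters <- 0L
      } else {
        bad_iters <- bad_iters + 1L
        if (bad_iters >= schedule$early_stop_patience) {
          stopped_early <- TRUE
          break
        }
      }
    }
  }
  model$norm_stats <- stats
  structure(list(model = model, history = history, train_images = train,
                 initial_targets = initial_targets, init_log = init$log,
                 snapshots = snapshots, stopped_early = stopped_early,
                 norm_stats = stats),
            class = "weak_training_run")
}

#' Fully supervised training on ground-truth masks
#'
#' Standard training with unit loss weights and no target refinement.
#' The `full_sup_3`-style fine-tuning recipe is obtained by passing a
#' 30-epoch, batch-1 schedule (see [finetune_schedule()]) together with
#' a `start_model` checkpoint.
#'
#' @param data A [dataset_split()]; every training image needs `gt_mask`.
#' @param schedule A [training_schedule()].
#' @param model_cfg A [unet_config()].
#' @param start_model Optional `unet_model` whose weights initialize
#'   training (transfer learning / fine-tuning).
#' @return A list of class `supervised_training_run`: `model`, `history`,
#'   `norm_stats`.
#' @export
run_supervised_training <- function(data, schedule = desk_schedule(),
                                    model_cfg = unet_tiny(),
                                    start_model = NULL) {
  train <- data$train
  for (im in train) {
    if (is.null(im$gt_mask)) stop("image ", im$image_id, " lacks gt_mask")
  }
  set.seed(schedule$seed)
  model <- if (!is.null(start_model)) start_model else
    build_model(model_cfg, seed = schedule$seed)
  stats <- dataset_stats(train)
  xs <- normalize_set(train, stats)
  ys <- lapply(train, `[[`, "gt_mask")
  ms <- lapply(ys, function(y) matrix(1, nrow(y), ncol(y)))
  opt <- adam_init(model$weights)
  history <- data.frame()
  n_iter <- length(schedule$epochs_per_iteration)
  decay_epoch0 <- if (schedule$decay_start_iteration <= n_iter) {
    sum(schedule$epochs_per_iteration[seq_len(schedule$decay_start_iteration - 1)]) + 1
  } else Inf
  global_epoch <- 0L
  for (iter in seq_len(n_iter)) {
    for (ep in seq_len(schedule$epochs_per_iteration[iter])) {
      global_epoch <- global_epoch + 1L
      lr <- epoch_lr(schedule, global_epoch, decay_epoch0)
      res <- train_one_epoch(model, opt, xs, ys, ms, schedule$batch_size, lr)
      model <- res$model; opt <- res$opt
      history <- rbind(history, data.frame(
        iteration = iter, epoch = global_epoch, lr = lr,
        train_loss = res$loss, val_loss = NA_real_))
    }
  }
  model$norm_stats <- stats
  structure(list(model = model, history = history, norm_stats = stats),
            class = "supervised_training_run")
}

#' Fine-tuning schedule: 30 epochs, batch 1, lr 1e-4 with 5e-4
#' inverse-time decay from the first epoch.
#' @param seed Run seed.
#' @return A `training_schedule`.
#' @export
finetune_schedule <- function(seed = 0L) {
  training_schedule(epochs_per_iteration = rep(1L, 30L), batch_size = 1L,
                    initial_lr = 1e-4, lr_decay = 5e-4,
                    decay_start_iteration = 1L, early_stop_patience = 0L,
                    seed = seed)
}

#' Train one variant on a training set
#'
#' Dispatcher used by [cross_validate()] and the CLI. Variants:
#' `full-sup` (ground-truth masks), `weak-ci` / `weak-pi` / `weak-hi`
#' (box-only with circle / prediction / hybrid initialization), and
#' `weak-mix` (a seeded `mix_fixed_fraction` of mask-labelled training
#' images kept as fixed targets, the rest box-supervised).
#'
#' @param data A [dataset_split()].
#' @param variant Variant name.
#' @param schedule,model_cfg,loss_params,init_model,augment_cfg Passed
#'   through to the training functions.
#' @param mix_fixed_fraction Fraction of mask-labelled images fixed in
#'   `weak-mix`.
#' @return A training-run object (weakly supervised or supervised).
#' @export
train_variant <- function(data,
                          variant = c("weak-ci", "weak-pi", "weak-hi",
                                      "weak-mix", "full-sup"),
                          schedule = desk_schedule(),
                          model_cfg = unet_tiny(),
                          loss_params = loss_mask_params(),
                          init_model = NULL, augment_cfg = NULL,
                          mix_fixed_fraction = 0.3) {
  variant <- match.arg(variant)
  if (variant == "full-sup") {
    return(run_supervised_training(data, schedule, model_cfg))
  }
  init_cfg <- switch(variant,
                     "weak-ci" = initializer_config("circle"),
                     "weak-pi" = initializer_config("prediction"),
                     "weak-hi" = initializer_config("hybrid"),
                     "weak-mix" = if (is.null(init_model))
                       initializer_config("circle") else
                       initializer_config("hybrid"))
  if (variant == "weak-mix") {
    n_fixable <- sum(vapply(data$train,
                            function(im) !is.null(im$gt_mask), TRUE))
    if (n_fixable == 0L) {
      stop("weak-mix requires mask-labelled training images")
    }
    data$train <- mark_fixed(data$train, mix_fixed_fraction,
                             seed = schedule$seed)
  }
  run_weakly_supervised_training(data, init_cfg, schedule, loss_params,
                                 model_cfg, init_model = init_model,
                                 augment_cfg = augment_cfg)
}

#' k-fold cross-validation
#'
#' Deterministic seeded partition of the images by `image_id` into `k`
#' folds; trains one model per fold on the remaining images and
#' evaluates on the held-out fold. Reports per-fold and mean +/- SEM
#' dice and accuracy.
#'
#' @param images List of [annotated_image()] with `gt_mask` (needed for
#'   test evaluation).
#' @param k Number of folds (>= 2).
#' @param variant Training variant (see [train_variant()]).
#' @param seed Partition seed; fold training seeds derive from it.
#' @param schedule Base [training_schedule()]; each fold runs it with a
#'   fold-specific seed derived from `seed`.
#' @param ... Passed to [train_variant()].
#' @return List with `folds` (data frame: fold, n_test, dice, accuracy),
#'   `mean_dice`, `sem_dice`, `mean_accuracy`, `sem_accuracy`.
#' @export
cross_validate <- function(images, k = 10L, variant = "weak-ci", seed = 0L,
                           schedule = desk_schedule(), ...) {
  stopifnot(k >= 2, length(images) >= k)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = length(images)))
  rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    if (length(test_idx) == 0L) stop("fold ", f, " would have no test images")
    split <- dataset_split(train = images[-test_idx],
                           test = images[test_idx], fold_index = f)
    sched <- schedule
    sched$seed <- as.integer((seed %% 2000000L) * 1000L + f)
    run <- train_variant(split, variant, schedule = sched, ...)
    ev <- evaluate_set(run$model, split$test, threshold = 0.5,
                       norm_stats = run$norm_stats)
    rows[[f]] <- data.frame(fold = f, n_test = length(test_idx),
                            dice = ev$mean_dice, accuracy = ev$mean_accuracy)
  }
  folds <- do.call(rbind, rows)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(folds = folds, mean_dice = mean(folds$dice),
       sem_dice = sem(folds$dice), mean_accuracy = mean(folds$accuracy),
       sem_accuracy = sem(folds$accuracy), fold_assignment = fold_of)
}

#' Seeded k-fold assignment of n items
#'
#' @param n Number of items.
#' @param k Number of folds.
#' @param seed Seed.
#' @return Integer vector of fold labels in `1..k`, balanced to within
#'   one item.
#' @export
fold_assignment <- function(n, k, seed = 0L) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}
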