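# Small shared fixtures: 64x64 scenes train in a few seconds.
smoke_images <- function(n = 6, seed = 3) {
  generate_dataset(scene_config(image_size = 64L, n_images = n,
                                seed = seed))
}

one_epoch_schedule <- function(seed = 0, lr = 3e-3) {
  training_schedule(epochs_per_iteration = 1L, batch_size = 6L,
                    initial_lr = lr, lr_decay = 5e-4,
                    decay_start_iteration = 3L, early_stop_patience = 0L,
                    seed = seed)
}

test_that("refine_targets clips predictions and protects fixed targets", {
  imgs <- smoke_images(3)
  # force the network to predict ~1 everywhere: zero head weights, bias 10
  model <- build_model(unet_config(depth = 3,
                                   channel_schedule = c(8L, 16L, 32L),
                                   bottleneck_channels = 64L,
                                   input_size = 64L), seed = 0)
  model$weights$head_W[] <- 0
  model$weights$head_b <- 10
  imgs[[2]]$fixed_target <- TRUE
  imgs[[2]]$target <- imgs[[2]]$gt_mask
  out <- refine_targets(model, imgs)
  expect_equal(out[[1]]$target, box_union_mask(imgs[[1]]$boxes, 64, 64))
  expect_identical(out[[2]]$target, imgs[[2]]$gt_mask)
  # a bias of -10 predicts ~0 everywhere: all-negative target is allowed
  model$weights$head_b <- -10
  out0 <- refine_targets(model, imgs)
  expect_equal(sum(out0[[1]]$target), 0)
})

test_that("refresh coverage guard rejects near-empty refreshed targets", {
  imgs <- smoke_images(2)
  model <- build_model(unet_config(depth = 3,
                                   channel_schedule = c(8L, 16L, 32L),
                                   bottleneck_channels = 64L,
                                   input_size = 64L), seed = 0)
  model$weights$head_W[] <- 0
  imgs <- lapply(imgs, function(im) {
    im$target <- Reduce(pmax, lapply(im$boxes, circle_init,
                                     width = 64, height = 64))
    im
  })
  # head bias -10: prediction ~0 everywhere -> refresh would empty the
  # targets; the guard must keep the circles instead
  model$weights$head_b <- -10
  kept <- boxseg:::refine_targets_guarded(model, imgs, 0.5, 0.3)
  expect_identical(kept[[1]]$target, imgs[[1]]$target)
  # with the guard disabled the empty refresh goes through
  bare <- boxseg:::refine_targets_guarded(model, imgs, 0.5, 0)
  expect_equal(sum(bare[[1]]$target), 0)
  # a decisive prediction (all ones -> full box coverage) is accepted
  model$weights$head_b <- 10
  full <- boxseg:::refine_targets_guarded(model, imgs, 0.5, 0.3)
  expect_equal(full[[1]]$target, box_union_mask(imgs[[1]]$boxes, 64, 64))
})

test_that("zero learning rate leaves the model untouched", {
  imgs <- smoke_images(6)
  split <- dataset_split(train = imgs)
  sched <- one_epoch_schedule(seed = 5, lr = 0)
  run <- run_weakly_supervised_training(split, initializer_config("circle"),
                                        sched,
                                        model_cfg = unet_tiny())
  fresh <- build_model(unet_tiny(), seed = 5)
  expect_identical(run$model$weights, fresh$weights)
})

test_that("seeded runs are bit-reproducible", {
  imgs <- smoke_images(6)
  split <- dataset_split(train = imgs)
  r1 <- run_weakly_supervised_training(split, initializer_config("circle"),
                                       one_epoch_schedule(seed = 2))
  r2 <- run_weakly_supervised_training(split, initializer_config("circle"),
                                       one_epoch_schedule(seed = 2))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$weights, r2$model$weights)
})

test_that("supervised training reduces the loss epoch over epoch", {
  imgs <- smoke_images(10, seed = 8)
  split <- dataset_split(train = imgs)
  sched <- training_schedule(epochs_per_iteration = c(2L, 2L),
                             batch_size = 6L, initial_lr = 3e-3,
                             early_stop_patience = 0L, seed = 1)
  run <- run_supervised_training(split, sched)
  losses <- run$history$train_loss
  drops <- diff(losses) < 0
  expect_gte(sum(drops), length(drops) - 1)  # at most one non-improving epoch
  expect_lt(losses[length(losses)], losses[1])
  # missing masks are rejected
  imgs[[1]]$gt_mask <- NULL
  expect_error(run_supervised_training(dataset_split(train = imgs), sched),
               "lacks gt_mask")
})

test_that("early stopping triggers after patience non-improving iterations", {
  imgs <- smoke_images(8, seed = 4)
  split <- dataset_split(train = imgs[1:5], validation = imgs[6:8])
  sched <- training_schedule(epochs_per_iteration = rep(1L, 6L),
                             batch_size = 5L, initial_lr = 0,
                             early_stop_patience = 2L, seed = 0)
  run <- run_weakly_supervised_training(split, initializer_config("circle"),
                                        sched)
  # with a frozen model the validation loss goes flat after the first
  # target refresh, so patience 2 must cut the run short
  expect_true(run$stopped_early)
  expect_lt(max(run$history$iteration), 6)
  # early stopping without validation is refused
  expect_error(
    run_weakly_supervised_training(dataset_split(train = imgs),
                                   initializer_config("circle"), sched),
    "validation")
})

test_that("training refuses refinable images without boxes", {
  imgs <- smoke_images(4)
  imgs[[2]]$boxes <- list()
  expect_error(
    run_weakly_supervised_training(dataset_split(train = imgs),
                                   initializer_config("circle"),
                                   one_epoch_schedule()),
    "has no boxes")
})

test_that("weak-mix requires mask labels and never rewrites them", {
  imgs <- smoke_images(8, seed = 6)
  no_masks <- lapply(imgs, function(im) { im$gt_mask <- NULL; im })
  expect_error(train_variant(dataset_split(train = no_masks), "weak-mix",
                             schedule = one_epoch_schedule()),
               "mask-labelled")
  marked <- mark_fixed(imgs, 0.5, seed = 1)
  expect_equal(sum(vapply(marked, `[[`, TRUE, "fixed_target")), 4)
  split <- dataset_split(train = marked)
  run <- run_weakly_supervised_training(
    split, initializer_config("circle"),
    training_schedule(epochs_per_iteration = c(1L, 1L), batch_size = 4L,
                      initial_lr = 3e-3, early_stop_patience = 0L, seed = 0))
  for (im in run$train_images) {
    if (im$fixed_target) expect_identical(im$target, im$gt_mask)
  }
})

test_that("learning-rate decay follows the inverse-time rule", {
  sched <- training_schedule(epochs_per_iteration = c(2L, 2L, 2L),
                             initial_lr = 1e-4, lr_decay = 5e-4,
                             decay_start_iteration = 3L)
  # decay starts at global epoch 5 (first epoch of iteration 3)
  expect_equal(boxseg:::epoch_lr(sched, 4, 5), 1e-4)
  expect_equal(boxseg:::epoch_lr(sched, 5, 5), 1e-4 / (1 + 5e-4))
  expect_equal(boxseg:::epoch_lr(sched, 7, 5), 1e-4 / (1 + 3 * 5e-4))
})

test_that("fold assignment partitions evenly and deterministically", {
  f <- fold_assignment(1200, 10, seed = 3)
  expect_equal(as.vector(table(f)), rep(120L, 10))
  expect_identical(f, fold_assignment(1200, 10, seed = 3))
  expect_false(identical(f, fold_assignment(1200, 10, seed = 4)))
  expect_equal(sort(unique(fold_assignment(4, 2, seed = 1))), 1:2)
  expect_equal(as.vector(table(fold_assignment(4, 2, seed = 1))), c(2L, 2L))
})

test_that("cross_validate trains one model per disjoint fold", {
  imgs <- smoke_images(6, seed = 10)
  res <- cross_validate(imgs, k = 2, variant = "weak-ci", seed = 1,
                        schedule = one_epoch_schedule())
  expect_equal(nrow(res$folds), 2)
  expect_equal(sum(res$folds$n_test), 6)
  expect_true(all(res$folds$dice >= 0 & res$folds$dice <= 1))
  expect_equal(res$mean_dice, mean(res$folds$dice))
  expect_error(cross_validate(imgs, k = 7, variant = "weak-ci"),
               "k")
})
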