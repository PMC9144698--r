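#' Dice coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; equals the pixel-level F1 score. Returns 1
#' when both masks are empty (perfect agreement on "nothing there").
#'
#' @param pred,truth 0/1 matrices of equal dimensions.
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask dimensions differ")
  a <- sum(pred != 0); b <- sum(truth != 0)
  if (a + b == 0) return(1)
  2 * sum(pred != 0 & truth != 0) / (a + b)
}

#' Pixel accuracy between two binary masks
#'
#' `(TP + TN) / total pixels`.
#'
#' @param pred,truth 0/1 matrices of equal dimensions.
#' @return Numeric in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask dimensions differ")
  mean((pred != 0) == (truth != 0))
}

#' Pixel confusion counts
#'
#' @param pred,truth 0/1 matrices of equal dimensions.
#' @return Named numeric vector `tp, tn, fp, fn`; entries sum to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask dimensions differ")
  p <- pred != 0; t <- truth != 0
  c(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Evaluate a model on a set of annotated images
#'
#' Runs the model on every image, thresholds at `threshold`, and
#' compares with ground truth. Metrics are averaged per image (not
#' pooled over pixels), so the averaged confusion counts are generally
#' fractional; their sum still equals the per-image pixel count.
#'
#' @param model A trained [unet_model].
#' @param images List of [annotated_image()], all with `gt_mask`.
#' @param threshold Probability threshold for positives.
#' @param tag Optional tag filter: only images whose `tags` contain it
#'   are evaluated (e.g. a histology subset).
#' @param norm_stats Optional per-channel `list(mean, sd)` applied to
#'   pixels before prediction; defaults to `model$norm_stats` (the
#'   training-set statistics attached by the training functions) so
#'   inference sees the same normalization as training.
#' @return List with `mean_dice`, `sem_dice`, `mean_accuracy`,
#'   `sem_accuracy`, `mean_confusion` (named vector), `n_images`, and
#'   `per_image` (data frame of per-image metrics).
#' @export
evaluate_set <- function(model, images, threshold = 0.5, tag = NULL,
                         norm_stats = NULL) {
  if (!is.null(tag)) {
    images <- Filter(function(im) tag %in% im$tags, images)
  }
  if (length(images) == 0L) stop("no images to evaluate")
  if (is.null(norm_stats)) norm_stats <- model$norm_stats
  rows <- lapply(images, function(im) {
    if (is.null(im$gt_mask)) stop("image ", im$image_id, " lacks gt_mask")
    px <- im$pixels
    if (!is.null(norm_stats)) {
      cfg <- preprocess_config(target_size = dim(px)[1],
                               normalization = "dataset-stats",
                               dataset_mean = norm_stats$mean,
                               dataset_std = norm_stats$sd)
      px <- normalize_image(px, cfg)
    }
    prob <- predict_prob(model, px, normalize = FALSE)
    pred <- matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
    cc <- confusion_counts(pred, im$gt_mask)
    data.frame(image_id = im$image_id, dice = dice(pred, im$gt_mask),
               accuracy = pixel_accuracy(pred, im$gt_mask),
               tp = cc["tp"], tn = cc["tn"], fp = cc["fp"], fn = cc["fn"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(mean_dice = mean(per_image$dice), sem_dice = sem(per_image$dice),
       mean_accuracy = mean(per_image$accuracy),
       sem_accuracy = sem(per_image$accuracy),
       mean_confusion = c(tp = mean(per_image$tp), tn = mean(per_image$tn),
                          fp = mean(per_image$fp), fn = mean(per_image$fn)),
       n_images = nrow(per_image), per_image = per_image)
}

#' Two-sample t-test on per-fold scores
#'
#' Small utility for comparing two training variants on their
#' cross-validation fold scores.
#'
#' @param scores_a,scores_b Numeric vectors of fold scores.
#' @return `htest` object from [stats::t.test()].
#' @export
fold_t_test <- function(scores_a, scores_b) {
  stats::t.test(scores_a, scores_b)
}
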