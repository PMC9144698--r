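#' Pseudo-mask initializer configuration
#'
#' Three strategies produce the initial training targets for
#' box-annotated images:
#' \describe{
#'   \item{`circle`}{A solid circle at the box centre with diameter
#'     `circle_diameter_fraction` times the box's shorter side (default
#'     4/5).}
#'   \item{`prediction`}{A pre-trained model's probability map,
#'     thresholded (strictly above `prediction_threshold`) and clipped
#'     to the boxes.}
#'   \item{`hybrid`}{Per box: keep the clipped prediction unless its
#'     in-box area fraction is below `hybrid_area_fraction` (default
#'     30%), in which case fall back to the circle.}
#' }
#'
#' @param strategy One of `"circle"`, `"prediction"`, `"hybrid"`.
#' @param circle_diameter_fraction Circle diameter as a fraction of the
#'   box's shorter side, in `(0, 1]`.
#' @param prediction_threshold Probability threshold (strict) in `(0, 1)`.
#' @param hybrid_area_fraction Minimum in-box predicted-area fraction
#'   below which the prediction is rejected, in `(0, 1)`.
#' @return An `initializer_config` object.
#' @export
initializer_config <- function(strategy = c("circle", "prediction", "hybrid"),
                               circle_diameter_fraction = 0.8,
                               prediction_threshold = 0.5,
                               hybrid_area_fraction = 0.3) {
  strategy <- match.arg(strategy)
  stopifnot(circle_diameter_fraction > 0, circle_diameter_fraction <= 1,
            prediction_threshold > 0, prediction_threshold < 1,
            hybrid_area_fraction > 0, hybrid_area_fraction < 1)
  structure(list(strategy = strategy,
                 circle_diameter_fraction = circle_diameter_fraction,
                 prediction_threshold = prediction_threshold,
                 hybrid_area_fraction = hybrid_area_fraction),
            class = "initializer_config")
}

#' Solid-circle pseudo-mask for one box
#'
#' Rasterizes a disc centred at the box centre with diameter
#' `circle_diameter_fraction * min(box_w, box_h)`. A pixel is positive
#' iff its centre lies strictly inside the disc; the result is clipped
#' to the box (relevant only when the box overhangs the image edge).
#'
#' @param box A [bounding_box()].
#' @param width,height Image dimensions.
#' @param cfg An [initializer_config()].
#' @return 0/1 integer `height x width` matrix.
#' @export
circle_init <- function(box, width, height, cfg = initializer_config()) {
  if (!box_intersects_image(box, width, height)) {
    stop("box does not intersect the image")
  }
  d <- cfg$circle_diameter_fraction * min(box$box_w, box$box_h)
  if (d < 1) stop("circle diameter below one pixel (", signif(d, 3), ")")
  r2 <- (d / 2)^2
  x <- 0:(width - 1)
  y <- 0:(height - 1)
  inside <- outer((y - box$center_y)^2, (x - box$center_x)^2, `+`) < r2
  clip_mask_to_boxes(matrix(as.integer(inside), height, width), list(box))
}

#' Thresholded-prediction pseudo-mask
#'
#' Thresholds a probability map strictly above
#' `cfg$prediction_threshold`, then removes all positives outside the
#' boxes via [clip_mask_to_boxes()].
#'
#' @param prob Numeric `height x width` matrix in `[0, 1]`.
#' @param boxes List of [bounding_box()].
#' @param cfg An [initializer_config()].
#' @return 0/1 integer matrix.
#' @export
prediction_init <- function(prob, boxes, cfg = initializer_config()) {
  stopifnot(is.matrix(prob), all(prob >= 0), all(prob <= 1))
  clip_mask_to_boxes(matrix(as.integer(prob > cfg$prediction_threshold),
                            nrow(prob), ncol(prob)),
                     boxes)
}

#' Hybrid pseudo-mask: clipped prediction with circle fallback
#'
#' Decides per box: if the predicted positive area inside a box occupies
#' less than `cfg$hybrid_area_fraction` of the continuous box area
#' `box_w * box_h`, that box's initial mask is replaced by a solid
#' circle; otherwise the clipped prediction is kept. Multi-box images
#' take the union of the per-box decisions.
#'
#' @param prob Numeric probability matrix.
#' @param boxes List of [bounding_box()].
#' @param width,height Image dimensions.
#' @param cfg An [initializer_config()].
#' @return List with `mask` (0/1 matrix) and `used_circle` (logical per
#'   box, for logging how many boxes fell back to circles).
#' @export
hybrid_init <- function(prob, boxes, width, height,
                        cfg = initializer_config()) {
  stopifnot(nrow(prob) == height, ncol(prob) == width)
  out <- matrix(0L, height, width)
  used_circle <- logical(length(boxes))
  for (i in seq_along(boxes)) {
    box <- boxes[[i]]
    pred_box <- prediction_init(prob, list(box), cfg)
    frac <- sum(pred_box) / (box$box_w * box$box_h)
    if (frac < cfg$hybrid_area_fraction) {
      out <- pmax(out, circle_init(box, width, height, cfg))
      used_circle[i] <- TRUE
    } else {
      out <- pmax(out, pred_box)
    }
  }
  list(mask = matrix(as.integer(out), height, width),
       used_circle = used_circle)
}

#' Build initial training targets for a list of annotated images
#'
#' Applies the configured initializer to every refinable image
#' (fixed-target images keep their ground-truth target). The
#' `prediction` and `hybrid` strategies require `init_model`, a trained
#' [unet_model] used to produce the initial probability maps.
#'
#' @param images List of [annotated_image()].
#' @param cfg An [initializer_config()].
#' @param init_model Optional trained model for prediction-based
#'   strategies.
#' @return List with `images` (targets filled in) and `log` (data frame:
#'   image_id, strategy, circle_boxes).
#' @export
build_initial_targets <- function(images, cfg = initializer_config(),
                                  init_model = NULL) {
  if (cfg$strategy %in% c("prediction", "hybrid") && is.null(init_model)) {
    stop("strategy '", cfg$strategy, "' requires init_model")
  }
  log <- data.frame(image_id = character(), strategy = character(),
                    circle_boxes = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (img$fixed_target) {
      log <- rbind(log, data.frame(image_id = img$image_id,
                                   strategy = "fixed", circle_boxes = 0L))
      next
    }
    if (length(img$boxes) == 0L) {
      stop("refinable image ", img$image_id, " has no boxes")
    }
    h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
    n_circle <- 0L
    target <- switch(
      cfg$strategy,
      circle = {
        n_circle <- length(img$boxes)
        Reduce(pmax, lapply(img$boxes, circle_init, width = w, height = h,
                            cfg = cfg))
      },
      prediction = prediction_init(predict_prob(init_model, img$pixels),
                                   img$boxes, cfg),
      hybrid = {
        res <- hybrid_init(predict_prob(init_model, img$pixels), img$boxes,
                           w, h, cfg)
        n_circle <- sum(res$used_circle)
        res$mask
      })
    images[[i]]$target <- matrix(as.integer(target), h, w)
    log <- rbind(log, data.frame(image_id = img$image_id,
                                 strategy = cfg$strategy,
                                 circle_boxes = n_circle))
  }
  list(images = images, log = log)
}
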