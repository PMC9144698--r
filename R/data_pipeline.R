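#' Preprocessing configuration
#'
#' @param target_size Square output size in pixels (default 384).
#' @param normalization `"dataset-stats"` (global per-channel statistics,
#'   computed once on the training set and stored here) or
#'   `"per-image"` (each image standardized by its own mean/sd).
#' @param dataset_mean,dataset_std Per-channel statistics used by
#'   `"dataset-stats"` mode.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(target_size = 384L,
                              normalization = c("dataset-stats", "per-image"),
                              dataset_mean = c(0.5, 0.5, 0.5),
                              dataset_std = c(0.25, 0.25, 0.25)) {
  normalization <- match.arg(normalization)
  stopifnot(target_size > 0, all(dataset_std > 0))
  structure(list(target_size = as.integer(target_size),
                 normalization = normalization,
                 dataset_mean = dataset_mean, dataset_std = dataset_std),
            class = "preprocess_config")
}

#' Augmentation configuration
#'
#' Four augmentations: random integer translation (clamped so no box
#' leaves the image), zoom in/out about the image centre, independent
#' horizontal/vertical mirroring, and an additive per-channel Gaussian
#' colour shift applied to normalized intensities.
#'
#' @param max_translation Maximum shift in pixels (default 60).
#' @param zoom_range Maximum relative zoom (default 0.10, i.e. x0.9-x1.1).
#' @param flips Character subset of `c("horizontal", "vertical")`.
#' @param color_shift_std Standard deviation of the per-channel shift.
#' @param enabled Master switch; `FALSE` makes [augment()] the identity.
#' @return An `augment_config` object.
#' @export
augment_config <- function(max_translation = 60, zoom_range = 0.10,
                           flips = c("horizontal", "vertical"),
                           color_shift_std = 0.1, enabled = TRUE) {
  stopifnot(max_translation >= 0, zoom_range >= 0, zoom_range < 1)
  structure(list(max_translation = max_translation, zoom_range = zoom_range,
                 flips = flips, color_shift_std = color_shift_std,
                 enabled = isTRUE(enabled)),
            class = "augment_config")
}

# sample() treats a length-1 numeric as 1:n; this keeps singletons fixed
sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

resize_array <- function(a, new_h, new_w, nearest = FALSE) {
  filt <- if (nearest) "none" else "bilinear"
  out <- EBImage::resize(a, w = new_h, h = new_w, filter = filt)
  if (is.matrix(a)) matrix(as.numeric(out), new_h, new_w) else
    array(as.numeric(out), c(new_h, new_w, dim(a)[3]))
}

#' Resize and pad an image (with boxes and mask) to a square
#'
#' Scales by `target_size / max(H, W)` preserving aspect ratio, then
#' pads symmetrically with zeros to `target_size x target_size`. A
#' 480x640 input becomes 288x384 content with 48 rows of padding above
#' and below. Masks use nearest-neighbour interpolation (binarity is
#' preserved); images are bilinear.
#'
#' @param image `H x W x 3` array.
#' @param boxes List of [bounding_box()] (may be empty).
#' @param mask Optional `H x W` 0/1 matrix.
#' @param cfg A [preprocess_config()].
#' @return List with `image`, `boxes`, `mask`, and `transform` (the
#'   `resize_pad` transform applied, usable with [transform_box()] and
#'   invertible via [invert_resize_pad()]).
#' @export
resize_and_pad <- function(image, boxes = list(), mask = NULL,
                           cfg = preprocess_config()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  ts <- cfg$target_size
  scale <- ts / max(h, w)
  nh <- round(h * scale); nw <- round(w * scale)
  img2 <- resize_array(image, nh, nw)
  pad_y <- (ts - nh) %/% 2
  pad_x <- (ts - nw) %/% 2
  out <- array(0, c(ts, ts, 3))
  out[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- img2
  tr <- list(type = "resize_pad", scale = scale, pad_x = pad_x, pad_y = pad_y,
             width = ts, height = ts, orig_width = w, orig_height = h)
  mask_out <- NULL
  if (!is.null(mask)) {
    m2 <- resize_array(matrix(as.numeric(mask), h, w), nh, nw, nearest = TRUE)
    mask_out <- matrix(0L, ts, ts)
    mask_out[pad_y + seq_len(nh), pad_x + seq_len(nw)] <- as.integer(m2 != 0)
  }
  list(image = out, boxes = lapply(boxes, transform_box, transform = tr),
       mask = mask_out, transform = tr)
}

#' Invert the resize-pad mapping on a box
#'
#' @param box A [bounding_box()] in padded coordinates.
#' @param transform The `transform` element returned by
#'   [resize_and_pad()].
#' @return The box in original-image coordinates.
#' @export
invert_resize_pad <- function(box, transform) {
  s <- transform$scale
  bounding_box((box$center_x - transform$pad_x + 0.5) / s - 0.5,
               (box$center_y - transform$pad_y + 0.5) / s - 0.5,
               box$box_w / s, box$box_h / s)
}

translate_array <- function(a, dy, dx) {
  d <- dim(a); h <- d[1]; w <- d[2]
  out <- if (length(d) == 3L) array(0, d) else matrix(0, h, w)
  src_r <- intersect(seq_len(h) - dy, seq_len(h))
  src_c <- intersect(seq_len(w) - dx, seq_len(w))
  if (length(src_r) && length(src_c)) {
    if (length(d) == 3L) {
      out[src_r + dy, src_c + dx, ] <- a[src_r, src_c, ]
    } else {
      out[src_r + dy, src_c + dx] <- a[src_r, src_c]
    }
  }
  out
}

zoom_array <- function(a, f, nearest = FALSE) {
  d <- dim(a); h <- d[1]; w <- d[2]
  nh <- max(1L, round(f * h)); nw <- max(1L, round(f * w))
  z <- resize_array(a, nh, nw, nearest = nearest)
  out <- if (length(d) == 3L) array(0, d) else matrix(0, h, w)
  if (f >= 1) {
    off_y <- (nh - h) %/% 2; off_x <- (nw - w) %/% 2
    if (length(d) == 3L) out <- z[off_y + seq_len(h), off_x + seq_len(w), , drop = FALSE]
    else out <- z[off_y + seq_len(h), off_x + seq_len(w)]
    out <- if (length(d) == 3L) array(out, d) else matrix(out, h, w)
  } else {
    off_y <- (h - nh) %/% 2; off_x <- (w - nw) %/% 2
    if (length(d) == 3L) out[off_y + seq_len(nh), off_x + seq_len(nw), ] <- z
    else out[off_y + seq_len(nh), off_x + seq_len(nw)] <- z
  }
  out
}

#' Randomly augment an image with its boxes and mask
#'
#' Applies, in order: integer translation (uniform up to
#' `max_translation`, clamped so every box stays fully inside the
#' image), zoom in `[1 - zoom_range, 1 + zoom_range]` about the image
#' centre, independent horizontal/vertical flips with probability 0.5
#' each, and an additive per-channel colour shift drawn from
#' `Normal(0, color_shift_std)`. Boxes and mask are co-transformed.
#' Randomness comes from R's RNG; seed it for reproducibility.
#'
#' @param image `H x W x 3` array (normalized intensities).
#' @param boxes List of [bounding_box()].
#' @param mask Optional 0/1 matrix.
#' @param cfg An [augment_config()].
#' @return List with `image`, `boxes`, `mask`.
#' @export
augment <- function(image, boxes = list(), mask = NULL,
                    cfg = augment_config()) {
  if (!cfg$enabled) return(list(image = image, boxes = boxes, mask = mask))
  h <- dim(image)[1]; w <- dim(image)[2]

  # translation range keeping every box inside the image extent
  lo_x <- -cfg$max_translation; hi_x <- cfg$max_translation
  lo_y <- -cfg$max_translation; hi_y <- cfg$max_translation
  for (b in boxes) {
    bb <- box_bounds(b)
    lo_x <- max(lo_x, -(bb["x_min"] + 0.5)); hi_x <- min(hi_x, (w - 0.5) - bb["x_max"])
    lo_y <- max(lo_y, -(bb["y_min"] + 0.5)); hi_y <- min(hi_y, (h - 0.5) - bb["y_max"])
  }
  dx <- if (hi_x >= lo_x) sample1(ceiling(lo_x):floor(hi_x)) else 0L
  dy <- if (hi_y >= lo_y) sample1(ceiling(lo_y):floor(hi_y)) else 0L
  image <- translate_array(image, dy, dx)
  if (!is.null(mask)) mask <- translate_array(mask, dy, dx)
  boxes <- lapply(boxes, transform_box,
                  transform = list(type = "translate", dx = dx, dy = dy,
                                   width = w, height = h))

  f <- stats::runif(1, 1 - cfg$zoom_range, 1 + cfg$zoom_range)
  image <- zoom_array(image, f)
  if (!is.null(mask)) mask <- matrix(as.integer(zoom_array(mask, f, TRUE) != 0), h, w)
  boxes <- lapply(boxes, transform_box,
                  transform = list(type = "zoom", factor = f,
                                   width = w, height = h))

  if ("horizontal" %in% cfg$flips && stats::runif(1) < 0.5) {
    image <- image[, w:1, , drop = FALSE]
    if (!is.null(mask)) mask <- mask[, w:1, drop = FALSE]
    boxes <- lapply(boxes, transform_box,
                    transform = list(type = "flip_h", width = w, height = h))
  }
  if ("vertical" %in% cfg$flips && stats::runif(1) < 0.5) {
    image <- image[h:1, , , drop = FALSE]
    if (!is.null(mask)) mask <- mask[h:1, , drop = FALSE]
    boxes <- lapply(boxes, transform_box,
                    transform = list(type = "flip_v", width = w, height = h))
  }
  shift <- stats::rnorm(3, 0, cfg$color_shift_std)
  for (c in 1:3) image[, , c] <- image[, , c] + shift[c]
  list(image = image, boxes = boxes, mask = mask)
}

#' Per-channel normalization statistics of a training set
#'
#' @param images List of [annotated_image()].
#' @return List with `mean` and `sd`, each length 3.
#' @export
dataset_stats <- function(images) {
  px <- vapply(1:3, function(c) {
    vals <- unlist(lapply(images, function(im) as.numeric(im$pixels[, , c])))
    c(mean(vals), stats::sd(vals))
  }, numeric(2))
  list(mean = px[1, ], sd = px[2, ])
}

#' Normalize image intensities
#'
#' @param pixels `H x W x 3` array.
#' @param cfg A [preprocess_config()]; `"dataset-stats"` subtracts the
#'   stored per-channel mean and divides by the stored sd, `"per-image"`
#'   uses the image's own global mean/sd.
#' @return Normalized array.
#' @export
normalize_image <- function(pixels, cfg = preprocess_config()) {
  if (cfg$normalization == "per-image") {
    m <- mean(pixels); s <- stats::sd(as.numeric(pixels))
    if (s == 0) s <- 1
    return((pixels - m) / s)
  }
  for (c in 1:3) {
    pixels[, , c] <- (pixels[, , c] - cfg$dataset_mean[c]) / cfg$dataset_std[c]
  }
  pixels
}

# ---- dataset IO -----------------------------------------------------------

read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Read / write a binary mask PNG (0 = background, 255 = foreground)
#'
#' @param path PNG file path.
#' @return `read_mask_png` returns a 0/1 integer matrix and errors on
#'   any intermediate grey value.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (!is.matrix(a)) a <- a[, , 1]
  v <- round(a * 255)
  if (!all(v %in% c(0, 255))) {
    stop("mask PNG ", path, " is not binary (values other than 0/255)")
  }
  matrix(as.integer(v == 255), nrow(a), ncol(a))
}

#' @rdname read_mask_png
#' @param mask 0/1 matrix to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a probability map as an 8-bit PNG (`round(255 p)` grey levels)
#'
#' @param prob Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_prob_png <- function(prob, path) {
  png::writePNG(pmin(pmax(prob, 0), 1), path)
  invisible(path)
}

#' Load a dataset from the standard on-disk layout
#'
#' Layout: `images/<id>.png`, `boxes.csv` (see [read_boxes_csv()]),
#' optional `masks/<id>.png`, optional `manifest.json` with per-image
#' tags. Images with a mask are loaded as fixed-target (their target is
#' the ground truth); box-only images are refinable.
#'
#' @param dir Dataset directory.
#' @return List of [annotated_image()].
#' @export
load_dataset <- function(dir) {
  boxes_by_image <- read_boxes_csv(file.path(dir, "boxes.csv"))
  manifest <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf)
  ids <- names(boxes_by_image)
  lapply(ids, function(id) {
    ipath <- file.path(dir, "images", paste0(id, ".png"))
    if (!file.exists(ipath)) stop("missing image file: ", ipath)
    pixels <- read_image_png(ipath)
    mpath <- file.path(dir, "masks", paste0(id, ".png"))
    gt <- if (file.exists(mpath)) read_mask_png(mpath) else NULL
    tags <- character()
    if (!is.null(manifest) && !is.null(manifest$tags[[id]])) {
      tags <- unlist(manifest$tags[[id]])
    }
    annotated_image(id, pixels, boxes_by_image[[id]], gt_mask = gt,
                    fixed_target = !is.null(gt), tags = tags)
  })
}

#' Write a dataset in the standard on-disk layout
#'
#' @param images List of [annotated_image()].
#' @param dir Output directory (created if needed).
#' @param seed Optional seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(images, dir, seed = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  boxes_by_image <- list()
  tags <- list()
  for (im in images) {
    png::writePNG(pmin(pmax(im$pixels, 0), 1),
                  file.path(dir, "images", paste0(im$image_id, ".png")))
    if (!is.null(im$gt_mask)) {
      write_mask_png(im$gt_mask,
                     file.path(dir, "masks", paste0(im$image_id, ".png")))
    }
    boxes_by_image[[im$image_id]] <- im$boxes
    if (length(im$tags)) tags[[im$image_id]] <- im$tags
  }
  write_boxes_csv(boxes_by_image, file.path(dir, "boxes.csv"))
  manifest <- list(n_images = length(images),
                   image_ids = vapply(images, `[[`, "", "image_id"),
                   tags = tags, seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
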