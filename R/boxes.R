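#' Axis-aligned bounding box
#'
#' Constructs a bounding box from its centre and side lengths, in the
#' package's 0-based pixel-centre coordinate frame (see
#' [boxseg-package]). The box covers the continuous rectangle
#' `[center_x - box_w/2, center_x + box_w/2) x
#'  [center_y - box_h/2, center_y + box_h/2)`.
#'
#' @param center_x,center_y Box centre in pixels (continuous).
#' @param box_w,box_h Box width and height in pixels; must be positive.
#' @return An object of class `bounding_box`.
#' @examples
#' bounding_box(center_x = 16, center_y = 12, box_w = 10, box_h = 6)
#' @export
bounding_box <- function(center_x, center_y, box_w, box_h) {
  stopifnot(is.numeric(center_x), is.numeric(center_y),
            is.numeric(box_w), is.numeric(box_h))
  if (box_w <= 0 || box_h <= 0) {
    stop("box_w and box_h must be positive, got ", box_w, " x ", box_h)
  }
  structure(
    list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
         box_w = as.numeric(box_w), box_h = as.numeric(box_h)),
    class = "bounding_box"
  )
}

#' @export
print.bounding_box <- function(x, ...) {
  b <- box_bounds(x)
  cat(sprintf("<bounding_box %gx%g @ (%g, %g): x [%g, %g), y [%g, %g)>\n",
              x$box_w, x$box_h, x$center_x, x$center_y,
              b["x_min"], b["x_max"], b["y_min"], b["y_max"]))
  invisible(x)
}

#' Corner bounds of a bounding box
#'
#' @param box A [bounding_box()].
#' @return Named numeric vector `x_min, x_max, y_min, y_max`.
#' @export
box_bounds <- function(box) {
  c(x_min = box$center_x - box$box_w / 2, x_max = box$center_x + box$box_w / 2,
    y_min = box$center_y - box$box_h / 2, y_max = box$center_y + box$box_h / 2)
}

#' Does a box intersect a width x height image extent?
#'
#' The image extent is the rectangle `[-0.5, width - 0.5) x [-0.5, height - 0.5)`
#' around the pixel centres.
#' @param box A [bounding_box()].
#' @param width,height Image dimensions in pixels.
#' @return Logical scalar.
#' @export
box_intersects_image <- function(box, width, height) {
  b <- box_bounds(box)
  b["x_min"] < width - 0.5 && b["x_max"] > -0.5 &&
    b["y_min"] < height - 0.5 && b["y_max"] > -0.5
}

#' Binary interior mask of a set of boxes
#'
#' Marks every pixel whose centre lies inside at least one box.
#'
#' @param boxes List of [bounding_box()] (may be empty).
#' @param width,height Image dimensions in pixels.
#' @return An integer `height x width` matrix of 0/1.
#' @export
box_union_mask <- function(boxes, width, height) {
  out <- matrix(0L, nrow = height, ncol = width)
  x <- 0:(width - 1)
  y <- 0:(height - 1)
  for (box in boxes) {
    b <- box_bounds(box)
    cols <- which(x >= b["x_min"] & x < b["x_max"])
    rows <- which(y >= b["y_min"] & y < b["y_max"])
    if (length(rows) && length(cols)) out[rows, cols] <- 1L
  }
  out
}

#' Clip a binary mask to the union of bounding boxes
#'
#' Positive pixels whose centres fall outside every box are set to zero;
#' negatives are never modified. This is the external-consistency
#' constraint of box supervision: boxes guarantee that everything outside
#' them is background. An empty box list yields the all-zero mask.
#'
#' @param mask Integer/numeric matrix of 0/1 (rows = y, cols = x).
#' @param boxes List of [bounding_box()].
#' @return A 0/1 integer matrix of the same dimensions.
#' @export
clip_mask_to_boxes <- function(mask, boxes) {
  stopifnot(is.matrix(mask))
  inside <- box_union_mask(boxes, width = ncol(mask), height = nrow(mask))
  out <- ifelse(mask != 0 & inside != 0, 1L, 0L)
  matrix(as.integer(out), nrow = nrow(mask))
}

#' Map a bounding box through a geometric transform
#'
#' Keeps box annotations aligned with their image under the augmentation
#' and preprocessing transforms. Supported transforms:
#' \describe{
#'   \item{`flip_h`, `flip_v`}{Mirror about the vertical/horizontal image
#'     axis; needs `width`/`height`.}
#'   \item{`translate`}{Shift by `dx`, `dy` pixels.}
#'   \item{`zoom`}{Scale by `factor` about the image centre; box sides
#'     scale with the factor.}
#'   \item{`resize_pad`}{Uniform scale by `scale` then offset by
#'     `pad_x`, `pad_y` (the mapping applied by [resize_and_pad()]).}
#' }
#'
#' @param box A [bounding_box()].
#' @param transform Named list with a `type` field and the parameters above,
#'   plus `width`/`height` of the *output* image for the intersection check.
#' @return The transformed [bounding_box()].
#' @export
transform_box <- function(box, transform) {
  type <- transform$type
  out <- switch(
    type,
    flip_h = bounding_box((transform$width - 1) - box$center_x, box$center_y,
                          box$box_w, box$box_h),
    flip_v = bounding_box(box$center_x, (transform$height - 1) - box$center_y,
                          box$box_w, box$box_h),
    translate = bounding_box(box$center_x + transform$dx,
                             box$center_y + transform$dy,
                             box$box_w, box$box_h),
    zoom = {
      f <- transform$factor
      cx <- (transform$width - 1) / 2
      cy <- (transform$height - 1) / 2
      bounding_box(cx + f * (box$center_x - cx), cy + f * (box$center_y - cy),
                   f * box$box_w, f * box$box_h)
    },
    # pixel-centre mapping of a uniform resize: x' = (x + 1/2) s - 1/2
    resize_pad = bounding_box(
      (box$center_x + 0.5) * transform$scale - 0.5 + transform$pad_x,
      (box$center_y + 0.5) * transform$scale - 0.5 + transform$pad_y,
      box$box_w * transform$scale, box$box_h * transform$scale),
    stop("unknown transform type: ", type)
  )
  if (!is.null(transform$width) && !is.null(transform$height) &&
      !box_intersects_image(out, transform$width, transform$height)) {
    stop("transformed box no longer intersects the image")
  }
  out
}

#' Read bounding boxes from CSV
#'
#' Expected columns: `image_id, x_min, y_min, box_w, box_h` (0-based
#' min-corner storage, pixels); centres are derived as
#' `center = min + size/2`.
#'
#' @param path CSV file path.
#' @return Named list mapping image_id to a list of [bounding_box()].
#' @export
read_boxes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "box_w", "box_h")
  if (!all(need %in% names(df))) {
    stop("boxes CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(df$box_w <= 0 | df$box_h <= 0)
  if (length(bad)) {
    stop("zero/negative-area box in CSV at data row(s): ",
         paste(bad, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- as.character(df$image_id[i])
    b <- bounding_box(df$x_min[i] + df$box_w[i] / 2,
                      df$y_min[i] + df$box_h[i] / 2,
                      df$box_w[i], df$box_h[i])
    out[[id]] <- c(out[[id]], list(b))
  }
  out
}

#' Write bounding boxes to CSV
#'
#' @param boxes_by_image Named list mapping image_id to lists of boxes.
#' @param path Output CSV path.
#' @export
write_boxes_csv <- function(boxes_by_image, path) {
  rows <- list()
  for (id in names(boxes_by_image)) {
    for (b in boxes_by_image[[id]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id,
        x_min = b$center_x - b$box_w / 2, y_min = b$center_y - b$box_h / 2,
        box_w = b$box_w, box_h = b$box_h, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Annotated image record
#'
#' Bundles an image with its box annotations, optional ground-truth mask,
#' and the current training target. Images carrying a human ground-truth
#' mask can be marked `fixed_target`: their target equals the ground truth
#' and is never rewritten by iterative refinement.
#'
#' @param image_id Character id, unique within a dataset.
#' @param pixels `H x W x 3` numeric array in `[0, 1]`.
#' @param boxes List of [bounding_box()].
#' @param gt_mask Optional `H x W` 0/1 matrix.
#' @param target Optional `H x W` 0/1 matrix (current training target);
#'   defaults to `gt_mask` when `fixed_target` is `TRUE`.
#' @param fixed_target Logical; `TRUE` pins the target to `gt_mask`.
#' @param tags Character vector of free-form labels (used by
#'   [evaluate_set()] subset filtering).
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, pixels, boxes = list(), gt_mask = NULL,
                            target = NULL, fixed_target = FALSE,
                            tags = character()) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (!is.null(gt_mask)) {
    stopifnot(is.matrix(gt_mask), nrow(gt_mask) == h, ncol(gt_mask) == w)
    if (!all(gt_mask %in% c(0, 1))) stop("gt_mask must be binary 0/1")
    gt_mask <- matrix(as.integer(gt_mask), h, w)
  }
  for (b in boxes) {
    if (!inherits(b, "bounding_box")) stop("boxes must be bounding_box objects")
    if (!box_intersects_image(b, w, h)) {
      stop("box outside image extent for image ", image_id)
    }
  }
  if (fixed_target) {
    if (is.null(gt_mask)) stop("fixed_target requires a gt_mask")
    target <- gt_mask
  } else if (!is.null(target)) {
    stopifnot(is.matrix(target), nrow(target) == h, ncol(target) == w)
    target <- matrix(as.integer(target != 0), h, w)
  }
  structure(
    list(image_id = image_id, pixels = pixels, boxes = boxes,
         gt_mask = gt_mask, target = target, fixed_target = isTRUE(fixed_target),
         tags = tags),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image '%s' %dx%d, %d box(es), gt_mask: %s, %s>\n",
              x$image_id, d[1], d[2], length(x$boxes),
              if (is.null(x$gt_mask)) "no" else "yes",
              if (x$fixed_target) "fixed target" else "refinable"))
  invisible(x)
}

#' Train/validation/test split of annotated images
#'
#' @param train,validation,test Lists of [annotated_image()]; the three
#'   lists must be disjoint by `image_id`.
#' @param fold_index Integer fold label (for cross-validation bookkeeping).
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train, validation = list(), test = list(),
                          fold_index = 0L) {
  ids <- c(vapply(train, `[[`, "", "image_id"),
           vapply(validation, `[[`, "", "image_id"),
           vapply(test, `[[`, "", "image_id"))
  if (anyDuplicated(ids)) stop("split lists share image_id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(train = train, validation = validation, test = test,
                 fold_index = as.integer(fold_index)),
            class = "dataset_split")
}
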