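# Independent scalar oracles used to cross-check the vectorized
# implementations. These are deliberately written as plain double loops.

# Oval-ring loss mask, evaluated pixel by pixel.
oracle_loss_mask <- function(box, width, height,
                             inner_ring_diameter = 0.6,
                             outer_ring_diameter = 1.0) {
  inner_radius <- min(box$box_w, box$box_h) * inner_ring_diameter * 0.5
  outer_radius <- max(box$box_w, box$box_h) * outer_ring_diameter * 0.5
  x_str <- if (box$box_w >= box$box_h) box$box_w / box$box_h else 1
  y_str <- if (box$box_h >= box$box_w) box$box_h / box$box_w else 1
  d <- matrix(0, height, width)
  inv <- matrix(0, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      x <- c - 1; y <- r - 1
      d[r, c] <- (x - box$center_x)^2 / x_str + (y - box$center_y)^2 / y_str
      inv[r, c] <- as.numeric(d[r, c] < outer_radius &&
                                d[r, c] > inner_radius)
    }
  }
  mid <- (outer_radius + inner_radius) / 2
  ramp <- matrix(0, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      ramp[r, c] <- abs(d[r, c] - mid)^1.5 * inv[r, c]
    }
  }
  ramp / max(ramp) + (1 - inv)
}

# Point-in-box clipping, pixel by pixel.
oracle_clip <- function(mask, boxes) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c] == 0) next
      x <- c - 1; y <- r - 1
      for (b in boxes) {
        if (x >= b$center_x - b$box_w / 2 && x < b$center_x + b$box_w / 2 &&
            y >= b$center_y - b$box_h / 2 && y < b$center_y + b$box_h / 2) {
          out[r, c] <- 1L
          break
        }
      }
    }
  }
  out
}

# Pixel-count metrics by explicit counting.
oracle_counts <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (c in seq_len(ncol(pred))) {
      p <- pred[r, c] != 0; t <- truth[r, c] != 0
      if (p && t) tp <- tp + 1L
      else if (!p && !t) tn <- tn + 1L
      else if (p && !t) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_dice <- function(pred, truth) {
  cc <- oracle_counts(pred, truth)
  if (cc["tp"] + cc["fp"] + cc["fn"] == 0) return(1)
  unname(2 * cc["tp"] / (2 * cc["tp"] + cc["fp"] + cc["fn"]))
}

# Random box that intersects a width x height image and whose ring
# region is guaranteed non-degenerate at these sizes.
random_box <- function(width, height, min_side = 8) {
  w <- runif(1, min_side, 0.8 * width)
  h <- runif(1, min_side, 0.8 * height)
  bounding_box(center_x = runif(1, 0.2 * width, 0.8 * width),
               center_y = runif(1, 0.2 * height, 0.8 * height),
               box_w = w, box_h = h)
}

# Small deterministic RGB test image.
test_pixels <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}
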