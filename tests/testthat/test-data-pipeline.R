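test_that("resize_and_pad maps 480x640 to 288x384 content with 48px bands", {
  set.seed(8)
  img <- array(runif(480 * 640 * 3), c(480, 640, 3))
  mask <- matrix(0L, 480, 640); mask[200:280, 300:400] <- 1L
  box <- bounding_box(349.5, 239.5, 101, 81)
  res <- resize_and_pad(img, list(box), mask)
  expect_equal(dim(res$image), c(384, 384, 3))
  expect_equal(res$transform$scale, 0.6)
  expect_equal(res$transform$pad_y, 48)
  expect_equal(res$transform$pad_x, 0)
  # zero padding above and below the 288-row content band
  expect_true(all(res$image[1:48, , ] == 0))
  expect_true(all(res$image[337:384, , ] == 0))
  expect_gt(sum(abs(res$image[49:336, , ])), 0)
  expect_true(all(res$mask %in% c(0L, 1L)))
  # box forward-then-inverse round trip within 1 px
  back <- invert_resize_pad(res$boxes[[1]], res$transform)
  expect_lt(abs(back$center_x - box$center_x), 1)
  expect_lt(abs(back$center_y - box$center_y), 1)
  expect_lt(abs(back$box_w - box$box_w), 1)
})

test_that("resize_and_pad on an already-square image is near-identity", {
  img <- array(runif(384 * 384 * 3), c(384, 384, 3))
  res <- resize_and_pad(img)
  expect_equal(res$transform$scale, 1)
  expect_equal(res$image, img, tolerance = 1e-8)
})

test_that("augmentation is the identity when disabled", {
  img <- test_pixels(32, 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  boxes <- list(bounding_box(10, 10, 8, 8))
  res <- augment(img, boxes, mask, augment_config(enabled = FALSE))
  expect_identical(res$image, img)
  expect_identical(res$mask, mask)
  expect_identical(res$boxes, boxes)
})

test_that("augmented boxes never leave the image; masks follow boxes", {
  set.seed(31)
  imgs <- generate_dataset(scene_config(image_size = 64L, n_images = 5L,
                                        seed = 13L))
  cfg <- augment_config(max_translation = 20, zoom_range = 0.1)
  for (im in imgs) {
    for (rep in 1:5) {
      res <- augment(im$pixels, im$boxes, im$gt_mask, cfg)
      # boxes stay on the image (zoom-out may overhang slightly, but a
      # transformed box must always keep intersecting the extent)
      for (b in res$boxes) {
        expect_true(box_intersects_image(b, 64, 64))
      }
      # transformed mask positives stay inside the transformed box union
      # (1-px dilation absorbs nearest-neighbour resampling at the rim)
      grown <- lapply(res$boxes, function(b) {
        bounding_box(b$center_x, b$center_y, b$box_w + 2.2, b$box_h + 2.2)
      })
      inside <- box_union_mask(grown, 64, 64)
      expect_equal(sum(res$mask > inside), 0)
    }
  }
})

test_that("a box at the image edge blocks outward translation", {
  img <- test_pixels(32, 32)
  box <- bounding_box(29, 16, 6, 6)  # right edge at x = 32 > 31.5
  cfg <- augment_config(max_translation = 10, zoom_range = 0,
                        flips = character(), color_shift_std = 0)
  set.seed(77)
  for (rep in 1:20) {
    res <- augment(img, list(box), NULL, cfg)
    expect_lte(box_bounds(res$boxes[[1]])["x_max"], 31.51)
  }
})

test_that("colour shifts follow the stated Gaussian", {
  img <- array(0.5, c(4, 4, 3))
  cfg <- augment_config(max_translation = 0, zoom_range = 0,
                        flips = character(), color_shift_std = 0.1)
  set.seed(55)
  shifts <- replicate(10000, {
    res <- augment(img, list(), NULL, cfg)
    res$image[1, 1, ] - 0.5
  })
  expect_lt(abs(mean(shifts)), 0.01)
  expect_lt(abs(sd(shifts) - 0.1), 0.01)
})

test_that("dataset-stats normalization standardizes the set", {
  imgs <- generate_dataset(scene_config(image_size = 64L, n_images = 6L,
                                        seed = 2L))
  st <- dataset_stats(imgs)
  cfg <- preprocess_config(64L, "dataset-stats", st$mean, st$sd)
  normed <- lapply(imgs, function(im) normalize_image(im$pixels, cfg))
  all_vals <- unlist(normed)
  expect_lt(abs(mean(all_vals)), 0.05)
  expect_lt(abs(sd(all_vals) - 1), 0.05)
})

test_that("datasets round-trip exactly through the on-disk layout", {
  imgs <- generate_dataset(scene_config(image_size = 64L, n_images = 3L,
                                        seed = 17L))
  imgs[[2]]$tags <- c("distractor", "SSA")
  dir <- withr::local_tempdir()
  write_dataset(imgs, dir, seed = 17L)
  back <- load_dataset(dir)
  ids <- vapply(back, `[[`, "", "image_id")
  for (i in seq_along(imgs)) {
    j <- match(imgs[[i]]$image_id, ids)
    expect_equal(back[[j]]$pixels, imgs[[i]]$pixels)
    expect_equal(back[[j]]$gt_mask, imgs[[i]]$gt_mask)
    expect_equal(back[[j]]$boxes, imgs[[i]]$boxes)
  }
  expect_setequal(back[[match("scene_0002", ids)]]$tags,
                  c("distractor", "SSA"))
  # images with masks load as fixed-target, and their target is the mask
  expect_true(all(vapply(back, `[[`, TRUE, "fixed_target")))
  expect_identical(back[[1]]$target, back[[1]]$gt_mask)
})

test_that("corrupt inputs are rejected with useful errors", {
  dir <- withr::local_tempdir()
  # non-binary mask PNG
  png::writePNG(matrix(128 / 255, 8, 8), file.path(dir, "grey.png"))
  expect_error(read_mask_png(file.path(dir, "grey.png")), "not binary")
  # boxes CSV referencing a missing image
  dir.create(file.path(dir, "images"))
  write_boxes_csv(list(ghost = list(bounding_box(4, 4, 4, 4))),
                  file.path(dir, "boxes.csv"))
  expect_error(load_dataset(dir), "missing image")
})

test_that("probability maps export as 8-bit PNG of round(255 p)", {
  prob <- matrix(seq(0, 1, length.out = 64), 8, 8)
  tmp <- withr::local_tempfile(fileext = ".png")
  write_prob_png(prob, tmp)
  back <- png::readPNG(tmp)
  expect_equal(round(back * 255), round(prob * 255))
})
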