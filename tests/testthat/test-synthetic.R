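test_that("generation is bit-reproducible and prefix-stable", {
  cfg <- scene_config(image_size = 64L, n_images = 6L, seed = 4L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  expect_identical(lapply(a, `[[`, "gt_mask"), lapply(b, `[[`, "gt_mask"))
  # counter-based seeding: scene i does not depend on n_images
  c3 <- generate_dataset(scene_config(image_size = 64L, n_images = 3L,
                                      seed = 4L))
  expect_identical(c3[[2]]$pixels, a[[2]]$pixels)
})

test_that("tight boxes hug the mask on all four sides", {
  imgs <- generate_dataset(scene_config(image_size = 96L, n_images = 8L,
                                        seed = 9L))
  for (im in imgs) {
    expect_length(im$boxes, 1)
    b <- box_bounds(im$boxes[[1]])
    pos <- which(im$gt_mask != 0, arr.ind = TRUE)
    expect_equal(unname(b["x_min"]), min(pos[, 2]) - 1 - 0.5)
    expect_equal(unname(b["x_max"]), max(pos[, 2]) - 1 + 0.5)
    expect_equal(unname(b["y_min"]), min(pos[, 1]) - 1 - 0.5)
    expect_equal(unname(b["y_max"]), max(pos[, 1]) - 1 + 0.5)
    # all positives inside the box
    expect_equal(sum(im$gt_mask > box_union_mask(im$boxes, 96, 96)), 0)
  }
})

test_that("polyp area sits in the inscribed-region sanity band", {
  imgs <- generate_dataset(scene_config(image_size = 96L, n_images = 15L,
                                        seed = 6L))
  for (im in imgs) {
    box_area <- sum(vapply(im$boxes, function(b) b$box_w * b$box_h, 0))
    ratio <- sum(im$gt_mask) / box_area
    expect_gt(ratio, pi / 8)
    expect_lt(ratio, pi / 4 + 0.1)
  }
})

test_that("loose boxes scale the tight box without touching the mask", {
  tight <- generate_dataset(scene_config(image_size = 96L, n_images = 6L,
                                         seed = 11L))
  loose <- generate_dataset(scene_config(image_size = 96L, n_images = 6L,
                                         loose_box_padding = 0.5,
                                         seed = 11L))
  for (i in seq_along(tight)) {
    expect_identical(loose[[i]]$gt_mask, tight[[i]]$gt_mask)
    tb <- tight[[i]]$boxes[[1]]; lb <- loose[[i]]$boxes[[1]]
    ratio <- (lb$box_w * lb$box_h) / (tb$box_w * tb$box_h)
    expect_gt(ratio, 2.0)   # clipping at image edges can shave the 4x
    expect_lte(ratio, 4.3)
    # padding never drops mask pixels from the box
    expect_equal(sum(loose[[i]]$gt_mask >
                       box_union_mask(loose[[i]]$boxes, 96, 96)), 0)
  }
})

test_that("distractor bars are tagged and stay off the polyp mask", {
  imgs <- generate_dataset(scene_config(image_size = 64L, n_images = 6L,
                                        distractor_probability = 1,
                                        seed = 21L))
  expect_true(all(vapply(imgs, function(im) "distractor" %in% im$tags, TRUE)))
  clean <- generate_dataset(scene_config(image_size = 64L, n_images = 6L,
                                         distractor_probability = 0,
                                         seed = 21L))
  expect_true(all(vapply(clean, function(im) length(im$tags) == 0L, TRUE)))
})

test_that("benchmark profiles have their published shapes", {
  smoke <- benchmark_suite("smoke", seed = 1)
  expect_equal(vapply(list(smoke$train, smoke$validation, smoke$test),
                      length, 0L), c(14L, 3L, 3L))
  expect_equal(dim(smoke$train[[1]]$pixels), c(64, 64, 3))

  rec <- benchmark_suite("recovery", seed = 1)
  expect_equal(length(rec$train), 200L)
  expect_equal(length(rec$validation), 0L)
  expect_equal(length(rec$test), 50L)
  expect_equal(dim(rec$train[[1]]$pixels), c(96, 96, 3))

  ord <- benchmark_suite("ordering", seed = 1)
  expect_equal(length(ord$train), 120L)
  expect_equal(length(ord$test), 30L)
  expect_equal(length(ord$init_train), 30L)
  # the profile mixes loose-box and distractor scenes
  expect_gt(sum(grepl("^ord_l", vapply(ord$train, `[[`, "", "image_id"))), 0)
  expect_gt(sum(vapply(c(ord$train, ord$test),
                       function(im) "distractor" %in% im$tags, TRUE)), 0)
})

test_that("two-polyp scenes get one tight box per blob", {
  imgs <- generate_dataset(scene_config(image_size = 96L, n_images = 4L,
                                        polyps_per_image = c(2L, 2L),
                                        polyp_axes_range = c(8, 12),
                                        seed = 31L))
  for (im in imgs) {
    expect_length(im$boxes, 2)
    expect_equal(sum(im$gt_mask > box_union_mask(im$boxes, 96, 96)), 0)
    # each box contains some mask and boxes are disjoint blobs
    for (b in im$boxes) {
      expect_gt(sum(im$gt_mask * box_union_mask(list(b), 96, 96)), 0)
    }
  }
})

test_that("oversized polyps are rejected", {
  expect_error(
    generate_dataset(scene_config(image_size = 24L, n_images = 1L,
                                  polyp_axes_range = c(14, 15), seed = 1L)),
    "too large")
})
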