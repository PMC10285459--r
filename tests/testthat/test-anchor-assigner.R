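small_pyramid <- function(size = 32, strides = c(4, 8, 16),
                          areas = c(16, 32, 64)^2)
  build_anchor_pyramid(c(size, size), strides, areas)

test_that("anchor pyramids have the prescribed layout", {
  pyr <- build_anchor_pyramid(c(64, 64))
  expect_length(pyr$levels, 5)
  # stride-4 level of a 64 px image: 16 x 16 positions x 3 ratios
  expect_equal(nrow(pyr$levels[[1]]$anchors), 16 * 16 * 3)
  for (l in seq_along(pyr$levels)) {
    a <- pyr$levels[[l]]$anchors
    # every anchor preserves its level's area through canonicalization
    expect_equal(unname(a[, "w"] * a[, "h"]),
                 rep(c(32, 64, 128, 256, 512)[l]^2, nrow(a)),
                 tolerance = 1e-6)
    # horizontal anchors: theta 0 (wide, square) or pi/2 (canonicalized tall)
    expect_true(all(a[, "theta"] %in% c(0, pi / 2)))
    expect_true(all(a[, "w"] >= a[, "h"]))
  }
  # centers at (i + 0.5) * stride
  a1 <- pyr$levels[[2]]$anchors
  expect_true(all(abs((a1[, "x"] / 8 - 0.5) -
                        round(a1[, "x"] / 8 - 0.5)) < 1e-9))
  # ratio set {2, 1, 0.5} collapses to w/h in {2, 1} after the long-edge swap
  expect_setequal(round(unique(a1[, "w"] / a1[, "h"]), 6), c(2, 1))
  expect_error(build_anchor_pyramid(c(64, 64), strides = numeric(0)),
               "stride")
})

test_that("adaptive assignment applies the mean + sd threshold per instance", {
  pyr <- small_pyramid()
  gt <- rbox(16, 16, 24, 6, 0.5)
  asg <- adaptive_assign(pyr, gt, n_per_level = 9)
  pos <- which(asg$labels == 1L)
  expect_gte(length(pos), 1)
  # every non-fallback positive clears the reported threshold
  anchors <- rotodet:::flatten_anchors(pyr)
  ious <- skew_iou(anchors[pos, ], gt)[, 1]
  if (length(pos) > 1) expect_true(all(ious >= asg$thresholds[1] - 1e-12))
  # candidates are m * n_per_level center-closest anchors
  expect_length(asg$candidates[[1]], 9 * 3)
  # no ground truths: everything negative
  none <- adaptive_assign(pyr, rotodet:::empty_rbox())
  expect_true(all(none$labels == 0L))
})

test_that("equal candidate overlaps make every candidate positive", {
  # sd = 0 so the threshold equals the common value and all candidates pass
  pyr <- build_anchor_pyramid(c(16, 16), strides = 4, areas = 16^2,
                              ratios = 1)
  gt <- rbox(8, 8, 16, 16, 0)   # symmetric around the grid center
  asg <- adaptive_assign(pyr, gt, n_per_level = 4)
  cand <- asg$candidates[[1]]
  ious <- skew_iou(rotodet:::flatten_anchors(pyr)[cand, ], gt)[, 1]
  expect_equal(length(unique(round(ious, 9))), 1L)
  expect_equal(sort(which(asg$labels == 1L)), sort(cand))
})

test_that("fallback guarantees a positive for hard instances", {
  # one level of 16x16 anchors on a 2x2 grid; a gt halfway between two
  # anchor centers draws candidates with IoUs {0.6, 0.6, 0.23}, whose
  # mean + sd threshold (~0.65) excludes them all -> fallback fires
  pyr <- build_anchor_pyramid(c(16, 16), strides = 8, areas = 16^2,
                              ratios = 1)
  gt <- rbox(8, 4, 16, 16, 0)
  asg <- adaptive_assign(pyr, gt, n_per_level = 3)
  cand <- asg$candidates[[1]]
  ious <- unname(skew_iou(rotodet:::flatten_anchors(pyr)[cand, ], gt)[, 1])
  expect_gt(asg$thresholds[1], max(ious))
  expect_equal(sum(asg$labels == 1L), 1L)
  pos <- which(asg$labels == 1L)
  expect_equal(skew_iou(rotodet:::flatten_anchors(pyr)[pos, ], gt),
               max(ious))
  # slivers still receive at least one positive
  sliver <- adaptive_assign(small_pyramid(), rbox(13, 17, 20, 0.5, 0.9))
  expect_gte(sum(sliver$labels == 1L), 1L)
})

test_that("assignment matches the explicit-loop reference", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      size <- sample(c(24, 32, 40), 1)
      pyr <- small_pyramid(size)
      n_gt <- sample(1:5, 1)
      gts <- rbox(runif(n_gt, 4, size - 4), runif(n_gt, 4, size - 4),
                  runif(n_gt, 6, size), runif(n_gt, 2, 10),
                  runif(n_gt, -pi / 4, 3 * pi / 4))
      fast <- adaptive_assign(pyr, gts, n_per_level = 6)$labels
      slow <- brute_adaptive_assign(pyr, gts, n_per_level = 6)
      expect_identical(fast, slow)
    }
  })
})

test_that("every instance in generated scenes receives a positive anchor", {
  pyr <- build_anchor_pyramid(c(128, 128))
  for (i in 1:25) {
    gts <- generate_scene(scene_spec(density = "medium", seed = 700 + i,
                                     image_size = c(128, 128)))$record$instances
    asg <- adaptive_assign(pyr, gts)
    expect_equal(sort(unique(asg$labels[asg$labels > 0L])),
                 seq_len(nrow(gts)))
  }
})

test_that("batch sampling keeps the 1:1 ratio and is seed-deterministic", {
  pyr <- small_pyramid()
  gts <- rbox(c(10, 22), c(10, 22), c(18, 14), c(5, 4), c(0.3, 1.2))
  asg <- adaptive_assign(pyr, gts)
  b <- sample_training_batch(asg, n_total = 256, seed = 9)
  expect_equal(length(b$positive), length(b$negative))
  expect_true(all(asg$labels[b$positive] > 0L))
  expect_true(all(asg$labels[b$negative] == 0L))
  b2 <- sample_training_batch(asg, n_total = 256, seed = 9)
  expect_identical(b, b2)
  # cap: a flood of positives is cut to n_total / 2
  fake <- structure(list(labels = rep(c(1L, 0L), 200)),
                    class = "assignment_result")
  bc <- sample_training_batch(fake, n_total = 256, seed = 1)
  expect_equal(bc$n_pos, 128)
  expect_equal(bc$n_total, 256)
  bd <- sample_training_batch(fake, n_total = 256, seed = 2)
  expect_false(identical(bc$positive, bd$positive))
  # all-positive assignment has no negatives to draw
  allpos <- structure(list(labels = rep(1L, 50)),
                      class = "assignment_result")
  expect_error(sample_training_batch(allpos), "negative")
})
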