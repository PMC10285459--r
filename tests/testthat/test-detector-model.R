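tiny_cfg <- detector_config("tiny", input_size = 64)

test_that("model building is deterministic and counts parameters exactly", {
  m1 <- build_model(tiny_cfg, seed = 3)
  m2 <- build_model(tiny_cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_cfg, seed = 4)
  expect_false(identical(m1$params$backbone$stem$W, m3$params$backbone$stem$W))
  # dense-head parameter arithmetic
  big <- detector_config("resnet50")
  mb <- build_model(big, seed = 0)
  expect_equal(length(mb$params$rcnn$cls$W) + length(mb$params$rcnn$cls$b),
               1024 * 2 + 2)
  expect_equal(length(mb$params$rcnn$reg$W) + length(mb$params$rcnn$reg$b),
               1024 * 5 + 5)
  # architecture total, frozen once computed; ~0.6% above the reference
  # implementation's 41.12M (which runs its backbone convolutions bias-free)
  expect_equal(count_parameters(mb), 41376537L)
  rm(mb); gc()
})

test_that("pyramid grids follow the stride arithmetic", {
  shp <- model_feature_shapes(detector_config("resnet50"), 1024)
  expect_equal(shp[, "width"], c(256, 128, 64, 32, 16))
  expect_equal(shp[, "stride"], c(4, 8, 16, 32, 64))
})

test_that("head outputs have the W*H*3 and W*H*15 shape contract", {
  m <- build_model(tiny_cfg, seed = 0)
  img <- array(0.5, dim = c(64, 64, 3))
  feats <- rotodet:::extract_pyramid(m, img)
  expect_named(feats$pyramid, c("p2", "p3", "p4", "p5", "p6"))
  shp <- model_feature_shapes(m, 64)
  head_out <- rotodet:::rpn_head_fwd(m$params$rpn, feats$pyramid)
  for (l in 1:5) {
    hw <- unname(c(shp[l, "height"], shp[l, "width"]))
    expect_equal(dim(feats$pyramid[[l]]), c(hw, m$config$fpn_channels))
    expect_equal(dim(head_out[[l]]$scores), c(hw, 3))
    expect_equal(dim(head_out[[l]]$deltas), c(hw, 15))
  }
})

test_that("proposal generation decodes, caps and respects scores", {
  m <- build_model(tiny_cfg, seed = 0)
  pyr <- build_anchor_pyramid(c(64, 64), tiny_cfg$strides, tiny_cfg$areas,
                              tiny_cfg$ratios)
  shp <- model_feature_shapes(m, 64)
  make_head <- function() lapply(1:5, function(l)
    list(scores = array(0, dim = c(shp[l, "height"], shp[l, "width"], 3)),
         deltas = array(0, dim = c(shp[l, "height"], shp[l, "width"], 15))))
  # uniform scores: enough survivors to fill the inference cap
  props <- rpn_propose(make_head(), pyr, m$config, training = FALSE)
  expect_equal(nrow(props$boxes), m$config$post_nms_top[2])
  expect_true(all(diff(props$scores) <= 0))
  # a single boosted logit with zero deltas puts its anchor box first
  head_out <- make_head()
  head_out[[2]]$scores[3, 4, 2] <- 9
  target_flat <- (2 - 1) * shp[2, "height"] * shp[2, "width"] +
    (4 - 1) * shp[2, "height"] + 3
  props2 <- rpn_propose(head_out, pyr, m$config)
  expect_equal(unname(unclass(props2$boxes)[1, ]),
               unname(unclass(pyr$levels[[2]]$anchors)[target_flat, ]))
  expect_equal(props2$scores[1], rotodet:::sigmoid(9))
})

test_that("refinement with a zeroed regression head returns the proposals", {
  m <- build_model(tiny_cfg, seed = 1)
  m$params$rcnn$reg$W[] <- 0
  m$params$rcnn$reg$b[] <- 0
  img <- generate_scene(scene_spec(n_instances = 2, seed = 5,
                                   image_size = c(64, 64)))$image
  feats <- rotodet:::extract_pyramid(m, img)
  proposals <- rbox(c(16, 48), c(16, 48), c(20, 24), c(8, 6), c(0.4, 1.1))
  dets <- rcnn_refine(feats$pyramid, proposals, m)
  expect_gt(nrow(dets$boxes), 0)
  for (i in seq_len(nrow(dets$boxes))) {
    gap <- min(abs(unclass(proposals)[, "x"] - dets$boxes[i, "x"]) +
                 abs(unclass(proposals)[, "y"] - dets$boxes[i, "y"]))
    expect_lt(gap, 1e-9)
  }
  # score threshold 1 silences everything
  cfg1 <- m$config; cfg1$score_threshold <- 1
  expect_equal(nrow(rcnn_refine(feats$pyramid, proposals, m, cfg1)$boxes), 0)
  expect_equal(nrow(rcnn_refine(feats$pyramid, rotodet:::empty_rbox(),
                                m)$boxes), 0)
})

test_that("pooling levels scale with proposal size", {
  lv <- rotodet:::pool_level_for(c(20, 60, 160, 500, 1200),
                                 c(8, 50, 120, 420, 1100))
  expect_equal(lv, c(2, 2, 3, 5, 5))
  expect_true(all(lv >= 2 & lv <= 5))
})

test_that("end-to-end detection is deterministic and score-bounded", {
  m <- build_model(tiny_cfg, seed = 2)
  scene <- generate_scene(scene_spec(n_instances = 3, seed = 11,
                                     image_size = c(64, 64)))
  d1 <- suppressWarnings(detect(scene$image, m))
  d2 <- suppressWarnings(detect(scene$image, m))
  expect_identical(unclass(d1$boxes), unclass(d2$boxes))
  expect_identical(d1$scores, d2$scores)
  expect_true(all(d1$scores >= m$config$score_threshold))
  # a high threshold on a blank image yields nothing
  cfg9 <- m$config; cfg9$score_threshold <- 0.999
  blank <- array(0.5, dim = c(64, 64, 3))
  expect_lte(nrow(suppressWarnings(detect(blank, m, cfg9))$boxes), 1)
})

test_that("the demo trainer is inert at lr 0 and reproducible by seed", {
  dir <- make_tiny_dataset(3, seed = 55, size = 64)
  m <- build_model(tiny_cfg, seed = 0)
  frozen <- train_demo(dir, m, iterations = 3, lr = 0, seed = 1)
  expect_identical(frozen$model$params, m$params)
  r1 <- train_demo(dir, m, iterations = 4, lr = 0.005, seed = 7,
                   rcnn_batch = 16)
  r2 <- train_demo(dir, m, iterations = 4, lr = 0.005, seed = 7,
                   rcnn_batch = 16)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model$params, r2$model$params)
  expect_error(train_demo(withr::local_tempdir(), m), "no annotation")
})

test_that("checkpoints round-trip through save and load", {
  m <- build_model(tiny_cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(load_model(path)$params, m$params)
})
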