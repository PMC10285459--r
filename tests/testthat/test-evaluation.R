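det_set <- function(boxes, scores)
  structure(list(boxes = boxes, scores = scores), class = "detection_set")

test_that("matching follows the greedy single-match rule", {
  gts <- rbox(c(10, 40), c(10, 40), 12, 4, c(0, 1))
  perfect <- det_set(gts, c(0.9, 0.8))
  m <- match_detections(perfect, gts, 0.99)
  expect_true(all(m$tp))
  expect_true(all(m$gt_matched))
  # two detections on one gt: only the higher-scoring one is a TP
  dbl <- det_set(rbox(c(10, 10), c(10, 10), 12, 4, 0), c(0.7, 0.95))
  m2 <- match_detections(dbl, gts, 0.5)
  expect_equal(m2$scores, c(0.95, 0.7))
  expect_equal(m2$tp, c(TRUE, FALSE))
  # empty detections leave all gts unmatched
  m3 <- match_detections(det_set(rotodet:::empty_rbox(), numeric(0)), gts)
  expect_equal(m3$gt_matched, c(FALSE, FALSE))
})

test_that("IoU and IoF criteria diverge for contained detections", {
  gt <- rbox(0, 0, 20, 20, 0)
  inner <- det_set(rbox(0, 0, 4, 4, 0), 0.9)
  expect_false(match_detections(inner, gt, 0.5, "iou")$tp)
  expect_true(match_detections(inner, gt, 0.5, "iof")$tp)
})

test_that("the worked precision-recall example integrates to 5/6", {
  gts <- rbox(c(10, 40), c(10, 40), 12, 4, 0)
  dets <- det_set(rbox(c(10, 25, 40), c(10, 25, 40), 12, 4, 0),
                  c(0.9, 0.8, 0.7))
  m <- match_detections(dets, gts, 0.9)
  expect_equal(m$tp, c(TRUE, FALSE, TRUE))
  curve <- pr_curve_ap(list(m))
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(curve$recall, c(1 / 2, 1 / 2, 1))
  expect_equal(curve$ap, 5 / 6)
  # degenerate cases
  expect_equal(pr_curve_ap(list(match_detections(
    det_set(rotodet:::empty_rbox(), numeric(0)), gts)))$ap, 0)
  all_tp <- pr_curve_ap(list(match_detections(det_set(gts, c(1, 1)), gts,
                                              0.99)))
  expect_equal(all_tp$ap, 1)
  expect_error(pr_curve_ap(list(match_detections(det_set(gts, c(1, 1)),
                                                 rotodet:::empty_rbox()))),
               "undefined|no ground")
})

test_that("AP is order-invariant and monotone in the threshold", {
  # gts are spaced so each detection contends for a single gt; with
  # shared gts the greedy matcher can re-pair detections between
  # criteria, which voids strict threshold dominance
  withr::with_seed(71, {
    for (rep in 1:10) {
      n_gt <- sample(2:6, 1)
      centers <- cbind(c(40, 160, 40, 160, 100, 100)[1:n_gt],
                       c(40, 40, 160, 160, 100, 220)[1:n_gt])
      gts <- rbox(centers[, 1], centers[, 2], runif(n_gt, 10, 25),
                  runif(n_gt, 3, 8), runif(n_gt, -pi / 4, 3 * pi / 4))
      n_det <- sample(3:10, 1)
      jitter <- sample(nrow(gts), n_det, replace = TRUE)
      dets_b <- rbox(gts[jitter, "x"] + rnorm(n_det, sd = 3),
                     gts[jitter, "y"] + rnorm(n_det, sd = 3),
                     gts[jitter, "w"] * runif(n_det, 0.7, 1.3),
                     gts[jitter, "h"] * runif(n_det, 0.7, 1.3),
                     gts[jitter, "theta"] + rnorm(n_det, sd = 0.15))
      sc <- runif(n_det)
      ap_at <- function(thr, crit = "iou") pr_curve_ap(list(
        match_detections(det_set(dets_b, sc), gts, thr, crit)))$ap
      expect_gte(ap_at(0.5), ap_at(0.75))
      expect_gte(ap_at(0.5, "iof"), ap_at(0.5, "iou"))
      # shuffling detection order changes nothing
      perm <- sample(n_det)
      expect_equal(pr_curve_ap(list(match_detections(
        det_set(dets_b[perm, ], sc[perm]), gts, 0.5)))$ap, ap_at(0.5))
    }
  })
})

test_that("pooled AP agrees with the brute-force threshold sweep", {
  withr::with_seed(73, {
    for (rep in 1:20) {
      n_img <- sample(1:3, 1)
      gt_list <- lapply(seq_len(n_img), function(i)
        random_rbox(sample(1:4, 1), xy_range = c(10, 90)))
      det_list <- lapply(gt_list, function(g) {
        n <- sample(1:6, 1)
        src <- sample(nrow(g), n, replace = TRUE)
        list(boxes = rbox(g[src, "x"] + rnorm(n, sd = 4),
                          g[src, "y"] + rnorm(n, sd = 4),
                          g[src, "w"] * runif(n, 0.6, 1.4),
                          g[src, "h"] * runif(n, 0.6, 1.4),
                          g[src, "theta"] + rnorm(n, sd = 0.2)),
             scores = round(runif(n), 3))
      })
      matches <- lapply(seq_len(n_img), function(i)
        match_detections(det_set(det_list[[i]]$boxes, det_list[[i]]$scores),
                         gt_list[[i]], 0.5))
      expect_equal(pr_curve_ap(matches)$ap,
                   brute_ap(det_list, gt_list, 0.5), tolerance = 1e-12)
    }
  })
})

test_that("dataset evaluation reports per-criterion and per-subset APs", {
  withr::with_seed(79, {
    records <- lapply(1:6, function(i) {
      n <- c(2, 5, 8, 12, 15, 22)[i]
      annotation_record(sprintf("im%d", i), c(128, 128),
                        random_rbox(n, xy_range = c(15, 110),
                                    w_range = c(4, 30)))
    })
  })
  dets <- lapply(records, function(r) det_set(r$instances,
                                              seq_len(nrow(r$instances)) /
                                                nrow(r$instances)))
  names(dets) <- vapply(records, function(r) r$image_id, character(1))
  s <- evaluate(records, dets)
  expect_true(all(s$ap$ap == 1))
  expect_setequal(unique(s$ap$subset), c("all", "sparse", "medium", "dense"))
  sparse_rows <- s$ap[s$ap$subset == "sparse", ]
  expect_true(all(sparse_rows$n_images == 3))
  expect_true(all(sparse_rows$n_gt == 15))
  expect_error(evaluate(records, setNames(dets[1], "missing_id")),
               "unknown image ids")
  # JSON report round-trips
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_json(s, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(nrow(back$ap), nrow(s$ap))
})
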