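test_that("angle normalization wraps into [-pi/4, 3pi/4) and is idempotent", {
  expect_equal(normalize_angle(3 * pi / 4), -pi / 4)
  expect_equal(normalize_angle(0), 0)
  expect_equal(normalize_angle(-pi / 2), pi / 2)
  th <- runif(200, -10, 10)
  out <- normalize_angle(th)
  expect_true(all(out >= -pi / 4 & out < 3 * pi / 4))
  expect_equal(normalize_angle(out), out)
  # congruence modulo pi
  expect_true(all(abs(((out - th) / pi) - round((out - th) / pi)) < 1e-9))
  expect_error(normalize_angle(Inf), "non-finite")
})

test_that("box construction canonicalizes into the long-edge convention", {
  expect_equal(unname(unclass(rbox(0, 0, 2, 4, 0))[1, ]),
               c(0, 0, 4, 2, pi / 2))
  expect_equal(unname(unclass(rbox(0, 0, 4, 2, pi))[1, ]),
               c(0, 0, 4, 2, 0))
  expect_equal(unname(unclass(rbox(1, 1, 3, 3, -pi / 3))[1, ]),
               c(1, 1, 3, 3, 2 * pi / 3))
  # canonicalization is idempotent
  b <- random_rbox(50)
  b2 <- rbox(b[, "x"], b[, "y"], b[, "w"], b[, "h"], b[, "theta"])
  expect_equal(unclass(b), unclass(b2))
  expect_error(rbox(0, 0, 0, 1, 0), "positive")
  expect_error(rbox(0, 0, 1, NA, 0), "finite")
})

test_that("corner conversion round-trips and preserves area", {
  q <- rbox_corners(rbox(0, 0, 4, 2, 0))
  expect_equal(q, cbind(x = c(-2, 2, 2, -2), y = c(-1, -1, 1, 1)))
  q45 <- rbox_corners(rbox(0, 0, 2, 2, pi / 4))
  expect_equal(q45, cbind(x = c(0, sqrt(2), 0, -sqrt(2)),
                          y = c(-sqrt(2), 0, sqrt(2), 0)))
  # translation equivariance
  qt <- rbox_corners(rbox(5, 7, 4, 2, 0))
  expect_equal(qt, sweep(q, 2, c(5, 7), "+"))
  # shoelace area equals w * h
  shoelace <- function(q) {
    n <- nrow(q)
    abs(sum(q[, 1] * q[c(2:n, 1), 2] - q[c(2:n, 1), 1] * q[, 2])) / 2
  }
  for (b in list(rbox(3, 3, 5, 1, pi / 3), rbox(-2, 9, 7, 6.9, -0.2))) {
    expect_equal(shoelace(rbox_corners(b)),
                 unname(b[1, "w"] * b[1, "h"]), tolerance = 1e-12)
  }
  # inverse recovers the canonical box from any starting corner / winding
  b <- rbox(3, 3, 5, 1, pi / 3)
  q <- rbox_corners(b)
  expect_equal(unclass(corners_to_rbox(q)), unclass(b), tolerance = 1e-9)
  expect_equal(unclass(corners_to_rbox(q[c(3, 4, 1, 2), ])), unclass(b),
               tolerance = 1e-9)
  expect_equal(unclass(corners_to_rbox(q[c(4, 3, 2, 1), ])), unclass(b),
               tolerance = 1e-9)
  expect_error(corners_to_rbox(matrix(c(0, 0, 1, 0, 2, 1, 0, 1), 4, 2,
                                      byrow = TRUE)), "rectangle")
})

test_that("circumscribed horizontal boxes are corner extrema", {
  expect_equal(unname(unclass(circumscribed_hbb(rbox(0, 0, 4, 2, pi / 2)))[1, ]),
               c(-1, -2, 1, 2))
  expect_equal(unname(unclass(circumscribed_hbb(rbox(0, 0, 2, 2, pi / 4)))[1, ]),
               c(-sqrt(2), -sqrt(2), sqrt(2), sqrt(2)))
  expect_equal(unname(unclass(circumscribed_hbb(rbox(0, 0, 4, 2, 0)))[1, ]),
               c(-2, -1, 2, 1))
  # never smaller than the rotated box in either extent
  b <- random_rbox(100)
  hb <- circumscribed_hbb(b)
  expect_true(all((hb[, "x2"] - hb[, "x1"]) * (hb[, "y2"] - hb[, "y1"]) >=
                    b[, "w"] * b[, "h"] - 1e-9))
})

test_that("convex intersection area matches closed forms", {
  a <- rbox(2, 1, 4, 2, 0)
  expect_equal(convex_intersection_area(a, a), 8)
  expect_equal(convex_intersection_area(a, rbox(3, 1, 4, 2, 0)), 6)
  # two unit-ish squares at 45 degrees: regular octagon, area 8(sqrt(2)-1)
  expect_equal(convex_intersection_area(rbox(0, 0, 2, 2, 0),
                                        rbox(0, 0, 2, 2, pi / 4)),
               8 * (sqrt(2) - 1), tolerance = 1e-9)
  # disjoint and edge-touching give zero
  expect_equal(convex_intersection_area(a, rbox(100, 100, 4, 2, 0)), 0)
  expect_equal(convex_intersection_area(rbox(0, 0, 2, 2, 0),
                                        rbox(2, 0, 2, 2, 0)), 0,
               tolerance = 1e-9)
})

test_that("skew IoU agrees with closed forms and the rasterization oracle", {
  expect_equal(skew_iou(rbox(1, 2, 5, 3, 0.7), rbox(1, 2, 5, 3, 0.7)), 1)
  expect_equal(skew_iou(rbox(0, 0, 4, 2, 0), rbox(100, 100, 4, 2, 0)), 0)
  octo <- 8 * (sqrt(2) - 1)
  expect_equal(skew_iou(rbox(0, 0, 2, 2, 0), rbox(0, 0, 2, 2, pi / 4)),
               octo / (8 - octo), tolerance = 1e-9)
  withr::with_seed(11, {
    for (i in 1:40) {
      a <- random_rbox(1)
      b <- random_rbox(1)
      expect_lt(abs(skew_iou(a, b) - mc_skew_iou(a, b, n = 2e5, seed = i)),
                0.015)
    }
  })
})

test_that("skew IoU is symmetric, bounded and rigid-motion invariant", {
  withr::with_seed(7, {
    a <- random_rbox(60); b <- random_rbox(60)
    iou_ab <- skew_iou(a, b, pairwise = TRUE)
    iou_ba <- skew_iou(b, a, pairwise = TRUE)
    expect_equal(iou_ab, iou_ba)
    expect_true(all(iou_ab >= 0 & iou_ab <= 1))
    # common translation + rotation about a pivot leaves IoU unchanged
    phi <- 0.73; tx <- 31; ty <- -17
    move <- function(x) {
      cs <- cos(phi); sn <- sin(phi)
      rbox(cs * x[, "x"] - sn * x[, "y"] + tx,
           sn * x[, "x"] + cs * x[, "y"] + ty,
           x[, "w"], x[, "h"], x[, "theta"] + phi)
    }
    expect_equal(skew_iou(move(a), move(b), pairwise = TRUE), iou_ab,
                 tolerance = 1e-9)
  })
})

test_that("slender rotated boxes overlap anchors less than their circumscribed boxes", {
  # the motivation for adaptive thresholds: an anchor's skew IoU with a
  # slender oriented gt is at most its IoU with the gt's circumscription
  hbb_iou <- function(h1, h2) {
    ix <- max(0, min(h1[1, "x2"], h2[1, "x2"]) - max(h1[1, "x1"], h2[1, "x1"]))
    iy <- max(0, min(h1[1, "y2"], h2[1, "y2"]) - max(h1[1, "y1"], h2[1, "y1"]))
    inter <- ix * iy
    a1 <- (h1[1, "x2"] - h1[1, "x1"]) * (h1[1, "y2"] - h1[1, "y1"])
    a2 <- (h2[1, "x2"] - h2[1, "x1"]) * (h2[1, "y2"] - h2[1, "y1"])
    inter / (a1 + a2 - inter)
  }
  withr::with_seed(21, {
    ok <- 0
    for (i in 1:100) {
      w <- runif(1, 20, 60); gt <- rbox(0, 0, w, w / runif(1, 3, 8),
                                        runif(1, -pi / 4, 3 * pi / 4))
      s <- sqrt(w * w / 2)
      anchor <- rbox(runif(1, -5, 5), runif(1, -5, 5), s, s, 0)
      lhs <- skew_iou(anchor, gt)
      rhs <- hbb_iou(circumscribed_hbb(anchor), circumscribed_hbb(gt))
      if (lhs <= rhs + 1e-9) ok <- ok + 1
    }
    expect_gte(ok, 99)
  })
})

test_that("skew IoF divides by the detection area and dominates IoU", {
  expect_equal(skew_iof(rbox(0, 0, 2, 2, 0), rbox(0, 0, 20, 20, 0)), 1)
  expect_equal(skew_iof(rbox(1, 0, 4, 2, 0), rbox(0, 0, 2, 2, 0)), 0.5)
  expect_equal(skew_iof(rbox(0, 0, 4, 2, 0), rbox(100, 0, 4, 2, 0)), 0)
  withr::with_seed(13, {
    a <- random_rbox(50); b <- random_rbox(50)
    expect_true(all(skew_iof(a, b, pairwise = TRUE) >=
                      skew_iou(a, b, pairwise = TRUE) - 1e-12))
  })
})

test_that("rotated NMS suppresses greedily by descending score", {
  two <- rbox(c(0, 0), c(0, 0), 4, 2, 0)
  expect_equal(rotated_nms(two, c(0.9, 0.95), 0.5), c(2L))
  disjoint <- rbox(c(0, 100), c(0, 100), 4, 2, 0)
  expect_equal(sort(rotated_nms(disjoint, c(0.3, 0.8), 0.5)), c(1L, 2L))
  # chain: A suppresses B (IoU 0.6); C survives because its overlap with
  # the kept A is below threshold
  chain <- rbox(c(0, 1, 2), c(0, 0, 0), 4, 2, 0)
  expect_equal(skew_iou(chain[1, ], chain[2, ]), 0.6)
  expect_equal(rotated_nms(chain, c(0.9, 0.8, 0.7), 0.5), c(1L, 3L))
  # idempotence on the kept set
  withr::with_seed(3, {
    b <- random_rbox(80, xy_range = c(0, 60))
    s <- runif(80)
    keep <- rotated_nms(b, s, 0.4)
    keep2 <- rotated_nms(b[keep, ], s[keep], 0.4)
    expect_equal(keep[keep2], keep)
  })
  expect_equal(rotated_nms(rbox(numeric(0), numeric(0), numeric(0),
                                numeric(0), numeric(0)),
                           numeric(0), 0.5), integer(0))
})
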