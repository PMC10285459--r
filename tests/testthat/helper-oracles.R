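# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms (Monte-Carlo rasterization,
# explicit-loop references) than the code under test.

# Monte-Carlo rasterization estimate of the skew IoU of two rotated boxes:
# sample points uniformly over the joint bounding region and classify them
# against each rectangle by rotating into its local frame.
mc_skew_iou <- function(a, b, n = 1e6, seed = 1) {
  a <- unclass(a); b <- unclass(b)
  corners <- rbind(rbox_corners(rotodet::rbox(a[1], a[2], a[3], a[4], a[5])),
                   rbox_corners(rotodet::rbox(b[1], b[2], b[3], b[4], b[5])))
  xr <- range(corners[, 1]); yr <- range(corners[, 2])
  withr::with_seed(seed, {
    px <- runif(n, xr[1], xr[2])
    py <- runif(n, yr[1], yr[2])
    inside <- function(bb) {
      dx <- px - bb[1]; dy <- py - bb[2]
      u <- cos(bb[5]) * dx + sin(bb[5]) * dy
      v <- -sin(bb[5]) * dx + cos(bb[5]) * dy
      abs(u) <= bb[3] / 2 & abs(v) <= bb[4] / 2
    }
    ia <- inside(a); ib <- inside(b)
    nu <- sum(ia | ib)
    if (nu == 0) return(0)
    sum(ia & ib) / nu
  })
}

random_rbox <- function(n = 1, xy_range = c(0, 100), w_range = c(2, 60)) {
  w <- runif(n, w_range[1], w_range[2])
  h <- runif(n, w_range[1], w_range[2])
  rotodet::rbox(runif(n, xy_range[1], xy_range[2]),
                runif(n, xy_range[1], xy_range[2]),
                w, h, runif(n, -pi, pi))
}

# Explicit-loop reference for the adaptive assignment rule: per gt, the
# n_per_level center-closest anchors on each level; threshold mean +
# population sd of their skew IoUs; fallback to the best candidate;
# cross-gt conflicts resolved by larger IoU; stripped gts repaired from
# unlabeled candidates.
brute_adaptive_assign <- function(pyramid, gts, n_per_level = 9) {
  gts <- unclass(gts)
  n_anchor <- sum(pyramid$counts)
  labels <- integer(n_anchor)
  if (nrow(gts) == 0L) return(labels)
  anchors <- matrix(0, 0, 5)
  for (lv in pyramid$levels) anchors <- rbind(anchors, unclass(lv$anchors))
  claimed_iou <- rep(-1, n_anchor)
  cand_store <- list(); iou_store <- list()
  for (g in seq_len(nrow(gts))) {
    gt <- rotodet::rbox(gts[g, 1], gts[g, 2], gts[g, 3], gts[g, 4], gts[g, 5])
    cand <- c()
    for (l in seq_along(pyramid$levels)) {
      lv <- pyramid$levels[[l]]
      d <- numeric(nrow(lv$anchors))
      for (i in seq_len(nrow(lv$anchors)))
        d[i] <- sqrt((lv$anchors[i, "x"] - gts[g, 1])^2 +
                     (lv$anchors[i, "y"] - gts[g, 2])^2)
      near <- order(d)[seq_len(min(n_per_level, length(d)))]
      cand <- c(cand, pyramid$offsets[l] + near)
    }
    ious <- numeric(length(cand))
    for (i in seq_along(cand)) {
      ab <- anchors[cand[i], ]
      ious[i] <- rotodet::skew_iou(
        rotodet::rbox(ab[1], ab[2], ab[3], ab[4], ab[5]), gt)
    }
    thr <- mean(ious) + sqrt(mean((ious - mean(ious))^2))
    sel <- which(ious >= thr)
    if (length(sel) == 0L) sel <- which.max(ious)
    for (i in sel) {
      if (ious[i] > claimed_iou[cand[i]]) {
        claimed_iou[cand[i]] <- ious[i]
        labels[cand[i]] <- g
      }
    }
    cand_store[[g]] <- cand; iou_store[[g]] <- ious
  }
  for (g in seq_len(nrow(gts))) {
    if (any(labels == g)) next
    free <- which(labels[cand_store[[g]]] == 0L)
    pick <- if (length(free) > 0L)
      cand_store[[g]][free[which.max(iou_store[[g]][free])]]
    else cand_store[[g]][which.max(iou_store[[g]])]
    labels[pick] <- g
  }
  labels
}

# Brute-force average precision: re-run greedy matching from scratch at
# every distinct score threshold, collect (P, R) operating points, and
# integrate the precision envelope over recall.
brute_ap <- function(det_list, gt_list, threshold = 0.5,
                     criterion = "iou") {
  scores <- sort(unique(unlist(lapply(det_list, function(d) d$scores))),
                 decreasing = TRUE)
  n_gt <- sum(vapply(gt_list, nrow, numeric(1)))
  pr <- matrix(0, 0, 2)
  for (s in scores) {
    tp <- 0; fp <- 0
    for (i in seq_along(det_list)) {
      d <- det_list[[i]]
      keep <- d$scores >= s
      if (!any(keep)) next
      boxes <- d$boxes[keep, ]
      sc <- d$scores[keep]
      ord <- order(sc, decreasing = TRUE)
      gts <- gt_list[[i]]
      used <- rep(FALSE, nrow(gts))
      for (j in ord) {
        best <- 0; best_g <- 0
        for (g in seq_len(nrow(gts))) {
          if (used[g]) next
          ov <- if (criterion == "iou")
            rotodet::skew_iou(boxes[j, ], gts[g, ])
          else rotodet::skew_iof(boxes[j, ], gts[g, ])
          if (ov > best) { best <- ov; best_g <- g }
        }
        if (best_g > 0 && best >= threshold) {
          tp <- tp + 1; used[best_g] <- TRUE
        } else fp <- fp + 1
      }
    }
    pr <- rbind(pr, c(tp / max(1, tp + fp), tp / n_gt))
  }
  if (nrow(pr) == 0L) return(0)
  # integrate envelope over recall (recall is non-decreasing down the rows)
  ap <- 0; prev_r <- 0
  for (i in seq_len(nrow(pr))) {
    env <- max(pr[i:nrow(pr), 1])
    ap <- ap + (pr[i, 2] - prev_r) * env
    prev_r <- pr[i, 2]
  }
  ap
}

# small deterministic synthetic dataset on disk, shared across tests
make_tiny_dataset <- function(n_images, seed, density = "sparse",
                              size = 128, dir = NULL) {
  if (is.null(dir))
    dir <- file.path(tempdir(), sprintf("rotodet_ds_%s_%d_%d", density,
                                        n_images, seed))
  if (!file.exists(file.path(dir, "manifest.json")))
    generate_dataset(scene_spec(density = density,
                                image_size = c(size, size)),
                     n_images, dir, seed = seed)
  dir
}
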