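#' Build a pyramid of horizontal anchors
#'
#' Places three horizontal anchors at every feature-map position of each
#' pyramid level. Level `l` has stride `strides[l]` and anchor area
#' `areas[l]`; the default five levels use strides (4, 8, 16, 32, 64) with
#' areas (32^2, 64^2, 128^2, 256^2, 512^2). At one position the anchors
#' have aspect ratios `w/h` of 2, 1 and 0.5 before canonicalization;
#' after canonicalization into the long-edge convention the ratio-0.5
#' anchor is stored with theta = pi/2. Anchor centers sit at
#' `((i + 0.5) s, (j + 0.5) s)`, and grids use the ceiling of
#' `image_size / stride`.
#'
#' Anchors at a level are ordered so that their flat index agrees with
#' column-major flattening of an `(H_l, W_l, 3)` prediction array: row
#' (y) fastest, then column (x), then anchor slot.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param strides Integer strides, one per level.
#' @param areas Anchor areas (pixels squared), one per level.
#' @param ratios Aspect ratios `w/h` at one position.
#' @return An `anchor_pyramid`: list with per-level `rbox` sets, grid
#'   sizes, strides, and the flat level offsets.
#' @export
build_anchor_pyramid <- function(image_size,
                                 strides = c(4, 8, 16, 32, 64),
                                 areas = c(32, 64, 128, 256, 512)^2,
                                 ratios = c(2, 1, 0.5)) {
  if (length(strides) == 0L) stop("at least one stride required", call. = FALSE)
  stopifnot(length(areas) == length(strides), length(ratios) >= 1)
  levels <- vector("list", length(strides))
  for (l in seq_along(strides)) {
    s <- strides[l]
    gw <- ceiling(image_size[1] / s)
    gh <- ceiling(image_size[2] / s)
    # column-major order of an (gh, gw, n_ratio) array: y, then x, then slot
    grid <- expand.grid(iy = seq_len(gh), ix = seq_len(gw),
                        a = seq_along(ratios))
    w <- sqrt(areas[l] * ratios[grid$a])
    h <- sqrt(areas[l] / ratios[grid$a])
    levels[[l]] <- list(
      stride = s, grid = c(gw, gh),
      anchors = rbox((grid$ix - 0.5) * s, (grid$iy - 0.5) * s, w, h, 0))
  }
  counts <- vapply(levels, function(x) nrow(x$anchors), integer(1))
  structure(list(levels = levels,
                 offsets = cumsum(c(0, head(counts, -1))),
                 counts = counts,
                 image_size = image_size),
            class = "anchor_pyramid")
}

#' @export
print.anchor_pyramid <- function(x, ...) {
  cat(sprintf("<anchor_pyramid> %d level(s), %d anchors total\n",
              length(x$levels), sum(x$counts)))
  for (l in x$levels)
    cat(sprintf("  stride %2d: %dx%d grid, %d anchors\n",
                l$stride, l$grid[1], l$grid[2], nrow(l$anchors)))
  invisible(x)
}

# All anchors of a pyramid as one rbox, in flat-index order.
flatten_anchors <- function(pyramid) {
  as_rbox(do.call(rbind, lapply(pyramid$levels,
                                function(l) unclass(l$anchors))))
}

#' Adaptive positive-sample selection
#'
#' Assigns anchors to rotated ground-truth boxes with a per-instance
#' adaptive skew-IoU threshold, which sidesteps the fixed-threshold problem
#' for slender oriented targets whose skew IoU with any horizontal anchor
#' is structurally low. For each ground truth, the `n_per_level` anchors
#' with the closest centers are gathered on every level (Euclidean center
#' distance, ties by ascending index); the skew IoUs of these candidates
#' with the ground truth are summarized as `t = mean + population sd`, and
#' candidates with IoU >= t become positive. A ground truth whose
#' candidates all fall below its threshold receives its best-IoU candidate
#' as a forced positive, so every instance owns at least one positive
#' sample. An anchor claimed by several ground truths is given to the one
#' with the larger IoU (ties to the lower gt index); if that leaves an
#' instance with no positive at all, its best still-unlabeled candidate is
#' assigned to it. All remaining anchors are negative.
#'
#' @param pyramid An `anchor_pyramid`.
#' @param gts An `rbox` of ground-truth instances (may be empty).
#' @param n_per_level Candidates gathered per level and ground truth.
#' @return An `assignment_result`: list with `labels` (integer per anchor:
#'   0 = negative, g > 0 = positive for gt g), `thresholds`, `candidates`
#'   (per-gt flat indices), and `n_positive` per gt.
#' @export
adaptive_assign <- function(pyramid, gts, n_per_level = 9) {
  stopifnot(inherits(pyramid, "anchor_pyramid"), n_per_level >= 1)
  gts <- as_rbox(gts)
  n_anchor <- sum(pyramid$counts)
  labels <- integer(n_anchor)
  n_gt <- nrow(gts)
  if (n_gt == 0L)
    return(structure(list(labels = labels, thresholds = numeric(0),
                          candidates = list(), n_positive = integer(0)),
                     class = "assignment_result"))
  all_anchors <- flatten_anchors(pyramid)
  thresholds <- numeric(n_gt)
  cand_list <- vector("list", n_gt)
  cand_ious <- vector("list", n_gt)
  best_iou <- rep(-1, n_anchor)   # best IoU seen per positive anchor
  for (g in seq_len(n_gt)) {
    cand <- integer(0)
    for (l in seq_along(pyramid$levels)) {
      lv <- pyramid$levels[[l]]
      d2 <- (lv$anchors[, "x"] - gts[g, "x"])^2 +
            (lv$anchors[, "y"] - gts[g, "y"])^2
      k <- min(n_per_level, nrow(lv$anchors))
      near <- order(d2)[seq_len(k)]
      cand <- c(cand, pyramid$offsets[l] + near)
    }
    ious <- skew_iou(all_anchors[cand, ], gts[g, ])[, 1]
    mu <- mean(ious)
    sigma <- sqrt(mean((ious - mu)^2))   # population sd
    t <- mu + sigma
    pos <- cand[ious >= t]
    pos_iou <- ious[ious >= t]
    if (length(pos) == 0L) {             # fallback: force the best candidate
      j <- which.max(ious)
      pos <- cand[j]
      pos_iou <- ious[j]
    }
    for (k in seq_along(pos)) {
      a <- pos[k]
      if (pos_iou[k] > best_iou[a]) {    # larger-IoU gt wins the anchor
        best_iou[a] <- pos_iou[k]
        labels[a] <- g
      }
    }
    thresholds[g] <- t
    cand_list[[g]] <- cand
    cand_ious[[g]] <- ious
  }
  # Conflict resolution can strip a gt of its only positive (its anchor
  # claimed by a higher-IoU neighbor); repair from still-unlabeled
  # candidates so that every instance keeps at least one positive sample.
  for (g in seq_len(n_gt)) {
    if (any(labels == g)) next
    free <- which(labels[cand_list[[g]]] == 0L)
    pick <- if (length(free) > 0L)
      cand_list[[g]][free[which.max(cand_ious[[g]][free])]]
    else cand_list[[g]][which.max(cand_ious[[g]])]
    labels[pick] <- g
  }
  structure(list(labels = labels, thresholds = thresholds,
                 candidates = cand_list,
                 n_positive = vapply(seq_len(n_gt),
                                     function(g) sum(labels == g), integer(1))),
            class = "assignment_result")
}

#' Sample a training batch from an assignment
#'
#' Draws up to `n_total / 2` positive and exactly as many negative anchors
#' (the 1:1 positive:negative rule). When positives are scarcer than
#' `n_total / 2` the batch shrinks instead of padding with extra negatives,
#' so the ratio is kept strict; losses normalize by the realized batch
#' size. Subsampling is uniform without replacement under `seed`.
#'
#' @param assignment An `assignment_result`.
#' @param n_total Batch-size cap (positives + negatives).
#' @param seed Integer seed for the subsampling draws.
#' @return A `sampled_batch`: list with `positive` and `negative` flat
#'   anchor indices, `n_total` and `n_pos`.
#' @export
sample_training_batch <- function(assignment, n_total = 256, seed = 0) {
  stopifnot(inherits(assignment, "assignment_result"))
  pos_all <- which(assignment$labels > 0L)
  neg_all <- which(assignment$labels == 0L)
  if (length(neg_all) == 0L)
    stop("no negative anchors available (degenerate configuration)",
         call. = FALSE)
  n_pos <- min(length(pos_all), n_total %/% 2)
  with_seed(seed, {
    pos <- if (length(pos_all) > n_pos)
      sort(sample(pos_all, n_pos)) else pos_all
    neg <- sort(sample(neg_all, min(n_pos, length(neg_all))))
    structure(list(positive = pos, negative = neg,
                   n_total = length(pos) + length(neg), n_pos = length(pos)),
              class = "sampled_batch")
  })
}
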