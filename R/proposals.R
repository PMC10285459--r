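# Proposal generation and refinement: the inference-side plumbing that
# turns raw head outputs into scored rotated boxes.

# Map flat per-level prediction arrays to per-anchor vectors/matrices.
# scores: (H, W, A) -> length H*W*A vector matching anchor flat order.
# deltas: (H, W, 5A) -> (H*W*A) x 5 matrix, channel block a holds the five
# components of anchor slot a.
level_scores_vec <- function(scores) as.numeric(scores)

level_deltas_mat <- function(deltas) {
  d <- dim(deltas)
  a <- d[3] %/% 5L
  out <- matrix(0, d[1] * d[2] * a, 5)
  for (slot in seq_len(a)) {
    rows <- (slot - 1L) * d[1] * d[2] + seq_len(d[1] * d[2])
    for (j in 1:5)
      out[rows, j] <- as.numeric(deltas[, , (slot - 1L) * 5L + j])
  }
  out
}

#' Generate rotated proposals from proposal-head outputs
#'
#' Per pyramid level: decode the predicted deltas against the horizontal
#' anchors, keep the `pre_nms_top` highest-scoring boxes, and run rotated
#' NMS; then aggregate the survivors of all levels and keep the global
#' top `post_nms_top` by score.
#'
#' @param head_out Per-level list with `scores` (H x W x A logits) and
#'   `deltas` (H x W x 5A), as produced by the proposal head.
#' @param pyramid An `anchor_pyramid` matching the head outputs.
#' @param config A `detector_config` (caps and thresholds).
#' @param training Use the training-time aggregated cap instead of the
#'   inference cap.
#' @return A `proposal_set`: list with `boxes` (`rbox`), `scores`
#'   (sigmoid objectness, descending), `level` (origin level per box).
#' @export
rpn_propose <- function(head_out, pyramid, config, training = FALSE) {
  stopifnot(length(head_out) == length(pyramid$levels))
  max_ext <- 2 * sqrt(sum(pyramid$image_size^2))
  all_boxes <- list(); all_scores <- list(); all_levels <- list()
  for (l in seq_along(head_out)) {
    sc <- sigmoid(level_scores_vec(head_out[[l]]$scores))
    dl <- level_deltas_mat(head_out[[l]]$deltas)
    anchors <- pyramid$levels[[l]]$anchors
    stopifnot(length(sc) == nrow(anchors))
    top <- order(sc, decreasing = TRUE)[seq_len(min(config$pre_nms_top,
                                                    length(sc)))]
    boxes <- suppressWarnings(
      decode_deltas(dl[top, , drop = FALSE], anchors[top, ],
                    max_extent = max_ext))
    keep <- rotated_nms(boxes, sc[top], config$rpn_nms_threshold)
    all_boxes[[l]] <- unclass(boxes[keep, ])
    all_scores[[l]] <- sc[top][keep]
    all_levels[[l]] <- rep(l, length(keep))
  }
  boxes <- do.call(rbind, all_boxes)
  scores <- unlist(all_scores)
  lvls <- unlist(all_levels)
  cap <- if (training) config$post_nms_top[1] else config$post_nms_top[2]
  ord <- order(scores, decreasing = TRUE)[seq_len(min(cap, length(scores)))]
  structure(list(boxes = as_rbox(boxes[ord, , drop = FALSE]),
                 scores = scores[ord], level = lvls[ord]),
            class = "proposal_set")
}

#' @export
print.proposal_set <- function(x, ...) {
  cat(sprintf("<proposal_set> %d proposal(s), score range [%.3f, %.3f]\n",
              nrow(x$boxes),
              if (length(x$scores)) min(x$scores) else NA,
              if (length(x$scores)) max(x$scores) else NA))
  invisible(x)
}

# FPN level (2..5) used to pool a proposal of a given size; coarser maps
# for larger proposals.
pool_level_for <- function(w, h) {
  pmin(pmax(floor(log2(sqrt(w * h) / 56)) + 2, 2), 5)
}

#' Refine rotated proposals into detections
#'
#' For each proposal: pool a `k x k` rotated-aligned feature grid from the
#' pyramid level matching its size, run the two fully-connected layers,
#' and emit the softmax foreground probability plus the decoded 5-delta
#' refinement (the proposal plays the anchor role in the coder). Refined
#' boxes below the score threshold are dropped and the survivors pass
#' through rotated NMS.
#'
#' @param pyramid_feats Named list `p2..p6` of feature arrays.
#' @param proposals A `proposal_set` (or `rbox`).
#' @param model A `detector_model`.
#' @param config Optional override of `model$config`.
#' @return A `detection_set`: list with `boxes` (`rbox`), `scores`.
#' @export
rcnn_refine <- function(pyramid_feats, proposals, model, config = NULL) {
  cfg <- if (is.null(config)) model$config else config
  boxes <- if (inherits(proposals, "proposal_set")) proposals$boxes
           else as_rbox(proposals)
  n <- nrow(boxes)
  if (n == 0L)
    return(structure(list(boxes = empty_rbox(), scores = numeric(0)),
                     class = "detection_set"))
  lvl <- pool_level_for(boxes[, "w"], boxes[, "h"])
  probs <- numeric(n)
  deltas <- matrix(0, n, 5)
  for (i in seq_len(n)) {
    fm <- feature_map(pyramid_feats[[paste0("p", lvl[i])]],
                      stride = cfg$strides[lvl[i] - 1])
    pooled <- rroi_align(fm, boxes[i, ], k = cfg$k, l = cfg$l)
    out <- rcnn_head_fwd(model$params$rcnn, as.numeric(pooled$values))
    probs[i] <- out$probs[2]
    deltas[i, ] <- out$deltas
  }
  refined <- suppressWarnings(
    decode_deltas(deltas, boxes, max_extent = 4 * cfg$input_size))
  keep <- which(probs >= cfg$score_threshold)
  if (length(keep) == 0L)
    return(structure(list(boxes = empty_rbox(), scores = numeric(0)),
                     class = "detection_set"))
  refined <- refined[keep, ]; probs <- probs[keep]
  sel <- rotated_nms(refined, probs, cfg$final_nms_threshold)
  structure(list(boxes = refined[sel, ], scores = probs[sel]),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d detection(s)\n", nrow(x$boxes)))
  invisible(x)
}

# aspect-preserving resize onto a square canvas; returns image + scale
letterbox_image <- function(image, size) {
  H <- dim(image)[1]; W <- dim(image)[2]
  scale <- min(size / W, size / H)
  nh <- max(1, round(H * scale)); nw <- max(1, round(W * scale))
  resized <- bilinear_resize(image, nh, nw)
  canvas <- array(0, dim = c(size, size, dim(image)[3]))
  canvas[seq_len(nh), seq_len(nw), ] <- resized
  list(image = canvas, scale = scale)
}

#' End-to-end detection on one image
#'
#' Letterboxes the image to the configured square input size, extracts the
#' feature pyramid, generates rotated proposals, refines them, and maps
#' the surviving boxes back to original image coordinates. Deterministic
#' given the model weights and the image.
#'
#' @param image H x W x 3 array in `[0, 1]`, or a path to a PNG file.
#' @param model A `detector_model`.
#' @param config Optional override of `model$config`.
#' @return A `detection_set` in original-image coordinates.
#' @export
detect <- function(image, model, config = NULL) {
  cfg <- if (is.null(config)) model$config else config
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 2L) image <- array(rep(image, 3),
                                               dim = c(dim(image), 3))
  if (length(dim(image)) != 3L || !is.numeric(image))
    stop("image must be an H x W x 3 numeric array or a PNG path",
         call. = FALSE)
  image <- image[, , 1:3, drop = FALSE]   # drop alpha if present
  lb <- letterbox_image(image, cfg$input_size)
  feats <- extract_pyramid(model, lb$image)
  pyramid <- build_anchor_pyramid(c(cfg$input_size, cfg$input_size),
                                  cfg$strides, cfg$areas, cfg$ratios)
  head_out <- rpn_head_fwd(model$params$rpn, feats$pyramid)
  props <- rpn_propose(head_out, pyramid, cfg, training = FALSE)
  dets <- rcnn_refine(feats$pyramid, props, model, cfg)
  if (nrow(dets$boxes) > 0L) {
    b <- unclass(dets$boxes)
    dets$boxes <- rbox(b[, "x"] / lb$scale, b[, "y"] / lb$scale,
                       b[, "w"] / lb$scale, b[, "h"] / lb$scale,
                       b[, "theta"])
  }
  dets
}

#' Write detections as JSON lines
#'
#' One record per detection: `image_id, x, y, w, h, theta, score`.
#'
#' @param image_id Image identifier.
#' @param dets A `detection_set`.
#' @param con Path or connection; lines are appended when `append = TRUE`.
#' @param append Append instead of overwrite.
#' @return Invisibly, the number of lines written.
#' @export
write_detections_jsonl <- function(image_id, dets, con, append = FALSE) {
  b <- unclass(dets$boxes)
  lines <- vapply(seq_len(nrow(b)), function(i) {
    jsonlite::toJSON(list(image_id = image_id, x = b[i, "x"], y = b[i, "y"],
                          w = b[i, "w"], h = b[i, "h"],
                          theta = b[i, "theta"], score = dets$scores[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  if (append) cat(lines, file = con, sep = "\n", append = TRUE)
  else writeLines(lines, con)
  if (length(lines) && append) cat("\n", file = con, append = TRUE)
  invisible(length(lines))
}

#' Read JSON-lines detections
#'
#' @param path JSONL file with fields `image_id, x, y, w, h, theta, score`.
#' @return Named list (by image id) of `detection_set`s.
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  recs <- lapply(lines, jsonlite::fromJSON)
  ids <- vapply(recs, function(r) as.character(r$image_id), character(1))
  out <- list()
  for (id in unique(ids)) {
    sel <- recs[ids == id]
    out[[id]] <- structure(list(
      boxes = rbox(vapply(sel, function(r) r$x, numeric(1)),
                   vapply(sel, function(r) r$y, numeric(1)),
                   vapply(sel, function(r) r$w, numeric(1)),
                   vapply(sel, function(r) r$h, numeric(1)),
                   vapply(sel, function(r) r$theta, numeric(1))),
      scores = vapply(sel, function(r) r$score, numeric(1))),
      class = "detection_set")
  }
  out
}
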