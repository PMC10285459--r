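#' Match detections against ground truth on one image
#'
#' Greedy matching in descending detection score: each detection is a true
#' positive if its best-overlap not-yet-matched ground truth meets the
#' threshold under the chosen criterion (skew IoU, or skew IoF = overlap
#' divided by the detection's own area), otherwise a false positive; ties
#' in overlap go to the lower ground-truth index. Each ground truth is
#' matched at most once; unmatched ground truths are the false negatives.
#'
#' @param dets A `detection_set` (boxes + scores) for one image.
#' @param gts An `rbox` of ground-truth instances for the same image.
#' @param threshold Overlap threshold in (0, 1].
#' @param criterion `"iou"` or `"iof"`.
#' @return A `match_result`: list with `tp` (logical per detection, in
#'   descending-score order), `scores` (sorted descending), `gt_matched`
#'   (logical per gt), `n_gt`, `threshold`, `criterion`.
#' @export
match_detections <- function(dets, gts, threshold = 0.5,
                             criterion = c("iou", "iof")) {
  criterion <- match.arg(criterion)
  stopifnot(threshold > 0, threshold <= 1)
  gts <- as_rbox(gts)
  n_det <- nrow(dets$boxes)
  n_gt <- nrow(gts)
  if (n_det == 0L)
    return(structure(list(tp = logical(0), scores = numeric(0),
                          gt_matched = rep(FALSE, n_gt), n_gt = n_gt,
                          threshold = threshold, criterion = criterion),
                     class = "match_result"))
  ord <- order(dets$scores, decreasing = TRUE)
  boxes <- dets$boxes[ord, ]
  ov <- if (n_gt == 0L) matrix(0, n_det, 0)
        else if (criterion == "iou")
          matrix(skew_iou(boxes, gts), n_det, n_gt)
        else matrix(skew_iof(boxes, gts), n_det, n_gt)
  tp <- logical(n_det)
  gt_matched <- rep(FALSE, n_gt)
  for (i in seq_len(n_det)) {
    if (n_gt == 0L) break
    free <- which(!gt_matched)
    if (length(free) == 0L) break
    j <- free[which.max(ov[i, free])]
    if (ov[i, j] >= threshold) {
      tp[i] <- TRUE
      gt_matched[j] <- TRUE
    }
  }
  structure(list(tp = tp, scores = dets$scores[ord], gt_matched = gt_matched,
                 n_gt = n_gt, threshold = threshold, criterion = criterion),
            class = "match_result")
}

#' Precision-recall curve and average precision
#'
#' Pools the matches of all images, sweeps the score threshold through
#' every distinct detection score, and computes precision `TP/(TP+FP)` and
#' recall `TP/(TP+FN)` at each operating point. AP is the area under the
#' precision envelope as a function of recall (all-points interpolation of
#' the precision-recall integral); the classic 11-point variant is
#' available for comparison.
#'
#' @param matches List of `match_result`s (one per image).
#' @param interpolation `"all_points"` or `"eleven_point"`.
#' @return A `pr_curve`: list with `precision`, `recall`, `scores`
#'   (descending), `ap`, `n_gt`.
#' @export
pr_curve_ap <- function(matches, interpolation = c("all_points",
                                                   "eleven_point")) {
  interpolation <- match.arg(interpolation)
  n_gt <- sum(vapply(matches, function(m) m$n_gt, numeric(1)))
  if (n_gt == 0)
    stop("no ground-truth instances: AP undefined", call. = FALSE)
  scores <- unlist(lapply(matches, function(m) m$scores))
  tp <- unlist(lapply(matches, function(m) m$tp))
  if (length(scores) == 0L)
    return(structure(list(precision = numeric(0), recall = numeric(0),
                          scores = numeric(0), ap = 0, n_gt = n_gt),
                     class = "pr_curve"))
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_gt
  ap <- if (interpolation == "all_points") {
    # precision envelope (monotone non-increasing hull), integrated over
    # the recall steps
    env <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      sel <- recall >= r - 1e-12
      if (any(sel)) max(precision[sel]) else 0
    }, numeric(1)))
  }
  structure(list(precision = precision, recall = recall,
                 scores = scores[ord], ap = ap, n_gt = n_gt),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> AP = %.4f over %d gt instance(s), %d detection(s)\n",
              x$ap, x$n_gt, length(x$scores)))
  invisible(x)
}

#' Evaluate detections over a dataset
#'
#' Computes AP for every combination of overlap criterion and threshold,
#' overall and per density subset. Detections and annotations are paired
#' by image id; ids present on one side only (other than images without
#' detections, which simply contribute false negatives) raise an error.
#'
#' @param records List of rotated `annotation_record`s (ground truth).
#' @param detections Named list of `detection_set`s keyed by image id.
#' @param thresholds Overlap thresholds to evaluate.
#' @param criteria Overlap criteria (`"iou"`, `"iof"`).
#' @param subsets Include per-density-subset APs.
#' @param interpolation Passed to [pr_curve_ap()].
#' @return An `eval_summary`: data frame `ap` with columns criterion,
#'   threshold, subset, ap, n_images, n_gt; plus the pooled `curves`.
#' @export
evaluate <- function(records, detections, thresholds = c(0.5, 0.75),
                     criteria = c("iou", "iof"), subsets = TRUE,
                     interpolation = "all_points") {
  gt_ids <- vapply(records, function(r) r$image_id, character(1))
  if (anyDuplicated(gt_ids))
    stop("duplicate image ids in annotations", call. = FALSE)
  extra <- setdiff(names(detections), gt_ids)
  if (length(extra) > 0L)
    stop("detections reference unknown image ids: ",
         paste(extra, collapse = ", "), call. = FALSE)
  empty_dets <- structure(list(boxes = empty_rbox(), scores = numeric(0)),
                          class = "detection_set")
  labels <- split_subsets(records)
  groups <- list(all = seq_along(records))
  if (subsets) {
    for (s in c("sparse", "medium", "dense")) {
      sel <- which(!is.na(labels) & labels == s)
      if (length(sel) > 0L) groups[[s]] <- sel
    }
  }
  rows <- list(); curves <- list()
  for (crit in criteria) {
    for (thr in thresholds) {
      for (gname in names(groups)) {
        idx <- groups[[gname]]
        matches <- lapply(idx, function(i) {
          d <- detections[[gt_ids[i]]]
          if (is.null(d)) d <- empty_dets
          match_detections(d, records[[i]]$instances, thr, crit)
        })
        n_gt <- sum(vapply(matches, function(m) m$n_gt, numeric(1)))
        ap <- if (n_gt == 0) NA_real_
              else pr_curve_ap(matches, interpolation)$ap
        rows[[length(rows) + 1L]] <-
          data.frame(criterion = crit, threshold = thr, subset = gname,
                     ap = ap, n_images = length(idx), n_gt = n_gt)
        if (gname == "all")
          curves[[paste(crit, thr, sep = "_")]] <-
            if (n_gt > 0) pr_curve_ap(matches, interpolation) else NULL
      }
    }
  }
  structure(list(ap = do.call(rbind, rows), curves = curves),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("<eval_summary>\n")
  print(x$ap, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param summary An `eval_summary`.
#' @param path Output path.
#' @param include_curves Include the pooled precision/recall arrays.
#' @return Invisibly, `path`.
#' @export
write_eval_json <- function(summary, path, include_curves = TRUE) {
  out <- list(ap = summary$ap)
  if (include_curves)
    out$curves <- lapply(summary$curves, function(cv)
      list(precision = cv$precision, recall = cv$recall,
           scores = cv$scores, ap = cv$ap, n_gt = cv$n_gt))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
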