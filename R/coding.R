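#' Encode a box as regression deltas against an anchor
#'
#' The five-parameter delta coding between a target box and its anchor (or
#' proposal): center offsets normalized by the anchor edges, log edge
#' ratios, and the raw angle difference:
#' `d_x = (x_t - x_a) / w_a`, `d_y = (y_t - y_a) / h_a`,
#' `d_w = log(w_t / w_a)`, `d_h = log(h_t / h_a)`,
#' `d_theta = theta_t - theta_a`.
#'
#' With `wrap_angle = TRUE` a `d_theta` whose magnitude exceeds `pi/2` is
#' wrapped into `(-pi/2, pi/2]` (the same box re-expressed through the
#' angle period), shortening the regression path across the angular
#' boundary; the default keeps the plain difference.
#'
#' @param target,anchor `rbox` sets of equal length (or length 1, recycled
#'   by row pairing).
#' @param wrap_angle Wrap `d_theta` into `(-pi/2, pi/2]`.
#' @return A numeric matrix with columns `dx, dy, dw, dh, dtheta`.
#' @export
encode_deltas <- function(target, anchor, wrap_angle = FALSE) {
  target <- as_rbox(target); anchor <- as_rbox(anchor)
  if (nrow(anchor) == 1L && nrow(target) > 1L)
    anchor <- anchor[rep(1L, nrow(target)), ]
  stopifnot(nrow(target) == nrow(anchor))
  dtheta <- target[, "theta"] - anchor[, "theta"]
  if (wrap_angle) dtheta <- -((-dtheta + pi / 2) %% pi) + pi / 2
  cbind(dx = (target[, "x"] - anchor[, "x"]) / anchor[, "w"],
        dy = (target[, "y"] - anchor[, "y"]) / anchor[, "h"],
        dw = log(target[, "w"] / anchor[, "w"]),
        dh = log(target[, "h"] / anchor[, "h"]),
        dtheta = dtheta)
}

#' Decode regression deltas into boxes
#'
#' Inverse of [encode_deltas()] followed by angle normalization into
#' `[-pi/4, 3*pi/4)` and canonicalization. Edge ratios `exp(d_w)`,
#' `exp(d_h)` are clamped so that no decoded edge exceeds `max_extent`
#' (guards against exploding predictions early in training); a warning is
#' emitted when clamping occurs.
#'
#' @param deltas Matrix with columns `dx, dy, dw, dh, dtheta`.
#' @param anchor `rbox` of matching length.
#' @param max_extent Upper bound for decoded edge lengths (pixels), or
#'   `Inf` to disable.
#' @return An `rbox`.
#' @export
decode_deltas <- function(deltas, anchor, max_extent = Inf) {
  deltas <- as.matrix(deltas)
  anchor <- as_rbox(anchor)
  if (nrow(anchor) == 1L && nrow(deltas) > 1L)
    anchor <- anchor[rep(1L, nrow(deltas)), ]
  stopifnot(nrow(deltas) == nrow(anchor), ncol(deltas) == 5)
  w <- anchor[, "w"] * exp(deltas[, 3])
  h <- anchor[, "h"] * exp(deltas[, 4])
  if (is.finite(max_extent) && any(c(w, h) > max_extent)) {
    warning("decoded edges clamped to max_extent", call. = FALSE)
    w <- pmin(w, max_extent)
    h <- pmin(h, max_extent)
  }
  rbox(anchor[, "x"] + deltas[, 1] * anchor[, "w"],
       anchor[, "y"] + deltas[, 2] * anchor[, "h"],
       w, h, anchor[, "theta"] + deltas[, 5])
}

#' Smooth L1 penalty
#'
#' `0.5 x^2` for `|x| < 1` and `|x| - 0.5` otherwise; continuous with
#' continuous first derivative at `|x| = 1`.
#'
#' @param x Numeric vector.
#' @return Elementwise smooth-L1 values.
#' @export
smooth_l1 <- function(x) {
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

# derivative of smooth_l1, used by the trainer
smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

#' Combined detection loss
#'
#' The two-stage training objective for one image:
#' `L = (sum_i^N CE(p_i, y_i) + sum_i^Np sum_j smooth_l1(d_gt[i,j] -
#' d_dt[i,j])) / N`, i.e. cross-entropy over all `N` sampled anchors plus
#' smooth-L1 over the five delta components of the `Np` positives, with the
#' single shared `1/N` normalization applied to both sums.
#'
#' @param class_probs Predicted foreground probabilities (length `N`,
#'   values in (0, 1)) for binary scoring, or an `N x 2` matrix of class
#'   probabilities whose second column is the foreground.
#' @param class_targets 0/1 labels of length `N`.
#' @param pred_deltas,target_deltas `Np x 5` delta matrices for the
#'   positive samples (may have zero rows).
#' @param n_total Batch size `N`; defaults to `length(class_targets)`.
#' @return A `loss_breakdown`: list with `total`, `classification`,
#'   `regression`, `n`, `n_pos`.
#' @export
detection_loss <- function(class_probs, class_targets, pred_deltas,
                           target_deltas, n_total = length(class_targets)) {
  if (is.matrix(class_probs)) class_probs <- class_probs[, 2]
  stopifnot(length(class_probs) == length(class_targets))
  pred_deltas <- as.matrix(pred_deltas)
  target_deltas <- as.matrix(target_deltas)
  n_pos <- nrow(pred_deltas)
  if (nrow(target_deltas) != n_pos)
    stop("delta matrices must have matching rows", call. = FALSE)
  if (n_pos > n_total)
    stop("more positives than total samples", call. = FALSE)
  eps <- 1e-12
  p <- pmin(pmax(class_probs, eps), 1 - eps)
  ce <- -sum(class_targets * log(p) + (1 - class_targets) * log(1 - p))
  reg <- if (n_pos > 0) sum(smooth_l1(target_deltas - pred_deltas)) else 0
  structure(list(total = (ce + reg) / n_total,
                 classification = ce / n_total,
                 regression = reg / n_total,
                 n = n_total, n_pos = n_pos),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> total %.4f = cls %.4f + reg %.4f (N=%d, Np=%d)\n",
              x$total, x$classification, x$regression, x$n, x$n_pos))
  invisible(x)
}
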