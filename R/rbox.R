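#' Rotated boxes in the long-edge convention
#'
#' A rotated bounding box is the 5-vector (x, y, w, h, theta): center
#' coordinates in continuous image pixels (origin at the top-left corner,
#' y growing downward), the long edge `w`, the short edge `h`, and the
#' rotation `theta` of the long edge with respect to the x-axis, in radians,
#' clockwise positive. The long-edge convention requires `w >= h` and
#' `theta` in `[-pi/4, 3*pi/4)`; `rbox()` canonicalizes its arguments into
#' that convention, so any (w, h, theta) triple describing the same
#' rectangle maps to a single representation.
#'
#' @param x,y Center coordinates (pixels). Vectors are recycled to a common
#'   length.
#' @param w,h Edge lengths (pixels, strictly positive). `w` need not exceed
#'   `h` on input; edges are swapped during canonicalization when needed.
#' @param theta Rotation of the `w` edge (radians, clockwise positive).
#' @return An `rbox` object: a numeric matrix with one row per box and
#'   columns `x, y, w, h, theta`, satisfying the long-edge invariants.
#' @examples
#' rbox(0, 0, 2, 4, 0)        # stored as w = 4, h = 2, theta = pi/2
#' rbox(10, 20, 8, 2, 0.5)
#' @export
rbox <- function(x, y, w, h, theta = 0) {
  n <- max(length(x), length(y), length(w), length(h), length(theta))
  m <- cbind(x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
             w = rep_len(as.numeric(w), n), h = rep_len(as.numeric(h), n),
             theta = rep_len(as.numeric(theta), n))
  if (anyNA(m) || any(!is.finite(m)))
    stop("rbox fields must be finite", call. = FALSE)
  if (any(m[, "w"] < 1e-6 | m[, "h"] < 1e-6))
    stop("rbox edges must be positive (>= 1e-6 px)", call. = FALSE)
  swap <- m[, "w"] < m[, "h"]
  if (any(swap)) {
    tmp <- m[swap, "w"]
    m[swap, "w"] <- m[swap, "h"]
    m[swap, "h"] <- tmp
    m[swap, "theta"] <- m[swap, "theta"] + pi / 2
  }
  m[, "theta"] <- normalize_angle(m[, "theta"])
  structure(m, class = c("rbox", "matrix", "array"))
}

#' @export
print.rbox <- function(x, ...) {
  cat(sprintf("<rbox> %d box(es), long-edge convention\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
`[.rbox` <- function(x, i, j, ..., drop = TRUE) {
  if (missing(j)) {
    m <- unclass(x)[i, , drop = FALSE]
    structure(m, class = c("rbox", "matrix", "array"))
  } else {
    unclass(x)[i, j, drop = drop]
  }
}

as_rbox <- function(m) {
  m <- unclass(as.matrix(m))
  if (ncol(m) != 5) stop("expected 5 columns (x, y, w, h, theta)", call. = FALSE)
  rbox(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
}

#' Horizontal (axis-aligned) boxes
#'
#' @param x1,y1 Top-left corner (pixels).
#' @param x2,y2 Bottom-right corner (pixels); must satisfy `x1 < x2`,
#'   `y1 < y2`.
#' @return An `hbox` object: a numeric matrix with columns `x1, y1, x2, y2`.
#' @export
hbox <- function(x1, y1, x2, y2) {
  n <- max(length(x1), length(y1), length(x2), length(y2))
  m <- cbind(x1 = rep_len(as.numeric(x1), n), y1 = rep_len(as.numeric(y1), n),
             x2 = rep_len(as.numeric(x2), n), y2 = rep_len(as.numeric(y2), n))
  if (anyNA(m) || any(!is.finite(m)))
    stop("hbox fields must be finite", call. = FALSE)
  if (any(m[, "x1"] >= m[, "x2"]) || any(m[, "y1"] >= m[, "y2"]))
    stop("hbox requires x1 < x2 and y1 < y2", call. = FALSE)
  structure(m, class = c("hbox", "matrix", "array"))
}

#' Wrap angles into the long-edge range
#'
#' Reduces angles modulo the rectangle symmetry period `pi` into
#' `[-pi/4, 3*pi/4)`, the canonical range of the long-edge convention.
#' Idempotent.
#'
#' @param theta Numeric vector of angles (radians).
#' @return Angles congruent to `theta` (mod pi) inside `[-pi/4, 3*pi/4)`.
#' @export
normalize_angle <- function(theta) {
  if (any(!is.finite(theta))) stop("non-finite angle", call. = FALSE)
  ((theta + pi / 4) %% pi) - pi / 4
}

#' Corner coordinates of rotated boxes
#'
#' Corners are `center + R(theta) %*% (+-w/2, +-h/2)` with the clockwise
#' rotation matrix in image coordinates, listed in clockwise winding order
#' starting from the (-w/2, -h/2) corner.
#'
#' @param b An `rbox`.
#' @return For a single box, a 4x2 matrix of (x, y) corners; for `n` boxes,
#'   an `n x 4 x 2` array.
#' @export
rbox_corners <- function(b) {
  b <- as_rbox(b)
  cs <- unname(cos(b[, "theta"])); sn <- unname(sin(b[, "theta"]))
  hw <- unname(b[, "w"] / 2); hh <- unname(b[, "h"] / 2)
  ox <- cbind(-hw, hw, hw, -hw)
  oy <- cbind(-hh, -hh, hh, hh)
  cx <- unname(b[, "x"]) + cs * ox - sn * oy
  cy <- unname(b[, "y"]) + sn * ox + cs * oy
  if (nrow(b) == 1L) {
    cbind(x = unname(cx[1, ]), y = unname(cy[1, ]))
  } else {
    out <- array(0, dim = c(nrow(b), 4, 2),
                 dimnames = list(NULL, NULL, c("x", "y")))
    out[, , 1] <- cx
    out[, , 2] <- cy
    out
  }
}

#' Recover a rotated box from its four corners
#'
#' Accepts the four vertices of a rectangle in either winding order and any
#' starting vertex, and returns the canonical long-edge `rbox`. The quad
#' must be a rectangle up to a small tolerance.
#'
#' @param q A 4x2 matrix of (x, y) vertices in consecutive order around the
#'   rectangle.
#' @param tol Maximum relative deviation from rectangularity.
#' @return A single-row `rbox`.
#' @export
corners_to_rbox <- function(q, tol = 1e-6) {
  q <- as.matrix(q)
  if (!all(dim(q) == c(4, 2))) stop("expected a 4x2 corner matrix", call. = FALSE)
  ctr <- colMeans(q)
  e1 <- q[2, ] - q[1, ]
  e2 <- q[3, ] - q[2, ]
  w <- sqrt(sum(e1^2)); h <- sqrt(sum(e2^2))
  scale <- max(w, h, 1)
  if (abs(sum(e1 * e2)) > tol * scale^2)
    stop("corners do not form a rectangle", call. = FALSE)
  e3 <- q[4, ] - q[3, ]
  if (max(abs(e3 + e1)) > tol * scale)
    stop("corners do not form a rectangle", call. = FALSE)
  theta <- atan2(e1[2], e1[1])
  rbox(ctr[1], ctr[2], w, h, theta)
}

#' Horizontal circumscribed rectangle
#'
#' The smallest axis-aligned box containing each rotated box: the min/max
#' of the four corners.
#'
#' @param b An `rbox`.
#' @return An `hbox` with one row per input box.
#' @export
circumscribed_hbb <- function(b) {
  b <- as_rbox(b)
  cs <- abs(cos(b[, "theta"])); sn <- abs(sin(b[, "theta"]))
  ex <- (b[, "w"] * cs + b[, "h"] * sn) / 2
  ey <- (b[, "w"] * sn + b[, "h"] * cs) / 2
  hbox(b[, "x"] - ex, b[, "y"] - ey, b[, "x"] + ex, b[, "y"] + ey)
}

#' Intersection area of rotated-box pairs
#'
#' Area of the convex polygon obtained by clipping one rectangle against the
#' other (Sutherland-Hodgman) and applying the shoelace formula; equal to
#' the triangular dissection of the intersection polygon. Symmetric, zero
#' for disjoint or edge-touching boxes.
#'
#' @param a,b `rbox` sets. With `pairwise = FALSE` (default) all rows of `a`
#'   are intersected with all rows of `b`; with `pairwise = TRUE` the sets
#'   must have equal length and are intersected row by row.
#' @param pairwise Logical; see above.
#' @return A length(a) x length(b) matrix of areas (pixels squared), or a
#'   vector when `pairwise = TRUE`.
#' @export
convex_intersection_area <- function(a, b, pairwise = FALSE) {
  a <- as_rbox(a); b <- as_rbox(b)
  if (pairwise) {
    cpp_intersection_pairs(unclass(a), unclass(b))
  } else {
    m <- cpp_intersection_matrix(unclass(a), unclass(b))
    if (nrow(a) == 1L && nrow(b) == 1L) as.numeric(m) else m
  }
}

#' Skew intersection-over-union
#'
#' IoU computed on the rotated rectangles themselves:
#' `I / (area(a) + area(b) - I)` with `I` the convex intersection area.
#' Symmetric, in `[0, 1]`, and 1 exactly when the boxes cover the same
#' point set.
#'
#' @inheritParams convex_intersection_area
#' @return Matrix (or vector when `pairwise = TRUE`) of IoU values.
#' @export
skew_iou <- function(a, b, pairwise = FALSE) {
  a <- as_rbox(a); b <- as_rbox(b)
  area_a <- unname(a[, "w"] * a[, "h"])
  area_b <- unname(b[, "w"] * b[, "h"])
  inter <- convex_intersection_area(a, b, pairwise = pairwise)
  if (pairwise) {
    inter / (area_a + area_b - inter)
  } else {
    u <- outer(area_a, area_b, "+") - inter
    out <- inter / u
    if (nrow(a) == 1L && nrow(b) == 1L) as.numeric(out) else out
  }
}

#' Skew intersection-over-foreground
#'
#' Intersection area divided by the area of the detection box (first
#' argument). Asymmetric and never smaller than the skew IoU of the same
#' pair; forgiving toward detections that cover only part of a truncated
#' symptom.
#'
#' @param det Detection boxes (`rbox`), the denominator side.
#' @param gt Ground-truth boxes (`rbox`).
#' @inheritParams convex_intersection_area
#' @return Matrix (or vector when `pairwise = TRUE`) of IoF values.
#' @export
skew_iof <- function(det, gt, pairwise = FALSE) {
  det <- as_rbox(det); gt <- as_rbox(gt)
  area_d <- unname(det[, "w"] * det[, "h"])
  inter <- convex_intersection_area(det, gt, pairwise = pairwise)
  out <- inter / area_d
  if (!pairwise && nrow(det) == 1L && nrow(gt) == 1L) as.numeric(out) else out
}

#' Rotated non-maximum suppression
#'
#' Greedy suppression in descending score order under skew IoU: a box is
#' removed when its IoU with an already-kept higher-scoring box exceeds the
#' threshold. Score ties are broken by ascending original index, so the
#' result is deterministic; re-running on the kept set is a no-op.
#'
#' @param boxes An `rbox` set.
#' @param scores Numeric scores, one per box.
#' @param iou_threshold Suppression threshold in `[0, 1]`.
#' @return Integer indices of the kept boxes, sorted by descending score.
#' @export
rotated_nms <- function(boxes, scores, iou_threshold) {
  boxes <- as_rbox(boxes)
  if (nrow(boxes) == 0L) return(integer(0))
  if (length(scores) != nrow(boxes))
    stop("scores must match the number of boxes", call. = FALSE)
  if (iou_threshold < 0 || iou_threshold > 1)
    stop("iou_threshold must lie in [0, 1]", call. = FALSE)
  as.integer(cpp_rotated_nms(unclass(boxes), as.numeric(scores),
                             iou_threshold))
}
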