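#' Feature maps
#'
#' A feature map is an `H x W x C` numeric array of activations plus the
#' stride `s` (image pixels per feature cell). Bilinear lookups anchor
#' feature values at integer cell coordinates `(1..W, 1..H)` in the
#' feature frame.
#'
#' @param values `H x W x C` array (a matrix is treated as `C = 1`).
#' @param stride Pixels per cell.
#' @return A `feature_map` list.
#' @export
feature_map <- function(values, stride = 1) {
  if (length(dim(values)) == 2L)
    values <- array(values, dim = c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, dim(values)[3] >= 1, stride > 0,
            all(is.finite(values)))
  structure(list(values = values, stride = stride), class = "feature_map")
}

#' Project a rotated proposal onto a feature map
#'
#' Scales the proposal from image to feature coordinates at stride `s`:
#' edges divide exactly (`w_f = w_p / s`, `h_f = h_p / s`) while the
#' center coordinates are floored (`x_f = floor(x_p / s)`); the angle is
#' unchanged. The floor introduces up to half a cell of quantization and is
#' kept as the reference behavior; `floor_center = FALSE` disables it for
#' ablation.
#'
#' @param p An `rbox` proposal (one or more rows), in image pixels.
#' @param s Stride (> 0).
#' @param floor_center Apply the floor to projected centers.
#' @return An `rbox` in the feature frame.
#' @export
project_proposal <- function(p, s, floor_center = TRUE) {
  stopifnot(s > 0)
  p <- as_rbox(p)
  cx <- p[, "x"] / s
  cy <- p[, "y"] / s
  if (floor_center) { cx <- floor(cx); cy <- floor(cy) }
  rbox(cx, cy, p[, "w"] / s, p[, "h"] / s, p[, "theta"])
}

# sample-point layout inside one bin: l points at sub-bin centers of an
# r x r grid with r = ceiling(sqrt(l)); l must be a perfect square.
subbin_offsets <- function(l) {
  r <- round(sqrt(l))
  if (r * r != l) stop("l must be a perfect square (sub-bin grid)", call. = FALSE)
  (seq_len(r) - 0.5) / r
}

# Shared sampling core: proposal given in the feature frame (already
# projected). Returns k x k x C pooled values; optionally the sampling
# positions and weights needed for the backward pass.
rroi_pool_core <- function(values, prop, k, l, want_grad = FALSE) {
  H <- dim(values)[1]; W <- dim(values)[2]; C <- dim(values)[3]
  off <- subbin_offsets(l)
  # local coordinates in [0, w_f] x [0, h_f]: bin (m, n) covers
  # [(m-1) w_f / k, m w_f / k] along the long edge
  bins <- expand.grid(m = seq_len(k), n = seq_len(k))
  sub <- expand.grid(u = off, v = off)
  # all k*k*l sample points, grouped by bin (bin index slow, sample fast)
  lx <- rep((bins$m - 1), each = l) + rep(sub$u, times = k * k)
  ly <- rep((bins$n - 1), each = l) + rep(sub$v, times = k * k)
  lx <- lx * prop[1, "w"] / k
  ly <- ly * prop[1, "h"] / k
  cs <- cos(prop[1, "theta"]); sn <- sin(prop[1, "theta"])
  ox <- lx - prop[1, "w"] / 2
  oy <- ly - prop[1, "h"] / 2
  sx <- cs * ox - sn * oy + prop[1, "x"]
  sy <- sn * ox + cs * oy + prop[1, "y"]
  nb <- bilinear_neighbors(sx, sy, H, W)
  vmat <- matrix(values, H * W, C)
  S <- length(sx)
  acc <- matrix(0, S, C)
  for (q in 1:4) {
    ok <- nb$ok[, q]
    if (any(ok))
      acc[ok, ] <- acc[ok, , drop = FALSE] +
        vmat[nb$idx[ok, q], , drop = FALSE] * nb$w[ok, q]
  }
  pooled <- array(rowsum(acc, group = rep(seq_len(k * k), each = l)) / l,
                  dim = c(k, k, C))
  if (!want_grad) return(pooled)
  list(pooled = pooled, nb = nb, k = k, l = l, H = H, W = W, C = C)
}

# the four bilinear neighbors of each sample point, with weights and
# in-bounds masks; idx is a linear index into an (H*W) matrix layout
bilinear_neighbors <- function(sx, sy, H, W) {
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  xs <- cbind(x0, x0 + 1, x0, x0 + 1)
  ys <- cbind(y0, y0, y0 + 1, y0 + 1)
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
  idx <- (pmin(pmax(xs, 1), W) - 1) * H + pmin(pmax(ys, 1), H)
  list(idx = idx, w = w, ok = ok)
}

# backward of rroi_pool_core: scatter bin gradients to the feature map
rroi_pool_bwd <- function(dpooled, info) {
  k <- info$k; l <- info$l
  G <- matrix(dpooled, k * k, info$C)[rep(seq_len(k * k), each = l), ,
                                      drop = FALSE] / l
  dv <- matrix(0, info$H * info$W, info$C)
  for (q in 1:4) {
    ok <- info$nb$ok[, q]
    if (!any(ok)) next
    contrib <- rowsum(G[ok, , drop = FALSE] * info$nb$w[ok, q],
                      group = info$nb$idx[ok, q])
    rows <- as.integer(rownames(contrib))
    dv[rows, ] <- dv[rows, , drop = FALSE] + contrib
  }
  array(dv, dim = c(info$H, info$W, info$C))
}

#' Rotated region-of-interest alignment
#'
#' Pools a `k x k` grid of features from inside a rotated proposal. The
#' proposal is projected to the feature frame at the map's stride, its
#' interior is divided into `k x k` bins in the proposal's local frame
#' (the first grid axis runs along the long edge), and each bin is sampled
#' at `l` sub-bin-center points; each point is mapped into the feature map
#' by the rotation `R(theta)` about the projected center and read by
#' bilinear interpolation (zero outside the map), then averaged per bin.
#'
#' @param fm A `feature_map`.
#' @param p A single-row `rbox` proposal in image pixels.
#' @param k Output grid size (default 7).
#' @param l Sample points per bin (perfect square, default 4).
#' @param floor_center Passed to [project_proposal()].
#' @return A `pooled_region`: list with `values` (`k x k x C`), the source
#'   proposal, `k` and `l`.
#' @export
rroi_align <- function(fm, p, k = 7, l = 4, floor_center = TRUE) {
  stopifnot(inherits(fm, "feature_map"), k >= 1, l >= 1)
  p <- as_rbox(p)
  stopifnot(nrow(p) == 1)
  prop <- project_proposal(p, fm$stride, floor_center = floor_center)
  H <- dim(fm$values)[1]; W <- dim(fm$values)[2]
  ext <- circumscribed_hbb(prop)
  if (ext[1, "x2"] < 1 || ext[1, "x1"] > W || ext[1, "y2"] < 1 ||
      ext[1, "y1"] > H)
    warning("proposal lies fully outside the feature map", call. = FALSE)
  structure(list(values = rroi_pool_core(fm$values, prop, k, l),
                 proposal = p, k = k, l = l),
            class = "pooled_region")
}

#' Axis-aligned RoI alignment (baseline)
#'
#' The horizontal counterpart of [rroi_align()]: identical sub-bin-center
#' bilinear sampling over an axis-aligned box (theta = 0), provided as the
#' comparison baseline for rotated alignment. Uses the same projection rule
#' (edges scaled, center floored).
#'
#' @param fm A `feature_map`.
#' @param b A single-row `hbox` in image pixels.
#' @inheritParams rroi_align
#' @return A `pooled_region`.
#' @export
hroi_align <- function(fm, b, k = 7, l = 4, floor_center = TRUE) {
  stopifnot(inherits(fm, "feature_map"), inherits(b, "hbox"), nrow(b) == 1)
  p <- rbox((b[1, "x1"] + b[1, "x2"]) / 2, (b[1, "y1"] + b[1, "y2"]) / 2,
            max(b[1, "x2"] - b[1, "x1"], b[1, "y2"] - b[1, "y1"]),
            min(b[1, "x2"] - b[1, "x1"], b[1, "y2"] - b[1, "y1"]),
            if ((b[1, "x2"] - b[1, "x1"]) >= (b[1, "y2"] - b[1, "y1"])) 0
            else pi / 2)
  rroi_align(fm, p, k = k, l = l, floor_center = floor_center)
}
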