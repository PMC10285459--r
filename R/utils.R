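# Internal image helpers shared by the scene generator, the detector input
# pipeline and the rotated-RoI sampler. Images are H x W (x 3) arrays in
# [0, 1]; continuous coordinates put pixel centers at integer positions
# (1 .. W, 1 .. H).

# Bilinear lookup of a single-channel matrix at continuous coordinates.
# Points outside the support read as `pad`.
bilinear_lookup <- function(mat, x, y, pad = 0) {
  H <- nrow(mat); W <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gather <- function(xi, yi) {
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    v <- rep(pad, length(xi))
    idx <- (xi[ok] - 1) * H + yi[ok]
    v[ok] <- mat[idx]
    v
  }
  v00 <- gather(x0, y0)
  v10 <- gather(x0 + 1, y0)
  v01 <- gather(x0, y0 + 1)
  v11 <- gather(x0 + 1, y0 + 1)
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
    (v01 * (1 - fx) + v11 * fx) * fy
}

# Resize a matrix (or H x W x C array) to out_h x out_w by bilinear sampling.
bilinear_resize <- function(img, out_h, out_w) {
  resize_one <- function(mat) {
    H <- nrow(mat); W <- ncol(mat)
    xs <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
    ys <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
    xs <- pmin(pmax(xs, 1), W)
    ys <- pmin(pmax(ys, 1), H)
    grid_x <- rep(xs, each = out_h)
    grid_y <- rep(ys, times = out_w)
    matrix(bilinear_lookup(mat, grid_x, grid_y), out_h, out_w)
  }
  if (length(dim(img)) == 2L) return(resize_one(img))
  out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- resize_one(img[, , c])
  out
}

# Smooth value noise: random values on a coarse grid, bilinearly upsampled.
value_noise <- function(H, W, cells) {
  coarse <- matrix(runif(cells * cells), cells, cells)
  bilinear_resize(coarse, H, W)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so generators are reproducible yet side-effect free.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Burn rectangle outlines into an image (for assignment / detection
# overlays). `boxes` is an rbox; color a length-3 RGB vector.
draw_boxes <- function(image, boxes, color = c(1, 0, 0)) {
  boxes <- as_rbox(boxes)
  H <- dim(image)[1]; W <- dim(image)[2]
  for (i in seq_len(nrow(boxes))) {
    q <- rbox_corners(boxes[i, ])
    for (e in 1:4) {
      a <- q[e, ]; b <- q[e %% 4 + 1, ]
      len <- max(2, ceiling(sqrt(sum((b - a)^2)) * 2))
      t <- seq(0, 1, length.out = len)
      xs <- round(a[1] + t * (b[1] - a[1]))
      ys <- round(a[2] + t * (b[2] - a[2]))
      ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
      for (c in 1:3) {
        idx <- cbind(ys[ok], xs[ok], c)
        image[idx] <- color[c]
      }
    }
  }
  image
}
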