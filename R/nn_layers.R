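# Minimal CPU neural-network layers used by the two-stage detector.
# Activations are H x W x C arrays; convolution weights are stored as
# (k*k*C_in) x C_out matrices so forward/backward reduce to BLAS matrix
# products over im2col patches. Gradients are computed by hand per layer
# (no autodiff); only the demo-scale backbone is trained, so clarity wins
# over generality.

conv_init <- function(kk, cin, cout, stride = 1, pad = (kk - 1) %/% 2,
                      gain = 2) {
  kk <- unname(kk); cin <- unname(cin); cout <- unname(cout)
  stride <- unname(stride); pad <- unname(pad)
  fan_in <- kk * kk * cin
  list(W = matrix(rnorm(fan_in * cout, sd = sqrt(gain / fan_in)),
                  fan_in, cout),
       b = numeric(cout),
       kk = kk, cin = cin, cout = cout, stride = stride, pad = pad,
       type = "conv")
}

linear_init <- function(din, dout, gain = 2) {
  din <- unname(din); dout <- unname(dout)
  list(W = matrix(rnorm(din * dout, sd = sqrt(gain / din)), din, dout),
       b = numeric(dout), din = din, dout = dout, type = "linear")
}

bn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c), c = c,
                            type = "bn")

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# im2col: rows are output positions (row-fastest, column-major over the
# output grid), columns are (dy, dx, channel) patch entries.
im2col <- function(xp, kk, stride, ho, wo) {
  C <- dim(xp)[3]
  cols <- matrix(0, ho * wo, kk * kk * C)
  col <- 1L
  ys <- stride * (seq_len(ho) - 1L)
  xs <- stride * (seq_len(wo) - 1L)
  for (c in seq_len(C)) {
    for (dx in seq_len(kk)) {
      for (dy in seq_len(kk)) {
        cols[, col] <- xp[ys + dy, xs + dx, c]
        col <- col + 1L
      }
    }
  }
  cols
}

conv_fwd <- function(layer, x) {
  d <- dim(x)
  stopifnot(d[3] == layer$cin)
  xp <- pad_hw(x, layer$pad)
  ho <- (d[1] + 2 * layer$pad - layer$kk) %/% layer$stride + 1L
  wo <- (d[2] + 2 * layer$pad - layer$kk) %/% layer$stride + 1L
  cols <- im2col(xp, layer$kk, layer$stride, ho, wo)
  y <- sweep(cols %*% layer$W, 2, layer$b, "+")
  list(y = array(y, dim = c(ho, wo, layer$cout)),
       cache = list(xdim = d, ho = ho, wo = wo))
}

conv_bwd <- function(layer, x, cache, dy) {
  ho <- cache$ho; wo <- cache$wo
  xp <- pad_hw(x, layer$pad)
  cols <- im2col(xp, layer$kk, layer$stride, ho, wo)
  dym <- matrix(dy, ho * wo, layer$cout)
  dW <- crossprod(cols, dym)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, layer$W)
  # col2im: scatter-add patch gradients back into the padded input
  d <- cache$xdim
  dxp <- array(0, dim = c(d[1] + 2 * layer$pad, d[2] + 2 * layer$pad, d[3]))
  col <- 1L
  ys <- layer$stride * (seq_len(ho) - 1L)
  xs <- layer$stride * (seq_len(wo) - 1L)
  for (c in seq_len(d[3])) {
    for (dx in seq_len(layer$kk)) {
      for (dyk in seq_len(layer$kk)) {
        dxp[ys + dyk, xs + dx, c] <- dxp[ys + dyk, xs + dx, c] +
          matrix(dcols[, col], ho, wo)
        col <- col + 1L
      }
    }
  }
  dx <- if (layer$pad > 0)
    dxp[layer$pad + seq_len(d[1]), layer$pad + seq_len(d[2]), , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)

linear_fwd <- function(layer, x) as.numeric(crossprod(layer$W, x) + layer$b)
linear_bwd <- function(layer, x, dy) {
  list(dx = as.numeric(layer$W %*% dy),
       dW = outer(x, dy), db = dy)
}

# inference-style batch normalization: per-channel affine (the running
# statistics are folded into gamma/beta); only used by the large backbone
bn_fwd <- function(layer, x) {
  d <- dim(x)
  sweep(sweep(x, 3, layer$gamma, "*"), 3, layer$beta, "+")
}

# nearest-neighbor x2 upsampling (FPN top-down path)
upsample2_fwd <- function(x, out_h, out_w) {
  d <- dim(x)
  yi <- pmin(ceiling(seq_len(out_h) / 2), d[1])
  xi <- pmin(ceiling(seq_len(out_w) / 2), d[2])
  x[yi, xi, , drop = FALSE]
}

upsample2_bwd <- function(dy, in_h, in_w) {
  d <- dim(dy)
  yi <- pmin(ceiling(seq_len(d[1]) / 2), in_h)
  xi <- pmin(ceiling(seq_len(d[2]) / 2), in_w)
  dx <- array(0, dim = c(in_h, in_w, d[3]))
  for (c in seq_len(d[3]))
    dx[, , c] <- rowsum(t(rowsum(t(dy[, , c]), xi)), yi)
  dx
}

# stride-2 subsampling (used to derive the coarsest pyramid level)
subsample2_fwd <- function(x) {
  d <- dim(x)
  x[seq(1, d[1], by = 2), seq(1, d[2], by = 2), , drop = FALSE]
}

subsample2_bwd <- function(dy, in_h, in_w) {
  dx <- array(0, dim = c(in_h, in_w, dim(dy)[3]))
  dx[seq(1, in_h, by = 2), seq(1, in_w, by = 2), ] <- dy
  dx
}

# 3x3 stride-2 max pooling with padding 1 (large-backbone stem)
maxpool3s2_fwd <- function(x) {
  d <- dim(x)
  xp <- pad_hw(x, 1)
  xp[is.na(xp)] <- -Inf
  ho <- (d[1] + 2 - 3) %/% 2 + 1L
  wo <- (d[2] + 2 - 3) %/% 2 + 1L
  out <- array(-Inf, dim = c(ho, wo, d[3]))
  for (dyk in 1:3) for (dxk in 1:3) {
    sl <- xp[2 * (seq_len(ho) - 1) + dyk, 2 * (seq_len(wo) - 1) + dxk, ,
             drop = FALSE]
    out <- pmax(out, sl)
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_row <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
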