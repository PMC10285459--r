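#' Detector configuration
#'
#' Configuration of the two-stage rotated detector: a backbone ("resnet50"
#' for the full-scale architecture, "tiny" for a compact CPU-friendly
#' variant with the same interface), a feature-pyramid neck over strides
#' (4, 8, 16, 32, 64), a proposal head with three horizontal anchors per
#' position regressing rotated proposals, and a refinement head pooling
#' `k x k` rotated-aligned features through two fully-connected layers
#' into 2-way classification and 5-parameter regression.
#'
#' @param backbone `"resnet50"` or `"tiny"`.
#' @param fpn_channels Pyramid channel width (256 for resnet50; the tiny
#'   preset uses 64).
#' @param head_dim Width of the two fully-connected refinement layers
#'   (1024 for resnet50; the tiny preset uses 128).
#' @param k Pooled grid size (default 7).
#' @param l Sample points per pooling bin (perfect square).
#' @param input_size Square input edge the detector is run at.
#' @param strides,areas,ratios Anchor pyramid layout; see
#'   [build_anchor_pyramid()].
#' @param n_per_level Candidates per level for adaptive assignment.
#' @param rpn_nms_threshold NMS threshold applied per level to proposals.
#' @param pre_nms_top Per-level score cap before NMS.
#' @param post_nms_top Aggregated proposal caps, `c(train, inference)`.
#' @param score_threshold Final detection score threshold.
#' @param final_nms_threshold NMS threshold on refined detections.
#' @return A `detector_config` list.
#' @export
detector_config <- function(backbone = c("tiny", "resnet50"),
                            fpn_channels = NULL, head_dim = NULL,
                            k = 7, l = 4, input_size = NULL,
                            strides = c(4, 8, 16, 32, 64),
                            areas = c(32, 64, 128, 256, 512)^2,
                            ratios = c(2, 1, 0.5),
                            n_per_level = 9,
                            rpn_nms_threshold = 0.8,
                            pre_nms_top = NULL,
                            post_nms_top = NULL,
                            score_threshold = 0.05,
                            final_nms_threshold = 0.1) {
  backbone <- match.arg(backbone)
  if (is.null(fpn_channels))
    fpn_channels <- if (backbone == "resnet50") 256L else 64L
  if (is.null(head_dim))
    head_dim <- if (backbone == "resnet50") 1024L else 128L
  if (is.null(input_size))
    input_size <- if (backbone == "resnet50") 1024L else 128L
  # proposal caps scale with the backbone: the demo-sized variant works on
  # small grids where a few hundred proposals already saturate recall
  if (is.null(pre_nms_top))
    pre_nms_top <- if (backbone == "resnet50") 2000L else 600L
  if (is.null(post_nms_top))
    post_nms_top <- if (backbone == "resnet50") c(2000L, 1000L)
                    else c(300L, 100L)
  structure(list(backbone = backbone, fpn_channels = as.integer(fpn_channels),
                 head_dim = as.integer(head_dim), k = as.integer(k),
                 l = as.integer(l), input_size = as.integer(input_size),
                 strides = strides, areas = areas, ratios = ratios,
                 n_per_level = n_per_level,
                 rpn_nms_threshold = rpn_nms_threshold,
                 pre_nms_top = pre_nms_top, post_nms_top = post_nms_top,
                 score_threshold = score_threshold,
                 final_nms_threshold = final_nms_threshold),
            class = "detector_config")
}

# ---- parameter construction ------------------------------------------------

tiny_channels <- c(stem = 16, c2 = 32, c3 = 64, c4 = 128, c5 = 128)

build_backbone_tiny <- function() {
  ch <- tiny_channels
  list(stem = conv_init(3, 3, ch["stem"], stride = 2),
       c2a = conv_init(3, ch["stem"], ch["c2"], stride = 2),
       c2b = conv_init(3, ch["c2"], ch["c2"]),
       c3a = conv_init(3, ch["c2"], ch["c3"], stride = 2),
       c3b = conv_init(3, ch["c3"], ch["c3"]),
       c4a = conv_init(3, ch["c3"], ch["c4"], stride = 2),
       c4b = conv_init(3, ch["c4"], ch["c4"]),
       c5a = conv_init(3, ch["c4"], ch["c5"], stride = 2),
       c5b = conv_init(3, ch["c5"], ch["c5"]))
}

bottleneck_init <- function(cin, mid, cout, stride) {
  blk <- list(conv1 = conv_init(1, cin, mid, pad = 0), bn1 = bn_init(mid),
              conv2 = conv_init(3, mid, mid, stride = stride), bn2 = bn_init(mid),
              conv3 = conv_init(1, mid, cout, pad = 0), bn3 = bn_init(cout))
  if (cin != cout || stride != 1) {
    blk$down <- conv_init(1, cin, cout, stride = stride, pad = 0)
    blk$down_bn <- bn_init(cout)
  }
  blk
}

build_backbone_resnet50 <- function() {
  stages <- list(c(n = 3, mid = 64, out = 256, stride = 1),
                 c(n = 4, mid = 128, out = 512, stride = 2),
                 c(n = 6, mid = 256, out = 1024, stride = 2),
                 c(n = 3, mid = 512, out = 2048, stride = 2))
  params <- list(stem = conv_init(7, 3, 64, stride = 2, pad = 3),
                 stem_bn = bn_init(64))
  cin <- 64
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    for (b in seq_len(st["n"])) {
      stride <- if (b == 1) st["stride"] else 1
      params[[sprintf("layer%d_block%d", s, b)]] <-
        bottleneck_init(cin, st["mid"], st["out"], stride)
      cin <- st["out"]
    }
  }
  params
}

backbone_out_channels <- function(backbone) {
  if (backbone == "tiny") unname(tiny_channels[c("c2", "c3", "c4", "c5")])
  else c(256, 512, 1024, 2048)
}

build_fpn <- function(backbone, fpn_ch) {
  cc <- backbone_out_channels(backbone)
  out <- list()
  for (i in 1:4) {
    out[[paste0("lat", i + 1)]] <- conv_init(1, cc[i], fpn_ch, pad = 0)
    out[[paste0("smooth", i + 1)]] <- conv_init(3, fpn_ch, fpn_ch)
  }
  out
}

build_rpn_head <- function(fpn_ch, n_anchor = 3) {
  list(conv = conv_init(3, fpn_ch, fpn_ch),
       cls = conv_init(1, fpn_ch, n_anchor, pad = 0, gain = 1),
       reg = conv_init(1, fpn_ch, n_anchor * 5, pad = 0, gain = 1))
}

build_rcnn_head <- function(fpn_ch, k, head_dim) {
  list(fc1 = linear_init(k * k * fpn_ch, head_dim),
       fc2 = linear_init(head_dim, head_dim),
       cls = linear_init(head_dim, 2, gain = 1),
       reg = linear_init(head_dim, 5, gain = 1))
}

#' Build a detector model
#'
#' Instantiates the full layer graph (backbone, pyramid neck, proposal
#' head, refinement head) with weights drawn under the given seed, so the
#' same `(config, seed)` pair always yields identical initial weights.
#'
#' @param config A `detector_config`.
#' @param seed Integer seed for weight initialization.
#' @return A `detector_model`: list with `config`, `params`, `seed`.
#' @export
build_model <- function(config = detector_config(), seed = 0) {
  stopifnot(inherits(config, "detector_config"))
  with_seed(seed, {
    params <- list(
      backbone = if (config$backbone == "tiny") build_backbone_tiny()
                 else build_backbone_resnet50(),
      fpn = build_fpn(config$backbone, config$fpn_channels),
      rpn = build_rpn_head(config$fpn_channels, length(config$ratios)),
      rcnn = build_rcnn_head(config$fpn_channels, config$k, config$head_dim))
    structure(list(config = config, params = params, seed = seed),
              class = "detector_model")
  })
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> backbone=%s fpn=%d head=%d, %.2fM parameters\n",
              x$config$backbone, x$config$fpn_channels, x$config$head_dim,
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and fully-connected
#' weights and biases, plus the affine normalization terms) across the
#' backbone, neck and both heads. The full-scale configuration lands at
#' about 41.1 million.
#'
#' @param model A `detector_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "detector_model"))
  count_rec <- function(x) {
    if (is.numeric(x)) return(length(x))
    if (is.list(x))
      return(sum(vapply(x[names(x) %in% c("W", "b", "gamma", "beta") |
                            vapply(x, is.list, logical(1))],
                        count_rec, numeric(1))))
    0
  }
  as.integer(count_rec(model$params))
}

#' Feature-map grid sizes for an input size
#'
#' @param model A `detector_model` (or `detector_config`).
#' @param image_size Square edge or `c(width, height)`.
#' @return Matrix with one row per pyramid level: stride, grid width,
#'   grid height.
#' @export
model_feature_shapes <- function(model, image_size) {
  cfg <- if (inherits(model, "detector_model")) model$config else model
  if (length(image_size) == 1L) image_size <- rep(image_size, 2)
  cbind(stride = cfg$strides,
        width = ceiling(image_size[1] / cfg$strides),
        height = ceiling(image_size[2] / cfg$strides))
}

# ---- forward passes --------------------------------------------------------

conv_relu_fwd <- function(layer, x, caches, name, keep) {
  cf <- conv_fwd(layer, x)
  y <- relu_fwd(cf$y)
  if (keep) {
    caches[[name]] <- list(x = x, conv = cf$cache, pre = cf$y)
  }
  list(y = y, caches = caches)
}

backbone_tiny_fwd <- function(p, x, keep_cache = FALSE) {
  caches <- list()
  st <- conv_relu_fwd(p$stem, x, caches, "stem", keep_cache)
  c2a <- conv_relu_fwd(p$c2a, st$y, st$caches, "c2a", keep_cache)
  c2b <- conv_relu_fwd(p$c2b, c2a$y, c2a$caches, "c2b", keep_cache)
  c3a <- conv_relu_fwd(p$c3a, c2b$y, c2b$caches, "c3a", keep_cache)
  c3b <- conv_relu_fwd(p$c3b, c3a$y, c3a$caches, "c3b", keep_cache)
  c4a <- conv_relu_fwd(p$c4a, c3b$y, c3b$caches, "c4a", keep_cache)
  c4b <- conv_relu_fwd(p$c4b, c4a$y, c4a$caches, "c4b", keep_cache)
  c5a <- conv_relu_fwd(p$c5a, c4b$y, c4b$caches, "c5a", keep_cache)
  c5b <- conv_relu_fwd(p$c5b, c5a$y, c5a$caches, "c5b", keep_cache)
  list(feats = list(c2 = c2b$y, c3 = c3b$y, c4 = c4b$y, c5 = c5b$y),
       caches = c5b$caches)
}

bottleneck_fwd <- function(blk, x) {
  h <- relu_fwd(bn_fwd(blk$bn1, conv_fwd(blk$conv1, x)$y))
  h <- relu_fwd(bn_fwd(blk$bn2, conv_fwd(blk$conv2, h)$y))
  h <- bn_fwd(blk$bn3, conv_fwd(blk$conv3, h)$y)
  idn <- if (!is.null(blk$down))
    bn_fwd(blk$down_bn, conv_fwd(blk$down, x)$y) else x
  relu_fwd(h + idn)
}

backbone_resnet50_fwd <- function(p, x) {
  h <- relu_fwd(bn_fwd(p$stem_bn, conv_fwd(p$stem, x)$y))
  h <- maxpool3s2_fwd(h)
  feats <- list()
  blocks_per_stage <- c(3, 4, 6, 3)
  for (s in 1:4) {
    for (b in seq_len(blocks_per_stage[s]))
      h <- bottleneck_fwd(p[[sprintf("layer%d_block%d", s, b)]], h)
    feats[[paste0("c", s + 1)]] <- h
  }
  feats
}

fpn_fwd <- function(p, feats, keep_cache = FALSE) {
  lat <- lapply(2:5, function(i) conv_fwd(p[[paste0("lat", i)]],
                                          feats[[paste0("c", i)]]))
  tops <- vector("list", 4)        # merged maps, index 1 = level 2
  ups <- vector("list", 4)
  tops[[4]] <- lat[[4]]$y
  for (i in 3:1) {
    d <- dim(lat[[i]]$y)
    up <- upsample2_fwd(tops[[i + 1]], d[1], d[2])
    ups[[i]] <- up
    tops[[i]] <- lat[[i]]$y + up
  }
  smooth <- lapply(1:4, function(i) conv_fwd(p[[paste0("smooth", i + 1)]],
                                             tops[[i]]))
  pyramid <- list(p2 = smooth[[1]]$y, p3 = smooth[[2]]$y,
                  p4 = smooth[[3]]$y, p5 = smooth[[4]]$y,
                  p6 = subsample2_fwd(smooth[[4]]$y))
  if (!keep_cache) return(list(pyramid = pyramid))
  list(pyramid = pyramid,
       cache = list(lat = lat, tops = tops, feats = feats,
                    smooth = lapply(smooth, `[[`, "cache")))
}

rpn_head_fwd <- function(p, pyramid, keep_cache = FALSE) {
  out <- lapply(pyramid, function(P) {
    cf <- conv_fwd(p$conv, P)
    h <- relu_fwd(cf$y)
    sc <- conv_fwd(p$cls, h)
    dl <- conv_fwd(p$reg, h)
    res <- list(scores = sc$y, deltas = dl$y)
    if (keep_cache)
      res$cache <- list(x = P, conv = cf$cache, pre = cf$y, h = h,
                        cls = sc$cache, reg = dl$cache)
    res
  })
  out
}

rcnn_head_fwd <- function(p, pooled_flat, keep_cache = FALSE) {
  z1 <- linear_fwd(p$fc1, pooled_flat)
  a1 <- pmax(z1, 0)
  z2 <- linear_fwd(p$fc2, a1)
  a2 <- pmax(z2, 0)
  cls_logits <- linear_fwd(p$cls, a2)
  reg <- linear_fwd(p$reg, a2)
  res <- list(cls_logits = cls_logits, probs = softmax_row(cls_logits),
              deltas = reg)
  if (keep_cache) res$cache <- list(x = pooled_flat, z1 = z1, a1 = a1,
                                    z2 = z2, a2 = a2)
  res
}

# full feature extraction: image array (H x W x 3) -> pyramid feature_maps
extract_pyramid <- function(model, image, keep_cache = FALSE) {
  if (model$config$backbone == "tiny") {
    bb <- backbone_tiny_fwd(model$params$backbone, image,
                            keep_cache = keep_cache)
    fp <- fpn_fwd(model$params$fpn, bb$feats, keep_cache = keep_cache)
    list(pyramid = fp$pyramid,
         bb_cache = if (keep_cache) bb$caches,
         fpn_cache = if (keep_cache) fp$cache)
  } else {
    feats <- backbone_resnet50_fwd(model$params$backbone, image)
    fp <- fpn_fwd(model$params$fpn, feats)
    list(pyramid = fp$pyramid)
  }
}
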