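# CPU demo trainer: stochastic gradient descent with momentum over the
# proposal-stage and refinement-stage losses, batch size one image.
# Gradients are assembled by hand, layer by layer; proposals are treated
# as constants in the refinement stage (gradients flow to the features
# through the rotated pooling, not to the proposal coordinates).

zero_like <- function(x) {
  if (is.numeric(x)) return(x * 0)
  if (is.list(x)) return(lapply(x, zero_like))
  x
}

TRAINABLE_FIELDS <- c("W", "b", "gamma", "beta")

# elementwise combine of two nested parameter structures
nested_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  if (is.list(a)) {
    for (nm in names(a)) {
      if (nm %in% TRAINABLE_FIELDS || is.list(a[[nm]]))
        a[[nm]] <- nested_map2(a[[nm]], b[[nm]], f)
    }
    return(a)
  }
  a
}

nested_reduce <- function(a, f, acc = 0) {
  if (is.numeric(a)) return(f(acc, a))
  if (is.list(a)) {
    for (nm in names(a)) {
      if (nm %in% TRAINABLE_FIELDS || is.list(a[[nm]]))
        acc <- nested_reduce(a[[nm]], f, acc)
    }
  }
  acc
}

grad_global_norm <- function(g)
  sqrt(nested_reduce(g, function(acc, x) acc + sum(x^2)))

# ---- head backward passes --------------------------------------------------

# backward through the shared proposal head on one level; dscores/ddeltas
# are full (H, W, A) / (H, W, 5A) gradient arrays
rpn_head_bwd <- function(p, cache, dscores, ddeltas) {
  bc <- conv_bwd(p$cls, cache$h, cache$cls, dscores)
  br <- conv_bwd(p$reg, cache$h, cache$reg, ddeltas)
  dh <- relu_bwd(cache$pre, bc$dx + br$dx)
  bconv <- conv_bwd(p$conv, cache$x, cache$conv, dh)
  list(dx = bconv$dx,
       grads = list(conv = list(W = bconv$dW, b = bconv$db),
                    cls = list(W = bc$dW, b = bc$db),
                    reg = list(W = br$dW, b = br$db)))
}

rcnn_head_bwd <- function(p, cache, dcls_logits, ddeltas) {
  g_cls <- linear_bwd(p$cls, cache$a2, dcls_logits)
  g_reg <- linear_bwd(p$reg, cache$a2, ddeltas)
  da2 <- g_cls$dx + g_reg$dx
  dz2 <- da2 * (cache$z2 > 0)
  g_fc2 <- linear_bwd(p$fc2, cache$a1, dz2)
  dz1 <- g_fc2$dx * (cache$z1 > 0)
  g_fc1 <- linear_bwd(p$fc1, cache$x, dz1)
  list(dx = g_fc1$dx,
       grads = list(fc1 = list(W = g_fc1$dW, b = g_fc1$db),
                    fc2 = list(W = g_fc2$dW, b = g_fc2$db),
                    cls = list(W = g_cls$dW, b = g_cls$db),
                    reg = list(W = g_reg$dW, b = g_reg$db)))
}

fpn_bwd <- function(p, cache, dpyramid) {
  # p6 is a stride-2 subsample of the smoothed p5
  d5 <- dim(cache$tops[[4]])
  dpyramid$p5 <- dpyramid$p5 + subsample2_bwd(dpyramid$p6, d5[1], d5[2])
  grads <- list()
  dtops <- vector("list", 4)
  for (i in 1:4) {
    bs <- conv_bwd(p[[paste0("smooth", i + 1)]], cache$tops[[i]],
                   cache$smooth[[i]], dpyramid[[paste0("p", i + 1)]])
    grads[[paste0("smooth", i + 1)]] <- list(W = bs$dW, b = bs$db)
    dtops[[i]] <- bs$dx
  }
  # reverse the top-down accumulation: level i feeds level i+1's merge
  dfeats <- list()
  for (i in 1:3) {
    d_next <- dim(cache$tops[[i + 1]])
    dtops[[i + 1]] <- dtops[[i + 1]] +
      upsample2_bwd(dtops[[i]], d_next[1], d_next[2])
  }
  for (i in 1:4) {
    bl <- conv_bwd(p[[paste0("lat", i + 1)]], cache$feats[[paste0("c", i + 1)]],
                   cache$lat[[i]]$cache, dtops[[i]])
    grads[[paste0("lat", i + 1)]] <- list(W = bl$dW, b = bl$db)
    dfeats[[paste0("c", i + 1)]] <- bl$dx
  }
  list(grads = grads, dfeats = dfeats)
}

backbone_tiny_bwd <- function(p, caches, dfeats) {
  grads <- list()
  back_one <- function(name, dy) {
    ca <- caches[[name]]
    dpre <- relu_bwd(ca$pre, dy)
    bw <- conv_bwd(p[[name]], ca$x, ca$conv, dpre)
    grads[[name]] <<- list(W = bw$dW, b = bw$db)
    bw$dx
  }
  d <- back_one("c5b", dfeats$c5)
  d <- back_one("c5a", d)
  d <- back_one("c4b", dfeats$c4 + d)   # stage output feeds both the FPN
  d <- back_one("c4a", d)               # lateral and the next stage
  d <- back_one("c3b", dfeats$c3 + d)
  d <- back_one("c3a", d)
  d <- back_one("c2b", dfeats$c2 + d)
  d <- back_one("c2a", d)
  back_one("stem", d)
  grads
}

# ---- one training step -----------------------------------------------------

# flat-index bookkeeping for per-level prediction arrays
delta_channel_index <- function(cell, slot, j, hw) cell + ((slot - 1) * 5 + j - 1) * hw

train_step <- function(model, image, gts, pyramid, iter_seed,
                       rcnn_batch = 64, fixed_proposals = NULL) {
  cfg <- model$config
  p <- model$params
  feats <- extract_pyramid(model, image, keep_cache = TRUE)
  head_out <- rpn_head_fwd(p$rpn, feats$pyramid, keep_cache = TRUE)

  # ---------- proposal-stage loss ----------
  assignment <- adaptive_assign(pyramid, gts, cfg$n_per_level)
  batch <- sample_training_batch(assignment, 256, seed = iter_seed)
  idx <- c(batch$positive, batch$negative)
  targets <- c(rep(1, length(batch$positive)), rep(0, length(batch$negative)))
  N <- batch$n_total
  lvl_of <- rep(seq_along(pyramid$counts), pyramid$counts)
  within <- idx - pyramid$offsets[lvl_of[idx]]
  logits <- numeric(length(idx))
  for (ii in seq_along(idx))
    logits[ii] <- head_out[[lvl_of[idx[ii]]]]$scores[within[ii]]
  probs <- sigmoid(logits)
  rpn_cls_loss <- -sum(targets * log(pmax(probs, 1e-12)) +
                       (1 - targets) * log(pmax(1 - probs, 1e-12))) / N
  dlogits <- (probs - targets) / N

  all_anchors <- flatten_anchors(pyramid)
  pos <- batch$positive
  rpn_reg_loss <- 0
  dscores <- lapply(head_out, function(h) zero_like(h$scores))
  ddeltas <- lapply(head_out, function(h) zero_like(h$deltas))
  for (ii in seq_along(idx))
    dscores[[lvl_of[idx[ii]]]][within[ii]] <-
      dscores[[lvl_of[idx[ii]]]][within[ii]] + dlogits[ii]
  if (length(pos) > 0) {
    tgt_deltas <- encode_deltas(gts[assignment$labels[pos], ],
                                all_anchors[pos, ])
    for (ii in seq_along(pos)) {
      l <- lvl_of[pos[ii]]
      a_idx <- pos[ii] - pyramid$offsets[l]
      diml <- dim(head_out[[l]]$scores)
      hw <- diml[1] * diml[2]
      slot <- (a_idx - 1) %/% hw + 1
      cell <- (a_idx - 1) %% hw + 1
      for (j in 1:5) {
        ci <- delta_channel_index(cell, slot, j, hw)
        pred <- head_out[[l]]$deltas[ci]
        diff <- tgt_deltas[ii, j] - pred
        rpn_reg_loss <- rpn_reg_loss + smooth_l1(diff) / N
        ddeltas[[l]][ci] <- ddeltas[[l]][ci] - smooth_l1_grad(diff) / N
      }
    }
  }

  # backward through the shared proposal head, accumulating over levels
  grads <- list(backbone = zero_like(p$backbone), fpn = zero_like(p$fpn),
                rpn = zero_like(p$rpn), rcnn = zero_like(p$rcnn))
  dpyramid <- lapply(feats$pyramid, zero_like)
  for (l in seq_along(head_out)) {
    hb <- rpn_head_bwd(p$rpn, head_out[[l]]$cache, dscores[[l]], ddeltas[[l]])
    dpyramid[[l]] <- dpyramid[[l]] + hb$dx
    grads$rpn <- nested_map2(grads$rpn, hb$grads, `+`)
  }

  # ---------- refinement-stage loss ----------
  # proposals are constants for the backward pass; fixed_proposals lets
  # tests freeze them entirely
  prop_boxes <- if (!is.null(fixed_proposals)) as_rbox(fixed_proposals)
  else {
    props <- rpn_propose(lapply(head_out, function(h)
      list(scores = h$scores, deltas = h$deltas)), pyramid, cfg,
      training = TRUE)
    # append ground truths so the refinement head always sees positives
    as_rbox(rbind(unclass(props$boxes), unclass(gts)))
  }
  iou <- matrix(skew_iou(prop_boxes, gts), nrow(prop_boxes), nrow(gts))
  best_gt <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(nrow(iou)), best_gt)]
  is_pos <- best_iou >= 0.5
  n_pos_cap <- max(1L, rcnn_batch %/% 4L)
  sel <- with_seed(iter_seed + 1, {
    pos_idx <- which(is_pos)
    neg_idx <- which(!is_pos)
    if (length(pos_idx) > n_pos_cap) pos_idx <- sort(sample(pos_idx, n_pos_cap))
    n_neg <- min(length(neg_idx), rcnn_batch - length(pos_idx))
    if (length(neg_idx) > n_neg) neg_idx <- sort(sample(neg_idx, n_neg))
    list(pos = pos_idx, neg = neg_idx)
  })
  samp <- c(sel$pos, sel$neg)
  labels2 <- c(rep(2L, length(sel$pos)), rep(1L, length(sel$neg)))
  N2 <- length(samp)
  rcnn_cls_loss <- 0; rcnn_reg_loss <- 0
  if (N2 > 0) {
    lvl2 <- pool_level_for(prop_boxes[samp, "w"], prop_boxes[samp, "h"])
    for (ii in seq_along(samp)) {
      b <- prop_boxes[samp[ii], ]
      lv <- lvl2[ii]
      stride <- cfg$strides[lv - 1]
      prop_f <- project_proposal(b, stride)
      info <- rroi_pool_core(feats$pyramid[[paste0("p", lv)]], prop_f,
                             cfg$k, cfg$l, want_grad = TRUE)
      out <- rcnn_head_fwd(p$rcnn, as.numeric(info$pooled), keep_cache = TRUE)
      onehot <- c(labels2[ii] == 1L, labels2[ii] == 2L)
      rcnn_cls_loss <- rcnn_cls_loss -
        log(pmax(out$probs[labels2[ii]], 1e-12)) / N2
      dcls <- (out$probs - onehot) / N2
      dreg <- numeric(5)
      if (labels2[ii] == 2L) {
        tgt <- encode_deltas(gts[best_gt[samp[ii]], ], b)
        diff <- as.numeric(tgt) - out$deltas
        rcnn_reg_loss <- rcnn_reg_loss + sum(smooth_l1(diff)) / N2
        dreg <- -smooth_l1_grad(diff) / N2
      }
      hb <- rcnn_head_bwd(p$rcnn, out$cache, dcls, dreg)
      grads$rcnn <- nested_map2(grads$rcnn, hb$grads, `+`)
      dpooled <- array(hb$dx, dim = c(cfg$k, cfg$k, cfg$fpn_channels))
      dpyramid[[paste0("p", lv)]] <- dpyramid[[paste0("p", lv)]] +
        rroi_pool_bwd(dpooled, info)
    }
  }

  # ---------- neck and backbone backward ----------
  fb <- fpn_bwd(p$fpn, feats$fpn_cache, dpyramid)
  grads$fpn <- nested_map2(grads$fpn, fb$grads, `+`)
  grads$backbone <- nested_map2(grads$backbone,
                                backbone_tiny_bwd(p$backbone, feats$bb_cache,
                                                  fb$dfeats), `+`)
  losses <- unname(c(rpn_cls_loss, rpn_reg_loss, rcnn_cls_loss,
                     rcnn_reg_loss))
  list(grads = grads,
       losses = c(rpn_cls = losses[1], rpn_reg = losses[2],
                  rcnn_cls = losses[3], rcnn_reg = losses[4],
                  total = sum(losses)))
}

# ---- training loop ---------------------------------------------------------

#' Train the demo detector on a synthetic dataset
#'
#' Stochastic gradient descent with momentum 0.9 over both stage losses,
#' one image per iteration, with step learning-rate decay at 2/3 and 11/12
#' of the run. Designed for the tiny backbone at demo scale; the run is
#' fully determined by `(model seed, dataset, seed)`.
#'
#' @param dataset_dir Directory produced by [generate_dataset()].
#' @param model A `detector_model` with the tiny backbone.
#' @param iterations Number of SGD steps (images visited).
#' @param lr Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param rcnn_batch Refinement-stage samples per image (1:3 pos:neg cap).
#' @param seed Seed controlling image order and per-step sampling.
#' @param clip Global gradient-norm clip.
#' @param verbose Print smoothed losses every 20 iterations.
#' @return List with `model` (trained) and `log` (per-iteration losses).
#' @export
train_demo <- function(dataset_dir, model, iterations = 200, lr = 0.01,
                       momentum = 0.9, rcnn_batch = 64, seed = 0,
                       clip = 10, verbose = FALSE) {
  stopifnot(inherits(model, "detector_model"),
            model$config$backbone == "tiny")
  cfg <- model$config
  records <- read_annotation_dir(dataset_dir)
  if (length(records) == 0L)
    stop("no annotation files found in dataset_dir", call. = FALSE)
  data <- list()
  for (r in records) {
    if (nrow(r$instances) == 0L) next
    img <- png::readPNG(file.path(dataset_dir, paste0(r$image_id, ".png")))
    lb <- letterbox_image(img[, , 1:3, drop = FALSE], cfg$input_size)
    b <- unclass(r$instances)
    gts <- rbox(b[, "x"] * lb$scale, b[, "y"] * lb$scale,
                b[, "w"] * lb$scale, b[, "h"] * lb$scale, b[, "theta"])
    data[[length(data) + 1L]] <- list(image = lb$image, gts = gts)
  }
  if (length(data) == 0L)
    stop("dataset contains no annotated instances", call. = FALSE)
  pyramid <- build_anchor_pyramid(c(cfg$input_size, cfg$input_size),
                                  cfg$strides, cfg$areas, cfg$ratios)
  velocity <- zero_like(model$params)
  decay_at <- ceiling(iterations * c(2 / 3, 11 / 12))
  log <- matrix(0, iterations, 6,
                dimnames = list(NULL, c("iteration", "total", "rpn_cls",
                                        "rpn_reg", "rcnn_cls", "rcnn_reg")))
  order_seq <- with_seed(seed, {
    unlist(lapply(seq_len(ceiling(iterations / length(data))),
                  function(e) sample(length(data))))
  })
  cur_lr <- lr
  for (it in seq_len(iterations)) {
    if (it %in% decay_at) cur_lr <- cur_lr * 0.1
    d <- data[[order_seq[it]]]
    step <- train_step(model, d$image, d$gts, pyramid,
                       iter_seed = (seed * 1009 + it) %% 2147483647,
                       rcnn_batch = rcnn_batch)
    gnorm <- grad_global_norm(step$grads)
    scale <- if (gnorm > clip) clip / gnorm else 1
    velocity <- nested_map2(velocity, step$grads,
                            function(v, g) momentum * v - cur_lr * scale * g)
    model$params <- nested_map2(model$params, velocity, `+`)
    log[it, ] <- c(it, step$losses["total"], step$losses["rpn_cls"],
                   step$losses["rpn_reg"], step$losses["rcnn_cls"],
                   step$losses["rcnn_reg"])
    if (verbose && it %% 20 == 0)
      message(sprintf("iter %4d  loss %.4f  (lr %.4f)", it,
                      mean(log[max(1, it - 19):it, "total"]), cur_lr))
  }
  list(model = model, log = as.data.frame(log))
}

#' Save / load a detector checkpoint
#'
#' @param model A `detector_model`.
#' @param path Checkpoint file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "detector_model"))
  m
}
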