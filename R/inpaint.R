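# Coarse-to-fine generative inpainting. A first encoder-decoder makes a
# rough prediction of the missing region; a refinement stage encodes the
# coarse composite through two parallel branches -- a dilated-convolution
# branch for imagined content and a contextual-attention branch that copies
# features from the known region -- whose features are concatenated and
# decoded to the final raster. Pixels live in [-1, 1] internally; the
# training objective is spatially discounted L1 on both outputs.

#' Inpainting model configuration
#'
#' @param size native square input size the model trains on.
#' @param channels base channel width of the generators.
#' @param ksize odd patch size of the contextual attention layer.
#' @param softmax_scale attention sharpening factor.
#' @param gamma spatial discount base of the reconstruction loss.
#' @param epochs,batch_size,lr training schedule defaults.
#' @param val_fraction used only when the corpus carries no split tags.
#' @export
inpaint_config <- function(size = 96L, channels = 32L, ksize = 3L,
                           softmax_scale = 10, gamma = 0.99,
                           epochs = 10L, batch_size = 10L, lr = 1e-4,
                           val_fraction = 0.1) {
  stopifnot(size %% 4 == 0, ksize %% 2 == 1)
  structure(list(size = as.integer(size), channels = as.integer(channels),
                 ksize = as.integer(ksize), softmax_scale = softmax_scale,
                 gamma = gamma, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 val_fraction = val_fraction),
            class = "inpaint_config")
}

# generator stacks; no normalization layers, leaky-ReLU activations, tanh
# output -- the usual recipe for this family of inpainting generators
.build_coarse <- function(c) {
  nn_seq(
    nn_conv(4, c, 5), nn_act("lrelu"),
    nn_conv(c, 2 * c, 3, stride = 2), nn_act("lrelu"),
    nn_conv(2 * c, 2 * c, 3), nn_act("lrelu"),
    nn_conv(2 * c, 4 * c, 3, stride = 2), nn_act("lrelu"),
    nn_conv(4 * c, 4 * c, 3, dil = 2), nn_act("lrelu"),
    nn_conv(4 * c, 4 * c, 3, dil = 4), nn_act("lrelu"),
    nn_upsample(), nn_conv(4 * c, 2 * c, 3), nn_act("lrelu"),
    nn_upsample(), nn_conv(2 * c, c, 3), nn_act("lrelu"),
    nn_conv(c, 3, 3), nn_act("tanh"))
}

.build_refine <- function(c, ksize, softmax_scale) {
  dilated <- nn_seq(
    nn_conv(4, c, 5), nn_act("lrelu"),
    nn_conv(c, 2 * c, 3, stride = 2), nn_act("lrelu"),
    nn_conv(2 * c, 2 * c, 3), nn_act("lrelu"),
    nn_conv(2 * c, 4 * c, 3, stride = 2), nn_act("lrelu"),
    nn_conv(4 * c, 4 * c, 3, dil = 2), nn_act("lrelu"),
    nn_conv(4 * c, 4 * c, 3, dil = 4), nn_act("lrelu"),
    nn_conv(4 * c, 4 * c, 3, dil = 8), nn_act("lrelu"))
  attn <- nn_seq(
    nn_conv(4, c, 5), nn_act("lrelu"),
    nn_conv(c, 2 * c, 3, stride = 2), nn_act("lrelu"),
    nn_conv(2 * c, 2 * c, 3), nn_act("lrelu"),
    nn_conv(2 * c, 4 * c, 3, stride = 2), nn_act("relu"),
    nn_cal_layer(ksize, softmax_scale),
    nn_conv(4 * c, 4 * c, 3), nn_act("lrelu"))
  nn_seq(
    nn_parallel_concat(list(dilated, attn)),
    nn_conv(8 * c, 4 * c, 3), nn_act("lrelu"),
    nn_upsample(), nn_conv(4 * c, 2 * c, 3), nn_act("lrelu"),
    nn_upsample(), nn_conv(2 * c, c, 3), nn_act("lrelu"),
    nn_conv(c, 3, 3), nn_act("tanh"))
}

#' Build an untrained inpainting model
#' @param config an [inpaint_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `inpaint_model`.
#' @export
build_inpaint_model <- function(config = inpaint_config(), seed = 1L) {
  local_seed(seed, {
    structure(list(coarse = .build_coarse(config$channels),
                   refine = .build_refine(config$channels, config$ksize,
                                          config$softmax_scale),
                   config = config, history = NULL, version = 1L),
              class = "inpaint_model")
  })
}

# broadcast (H,W,N) mask to (H,W,3,N)
.mask_rgb <- function(mask) {
  d <- dim(mask)
  n <- if (length(d) == 3) d[3] else 1
  m <- array(mask, c(d[1], d[2], n))
  aperm(array(m[, , rep(seq_len(n), times = 3)],
              c(d[1], d[2], n, 3)), c(1, 2, 4, 3))
}

#' Coarse network forward pass
#'
#' The network sees the image with masked pixels zeroed, concatenated with
#' the mask channel, and emits a full raster; the composite replaces only
#' the masked pixels and is bit-exact elsewhere.
#'
#' @param model an `inpaint_model`.
#' @param image H x W x 3 x N array in \[-1, 1\].
#' @param mask H x W (x N) binary array, 1 = missing.
#' @param training forward in training mode.
#' @return list with `pred`, `composite` and (for training) `cache`.
#' @export
coarse_forward <- function(model, image, mask, training = FALSE) {
  d <- dim(image)
  if (length(dim(mask)) == 2) mask <- array(mask, c(dim(mask), d[4]))
  stopifnot(all(dim(mask) == d[c(1, 2, 4)]))
  m3 <- .mask_rgb(mask)
  x <- array(0, dim = c(d[1], d[2], 4, d[4]))
  x[, , 1:3, ] <- image * (1 - m3)
  x[, , 4, ] <- mask
  r <- nn_forward(model$coarse, x, training = training)
  composite <- image
  composite[m3 == 1] <- r$y[m3 == 1]
  list(pred = r$y, composite = composite, cache = r$cache, input = x,
       m3 = m3)
}

# walk the module/cache trees and collect contextual-attention offsets
.collect_cal_offsets <- function(mod, cache) {
  if (mod$kind == "cal") {
    offs <- lapply(cache, function(cn)
      if (isTRUE(cn$skip)) NULL else cn$core$offsets)
    return(offs)
  }
  if (mod$kind == "seq") {
    for (i in seq_along(mod$layers)) {
      r <- .collect_cal_offsets(mod$layers[[i]], cache[[i]])
      if (!is.null(r)) return(r)
    }
  }
  if (mod$kind == "parallel_concat") {
    for (i in seq_along(mod$branches)) {
      r <- .collect_cal_offsets(mod$branches[[i]], cache$caches[[i]])
      if (!is.null(r)) return(r)
    }
  }
  if (mod$kind == "resblock") {
    r <- .collect_cal_offsets(mod$main, cache$main)
    if (!is.null(r)) return(r)
  }
  NULL
}

#' Refinement network forward pass
#'
#' Encodes the coarse composite (plus mask channel) through the dilated and
#' attention branches, concatenates their features and decodes the final
#' raster. The composite is `mask * prediction + (1 - mask) * original`,
#' bit-exact outside the mask.
#'
#' @param model an `inpaint_model`.
#' @param image original H x W x 3 x N array in \[-1, 1\].
#' @param coarse_result value of [coarse_forward()].
#' @param mask binary array as in [coarse_forward()].
#' @param training forward in training mode.
#' @return list with `pred`, `composite`, `attention_offsets` (one
#'   (dy, dx) raster per sample at feature resolution, NULL where attention
#'   was inactive) and `cache`.
#' @export
refine_forward <- function(model, image, coarse_result, mask,
                           training = FALSE) {
  d <- dim(image)
  if (length(dim(mask)) == 2) mask <- array(mask, c(dim(mask), d[4]))
  m3 <- coarse_result$m3
  x <- array(0, dim = c(d[1], d[2], 4, d[4]))
  x[, , 1:3, ] <- coarse_result$composite
  x[, , 4, ] <- mask
  ctx <- list(mask = mask)
  r <- nn_forward(model$refine, x, training = training, ctx = ctx)
  composite <- image
  composite[m3 == 1] <- r$y[m3 == 1]
  list(pred = r$y, composite = composite,
       attention_offsets = .collect_cal_offsets(model$refine, r$cache),
       cache = r$cache, input = x, m3 = m3)
}

#' Sample a rectangular training mask
#'
#' One axis-aligned rectangle with area fraction uniform in `area_range`,
#' aspect ratio uniform in \[0.5, 2\], position uniform; deterministic per
#' seed.
#'
#' @param shape integer (H, W).
#' @param seed integer seed.
#' @param area_range fraction bounds of the rectangle area.
#' @export
random_training_mask <- function(shape, seed, area_range = c(0.10, 0.35)) {
  h <- shape[1]; w <- shape[2]
  local_seed(seed, {
    frac <- stats::runif(1, area_range[1], area_range[2])
    aspect <- stats::runif(1, 0.5, 2)
    hm <- max(1L, min(h, round(sqrt(frac * h * w * aspect))))
    wm <- max(1L, min(w, round(frac * h * w / hm)))
    r0 <- sample.int(h - hm + 1L, 1) - 1L
    c0 <- sample.int(w - wm + 1L, 1) - 1L
    m <- matrix(0, h, w)
    m[r0 + seq_len(hm), c0 + seq_len(wm)] <- 1
    m
  })
}

#' Chebyshev distance to the nearest known pixel
#'
#' Two-pass chamfer transform with the 8-neighborhood; known pixels
#' (mask == 0) have distance 0.
#'
#' @param mask binary matrix, 1 = missing.
#' @export
chebyshev_distance <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  d <- matrix(Inf, h, w)
  d[mask == 0] <- 0
  if (all(mask == 0) || all(mask == 1)) {
    if (all(mask == 1)) d[] <- Inf
    return(d)
  }
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i > 1) v <- min(v, d[i - 1, j] + 1)
    if (j > 1) v <- min(v, d[i, j - 1] + 1)
    if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + 1)
    if (i < h && j > 1) v <- min(v, d[i + 1, j - 1] + 1)
    d[i, j] <- v
  }
  for (j in rev(seq_len(w))) for (i in rev(seq_len(h))) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i < h) v <- min(v, d[i + 1, j] + 1)
    if (j < w) v <- min(v, d[i, j + 1] + 1)
    if (i < h && j < w) v <- min(v, d[i + 1, j + 1] + 1)
    if (i > 1 && j < w) v <- min(v, d[i - 1, j + 1] + 1)
    d[i, j] <- v
  }
  d
}

#' Spatially discounted L1 reconstruction loss
#'
#' Mean of `gamma^l * |pred - target|` over all pixels and channels, where
#' `l` is the Chebyshev distance to the nearest known pixel (0 outside the
#' mask, so known pixels carry weight 1). `gamma = 1` reduces to plain L1.
#'
#' @param pred,target H x W x 3 x N arrays.
#' @param mask H x W (x N) binary array.
#' @param gamma discount base in (0, 1\].
#' @return list with `loss` (scalar) and `grad` (d loss / d pred).
#' @export
discounted_l1 <- function(pred, target, mask, gamma = 0.99) {
  d <- dim(pred)
  if (length(dim(mask)) == 2) mask <- array(mask, c(dim(mask), d[4]))
  wts <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    l <- chebyshev_distance(mask[, , n])
    wn <- gamma^l
    wn[is.infinite(l)] <- 0
    wts[, , , n] <- array(rep(wn, 3), c(d[1], d[2], 3))
  }
  diff <- pred - target
  list(loss = mean(wts * abs(diff)),
       grad = wts * sign(diff) / length(diff))
}

# one optimization step over a batch; returns updated model/opt plus loss
.inpaint_step <- function(model, opt, x, masks, gamma, lr) {
  cf <- coarse_forward(model, x, masks, training = TRUE)
  rf <- refine_forward(model, x, cf, masks, training = TRUE)
  l1 <- discounted_l1(cf$pred, x, masks, gamma)
  l2 <- discounted_l1(rf$pred, x, masks, gamma)
  br <- nn_backward(model$refine, rf$cache, l2$grad)
  # refine input = coarse composite (+ mask channel); composite passes the
  # coarse prediction through on masked pixels only
  dcomp <- br$dx[, , 1:3, , drop = FALSE]
  dpred1 <- l1$grad
  dpred1[cf$m3 == 1] <- dpred1[cf$m3 == 1] + dcomp[cf$m3 == 1]
  bc <- nn_backward(model$coarse, cf$cache, dpred1)
  s1 <- nn_adam_step(model$coarse, bc$grads, opt$coarse, lr)
  s2 <- nn_adam_step(model$refine, br$grads, opt$refine, lr)
  model$coarse <- s1$mod
  model$refine <- s2$mod
  list(model = model, opt = list(coarse = s1$opt, refine = s2$opt),
       loss = l1$loss + l2$loss)
}

# evaluate the discounted loss on a stack with fixed masks (no update)
.inpaint_eval <- function(model, x, masks, gamma) {
  cf <- coarse_forward(model, x, masks, training = FALSE)
  rf <- refine_forward(model, x, cf, masks, training = FALSE)
  l1 <- discounted_l1(cf$pred, x, masks, gamma)
  l2 <- discounted_l1(rf$pred, x, masks, gamma)
  l1$loss + l2$loss
}

#' Train the inpainter on a patch corpus
#'
#' Minimizes spatially discounted L1 on the coarse and final outputs under
#' random rectangular corruption masks. Uses the corpus split tags if
#' present (otherwise holds out `val_fraction` internally), logs the
#' validation loss per epoch and keeps the best-validation weights.
#'
#' @param corpus a `patch_corpus` of square body patches.
#' @param config an [inpaint_config()]; patches are resized to
#'   `config$size` if they differ.
#' @param seed integer seed (weights, masks, batch order).
#' @return a trained `inpaint_model` with a `history` data.frame
#'   (`epoch,train_loss,val_loss`) and `initial_val_loss`.
#' @export
train_inpainter <- function(corpus, config = inpaint_config(), seed = 1L) {
  n <- length(corpus$patches)
  if (n == 0) stop("empty patch corpus")
  s <- config$size
  to_tensor <- function(ix) {
    x <- array(0, dim = c(s, s, 3, length(ix)))
    for (i in seq_along(ix)) {
      p <- corpus$patches[[ix[i]]]
      if (dim(p)[1] != s || dim(p)[2] != s) p <- resize_bilinear(p, s, s)
      x[, , , i] <- p * 2 - 1
    }
    x
  }
  split <- corpus$index$split
  if (is.null(split) || all(is.na(split))) {
    nval <- max(1L, round(n * config$val_fraction))
    vi <- local_seed(seed + 17L, sample.int(n, nval))
    ti <- setdiff(seq_len(n), vi)
  } else {
    ti <- which(split == "train")
    vi <- which(split == "val")
  }
  model <- build_inpaint_model(config, seed = seed)
  opt <- list(coarse = adam_init(), refine = adam_init())
  xval <- to_tensor(vi)
  vmasks <- array(0, dim = c(s, s, length(vi)))
  for (i in seq_along(vi))
    vmasks[, , i] <- random_training_mask(c(s, s), seed = seed + 9000L + i)
  initial_val <- .inpaint_eval(model, xval, vmasks, config$gamma)
  best_val <- Inf
  best <- model[c("coarse", "refine")]
  hist <- NULL
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- local_seed(seed + 100L * ep, sample(ti))
    tl <- 0; nb <- 0L
    for (b in seq(1, length(ord), by = config$batch_size)) {
      ix <- ord[b:min(b + config$batch_size - 1L, length(ord))]
      step <- step + 1L
      x <- to_tensor(ix)
      masks <- array(0, dim = c(s, s, length(ix)))
      for (i in seq_along(ix))
        masks[, , i] <- random_training_mask(c(s, s),
                                             seed = seed + 37L * step + i)
      r <- .inpaint_step(model, opt, x, masks, config$gamma, config$lr)
      model <- r$model
      opt <- r$opt
      tl <- tl + r$loss; nb <- nb + 1L
    }
    vl <- .inpaint_eval(model, xval, vmasks, config$gamma)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl))
    if (vl < best_val) {
      best_val <- vl
      best <- model[c("coarse", "refine")]
    }
  }
  model$coarse <- best$coarse
  model$refine <- best$refine
  model$history <- hist
  model$initial_val_loss <- initial_val
  model$best_val_loss <- best_val
  model
}

# raised-cosine (Hann) blend window for overlapping tiles
.hann2 <- function(s) {
  v <- 0.5 - 0.5 * cos(2 * pi * (seq_len(s) - 0.5) / s)
  outer(v, v) + 1e-6
}

#' Inpaint the coating region of a tongue image
#'
#' Runs the full coarse-to-fine model with the coating mask as the
#' inpainting mask. Rasters larger than the model's native size are
#' processed in 50 percent overlapping tiles blended with a raised-cosine
#' window; tiles without coating pixels are untouched. Non-coating pixels
#' are returned bit-identical.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param tongue_mask,coating_mask H x W 0/1 matrices,
#'   `coating_mask` a subset of `tongue_mask`.
#' @param model a trained `inpaint_model`.
#' @return inpainted H x W x 3 array in \[0,1\].
#' @export
inpaint_coating <- function(image, tongue_mask, coating_mask, model) {
  if (any(coating_mask == 1 & tongue_mask == 0))
    stop("coating_mask must be a subset of tongue_mask")
  if (sum(coating_mask) == 0) return(image)
  if (all((tongue_mask == 1) == (coating_mask == 1)))
    stop("no known background: coating covers the whole tongue")
  h <- dim(image)[1]; w <- dim(image)[2]
  s <- model$config$size
  xin <- image * 2 - 1
  run_tile <- function(img_t, mask_t) {
    x <- array(img_t, c(s, s, 3, 1))
    m <- array(mask_t, c(s, s, 1))
    cf <- coarse_forward(model, x, m)
    rf <- refine_forward(model, x, cf, m)
    array(rf$pred, c(s, s, 3))
  }
  if (h == s && w == s) {
    pred <- run_tile(xin, coating_mask)
  } else {
    if (h < s || w < s) stop("image smaller than the model's native size")
    stride <- max(1L, s %/% 2L)
    pos <- function(n) unique(c(seq(0L, n - s, by = stride), n - s))
    acc <- array(0, dim = c(h, w, 3))
    wacc <- matrix(0, h, w)
    blend <- .hann2(s)
    for (r0 in pos(h)) for (c0 in pos(w)) {
      ri <- r0 + seq_len(s); ci <- c0 + seq_len(s)
      mt <- coating_mask[ri, ci]
      pt <- if (sum(mt) == 0) xin[ri, ci, , drop = FALSE]
            else run_tile(xin[ri, ci, , drop = FALSE], mt)
      for (ch in 1:3)
        acc[ri, ci, ch] <- acc[ri, ci, ch] + pt[, , ch] * blend
      wacc[ri, ci] <- wacc[ri, ci] + blend
    }
    pred <- acc / array(rep(wacc, 3), c(h, w, 3))
  }
  pred01 <- (pred + 1) / 2
  pred01[pred01 < 0] <- 0
  pred01[pred01 > 1] <- 1
  out <- image
  m3 <- array(rep(coating_mask, 3), c(h, w, 3))
  out[m3 == 1] <- pred01[m3 == 1]
  out
}

#' Save / load an inpainting model checkpoint
#' @param model an `inpaint_model`.
#' @param path checkpoint file.
#' @export
save_inpaint_model <- function(model, path) {
  saveRDS(list(format = "tonguetex-inpaint", version = model$version,
               model = model), path)
  invisible(path)
}

#' @rdname save_inpaint_model
#' @export
load_inpaint_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "tonguetex-inpaint"))
    stop("not an inpainting checkpoint")
  x$model
}
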