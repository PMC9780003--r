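# Contextual attention: reconstruct missing (foreground) feature patches as
# softmax-weighted combinations of known (background) patches, matched by
# correlation with L2-normalized background patches. Used both as a
# standalone operator and as a layer inside the refinement network.

#' Downsample a binary mask by block maximum
#'
#' Conservative reduction to a coarser grid: a low-resolution cell is marked
#' missing if any pixel inside it is missing. Used to carry an image-space
#' inpainting mask down to feature-map resolution.
#'
#' @param mask numeric/logical matrix (1 = missing, 0 = known).
#' @param target_hw integer vector (height, width) of the reduced grid; must
#'   divide the mask dimensions exactly.
#' @return binary matrix of size `target_hw`.
#' @export
downsample_mask_max <- function(mask, target_hw) {
  H <- nrow(mask); W <- ncol(mask)
  hf <- target_hw[1]; wf <- target_hw[2]
  if (H %% hf != 0 || W %% wf != 0)
    stop("mask dimensions must be integer multiples of the target grid")
  fh <- H %/% hf; fw <- W %/% wf
  a <- array(as.numeric(mask), dim = c(fh, hf, fw, wf))
  apply(a, c(2, 4), max)
}

#' Extract background patches from a feature map
#'
#' Slides a `ksize` x `ksize` window over the feature map at the given
#' stride (windows fully inside the raster) and flags each patch as valid
#' iff it contains no masked pixel. The mask is reduced to feature
#' resolution by block-maximum if needed.
#'
#' @param features H x W x C array.
#' @param mask binary matrix (1 = missing); same size as the feature map or
#'   an integer multiple of it.
#' @param ksize odd patch size.
#' @param stride placement stride, >= 1.
#' @return list with `patches` (ksize x ksize x C x M array), `valid`
#'   (logical M), `positions` (M x 2 matrix of 0-based top-left row/col).
#' @export
extract_background_patches <- function(features, mask, ksize = 3L,
                                       stride = 1L) {
  if (ksize %% 2 == 0) stop("ksize must be odd")
  d <- dim(features)
  if (length(d) == 2) { features <- array(features, c(d, 1L)); d <- dim(features) }
  if (!all(dim(mask) == d[1:2]))
    mask <- downsample_mask_max(mask, d[1:2])
  Ho <- (d[1] - ksize) %/% stride + 1L
  Wo <- (d[2] - ksize) %/% stride + 1L
  if (Ho < 1 || Wo < 1) stop("feature map smaller than ksize")
  cols <- cpp_im2col(features, d, ksize, ksize, stride, 0L, 1L)
  mcols <- cpp_im2col(array(as.numeric(mask), c(d[1:2], 1L)),
                      c(d[1:2], 1L), ksize, ksize, stride, 0L, 1L)
  valid <- apply(mcols, 2, max) == 0
  if (!any(valid)) stop("no known background")
  M <- Ho * Wo
  l <- seq_len(M) - 1L
  positions <- cbind(row = (l %% Ho) * stride, col = (l %/% Ho) * stride)
  list(patches = array(cols, dim = c(ksize, ksize, d[3], M)),
       valid = valid, positions = positions,
       cols = cols, out_hw = c(Ho, Wo))
}

# Shared core: returns reconstruction over every location of `fg`, the full
# attention matrix, argmax offsets, and everything backward needs.
.cal_core <- function(fg, bg, mask, ksize, stride, softmax_scale) {
  d <- dim(fg)
  bp <- extract_background_patches(bg, mask, ksize, stride)
  P_all <- bp$cols                              # (k*k*C) x Mall
  valid <- bp$valid
  P <- P_all[, valid, drop = FALSE]
  nrm <- sqrt(colSums(P * P))
  Pn <- sweep(P, 2, pmax(nrm, 1e-4), `/`)
  pad <- (ksize - 1L) %/% 2L
  cols_fg <- cpp_im2col(fg, d, ksize, ksize, 1L, pad, 1L)  # rows x L
  S <- crossprod(Pn, cols_fg)                   # Mvalid x L
  E <- exp(softmax_scale * sweep(S, 2, apply(S, 2, max)))
  A <- sweep(E, 2, colSums(E), `/`)             # columns sum to 1
  recon_pre <- cpp_col2im(P %*% A, d, ksize, ksize, 1L, pad, 1L)
  ones <- matrix(1, ksize * ksize, ncol(A))
  count <- cpp_col2im(ones, c(d[1:2], 1L), ksize, ksize, 1L, pad, 1L)
  count <- array(rep(count, d[3]), dim = d)
  recon <- recon_pre / count
  # winning background patch centers -> (dy, dx) offsets per location
  win <- max.col(t(A), ties.method = "first")   # index into valid patches
  pos <- bp$positions[valid, , drop = FALSE]
  ctr <- pos + (ksize - 1L) / 2
  l <- seq_len(d[1] * d[2]) - 1L
  locr <- l %% d[1]; locc <- l %/% d[1]
  offsets <- array(0, dim = c(d[1], d[2], 2))
  offsets[, , 1] <- matrix(ctr[win, 1] - locr, d[1], d[2])
  offsets[, , 2] <- matrix(ctr[win, 2] - locc, d[1], d[2])
  list(recon = recon, A = A, valid = valid, offsets = offsets,
       count = count, d = d, ksize = ksize, stride = stride, pad = pad,
       n_all = ncol(P_all))
}

#' Contextual attention over a feature map
#'
#' Matches each location of the foreground feature map against every valid
#' background patch by correlation with the L2-normalized patch (cosine
#' similarity up to the location's own norm), softmax-normalizes the scaled
#' scores, and rebuilds features as the attention-weighted overlap-add of
#' the raw background patches with overlap counts divided out.
#'
#' @param fg_features,bg_features H x W x C arrays, spatially aligned.
#' @param mask binary missing-pixel matrix (foreground = 1).
#' @param ksize odd patch size (default 3).
#' @param softmax_scale sharpening factor applied before the softmax.
#' @param stride background patch stride.
#' @return list with `reconstructed_features` (H x W x C),
#'   `attention_scores` (M x (H*W); rows for patches overlapping the mask
#'   are exactly zero, columns sum to 1) and `argmax_offsets`
#'   (H x W x 2 array of (dy, dx) to the winning patch center).
#' @export
contextual_attention <- function(fg_features, bg_features, mask,
                                 ksize = 3L, softmax_scale = 10,
                                 stride = 1L) {
  if (length(dim(fg_features)) == 2)
    fg_features <- array(fg_features, c(dim(fg_features), 1L))
  if (length(dim(bg_features)) == 2)
    bg_features <- array(bg_features, c(dim(bg_features), 1L))
  stopifnot(all(dim(fg_features)[1:2] == dim(bg_features)[1:2]))
  r <- .cal_core(fg_features, bg_features, mask, ksize, stride, softmax_scale)
  scores <- matrix(0, r$n_all, ncol(r$A))
  scores[r$valid, ] <- r$A
  list(reconstructed_features = r$recon,
       attention_scores = scores,
       argmax_offsets = r$offsets)
}

# --- network-layer wrapper --------------------------------------------------
# ctx$mask holds the image-resolution inpainting masks, one slice per batch
# sample (H x W x N). Foreground locations get the attention reconstruction,
# background locations pass through. If a sample has no valid background
# patch (mask too large at feature resolution) the layer degrades to
# identity for that sample.
cal_layer_forward <- function(mod, x, ctx) {
  d <- dim(x)
  y <- x
  caches <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    m_img <- if (is.null(ctx$mask)) NULL else ctx$mask[, , n]
    if (is.null(m_img) || sum(m_img) == 0) {
      caches[[n]] <- list(skip = TRUE)
      next
    }
    mf <- downsample_mask_max(m_img, d[1:2])
    if (sum(mf) == 0) { caches[[n]] <- list(skip = TRUE); next }
    f <- array(x[, , , n], d[1:3])
    core <- tryCatch(.cal_core(f, f, mf, mod$ksize, 1L, mod$softmax_scale),
                     error = function(e) NULL)
    if (is.null(core)) { caches[[n]] <- list(skip = TRUE); next }
    m3 <- array(rep(mf, d[3]), dim = d[1:3])
    y[, , , n] <- m3 * core$recon + (1 - m3) * f
    caches[[n]] <- list(skip = FALSE, core = core, m3 = m3)
  }
  list(y = y, cache = caches)
}

# Gradient flows through the value path (overlap-add of background patches)
# and the pass-through; the attention weights are treated as constants.
cal_layer_backward <- function(mod, cache, dy) {
  d <- dim(dy)
  dx <- dy
  for (n in seq_len(d[4])) {
    cn <- cache[[n]]
    if (isTRUE(cn$skip)) next
    core <- cn$core
    m3 <- cn$m3
    dyn <- array(dy[, , , n], d[1:3])
    drecon <- m3 * dyn
    # recon = col2im(P %*% A) / count ; adjoint of col2im is im2col
    dZcols <- cpp_im2col(drecon / core$count, core$d,
                         core$ksize, core$ksize, 1L, core$pad, 1L)
    dP <- dZcols %*% t(core$A)                  # rows x Mvalid
    dAll <- matrix(0, nrow(dP), core$n_all)
    dAll[, core$valid] <- dP
    dbg <- cpp_col2im(dAll, core$d, core$ksize, core$ksize,
                      core$stride, 0L, 1L)
    dx[, , , n] <- (1 - m3) * dyn + dbg
  }
  list(dx = dx, grads = NULL)
}

#' Color-code attention offsets
#'
#' Renders per-location argmax offsets as an RGB raster: zero offset is
#' white (attention on itself); the offset angle selects the hue on a fixed
#' wheel (up-right maps to the green sector, down-left to the pink/magenta
#' sector) and the magnitude drives saturation, clipped at a quarter of the
#' raster diagonal.
#'
#' @param argmax_offsets H x W x 2 array of (dy, dx) offsets.
#' @return H x W x 3 numeric array with values in 0..255.
#' @export
attention_colormap <- function(argmax_offsets) {
  d <- dim(argmax_offsets)
  dyo <- argmax_offsets[, , 1]
  dxo <- argmax_offsets[, , 2]
  mag <- sqrt(dyo^2 + dxo^2)
  # screen coords: +dy is down; convert to math angle with up positive
  theta <- atan2(-dyo, dxo)                     # radians, up-right ~ pi/4
  hue <- ((theta - pi / 4) / (2 * pi) + 1/3) %% 1
  sat <- pmin(1, mag / (sqrt(d[1]^2 + d[2]^2) / 4))
  sat[mag == 0] <- 0
  cols <- grDevices::hsv(h = as.vector(hue), s = as.vector(sat), v = 1)
  rgb <- grDevices::col2rgb(cols)
  out <- array(0, dim = c(d[1], d[2], 3))
  out[, , 1] <- matrix(rgb[1, ], d[1], d[2])
  out[, , 2] <- matrix(rgb[2, ], d[1], d[2])
  out[, , 3] <- matrix(rgb[3, ], d[1], d[2])
  out
}
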