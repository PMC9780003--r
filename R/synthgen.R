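# Synthetic tongue imagery with ground truth. Emulates segmented clinical
# tongue photographs: an elliptical tongue whose body pixels follow one
# color Gaussian and whose coating blobs follow a second, lighter Gaussian,
# with class-conditional band-pass texture on the body (coarse high-contrast
# for tough, fine low-contrast for tender, intermediate for normal).

#' Canonical class order for tongue texture labels
#' @export
TONGUE_CLASSES <- c("tough", "normal", "tender")

# run code under a seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

.check_spd <- function(S, what) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop(what, " must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop(what, " must be positive definite")
  invisible(TRUE)
}

#' Parameters of the synthetic tongue generator
#'
#' Defaults describe a 128 x 128 raster with a centred elliptical tongue, a
#' reddish body color model, a lighter (whitish) coating color model
#' covering about 20 percent of the tongue, and three texture classes whose
#' band-pass luminance texture increases in contrast from tender through
#' normal to tough.
#'
#' @param image_size integer (H, W).
#' @param ellipse_axes semi-axes in pixels (rows, cols).
#' @param body_color_mean,coating_color_mean RGB means in \[0,1\]; the
#'   coating mean must be strictly lighter per channel.
#' @param body_color_cov,coating_color_cov 3 x 3 SPD covariance matrices.
#' @param coating_area_fraction target fraction of the tongue covered by
#'   coating; must be below 0.5.
#' @param texture named list per class with `frequency` (cycles/pixel) and
#'   `amplitude` (luminance contrast).
#' @param seed integer; all randomness derives from it.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(image_size = c(128L, 128L),
                         ellipse_axes = c(48, 40),
                         body_color_mean = c(0.62, 0.35, 0.38),
                         body_color_cov = diag(c(1.5, 1.0, 1.0)) * 1e-3,
                         coating_color_mean = c(0.84, 0.78, 0.72),
                         coating_color_cov = diag(3) * 1e-3,
                         coating_area_fraction = 0.2,
                         texture = list(
                           tough  = list(frequency = 0.08, amplitude = 0.18),
                           normal = list(frequency = 0.12, amplitude = 0.10),
                           tender = list(frequency = 0.18, amplitude = 0.04)),
                         seed = 1L) {
  if (coating_area_fraction < 0 || coating_area_fraction >= 0.5)
    stop("coating_area_fraction must lie in [0, 0.5); parameter rejected")
  if (!all(coating_color_mean > body_color_mean))
    stop("coating_color_mean must be strictly lighter than body_color_mean ",
         "in every channel")
  .check_spd(body_color_cov, "body_color_cov")
  .check_spd(coating_color_cov, "coating_color_cov")
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            length(ellipse_axes) == 2, all(ellipse_axes > 0),
            all(TONGUE_CLASSES %in% names(texture)))
  structure(list(image_size = as.integer(image_size),
                 ellipse_axes = ellipse_axes,
                 body_color_mean = body_color_mean,
                 body_color_cov = body_color_cov,
                 coating_color_mean = coating_color_mean,
                 coating_color_cov = coating_color_cov,
                 coating_area_fraction = coating_area_fraction,
                 texture = texture,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# separable Gaussian blur with row-renormalized border handling
gauss_blur <- function(m, sigma_r, sigma_c = sigma_r) {
  band <- function(n, s) {
    if (s <= 0) return(diag(n))
    A <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * s^2))
    A[A < 1e-12] <- 0
    A / rowSums(A)
  }
  band(nrow(m), sigma_r) %*% m %*% t(band(ncol(m), sigma_c))
}

# sum of two oriented band-pass (difference-of-Gaussians) noise fields,
# normalized to unit standard deviation
bandpass_texture <- function(h, w, frequency) {
  s1 <- 1 / (4 * frequency)
  bp <- function(sr, sc) {
    z <- matrix(stats::rnorm(h * w), h, w)
    gauss_blur(z, sr, sc) - gauss_blur(z, 2 * sr, 2 * sc)
  }
  t <- bp(s1, 2 * s1) + bp(2 * s1, s1)
  t / stats::sd(t)
}

# draw n RGB colors from a trivariate Gaussian
.rmvn3 <- function(n, mu, Sigma) {
  z <- matrix(stats::rnorm(n * 3), n, 3)
  sweep(z %*% chol(Sigma), 2, mu, `+`)
}

#' Generate one synthetic tongue sample
#'
#' @param params a [synth_params()] object.
#' @param label one of `"tough"`, `"normal"`, `"tender"`.
#' @param seed optional override of `params$seed`.
#' @return list with `image` (H x W x 3 in \[0,1\]), `tongue_mask` and
#'   `coating_mask` (H x W 0/1 matrices, coating a subset of tongue) and
#'   `label`.
#' @export
generate_sample <- function(params, label, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  label <- match.arg(label, TONGUE_CLASSES)
  h <- params$image_size[1]; w <- params$image_size[2]
  local_seed(seed, {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ry <- params$ellipse_axes[1]; rx <- params$ellipse_axes[2]
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    tongue <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
    tongue <- tongue * 1

    coating <- matrix(0, h, w)
    if (params$coating_area_fraction > 0) {
      field <- gauss_blur(matrix(stats::rnorm(h * w), h, w), 8)
      vals <- field[tongue == 1]
      thr <- stats::quantile(vals, 1 - params$coating_area_fraction)
      coating <- (tongue == 1 & field > thr) * 1
    }

    img <- array(0, dim = c(h, w, 3))
    body_idx <- which(tongue == 1 & coating == 0)
    coat_idx <- which(coating == 1)
    tex <- bandpass_texture(h, w, params$texture[[label]]$frequency) *
      params$texture[[label]]$amplitude
    if (length(body_idx)) {
      cols <- .rmvn3(length(body_idx), params$body_color_mean,
                     params$body_color_cov)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[body_idx] <- cols[, ch] + tex[body_idx]
        img[, , ch] <- plane
      }
    }
    if (length(coat_idx)) {
      cols <- .rmvn3(length(coat_idx), params$coating_color_mean,
                     params$coating_color_cov)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[coat_idx] <- cols[, ch]
        img[, , ch] <- plane
      }
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, tongue_mask = tongue, coating_mask = coating,
         label = label)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes one PNG image plus tongue and coating mask PNGs per sample and a
#' CSV manifest with columns `image,tongue_mask,coating_mask,label` (paths
#' relative to `out_dir`).
#'
#' @param params a [synth_params()] object.
#' @param counts_per_class named integer vector/list; names among the class
#'   labels, values >= 0.
#' @param out_dir output directory, created if needed.
#' @return the manifest as a data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(params, counts_per_class, out_dir) {
  stopifnot(inherits(params, "synth_params"))
  counts <- vapply(TONGUE_CLASSES, function(cl) {
    v <- counts_per_class[[cl]]
    if (is.null(v)) 0L else as.integer(v)
  }, integer(1))
  if (any(counts < 0)) stop("counts must be >= 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  idx <- 0L
  for (cl in TONGUE_CLASSES) {
    for (i in seq_len(counts[[cl]])) {
      idx <- idx + 1L
      s <- generate_sample(params, cl,
                           seed = (params$seed + 7919 * idx) %%
                             .Machine$integer.max)
      stem <- sprintf("%s_%04d", cl, i)
      fi <- paste0(stem, "_img.png")
      ft <- paste0(stem, "_tongue.png")
      fc <- paste0(stem, "_coating.png")
      write_image_png(s$image, file.path(out_dir, fi))
      write_mask_png(s$tongue_mask, file.path(out_dir, ft))
      write_mask_png(s$coating_mask, file.path(out_dir, fc))
      rows[[idx]] <- data.frame(image = fi, tongue_mask = ft,
                                coating_mask = fc, label = cl,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image = character(), tongue_mask = character(),
               coating_mask = character(), label = character(),
               stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate class-conditional texture patches in memory
#'
#' Produces square body-texture patches (no coating, tongue filling the
#' whole raster) for classifier experiments: each class draws its band-pass
#' texture at the class frequency/amplitude over the body color model.
#'
#' @param params a [synth_params()] object (color and texture models reused).
#' @param n_per_class patches per class.
#' @param patch_size side length in pixels.
#' @param seed integer seed.
#' @return list with `x` (patch_size x patch_size x 3 x N array) and `y`
#'   (factor of class labels, levels in canonical order).
#' @export
generate_texture_patches <- function(params, n_per_class, patch_size = 32L,
                                     seed = params$seed) {
  p2 <- params
  p2$image_size <- c(patch_size, patch_size)
  p2$ellipse_axes <- c(patch_size * 2, patch_size * 2)  # tongue fills raster
  p2$coating_area_fraction <- 0
  n_total <- 3L * n_per_class
  x <- array(0, dim = c(patch_size, patch_size, 3, n_total))
  y <- character(n_total)
  k <- 0L
  for (cl in TONGUE_CLASSES) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      s <- generate_sample(p2, cl,
                           seed = (seed + 104729 * k) %% .Machine$integer.max)
      x[, , , k] <- s$image
      y[k] <- cl
    }
  }
  list(x = x, y = factor(y, levels = TONGUE_CLASSES))
}

#' Texture energy of an image region
#'
#' Variance of the high-pass filtered luminance (luminance minus a Gaussian
#' blur) over the given mask; the statistic that orders the synthetic
#' classes tender < normal < tough.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param mask binary matrix selecting the region (default: whole raster).
#' @param sigma blur scale of the low-pass reference.
#' @return nonnegative scalar.
#' @export
texture_energy <- function(image, mask = NULL, sigma = 1.5) {
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  hp <- lum - gauss_blur(lum, sigma)
  if (is.null(mask)) stats::var(as.vector(hp)) else stats::var(hp[mask == 1])
}
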