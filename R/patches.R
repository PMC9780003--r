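# Sliding-window harvesting of tongue-body patches with a coverage filter,
# mirror augmentation, class balancing and train/validation splitting.

#' Patch harvesting configuration
#'
#' @param window square window side in pixels (default 96).
#' @param stride window placement stride; defaults to `window`
#'   (non-overlapping tiling).
#' @param min_body_fraction a window is kept iff its body-pixel fraction is
#'   strictly greater than this (default 0.8).
#' @param mirror whether downstream augmentation mirrors patches.
#' @export
patch_config <- function(window = 96L, stride = window,
                         min_body_fraction = 0.8, mirror = TRUE) {
  stopifnot(window >= 1, stride >= 1,
            min_body_fraction >= 0, min_body_fraction < 1)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 min_body_fraction = min_body_fraction, mirror = mirror),
            class = "patch_config")
}

.empty_corpus <- function(window) {
  structure(list(patches = list(),
                 index = data.frame(source = character(), row = integer(),
                                    col = integer(), fraction = numeric(),
                                    op = character(), split = character(),
                                    stringsAsFactors = FALSE),
                 window = window),
            class = "patch_corpus")
}

#' Harvest body patches from one image
#'
#' Traverses the raster with `window` x `window` windows at top-left
#' coordinates `(r*stride, c*stride)` (0-based), keeping only windows that
#' lie fully inside the image and whose body-mask coverage strictly exceeds
#' `min_body_fraction`.
#'
#' @param body_image H x W x 3 array.
#' @param tongue_body_mask H x W 0/1 matrix, same size as the image.
#' @param cfg a [patch_config()].
#' @param source_id identifier recorded per patch.
#' @return object of class `patch_corpus` with `patches` (list of crops)
#'   and `index` (source, 0-based row/col, body fraction, provenance op,
#'   split tag).
#' @export
harvest_patches <- function(body_image, tongue_body_mask, cfg = patch_config(),
                            source_id = "img") {
  h <- dim(body_image)[1]; w <- dim(body_image)[2]
  stopifnot(all(dim(tongue_body_mask) == c(h, w)))
  win <- cfg$window
  if (h < win || w < win) {
    warning("image smaller than the window; empty corpus")
    return(.empty_corpus(win))
  }
  rows0 <- seq(0L, h - win, by = cfg$stride)
  cols0 <- seq(0L, w - win, by = cfg$stride)
  patches <- list()
  idx <- list()
  n <- 0L
  for (c0 in cols0) for (r0 in rows0) {
    frac <- sum(tongue_body_mask[r0 + seq_len(win), c0 + seq_len(win)]) / win^2
    if (frac > cfg$min_body_fraction) {
      n <- n + 1L
      patches[[n]] <- body_image[r0 + seq_len(win), c0 + seq_len(win), ,
                                 drop = FALSE]
      idx[[n]] <- data.frame(source = source_id, row = r0, col = c0,
                             fraction = frac, op = "orig", split = NA_character_,
                             stringsAsFactors = FALSE)
    }
  }
  out <- .empty_corpus(win)
  if (n > 0) {
    out$patches <- patches
    out$index <- do.call(rbind, idx)
  }
  out
}

#' Merge patch corpora
#' @param ... `patch_corpus` objects with matching window size.
#' @export
merge_corpora <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && is.list(cs[[1]]) && !inherits(cs[[1]], "patch_corpus"))
    cs <- cs[[1]]
  cs <- Filter(function(c) nrow(c$index) > 0, cs)
  if (!length(cs)) return(.empty_corpus(96L))
  out <- .empty_corpus(cs[[1]]$window)
  out$patches <- do.call(c, lapply(cs, `[[`, "patches"))
  out$index <- do.call(rbind, lapply(cs, `[[`, "index"))
  rownames(out$index) <- NULL
  out
}

#' Double a corpus by horizontal mirroring
#'
#' Appends the left-right mirror of every patch; provenance is recorded in
#' the index (`op = "mirror"`). Mirroring twice returns the original crop.
#'
#' @param corpus a `patch_corpus`.
#' @export
mirror_augment <- function(corpus) {
  n <- length(corpus$patches)
  if (n == 0) return(corpus)
  mir <- lapply(corpus$patches, function(p) p[, rev(seq_len(dim(p)[2])), ,
                                              drop = FALSE])
  mi <- corpus$index
  mi$op <- "mirror"
  corpus$patches <- c(corpus$patches, mir)
  corpus$index <- rbind(corpus$index, mi)
  rownames(corpus$index) <- NULL
  corpus
}

#' Balance class counts in a manifest
#'
#' Brings every class to exactly `target_per_class` rows. Deficit classes
#' are filled first by horizontal mirrors of a without-replacement sample of
#' the originals (each original mirrored at most once), then by rescaled
#' copies of originals sampled with replacement, with scale factors uniform
#' in \[0.9, 1.1\]. Surplus classes are downsampled uniformly. The
#' augmentation is recorded in columns `op` (`orig`/`mirror`/`rescale`) and
#' `scale`; pixels are only ever derived from an original by mirror or
#' rescale, and labels are conserved.
#'
#' @param manifest data.frame with a `label` column (plus any path columns).
#' @param target_per_class target rows per class.
#' @param seed integer seed; output is deterministic per seed.
#' @export
balance_classes <- function(manifest, target_per_class, seed = 1L) {
  if (target_per_class == 0)
    return(cbind(manifest[0, , drop = FALSE],
                 data.frame(op = character(), scale = numeric())))
  if (!"label" %in% names(manifest)) stop("manifest needs a label column")
  cnt <- table(factor(manifest$label, levels = TONGUE_CLASSES))
  if (any(cnt < 1)) stop("every class needs at least one entry")
  if (!"op" %in% names(manifest)) manifest$op <- "orig"
  if (!"scale" %in% names(manifest)) manifest$scale <- NA_real_
  out <- list()
  for (ci in seq_along(TONGUE_CLASSES)) {
    cl <- TONGUE_CLASSES[ci]
    rows <- manifest[manifest$label == cl, , drop = FALSE]
    n <- nrow(rows)
    res <- local_seed(seed + 131 * ci, {
      if (n >= target_per_class) {
        rows[sort(sample.int(n, target_per_class)), , drop = FALSE]
      } else {
        deficit <- target_per_class - n
        m <- min(deficit, n)
        mirrored <- rows[sample.int(n, m), , drop = FALSE]
        mirrored$op <- "mirror"
        extra <- deficit - m
        resc <- rows[0, , drop = FALSE]
        if (extra > 0) {
          resc <- rows[sample.int(n, extra, replace = TRUE), , drop = FALSE]
          resc$op <- "rescale"
          resc$scale <- stats::runif(extra, 0.9, 1.1)
        }
        rbind(rows, mirrored, resc)
      }
    })
    out[[ci]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply a balancing provenance op to an image
#'
#' `orig` returns the image unchanged, `mirror` flips it horizontally, and
#' `rescale` resizes by the scale factor and back (a mild resampling
#' perturbation that keeps the raster size).
#'
#' @param image H x W x 3 array.
#' @param op one of `"orig"`, `"mirror"`, `"rescale"`.
#' @param scale numeric factor for `rescale`.
#' @export
apply_balance_op <- function(image, op, scale = NA) {
  switch(op,
         orig = image,
         mirror = image[, rev(seq_len(dim(image)[2])), , drop = FALSE],
         rescale = {
           d <- dim(image)
           tmp <- resize_bilinear(image, max(2L, round(d[1] * scale)),
                                  max(2L, round(d[2] * scale)))
           resize_bilinear(tmp, d[1], d[2])
         },
         stop("unknown op: ", op))
}

#' Split a corpus or manifest into train and validation parts
#'
#' Disjoint, exhaustive, uniformly sampled per seed. For class-labeled
#' manifests the counts apply per class (stratified split); otherwise they
#' apply to the whole collection. `counts` must sum to the (per-class)
#' total.
#'
#' @param x a `patch_corpus` or a data.frame manifest.
#' @param counts integer (train, val).
#' @param seed integer seed.
#' @param tags names for the two parts.
#' @return the input with its `split` column/tag filled in.
#' @export
split_corpus <- function(x, counts, seed = 1L, tags = c("train", "val")) {
  assign_tags <- function(n, counts, seed) {
    if (sum(counts) != n)
      stop("split counts (", paste(counts, collapse = "+"),
           ") must sum to the total (", n, ")")
    tag <- rep(tags[2], n)
    tr <- local_seed(seed, sample.int(n, counts[1]))
    tag[tr] <- tags[1]
    tag
  }
  if (inherits(x, "patch_corpus")) {
    x$index$split <- assign_tags(nrow(x$index), counts, seed)
    return(x)
  }
  m <- x
  if ("label" %in% names(m)) {
    m$split <- NA_character_
    for (ci in seq_along(TONGUE_CLASSES)) {
      cl <- TONGUE_CLASSES[ci]
      sel <- which(m$label == cl)
      if (!length(sel)) next
      m$split[sel] <- assign_tags(length(sel), counts, seed + 977 * ci)
    }
  } else {
    m$split <- assign_tags(nrow(m), counts, seed)
  }
  m
}

#' Persist a patch corpus as PNGs plus a CSV index
#' @param corpus a `patch_corpus`.
#' @param dir output directory.
#' @export
save_patch_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- corpus$index
  idx$file <- sprintf("patch_%05d.png", seq_len(nrow(idx)))
  for (i in seq_len(nrow(idx)))
    write_image_png(corpus$patches[[i]], file.path(dir, idx$file[i]))
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a patch corpus saved by [save_patch_corpus()]
#' @param dir directory with `index.csv` and patch PNGs.
#' @export
load_patch_corpus <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  patches <- lapply(idx$file, function(f) read_image_png(file.path(dir, f)))
  out <- .empty_corpus(if (length(patches)) dim(patches[[1]])[1] else 96L)
  out$patches <- patches
  idx$file <- NULL
  out$index <- idx
  out
}
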