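# Shared fixtures and independent oracles used across the test files.

# Brute-force contextual attention: per-location cosine scores against
# explicitly enumerated valid background patches, softmax, and overlap-add
# of the raw patches with counts divided out.
cal_brute_force <- function(f, mask, k = 3L, scale = 10) {
  H <- dim(f)[1]; W <- dim(f)[2]; C <- dim(f)[3]
  hk <- (k - 1) %/% 2
  pats <- list()
  for (c0 in 0:(W - k)) for (r0 in 0:(H - k)) {
    if (any(mask[r0 + 1:k, c0 + 1:k] == 1)) next
    pats[[length(pats) + 1]] <- f[r0 + 1:k, c0 + 1:k, , drop = FALSE]
  }
  M <- length(pats)
  recon <- array(0, dim(f)); cnt <- array(0, dim(f))
  scores <- matrix(0, M, H * W)
  for (w0 in 1:W) for (h0 in 1:H) {
    fp <- array(0, c(k, k, C))
    for (j in 1:k) for (i in 1:k) {
      hi <- h0 + i - 1 - hk; wi <- w0 + j - 1 - hk
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) fp[i, j, ] <- f[hi, wi, ]
    }
    s <- sapply(pats, function(p) sum(fp * p) / max(sqrt(sum(p^2)), 1e-4))
    a <- exp(scale * (s - max(s))); a <- a / sum(a)
    scores[, h0 + H * (w0 - 1)] <- a
    wp <- Reduce(`+`, Map(function(p, ai) p * ai, pats, as.list(a)))
    for (j in 1:k) for (i in 1:k) {
      hi <- h0 + i - 1 - hk; wi <- w0 + j - 1 - hk
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        recon[hi, wi, ] <- recon[hi, wi, ] + wp[i, j, ]
        cnt[hi, wi, ] <- cnt[hi, wi, ] + 1
      }
    }
  }
  list(recon = recon / cnt, scores = scores)
}

# Brute-force sliding-window harvest: double loop over all placements.
harvest_brute_force <- function(mask, window, stride, min_frac) {
  h <- nrow(mask); w <- ncol(mask)
  kept <- NULL
  for (c0 in seq(0, w - window, by = stride))
    for (r0 in seq(0, h - window, by = stride)) {
      frac <- sum(mask[r0 + seq_len(window), c0 + seq_len(window)]) / window^2
      if (frac > min_frac) kept <- rbind(kept, c(r0, c0))
    }
  kept
}

# Independent plateau/early-stop oracle: given a validation-loss trace,
# returns the per-epoch learning rates actually used and the epoch at which
# training terminates (the first epoch NOT run), via direct scanning.
scheduler_oracle <- function(trace, lr0 = 0.001, factor = 0.1,
                             plateau = 5L, stop_after = 15L) {
  lr <- lr0
  lrs <- numeric(0)
  best <- Inf
  bad_p <- 0L; bad_s <- 0L
  stop_epoch <- NA_integer_
  for (e in seq_along(trace)) {
    lrs <- c(lrs, lr)
    if (trace[e] < best) {
      best <- trace[e]; bad_p <- 0L; bad_s <- 0L
    } else {
      bad_p <- bad_p + 1L; bad_s <- bad_s + 1L
      if (bad_p >= plateau) { lr <- lr * factor; bad_p <- 0L }
      if (bad_s >= stop_after) { stop_epoch <- e + 1L; break }
    }
  }
  list(lrs = lrs, stop_epoch = stop_epoch)
}

# Wrap an (s, s, 3, N) patch array as a patch_corpus.
array_corpus <- function(x) {
  s <- dim(x)[1]
  n <- dim(x)[4]
  structure(list(
    patches = lapply(seq_len(n), function(i) array(x[, , , i], c(s, s, 3))),
    index = data.frame(source = "synth", row = 0L, col = 0L, fraction = 1,
                       op = "orig", split = NA_character_,
                       stringsAsFactors = FALSE)[rep(1, n), ],
    window = as.integer(s)), class = "patch_corpus")
}

# Default synthetic color/texture model shared by several files.
default_params <- function(seed = 8L, ...) synth_params(seed = seed, ...)
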