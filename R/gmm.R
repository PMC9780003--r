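# Gaussian mixture model over pixel colors, fitted by EM, and the derived
# tongue coating / tongue body separation. The mixture density is
#   p(x) = sum_k w_k N(x | mu_k, Sigma_k),  sum_k w_k = 1, 0 <= w_k <= 1.

.log_gauss_rows <- function(X, mean, covariance, component = NULL) {
  d <- ncol(X)
  L <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(L))
    stop("singular covariance",
         if (!is.null(component)) paste0(" in component ", component) else "")
  logdet <- 2 * sum(log(diag(L)))
  Xc <- sweep(X, 2, mean)
  Z <- Xc %*% backsolve(L, diag(d))
  -0.5 * (d * log(2 * pi) + logdet + rowSums(Z * Z))
}

#' Multivariate Gaussian density
#'
#' `(2*pi)^(-d/2) |Sigma|^(-1/2) exp(-(x-mu)' Sigma^{-1} (x-mu) / 2)`.
#'
#' @param x numeric d-vector (or N x d matrix for several points).
#' @param mean d-vector.
#' @param covariance d x d SPD matrix.
#' @param component optional label used in the singular-covariance error.
#' @return density value(s), nonnegative.
#' @export
gaussian_pdf <- function(x, mean, covariance, component = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(mean)) stop("dimension mismatch")
  v <- exp(.log_gauss_rows(X, mean, covariance, component))
  if (is.matrix(x)) v else v[1]
}

#' Mixture density of a fitted GMM
#' @param x d-vector or N x d matrix.
#' @param model a `gmm_model`.
#' @export
mixture_density <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$dimension) stop("dimension mismatch")
  ld <- .log_dens_matrix(X, model)
  v <- exp(.logsumexp_rows(ld))
  if (is.matrix(x)) v else v[1]
}

.log_dens_matrix <- function(X, model) {
  K <- length(model$components)
  ld <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    cmp <- model$components[[k]]
    ld[, k] <- log(cmp$weight) +
      .log_gauss_rows(X, cmp$mean, cmp$covariance, component = k)
  }
  ld
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# farthest-point seeding: one random point, then iteratively the point
# farthest from the chosen set
.fps_init <- function(X, K) {
  N <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(N, 1)
  dmin <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  if (K > 1) {
    for (k in 2:K) {
      if (max(dmin) <= 0)
        stop("component collapsed: fewer than K distinct points")
      centers[k] <- which.max(dmin)
      dmin <- pmin(dmin, rowSums(sweep(X, 2, X[centers[k], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Farthest-point seeding from the given seed, log-space responsibilities,
#' and a ridge of `reg` on each covariance per M-step. Terminates when the
#' relative log-likelihood gain drops below `tol` or after `max_iter`
#' iterations. A component collapsing onto fewer than 2 effective points
#' triggers one re-seeded restart, then an error.
#'
#' @param samples N x d numeric matrix.
#' @param K number of components.
#' @param seed integer seed for the initialization.
#' @param tol relative log-likelihood tolerance.
#' @param max_iter iteration cap.
#' @param reg covariance ridge added each M-step.
#' @return object of class `gmm_model` with `components` (each `weight`,
#'   `mean`, `covariance`), `dimension` and `log_likelihood_trace`.
#' @export
fit_gmm_em <- function(samples, K, seed = 1L, tol = 1e-6, max_iter = 200L,
                       reg = 1e-6) {
  X <- as.matrix(samples)
  N <- nrow(X); d <- ncol(X)
  if (N < K * (d + 1))
    stop("insufficient data: need at least K*(d+1) = ", K * (d + 1),
         " samples, got ", N)
  fit_once <- function(seed) {
    mu0 <- local_seed(seed, .fps_init(X, K))
    # hard-assign to nearest seed for the initial parameters
    d2 <- sapply(seq_len(K), function(k) rowSums(sweep(X, 2, mu0[k, ])^2))
    assign0 <- max.col(-d2, ties.method = "first")
    comps <- lapply(seq_len(K), function(k) {
      idx <- which(assign0 == k)
      if (length(idx) < 2) idx <- seq_len(N)
      Xi <- X[idx, , drop = FALSE]
      list(weight = max(length(which(assign0 == k)), 1) / N,
           mean = colMeans(Xi),
           covariance = stats::cov(Xi) + reg * diag(d))
    })
    wsum <- sum(vapply(comps, `[[`, numeric(1), "weight"))
    for (k in seq_len(K)) comps[[k]]$weight <- comps[[k]]$weight / wsum
    model <- structure(list(components = comps, dimension = d,
                            log_likelihood_trace = numeric(0)),
                       class = "gmm_model")
    ll_prev <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      ld <- .log_dens_matrix(X, model)
      lse <- .logsumexp_rows(ld)
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(ld - lse)
      Nk <- colSums(resp)
      if (any(Nk < 2)) stop("component collapsed: effective count below 2")
      for (k in seq_len(K)) {
        rk <- resp[, k]
        mk <- colSums(X * rk) / Nk[k]
        Xc <- sweep(X, 2, mk)
        Sk <- crossprod(Xc * sqrt(rk)) / Nk[k] + reg * diag(d)
        model$components[[k]] <- list(weight = Nk[k] / N, mean = mk,
                                      covariance = Sk)
      }
      if (is.finite(ll_prev) &&
          (ll - ll_prev) / max(abs(ll_prev), 1e-12) < tol) break
      ll_prev <- ll
    }
    model$log_likelihood_trace <- trace
    model
  }
  tryCatch(fit_once(seed), error = function(e) {
    if (grepl("collapsed", conditionMessage(e))) {
      tryCatch(fit_once(seed + 1L), error = function(e2)
        stop("EM failed after re-seeding: ", conditionMessage(e2)))
    } else stop(e)
  })
}

#' Posterior component probabilities under a GMM
#'
#' Entry k is proportional to `w_k N(x | mu_k, Sigma_k)`; computed in log
#' space so heavy underflow never produces NaN.
#'
#' @param x d-vector or N x d matrix.
#' @param model a `gmm_model`.
#' @return K-vector (or N x K matrix) of probabilities summing to 1.
#' @export
gmm_posterior <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$dimension) stop("dimension mismatch")
  ld <- .log_dens_matrix(X, model)
  p <- exp(ld - .logsumexp_rows(ld))
  if (is.matrix(x)) p else p[1, ]
}

# 3x3 majority filter restricted to the tongue region (optional cleanup)
.majority3 <- function(mask, tongue) {
  k <- matrix(1, 3, 3)
  cnt <- cpp_conv2d_fwd(array(mask, c(dim(mask), 1, 1)),
                        c(dim(mask), 1L, 1L),
                        array(k, c(3, 3, 1, 1)), c(3L, 3L, 1L, 1L),
                        0, 1L, 1L, 1L)[, , 1, 1]
  tot <- cpp_conv2d_fwd(array(tongue, c(dim(mask), 1, 1)),
                        c(dim(mask), 1L, 1L),
                        array(k, c(3, 3, 1, 1)), c(3L, 3L, 1L, 1L),
                        0, 1L, 1L, 1L)[, , 1, 1]
  out <- (cnt > tot / 2) * 1
  out * (tongue == 1)
}

#' Separate tongue coating from tongue body by GMM clustering
#'
#' Fits a K-component GMM to the colors of tongue pixels only, hard-assigns
#' every tongue pixel to its maximum-posterior component, and labels the
#' component with larger mean luminance (mean of the RGB channels over its
#' assigned pixels) as coating -- coating is clinically whitish. On a
#' luminance tie (< 1e-6) the component with the smaller weight becomes
#' coating. Body and coating masks partition the tongue mask.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param tongue_mask H x W 0/1 matrix; needs at least `K*(d+1)` pixels.
#' @param K number of color components (default 2: body vs coating).
#' @param seed integer seed for EM initialization.
#' @param colorspace `"rgb"` (default) or `"hsv"` feature space for the fit.
#' @param cleanup apply an optional 3 x 3 majority filter to the hard masks.
#' @param min_contrast minimum chroma separation between the coating and
#'   body clusters, in units of the pooled within-cluster standard
#'   deviation along the gap direction (chroma = color with the luminance
#'   component removed). Below it the tongue is declared coating-free (the
#'   K-way fit would otherwise split unimodal body texture, which moves
#'   luminance but not chroma); 0 disables the guard.
#' @param model optional pre-fitted `gmm_model` (skips the EM fit).
#' @param ... further arguments passed to [fit_gmm_em()].
#' @return object of class `separation_result`: `posterior_map`
#'   (H x W x K, rows summing to 1 on tongue pixels, zero outside),
#'   `body_mask`, `coating_mask`, `body_component_index`, `model`.
#' @export
separate_coating <- function(image, tongue_mask, K = 2L, seed = 1L,
                             colorspace = c("rgb", "hsv"), cleanup = FALSE,
                             min_contrast = 3, model = NULL, ...) {
  colorspace <- match.arg(colorspace)
  h <- dim(image)[1]; w <- dim(image)[2]
  stopifnot(all(dim(tongue_mask) == c(h, w)))
  idx <- which(tongue_mask == 1)
  if (length(idx) == 0) stop("tongue mask is empty")
  rgbX <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  X <- if (colorspace == "hsv")
    t(grDevices::rgb2hsv(t(rgbX), maxColorValue = 1)) else rgbX
  if (is.null(model)) {
    if (length(idx) < K * (ncol(X) + 1))
      stop("tongue mask has too few pixels for K = ", K)
    model <- fit_gmm_em(X, K = K, seed = seed, ...)
  }
  K <- length(model$components)
  post <- gmm_posterior(X, model)
  hard <- max.col(post, ties.method = "first")
  # label components by mean RGB luminance of their assigned pixels;
  # fall back to the component color means if a component got no pixels
  lum_px <- rowMeans(rgbX)
  lum_k <- vapply(seq_len(K), function(k) {
    sel <- hard == k
    if (any(sel)) mean(lum_px[sel]) else mean(model$components[[k]]$mean)
  }, numeric(1))
  wts <- vapply(model$components, `[[`, numeric(1), "weight")
  if (diff(range(lum_k)) < 1e-6) {
    coating_k <- which.min(wts)      # tie: smaller weight is coating
  } else {
    coating_k <- which.max(lum_k)
  }
  body_k <- which.max(ifelse(seq_len(K) == coating_k, -Inf, wts))
  # chroma guard: real coating is whitish (desaturated) against the red
  # body, so the clusters must separate in chroma -- the color component
  # orthogonal to luminance -- and not merely in brightness, which texture
  # and shading also move. The gap between the cluster chroma means, in
  # pooled within-cluster sd units along the gap direction, must reach
  # min_contrast; otherwise the tongue is declared coating-free.
  keep <- TRUE
  if (min_contrast > 0) {
    chroma <- rgbX - lum_px
    sel_c <- hard == coating_k
    sel_b <- hard == body_k
    if (sum(sel_c) < 2 || sum(sel_b) < 2) {
      keep <- FALSE
    } else {
      dvec <- colMeans(chroma[sel_c, , drop = FALSE]) -
        colMeans(chroma[sel_b, , drop = FALSE])
      gap <- sqrt(sum(dvec^2))
      if (gap < 1e-12) {
        keep <- FALSE
      } else {
        pr <- chroma %*% (dvec / gap)
        psd <- sqrt(mean(sel_c) * stats::var(pr[sel_c]) +
                      mean(sel_b) * stats::var(pr[sel_b]))
        keep <- psd == 0 || gap >= min_contrast * psd
      }
    }
  }
  coating_mask <- matrix(0, h, w)
  if (keep) coating_mask[idx[hard == coating_k]] <- 1
  if (cleanup) coating_mask <- .majority3(coating_mask, tongue_mask)
  body_mask <- (tongue_mask == 1 & coating_mask == 0) * 1
  pm <- array(0, dim = c(h, w, K))
  for (k in seq_len(K)) {
    plane <- matrix(0, h, w)
    plane[idx] <- post[, k]
    pm[, , k] <- plane
  }
  structure(list(posterior_map = pm, body_mask = body_mask,
                 coating_mask = coating_mask,
                 body_component_index = body_k, model = model),
            class = "separation_result")
}
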