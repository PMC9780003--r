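test_that("gaussian density matches closed forms and an independent oracle", {
  expect_equal(gaussian_pdf(0, 0, matrix(1)), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_pdf(c(0, 0), c(0, 0), diag(2)), 1 / (2 * pi),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    mu <- rnorm(3)
    A <- matrix(rnorm(9), 3)
    S <- crossprod(A) + diag(3) * 0.5
    x <- rnorm(3)
    # independent linear-algebra route: explicit inverse and determinant
    ref <- (2 * pi)^(-3 / 2) * det(S)^(-1 / 2) *
      exp(-0.5 * t(x - mu) %*% solve(S) %*% (x - mu))
    expect_equal(gaussian_pdf(x, mu, S), as.numeric(ref), tolerance = 1e-10)
    expect_equal(gaussian_pdf(x, mu, S),
                 mclust::dmvnorm(matrix(x, 1), mu, S), tolerance = 1e-10)
  }
  expect_error(gaussian_pdf(c(0, 0), c(0, 0), matrix(0, 2, 2),
                            component = 2), "component 2")
  expect_error(gaussian_pdf(c(0, 0, 0), c(0, 0), diag(2)), "dimension")
})

test_that("mixture density degenerates, marginalizes and normalizes", {
  cmp <- function(w, m, S) list(weight = w, mean = m, covariance = S)
  m1 <- structure(list(components = list(cmp(1, c(0.2, 0.5), diag(2) * 0.3)),
                       dimension = 2L), class = "gmm_model")
  x <- c(0.1, 0.4)
  expect_equal(mixture_density(x, m1),
               gaussian_pdf(x, c(0.2, 0.5), diag(2) * 0.3))
  # two identical components marginalize their weights
  m2 <- structure(list(components = list(cmp(0.3, c(0.2, 0.5), diag(2) * 0.3),
                                         cmp(0.7, c(0.2, 0.5), diag(2) * 0.3)),
                       dimension = 2L), class = "gmm_model")
  expect_equal(mixture_density(x, m2), mixture_density(x, m1),
               tolerance = 1e-12)
  # Monte-Carlo integral of a random 3-component model over a bounding box
  set.seed(9)
  comps <- lapply(1:3, function(k) {
    A <- matrix(rnorm(4, sd = 0.3), 2)
    cmp(c(0.2, 0.3, 0.5)[k], runif(2, -1, 1), crossprod(A) + diag(2) * 0.05)
  })
  m3 <- structure(list(components = comps, dimension = 2L),
                  class = "gmm_model")
  lo <- -6; hi <- 6
  pts <- matrix(runif(2e6, lo, hi), ncol = 2)
  est <- mean(mixture_density(pts, m3)) * (hi - lo)^2
  expect_lt(abs(est - 1), 0.01)
  expect_error(mixture_density(c(1, 2, 3), m3), "dimension")
})

test_that("EM recovers a single component in closed form", {
  set.seed(11)
  X <- matrix(rnorm(600, sd = 0.2), ncol = 3) + rep(c(1, 2, 3), each = 200)
  fit <- fit_gmm_em(X, K = 1, seed = 1)
  expect_equal(fit$components[[1]]$weight, 1)
  expect_equal(fit$components[[1]]$mean, colMeans(X), tolerance = 1e-9,
               ignore_attr = TRUE)
  n <- nrow(X)
  expect_equal(fit$components[[1]]$covariance,
               stats::cov(X) * (n - 1) / n + 1e-6 * diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("EM recovers well-separated clusters and keeps weights on the simplex", {
  sd0 <- 0.05
  mu1 <- rep(0.25, 3); mu2 <- mu1 + 10 * sd0 / sqrt(3)
  set.seed(21)
  X <- rbind(matrix(rnorm(3000, sd = sd0), ncol = 3) + rep(mu1, each = 1000),
             matrix(rnorm(3000, sd = sd0), ncol = 3) + rep(mu2, each = 1000))
  fit <- fit_gmm_em(X, K = 2, seed = 2)
  w <- vapply(fit$components, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0 & w <= 1))
  tr <- fit$log_likelihood_trace
  expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  mus <- t(sapply(fit$components, `[[`, "mean"))
  perm <- if (sum((mus[1, ] - mu1)^2) < sum((mus[2, ] - mu1)^2)) 1:2 else 2:1
  expect_lt(sqrt(sum((mus[perm[1], ] - mu1)^2)), 0.05)
  expect_lt(sqrt(sum((mus[perm[2], ] - mu2)^2)), 0.05)
  expect_true(all(abs(w - 0.5) < 0.03))
})

test_that("EM errors on insufficient or degenerate data", {
  expect_error(fit_gmm_em(matrix(rnorm(9), 3), K = 2), "insufficient")
  X <- matrix(0.4, nrow = 500, ncol = 3)  # 500 copies of one point
  expect_error(fit_gmm_em(X, K = 2, seed = 1), "collaps")
})

test_that("posteriors are normalized, symmetric and underflow-safe", {
  cmp <- function(w, m, S) list(weight = w, mean = m, covariance = S)
  m <- structure(list(components = list(cmp(0.5, c(-1, 0), diag(2)),
                                        cmp(0.5, c(1, 0), diag(2))),
                      dimension = 2L), class = "gmm_model")
  expect_equal(gmm_posterior(c(0, 0), m), c(0.5, 0.5), tolerance = 1e-9)
  # 10-sigma separation: posterior at a component mean is sharp
  m2 <- structure(list(components = list(cmp(0.5, c(0, 0), diag(2) * 0.01),
                                         cmp(0.5, c(1, 1), diag(2) * 0.01)),
                      dimension = 2L), class = "gmm_model")
  expect_gt(gmm_posterior(c(0, 0), m2)[1], 0.999)
  # far point: log-space evaluation never yields NaN
  p_far <- gmm_posterior(c(1e4, 1e4), m2)
  expect_false(any(is.nan(p_far)))
  expect_equal(sum(p_far), 1, tolerance = 1e-9)
  # argmax of posterior equals argmax of log weight + log density
  set.seed(3)
  for (i in 1:20) {
    x <- runif(2, -2, 2)
    lp <- sapply(m2$components, function(cc)
      log(cc$weight) + log(gaussian_pdf(x, cc$mean, cc$covariance)))
    expect_equal(which.max(gmm_posterior(x, m2)), which.max(lp))
  }
})

test_that("converged responsibilities match an independently coded E-step", {
  set.seed(31)
  X <- rbind(matrix(rnorm(300, sd = 0.05), ncol = 3) + rep(0.3, each = 100),
             matrix(rnorm(300, sd = 0.05), ncol = 3) + rep(0.7, each = 100))
  fit <- fit_gmm_em(X, K = 2, seed = 5)
  resp <- gmm_posterior(X, fit)
  # direct formula evaluation with explicit inverse/determinant
  dens <- sapply(fit$components, function(cc) {
    Si <- solve(cc$covariance)
    dt <- det(cc$covariance)
    apply(X, 1, function(x) {
      cc$weight * (2 * pi)^(-3 / 2) * dt^(-1 / 2) *
        exp(-0.5 * t(x - cc$mean) %*% Si %*% (x - cc$mean))
    })
  })
  ref <- dens / rowSums(dens)
  expect_lt(max(abs(resp - ref)), 1e-8)
})

test_that("separation recovers ground-truth coating masks", {
  p <- default_params(seed = 5)
  s <- generate_sample(p, "normal", seed = 9)
  sep <- separate_coating(s$image, s$tongue_mask, K = 2, seed = 1)
  expect_gte(mask_iou(sep$coating_mask, s$coating_mask), 0.90)
  # masks partition the tongue
  expect_true(all(sep$body_mask + sep$coating_mask == s$tongue_mask))
  expect_equal(sum(sep$body_mask * sep$coating_mask), 0)
  # posteriors: rows sum to 1 on tongue pixels, zero outside
  ps <- apply(sep$posterior_map, c(1, 2), sum)
  expect_true(all(abs(ps[s$tongue_mask == 1] - 1) < 1e-6))
  expect_true(all(ps[s$tongue_mask == 0] == 0))
})

test_that("separation of a coating-free tongue yields a near-empty mask", {
  p <- synth_params(coating_area_fraction = 0, seed = 3)
  for (cl in TONGUE_CLASSES) {
    s <- generate_sample(p, cl, seed = 11)
    sep <- separate_coating(s$image, s$tongue_mask, K = 2, seed = 2)
    expect_lte(sum(sep$coating_mask) / sum(s$tongue_mask), 0.02)
  }
})

test_that("component order permutation leaves the masks unchanged", {
  p <- default_params(seed = 5)
  s <- generate_sample(p, "normal", seed = 9)
  sep <- separate_coating(s$image, s$tongue_mask, K = 2, seed = 1)
  perm <- sep$model
  perm$components <- rev(perm$components)
  sep2 <- separate_coating(s$image, s$tongue_mask, model = perm)
  expect_identical(sep$coating_mask, sep2$coating_mask)
  expect_identical(sep$body_mask, sep2$body_mask)
})

test_that("separation rejects empty masks and tiny pixel counts", {
  img <- array(runif(48), c(4, 4, 3))
  expect_error(separate_coating(img, matrix(0, 4, 4)), "empty")
  m <- matrix(0, 4, 4); m[1:2, 1] <- 1
  expect_error(separate_coating(img, m), "too few")
})
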