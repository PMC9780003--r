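#' @useDynLib tonguetex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode neural-network engine.
#
# Tensors are dense R arrays in (H, W, C, N) order; convolution filters are
# (kh, kw, Cin, Cout). Every module is a tagged list with a `kind`; forward
# returns the output plus a cache, backward consumes the cache and returns
# the input gradient plus a gradient tree mirroring the parameter tree.
# Composite kinds (seq, resblock, parallel_concat) recurse. The contextual
# attention layer is wired in as a module kind of its own (see attention.R).
# ---------------------------------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, stride = 1L, dil = 1L,
                    pad = NULL, init_gain = sqrt(2)) {
  if (is.null(pad)) pad <- ((k - 1L) * dil) %/% 2L   # "same" for stride 1
  list(kind = "conv",
       par = list(w = array(stats::rnorm(k * k * cin * cout,
                                         sd = init_gain / sqrt(k * k * cin)),
                            dim = c(k, k, cin, cout)),
                  b = numeric(cout)),
       stride = as.integer(stride), pad = as.integer(pad),
       dil = as.integer(dil))
}

nn_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(kind = "bn",
       par = list(gamma = rep(1, c), beta = rep(0, c)),
       state = list(rm = rep(0, c), rv = rep(1, c)),
       momentum = momentum, eps = eps)
}

nn_act <- function(fun = c("relu", "lrelu", "tanh")) {
  list(kind = "act", fun = match.arg(fun))
}

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(kind = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))

nn_upsample <- function(factor = 2L)
  list(kind = "upsample", factor = as.integer(factor))

nn_gap <- function() list(kind = "gap")

nn_dense <- function(fin, fout)
  list(kind = "dense",
       par = list(w = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)),
                             fin, fout),
                  b = numeric(fout)))

nn_seq <- function(...) list(kind = "seq", layers = list(...))

nn_resblock <- function(main, shortcut = NULL)
  list(kind = "resblock", main = main, shortcut = shortcut)

nn_parallel_concat <- function(branches)
  list(kind = "parallel_concat", branches = branches)

nn_cal_layer <- function(ksize = 3L, softmax_scale = 10)
  list(kind = "cal", ksize = as.integer(ksize), softmax_scale = softmax_scale)

# --- helpers ----------------------------------------------------------------

# reshape (H,W,C,N) so each channel is one column over (H,W,N)
.channel_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
.channel_unmat <- function(m, d) {
  aperm(array(m, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# --- forward ----------------------------------------------------------------

nn_forward <- function(mod, x, training = FALSE, ctx = NULL) {
  switch(mod$kind,
    conv = {
      y <- cpp_conv2d_fwd(x, dim(x), mod$par$w, dim(mod$par$w), mod$par$b,
                          mod$stride, mod$pad, mod$dil)
      list(y = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      m <- .channel_mat(x)
      if (training) {
        mu <- colMeans(m)
        v <- colMeans(m * m) - mu^2
      } else {
        mu <- mod$state$rm
        v <- mod$state$rv
      }
      inv <- 1 / sqrt(v + mod$eps)
      xhat <- sweep(sweep(m, 2, mu), 2, inv, `*`)
      y <- sweep(sweep(xhat, 2, mod$par$gamma, `*`), 2, mod$par$beta, `+`)
      list(y = .channel_unmat(y, d),
           cache = list(xhat = xhat, inv = inv, d = d, mu = mu, v = v,
                        training = training))
    },
    act = {
      y <- switch(mod$fun,
                  relu = pmax(x, 0),
                  lrelu = ifelse(x > 0, x, 0.2 * x),
                  tanh = tanh(x))
      list(y = y, cache = if (mod$fun == "tanh") list(y = y) else list(x = x))
    },
    maxpool = {
      r <- cpp_maxpool_fwd(x, dim(x), mod$k, mod$stride, mod$pad)
      list(y = r$y, cache = list(argmax = r$argmax, xdims = dim(x)))
    },
    upsample = {
      f <- mod$factor
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , ,
             drop = FALSE]
      list(y = y, cache = list(d = d))
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, nrow = d[1] * d[2])          # (H*W) x (C*N)
      y <- t(matrix(colMeans(m), d[3], d[4]))      # N x C
      list(y = y, cache = list(d = d))
    },
    dense = {
      y <- sweep(x %*% mod$par$w, 2, mod$par$b, `+`)
      list(y = y, cache = list(x = x))
    },
    seq = {
      caches <- vector("list", length(mod$layers))
      h <- x
      for (i in seq_along(mod$layers)) {
        r <- nn_forward(mod$layers[[i]], h, training, ctx)
        h <- r$y
        caches[[i]] <- r$cache
      }
      list(y = h, cache = caches)
    },
    resblock = {
      rm <- nn_forward(mod$main, x, training, ctx)
      if (is.null(mod$shortcut)) {
        s <- x
        sc <- NULL
      } else {
        rs <- nn_forward(mod$shortcut, x, training, ctx)
        s <- rs$y
        sc <- rs$cache
      }
      pre <- rm$y + s
      list(y = pmax(pre, 0),
           cache = list(main = rm$cache, shortcut = sc, pre = pre))
    },
    parallel_concat = {
      outs <- lapply(mod$branches, function(b) nn_forward(b, x, training, ctx))
      ys <- lapply(outs, `[[`, "y")
      nch <- vapply(ys, function(y) dim(y)[3], integer(1))
      d1 <- dim(ys[[1]])
      y <- array(0, dim = c(d1[1], d1[2], sum(nch), d1[4]))
      at <- 0L
      for (i in seq_along(ys)) {
        y[, , at + seq_len(nch[i]), ] <- ys[[i]]
        at <- at + nch[i]
      }
      list(y = y, cache = list(caches = lapply(outs, `[[`, "cache"),
                               nch = nch))
    },
    cal = {
      cal_layer_forward(mod, x, ctx)
    },
    stop("unknown module kind: ", mod$kind)
  )
}

# --- backward ---------------------------------------------------------------

nn_backward <- function(mod, cache, dy) {
  switch(mod$kind,
    conv = {
      r <- cpp_conv2d_bwd(cache$x, dim(cache$x), mod$par$w, dim(mod$par$w),
                          dy, mod$stride, mod$pad, mod$dil)
      list(dx = r$dx, grads = list(w = r$dw, b = as.numeric(r$db)))
    },
    bn = {
      d <- cache$d
      dm <- .channel_mat(dy)
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      if (cache$training) {
        m <- nrow(dm)
        dxhat <- sweep(dm, 2, mod$par$gamma, `*`)
        t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
        t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / m, `*`)
        dx <- sweep(t1 - t2, 2, cache$inv, `*`)
      } else {
        dx <- sweep(sweep(dm, 2, mod$par$gamma, `*`), 2, cache$inv, `*`)
      }
      list(dx = .channel_unmat(dx, d),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      dx <- switch(mod$fun,
                   relu = dy * (cache$x > 0),
                   lrelu = dy * ifelse(cache$x > 0, 1, 0.2),
                   tanh = dy * (1 - cache$y^2))
      list(dx = dx, grads = NULL)
    },
    maxpool = {
      list(dx = cpp_maxpool_bwd(dy, cache$argmax, cache$xdims), grads = NULL)
    },
    upsample = {
      f <- mod$factor
      d <- cache$d
      # block-sum the upsampled gradient back to the source grid
      a <- array(dy, dim = c(f, d[1], f, d[2], d[3], d[4]))
      a <- aperm(a, c(1, 3, 2, 4, 5, 6))
      dim(a) <- c(f * f, prod(d))
      dx <- array(colSums(a), dim = d)
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$d
      per <- t(dy) / (d[1] * d[2])                # C x N
      dx <- array(rep(per, each = d[1] * d[2]), dim = d)
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = dy %*% t(mod$par$w),
           grads = list(w = t(cache$x) %*% dy, b = colSums(dy)))
    },
    seq = {
      grads <- vector("list", length(mod$layers))
      dh <- dy
      for (i in rev(seq_along(mod$layers))) {
        r <- nn_backward(mod$layers[[i]], cache[[i]], dh)
        dh <- r$dx
        grads[i] <- list(r$grads)
      }
      list(dx = dh, grads = grads)
    },
    resblock = {
      dpre <- dy * (cache$pre > 0)
      rm <- nn_backward(mod$main, cache$main, dpre)
      if (is.null(mod$shortcut)) {
        dx <- rm$dx + dpre
        gs <- NULL
      } else {
        rs <- nn_backward(mod$shortcut, cache$shortcut, dpre)
        dx <- rm$dx + rs$dx
        gs <- rs$grads
      }
      list(dx = dx, grads = list(main = rm$grads, shortcut = gs))
    },
    parallel_concat = {
      at <- 0L
      dx <- NULL
      grads <- vector("list", length(mod$branches))
      for (i in seq_along(mod$branches)) {
        dyi <- dy[, , at + seq_len(cache$nch[i]), , drop = FALSE]
        at <- at + cache$nch[i]
        r <- nn_backward(mod$branches[[i]], cache$caches[[i]], dyi)
        grads[i] <- list(r$grads)
        dx <- if (is.null(dx)) r$dx else dx + r$dx
      }
      list(dx = dx, grads = grads)
    },
    cal = {
      cal_layer_backward(mod, cache, dy)
    },
    stop("unknown module kind: ", mod$kind)
  )
}

# After a training-mode forward pass, fold the batch statistics into the
# module's running mean/variance (returns the updated module tree).
nn_update_bn_stats <- function(mod, cache) {
  switch(mod$kind,
    bn = {
      if (isTRUE(cache$training)) {
        mom <- mod$momentum
        mod$state$rm <- mom * mod$state$rm + (1 - mom) * cache$mu
        mod$state$rv <- mom * mod$state$rv + (1 - mom) * cache$v
      }
      mod
    },
    seq = {
      for (i in seq_along(mod$layers))
        mod$layers[[i]] <- nn_update_bn_stats(mod$layers[[i]], cache[[i]])
      mod
    },
    resblock = {
      mod$main <- nn_update_bn_stats(mod$main, cache$main)
      if (!is.null(mod$shortcut))
        mod$shortcut <- nn_update_bn_stats(mod$shortcut, cache$shortcut)
      mod
    },
    parallel_concat = {
      for (i in seq_along(mod$branches))
        mod$branches[[i]] <- nn_update_bn_stats(mod$branches[[i]],
                                                cache$caches[[i]])
      mod
    },
    mod
  )
}

# --- Adam optimizer over the module/grad trees ------------------------------

adam_init <- function() list(t = 0L)

# Applies one Adam step; `path` keys the per-parameter moment slots.
nn_adam_step <- function(mod, grads, opt, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  step <- function(mod, grads, path) {
    if (!is.null(mod$par)) {
      for (nm in names(mod$par)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        key <- paste0(path, ".", nm)
        m <- opt[[paste0(key, ".m")]]
        v <- opt[[paste0(key, ".v")]]
        if (is.null(m)) { m <- g * 0; v <- g * 0 }
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        mhat <- m / (1 - beta1^opt$t)
        vhat <- v / (1 - beta2^opt$t)
        mod$par[[nm]] <- mod$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        opt[[paste0(key, ".m")]] <<- m
        opt[[paste0(key, ".v")]] <<- v
      }
      return(mod)
    }
    if (mod$kind == "seq") {
      for (i in seq_along(mod$layers))
        mod$layers[[i]] <- step(mod$layers[[i]], grads[[i]],
                                paste0(path, ".", i))
    } else if (mod$kind == "resblock") {
      mod$main <- step(mod$main, grads$main, paste0(path, ".m"))
      if (!is.null(mod$shortcut))
        mod$shortcut <- step(mod$shortcut, grads$shortcut, paste0(path, ".s"))
    } else if (mod$kind == "parallel_concat") {
      for (i in seq_along(mod$branches))
        mod$branches[[i]] <- step(mod$branches[[i]], grads[[i]],
                                  paste0(path, ".b", i))
    }
    mod
  }
  mod <- step(mod, grads, "r")
  list(mod = mod, opt = opt)
}

# row-wise softmax with the max-subtraction trick
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
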