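# Bottleneck residual network for 3-class tongue texture, plus the training
# schedule (reduce-on-plateau and early stopping on validation loss) and
# accuracy evaluation. A residual block computes H(X) = F(X) + shortcut(X):
# the identity shortcut passes X unchanged (ID block), the projection
# shortcut rescales it (CONV block). Each block holds 3 convolutions
# (1x1, 3x3, 1x1) with batch normalization, ReLU after the addition.

#' Residual network specification
#'
#' The depth-101 plan uses stage blocks (3, 4, 23, 3), depth-50 uses
#' (3, 4, 6, 3); both have one stem convolution and 3 convolutions per
#' bottleneck block, so the convolutional layer count is
#' `1 + 3 * sum(stage_blocks)` and the weighted layer total adds one fully
#' connected layer.
#'
#' @param depth 50 or 101 (ignored when `stage_blocks` is given).
#' @param stage_blocks optional 4 positive integers overriding the plan.
#' @param num_classes output classes (default 3).
#' @param input_size square input side in pixels.
#' @param base_channels bottleneck width of stage 2 (stages double it).
#' @return object of class `resnet_spec`.
#' @export
resnet_spec <- function(depth = 101L, stage_blocks = NULL, num_classes = 3L,
                        input_size = 224L, base_channels = 64L) {
  if (is.null(stage_blocks)) {
    stage_blocks <- switch(as.character(depth),
                           "50" = c(3L, 4L, 6L, 3L),
                           "101" = c(3L, 4L, 23L, 3L),
                           stop("depth must be 50 or 101 unless ",
                                "stage_blocks is given"))
  }
  stage_blocks <- as.integer(stage_blocks)
  if (length(stage_blocks) != 4 || any(stage_blocks < 1))
    stop("stage_blocks must be 4 positive integers")
  structure(list(stage_blocks = stage_blocks, convs_per_block = 3L,
                 stem_convs = 1L, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels)),
            class = "resnet_spec")
}

#' Convolutional layer count of a spec
#' @param spec a `resnet_spec`.
#' @export
conv_layer_count <- function(spec) {
  spec$stem_convs + spec$convs_per_block * sum(spec$stage_blocks)
}

#' Total weighted layers (convolutions plus the fully connected head)
#' @param spec a `resnet_spec`.
#' @export
weighted_layer_count <- function(spec) conv_layer_count(spec) + 1L

#' Construct one bottleneck residual block
#'
#' Main branch: 1x1 (stride `stride`), 3x3, 1x1 convolutions, each with
#' batch normalization, ReLU between them and after the addition. With
#' `projection = FALSE` the shortcut is the identity and the input channel
#' count must already equal `4 * width`.
#'
#' @param cin input channels.
#' @param width bottleneck width (output channels are `4 * width`).
#' @param stride spatial stride of the block.
#' @param projection use a projecting 1x1 convolution on the shortcut.
#' @export
bottleneck_block <- function(cin, width, stride = 1L, projection = FALSE) {
  cout <- 4L * width
  if (!projection && (cin != cout || stride != 1L))
    stop("channel/stride mismatch without a projection shortcut")
  main <- nn_seq(
    nn_conv(cin, width, 1, stride = stride), nn_bn(width), nn_act("relu"),
    nn_conv(width, width, 3), nn_bn(width), nn_act("relu"),
    nn_conv(width, cout, 1), nn_bn(cout))
  shortcut <- if (projection)
    nn_seq(nn_conv(cin, cout, 1, stride = stride), nn_bn(cout)) else NULL
  nn_resblock(main, shortcut)
}

#' Build a residual network from a spec
#'
#' Stage 1: zero padding + 7x7 stride-2 convolution + batch norm + ReLU +
#' 3x3 stride-2 max pooling. Stages 2-5: one CONV block (projection
#' shortcut) followed by `n_i - 1` ID blocks, with widths doubling per
#' stage. Head: global average pooling, flatten, fully connected layer;
#' class probabilities come from a softmax over its output.
#'
#' @param spec a `resnet_spec`.
#' @param seed integer seed for weight initialization.
#' @return object of class `resnet_model` with elements `net`, `spec`,
#'   `classes` and `conv_layers` (the realized convolution count).
#' @export
build_resnet <- function(spec, seed = 1L) {
  local_seed(seed, {
    b <- spec$base_channels
    layers <- list(nn_conv(3, b, 7, stride = 2, pad = 3), nn_bn(b),
                   nn_act("relu"), nn_maxpool(3, 2, 1))
    cin <- b
    nconv <- 1L
    for (stage in 1:4) {
      width <- b * 2L^(stage - 1L)
      stride <- if (stage == 1) 1L else 2L
      for (blk in seq_len(spec$stage_blocks[stage])) {
        if (blk == 1) {
          layers <- c(layers, list(bottleneck_block(cin, width, stride,
                                                    projection = TRUE)))
        } else {
          layers <- c(layers, list(bottleneck_block(4L * width, width)))
        }
        cin <- 4L * width
        nconv <- nconv + 3L
      }
    }
    layers <- c(layers, list(nn_gap(), nn_dense(cin, spec$num_classes)))
    net <- list(kind = "seq", layers = layers)
    stopifnot(nconv == conv_layer_count(spec))
    structure(list(net = net, spec = spec, classes = TONGUE_CLASSES,
                   conv_layers = nconv, version = 1L),
              class = "resnet_model")
  })
}

#' Forward pass: logits, and class probabilities via softmax
#' @param model a `resnet_model`.
#' @param x H x W x 3 x N array in \[0,1\] (resized to the spec input size
#'   if needed).
#' @param training forward in training mode (batch statistics).
#' @return list with `logits` (N x K), `probs` (rows summing to 1) and
#'   `cache` for the backward pass.
#' @export
resnet_forward <- function(model, x, training = FALSE) {
  s <- model$spec$input_size
  if (dim(x)[1] != s || dim(x)[2] != s) {
    xr <- array(0, dim = c(s, s, 3, dim(x)[4]))
    for (n in seq_len(dim(x)[4]))
      xr[, , , n] <- resize_bilinear(array(x[, , , n], dim(x)[1:3]), s, s)
    x <- xr
  }
  r <- nn_forward(model$net, x * 2 - 1, training = training)
  list(logits = r$y, probs = softmax_rows(r$y), cache = r$cache)
}

#' Training schedule for the classifier
#'
#' Validation loss is monitored with strict improvement of the best value
#' (min-delta 0): after `plateau_patience` consecutive non-improving epochs
#' the learning rate is multiplied by `lr_decay_factor`; after
#' `early_stop_patience` consecutive non-improving epochs training stops.
#'
#' @param epochs cap on training epochs (default 1000).
#' @param initial_lr starting learning rate (default 0.001).
#' @param batch_size minibatch size (default 10).
#' @param plateau_patience epochs without improvement before a decay.
#' @param lr_decay_factor multiplicative decay in (0, 1).
#' @param early_stop_patience epochs without improvement before stopping.
#' @export
train_schedule <- function(epochs = 1000L, initial_lr = 0.001,
                           batch_size = 10L, plateau_patience = 5L,
                           lr_decay_factor = 0.1,
                           early_stop_patience = 15L) {
  stopifnot(plateau_patience > 0, early_stop_patience > 0,
            lr_decay_factor > 0, lr_decay_factor < 1)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay_factor = lr_decay_factor,
                 early_stop_patience = as.integer(early_stop_patience)),
            class = "train_schedule")
}

#' Plateau/early-stop scheduler state machine
#'
#' [scheduler_init()] returns the initial state; [scheduler_step()] consumes
#' one epoch's validation loss and returns the updated state. `state$lr` is
#' the learning rate for the *next* epoch and `state$stop` indicates the
#' next epoch must not run; `stop_epoch` records that epoch's index.
#'
#' @param schedule a [train_schedule()].
#' @export
scheduler_init <- function(schedule) {
  list(schedule = schedule, best = Inf, bad_plateau = 0L, bad_stop = 0L,
       lr = schedule$initial_lr, epoch = 0L, stop = FALSE,
       stop_epoch = NA_integer_, lr_drops = integer(0))
}

#' @rdname scheduler_init
#' @param state current scheduler state.
#' @param val_loss the epoch's validation loss.
#' @export
scheduler_step <- function(state, val_loss) {
  s <- state$schedule
  state$epoch <- state$epoch + 1L
  if (val_loss < state$best) {
    state$best <- val_loss
    state$bad_plateau <- 0L
    state$bad_stop <- 0L
  } else {
    state$bad_plateau <- state$bad_plateau + 1L
    state$bad_stop <- state$bad_stop + 1L
    if (state$bad_plateau >= s$plateau_patience) {
      state$lr <- state$lr * s$lr_decay_factor
      state$lr_drops <- c(state$lr_drops, state$epoch + 1L)
      state$bad_plateau <- 0L
    }
    if (state$bad_stop >= s$early_stop_patience) {
      state$stop <- TRUE
      state$stop_epoch <- state$epoch + 1L
    }
  }
  state
}

# cross-entropy loss and gradient for one-hot labels
.xent <- function(logits, yidx) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yidx)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), yidx)] <- g[cbind(seq_len(n), yidx)] - 1
  list(loss = loss, grad = g / n)
}

#' Train the texture classifier
#'
#' Minimizes cross-entropy with Adam under the plateau/early-stop schedule;
#' the best-validation-loss weights are restored at the end.
#'
#' @param train,val lists with `x` (H x W x 3 x N array in \[0,1\]) and `y`
#'   (factor with the canonical class levels).
#' @param spec a `resnet_spec`.
#' @param schedule a [train_schedule()].
#' @param seed integer seed.
#' @return list with `model` (a `resnet_model`) and `history`
#'   (`epoch,lr,train_loss,val_loss,val_acc`).
#' @export
train_classifier <- function(train, val, spec, schedule = train_schedule(),
                             seed = 1L) {
  if (length(train$y) == 0 || length(val$y) == 0)
    stop("empty training or validation set")
  stopifnot(all(levels(train$y) == TONGUE_CLASSES))
  model <- build_resnet(spec, seed = seed)
  opt <- adam_init()
  st <- scheduler_init(schedule)
  ntr <- length(train$y)
  ytr <- as.integer(train$y)
  yva <- as.integer(val$y)
  best_val <- Inf
  best_net <- model$net
  hist <- NULL
  for (ep in seq_len(schedule$epochs)) {
    if (st$stop) break
    lr <- st$lr
    ord <- local_seed(seed + 1000L * ep, sample.int(ntr))
    tl <- 0; nb <- 0L
    for (b in seq(1, ntr, by = schedule$batch_size)) {
      ix <- ord[b:min(b + schedule$batch_size - 1L, ntr)]
      fw <- resnet_forward(model, train$x[, , , ix, drop = FALSE],
                           training = TRUE)
      lo <- .xent(fw$logits, ytr[ix])
      bw <- nn_backward(model$net, fw$cache, lo$grad)
      up <- nn_adam_step(model$net, bw$grads, opt, lr)
      model$net <- nn_update_bn_stats(up$mod, fw$cache)
      opt <- up$opt
      tl <- tl + lo$loss; nb <- nb + 1L
    }
    fv <- resnet_forward(model, val$x, training = FALSE)
    vl <- .xent(fv$logits, yva)$loss
    vacc <- mean(max.col(fv$probs, ties.method = "first") == yva)
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tl / nb,
                                   val_loss = vl, val_acc = vacc))
    if (vl < best_val) {
      best_val <- vl
      best_net <- model$net
    }
    st <- scheduler_step(st, vl)
  }
  model$net <- best_net
  list(model = model, history = hist, scheduler = st,
       best_val_loss = best_val)
}

#' Build an evaluation report from labels and predictions
#'
#' @param truth,pred factors/characters over the canonical classes.
#' @return object of class `eval_report`: `confusion` (rows = truth,
#'   cols = predicted), `per_class_accuracy`, `overall_accuracy = R/S`,
#'   `R` (correct count), `S` (total count).
#' @export
eval_report <- function(truth, pred) {
  if (!all(truth %in% TONGUE_CLASSES) || !all(pred %in% TONGUE_CLASSES))
    stop("labels outside the class set")
  tf <- factor(truth, levels = TONGUE_CLASSES)
  pf <- factor(pred, levels = TONGUE_CLASSES)
  confusion <- table(truth = tf, predicted = pf)
  R <- sum(diag(confusion))
  S <- sum(confusion)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(confusion = unclass(confusion),
                 per_class_accuracy = per_class,
                 overall_accuracy = R / S, R = R, S = S),
            class = "eval_report")
}

#' Evaluate a classifier on a test set
#'
#' Hard predictions are the argmax of the softmax output; accuracy is the
#' correct count over the total count.
#'
#' @param model a `resnet_model`.
#' @param test list with `x` and `y` as in [train_classifier()].
#' @param batch_size evaluation batch size.
#' @export
evaluate_classifier <- function(model, test, batch_size = 25L) {
  n <- length(test$y)
  if (n == 0) stop("empty test set")
  pred <- integer(n)
  for (b in seq(1, n, by = batch_size)) {
    ix <- b:min(b + batch_size - 1L, n)
    fw <- resnet_forward(model, test$x[, , , ix, drop = FALSE])
    pred[ix] <- max.col(fw$probs, ties.method = "first")
  }
  eval_report(as.character(test$y), TONGUE_CLASSES[pred])
}

#' Save / load a classifier checkpoint
#' @param model a `resnet_model`.
#' @param path checkpoint file.
#' @export
save_resnet_model <- function(model, path) {
  saveRDS(list(format = "tonguetex-resnet", version = model$version,
               model = model), path)
  invisible(path)
}

#' @rdname save_resnet_model
#' @export
load_resnet_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "tonguetex-resnet"))
    stop("not a classifier checkpoint")
  x$model
}
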