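# End-to-end orchestration: coating separation -> patch harvesting ->
# inpainter training -> coating inpainting -> class balancing/splitting ->
# classifier training -> evaluation. All stage randomness derives from one
# master seed; stages write their artifacts under the work directory and
# are skipped on resume when their outputs already exist.

.default_pipeline_config <- function() {
  list(
    manifest = NULL,
    work_dir = NULL,
    seed = 1L,
    gmm = list(K = 2L, colorspace = "rgb", cleanup = FALSE),
    patches = list(window = 32L, stride = 16L, min_body_fraction = 0.8,
                   train = 0L, val = 0L, val_fraction = 0.1),
    inpaint = list(size = 32L, channels = 16L, epochs = 3L, batch_size = 10L,
                   lr = 1e-4, ksize = 3L, softmax_scale = 10, gamma = 0.99),
    classifier = list(stage_blocks = c(1L, 1L, 1L, 1L), base_channels = 8L,
                      input_size = 32L, epochs = 12L, initial_lr = 0.001,
                      batch_size = 10L, plateau_patience = 5L,
                      lr_decay_factor = 0.1, early_stop_patience = 15L,
                      val_fraction = 0.15),
    balance = list(train_per_class = 8L, test_per_class = 2L,
                   augment_before_split = FALSE)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], as.list(user[[nm]]),
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds the full configuration from the defaults (sized for desk-scale
#' synthetic runs), overriding any subset of keys. Unknown keys are
#' rejected. The configuration round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   `gmm = list(K = 2)`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .merge_config(.default_pipeline_config(), list(...))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# deterministic per-stage seed derivation from the master seed
stage_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 1299709) %% 2147483647)
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  list(value = out, seconds = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")))
}

# Separate every manifest row; reuses existing mask files on resume.
.stage_separate <- function(manifest, work_dir, cfg, seed) {
  dir <- file.path(work_dir, "separated")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  body_paths <- character(nrow(manifest))
  coat_paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    bp <- file.path(dir, sprintf("row%04d_body.png", i))
    cp <- file.path(dir, sprintf("row%04d_coating.png", i))
    if (!(file.exists(bp) && file.exists(cp))) {
      img <- read_image_png(manifest$image[i])
      tm <- read_mask_png(manifest$tongue_mask[i])
      sep <- separate_coating(img, tm, K = cfg$K,
                              seed = stage_seed(seed, i),
                              colorspace = cfg$colorspace,
                              cleanup = cfg$cleanup)
      write_mask_png(sep$body_mask, bp)
      write_mask_png(sep$coating_mask, cp)
    }
    body_paths[i] <- bp
    coat_paths[i] <- cp
  }
  data.frame(body_mask = body_paths, pred_coating = coat_paths,
             stringsAsFactors = FALSE)
}

.stage_harvest <- function(manifest, sep, pcfg, seed) {
  cfg <- patch_config(window = pcfg$window, stride = pcfg$stride,
                      min_body_fraction = pcfg$min_body_fraction)
  corpora <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image_png(manifest$image[i])
    bm <- read_mask_png(sep$body_mask[i])
    suppressWarnings(harvest_patches(img, bm, cfg,
                                     source_id = basename(manifest$image[i])))
  })
  corpus <- merge_corpora(corpora)
  n <- nrow(corpus$index)
  if (n < 2) stop("too few body patches harvested (", n, ")")
  tr <- if (pcfg$train < 1) n - max(1L, round(n * pcfg$val_fraction))
        else pcfg$train
  va <- if (pcfg$val < 1) n - tr else pcfg$val
  split_corpus(corpus, c(tr, va), seed = seed)
}

.stage_inpaint_images <- function(manifest, sep, model, work_dir) {
  dir <- file.path(work_dir, "inpainted")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    out <- file.path(dir, sprintf("row%04d.png", i))
    if (!file.exists(out)) {
      img <- read_image_png(manifest$image[i])
      tm <- read_mask_png(manifest$tongue_mask[i])
      cm <- read_mask_png(sep$pred_coating[i])
      # guard: never inpaint an (estimated) coating that swallowed the tongue
      if (sum(cm) > 0 && !all((tm == 1) == (cm == 1))) {
        img <- inpaint_coating(img, tm, cm, model)
      }
      write_image_png(img, out)
    }
    paths[i] <- out
  }
  paths
}

# balanced + split classification manifest; split-before-augment by default
.stage_balance_split <- function(manifest, bal, seed) {
  if (isTRUE(bal$augment_before_split)) {
    total <- bal$train_per_class + bal$test_per_class
    m <- balance_classes(manifest, total, seed = seed)
    m <- split_corpus(m, c(bal$train_per_class, bal$test_per_class),
                      seed = seed + 1L, tags = c("train", "test"))
  } else {
    counts <- table(factor(manifest$label, levels = TONGUE_CLASSES))
    ntest <- pmax(1L, round(as.integer(counts) * bal$test_per_class /
                              (bal$train_per_class + bal$test_per_class)))
    parts <- lapply(seq_along(TONGUE_CLASSES), function(ci) {
      rows <- manifest[manifest$label == TONGUE_CLASSES[ci], , drop = FALSE]
      sp <- split_corpus(rows[, setdiff(names(rows), "label"), drop = FALSE],
                         c(nrow(rows) - ntest[ci], ntest[ci]),
                         seed = seed + 13L * ci, tags = c("train", "test"))
      sp$label <- TONGUE_CLASSES[ci]
      sp
    })
    m <- do.call(rbind, parts)
    tr <- balance_classes(m[m$split == "train", , drop = FALSE],
                          bal$train_per_class, seed = seed + 101L)
    te <- balance_classes(m[m$split == "test", , drop = FALSE],
                          bal$test_per_class, seed = seed + 103L)
    tr$split <- "train"
    te$split <- "test"
    m <- rbind(tr, te)
  }
  m
}

# materialize (x, y) arrays from a classification manifest
.load_class_set <- function(rows, image_col, input_size) {
  n <- nrow(rows)
  x <- array(0, dim = c(input_size, input_size, 3, n))
  for (i in seq_len(n)) {
    img <- read_image_png(rows[[image_col]][i])
    op <- if ("op" %in% names(rows)) rows$op[i] else "orig"
    img <- apply_balance_op(img, op,
                            if ("scale" %in% names(rows)) rows$scale[i] else NA)
    x[, , , i] <- resize_bilinear(img, input_size, input_size)
  }
  list(x = x, y = factor(rows$label, levels = TONGUE_CLASSES))
}

.train_eval_arm <- function(m, image_col, ccfg, seed) {
  spec <- resnet_spec(stage_blocks = ccfg$stage_blocks,
                      base_channels = ccfg$base_channels,
                      input_size = ccfg$input_size)
  sched <- train_schedule(epochs = ccfg$epochs, initial_lr = ccfg$initial_lr,
                          batch_size = ccfg$batch_size,
                          plateau_patience = ccfg$plateau_patience,
                          lr_decay_factor = ccfg$lr_decay_factor,
                          early_stop_patience = ccfg$early_stop_patience)
  trrows <- m[m$split == "train", , drop = FALSE]
  terows <- m[m$split == "test", , drop = FALSE]
  # carve an internal validation set out of the training rows per class
  nval <- max(3L, round(nrow(trrows) * ccfg$val_fraction))
  vi <- local_seed(seed, sample.int(nrow(trrows), nval))
  vrows <- trrows[vi, , drop = FALSE]
  trows <- trrows[-vi, , drop = FALSE]
  tr <- .load_class_set(trows, image_col, ccfg$input_size)
  va <- .load_class_set(vrows, image_col, ccfg$input_size)
  te <- .load_class_set(terows, image_col, ccfg$input_size)
  fit <- train_classifier(tr, va, spec, sched, seed = seed)
  list(report = evaluate_classifier(fit$model, te), fit = fit)
}

#' Serialize an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    per_class_accuracy = as.list(report$per_class_accuracy),
    overall_accuracy = report$overall_accuracy,
    confusion = unclass(report$confusion),
    R = report$R, S = report$S), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the whole pipeline on a manifest
#'
#' Stages, in order: coating/body separation, body-patch harvesting,
#' inpainter training, coating inpainting, class balancing and stratified
#' splitting, classifier training, evaluation. Each stage reads only the
#' previous stage's artifacts; a stage failure aborts with the stage name.
#' The final report is written to `work_dir/report.json`.
#'
#' @param config a [pipeline_config()] with `manifest` and `work_dir` set.
#' @return a run record: per-stage timings, artifact paths, and the final
#'   `eval_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$manifest) || is.null(config$work_dir))
    stop("config needs `manifest` and `work_dir`")
  wd <- config$work_dir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  timings <- list()

  manifest <- .stage("manifest", read_manifest(config$manifest))$value

  s1 <- .stage("separate",
               .stage_separate(manifest, wd, config$gmm, stage_seed(seed, 1)))
  timings$separate <- s1$seconds
  sep <- s1$value

  s2 <- .stage("harvest",
               .stage_harvest(manifest, sep, config$patches,
                              stage_seed(seed, 2)))
  timings$harvest <- s2$seconds
  corpus <- s2$value

  icfg <- inpaint_config(size = config$inpaint$size,
                         channels = config$inpaint$channels,
                         ksize = config$inpaint$ksize,
                         softmax_scale = config$inpaint$softmax_scale,
                         gamma = config$inpaint$gamma,
                         epochs = config$inpaint$epochs,
                         batch_size = config$inpaint$batch_size,
                         lr = config$inpaint$lr)
  s3 <- .stage("train-inpaint",
               train_inpainter(corpus, icfg, seed = stage_seed(seed, 3)))
  timings$train_inpaint <- s3$seconds
  imodel <- s3$value
  save_inpaint_model(imodel, file.path(wd, "inpaint_model.rds"))

  s4 <- .stage("inpaint",
               .stage_inpaint_images(manifest, sep, imodel, wd))
  timings$inpaint <- s4$seconds
  manifest$inpainted <- s4$value

  s5 <- .stage("balance-split",
               .stage_balance_split(manifest, config$balance,
                                    stage_seed(seed, 5)))
  timings$balance_split <- s5$seconds
  clsman <- s5$value

  s6 <- .stage("train-clf",
               .train_eval_arm(clsman, "inpainted", config$classifier,
                               stage_seed(seed, 6)))
  timings$train_clf <- s6$seconds
  report <- s6$value$report
  write_eval_report(report, file.path(wd, "report.json"))

  list(report = report, timings = timings,
       artifacts = list(report = file.path(wd, "report.json"),
                        inpaint_model = file.path(wd, "inpaint_model.rds"),
                        inpainted = manifest$inpainted),
       history = s6$value$fit$history,
       config = config)
}

#' Compare classifiers with and without inpainting pretreatment
#'
#' Trains and evaluates two classifiers from the same seed and the same
#' balanced split -- one on the raw (non-inpainted) tongue images, one on
#' the inpainted images -- so test-set membership is identical between the
#' arms (asserted by a membership hash).
#'
#' @param config a [pipeline_config()].
#' @return list with `nonpretreatment` and `inpainted` `eval_report`s, the
#'   shared `membership_hash`, and per-arm histories.
#' @export
compare_pretreatments <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$work_dir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- read_manifest(config$manifest)
  sep <- .stage("separate",
                .stage_separate(manifest, wd, config$gmm,
                                stage_seed(seed, 1)))$value
  corpus <- .stage("harvest",
                   .stage_harvest(manifest, sep, config$patches,
                                  stage_seed(seed, 2)))$value
  icfg <- inpaint_config(size = config$inpaint$size,
                         channels = config$inpaint$channels,
                         ksize = config$inpaint$ksize,
                         softmax_scale = config$inpaint$softmax_scale,
                         gamma = config$inpaint$gamma,
                         epochs = config$inpaint$epochs,
                         batch_size = config$inpaint$batch_size,
                         lr = config$inpaint$lr)
  imodel <- .stage("train-inpaint",
                   train_inpainter(corpus, icfg,
                                   seed = stage_seed(seed, 3)))$value
  manifest$inpainted <- .stage("inpaint",
                               .stage_inpaint_images(manifest, sep, imodel,
                                                     wd))$value
  clsman <- .stage_balance_split(manifest, config$balance,
                                 stage_seed(seed, 5))
  membership <- clsman[clsman$split == "test", c("image", "op")]
  hash <- sum(utf8ToInt(paste(membership$image, membership$op,
                              collapse = "|")) * 1.0)
  arm_seed <- stage_seed(seed, 6)
  raw <- .stage("train-clf-raw",
                .train_eval_arm(clsman, "image", config$classifier, arm_seed))
  inp <- .stage("train-clf-inpainted",
                .train_eval_arm(clsman, "inpainted", config$classifier,
                                arm_seed))
  list(nonpretreatment = raw$value$report, inpainted = inp$value$report,
       membership_hash = hash,
       histories = list(nonpretreatment = raw$value$fit$history,
                        inpainted = inp$value$fit$history))
}
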