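test_that("exhaustive tiling of an all-body raster keeps every window", {
  img <- array(runif(192 * 192 * 3), c(192, 192, 3))
  mask <- matrix(1, 192, 192)
  corp <- harvest_patches(img, mask, patch_config(window = 96, stride = 96))
  expect_equal(nrow(corp$index), 4)
  expect_true(all(corp$index$fraction == 1))
  expect_equal(dim(corp$patches[[1]]), c(96, 96, 3))
  # crops are copied from the image at the recorded coordinates
  r <- corp$index[3, ]
  expect_identical(corp$patches[[3]],
                   img[r$row + 1:96, r$col + 1:96, , drop = FALSE])
})

test_that("the 80 percent coverage rule is a strict inequality", {
  img <- array(0.5, c(96, 96, 3))
  win2 <- 96^2
  # 7372 body pixels = 79.99 percent -> rejected; 7373 -> accepted
  m_rej <- matrix(0, 96, 96); m_rej[seq_len(7372)] <- 1
  m_acc <- matrix(0, 96, 96); m_acc[seq_len(7373)] <- 1
  expect_lt(7372 / win2, 0.8)
  expect_gt(7373 / win2, 0.8)
  expect_equal(nrow(harvest_patches(img, m_rej, patch_config())$index), 0)
  expect_equal(nrow(harvest_patches(img, m_acc, patch_config())$index), 1)
})

test_that("an image smaller than the window warns and yields an empty corpus", {
  img <- array(0.5, c(50, 50, 3))
  expect_warning(corp <- harvest_patches(img, matrix(1, 50, 50),
                                         patch_config(window = 96)),
                 "smaller")
  expect_equal(nrow(corp$index), 0)
})

test_that("harvest matches a brute-force double loop on random masks", {
  set.seed(17)
  for (case in 1:50) {
    combo <- list(c(32L, 16L), c(48L, 24L), c(24L, 24L))[[case %% 3 + 1]]
    win <- combo[1]; stride <- combo[2]
    h <- sample(80:120, 1); w <- sample(80:120, 1)
    mask <- matrix(rbinom(h * w, 1, runif(1, 0.5, 0.95)), h, w)
    img <- array(runif(h * w * 3), c(h, w, 3))
    corp <- harvest_patches(img, mask,
                            patch_config(window = win, stride = stride))
    ref <- harvest_brute_force(mask, win, stride, 0.8)
    got <- as.matrix(corp$index[, c("row", "col")])
    if (is.null(ref)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   ref[order(ref[, 1], ref[, 2]), , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("raising the coverage threshold never keeps more patches", {
  set.seed(23)
  img <- array(runif(120 * 120 * 3), c(120, 120, 3))
  mask <- matrix(rbinom(120 * 120, 1, 0.85), 120, 120)
  kept <- sapply(c(0.5, 0.7, 0.8, 0.9), function(f)
    nrow(harvest_patches(img, mask,
                         patch_config(window = 32, stride = 16,
                                      min_body_fraction = f))$index))
  expect_true(all(diff(kept) <= 0))
})

test_that("mirroring doubles the corpus and is an involution", {
  x <- array(runif(8 * 8 * 3 * 222), c(8, 8, 3, 222))
  corp <- array_corpus(x)
  aug <- mirror_augment(corp)
  expect_equal(length(aug$patches), 444)
  expect_equal(sum(aug$index$op == "mirror"), 222)
  # mirror of mirror equals the original crop pixelwise
  again <- aug$patches[[223]][, rev(seq_len(8)), , drop = FALSE]
  expect_identical(again, corp$patches[[1]])
  # empty corpus passes through
  empty <- tonguetex:::.empty_corpus(8L)
  expect_equal(length(mirror_augment(empty)$patches), 0)
})

test_that("balancing the clinical class counts reaches 700 per class", {
  counts <- c(tough = 530, tender = 198, normal = 225)
  man <- data.frame(image = sprintf("i%04d", seq_len(sum(counts))),
                    label = rep(names(counts), counts),
                    stringsAsFactors = FALSE)
  bal <- balance_classes(man, 700, seed = 1)
  expect_equal(nrow(bal), 2100)
  expect_true(all(table(bal$label) == 700))
  # derived entries keep their label and only mirror/rescale originals
  expect_true(all(bal$op %in% c("orig", "mirror", "rescale")))
  expect_true(all(bal$image %in% man$image))
  orig_label <- setNames(man$label, man$image)
  expect_true(all(bal$label == orig_label[bal$image]))
  # deterministic per seed
  expect_identical(bal, balance_classes(man, 700, seed = 1))
  expect_false(identical(bal$image, balance_classes(man, 700, seed = 2)$image))
})

test_that("balancing is a fixed point on already-balanced data", {
  man <- data.frame(image = sprintf("i%03d", 1:30),
                    label = rep(TONGUE_CLASSES, each = 10),
                    stringsAsFactors = FALSE)
  bal <- balance_classes(man, 10, seed = 4)
  expect_equal(sort(bal$image), sort(man$image))
  expect_true(all(bal$op == "orig"))
})

test_that("balancing small classes uses subsets and augmented copies", {
  man <- data.frame(image = sprintf("i%02d", 1:15),
                    label = rep(c("tough", "normal", "tender"), c(10, 2, 3)),
                    stringsAsFactors = FALSE)
  bal <- balance_classes(man, 4, seed = 2)
  expect_true(all(table(bal$label) == 4))
  # the surplus class is downsampled to a 4-subset of its originals
  tough <- bal[bal$label == "tough", ]
  expect_true(all(tough$op == "orig"))
  expect_equal(anyDuplicated(tough$image), 0)
  # the 2-entry class gains 2 mirrors (one per original, no rescale needed)
  normal <- bal[bal$label == "normal", ]
  expect_equal(sum(normal$op == "mirror"), 2)
  # target 0 gives an empty manifest
  expect_equal(nrow(balance_classes(man, 0, seed = 1)), 0)
  man$label[1] <- "normal"
  expect_error(balance_classes(man[man$label != "tender", ], 4), "class")
})

test_that("balance ops only mirror or rescale pixels", {
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_identical(apply_balance_op(img, "orig"), img)
  mir <- apply_balance_op(img, "mirror")
  expect_identical(mir[, rev(seq_len(12)), , drop = FALSE], img)
  res <- apply_balance_op(img, "rescale", scale = 1.1)
  expect_equal(dim(res), dim(img))
  expect_true(all(res >= min(img) - 1e-9 & res <= max(img) + 1e-9))
})

test_that("splits are disjoint, exhaustive, stratified and arity-checked", {
  x <- array(runif(4 * 4 * 3 * 444), c(4, 4, 3, 444))
  corp <- split_corpus(array_corpus(x), c(396, 48), seed = 3)
  expect_equal(sum(corp$index$split == "train"), 396)
  expect_equal(sum(corp$index$split == "val"), 48)
  # stratified per-class split of the balanced image set
  man <- data.frame(image = sprintf("i%04d", 1:2100),
                    label = rep(TONGUE_CLASSES, each = 700),
                    stringsAsFactors = FALSE)
  sp <- split_corpus(man, c(600, 100), seed = 5, tags = c("train", "test"))
  expect_equal(sum(sp$split == "train"), 1800)
  expect_equal(sum(sp$split == "test"), 300)
  expect_true(all(table(sp$label[sp$split == "test"]) == 100))
  expect_error(split_corpus(man[1:14, ], c(10, 5), seed = 1), "sum")
})

test_that("a corpus round-trips through its on-disk PNG + CSV form", {
  x <- array(round(runif(6 * 6 * 3 * 5) * 255) / 255, c(6, 6, 3, 5))
  corp <- split_corpus(array_corpus(x), c(4, 1), seed = 1)
  dir <- file.path(tempdir(), "corp1")
  save_patch_corpus(corp, dir)
  back <- load_patch_corpus(dir)
  expect_equal(length(back$patches), 5)
  expect_equal(back$patches[[2]], corp$patches[[2]], tolerance = 1 / 254)
  expect_equal(back$index$split, corp$index$split)
})
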