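# Data pipeline: normalization, resizing, disk round trips, stratified
# splits, and the mixed-domain batch stream.

test_that("normalization maps [0,1] to [-1,1] by the stated formula", {
  expect_equal(normalize_image(array(0.5, c(2, 2, 1, 1))),
               array(0, c(2, 2, 1, 1)))
  expect_equal(normalize_image(0), -1)
  expect_equal(normalize_image(1), 1)
  expect_equal(normalize_image(0.75), 0.5)
  expect_error(normalize_image(c(0.2, 1.3)), "\\[0, 1\\]")
  # bijection: denormalize(normalize(x)) = x to machine precision
  x <- array(runif(64), c(4, 4, 2, 2))
  expect_equal(denormalize_image(normalize_image(x)), x, tolerance = 1e-15)
})

test_that("nearest-neighbour resize follows the index arithmetic", {
  set.seed(21)
  img <- array(runif(28 * 28 * 3), c(28, 28, 3))
  out <- resize_image(img, c(32, 32), "nearest")
  for (i in c(0, 7, 19, 31)) for (j in c(0, 13, 31)) {
    expect_identical(out[i + 1, j + 1, ],
                     img[floor(i * 28 / 32) + 1, floor(j * 28 / 32) + 1, ])
  }
  # identity when sizes match
  expect_equal(resize_image(img, c(28, 28), "nearest"), img)
})

test_that("bilinear resize agrees with a direct interpolation oracle", {
  set.seed(22)
  img <- array(runif(6 * 6), c(6, 6, 1))
  out <- resize_image(img, c(12, 12), "bilinear")
  # oracle: half-pixel-centre bilinear at a few positions
  for (i in c(0, 5, 11)) for (j in c(2, 8)) {
    sy <- (i + 0.5) * 6 / 12 - 0.5; sx <- (j + 0.5) * 6 / 12 - 0.5
    y0 <- min(max(floor(sy), 0), 5); y1 <- min(y0 + 1, 5)
    x0 <- min(max(floor(sx), 0), 5); x1 <- min(x0 + 1, 5)
    wy <- min(max(sy - y0, 0), 1); wx <- min(max(sx - x0, 0), 1)
    val <- (1 - wy) * ((1 - wx) * img[y0 + 1, x0 + 1, 1] +
                         wx * img[y0 + 1, x1 + 1, 1]) +
      wy * ((1 - wx) * img[y1 + 1, x0 + 1, 1] + wx * img[y1 + 1, x1 + 1, 1])
    expect_equal(out[i + 1, j + 1, 1], val, tolerance = 1e-12)
  }
})

test_that("datasets round-trip through PNG + CSV manifest", {
  set.seed(23)
  dir <- withr::local_tempdir()
  imgs <- normalize_image(array(runif(16 * 16 * 3 * 10), c(16, 16, 3, 10)))
  set <- image_set(imgs, rep(0:4, 2), rep(0:1, 5))
  mpath <- write_dataset(set, dir)
  back <- load_dataset(mpath, image_size = c(16, 16), interp = "nearest")
  expect_identical(back$class_labels, set$class_labels)
  expect_identical(back$domain_labels, set$domain_labels)
  # pixel values within 8-bit quantization of the storage format
  expect_lt(max(abs(back$images - set$images)), 2 / 255 + 1e-9)
  # grayscale inputs are replicated to three identical channels
  png::writePNG(matrix(runif(16 * 16), 16, 16), file.path(dir, "gray.png"))
  readr::write_csv(tibble::tibble(path = "gray.png", class = 0, domain = 0),
                   file.path(dir, "m2.csv"))
  g <- load_dataset(file.path(dir, "m2.csv"), c(32, 32), "nearest")
  expect_identical(dim(g$images), c(32L, 32L, 3L, 1L))
  expect_equal(g$images[, , 1, 1], g$images[, , 2, 1])
  expect_equal(g$images[, , 1, 1], g$images[, , 3, 1])
})

test_that("bad manifests are rejected with informative errors", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(path = "nope.png", class = 0, domain = 0),
                   file.path(dir, "m.csv"))
  expect_error(load_dataset(file.path(dir, "m.csv"), c(8, 8)),
               "missing image file.*nope.png")
  readr::write_csv(tibble::tibble(path = "a.png", class = -1, domain = 0),
                   file.path(dir, "m3.csv"))
  expect_error(load_dataset(file.path(dir, "m3.csv"), c(8, 8)),
               "class labels")
  readr::write_csv(tibble::tibble(path = "a.png", klass = 1),
                   file.path(dir, "m4.csv"))
  expect_error(load_dataset(file.path(dir, "m4.csv"), c(8, 8)),
               "path,class,domain")
})

test_that("stratified split is exact, deterministic, and a partition", {
  imgs <- normalize_image(array(runif(4 * 4 * 1 * 100), c(4, 4, 1, 100)))
  set <- image_set(imgs, rep(0:1, each = 50), rep(0L, 100))
  sp <- split_dataset(set, seed = 5)
  expect_identical(sapply(sp, length), c(train = 80L, val = 10L, test = 10L))
  for (part in sp) {
    expect_identical(as.vector(table(part$class_labels)),
                     rep(length(part) %/% 2L, 2))
  }
  sp2 <- split_dataset(set, seed = 5)
  expect_identical(sp, sp2)
  # partition: disjoint manifest-free reconstruction by pixel identity
  key <- function(s) apply(s$images, 4, function(im) paste(head(im, 4), collapse = ","))
  all_keys <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_identical(sort(all_keys), sort(key(set)))
})

test_that("split per-class counts stay within one item of proportional", {
  set.seed(26)
  n <- 1000
  imgs <- normalize_image(array(runif(2 * 2 * 1 * n), c(2, 2, 1, n)))
  cls <- sample(0:9, n, replace = TRUE)
  set <- image_set(imgs, cls, rep(0L, n))
  sp <- split_dataset(set, seed = 99)
  fr <- c(0.8, 0.1, 0.1)
  for (i in 1:3) {
    part <- sp[[i]]
    for (k in 0:9) {
      expected <- fr[i] * sum(cls == k)
      expect_lte(abs(sum(part$class_labels == k) - expected), 1)
    }
  }
  # a tiny stratum triggers the best-effort warning
  small <- image_set(imgs[, , , 1:5, drop = FALSE], c(0, 0, 0, 0, 1),
                     rep(0L, 5))
  expect_warning(split_dataset(small, seed = 1), "fewer than 3")
})

test_that("mixed batches honour the even-domain and class-balance contracts", {
  sp <- fixture_splits()
  src <- sp[[1]]$train; tgt <- sp[[2]]$train
  nb <- iterate_batches(src, tgt, batch_plan(20, seed = 3))
  b <- nb()
  expect_identical(sum(b$is_source), 10L)
  expect_identical(sum(!b$is_source), 10L)
  expect_true(all(is.na(b$class[!b$is_source]) | !b$is_source))
  expect_identical(dim(b$x), c(3L, 16L, 16L, 20L))
  # odd batch size: floor(B/2) source, ceiling(B/2) target
  b2 <- iterate_batches(src, tgt, batch_plan(7, seed = 3))()
  expect_identical(sum(b2$is_source), 3L)
  expect_identical(sum(!b2$is_source), 4L)
  expect_error(batch_plan(1), "at least 2")
  # class balance on binary labels: 10 source slots -> 5 per class
  bsrc <- subset_items(src, which(src$class_labels %in% c(0, 1)))
  bsrc$n_classes <- 2L
  nb3 <- iterate_batches(bsrc, tgt, batch_plan(20, balance_by_class = TRUE,
                                               seed = 4))
  b3 <- nb3()
  expect_identical(as.vector(table(b3$class[b3$is_source])), rep(5L, 2))
})

test_that("unbalanced sampling of balanced classes is uniform (chi-square)", {
  sp <- fixture_splits()
  src <- sp[[1]]$train
  nb <- iterate_batches(src, src, batch_plan(20, seed = 7))
  counts <- integer(10)
  for (i in 1:2000) {
    b <- nb()
    tab <- tabulate(b$class[b$is_source] + 1L, 10)
    counts <- counts + tab
  }
  # compare against the empirical class frequencies of the source pool
  expected <- sum(counts) * tabulate(src$class_labels + 1L, 10) / length(src)
  stat <- sum((counts - expected)^2 / expected)
  expect_gt(stats::pchisq(stat, df = 9, lower.tail = FALSE), 0.05)
})
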