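# Training procedures: schedule arithmetic, the early-stopping rule,
# classifier training behaviour, and the adaptation loop's contracts.

test_that("learning-rate schedule is flat then decays linearly to zero", {
  cfg <- adaptation_config(iterations = 200000, lr = 1e-4)
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(100000, cfg), 1e-4)
  expect_equal(lr_schedule(150000, cfg), 5e-5)
  expect_equal(lr_schedule(200000, cfg), 0)
  expect_error(lr_schedule(200001, cfg), "exceeds")
  cfg2 <- adaptation_config(iterations = 1000)
  expect_equal(lr_schedule(750, cfg2), 5e-5)
})

test_that("early stopping fires after exactly `patience` non-improving epochs", {
  # monotone-degrading sequence: first epoch is best, then 10 bad epochs
  expect_identical(early_stop_epochs(seq(0.9, by = -0.01, length.out = 50), 10),
                   11L)
  # plateaus count as non-improving
  expect_identical(early_stop_epochs(rep(0.8, 50), 10), 11L)
  # strictly improving sequence never stops
  expect_identical(early_stop_epochs(seq(0.5, 0.99, length.out = 30), 10), 30L)
  # improvement inside the patience window resets the counter
  aucs <- c(0.8, rep(0.7, 9), 0.85, rep(0.7, 10))
  expect_identical(early_stop_epochs(aucs, 10), 21L)
})

test_that("a linearly separable toy task reaches high validation AUC", {
  set.seed(71)
  n <- 120
  imgs <- array(0, c(8, 8, 3, n))
  y <- rep(0:1, n / 2)
  imgs[, , , y == 1] <- 0.7
  imgs <- normalize_image(imgs + array(runif(length(imgs)) * 0.2, dim(imgs)))
  set <- image_set(imgs, y, rep(0L, n))
  sp <- split_dataset(set, c(0.6, 0.2, 0.2), seed = 1)
  cl <- train_classifier(sp$train, sp$val,
                         classifier_config(batch_size = 16, max_epochs = 20,
                                           seed = 2),
                         spec = task_net_spec(8, 3, 2, conv_widths = c(4, 8),
                                              fc_width = 8))
  expect_gte(cl$best_val_auc, 0.99)
  expect_named(cl$history, c("epoch", "train_loss", "val_auc"))
})

test_that("random labels stop early near chance AUC, following the rule", {
  set.seed(72)
  n <- 80
  imgs <- normalize_image(array(runif(8 * 8 * 3 * n), c(8, 8, 3, n)))
  set <- image_set(imgs, sample(0:1, n, replace = TRUE), rep(0L, n))
  sp <- split_dataset(set, c(0.5, 0.3, 0.2), seed = 1)
  cl <- train_classifier(sp$train, sp$val,
                         classifier_config(batch_size = 16, max_epochs = 60,
                                           patience = 5, seed = 3),
                         spec = task_net_spec(8, 3, 2, conv_widths = c(2, 4),
                                              fc_width = 4))
  expect_lt(nrow(cl$history), 60)
  expect_lt(abs(cl$best_val_auc - 0.5), 0.35)
  # the run length agrees with the pure early-stopping rule on the history
  expect_identical(nrow(cl$history),
                   as.integer(early_stop_epochs(cl$history$val_auc, 5)))
})

test_that("validation sets with a single class are rejected", {
  set.seed(73)
  imgs <- normalize_image(array(runif(8 * 8 * 3 * 20), c(8, 8, 3, 20)))
  train <- image_set(imgs, rep(0:1, 10), rep(0L, 20))
  val <- image_set(imgs, rep(0L, 20), rep(0L, 20))
  expect_error(train_classifier(train, val), "single class")
})

test_that("adaptation history records five critic updates per generator update", {
  sp <- fixture_splits()
  cl <- fixture_classifier()
  ad <- train_adaptation(sp[[1]]$train, sp[[2]]$train, cl,
                         adaptation_config(iterations = 4, batch_size = 8,
                                           g_base_width = 4, d_base_width = 4,
                                           n_res = 1, seed = 5))
  h <- ad$history
  per_iter <- table(h$phase[h$iteration == 2])
  expect_identical(unname(per_iter["critic"]), 5L)
  expect_identical(unname(per_iter["generator"]), 1L)
  expect_true(all(c("gp", "cls_real", "cyc", "sem") %in% names(h)))
  expect_true(all(is.finite(h$loss_d[h$phase == "critic"])))
})

test_that("zero-iteration adaptation returns the source net unchanged", {
  sp <- fixture_splits()
  cl <- fixture_classifier()
  ad <- train_adaptation(sp[[1]]$train, sp[[2]]$train, cl,
                         adaptation_config(iterations = 0, seed = 5))
  expect_identical(ad$F_T$params, cl$model$params)
  expect_identical(nrow(ad$history), 0L)
})

test_that("adaptation is reproducible and never reads target labels", {
  sp <- fixture_splits()
  cl <- fixture_classifier()
  cfg <- adaptation_config(iterations = 3, batch_size = 8, g_base_width = 4,
                           d_base_width = 4, n_res = 1, seed = 17)
  run <- function(target) train_adaptation(sp[[1]]$train, target, cl, cfg)
  tgt <- sp[[2]]$train
  a <- run(tgt)
  b <- run(tgt)
  expect_identical(a$history, b$history)           # bit-identical reruns
  expect_identical(a$G$params, b$G$params)
  scrambled <- tgt
  scrambled$class_labels <- rev(tgt$class_labels)  # garbage labels
  c_ <- run(scrambled)
  expect_identical(a$history, c_$history)          # labels never consulted
  expect_identical(a$F_T$params, c_$F_T$params)
})

test_that("translation carries labels, preserves range, reports change", {
  sp <- fixture_splits()
  cl <- fixture_classifier()
  ad <- train_adaptation(sp[[1]]$train, sp[[2]]$train, cl,
                         adaptation_config(iterations = 2, batch_size = 8,
                                           g_base_width = 4, d_base_width = 4,
                                           n_res = 1, seed = 5))
  tr <- translate_set(ad, sp[[1]]$val, 1L)
  expect_identical(length(tr), length(sp[[1]]$val))
  expect_identical(tr$class_labels, sp[[1]]$val$class_labels)
  expect_true(all(tr$domain_labels == 1L))
  expect_true(all(abs(tr$images) <= 1))
  expect_true(is.finite(attr(tr, "mean_abs_change")))
})

test_that("fine-tuning starts from the source weights and shares the protocol", {
  sp <- fixture_splits()
  cl <- fixture_classifier()
  ft0 <- finetune_on_translated(cl, sp[[1]]$train, sp[[1]]$val,
                                classifier_config(max_epochs = 0))
  expect_identical(ft0$model$params, cl$model$params)  # zero-epoch identity
  ft <- finetune_on_translated(cl, sp[[1]]$train, sp[[1]]$val,
                               classifier_config(batch_size = 64,
                                                 max_epochs = 2, seed = 9))
  expect_named(ft$history, names(cl$history))  # identical history schema
})

test_that("self-fine-tuning on untranslated source data is not destructive", {
  sp <- fixture_splits()
  cl <- fixture_classifier()
  base <- macro_auc(predict(cl, sp[[1]]$val), sp[[1]]$val$class_labels)
  for (seed in 1:3) {
    ft <- finetune_on_translated(cl, sp[[1]]$train, sp[[1]]$val,
                                 classifier_config(batch_size = 64,
                                                   max_epochs = 4,
                                                   seed = seed))
    after <- macro_auc(predict(ft, sp[[1]]$val), sp[[1]]$val$class_labels)
    expect_gte(after, base - 0.02)
  }
})
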