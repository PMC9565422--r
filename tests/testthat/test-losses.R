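# Loss functions: closed-form examples, identities between components, and
# the composition arithmetic of the final objectives.

test_that("saturating adversarial loss matches its closed form", {
  expect_equal(adv_loss_saturating(0.5, 0.5), log(0.5) + log(0.5),
               tolerance = 1e-12)
  expect_equal(adv_loss_saturating(0.8, 0.3), log(0.8) + log(0.7),
               tolerance = 1e-12)
  # perfect-discriminator limit approaches 0 from below
  expect_gt(adv_loss_saturating(1 - 1e-12, 1e-12), -1e-9)
  expect_lt(adv_loss_saturating(1 - 1e-12, 1e-12), 0)
  expect_error(adv_loss_saturating(1.2, 0.5), "probabilities")
})

test_that("Wasserstein adversarial loss is the stated arithmetic", {
  expect_equal(adv_loss_wgan(0.5, 0.5, gp = 1, lambda_gp = 10), -10)
  expect_equal(adv_loss_wgan(2, -1, gp = 0), 3)
  set.seed(61)
  for (r in 1:5) {
    dr <- rnorm(7); df <- rnorm(7); gp <- abs(rnorm(1))
    expect_equal(adv_loss_wgan(dr, df, gp, 10),
                 mean(dr) - mean(df) - 10 * gp, tolerance = 1e-12)
  }
  expect_error(adv_loss_wgan(1, 1, gp = -0.1), "non-negative")
})

test_that("gradient penalty matches closed forms for linear critics", {
  set.seed(62)
  # critic D(x) = sum(x): gradient norm 1 on 1-pixel images -> penalty 0
  one_px <- function(a) function(xh) ns$d_scale(
    ns$d_matmul(ns$dconst(matrix(1, 1, 1)),
                ns$d_reshape(xh, c(1, dim(xh$value)[4]))), a)
  x <- array(runif(1), c(1, 1, 1, 1))
  gp <- gradient_penalty(one_px(1), x, x, alpha = 0.5)
  expect_equal(ns$dval(gp), 0, tolerance = 1e-12)
  # constant critic: gradient norm 0 -> penalty 1, so lambda * gp = 10
  const_critic <- function(xh) ns$d_shift(ns$d_scale(
    ns$d_matmul(ns$dconst(matrix(1, 1, prod(dim(xh$value)[1:3]))),
                ns$d_reshape(xh, c(prod(dim(xh$value)[1:3]),
                                   dim(xh$value)[4]))), 0), 3)
  x <- array(runif(2 * 2 * 1 * 3), c(1, 2, 2, 3))
  gp <- gradient_penalty(const_critic, x, x + 0.1 * runif(length(x)))
  expect_equal(ns$dval(gp), 1, tolerance = 1e-12)
  # D(x) = 2 * sum(x) on 2x2x1 images: norm 2*sqrt(4) = 4 -> penalty 9
  critic2 <- function(xh) ns$d_scale(
    ns$d_matmul(ns$dconst(matrix(1, 1, 4)), ns$d_reshape(xh, c(4, dim(xh$value)[4]))), 2)
  gp <- gradient_penalty(critic2, x, x)
  expect_equal(ns$dval(gp), 9, tolerance = 1e-12)
})

test_that("gradient penalty is minimized at |a| = 1/sqrt(d) for linear critics", {
  set.seed(63)
  d <- 2 * 2 * 1
  pen_for <- function(a) {
    critic <- function(xh) ns$d_scale(
      ns$d_matmul(ns$dconst(matrix(1, 1, d)),
                  ns$d_reshape(xh, c(d, dim(xh$value)[4]))), a)
    x <- array(runif(d * 2), c(1, 2, 2, 2))
    ns$dval(gradient_penalty(critic, x, x))
  }
  astar <- 1 / sqrt(d)
  expect_equal(pen_for(astar), 0, tolerance = 1e-12)
  expect_equal(pen_for(-astar), 0, tolerance = 1e-12)
  for (a in c(0.1, 0.8, 2)) expect_gt(pen_for(a), pen_for(astar))
})

test_that("domain-classification losses match the NLL arithmetic", {
  # uniform logits over K = 3 domains
  expect_equal(cls_loss_real(matrix(0, 3, 5), rep(1L, 5)), log(3),
               tolerance = 1e-12)
  # probabilities (0.7, 0.2, 0.1), true domain 0
  expect_equal(cls_loss_real(matrix(log(c(0.7, 0.2, 0.1)), 3, 1), 0L),
               -log(0.7), tolerance = 1e-12)
  # near-one-hot correct prediction -> 0 in the limit
  expect_lt(cls_loss_real(matrix(c(50, 0, 0), 3, 1), 0L), 1e-9)
  expect_error(cls_loss_real(matrix(0, 3, 2), c(0L, 3L)), "outside")
  # the fake-image loss is the identical arithmetic at the target code
  z <- matrix(rnorm(8), 4, 2)
  expect_equal(cls_loss_fake(z, c(2L, 0L)), cls_loss_real(z, c(2L, 0L)))
  # uniform over K = 4
  expect_equal(cls_loss_fake(matrix(1, 4, 3), c(0L, 1L, 3L)), log(4),
               tolerance = 1e-12)
})

test_that("cycle loss is mean absolute error, permutation invariant", {
  x <- array(0, c(2, 4, 4, 3))
  rec <- array(0.1, c(2, 4, 4, 3))
  expect_equal(cycle_loss(x, rec), 0.1, tolerance = 1e-12)
  expect_equal(cycle_loss(x, x), 0)
  set.seed(64)
  a <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  b <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  perm <- sample(3)
  expect_equal(cycle_loss(a, b),
               cycle_loss(a[, , , perm, drop = FALSE],
                          b[, , , perm, drop = FALSE]),
               tolerance = 1e-12)
})

test_that("task loss matches softmax cross-entropy closed forms", {
  expect_equal(task_loss(matrix(0, 10, 4), rep(3L, 4)), log(10),
               tolerance = 1e-12)
  z <- matrix(c(2, 1, 0), 3, 1)
  expect_equal(task_loss(z, 0L), -log(exp(2) / (exp(2) + exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(task_loss(z, 0L), 0.4076, tolerance = 1e-4)
  expect_lt(task_loss(matrix(c(60, 0), 2, 1), 0L), 1e-9)
})

test_that("semantic loss is the sum of its three task-loss terms", {
  set.seed(65)
  N <- 4
  z1 <- matrix(rnorm(N * 3), N, 3); y1 <- sample(0:(N - 1), 3, replace = TRUE)
  z2 <- matrix(rnorm(N * 3), N, 3)
  z3 <- matrix(rnorm(N * 2), N, 2); y3 <- sample(0:(N - 1), 2, replace = TRUE)
  expect_equal(semantic_loss(z1, z2, z3, y1, y3),
               task_loss(z1, y1) + task_loss(z2, y1) + task_loss(z3, y3),
               tolerance = 1e-12)
  # all-uniform classifiers give 3 log N
  u <- matrix(0, 5, 2)
  expect_equal(semantic_loss(u, u, u, c(0L, 1L), c(2L, 3L)), 3 * log(5),
               tolerance = 1e-12)
  # identity generator + perfectly confident correct classifiers -> 0
  conf <- matrix(-50, 5, 2); conf[cbind(c(1, 2), c(1, 2))] <- 50
  expect_lt(semantic_loss(conf, conf, conf, c(0L, 1L), c(0L, 1L)), 1e-9)
})

test_that("final objectives compose components with the stated weights", {
  w <- loss_weights()
  expect_identical(c(w$lambda_gp, w$lambda_cls, w$lambda_cyc), c(10, 1, 10))
  expect_equal(discriminator_objective(1, 1, w), 0)
  expect_equal(generator_objective(1, 1, 1, 1, w), 13)
  set.seed(66)
  for (r in 1:5) {
    v <- rnorm(6)
    expect_equal(discriminator_objective(v[1], v[2], w), -v[1] + v[2],
                 tolerance = 1e-12)
    expect_equal(generator_objective(v[3], v[4], v[5], v[6], w),
                 v[3] + 1 * v[4] + 10 * v[5] + v[6], tolerance = 1e-12)
    # zero cycle weight removes the cycle term's influence
    w0 <- loss_weights(lambda_cyc = 0)
    expect_equal(generator_objective(v[3], v[4], v[5], v[6], w0),
                 generator_objective(v[3], v[4], 999, v[6], w0),
                 tolerance = 1e-12)
  }
  expect_error(loss_weights(lambda_gp = -1))
})

test_that("losses are finite and appropriately signed on random inputs", {
  set.seed(67)
  for (r in 1:10) {
    z <- matrix(rnorm(12, sd = 5), 4, 3)
    y <- sample(0:3, 3, replace = TRUE)
    expect_true(is.finite(task_loss(z, y)))
    expect_gte(task_loss(z, y), 0)
    expect_gte(cls_loss_real(z, y), 0)
    a <- array(rnorm(8), c(2, 2, 2, 1)); b <- array(rnorm(8), c(2, 2, 2, 1))
    expect_gte(cycle_loss(a, b), 0)
    expect_true(is.finite(adv_loss_wgan(rnorm(3), rnorm(3), abs(rnorm(1)))))
  }
})
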