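# Architecture contracts: shapes, ranges, conditioning, convolution
# arithmetic, auto-depth, parameter counts, and trainability.

test_that("generator output matches input shape, range, and is conditioned", {
  set.seed(51)
  g <- build_generator(generator_spec(16, 3, 2, n_res = 2, base_width = 8))
  x <- array(runif(3 * 16 * 16 * 4, -1, 1), c(3, 16, 16, 4))
  pn <- ns$.cnodes(g$params)
  o0 <- ns$dval(g$forward(pn, ns$dconst(x), onehot_code(rep(0L, 4), 2)))
  o1 <- ns$dval(g$forward(pn, ns$dconst(x), onehot_code(rep(1L, 4), 2)))
  expect_identical(dim(o0), dim(x))
  expect_true(all(abs(o0) <= 1))
  expect_gt(max(abs(o0 - o1)), 0)  # conditioning is live at initialization
  expect_error(generator_spec(image_size = 6), "divisible by 4")
})

test_that("generator gradients w.r.t. input pixels are finite (8x8 toy)", {
  set.seed(52)
  g <- build_generator(generator_spec(8, 1, 2, n_res = 1, base_width = 4))
  x <- array(runif(1 * 8 * 8 * 1, -1, 1), c(1, 8, 8, 1))
  xn <- ns$dparam(x)
  out <- g$forward(ns$.cnodes(g$params), xn, onehot_code(0L, 2))
  gx <- ns$dval(ns$dst_grad(ns$d_sum(out), list(xn))[[1]])
  expect_true(all(is.finite(gx)))
  # finite-difference agreement on a few pixels
  f <- function(xv) sum(ns$dval(g$forward(ns$.cnodes(g$params),
                                          ns$dconst(xv), onehot_code(0L, 2))))
  eps <- 1e-5
  for (i in sample(length(x), 3)) {
    x1 <- x; x1[i] <- x1[i] + eps
    expect_equal(gx[i], (f(x1) - f(x)) / eps, tolerance = 1e-2)
  }
})

test_that("critic patch-map size follows convolution arithmetic", {
  # six stride-2 (k=4, p=1) layers on 224px input give a 3x3 patch map
  sp224 <- discriminator_spec(224, 3, 2, n_conv = 6)
  expect_identical(sp224$n_conv, 6L)
  expect_identical(ns$patch_map_size(sp224), 3)
  # small inputs force a reduced depth with a final map of at least 2x2
  sp32 <- discriminator_spec(32, 3, 2, n_conv = 6)
  expect_lt(sp32$n_conv, 6L)
  expect_gte(ns$patch_map_size(sp32), 2)
  sp16 <- discriminator_spec(16, 3, 2, n_conv = 6)
  expect_gte(ns$patch_map_size(sp16), 2)
  expect_error(discriminator_spec(7), "too small")
})

test_that("critic heads emit patch scores and K domain logits", {
  set.seed(53)
  for (K in 2:4) {
    d <- build_discriminator(discriminator_spec(16, 3, K, base_width = 4))
    x <- array(runif(3 * 16 * 16 * 3, -1, 1), c(3, 16, 16, 3))
    out <- d$forward(ns$.cnodes(d$params), ns$dconst(x))
    expect_identical(dim(ns$dval(out$cls)), c(K, 3L))
    src <- ns$dval(out$src)
    expect_identical(dim(src)[1], 1L)
    expect_gte(dim(src)[2], 2L)  # spatial map, not a single score
  }
})

test_that("task nets emit N logits; dropout only acts in training mode", {
  set.seed(54)
  f <- build_task_net(task_net_spec(16, 3, 10))
  x <- array(runif(3 * 16 * 16 * 5, -1, 1), c(3, 16, 16, 5))
  z <- ns$dval(f$forward(ns$.cnodes(f$params), ns$dconst(x)))
  expect_identical(dim(z), c(10L, 5L))
  p <- exp(z) / rep(colSums(exp(z)), each = 10)
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  # dense head: two eval-mode passes identical, training passes differ
  fd <- build_task_net(task_net_spec(16, 3, 2, backbone = "dense_head",
                                     head_widths = c(32, 16)))
  pn <- ns$.cnodes(fd$params)
  e1 <- ns$dval(fd$forward(pn, ns$dconst(x), train = FALSE))
  e2 <- ns$dval(fd$forward(pn, ns$dconst(x), train = FALSE))
  expect_identical(e1, e2)
  set.seed(1); t1 <- ns$dval(fd$forward(pn, ns$dconst(x), train = TRUE))
  set.seed(2); t2 <- ns$dval(fd$forward(pn, ns$dconst(x), train = TRUE))
  expect_gt(max(abs(t1 - t2)), 0)
})

test_that("parameter counts match hand-computed arithmetic (digit scale)", {
  # generator: 32x32x3 input, K = 2, 4 residual blocks, base width 32
  g <- build_generator(generator_spec(32, 3, 2, n_res = 4, base_width = 32))
  ngf <- 32
  count_g <- (ngf * (3 + 2) * 16 + ngf) + 2 * ngf +            # down 1 + IN
    (2 * ngf * ngf * 16 + 2 * ngf) + 4 * ngf +                 # down 2 + IN
    4 * (2 * ((2 * ngf) * (2 * ngf) * 9 + 2 * ngf + 4 * ngf)) + # res blocks
    (2 * ngf * ngf * 16 + ngf) + 2 * ngf +                     # up 1 + IN
    (ngf * 3 * 16 + 3)                                         # up 2
  expect_identical(n_parameters(g), as.integer(count_g))
  # task net: two 5x5 convs (8, 16) + fc 64 + 10-way head on 32x32
  f <- build_task_net(task_net_spec(32, 3, 10))
  count_f <- (8 * 3 * 25 + 8) + (16 * 8 * 25 + 16) +
    (64 * (16 * 8 * 8) + 64) + (10 * 64 + 10)
  expect_identical(n_parameters(f), as.integer(count_f))
  # critic: depth-4 auto-adjusted at 32px, widths 32,64,128,256, two heads
  d <- build_discriminator(discriminator_spec(32, 3, 2, base_width = 32))
  widths <- c(32, 64, 128, 256)
  cin <- c(3, 32, 64, 128)
  count_d <- sum(widths * cin * 16 + widths) +
    (1 * 256 * 9 + 1) + (2 * 256 * 4 + 2)
  expect_identical(n_parameters(d), as.integer(count_d))
})

test_that("one optimizer step decreases each network's loss on a toy batch", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- array(runif(3 * 16 * 16 * 8, -1, 1), c(3, 16, 16, 8))
    y <- sample(0:1, 8, replace = TRUE)
    f <- build_task_net(task_net_spec(16, 3, 2, conv_widths = c(4, 8),
                                      fc_width = 16))
    opt <- ns$adam_init(f$params)
    loss_at <- function(params) {
      ns$dval(task_loss(f$forward(ns$.cnodes(params), ns$dconst(x)), y))
    }
    l0 <- loss_at(f$params)
    pn <- ns$.pnodes(f$params)
    loss <- task_loss(f$forward(pn, ns$dconst(x), train = TRUE), y)
    grads <- ns$param_grads(loss, pn)
    up <- ns$adam_step(f$params, grads, opt, 1e-3)
    expect_lt(loss_at(up$params), l0)
  }
})
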