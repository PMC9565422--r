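# Network architectures: conditional image-translation generator, PatchGAN
# critic with a domain-classification head, and task (classification) nets.
#
# A model is a list with $params (named numeric arrays), $forward (a function
# of parameter nodes and input nodes), $spec, and $state (mutable environment
# for things like batch-norm running statistics). Forwards are pure tape
# computations, so one set of code serves training (parameter nodes) and
# inference (constant nodes).

new_model <- function(params, forward, spec, kind) {
  structure(list(params = params, forward = forward, spec = spec, kind = kind,
                 state = new.env(parent = emptyenv())),
            class = "ds_model")
}

#' @export
print.ds_model <- function(x, ...) {
  cat("<ds_model:", x$kind, "|", n_parameters(x), "parameters>\n")
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' A pure function of the architecture specification.
#'
#' @param model a `ds_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

#' Generator specification
#'
#' The generator maps an image plus a one-hot target-domain code to an image
#' of the same size in the requested domain. It uses two downsampling
#' convolutions (kernel 4, stride 2, padding 1), a stack of residual blocks,
#' and two transposed-convolution upsampling layers, with instance
#' normalization and ReLU between layers. The convolutional stack predicts a
#' residual on a global identity skip of the input image, and a final tanh
#' keeps outputs in \[-1, 1\]; with the last layer initialized near zero a
#' fresh generator is therefore close to the identity map, so short
#' adaptation runs start from a non-destructive translation. The domain code
#' is tiled spatially and appended to the input channels.
#'
#' @param image_size input (and output) spatial size in pixels (square).
#' @param channels image channels (3 for RGB).
#' @param n_domains number of domains K the generator is conditioned on.
#' @param n_res number of residual blocks (4 at digit scale, 9 at
#'   radiograph scale).
#' @param base_width channel width after the first downsampling convolution.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(image_size = 32, channels = 3, n_domains = 2,
                           n_res = 4, base_width = 32) {
  if (image_size %% 4 != 0 || image_size < 8) {
    stop("generator needs image_size divisible by 4 and >= 8 (two stride-2 ",
         "down/upsampling stages); got ", image_size)
  }
  structure(list(image_size = image_size, channels = channels,
                 n_domains = n_domains, n_res = n_res,
                 base_width = base_width),
            class = "generator_spec")
}

#' Build the conditional image-translation generator
#'
#' @param spec a [generator_spec()].
#' @return a `ds_model` whose forward is `G(x, c)`: `x` an image node shaped
#'   `(C, H, W, N)` with values in `[-1, 1]`, `c` a one-hot `(K, N)` matrix.
#' @export
build_generator <- function(spec) {
  C <- spec$channels; K <- spec$n_domains
  ngf <- spec$base_width
  p <- list()
  p$d1.W <- init_conv(ngf, C + K, 4);      p$d1.b <- matrix(0, ngf, 1)
  p$d1.g <- matrix(1, ngf, 1);             p$d1.be <- matrix(0, ngf, 1)
  p$d2.W <- init_conv(2 * ngf, ngf, 4);    p$d2.b <- matrix(0, 2 * ngf, 1)
  p$d2.g <- matrix(1, 2 * ngf, 1);         p$d2.be <- matrix(0, 2 * ngf, 1)
  for (i in seq_len(spec$n_res)) {
    for (j in 1:2) {
      nm <- paste0("r", i, ".", j)
      p[[paste0(nm, ".W")]] <- init_conv(2 * ngf, 2 * ngf, 3)
      p[[paste0(nm, ".b")]] <- matrix(0, 2 * ngf, 1)
      p[[paste0(nm, ".g")]] <- matrix(1, 2 * ngf, 1)
      p[[paste0(nm, ".be")]] <- matrix(0, 2 * ngf, 1)
    }
  }
  p$u1.W <- init_deconv(2 * ngf, ngf, 4);  p$u1.b <- matrix(0, ngf, 1)
  p$u1.g <- matrix(1, ngf, 1);             p$u1.be <- matrix(0, ngf, 1)
  # final layer starts near zero: with the global identity skip below, a
  # freshly initialized generator is close to the identity map
  p$u2.W <- init_deconv(ngf, C, 4, sd = 0.002)
  p$u2.b <- matrix(0, C, 1)

  forward <- function(pn, x, code, train = FALSE) {
    if (!inherits(x, "dstensor")) x <- dconst(x)
    h <- d_cat1(x, nn_tile_code(dim(x$value), code))
    h <- d_relu(nn_instancenorm(nn_conv(h, pn$d1.W, pn$d1.b, 4, 2, 1),
                                pn$d1.g, pn$d1.be))
    h <- d_relu(nn_instancenorm(nn_conv(h, pn$d2.W, pn$d2.b, 4, 2, 1),
                                pn$d2.g, pn$d2.be))
    for (i in seq_len(spec$n_res)) {
      n1 <- paste0("r", i, ".1"); n2 <- paste0("r", i, ".2")
      r <- d_relu(nn_instancenorm(
        nn_conv(h, pn[[paste0(n1, ".W")]], pn[[paste0(n1, ".b")]], 3, 1, 1),
        pn[[paste0(n1, ".g")]], pn[[paste0(n1, ".be")]]))
      r <- nn_instancenorm(
        nn_conv(r, pn[[paste0(n2, ".W")]], pn[[paste0(n2, ".b")]], 3, 1, 1),
        pn[[paste0(n2, ".g")]], pn[[paste0(n2, ".be")]])
      h <- d_add(h, r)
    }
    h <- d_relu(nn_instancenorm(
      nn_deconv(h, pn$u1.W, pn$u1.b, 4, 2, 1, ngf), pn$u1.g, pn$u1.be))
    r <- nn_deconv(h, pn$u2.W, pn$u2.b, 4, 2, 1, C)
    # the network predicts a residual on a global identity skip; tanh keeps
    # the output in [-1, 1] while tanh(2x) stays close to x on that range
    d_tanh(d_add(r, d_scale(x, 2)))
  }
  new_model(p, forward, spec, "generator")
}

#' Critic / discriminator specification
#'
#' A PatchGAN critic: stride-2 convolutions (kernel 4, padding 1) with
#' leaky-ReLU (slope 0.01) and no normalization layers, followed by two
#' heads: `src`, a spatial map of unbounded real/fake patch scores, and
#' `cls`, K-way domain logits (one vector per image). The requested depth is
#' automatically reduced for small inputs so the final feature map stays at
#' least 2x2.
#'
#' @param image_size input spatial size.
#' @param channels image channels.
#' @param n_domains K, width of the domain-classification head.
#' @param n_conv requested number of stride-2 convolutions (6 at radiograph
#'   scale; reduced automatically when infeasible).
#' @param base_width channel width of the first convolution.
#' @return a `discriminator_spec` list; `$n_conv` holds the effective depth.
#' @export
discriminator_spec <- function(image_size = 32, channels = 3, n_domains = 2,
                               n_conv = 6, base_width = 32) {
  s <- image_size
  feasible <- 0L
  while (s %/% 2 >= 2) { s <- s %/% 2; feasible <- feasible + 1L }
  if (feasible < 2L) {
    stop("image_size ", image_size, " too small for a stride-2 critic ",
         "stack; need at least 8 pixels")
  }
  eff <- as.integer(min(n_conv, feasible))
  structure(list(image_size = image_size, channels = channels,
                 n_domains = n_domains, n_conv = eff,
                 n_conv_requested = n_conv, base_width = base_width),
            class = "discriminator_spec")
}

# spatial size of the critic's patch-score map
patch_map_size <- function(spec) {
  s <- spec$image_size
  for (i in seq_len(spec$n_conv)) s <- conv_out_size(s, 4, 2, 1)
  s
}

#' Build the PatchGAN critic with domain-classification head
#'
#' @param spec a [discriminator_spec()].
#' @return a `ds_model`; its forward returns `list(src =, cls =)` where `src`
#'   is the `(1, M, M, N)` patch score map (unbounded reals, Wasserstein
#'   critic) and `cls` the `(K, N)` domain logits.
#' @export
build_discriminator <- function(spec) {
  C <- spec$channels; K <- spec$n_domains; ndf <- spec$base_width
  widths <- pmin(ndf * 2^(seq_len(spec$n_conv) - 1), 8 * ndf)
  p <- list()
  cin <- C
  for (i in seq_len(spec$n_conv)) {
    p[[paste0("c", i, ".W")]] <- init_conv(widths[i], cin, 4)
    p[[paste0("c", i, ".b")]] <- matrix(0, widths[i], 1)
    cin <- widths[i]
  }
  m <- patch_map_size(spec)
  p$src.W <- init_conv(1, cin, 3); p$src.b <- matrix(0, 1, 1)
  p$cls.W <- init_conv(K, cin, m); p$cls.b <- matrix(0, K, 1)

  forward <- function(pn, x, train = FALSE) {
    if (!inherits(x, "dstensor")) x <- dconst(x)
    h <- x
    for (i in seq_len(spec$n_conv)) {
      h <- d_lrelu(nn_conv(h, pn[[paste0("c", i, ".W")]],
                           pn[[paste0("c", i, ".b")]], 4, 2, 1), 0.01)
    }
    src <- nn_conv(h, pn$src.W, pn$src.b, 3, 1, 1)
    cls <- nn_conv(h, pn$cls.W, pn$cls.b, m, 1, 0)
    list(src = src, cls = d_reshape(cls, c(K, dim(x$value)[4])))
  }
  new_model(p, forward, spec, "discriminator")
}

#' Task-network specification
#'
#' Either a small LeNet-style CNN (default: two 5x5 convolutions with 2x2 max
#' pooling, then two fully connected layers) or the same convolutional
#' feature extractor followed by a dense head of two fully connected layers
#' (1,000 and 100 hidden units) with batch normalization, ReLU and 50%
#' dropout before a linear classifier.
#'
#' @param image_size input spatial size (multiple of 4).
#' @param channels image channels.
#' @param n_classes number of class logits N.
#' @param backbone `"small_cnn"` or `"dense_head"`.
#' @param conv_widths widths of the two convolutions.
#' @param fc_width hidden width of the small CNN's fully connected layer.
#' @param head_widths hidden widths of the dense head.
#' @param dropout dropout probability in the dense head.
#' @return a `task_net_spec` list.
#' @export
task_net_spec <- function(image_size = 32, channels = 3, n_classes = 10,
                          backbone = c("small_cnn", "dense_head"),
                          conv_widths = c(8, 16), fc_width = 64,
                          head_widths = c(1000, 100), dropout = 0.5) {
  backbone <- match.arg(backbone)
  if (image_size %% 4 != 0) stop("image_size must be a multiple of 4")
  structure(list(image_size = image_size, channels = channels,
                 n_classes = n_classes, backbone = backbone,
                 conv_widths = conv_widths, fc_width = fc_width,
                 head_widths = head_widths, dropout = dropout),
            class = "task_net_spec")
}

#' Build a task (classification) network
#'
#' @param spec a [task_net_spec()].
#' @return a `ds_model`; its forward maps an image node `(C, H, W, N)` to
#'   `(n_classes, N)` logits. Dropout and batch normalization are active only
#'   when `train = TRUE`.
#' @export
build_task_net <- function(spec) {
  cw <- spec$conv_widths
  flat <- cw[2] * (spec$image_size / 4)^2
  p <- list()
  p$c1.W <- init_conv(cw[1], spec$channels, 5); p$c1.b <- matrix(0, cw[1], 1)
  p$c2.W <- init_conv(cw[2], cw[1], 5);         p$c2.b <- matrix(0, cw[2], 1)
  if (spec$backbone == "small_cnn") {
    p$f1.W <- init_dense(spec$fc_width, flat)
    p$f1.b <- matrix(0, spec$fc_width, 1)
    p$out.W <- init_dense(spec$n_classes, spec$fc_width)
    p$out.b <- matrix(0, spec$n_classes, 1)
  } else {
    hw <- spec$head_widths
    p$f1.W <- init_dense(hw[1], flat);  p$f1.b <- matrix(0, hw[1], 1)
    p$f1.g <- matrix(1, hw[1], 1);      p$f1.be <- matrix(0, hw[1], 1)
    p$f2.W <- init_dense(hw[2], hw[1]); p$f2.b <- matrix(0, hw[2], 1)
    p$f2.g <- matrix(1, hw[2], 1);      p$f2.be <- matrix(0, hw[2], 1)
    p$out.W <- init_dense(spec$n_classes, hw[2])
    p$out.b <- matrix(0, spec$n_classes, 1)
  }

  model <- NULL  # assigned below so forward can reach $state for batch norm
  forward <- function(pn, x, train = FALSE) {
    if (!inherits(x, "dstensor")) x <- dconst(x)
    h <- d_maxpool2(d_relu(nn_conv(x, pn$c1.W, pn$c1.b, 5, 1, 2)))
    h <- d_maxpool2(d_relu(nn_conv(h, pn$c2.W, pn$c2.b, 5, 1, 2)))
    h <- nn_flatten(h)
    if (spec$backbone == "small_cnn") {
      h <- d_relu(nn_dense(h, pn$f1.W, pn$f1.b))
      nn_dense(h, pn$out.W, pn$out.b)
    } else {
      h <- nn_dense(h, pn$f1.W, pn$f1.b)
      h <- nn_dropout(d_relu(nn_batchnorm(h, pn$f1.g, pn$f1.be, model$state,
                                          "f1", train)), spec$dropout, train)
      h <- nn_dense(h, pn$f2.W, pn$f2.b)
      h <- nn_dropout(d_relu(nn_batchnorm(h, pn$f2.g, pn$f2.be, model$state,
                                          "f2", train)), spec$dropout, train)
      nn_dense(h, pn$out.W, pn$out.b)
    }
  }
  model <- new_model(p, forward, spec, "task_net")
  model
}

#' Class probabilities / logits for an image set
#'
#' Runs a task network in evaluation mode over an [image_set()] in
#' mini-batches.
#'
#' @param object a task-net `ds_model`.
#' @param newdata an [image_set()].
#' @param type `"prob"` for softmax probabilities or `"logit"`.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return an `N x n_classes` matrix.
#' @export
predict.ds_model <- function(object, newdata, type = c("prob", "logit"),
                             batch_size = 250, ...) {
  stopifnot(object$kind == "task_net")
  type <- match.arg(type)
  x <- internal_layout(newdata$images)
  n <- dim(x)[4]
  pn <- .cnodes(object$params)
  out <- matrix(NA_real_, n, object$spec$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    z <- dval(object$forward(pn, dconst(x[, , , idx, drop = FALSE]),
                             train = FALSE))
    out[idx, ] <- t(z)
  }
  if (type == "prob") {
    e <- exp(out - apply(out, 1, max))
    out <- e / rowSums(e)
  }
  out
}

# deep-copy a model: rebuild the architecture (so the forward closure binds
# the new state environment), then copy parameters and state over
clone_model <- function(model) {
  m <- switch(model$kind,
              task_net = build_task_net(model$spec),
              generator = build_generator(model$spec),
              discriminator = build_discriminator(model$spec))
  m$params <- model$params
  for (nm in ls(model$state)) m$state[[nm]] <- model$state[[nm]]
  m
}

onehot_code <- function(code, K) {
  m <- matrix(0, K, length(code))
  m[cbind(code + 1L, seq_along(code))] <- 1
  m
}
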