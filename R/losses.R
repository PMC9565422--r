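# Training losses: adversarial (classic saturating and Wasserstein with
# gradient penalty), domain classification on real and translated images,
# cycle consistency, task cross-entropy, semantic consistency, and the final
# discriminator/generator objectives.
#
# Each loss is a pure function of network outputs and labels. Inputs may be
# plain numeric arrays (the value is returned as a numeric scalar) or tape
# nodes (a differentiable node is returned); a single code path serves both.

as_node <- function(x) if (inherits(x, "dstensor")) x else dconst(x)

.maybe_value <- function(node, inputs) {
  if (any(vapply(inputs, inherits, TRUE, "dstensor"))) node else dval(node)
}

#' Loss weights for the adaptation objectives
#'
#' Defaults are the values used for all experiments: gradient penalty 10,
#' domain classification 1, cycle consistency 10.
#'
#' @param lambda_gp,lambda_cls,lambda_cyc non-negative weights.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_gp = 10, lambda_cls = 1, lambda_cyc = 10) {
  stopifnot(lambda_gp >= 0, lambda_cls >= 0, lambda_cyc >= 0)
  structure(list(lambda_gp = lambda_gp, lambda_cls = lambda_cls,
                 lambda_cyc = lambda_cyc), class = "loss_weights")
}

#' Classic (saturating) adversarial loss
#'
#' `mean(log d_real) + mean(log(1 - d_fake))` with scores interpreted as
#' probabilities in (0, 1). Kept as a reference implementation; training
#' defaults to the Wasserstein objective ([adv_loss_wgan()]).
#'
#' @param d_real,d_fake discriminator probabilities for real and generated
#'   images.
#' @return scalar loss (numeric, or a tape node if inputs are nodes).
#' @export
adv_loss_saturating <- function(d_real, d_fake) {
  inputs <- list(d_real, d_fake)
  rv <- if (inherits(d_real, "dstensor")) d_real$value else d_real
  fv <- if (inherits(d_fake, "dstensor")) d_fake$value else d_fake
  if (any(rv <= 0 | rv >= 1) || any(fv <= 0 | fv >= 1)) {
    stop("saturating adversarial loss needs probabilities strictly in (0, 1)")
  }
  out <- d_add(d_mean(d_log(as_node(d_real))),
               d_mean(d_log(d_shift(d_neg(as_node(d_fake)), 1))))
  .maybe_value(out, inputs)
}

#' Wasserstein adversarial loss with gradient penalty
#'
#' `mean(d_real) - mean(d_fake) - lambda_gp * gp`. The critic maximizes this
#' quantity; the generator minimizes its fake term.
#'
#' @param d_real,d_fake critic scores (unbounded reals; patch maps are
#'   averaged by the caller or passed whole, the mean is taken here).
#' @param gp gradient penalty term, see [gradient_penalty()].
#' @param lambda_gp penalty weight (default 10).
#' @return scalar loss (numeric or tape node).
#' @export
adv_loss_wgan <- function(d_real, d_fake, gp = 0, lambda_gp = 10) {
  gv <- if (inherits(gp, "dstensor")) gp$value else gp
  if (gv < 0) stop("gradient penalty must be non-negative")
  inputs <- list(d_real, d_fake, gp)
  out <- d_sub(d_sub(d_mean(as_node(d_real)), d_mean(as_node(d_fake))),
               d_scale(as_node(gp), lambda_gp))
  .maybe_value(out, inputs)
}

#' Gradient penalty on interpolated samples
#'
#' Draws `x_hat = alpha * x_real + (1 - alpha) * x_fake` with `alpha ~
#' U(0, 1)` per item, and returns the batch mean of
#' `(||grad_{x_hat} D_src(x_hat)||_2 - 1)^2`, the gradient norm taken over
#' all pixels of each item. The result is a tape node differentiable with
#' respect to the critic parameters used inside `d_src_fn`.
#'
#' @param d_src_fn function mapping an image node `(C, H, W, N)` to per-item
#'   critic scores (any shape whose per-item slices sum independently; the
#'   patch map is fine).
#' @param x_real,x_fake numeric arrays `(C, H, W, N)` of equal shape.
#' @param alpha optional numeric vector of mixing weights (drawn uniformly
#'   when omitted).
#' @return scalar tape node.
#' @export
gradient_penalty <- function(d_src_fn, x_real, x_fake, alpha = NULL) {
  if (inherits(x_real, "dstensor")) x_real <- x_real$value
  if (inherits(x_fake, "dstensor")) x_fake <- x_fake$value
  stopifnot(identical(dim(x_real), dim(x_fake)))
  dm <- dim(x_real)
  N <- dm[4]
  if (is.null(alpha)) alpha <- runif(N)
  am <- array(rep(alpha, each = prod(dm[1:3])), dm)
  xh <- dparam(am * x_real + (1 - am) * x_fake)
  s <- d_src_fn(xh)
  if (is.list(s) && !inherits(s, "dstensor")) s <- s$src
  g <- dst_grad(d_sum(s), list(xh))[[1]]
  gm <- d_reshape(g, c(prod(dm[1:3]), N))
  sq <- d_matmul(dconst(matrix(1, 1, prod(dm[1:3]))), d_square(gm))
  nrm <- d_sqrt(sq)
  d_mean(d_square(d_shift(nrm, -1)))
}

# mean negative log-likelihood of softmax(logits) at 0-based labels
.nll <- function(logits, labels, K) {
  lv <- if (inherits(logits, "dstensor")) logits$value else logits
  if (any(labels < 0 | labels >= K)) {
    stop("label index outside 0..", K - 1)
  }
  nn_cross_entropy(as_node(logits), as.integer(labels))
}

#' Domain-classification loss on real images (critic head)
#'
#' Mean negative log-likelihood of the critic's domain head at the true
#' domain of each (real) image.
#'
#' @param d_cls_logits `(K, N)` domain logits (node or matrix).
#' @param true_domain integer domain codes in `0..K-1`.
#' @return scalar loss (numeric or tape node).
#' @export
cls_loss_real <- function(d_cls_logits, true_domain) {
  lv <- if (inherits(d_cls_logits, "dstensor")) d_cls_logits$value else d_cls_logits
  out <- .nll(d_cls_logits, true_domain, nrow(lv))
  .maybe_value(out, list(d_cls_logits))
}

#' Domain-classification loss on translated images (generator side)
#'
#' Mean negative log-likelihood of the critic's domain head, evaluated on
#' `G(x, c)`, at the requested target domain `c`. Identical arithmetic to
#' [cls_loss_real()]; gradients flow to the generator because the translated
#' images carry the generator's tape history.
#'
#' @param d_cls_logits_fake `(K, N)` domain logits of translated images.
#' @param target_domain integer target codes in `0..K-1`.
#' @return scalar loss (numeric or tape node).
#' @export
cls_loss_fake <- function(d_cls_logits_fake, target_domain) {
  cls_loss_real(d_cls_logits_fake, target_domain)
}

#' Cycle-consistency loss
#'
#' Mean absolute pixel difference between `x` and its reconstruction
#' `G(G(x, c), c')`. The L1 norm is averaged over pixels and batch so the
#' weight `lambda_cyc` is image-size-invariant.
#'
#' @param x original images (array or node).
#' @param x_rec reconstructed images of the same shape.
#' @return scalar loss (numeric or tape node).
#' @export
cycle_loss <- function(x, x_rec) {
  out <- d_mean(d_abs(d_sub(as_node(x), as_node(x_rec))))
  .maybe_value(out, list(x, x_rec))
}

#' Task (classification) cross-entropy
#'
#' Mean cross-entropy of `softmax(F(x))` at labels `y`.
#'
#' @param logits `(N_classes, B)` logits (node or matrix).
#' @param y integer class labels in `0..N_classes-1`.
#' @return scalar loss (numeric or tape node).
#' @export
task_loss <- function(logits, y) {
  lv <- if (inherits(logits, "dstensor")) logits$value else logits
  out <- .nll(logits, y, nrow(lv))
  .maybe_value(out, list(logits))
}

#' Semantic-consistency loss
#'
#' Sum of three task losses that tie labels to images across translation:
#' the target net on source images translated to the target domain (true
#' source labels); the frozen source net on cycle reconstructions (true
#' source labels); and the frozen source net on target images translated to
#' the source domain, scored against the target net's hard (argmax)
#' predictions on the original target images as pseudo-labels.
#'
#' @param ft_logits_trans `(N, B_s)` target-net logits on `G(x_s, c)`.
#' @param fs_logits_cyc `(N, B_s)` source-net logits on `G(G(x_s, c), c')`.
#' @param fs_logits_tgt `(N, B_t)` source-net logits on `G(x_t, c')`.
#' @param y_s source labels.
#' @param pseudo_t hard pseudo-labels `argmax F_T(x_t)` for the target items.
#' @return scalar loss (numeric or tape node).
#' @export
semantic_loss <- function(ft_logits_trans, fs_logits_cyc, fs_logits_tgt,
                          y_s, pseudo_t) {
  out <- d_add(d_add(.as_loss_node(ft_logits_trans, y_s),
                     .as_loss_node(fs_logits_cyc, y_s)),
               .as_loss_node(fs_logits_tgt, pseudo_t))
  .maybe_value(out, list(ft_logits_trans, fs_logits_cyc, fs_logits_tgt))
}

.as_loss_node <- function(logits, y) {
  lv <- if (inherits(logits, "dstensor")) logits$value else logits
  .nll(logits, y, nrow(lv))
}

#' Final discriminator objective
#'
#' `L_D = -L_adv + lambda_cls * L_cls_real`, with the gradient penalty kept
#' inside `L_adv` (so the critic minimizes `-mean(real) + mean(fake) +
#' lambda_gp * gp + lambda_cls * L_cls_real`).
#'
#' @param adv adversarial loss ([adv_loss_wgan()] value, penalty included).
#' @param cls_real real-image domain-classification loss.
#' @param weights a [loss_weights()].
#' @return scalar objective (numeric or tape node).
#' @export
discriminator_objective <- function(adv, cls_real, weights = loss_weights()) {
  out <- d_add(d_neg(as_node(adv)),
               d_scale(as_node(cls_real), weights$lambda_cls))
  .maybe_value(out, list(adv, cls_real))
}

#' Final generator objective
#'
#' `L_G = L_adv + lambda_cls * L_cls_fake + lambda_cyc * L_cyc + L_sem`.
#'
#' @param adv adversarial loss as seen by the generator.
#' @param cls_fake translated-image domain-classification loss.
#' @param cyc cycle-consistency loss.
#' @param sem semantic-consistency loss.
#' @param weights a [loss_weights()].
#' @return scalar objective (numeric or tape node).
#' @export
generator_objective <- function(adv, cls_fake, cyc, sem,
                                weights = loss_weights()) {
  out <- d_add(d_add(as_node(adv),
                     d_scale(as_node(cls_fake), weights$lambda_cls)),
               d_add(d_scale(as_node(cyc), weights$lambda_cyc),
                     as_node(sem)))
  .maybe_value(out, list(adv, cls_fake, cyc, sem))
}
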