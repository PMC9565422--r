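# Adam optimizer on flat named parameter lists, and the adaptation learning
# rate schedule (constant for the first half of training, then linear decay
# to exactly zero at the final iteration).

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# gradients of a scalar node with respect to a named list of parameter nodes
param_grads <- function(loss, pnodes) {
  gs <- dst_grad(loss, unname(pnodes))
  setNames(lapply(gs, dval), names(pnodes))
}

#' Adaptation learning-rate schedule
#'
#' The learning rate stays at `cfg$lr` for the first half of training and
#' then decays linearly, reaching exactly zero at the final iteration.
#'
#' @param iter iteration index in `0..cfg$iterations`.
#' @param cfg an [adaptation_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(iter, cfg) {
  total <- cfg$iterations
  if (iter > total) stop("iter ", iter, " exceeds total iterations ", total)
  half <- total / 2
  if (iter <= half) cfg$lr else cfg$lr * (1 - (iter - half) / half)
}
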