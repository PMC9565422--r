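# Training procedures: baseline classifier training with early stopping on
# validation AUC, adversarial adaptation training (the 5:1
# critic/generator loop with interleaved task-net updates), and the
# translate-then-fine-tune step that produces the adapted classifier.

#' Classifier training configuration
#'
#' Defaults follow the small-CNN protocol: Adam, learning rate 0.001, batch
#' size 128, at most 200 epochs with early stopping once validation AUC
#' fails to improve for 10 consecutive epochs. The dense-backbone protocol
#' uses learning rate 2e-4, weight decay 5e-4 and batch size 50.
#'
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param weight_decay L2 penalty added to gradients.
#' @param augment apply random affine augmentation (flips, small rotations
#'   and translations) to training batches.
#' @param beta1,beta2 Adam moment decays.
#' @param seed integer seed (weight init, batch order, augmentation).
#' @return a `classifier_config`.
#' @export
classifier_config <- function(lr = 0.001, batch_size = 128, max_epochs = 200,
                              patience = 10, weight_decay = 0,
                              augment = FALSE, beta1 = 0.9, beta2 = 0.999,
                              seed = 1) {
  stopifnot(patience >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, augment = augment,
                 beta1 = beta1, beta2 = beta2, seed = seed),
            class = "classifier_config")
}

# random flips/rotations/translations on a (C, H, W, N) batch
augment_images <- function(x, max_shift = 2, max_rot = 10 * pi / 180,
                           flip = TRUE) {
  dm <- dim(x)
  H <- dm[2]; W <- dm[3]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W); gx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(dm[4])) {
    th <- runif(1, -max_rot, max_rot)
    dy <- sample(-max_shift:max_shift, 1)
    dx <- sample(-max_shift:max_shift, 1)
    fl <- flip && runif(1) < 0.5
    sy <- round(cy + cos(th) * (gy - cy) - sin(th) * (gx - cx)) + dy
    sx0 <- if (fl) 2 * cx - gx else gx
    sx <- round(cx + sin(th) * (gy - cy) + cos(th) * (sx0 - cx)) + dx
    ok <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
    sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
    for (c in seq_len(dm[1])) {
      ch <- x[c, , , i]
      out <- ch[cbind(as.vector(sy), as.vector(sx))]
      out[!ok] <- 0
      x[c, , , i] <- matrix(out, H, W)
    }
  }
  x
}

as_task_model <- function(f) {
  if (inherits(f, "ds_classifier")) f$model else f
}

#' Early-stopping rule on a validation-AUC sequence
#'
#' Training stops after the first run of `patience` consecutive epochs with
#' no strict improvement over the best validation AUC so far. This pure
#' function applies the rule to a (possibly hypothetical) AUC sequence and
#' returns the number of epochs that would be run; [train_classifier()]
#' implements the same rule incrementally.
#'
#' @param val_aucs chronological validation AUCs, one per epoch.
#' @param patience consecutive non-improving epochs tolerated.
#' @return number of epochs run (length of the sequence if never triggered).
#' @export
early_stop_epochs <- function(val_aucs, patience = 10) {
  best <- -Inf
  bad <- 0L
  for (i in seq_along(val_aucs)) {
    if (val_aucs[i] > best) {
      best <- val_aucs[i]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(i)
    }
  }
  length(val_aucs)
}

#' Train a task classifier with early stopping on validation AUC
#'
#' Minimizes categorical cross-entropy with Adam. After every epoch the
#' macro (one-vs-rest) AUC on the validation set is computed; training stops
#' at `max_epochs` or once validation AUC has not improved for `patience`
#' consecutive epochs, and the returned model is the checkpoint with the
#' best validation AUC.
#'
#' @param train,val disjoint [image_set()]s; `val` must contain at least two
#'   classes.
#' @param cfg a [classifier_config()].
#' @param spec a [task_net_spec()] (defaults to a small CNN matching the
#'   data dimensions).
#' @param init_model optional `ds_model` (or `ds_classifier`) to start from,
#'   used by fine-tuning.
#' @return a `ds_classifier`: list with `$model`, `$history` (tibble of
#'   epoch, train_loss, val_auc), `$best_epoch`, `$best_val_auc`.
#' @export
train_classifier <- function(train, val, cfg = classifier_config(),
                             spec = NULL, init_model = NULL) {
  if (length(unique(val$class_labels)) < 2) {
    stop("validation AUC undefined: validation set has a single class")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  if (!is.null(init_model)) {
    model <- clone_model(as_task_model(init_model))
  } else {
    if (is.null(spec)) {
      dm <- dim(train$images)
      spec <- task_net_spec(image_size = dm[1], channels = dm[3],
                            n_classes = train$n_classes)
    }
    model <- build_task_net(spec)
  }
  if (cfg$max_epochs == 0) {
    return(structure(list(model = model,
                          history = tibble::tibble(epoch = integer(),
                                                   train_loss = numeric(),
                                                   val_auc = numeric()),
                          best_epoch = 0L,
                          best_val_auc = NA_real_, cfg = cfg),
                     class = "ds_classifier"))
  }
  x <- internal_layout(train$images)
  y <- train$class_labels
  n <- dim(x)[4]
  opt <- adam_init(model$params)
  best <- list(params = model$params, state_snapshot = NULL,
               val_auc = -Inf, epoch = 0L)
  bad <- 0L
  hist_epoch <- integer(); hist_loss <- numeric(); hist_auc <- numeric()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      if (length(idx) < 2) next
      xb <- x[, , , idx, drop = FALSE]
      if (cfg$augment) xb <- augment_images(xb)
      pn <- .pnodes(model$params)
      logits <- model$forward(pn, dconst(xb), train = TRUE)
      loss <- task_loss(logits, y[idx])
      grads <- param_grads(loss, pn)
      up <- adam_step(model$params, grads, opt, cfg$lr, cfg$beta1, cfg$beta2,
                      weight_decay = cfg$weight_decay)
      model$params <- up$params; opt <- up$state
      losses <- c(losses, dval(loss))
    }
    va <- macro_auc(predict(model, val), val$class_labels)
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, mean(losses))
    hist_auc <- c(hist_auc, va)
    if (va > best$val_auc) {
      best <- list(params = model$params,
                   state_snapshot = as.list(model$state),
                   val_auc = va, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  model$params <- best$params
  if (!is.null(best$state_snapshot)) {
    for (nm in names(best$state_snapshot)) model$state[[nm]] <- best$state_snapshot[[nm]]
  }
  structure(list(model = model,
                 history = tibble::tibble(epoch = hist_epoch,
                                          train_loss = hist_loss,
                                          val_auc = hist_auc),
                 best_epoch = best$epoch, best_val_auc = best$val_auc,
                 cfg = cfg),
            class = "ds_classifier")
}

#' @export
print.ds_classifier <- function(x, ...) {
  cat("<ds_classifier: best val AUC ", round(x$best_val_auc, 4),
      " at epoch ", x$best_epoch, " (", nrow(x$history), " epochs)>\n",
      sep = "")
  invisible(x)
}

#' @export
predict.ds_classifier <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Adaptation training configuration
#'
#' Defaults follow the adaptation protocol: Adam with `beta1 = 0.5`,
#' `beta2 = 0.999`, learning rate 1e-4 decaying linearly to zero over the
#' second half of training, five critic updates per generator update, task
#' nets updated every generator update (every 10 for unstable pairs), even
#' source/target batch split.
#'
#' @param iterations total generator iterations (200,000 at full scale;
#'   3,000 for the desk preset).
#' @param batch_size mixed batch size (200 digit scale, 20 radiograph scale).
#' @param lr initial learning rate.
#' @param n_critic critic updates per generator update.
#' @param task_update_period generator updates between task-net updates.
#' @param weights a [loss_weights()].
#' @param balance_by_class class-balance the source half of each batch.
#' @param g_base_width,d_base_width,n_res architecture widths/depth.
#' @param adv_loss `"wgan_gp"` (training default) or `"saturating"`
#'   (reference implementation).
#' @param checkpoint_every save a checkpoint every this many iterations
#'   (0 disables); requires `checkpoint_dir`.
#' @param checkpoint_dir directory for checkpoints.
#' @param log_every record component losses every this many iterations.
#' @param seed master seed; fans out to weight init, batch order and the
#'   gradient-penalty mixing weights.
#' @return an `adaptation_config`.
#' @export
adaptation_config <- function(iterations = 3000, batch_size = 32, lr = 1e-4,
                              n_critic = 5, task_update_period = 1,
                              weights = loss_weights(),
                              balance_by_class = FALSE,
                              g_base_width = 32, d_base_width = 32,
                              n_res = 4,
                              adv_loss = c("wgan_gp", "saturating"),
                              checkpoint_every = 0, checkpoint_dir = NULL,
                              log_every = 1, seed = 1) {
  adv_loss <- match.arg(adv_loss)
  stopifnot(iterations >= 0, batch_size >= 2, n_critic >= 1,
            task_update_period >= 1)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 n_critic = as.integer(n_critic),
                 task_update_period = as.integer(task_update_period),
                 weights = weights, balance_by_class = balance_by_class,
                 g_base_width = g_base_width, d_base_width = d_base_width,
                 n_res = n_res, adv_loss = adv_loss,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir,
                 log_every = as.integer(log_every), seed = seed),
            class = "adaptation_config")
}

.check_finite <- function(value, component, iter) {
  if (!all(is.finite(value))) {
    stop("non-finite ", component, " at iteration ", iter,
         "; aborting adaptation", call. = FALSE)
  }
  value
}

#' Adversarial adaptation training
#'
#' Trains a single conditional generator and critic pair on unlabeled images
#' from two domains. Per generator step the critic is updated `n_critic`
#' times on fresh mixed batches (Wasserstein loss with gradient penalty plus
#' the real-image domain-classification term), the generator once
#' (adversarial + domain-classification + cycle-consistency + semantic
#' losses), and the target task net is fine-tuned on translated source
#' images every `task_update_period` generator steps. Target-domain class
#' labels are discarded at entry and never read (unsupervised contract);
#' only evaluation code sees them.
#'
#' @param source labeled [image_set()] of the source domain.
#' @param target [image_set()] of the target domain; class labels ignored.
#' @param f_s source task network (a `ds_classifier` from
#'   [train_classifier()] or a bare `ds_model`), used frozen.
#' @param cfg an [adaptation_config()].
#' @return a `ds_adaptation`: generator `G`, critic `D`, frozen source net
#'   `F_S`, fine-tuned target net `F_T`, the per-update loss `history`
#'   tibble, and the domain-code mapping.
#' @export
train_adaptation <- function(source, target, f_s, cfg = adaptation_config()) {
  fs_model <- as_task_model(f_s)
  # unsupervised contract: drop target class labels before anything else
  target$class_labels <- rep(NA_integer_, length(target))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  batch_seed <- sample.int(.Machine$integer.max - 1, 1)

  dm <- dim(source$images)
  gspec <- generator_spec(image_size = dm[1], channels = dm[3],
                          n_domains = 2, n_res = cfg$n_res,
                          base_width = cfg$g_base_width)
  dspec <- discriminator_spec(image_size = dm[1], channels = dm[3],
                              n_domains = 2, base_width = cfg$d_base_width)
  G <- build_generator(gspec)
  D <- build_discriminator(dspec)
  FT <- clone_model(fs_model)

  plan <- batch_plan(cfg$batch_size, even_domain_split = TRUE,
                     balance_by_class = cfg$balance_by_class,
                     seed = batch_seed)
  next_batch <- iterate_batches(source, target, plan)

  opt_g <- adam_init(G$params)
  opt_d <- adam_init(D$params)
  opt_f <- adam_init(FT$params)
  w <- cfg$weights

  hist <- vector("list", 2048L); nh <- 0L
  log_row <- function(iter, phase, ...) {
    nh <<- nh + 1L
    if (nh > length(hist)) length(hist) <<- 2L * nh
    hist[[nh]] <<- tibble::tibble(iteration = iter, phase = phase, ...)
  }

  for (iter in seq_len(cfg$iterations)) {
    lr <- lr_schedule(iter, cfg)
    do_log <- (iter %% cfg$log_every == 0) || iter == cfg$iterations

    for (j in seq_len(cfg$n_critic)) {
      b <- next_batch()
      code <- as.integer(!b$is_source)      # 0 = source, 1 = target
      c_t <- 1L - code
      fake <- dval(G$forward(.cnodes(G$params), dconst(b$x),
                             onehot_code(c_t, 2)))
      Dp <- .pnodes(D$params)
      dr <- D$forward(Dp, dconst(b$x))
      df <- D$forward(Dp, dconst(fake))
      if (cfg$adv_loss == "wgan_gp") {
        gp <- gradient_penalty(function(xh) D$forward(Dp, xh)$src,
                               b$x, fake, alpha = runif(cfg$batch_size))
        adv <- adv_loss_wgan(d_mean(dr$src), d_mean(df$src), gp,
                             w$lambda_gp)
      } else {
        gp <- dconst(0)
        adv <- adv_loss_saturating(.sigmoid_node(dr$src), .sigmoid_node(df$src))
      }
      clsr <- cls_loss_real(dr$cls, code)
      ld <- discriminator_objective(adv, clsr, w)
      .check_finite(dval(ld), "discriminator loss", iter)
      grads <- param_grads(ld, Dp)
      up <- adam_step(D$params, grads, opt_d, lr, 0.5, 0.999)
      D$params <- up$params; opt_d <- up$state
      if (do_log) {
        log_row(iter, "critic", loss_d = dval(ld), adv = dval(adv),
                gp = dval(gp), cls_real = dval(clsr))
      }
    }

    b <- next_batch()
    code <- as.integer(!b$is_source)
    c_t <- 1L - code
    sidx <- which(b$is_source); tidx <- which(!b$is_source)
    Gp <- .pnodes(G$params)
    Dc <- .cnodes(D$params)
    Fsc <- .cnodes(fs_model$params)
    Ftc <- .cnodes(FT$params)
    xn <- dconst(b$x)
    fake <- G$forward(Gp, xn, onehot_code(c_t, 2))
    dfake <- D$forward(Dc, fake)
    mean_real <- mean(dval(D$forward(Dc, xn)$src))
    adv_g <- d_shift(d_neg(d_mean(dfake$src)), mean_real)
    clsf <- cls_loss_fake(dfake$cls, c_t)
    rec <- G$forward(Gp, fake, onehot_code(code, 2))
    cyc <- cycle_loss(xn, rec)
    ft_tr <- FT$forward(Ftc, d_slice4(fake, sidx))
    fs_cy <- fs_model$forward(Fsc, d_slice4(rec, sidx))
    fs_tg <- fs_model$forward(Fsc, d_slice4(fake, tidx))
    xt_cont <- container_layout(b$x[, , , tidx, drop = FALSE])
    pseudo <- max.col(predict(FT, image_set(
      xt_cont, rep(0L, length(tidx)), rep(0L, length(tidx)),
      n_classes = FT$spec$n_classes, n_domains = 1L), type = "logit")) - 1L
    sem <- semantic_loss(ft_tr, fs_cy, fs_tg, b$class[sidx], pseudo)
    lg <- generator_objective(adv_g, clsf, cyc, sem, w)
    for (nmv in list(list("generator adversarial loss", dval(adv_g)),
                     list("generator domain-classification loss", dval(clsf)),
                     list("cycle loss", dval(cyc)),
                     list("semantic loss", dval(sem)))) {
      .check_finite(nmv[[2]], nmv[[1]], iter)
    }
    grads <- param_grads(lg, Gp)
    up <- adam_step(G$params, grads, opt_g, lr, 0.5, 0.999)
    G$params <- up$params; opt_g <- up$state
    if (do_log) {
      log_row(iter, "generator", loss_g = dval(lg), adv = dval(adv_g),
              cls_fake = dval(clsf), cyc = dval(cyc), sem = dval(sem))
    }

    if (iter %% cfg$task_update_period == 0 && length(sidx) > 0) {
      Ftp <- .pnodes(FT$params)
      logits <- FT$forward(Ftp, dconst(dval(fake)[, , , sidx, drop = FALSE]),
                           train = TRUE)
      lf <- task_loss(logits, b$class[sidx])
      .check_finite(dval(lf), "task-net loss", iter)
      grads <- param_grads(lf, Ftp)
      up <- adam_step(FT$params, grads, opt_f, lr, 0.5, 0.999)
      FT$params <- up$params; opt_f <- up$state
      if (do_log) log_row(iter, "task_net", loss_f = dval(lf))
    }

    if (cfg$checkpoint_every > 0 && !is.null(cfg$checkpoint_dir) &&
        iter %% cfg$checkpoint_every == 0) {
      dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(iteration = iter, G = G$params, D = D$params,
                   FT = FT$params, cfg = cfg),
              file.path(cfg$checkpoint_dir,
                        sprintf("checkpoint_%06d.rds", iter)))
    }
  }

  history <- if (nh > 0) dplyr::bind_rows(hist[seq_len(nh)]) else
    tibble::tibble(iteration = integer(), phase = character())
  structure(list(G = G, D = D, F_S = fs_model, F_T = FT,
                 history = history, cfg = cfg,
                 domain_codes = c(source = 0L, target = 1L)),
            class = "ds_adaptation")
}

.sigmoid_node <- function(x) {
  d_recip(d_shift(d_exp(d_neg(x)), 1))
}

#' @export
print.ds_adaptation <- function(x, ...) {
  cat("<ds_adaptation: ", x$cfg$iterations, " iterations, ",
      n_parameters(x$G), " generator / ", n_parameters(x$D),
      " critic parameters>\n", sep = "")
  invisible(x)
}

#' Translate an image set into a target domain
#'
#' Replaces every image by `G(x, target_code)`; class labels are carried
#' over unchanged and domain labels are set to the target code. The mean
#' absolute pixel change is attached as attribute `mean_abs_change`.
#'
#' @param adaptation a `ds_adaptation` (or a generator `ds_model`).
#' @param set an [image_set()].
#' @param target_code domain code to translate into (0 = source, 1 = target
#'   of the adaptation pair).
#' @param batch_size forward batch size.
#' @return an [image_set()].
#' @export
translate_set <- function(adaptation, set, target_code = 1L,
                          batch_size = 64) {
  G <- if (inherits(adaptation, "ds_adaptation")) adaptation$G else adaptation
  x <- internal_layout(set$images)
  n <- dim(x)[4]
  out <- array(0, dim(x))
  pn <- .cnodes(G$params)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    code <- onehot_code(rep(as.integer(target_code), length(idx)), 2)
    out[, , , idx] <- dval(G$forward(pn, dconst(x[, , , idx, drop = FALSE]),
                                     code))
  }
  res <- image_set(container_layout(out), set$class_labels,
                   rep(as.integer(target_code), n),
                   n_classes = set$n_classes, n_domains = set$n_domains)
  attr(res, "mean_abs_change") <- mean(abs(out - x))
  res
}

#' Fine-tune the source classifier on translated images
#'
#' Starts from the source network's weights and applies the same training
#' and early-stopping protocol as [train_classifier()].
#'
#' @param f_s source classifier (`ds_classifier` or `ds_model`).
#' @param translated source-labeled images translated into the target domain.
#' @param val validation set (translated source validation images, so that
#'   target labels are never consulted).
#' @param cfg a [classifier_config()].
#' @return a `ds_classifier`.
#' @export
finetune_on_translated <- function(f_s, translated, val,
                                   cfg = classifier_config()) {
  train_classifier(translated, val, cfg, init_model = as_task_model(f_s))
}
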