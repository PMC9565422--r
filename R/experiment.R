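# One-command experiment harness: synthesize domains, train per-domain
# baselines, adapt across configured pairs, translate + fine-tune, and
# evaluate every deployment strategy. Every numeric result written to the
# run directory is traceable to the config + master seed stored beside it.

#' Experiment configuration presets
#'
#' * `desk`: the desk-scale synthetic digit benchmark — 32x32 glyphs,
#'   2,000/250/250 images per domain, 3,000 adaptation iterations, batch 32.
#' * `micro`: a fast smoke/CI scale — 16x16 glyphs, 600/100/300 per domain,
#'   200 adaptation iterations, narrow networks.
#' * `full_digit`: the full digit-scale protocol (200,000 iterations,
#'   batch 200, 32x32).
#' * `full_cxr`: the full radiograph-scale protocol (224x224, 9 residual
#'   blocks, batch 20, class-balanced batches, dense-head task net with
#'   affine augmentation).
#'
#' @param preset preset name.
#' @param seed master seed; all stage seeds are derived from it.
#' @param ... named overrides merged into the preset (e.g. `n_domains = 3`).
#' @return a `run_config` list.
#' @export
run_config <- function(preset = c("desk", "micro", "full_digit",
                                  "full_cxr"),
                       seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(
      task = "digitlike", image_size = 32, n_per_domain = 2500,
      fractions = c(0.8, 0.1, 0.1), severities = c(0, 1),
      classifier = classifier_config(lr = 0.001, batch_size = 128,
                                     max_epochs = 200, patience = 10),
      adaptation = adaptation_config(iterations = 3000, batch_size = 32,
                                     g_base_width = 32, d_base_width = 32,
                                     n_res = 4),
      eval_n_rep = 1000, eval_rep_size = 1000,
      backbone = "small_cnn", spread_fractions = numeric(0)),
    micro = list(
      task = "digitlike", image_size = 16, n_per_domain = 1000,
      fractions = c(0.6, 0.1, 0.3), severities = c(0, 1),
      classifier = classifier_config(lr = 0.001, batch_size = 64,
                                     max_epochs = 30, patience = 10),
      adaptation = adaptation_config(iterations = 200, batch_size = 16,
                                     g_base_width = 8, d_base_width = 8,
                                     n_res = 2),
      eval_n_rep = 200, eval_rep_size = 300,
      backbone = "small_cnn", spread_fractions = numeric(0)),
    full_digit = list(
      task = "digitlike", image_size = 32, n_per_domain = 50000,
      fractions = c(0.8, 0.1, 0.1), severities = c(0, 1),
      classifier = classifier_config(lr = 0.001, batch_size = 128,
                                     max_epochs = 200, patience = 10),
      adaptation = adaptation_config(iterations = 200000, batch_size = 200,
                                     g_base_width = 64, d_base_width = 64,
                                     n_res = 4),
      eval_n_rep = 1000, eval_rep_size = 1000,
      backbone = "small_cnn",
      spread_fractions = c(0.001, 0.01, 0.1, 1)),
    full_cxr = list(
      task = "opacitylike", image_size = 224, n_per_domain = 50000,
      fractions = c(0.8, 0.1, 0.1), severities = c(0, 1),
      classifier = classifier_config(lr = 2e-4, batch_size = 50,
                                     max_epochs = 200, patience = 10,
                                     weight_decay = 5e-4, augment = TRUE),
      adaptation = adaptation_config(iterations = 200000, batch_size = 20,
                                     g_base_width = 64, d_base_width = 64,
                                     n_res = 9, balance_by_class = TRUE),
      eval_n_rep = 1000, eval_rep_size = 1000,
      backbone = "dense_head",
      spread_fractions = c(0.001, 0.01, 0.1, 1)))
  cfg <- modifyList(base, list(...))
  cfg$preset <- preset
  cfg$seed <- seed
  structure(cfg, class = "run_config")
}

.derive_seeds <- function(seed, n) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, n)
}

#' Run the full adaptation experiment
#'
#' Executes synth -> per-domain baselines -> adaptation (per ordered domain
#' pair) -> translate + fine-tune -> evaluation, writing the configuration,
#' stage outputs, loss histories and JSON reports into `out_dir`. Stages
#' whose output file already exists are reloaded, so an interrupted run
#' resumes from its last completed stage.
#'
#' @param config a [run_config()].
#' @param out_dir run directory; created if missing. `NULL` keeps everything
#'   in memory and writes nothing.
#' @param pairs list of ordered source-target domain pairs (0-based codes);
#'   default adapts domain 0 to every other domain.
#' @param dry_run print the stage plan and return it without computing.
#' @param quiet suppress console progress.
#' @return a `ds_experiment` list: `$data`, `$baselines`, `$adaptations`,
#'   `$adapted`, `$report` (pair-level salvage tibble), `$deployment`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           pairs = NULL, dry_run = FALSE, quiet = FALSE) {
  n_dom <- length(config$severities)
  if (is.null(pairs)) {
    pairs <- lapply(setdiff(seq_len(n_dom) - 1L, 0L), function(t) c(0L, t))
  }
  plan <- c("synth: generate styled domains and splits",
            sprintf("baseline: train %d per-domain classifiers", n_dom),
            sprintf("adapt: %d source->target pair(s)", length(pairs)),
            "finetune: translate source data and fine-tune",
            "eval: AUC/CI, salvage, relative change, deployment report")
  if (dry_run) {
    if (!quiet) cat(paste0(seq_along(plan), ". ", plan, collapse = "\n"), "\n")
    return(invisible(plan))
  }
  say <- function(...) if (!quiet) message(...)
  seeds <- .derive_seeds(config$seed, 6)
  persist <- !is.null(out_dir)
  if (persist) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(.config_as_list(config), file.path(out_dir, "config.yaml"))
  }
  stage <- function(name, fn) {
    f <- if (persist) file.path(out_dir, paste0(name, ".rds")) else NULL
    if (persist && file.exists(f)) {
      say("[", name, "] reusing ", f)
      return(readRDS(f))
    }
    res <- tryCatch(fn(), error = function(e) {
      if (persist) writeLines(conditionMessage(e),
                              file.path(out_dir, paste0("FAILED_", name)))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    if (persist) saveRDS(res, f)
    res
  }

  say("[synth] generating ", n_dom, " domains (", config$task, ", ",
      config$image_size, "px, ", config$n_per_domain, "/domain)")
  data <- stage("synth", function() {
    styles <- lapply(config$severities, style_ladder)
    doms <- make_domains(task_spec(config$task,
                                   n_per_domain = config$n_per_domain,
                                   image_size = config$image_size,
                                   seed = seeds[1]), styles)
    lapply(doms, split_dataset, fractions = config$fractions,
           seed = seeds[2])
  })

  say("[baseline] training per-domain classifiers")
  baselines <- stage("baselines", function() {
    lapply(seq_len(n_dom), function(d) {
      cfg <- config$classifier
      cfg$seed <- seeds[3] + d
      spec <- task_net_spec(image_size = config$image_size, channels = 3,
                            n_classes = data[[d]]$train$n_classes,
                            backbone = config$backbone)
      train_classifier(data[[d]]$train, data[[d]]$val, cfg, spec = spec)
    })
  })

  say("[adapt] ", length(pairs), " pair(s), ",
      config$adaptation$iterations, " iterations each")
  adaptations <- stage("adaptations", function() {
    lapply(pairs, function(pr) {
      acfg <- config$adaptation
      acfg$seed <- seeds[4] + pr[2]
      train_adaptation(data[[pr[1] + 1]]$train, data[[pr[2] + 1]]$train,
                       baselines[[pr[1] + 1]], acfg)
    })
  })

  say("[finetune] translate-then-fine-tune")
  adapted <- stage("adapted", function() {
    out <- list()
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      tr <- translate_set(adaptations[[i]], data[[pr[1] + 1]]$train, 1L)
      va <- translate_set(adaptations[[i]], data[[pr[1] + 1]]$val, 1L)
      cfg <- config$classifier
      cfg$seed <- seeds[5] + i
      out[[paste0(pr[1], "->", pr[2])]] <-
        finetune_on_translated(baselines[[pr[1] + 1]], tr, va, cfg)
    }
    out
  })

  say("[eval] computing reports")
  report <- stage("report", function() {
    rows <- lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      s <- pr[1] + 1; t <- pr[2] + 1
      ev <- function(cl, ts) evaluate_classifier(
        cl, ts, n_rep = config$eval_n_rep, rep_size = config$eval_rep_size,
        seed = seeds[6])
      internal <- ev(baselines[[s]], data[[s]]$test)
      external <- ev(baselines[[s]], data[[t]]$test)
      adapted_ev <- ev(adapted[[i]], data[[t]]$test)
      ceiling_ev <- ev(baselines[[t]], data[[t]]$test)
      tibble::tibble(
        pair = paste0(pr[1], "->", pr[2]),
        internal_auc = internal$auc, internal_lo = internal$ci_low,
        internal_hi = internal$ci_high,
        external_auc = external$auc, external_lo = external$ci_low,
        external_hi = external$ci_high,
        adapted_auc = adapted_ev$auc, adapted_lo = adapted_ev$ci_low,
        adapted_hi = adapted_ev$ci_high,
        ceiling_auc = ceiling_ev$auc,
        abs_change = adapted_ev$auc - external$auc,
        rel_change = relative_change(external$auc, adapted_ev$auc),
        salvage = if (internal$auc > external$auc)
          salvage(internal$auc, external$auc, adapted_ev$auc) else NA_real_)
    })
    dplyr::bind_rows(rows)
  })

  deployment <- stage("deployment", function() {
    test_sets <- lapply(data, `[[`, "test")
    models <- list(local = baselines[[1]], bespoke = baselines,
                   adapted = adapted)
    if (length(config$spread_fractions) > 0) {
      pooled_train <- bind_sets(lapply(data, `[[`, "train"))
      pooled_val <- bind_sets(lapply(data, `[[`, "val"))
      models$global <- lapply(
        setNames(config$spread_fractions, config$spread_fractions),
        function(fr) {
          idx <- .derived_fraction_idx(pooled_train, fr, seeds[6])
          cfg <- config$classifier
          cfg$seed <- seeds[6] + round(1e6 * fr)
          spec <- task_net_spec(image_size = config$image_size, channels = 3,
                                n_classes = pooled_train$n_classes,
                                backbone = config$backbone)
          train_classifier(subset_items(pooled_train, idx), pooled_val, cfg,
                           spec = spec)
        })
    }
    deployment_report(models, test_sets, n_rep = min(config$eval_n_rep, 200),
                      rep_size = config$eval_rep_size, seed = seeds[6])
  })

  if (persist) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", digits = NA)
    readr::write_csv(deployment, file.path(out_dir, "deployment.csv"))
    for (i in seq_along(adaptations)) {
      readr::write_csv(adaptations[[i]]$history,
                       file.path(out_dir, paste0("history_",
                                                 gsub("->", "_to_",
                                                      names(adapted)[i]),
                                                 ".csv")))
    }
  }
  structure(list(config = config, data = data, baselines = baselines,
                 adaptations = adaptations, adapted = adapted,
                 report = report, deployment = deployment,
                 out_dir = out_dir),
            class = "ds_experiment")
}

# stratified subsample of a fraction of a set (at least one item per class)
.derived_fraction_idx <- function(set, fraction, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed + round(1e6 * fraction))
  idx <- unlist(lapply(split(seq_len(length(set)), set$class_labels),
                       function(ix) {
                         k <- max(1L, round(length(ix) * fraction))
                         ix[sample.int(length(ix), k)]
                       }))
  sort(idx)
}

.config_as_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.ds_experiment <- function(x, ...) {
  cat("<ds_experiment: preset", x$config$preset, "seed", x$config$seed, ">\n")
  print(x$report)
  invisible(x)
}
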