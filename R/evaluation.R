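# Deployment evaluation metrics: rank-based AUC (binary and macro
# one-vs-rest), percentile-bootstrap confidence intervals, salvage, relative
# change, domain spread, calibration curves, and the four-strategy
# deployment report.

#' Rank-based AUC
#'
#' Mann-Whitney AUC with average ranks for ties: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro (one-vs-rest) AUC for multiclass scores
#'
#' Averages the binary AUC of each class column against the rest. Classes
#' absent from `labels` are skipped.
#'
#' @param scores `N x K` matrix of per-class scores or probabilities.
#' @param labels integer class labels in `0..K-1`.
#' @return macro-averaged AUC.
#' @export
macro_auc <- function(scores, labels) {
  if (is.null(dim(scores))) return(auc(scores, labels))
  if (ncol(scores) == 2) return(auc(scores[, 2], labels))
  present <- sort(unique(labels))
  present <- present[vapply(present, function(k) any(labels != k), TRUE)]
  mean(vapply(present, function(k) auc(scores[, k + 1], labels == k), 0))
}

#' Percentile-bootstrap confidence interval for AUC
#'
#' Draws `n_rep` bootstrap replicates of size `rep_size` with replacement
#' (capped at the test-set size with a warning when larger) and returns the
#' percentile interval of the replicate AUCs around the full-sample point
#' estimate. Replicates containing a single class are redrawn and counted.
#'
#' @param scores,labels as in [auc()]; multiclass accepted when `scores` is
#'   a matrix (macro AUC is bootstrapped).
#' @param n_rep number of replicates (default 1,000).
#' @param rep_size replicate size (default 1,000).
#' @param alpha interval level (default 0.05 for a 95% CI).
#' @param seed RNG seed for the resampling.
#' @return tibble with `auc`, `ci_low`, `ci_high`, `n_rep`, `rep_size`,
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(scores, labels, n_rep = 1000, rep_size = 1000,
                         alpha = 0.05, seed = 1) {
  n <- length(labels)
  rep_size <- as.integer(rep_size)
  if (n == 0) stop("empty test set")
  if (rep_size > n) {
    warning("rep_size ", rep_size, " exceeds test-set size ", n,
            "; capping at ", n)
    rep_size <- n
  }
  point <- macro_auc(scores, labels)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- numeric(n_rep)
  redrawn <- 0L
  for (i in seq_len(n_rep)) {
    repeat {
      idx <- sample.int(n, rep_size, replace = TRUE)
      lb <- labels[idx]
      if (length(unique(lb)) >= 2) break
      redrawn <- redrawn + 1L
      if (redrawn > 100 * n_rep) stop("cannot draw two-class replicates")
    }
    sc <- if (is.null(dim(scores))) scores[idx] else scores[idx, , drop = FALSE]
    reps[i] <- macro_auc(sc, lb)
  }
  qs <- unname(quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  tibble::tibble(auc = point, ci_low = qs[1], ci_high = qs[2],
                 n_rep = n_rep, rep_size = rep_size, n_redrawn = redrawn)
}

#' Salvage: fraction of the internal-to-external AUC gap recovered
#'
#' `100 * (adapted - external) / (internal - external)`, in percent. Defined
#' only when the internal AUC exceeds the external AUC.
#'
#' @param internal,external,adapted AUCs in percent (or any common scale).
#' @return salvage in percent.
#' @export
salvage <- function(internal, external, adapted) {
  if (internal <= external) {
    stop("salvage undefined: internal AUC (", internal,
         ") must exceed external AUC (", external, ")")
  }
  100 * (adapted - external) / (internal - external)
}

#' Relative change of a metric against a baseline
#'
#' `100 * (other - baseline) / baseline`; a negative value is a relative
#' loss (reported by its magnitude).
#'
#' @param baseline,other metric values; `baseline` must be positive.
#' @return relative change in percent.
#' @export
relative_change <- function(baseline, other) {
  if (baseline <= 0) stop("baseline must be positive")
  100 * (other - baseline) / baseline
}

#' Domain spread: inter-domain variance of per-domain AUCs
#'
#' An a priori indicator of deployment fragility: the variance of one
#' model's AUCs across domain-specific test sets. The convention is
#' population variance of the AUCs in percentage points; sample variance is
#' available as an option.
#'
#' @param per_domain_aucs numeric vector of per-domain AUCs (>= 2 entries).
#' @param type `"population"` (divide by K) or `"sample"` (divide by K-1).
#' @return variance of the per-domain AUCs.
#' @export
domain_spread <- function(per_domain_aucs, type = c("population", "sample")) {
  type <- match.arg(type)
  k <- length(per_domain_aucs)
  if (k < 2) stop("domain spread needs at least 2 domains")
  v <- var(per_domain_aucs) * (k - 1)
  if (type == "population") v / k else v / (k - 1)
}

#' Calibration curve
#'
#' Bins predicted probabilities into `n_bins` equal-width bins over `[0, 1]`
#' and reports, per bin, the mean predicted probability, the observed
#' positive fraction, and the count. Empty bins are emitted with count 0 and
#' `NA` observed fraction.
#'
#' @param probs predicted positive-class probabilities in `[0, 1]`.
#' @param labels binary labels.
#' @param n_bins number of bins.
#' @return a `ds_calibration` tibble: `bin`, `bin_mid`, `mean_pred`,
#'   `obs_frac`, `count`.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  labels <- as.integer(labels)
  bin <- pmin(floor(probs * n_bins), n_bins - 1) + 1
  out <- tibble::tibble(bin = seq_len(n_bins),
                        bin_mid = (seq_len(n_bins) - 0.5) / n_bins,
                        mean_pred = NA_real_, obs_frac = NA_real_,
                        count = 0L)
  for (b in seq_len(n_bins)) {
    in_b <- bin == b
    if (any(in_b)) {
      out$mean_pred[b] <- mean(probs[in_b])
      out$obs_frac[b] <- mean(labels[in_b])
      out$count[b] <- sum(in_b)
    }
  }
  class(out) <- c("ds_calibration", class(out))
  out
}

#' Evaluate a classifier on an image set
#'
#' Computes the AUC point estimate with a bootstrap CI, and optionally a
#' calibration table (binary tasks).
#'
#' @param classifier a `ds_classifier` or task-net `ds_model`.
#' @param test an [image_set()].
#' @param n_rep,rep_size,seed bootstrap settings, see [bootstrap_ci()].
#' @param calibration attach a calibration table (binary tasks only).
#' @return a `ds_eval` tibble row (AUC in percent).
#' @export
evaluate_classifier <- function(classifier, test, n_rep = 1000,
                                rep_size = 1000, seed = 1,
                                calibration = FALSE) {
  probs <- predict(classifier, test)
  ci <- bootstrap_ci(probs, test$class_labels, n_rep = n_rep,
                     rep_size = rep_size, seed = seed)
  out <- tibble::tibble(auc = 100 * ci$auc, ci_low = 100 * ci$ci_low,
                        ci_high = 100 * ci$ci_high, n = length(test),
                        n_rep = ci$n_rep, rep_size = ci$rep_size)
  if (calibration && ncol(probs) == 2) {
    attr(out, "calibration") <- calibration_curve(probs[, 2],
                                                  test$class_labels)
  }
  class(out) <- c("ds_eval", class(out))
  out
}

#' Four-strategy deployment report
#'
#' Evaluates each deployment strategy on each per-domain test set and on the
#' pooled test set:
#' * `local`: one model trained on a single domain, deployed everywhere;
#' * `bespoke`: one model per domain, deployed on its own domain (the
#'   per-domain performance ceiling);
#' * `global`: a single model trained on pooled data, optionally at several
#'   training-data fractions;
#' * `adapted`: translate-then-fine-tune models for specific source-target
#'   pairs.
#'
#' The pooled AUC of a strategy can fall outside the range of its per-domain
#' AUCs; when it does the row is flagged rather than treated as an error.
#'
#' @param models named list with any of: `local` (one classifier),
#'   `bespoke` (list of classifiers indexed by domain code + 1), `global`
#'   (a classifier, or list of classifiers named by data fraction),
#'   `adapted` (named list `"src->tgt"` of classifiers).
#' @param test_sets list of per-domain test [image_set()]s (domain code
#'   order); missing entries yield absent cells.
#' @param n_rep,rep_size,seed bootstrap settings.
#' @return a `ds_deployment` tibble: strategy, variant, eval_domain
#'   (`"pooled"` or the domain code), auc/ci in percent, and a
#'   `pooled_outside_range` flag; the per-strategy [domain_spread()] table is
#'   attached as attribute `spread`.
#' @export
deployment_report <- function(models, test_sets, n_rep = 200,
                              rep_size = 1000, seed = 1) {
  pooled <- bind_sets(test_sets[!vapply(test_sets, is.null, TRUE)])
  rows <- list()
  eval_on <- function(model, strategy, variant) {
    per <- rep(NA_real_, length(test_sets))
    for (d in seq_along(test_sets)) {
      ts <- test_sets[[d]]
      if (is.null(ts)) next
      ev <- evaluate_classifier(model, ts, n_rep = n_rep,
                                rep_size = rep_size, seed = seed)
      per[d] <- ev$auc
      rows[[length(rows) + 1]] <<- tibble::tibble(
        strategy = strategy, variant = variant,
        eval_domain = as.character(d - 1L), auc = ev$auc,
        ci_low = ev$ci_low, ci_high = ev$ci_high, n = ev$n)
    }
    ev <- evaluate_classifier(model, pooled, n_rep = n_rep,
                              rep_size = rep_size, seed = seed)
    outside <- ev$auc < min(per, na.rm = TRUE) - 1e-9 ||
      ev$auc > max(per, na.rm = TRUE) + 1e-9
    rows[[length(rows) + 1]] <<- tibble::tibble(
      strategy = strategy, variant = variant, eval_domain = "pooled",
      auc = ev$auc, ci_low = ev$ci_low, ci_high = ev$ci_high, n = ev$n,
      pooled_outside_range = outside)
    per
  }
  spread_rows <- list()
  if (!is.null(models$local)) eval_on(models$local, "local", "")
  if (!is.null(models$bespoke)) {
    for (d in seq_along(models$bespoke)) {
      ts <- test_sets[[d]]
      if (is.null(ts) || is.null(models$bespoke[[d]])) next
      ev <- evaluate_classifier(models$bespoke[[d]], ts, n_rep = n_rep,
                                rep_size = rep_size, seed = seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        strategy = "bespoke", variant = as.character(d - 1L),
        eval_domain = as.character(d - 1L), auc = ev$auc,
        ci_low = ev$ci_low, ci_high = ev$ci_high, n = ev$n)
    }
  }
  if (!is.null(models$global)) {
    gl <- models$global
    if (inherits(gl, "ds_classifier") || inherits(gl, "ds_model")) {
      gl <- list(`1` = gl)
    }
    for (fr in names(gl)) {
      per <- eval_on(gl[[fr]], "global", fr)
      spread_rows[[length(spread_rows) + 1]] <- tibble::tibble(
        data_fraction = as.numeric(fr),
        spread = domain_spread(per[!is.na(per)]))
    }
  }
  if (!is.null(models$adapted)) {
    for (nm in names(models$adapted)) {
      tgt <- suppressWarnings(as.integer(sub(".*->", "", nm)))
      ts <- if (!is.na(tgt)) test_sets[[tgt + 1]] else NULL
      if (is.null(ts)) next
      ev <- evaluate_classifier(models$adapted[[nm]], ts, n_rep = n_rep,
                                rep_size = rep_size, seed = seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        strategy = "adapted", variant = nm,
        eval_domain = as.character(tgt), auc = ev$auc,
        ci_low = ev$ci_low, ci_high = ev$ci_high, n = ev$n)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!"pooled_outside_range" %in% names(out)) {
    out$pooled_outside_range <- NA
  }
  attr(out, "spread") <- if (length(spread_rows)) dplyr::bind_rows(spread_rows)
  class(out) <- c("ds_deployment", class(out))
  out
}
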