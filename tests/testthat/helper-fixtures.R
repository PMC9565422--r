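# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

# a small two-domain glyph benchmark: identity style vs full-severity style
fixture_domains <- function() {
  if (is.null(.fx$domains)) {
    .fx$domains <- make_domains(
      task_spec("digitlike", n_per_domain = 400, image_size = 16, seed = 71),
      list(style_ladder(0), style_ladder(1)))
  }
  .fx$domains
}

fixture_splits <- function() {
  if (is.null(.fx$splits)) {
    .fx$splits <- lapply(fixture_domains(), split_dataset,
                         fractions = c(0.6, 0.1, 0.3), seed = 72)
  }
  .fx$splits
}

# a baseline classifier on the identity-style domain
fixture_classifier <- function() {
  if (is.null(.fx$classifier)) {
    sp <- fixture_splits()[[1]]
    .fx$classifier <- train_classifier(
      sp$train, sp$val,
      classifier_config(batch_size = 64, max_epochs = 12, seed = 73))
  }
  .fx$classifier
}

# exhaustive pair-counting AUC used as an independent oracle
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# train a small CNN to distinguish two domains; returns held-out AUC
.domain_probe <- function(a, b, seed) {
  both <- bind_sets(a, b)
  both$class_labels <- both$domain_labels  # classify the domain
  both$n_classes <- 2L
  sp <- split_dataset(both, c(0.7, 0.15, 0.15), seed = seed)
  cl <- train_classifier(sp$train, sp$val,
                         classifier_config(batch_size = 64, max_epochs = 6,
                                           seed = seed),
                         spec = task_net_spec(16, 3, 2, conv_widths = c(4, 8),
                                              fc_width = 16))
  macro_auc(predict(cl, sp$test), sp$test$class_labels)
}

# internals used by white-box tests
ns <- asNamespace("domainsalvage")
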