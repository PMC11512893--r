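## Evaluation protocols: stratified K-fold and single learning-set splits.
## Both are generic over a `trainer`: a function(train_samples, seed) that
## returns a prediction function mapping samples to an N x K probability
## matrix.  Augmentation, when requested, is applied to training folds
## only -- never to held-out data.

sample_labels <- function(samples) vapply(samples, function(s) as.character(s$label), "")

## stratified fold ids 1..K
stratified_folds <- function(labels, K) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(seq_len(K), length(i))
  }
  fold
}

evaluate_split <- function(samples, train_idx, test_idx, trainer, seed,
                           augment_multiplier = 1L, classes = CLASS_LEVELS) {
  labels <- sample_labels(samples)
  present <- unique(labels)
  missing <- setdiff(intersect(classes, present), unique(labels[train_idx]))
  if (length(missing))
    stop_classed("spinalzfnet_stratification_error",
                 "class absent from a training split: %s",
                 paste(missing, collapse = ", "))
  train_set <- samples[train_idx]
  if (augment_multiplier > 1L)
    train_set <- augment_dataset(train_set, augment_multiplier, seed = seed)
  predict_fn <- trainer(train_set, seed)
  probs <- predict_fn(samples[test_idx])
  truth <- labels[test_idx]
  pred <- classes[max.col(probs)]
  rep <- compute_metrics(confusion_counts(truth, pred, classes))
  rep$truth <- truth
  rep$probs <- probs
  rep
}

#' Stratified K-fold evaluation
#'
#' Splits the dataset into K stratified folds, trains on K-1 and tests on
#' the held-out fold in rotation, and aggregates the metric suite as the
#' unweighted mean over folds.
#'
#' @param samples list of labelled samples.
#' @param K number of folds (>= 2, at most the dataset size).
#' @param trainer function(train_samples, seed) returning a function that
#'   maps samples to a probability matrix.
#' @param seed controls fold assignment and is forwarded to the trainer.
#' @param augment_multiplier training-fold augmentation factor (1 = none).
#' @param classes ordered class levels.
#' @return list with `folds` (per-fold `eval_report`s), `aggregate`
#'   (mean macro metrics, %), `pooled` (metrics of the pooled
#'   predictions), and `provenance`.
#' @export
kfold_evaluate <- function(samples, K, trainer, seed = 1L,
                           augment_multiplier = 1L, classes = CLASS_LEVELS) {
  if (K < 2 || K > length(samples)) stop_arg("K must be in [2, n]")
  labels <- sample_labels(samples)
  with_seed(seed, {
    fold <- stratified_folds(labels, K)
    reports <- lapply(seq_len(K), function(k) {
      evaluate_split(samples, which(fold != k), which(fold == k),
                     trainer, derive_seed(seed, paste0("fold", k)),
                     augment_multiplier, classes)
    })
    agg <- Reduce(`+`, lapply(reports, function(r) r$macro)) / K
    truth <- unlist(lapply(reports, `[[`, "truth"))
    probs <- do.call(rbind, lapply(reports, `[[`, "probs"))
    pooled <- compute_metrics(confusion_counts(truth, classes[max.col(probs)], classes))
    list(folds = reports, aggregate = agg, pooled = pooled,
         roc = roc_curves(truth, probs, classes),
         provenance = list(protocol = "kfold", K = K, seed = seed,
                           augment_multiplier = augment_multiplier))
  })
}

#' Learning-set (single stratified split) evaluation
#'
#' @param samples list of labelled samples.
#' @param train_pct training percentage (50-90 in the reported protocols).
#' @inheritParams kfold_evaluate
#' @return an `eval_report` with `roc` and `provenance` attached.
#' @export
learning_set_evaluate <- function(samples, train_pct, trainer, seed = 1L,
                                  augment_multiplier = 1L,
                                  classes = CLASS_LEVELS) {
  if (train_pct <= 0 || train_pct >= 100)
    stop_arg("train_pct must be strictly between 0 and 100")
  labels <- sample_labels(samples)
  with_seed(seed, {
    # per-class counts by largest remainder, so the total training size is
    # exactly round(train_pct% of n)
    cls <- unique(labels)
    ni <- vapply(cls, function(cl) sum(labels == cl), 0)
    exact <- train_pct / 100 * ni
    k <- floor(exact)
    extra <- round(train_pct / 100 * length(samples)) - sum(k)
    if (extra > 0) {
      ord <- order(exact - k, decreasing = TRUE)
      k[ord[seq_len(extra)]] <- k[ord[seq_len(extra)]] + 1
    }
    k <- pmax(k, 1)
    tr <- unlist(lapply(seq_along(cls), function(j) {
      i <- sample(which(labels == cls[j]))
      i[seq_len(min(k[j], length(i)))]
    }), use.names = FALSE)
    te <- setdiff(seq_along(samples), tr)
    if (!length(te)) stop_arg("empty evaluation split at train_pct %s", train_pct)
    rep <- evaluate_split(samples, tr, te, trainer,
                          derive_seed(seed, "learnset"),
                          augment_multiplier, classes)
    rep$roc <- roc_curves(rep$truth, rep$probs, classes)
    rep$provenance <- list(protocol = "learning_set", train_pct = train_pct,
                           n_train = length(tr), seed = seed,
                           augment_multiplier = augment_multiplier)
    rep
  })
}

#' Default trainer: the full hybrid classifier
#'
#' Builds feature records, initializes a fresh model and trains it; the
#' returned closure predicts probabilities for held-out samples.
#'
#' @param config a [train_config()] template (its seed is replaced by the
#'   protocol's per-fold seed).
#' @param ... passed to [spinalzfnet_new()].
#' @return a trainer function usable with [kfold_evaluate()] /
#'   [learning_set_evaluate()].
#' @export
spinalzfnet_trainer <- function(config = train_config(max_epochs = 30L,
                                                      batch_size = 4L), ...) {
  function(train_samples, seed) {
    cfg <- config
    cfg$seed <- seed
    records <- extract_records(train_samples)
    model <- spinalzfnet_new(record_dim = length(records[[1]]), seed = seed, ...)
    model <- train_spinalzfnet(model, train_samples, records, cfg)
    function(test_samples) {
      predict_spinalzfnet(model, test_samples)$probabilities
    }
  }
}
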