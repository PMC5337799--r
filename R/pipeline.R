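#' Experiment configuration for the full classification protocol
#'
#' Defaults mirror the standard protocol: 100 training and 50 test
#' samples per class, IMF1 features, an ELM with 20 sigmoid hidden
#' neurons, and a stratified random split. The split seed and the ELM
#' weight seed are independent so the two sources of run-to-run
#' variance can be isolated.
#'
#' @param filter A [filter_spec()].
#' @param sift A [sift_config()].
#' @param imf_index IMF supplying the per-channel feature (1-3).
#' @param n_train_per_class,n_test_per_class Per-class split sizes.
#' @param n_hidden ELM hidden-layer size (default 20).
#' @param elm_seed Seed for the ELM's random hidden layer.
#' @param split_seed Seed for the stratified train/test split.
#' @param scaling `"none"` (raw amplitudes, default) or `"minmax"`
#'   (per-feature min-max scaling fitted on the training set — useful
#'   numerical hygiene for the sigmoid hidden layer, off by default).
#' @param trim Edge-trim fraction for the amplitude maximum.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(filter = filter_spec(), sift = sift_config(),
                              imf_index = 1L, n_train_per_class = 100L,
                              n_test_per_class = 50L, n_hidden = 20L,
                              elm_seed = 1L, split_seed = 1L,
                              scaling = c("none", "minmax"), trim = 0) {
  scaling <- match.arg(scaling)
  imf_index <- as.integer(imf_index)
  if (imf_index < 1L) stopf("`imf_index` must be >= 1")
  if (n_train_per_class < 1L) stopf("`n_train_per_class` must be >= 1")
  if (n_test_per_class < 1L) stopf("`n_test_per_class` must be >= 1")
  structure(list(filter = filter, sift = sift, imf_index = imf_index,
                 n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 n_hidden = as.integer(n_hidden),
                 elm_seed = elm_seed, split_seed = split_seed,
                 scaling = scaling, trim = trim),
            class = "experiment_config")
}

# Stratified per-class split; returns list(train=idx, test=idx).
stratified_split <- function(labels, n_train, n_test, seed) {
  idx <- with_seed(seed, {
    picks <- lapply(c(1L, 2L), function(cl) {
      pool <- which(labels == cl)
      if (length(pool) < n_train + n_test) {
        stopf("class %d has %d samples; %d needed (%d train + %d test)",
              cl, length(pool), n_train + n_test, n_train, n_test)
      }
      sel <- sample(pool, n_train + n_test)
      list(train = sel[seq_len(n_train)],
           test = sel[n_train + seq_len(n_test)])
    })
    list(train = c(picks[[1]]$train, picks[[2]]$train),
         test = c(picks[[1]]$test, picks[[2]]$test))
  })
  idx
}

fit_minmax <- function(train) {
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  list(lo = lo, rng = rng)
}

apply_minmax <- function(x, sc) {
  sweep(sweep(x, 2L, sc$lo, "-"), 2L, sc$rng, "/")
}

#' Run the full classification experiment
#'
#' Band-pass filter every sample, extract the per-channel
#' maximum-amplitude feature of the configured IMF, split the corpus
#' into stratified train/test sets, fit the ELM on the training
#' features, and evaluate on the held-out test set. Fully reproducible
#' from `(samples, cfg)`.
#'
#' @param samples List of labelled [ehg_sample()] objects.
#' @param cfg An [experiment_config()].
#' @param features Optional precomputed feature table (a data.frame
#'   from [feature_table()] on the *filtered* samples, row order
#'   matching `samples`). When supplied, filtering and feature
#'   extraction are skipped — useful when many splits are evaluated on
#'   one corpus.
#' @return An object of class `ehg_experiment`: list with the config,
#'   split indices, per-sample test predictions and scores, `confusion`,
#'   `metrics` (percent), `roc` and the fitted `model`.
#' @export
run_experiment <- function(samples, cfg = experiment_config(),
                           features = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(features)) {
    filtered <- lapply(samples, apply_filter, spec = cfg$filter)
    features <- feature_table(filtered, imf_index = cfg$imf_index,
                              sift_cfg = cfg$sift, trim = cfg$trim)
  }
  labels <- features$label
  if (anyNA(labels)) stopf("all samples must be labelled")
  X <- as.matrix(features[, setdiff(names(features),
                                    c("label", "imf_index")), drop = FALSE])
  split <- stratified_split(labels, cfg$n_train_per_class,
                            cfg$n_test_per_class, cfg$split_seed)
  Xtr <- X[split$train, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE]
  if (cfg$scaling == "minmax") {
    sc <- fit_minmax(Xtr)
    Xtr <- apply_minmax(Xtr, sc)
    Xte <- apply_minmax(Xte, sc)
  }
  model <- elm(Xtr, labels[split$train], n_hidden = cfg$n_hidden,
               seed = cfg$elm_seed)
  scores <- predict(model, Xte, type = "score")
  pred <- ifelse(scores < 1.5, 1L, 2L)
  truth <- labels[split$test]
  cm <- confusion(truth, pred)
  structure(list(config = cfg, split = split, model = model,
                 truth = truth, pred = pred, scores = scores,
                 confusion = cm, metrics = classification_metrics(cm),
                 roc = roc_curve(truth, scores)),
            class = "ehg_experiment")
}

#' @export
print.ehg_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ehg_experiment> IMF%d features, ELM L=%d, %d train + %d test per class\n",
              cfg$imf_index, cfg$n_hidden,
              cfg$n_train_per_class, cfg$n_test_per_class))
  m <- x$metrics
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  AUC %.4f\n",
              m["sensitivity"], m["specificity"], m["accuracy"], x$roc$auc))
  invisible(x)
}

#' @export
summary.ehg_experiment <- function(object, ...) {
  print(object)
  cat("test confusion:\n")
  print(object$confusion)
  invisible(object)
}

#' Compare feature IMF indices under a shared split
#'
#' Runs the experiment for each requested IMF index with one shared
#' train/test partition (and one decomposition per channel), and
#' tabulates sensitivity, specificity, accuracy and AUC per index.
#'
#' @param samples List of labelled [ehg_sample()] objects.
#' @param cfg An [experiment_config()] (its `imf_index` is ignored).
#' @param imf_indices IMF indices to compare (default 1:3).
#' @return A data.frame with one row per IMF index and columns `imf`,
#'   `n_train`, `n_test`, `sensitivity`, `specificity`, `accuracy`,
#'   `auc`, with the experiment objects in attribute `"experiments"`.
#' @export
compare_imfs <- function(samples, cfg = experiment_config(),
                         imf_indices = 1:3) {
  stopifnot(inherits(cfg, "experiment_config"))
  filtered <- lapply(samples, apply_filter, spec = cfg$filter)
  tabs <- feature_table(filtered, imf_index = imf_indices,
                        sift_cfg = cfg$sift, trim = cfg$trim)
  if (is.data.frame(tabs)) tabs <- stats::setNames(list(tabs),
                                                   paste0("IMF", imf_indices))
  runs <- lapply(seq_along(imf_indices), function(i) {
    cfg_i <- cfg
    cfg_i$imf_index <- as.integer(imf_indices[i])
    run_experiment(samples, cfg_i, features = tabs[[i]])
  })
  out <- data.frame(
    imf = paste0("IMF", imf_indices),
    n_train = 2L * cfg$n_train_per_class,
    n_test = 2L * cfg$n_test_per_class,
    sensitivity = vapply(runs, function(r) unname(r$metrics["sensitivity"]), numeric(1)),
    specificity = vapply(runs, function(r) unname(r$metrics["specificity"]), numeric(1)),
    accuracy = vapply(runs, function(r) unname(r$metrics["accuracy"]), numeric(1)),
    auc = vapply(runs, function(r) r$roc$auc, numeric(1)))
  attr(out, "experiments") <- runs
  out
}
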