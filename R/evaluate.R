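#' Stratified train/test split
#'
#' Allocates training rows per class by floor-with-largest-remainder so the
#' overall training fraction is hit exactly (the same arithmetic reproduces
#' the study's printed per-class train counts from its per-class totals,
#' e.g. 0.7 x 19,230 = 13,461). Row assignment within a class is random
#' but deterministic given the seed.
#'
#' @param table Data.frame with a `label` column; every class needs >= 2
#'   rows.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Seed controlling the within-class assignment.
#' @return List with `train` and `test` (disjoint, union complete).
#' @export
stratified_split <- function(table, train_frac = 0.7, seed = 123L) {
  y <- table$label
  if (anyNA(y)) abort_config("table has missing labels")
  counts <- table(y)
  if (any(counts < 2))
    abort_data("class(es) with a single row cannot be split: %s",
               paste(names(counts)[counts < 2], collapse = ", "))
  n_train <- split_counts(as.integer(counts), train_frac)
  classes <- names(counts)
  train_idx <- integer(0)
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(y == classes[i])
      take <- idx[sample.int(length(idx), n_train[i])]
      train_idx <- c(train_idx, take)
    }
  })
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), ,
                    drop = FALSE])
}

#' Per-class training counts for a stratified split
#'
#' The allocation arithmetic of [stratified_split()], exposed so the split
#' bookkeeping can be checked against printed tables: per-class
#' `floor(frac * n)` plus largest-remainder top-up to
#' `floor(frac * total)`.
#'
#' @param class_sizes Integer vector of per-class totals.
#' @param train_frac Training fraction.
#' @return Integer vector of per-class training counts.
#' @export
split_counts <- function(class_sizes, train_frac = 0.7) {
  largest_remainder(class_sizes, train_frac)
}

#' Classification metrics report
#'
#' Accuracy plus support-weighted precision, recall and F1, a per-class
#' table, and the confusion matrix (true classes in rows, fixed ascending
#' class order). A class never predicted has precision 0.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class ordering for the confusion matrix (default: sorted
#'   union of observed labels).
#' @return An `eval_report` list with `accuracy`, `precision`, `recall`,
#'   `f1`, `per_class`, `confusion`.
#' @export
eval_metrics <- function(y_true, y_pred,
                         classes = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0)
    abort_data("y_true and y_pred must be nonempty and of equal length")
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  cm <- unclass(cm)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wt <- support / sum(support)
  structure(list(accuracy = sum(tp) / sum(cm),
                 precision = sum(wt * prec),
                 recall = sum(wt * rec),
                 f1 = sum(wt * f1),
                 per_class = data.frame(class = classes, support = support,
                                        precision = prec, recall = rec,
                                        f1 = f1, row.names = NULL),
                 confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> accuracy %.4f | precision %.4f | ",
                     "recall %.4f | F1 %.4f (weighted)\n"),
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Accuracy on each held-out fold; the summary reports the mean and the
#' population standard deviation (divisor k) across folds.
#'
#' @param spec A [model_spec()].
#' @param table Labelled feature/fused table; every class needs >= k rows.
#' @param k Number of folds (study value 5).
#' @param seed Seed for the fold assignment.
#' @return List with `fold_accuracy`, `cv_mean`, `cv_sd`.
#' @export
kfold_cv <- function(spec, table, k = 5L, seed = 123L) {
  fold <- stratified_folds(table$label, k, seed)
  acc <- vapply(seq_len(k), function(i) {
    fitted <- train_model(spec, table[fold != i, , drop = FALSE])
    held <- table[fold == i, , drop = FALSE]
    mean(predict(fitted, held) == held$label)
  }, numeric(1))
  list(fold_accuracy = acc, cv_mean = mean(acc),
       cv_sd = sqrt(mean((acc - mean(acc))^2)))
}

#' Raw-descriptor vs fused-feature comparison
#'
#' The comparison protocol behind the study's before/after tables: one
#' stratified split, min--max normalization fitted on the training rows,
#' a fusion model fitted on the normalized training descriptors, then every
#' requested classifier trained twice — on the raw (normalized) descriptors
#' and on the fused probability features (cross-fitted on training data,
#' full-model on test data) — and evaluated on the same held-out rows.
#'
#' @param features A labelled `feature_table`.
#' @param specs List of [model_spec()]s.
#' @param train_frac Training fraction.
#' @param seed Seed for the split (fusion/model seeds come from their
#'   configs).
#' @param fusion_cfg A [fusion_config()].
#' @param crossfit Use cross-fitted probabilities for training rows.
#' @return List with `report` (one row per model x feature-set), `metrics`
#'   (named list of `eval_report`s), and the fitted `fusion` model.
#' @export
compare_raw_vs_fused <- function(features, specs, train_frac = 0.7,
                                 seed = 123L,
                                 fusion_cfg = fusion_config(),
                                 crossfit = TRUE) {
  if (!length(specs)) abort_config("no model specs given")
  split <- stratified_split(features, train_frac, seed)
  norm <- fit_normalizer(split$train)
  train_raw <- apply_normalizer(norm, split$train)
  test_raw <- apply_normalizer(norm, split$test)
  fusion <- fit_fusion(train_raw, fusion_cfg)
  train_fused <- fused_features(fusion, train_raw, crossfit = crossfit)
  test_fused <- fused_features(fusion, test_raw, crossfit = FALSE)

  rows <- list()
  metrics <- list()
  for (spec in specs) {
    for (fs in c("raw", "fused")) {
      tr <- if (fs == "raw") train_raw else train_fused
      te <- if (fs == "raw") test_raw else test_fused
      fitted <- train_model(spec, tr)
      rep_i <- eval_metrics(te$label, predict(fitted, te))
      key <- paste(spec$name, fs, sep = ".")
      metrics[[key]] <- rep_i
      rows[[key]] <- data.frame(model = spec$name, features = fs,
                                accuracy = rep_i$accuracy,
                                precision = rep_i$precision,
                                recall = rep_i$recall, f1 = rep_i$f1)
    }
  }
  list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       metrics = metrics, fusion = fusion, normalizer = norm,
       split = split)
}
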