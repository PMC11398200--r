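# Stacked ensemble: ridge regression meta-learner over the concatenated
# class-probability vectors of a random forest and a gradient-boosting
# machine (the "RRGraBoost" construction). Meta-features on the training
# set are produced by k-fold cross-fitting so the meta-learner never sees
# in-sample base probabilities; full-data base models serve held-out rows.

ensemble_base_fits <- function(X, y, p, seed, classes) {
  df <- data.frame(X)
  df$.y <- factor(y, levels = classes)
  rf <- ranger::ranger(.y ~ ., data = df, num.trees = p$n_estimators,
                       max.depth = p$max_depth, probability = TRUE,
                       seed = seed, num.threads = 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L)
  gbm <- xgboost::xgb.train(params = list(objective = "multi:softprob",
                                          num_class = length(classes),
                                          eta = p$learning_rate,
                                          max_depth = p$max_depth,
                                          nthread = 1, seed = seed),
                            data = dtrain, nrounds = p$n_estimators,
                            verbose = 0)
  list(rf = rf, gbm = gbm)
}

ensemble_base_proba <- function(bases, X, classes) {
  cbind(rf_proba(bases$rf, X, classes),
        xgb_proba(bases$gbm, X, length(classes)))
}

ensemble_rrgraboost_fit <- function(X, y, p, seed) {
  classes <- sort(unique(y))
  fold <- stratified_folds(y, p$crossfit_folds, seed)
  meta_X <- matrix(0, nrow(X), 2 * length(classes))
  for (k in seq_len(p$crossfit_folds)) {
    tr <- fold != k
    bases_k <- ensemble_base_fits(X[tr, , drop = FALSE], y[tr], p,
                                  seed + k, classes)
    meta_X[!tr, ] <- ensemble_base_proba(bases_k, X[!tr, , drop = FALSE],
                                         classes)
  }
  list(bases = ensemble_base_fits(X, y, p, seed, classes),
       meta = ridge_fit(meta_X, y, p$alpha),
       classes = classes,
       meta_dim = ncol(meta_X))
}

ensemble_rrgraboost_proba <- function(fit, X) {
  meta_X <- ensemble_base_proba(fit$bases, X, fit$classes)
  softmax_rows(ridge_scores(fit$meta, meta_X))
}

#' Train the stacked RRGraBoost ensemble
#'
#' Convenience wrapper equivalent to
#' `train_model(model_spec("ensemble_rrgraboost", ...), table)`: level-0
#' random forest and gradient boosting (100 trees/rounds, depth 3), level-1
#' ridge (`alpha = 1`) on the concatenated cross-fitted class-probability
#' vectors (10 meta-features for 5 classes); prediction is the argmax of
#' the ridge scores.
#'
#' @param table Training table (raw or fused) with labels.
#' @param ... Hyperparameter overrides passed to [model_spec()].
#' @param seed Seed.
#' @return A `trained_model`.
#' @export
train_ensemble_rrgraboost <- function(table, ..., seed = 123L) {
  train_model(model_spec("ensemble_rrgraboost", ..., seed = seed), table)
}
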