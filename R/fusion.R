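#' Configuration of the probability-fusion stage
#'
#' Architecture of the small 1-D convolutional network and the random
#' forest whose output probabilities are concatenated into the fused
#' feature set. The convolutional head deliberately has 16 softmax units
#' even though there are 5 classes: the published architecture is
#' reproduced literally, labels occupy the first 5 slots, and the full
#' 16-dimensional softmax vector forms the "temporal probability" block.
#' Set `head_units = 5` for the compact variant.
#'
#' Training hyperparameters (Adam, learning rate 1e-3, 50 epochs, batch
#' 128) are conventional defaults recorded here for reproducibility.
#'
#' @param conv_filters,conv_kernel,pool_size,dense_units,head_units
#'   Convolutional-network architecture (defaults 64, 3, 2, 64, 16).
#' @param rf_trees,rf_max_depth Random-forest size and depth (100, 3).
#' @param crossfit_folds Folds used to produce out-of-fold probabilities on
#'   training data (>= 2).
#' @param epochs,batch_size,learning_rate Net training schedule.
#' @param seed Seed for both learners.
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(conv_filters = 64L, conv_kernel = 3L,
                          pool_size = 2L, dense_units = 64L,
                          head_units = 16L, rf_trees = 100L,
                          rf_max_depth = 3L, crossfit_folds = 5L,
                          epochs = 50L, batch_size = 128L,
                          learning_rate = 1e-3, seed = 123L) {
  if (!is_count(crossfit_folds) || crossfit_folds < 2)
    abort_config("crossfit_folds must be >= 2")
  if (!is_count(head_units) || head_units < 1)
    abort_config("head_units must be a positive integer")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 head_units = as.integer(head_units),
                 rf_trees = as.integer(rf_trees),
                 rf_max_depth = as.integer(rf_max_depth),
                 crossfit_folds = as.integer(crossfit_folds),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "fusion_config")
}

feature_matrix <- function(table) {
  missing <- setdiff(feature_names, names(table))
  if (length(missing))
    abort_schema("table lacks descriptor columns: %s",
                 paste(missing, collapse = ", "))
  as.matrix(table[, feature_names])
}

fusion_cnn_layers <- function(cfg) {
  list(list(type = "conv1d", filters = cfg$conv_filters,
            kernel = cfg$conv_kernel),
       list(type = "maxpool", pool = cfg$pool_size),
       list(type = "flatten"),
       list(type = "dense", units = cfg$dense_units, act = "relu"),
       list(type = "dense", units = cfg$head_units, act = "softmax"))
}

fit_fusion_cnn <- function(X, y_idx, cfg, seed) {
  if (cfg$head_units < max(y_idx))
    abort_config("head_units (%d) < number of classes (%d)",
                 cfg$head_units, max(y_idx))
  net <- nn_new(fusion_cnn_layers(cfg), ncol(X), cfg$head_units, seed)
  nn_fit(net, X, y_idx, epochs = cfg$epochs, batch_size = cfg$batch_size,
         lr = cfg$learning_rate)
}

fit_fusion_rf <- function(X, y, cfg, seed) {
  df <- data.frame(X)
  df$.y <- factor(y, levels = sort(unique(y)))
  ranger::ranger(.y ~ ., data = df, num.trees = cfg$rf_trees,
                 max.depth = cfg$rf_max_depth, probability = TRUE,
                 seed = seed, num.threads = 1)
}

#' Fit the probability-fusion model
#'
#' Trains the 1-D convolutional network (over the ordered, normalized
#' 19-descriptor vector, one channel) and the random forest on the full
#' training table, plus one pair of fold models per cross-fit fold so that
#' training rows can later receive probabilities from models that never saw
#' them.
#'
#' @param train A normalized `feature_table` with labels; every class needs
#'   at least `crossfit_folds` rows.
#' @param cfg A [fusion_config()].
#' @return A `fusion_model` object.
#' @export
fit_fusion <- function(train, cfg = fusion_config()) {
  stopifnot(inherits(cfg, "fusion_config"))
  X <- feature_matrix(train)
  y <- train$label
  if (anyNA(y)) abort_config("training table has missing labels")
  classes <- sort(unique(y))
  if (length(classes) < 2) abort_config("need >= 2 classes to fit fusion")
  y_idx <- match(y, classes)
  fold <- stratified_folds(y, cfg$crossfit_folds, cfg$seed)

  fold_models <- lapply(seq_len(cfg$crossfit_folds), function(k) {
    tr <- fold != k
    list(cnn = fit_fusion_cnn(X[tr, , drop = FALSE], y_idx[tr], cfg,
                              seed = cfg$seed + k),
         rf = fit_fusion_rf(X[tr, , drop = FALSE], y[tr], cfg,
                            seed = cfg$seed + k))
  })
  structure(list(cfg = cfg, classes = classes,
                 cnn = fit_fusion_cnn(X, y_idx, cfg, seed = cfg$seed),
                 rf = fit_fusion_rf(X, y, cfg, seed = cfg$seed),
                 train_fold = fold,
                 train_n = nrow(X),
                 fold_models = fold_models),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(paste0("<fusion_model> conv net (%d filters, %d-unit head) + ",
                     "random forest (%d trees); fused dim %d\n"),
              x$cfg$conv_filters, x$cfg$head_units, x$cfg$rf_trees,
              fused_dim(x)))
  invisible(x)
}

#' Fused feature dimensionality (`head_units + n_classes`)
#' @param model A fitted `fusion_model`.
#' @export
fused_dim <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  model$cfg$head_units + length(model$classes)
}

rf_proba <- function(rf, X, classes) {
  p <- stats::predict(rf, data.frame(X), num.threads = 1)$predictions
  out <- matrix(0, nrow(X), length(classes))
  colnames(p) <- colnames(p)
  out[, match(colnames(p), as.character(classes))] <- p
  out
}

#' Transform a feature table into fused probability features
#'
#' Each row becomes `[softmax vector of the conv net || class probabilities
#' of the forest]`. With `crossfit = TRUE` (the default for the training
#' table itself) every row's probabilities come from the fold models that
#' did not see that row, preventing label leakage into the fused features;
#' with `crossfit = FALSE` (held-out data) the full models are used. Set
#' `keep_raw = TRUE` to append the 19 raw descriptor columns.
#'
#' @param model A fitted `fusion_model`.
#' @param table A normalized `feature_table` (for `crossfit = TRUE` it must
#'   be the training table the model was fitted on, in the same row order).
#' @param crossfit Use out-of-fold probabilities.
#' @param keep_raw Also retain the raw descriptor columns.
#' @return A `fused_table` data.frame: `t_0..t_<head-1>`, `p_<class>`
#'   columns, optional raw descriptors, and `label`.
#' @export
fused_features <- function(model, table, crossfit = FALSE,
                           keep_raw = FALSE) {
  if (!inherits(model, "fusion_model"))
    abort_state("fused_features() needs a fitted fusion model")
  X <- feature_matrix(table)
  K <- length(model$classes)
  H <- model$cfg$head_units
  tblock <- matrix(0, nrow(X), H)
  pblock <- matrix(0, nrow(X), K)
  if (crossfit) {
    if (nrow(X) != model$train_n)
      abort_schema(paste0("crossfit = TRUE expects the training table ",
                          "(%d rows), got %d rows"), model$train_n, nrow(X))
    for (k in seq_along(model$fold_models)) {
      idx <- model$train_fold == k
      fm <- model$fold_models[[k]]
      tblock[idx, ] <- nn_predict_proba(fm$cnn, X[idx, , drop = FALSE])
      pblock[idx, ] <- rf_proba(fm$rf, X[idx, , drop = FALSE], model$classes)
    }
  } else {
    tblock <- nn_predict_proba(model$cnn, X)
    pblock <- rf_proba(model$rf, X, model$classes)
  }
  colnames(tblock) <- paste0("t_", seq_len(H) - 1L)
  colnames(pblock) <- paste0("p_", model$classes)
  out <- data.frame(tblock, pblock, check.names = FALSE)
  if (keep_raw) out <- cbind(out, table[, feature_names])
  out$label <- table$label
  if ("source_id" %in% names(table)) {
    out <- cbind(source_id = table$source_id, out)
  }
  class(out) <- c("fused_table", "data.frame")
  out
}
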