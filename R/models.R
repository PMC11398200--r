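#' Final-classifier specification
#'
#' Names one of the eight supported classifiers and its hyperparameters.
#' Defaults follow the study's tuned values: ridge `alpha = 1.0`; random
#' forest 100 trees of depth 3; gradient boosting `learning_rate = 0.1`,
#' `max_depth = 3`, 100 rounds; AdaBoost SAMME.R over depth-1 stumps,
#' `learning_rate = 1.0`, 50 rounds; Gaussian naive Bayes
#' `var_smoothing = 1e-9`; the stacked `ensemble_rrgraboost` (ridge
#' meta-learner over forest + boosting base probabilities); `dnn`
#' (64-relu / 64-relu / softmax) and `cnn2d` (two conv blocks with (3,1)
#' kernels, the feature vector laid out as a (d, 1) image, and a softmax
#' output appended since the published layer list stops at the dense layer).
#'
#' @param name One of `"ridge"`, `"rf"`, `"gbm"`, `"adaboost"`, `"gnb"`,
#'   `"ensemble_rrgraboost"`, `"dnn"`, `"cnn2d"`.
#' @param ... Hyperparameter overrides (validated per model).
#' @param seed Seed (default 123, the study's `random_state`).
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, ..., seed = 123L) {
  name <- match.arg(name, c("ridge", "rf", "gbm", "adaboost", "gnb",
                            "ensemble_rrgraboost", "dnn", "cnn2d"))
  defaults <- switch(name,
    ridge = list(alpha = 1.0),
    rf = list(n_estimators = 100L, max_depth = 3L),
    gbm = list(learning_rate = 0.1, max_depth = 3L, n_estimators = 100L),
    adaboost = list(learning_rate = 1.0, n_estimators = 50L),
    gnb = list(var_smoothing = 1e-9),
    ensemble_rrgraboost = list(alpha = 1.0, n_estimators = 100L,
                               max_depth = 3L, learning_rate = 0.1,
                               crossfit_folds = 5L),
    dnn = list(units = 64L, epochs = 50L, batch_size = 128L,
               learning_rate = 1e-3),
    cnn2d = list(epochs = 50L, batch_size = 128L, learning_rate = 1e-3,
                 dropout = 0.25))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    abort_config("unknown hyperparameter(s) for %s: %s", name,
                 paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  structure(list(name = name, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

model_matrix <- function(table) {
  drop <- c("label", "source_id")
  cols <- setdiff(names(table), drop)
  num <- vapply(table[cols], is.numeric, logical(1))
  as.matrix(table[, cols[num], drop = FALSE])
}

# ---- ridge-regression-to-one-hot classifier (closed form) ------------------

ridge_fit <- function(X, y, alpha) {
  classes <- sort(unique(y))
  Y <- matrix(-1, nrow(X), length(classes))
  Y[cbind(seq_len(nrow(X)), match(y, classes))] <- 1
  xm <- colMeans(X)
  ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm)
  Yc <- sweep(Y, 2, ym)
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  W <- solve(A, crossprod(Xc, Yc))
  list(W = W, b = ym - as.numeric(xm %*% W), classes = classes)
}

ridge_scores <- function(fit, X) {
  sweep(X %*% fit$W, 2, fit$b, `+`)
}

# ---- Gaussian naive Bayes with variance smoothing --------------------------

gnb_fit <- function(X, y, var_smoothing) {
  classes <- sort(unique(y))
  mu <- var <- matrix(0, length(classes), ncol(X))
  prior <- numeric(length(classes))
  pop_var <- function(v) mean((v - mean(v))^2)
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    mu[i, ] <- colMeans(Xi)
    var[i, ] <- apply(Xi, 2, pop_var)
    prior[i] <- nrow(Xi) / nrow(X)
  }
  # smoothing is relative to the largest overall feature variance
  var <- var + var_smoothing * max(apply(X, 2, pop_var))
  list(mu = mu, var = var, prior = prior, classes = classes)
}

gnb_log_posterior <- function(fit, X) {
  K <- length(fit$classes)
  lp <- matrix(0, nrow(X), K)
  for (i in seq_len(K)) {
    ll <- -0.5 * sweep((sweep(X, 2, fit$mu[i, ]))^2, 2, fit$var[i, ], `/`) -
      0.5 * matrix(log(2 * pi * fit$var[i, ]), nrow(X), ncol(X), byrow = TRUE)
    lp[, i] <- rowSums(ll) + log(fit$prior[i])
  }
  lp
}

# ---- AdaBoost SAMME.R over depth-1 stumps ----------------------------------

adaboost_fit <- function(X, y, n_estimators, learning_rate, seed) {
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X)
  df <- data.frame(X)
  df$.y <- factor(y, levels = classes)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  yc <- matrix(-1 / (K - 1), n, K)
  yc[cbind(seq_len(n), match(y, classes))] <- 1
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      fitm <- rpart::rpart(.y ~ ., data = df, weights = w,
                           method = "class",
                           control = rpart::rpart.control(
                             maxdepth = 1, cp = -1, minsplit = 2,
                             minbucket = 1, xval = 0))
      P <- stats::predict(fitm, df, type = "prob")
      P <- pmax(P, 1e-10)
      # match probability columns to the class order
      P <- P[, match(as.character(classes), colnames(P)), drop = FALSE]
      logP <- log(P)
      # weight update of the real-valued multiclass algorithm
      expo <- -((K - 1) / K) * learning_rate * rowSums(yc * logP)
      w <- w * exp(expo)
      if (!all(is.finite(w)) || sum(w) <= 0) break
      w <- w / sum(w)
      stumps[[m]] <- fitm
    }
  })
  list(stumps = Filter(Negate(is.null), stumps), classes = classes,
       learning_rate = learning_rate)
}

adaboost_decision <- function(fit, X) {
  df <- data.frame(X)
  K <- length(fit$classes)
  dec <- matrix(0, nrow(df), K)
  for (fitm in fit$stumps) {
    P <- stats::predict(fitm, df, type = "prob")
    P <- pmax(P[, match(as.character(fit$classes), colnames(P)),
                drop = FALSE], 1e-10)
    logP <- log(P)
    h <- (K - 1) * (logP - rowMeans(logP))
    dec <- dec + fit$learning_rate * h
  }
  dec / length(fit$stumps)
}

# ---- neural baselines ------------------------------------------------------

dnn_layers <- function(units, K) {
  list(list(type = "dense", units = units, act = "relu"),
       list(type = "dense", units = units, act = "relu"),
       list(type = "dense", units = K, act = "softmax"))
}

cnn2d_layers <- function(dropout, K) {
  list(list(type = "conv1d", filters = 32L, kernel = 3L),
       list(type = "maxpool", pool = 2L),
       list(type = "dropout", rate = dropout),
       list(type = "conv1d", filters = 64L, kernel = 3L),
       list(type = "maxpool", pool = 2L),
       list(type = "dropout", rate = dropout),
       list(type = "flatten"),
       list(type = "dense", units = 128L, act = "relu"),
       list(type = "dropout", rate = dropout),
       list(type = "dense", units = K, act = "softmax"))
}

#' Train a final classifier
#'
#' Accepts either a raw `feature_table` (19 descriptors) or a `fused_table`
#' (probability blocks); any `source_id` column is ignored. Deterministic
#' given the spec seed.
#'
#' @param spec A [model_spec()].
#' @param table Training table with a `label` column and >= 2 classes.
#' @return A `trained_model` object supporting [predict()][predict.trained_model]
#'   and [predict_proba()].
#' @export
train_model <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  X <- model_matrix(table)
  y <- table$label
  if (anyNA(y)) abort_config("training table has missing labels")
  classes <- sort(unique(y))
  if (length(classes) < 2)
    abort_data("need >= 2 classes to train, got %d", length(classes))
  p <- spec$params
  fit <- switch(spec$name,
    ridge = ridge_fit(X, y, p$alpha),
    rf = {
      df <- data.frame(X)
      df$.y <- factor(y, levels = classes)
      ranger::ranger(.y ~ ., data = df, num.trees = p$n_estimators,
                     max.depth = p$max_depth, probability = TRUE,
                     seed = spec$seed, num.threads = 1)
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = length(classes),
                                       eta = p$learning_rate,
                                       max_depth = p$max_depth,
                                       nthread = 1, seed = spec$seed),
                         data = dtrain, nrounds = p$n_estimators,
                         verbose = 0)
    },
    adaboost = adaboost_fit(X, y, p$n_estimators, p$learning_rate,
                            spec$seed),
    gnb = gnb_fit(X, y, p$var_smoothing),
    ensemble_rrgraboost = ensemble_rrgraboost_fit(X, y, p, spec$seed),
    dnn = {
      net <- nn_new(dnn_layers(p$units, length(classes)), ncol(X),
                    length(classes), spec$seed)
      nn_fit(net, X, match(y, classes), epochs = p$epochs,
             batch_size = p$batch_size, lr = p$learning_rate)
    },
    cnn2d = {
      net <- nn_new(cnn2d_layers(p$dropout, length(classes)), ncol(X),
                    length(classes), spec$seed)
      nn_fit(net, X, match(y, classes), epochs = p$epochs,
             batch_size = p$batch_size, lr = p$learning_rate)
    })
  structure(list(spec = spec, fit = fit, classes = classes,
                 schema = colnames(X)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d features, classes {%s}\n",
              x$spec$name, length(x$schema),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

check_schema <- function(model, table) {
  X <- model_matrix(table)
  if (!identical(colnames(X), model$schema))
    abort_schema("feature columns do not match the training schema")
  X
}

#' Class probabilities from a trained classifier
#'
#' Rows sum to 1. Forest and boosting probabilities are native; ridge,
#' AdaBoost and the neural nets expose softmax-normalized decision scores;
#' Gaussian naive Bayes exposes normalized posteriors.
#'
#' @param model A `trained_model`.
#' @param table Table with the training feature columns.
#' @return Numeric matrix, one column per training class.
#' @export
predict_proba <- function(model, table) {
  stopifnot(inherits(model, "trained_model"))
  X <- check_schema(model, table)
  if (nrow(X) == 0) return(matrix(numeric(0), 0, length(model$classes),
                                  dimnames = list(NULL, model$classes)))
  P <- switch(model$spec$name,
    ridge = softmax_rows(ridge_scores(model$fit, X)),
    rf = rf_proba(model$fit, X, model$classes),
    gbm = xgb_proba(model$fit, X, length(model$classes)),
    adaboost = softmax_rows(adaboost_decision(model$fit, X) /
                              (length(model$classes) - 1)),
    gnb = softmax_rows(gnb_log_posterior(model$fit, X)),
    ensemble_rrgraboost = ensemble_rrgraboost_proba(model$fit, X),
    dnn = nn_predict_proba(model$fit, X),
    cnn2d = nn_predict_proba(model$fit, X))
  dimnames(P) <- list(NULL, model$classes)
  P
}

xgb_proba <- function(fit, X, K) {
  p <- stats::predict(fit, xgboost::xgb.DMatrix(X))
  if (!is.matrix(p)) p <- matrix(p, nrow(X), K, byrow = TRUE)
  unname(p)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Predict class labels
#'
#' @param object A `trained_model`.
#' @param table Table with the training feature columns.
#' @param ... Unused.
#' @return Integer vector of predicted labels (argmax of
#'   [predict_proba()]).
#' @export
predict.trained_model <- function(object, table, ...) {
  P <- predict_proba(object, table)
  if (nrow(P) == 0) return(integer(0))
  object$classes[max.col(P, ties.method = "first")]
}
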