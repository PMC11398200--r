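fast_specs <- function() list(
  model_spec("ridge"),
  model_spec("rf", n_estimators = 30L),
  model_spec("gbm", n_estimators = 30L),
  model_spec("adaboost", n_estimators = 10L),
  model_spec("gnb"),
  model_spec("ensemble_rrgraboost", n_estimators = 20L,
             crossfit_folds = 3L),
  model_spec("dnn", epochs = 15L),
  model_spec("cnn2d", epochs = 15L))

test_that("every classifier separates the toy problem and is deterministic", {
  tab <- toy_feature_table(25)
  probe <- toy_feature_table(10, seed = 101)
  for (spec in fast_specs()) {
    m1 <- train_model(spec, tab)
    m2 <- train_model(spec, tab)
    p1 <- predict(m1, probe)
    expect_identical(p1, predict(m2, probe))          # seeded determinism
    expect_gte(mean(p1 == probe$label), 0.95)
    P <- predict_proba(m1, probe)
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
    expect_identical(m1$classes[max.col(P, ties.method = "first")], p1)
    expect_identical(predict(m1, probe[0, , drop = FALSE]), integer(0))
  }
})

test_that("gradient boosting reaches training accuracy 1 on separated data", {
  tab <- toy_feature_table(15)
  m <- train_model(model_spec("gbm"), tab)
  expect_identical(mean(predict(m, tab) == tab$label), 1)
})

test_that("classical models are equivariant under label permutation", {
  tab <- toy_feature_table(15, labels = c(1L, 2L, 3L))
  probe <- toy_feature_table(6, seed = 55, labels = c(1L, 2L, 3L))
  swap <- c(3L, 1L, 2L)   # 1->3, 2->1, 3->2
  tab2 <- tab; tab2$label <- swap[tab$label]
  for (name in c("ridge", "gnb", "adaboost")) {
    m <- train_model(model_spec(name), tab)
    m2 <- train_model(model_spec(name), tab2)
    expect_identical(swap[predict(m, probe)], predict(m2, probe))
  }
})

test_that("single-class tables and schema mismatches are rejected", {
  tab <- toy_feature_table(10)
  solo <- tab[tab$label == 1L, ]
  expect_error(train_model(model_spec("ridge"), solo),
               class = "radrehab_data_error")
  m <- train_model(model_spec("ridge"), tab)
  bad <- tab; names(bad)[3] <- "not_a_feature"
  expect_error(predict(m, bad), class = "radrehab_schema_error")
})

test_that("Gaussian naive Bayes matches a scalar log-posterior oracle", {
  tab <- toy_feature_table(12)
  m <- train_model(model_spec("gnb"), tab)
  X <- as.matrix(tab[, feature_names])
  y <- tab$label
  x0 <- X[5, ]
  # scalar oracle with smoothing relative to the largest feature variance
  pop_var <- function(v) mean((v - mean(v))^2)
  eps <- 1e-9 * max(apply(X, 2, pop_var))
  lp <- vapply(c(1L, 2L), function(cl) {
    Xi <- X[y == cl, ]
    acc <- log(mean(y == cl))
    for (j in seq_len(ncol(X))) {
      mu <- mean(Xi[, j]); v <- pop_var(Xi[, j]) + eps
      acc <- acc - 0.5 * log(2 * pi * v) - (x0[j] - mu)^2 / (2 * v)
    }
    acc
  }, numeric(1))
  got <- predict_proba(m, tab[5, , drop = FALSE])
  expect_equal(as.numeric(got), exp(lp - max(lp)) / sum(exp(lp - max(lp))),
               tolerance = 1e-9)
})

test_that("one boosting round equals the best brute-force stump", {
  # 1-D data, uniform weights: the first SAMME.R stump must split where an
  # exhaustive threshold search does
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  tab <- data.frame(f1 = x, f2 = 0, label = y)
  m <- train_model(model_spec("adaboost", n_estimators = 1L), tab)
  # brute-force: error of every threshold
  errs <- vapply(sort(x), function(thr) mean((x > thr) + 1L != y),
                 numeric(1))
  expect_identical(min(errs), 0)  # separable
  expect_identical(predict(m, tab), y)
})

test_that("the stacked ensemble wires 2 x n_classes meta-features", {
  tab <- toy_feature_table(12, labels = c(1L, 2L, 3L, 4L, 5L))
  m <- train_model(model_spec("ensemble_rrgraboost", n_estimators = 10L,
                              crossfit_folds = 2L), tab)
  expect_identical(m$fit$meta_dim, 10L)
  expect_identical(ncol(m$fit$meta$W), 5L)
  expect_gte(mean(predict(m, tab) == tab$label), 0.9)
})

test_that("ridge on duplicated features equals ridge at half the penalty", {
  tab <- toy_feature_table(20)
  P <- as.matrix(tab[, feature_names[1:5]])
  y <- tab$label
  fit_dup <- radrehab:::ridge_fit(cbind(P, P), y, alpha = 1.0)
  fit_half <- radrehab:::ridge_fit(P, y, alpha = 0.5)
  s_dup <- radrehab:::ridge_scores(fit_dup, cbind(P, P))
  s_half <- radrehab:::ridge_scores(fit_half, P)
  expect_equal(s_dup, s_half, tolerance = 1e-8)
})

test_that("the stack keeps pace with its base learners on easy data", {
  tab <- toy_feature_table(20, labels = c(1L, 2L, 3L))
  probe <- toy_feature_table(8, seed = 77, labels = c(1L, 2L, 3L))
  accs <- vapply(c("rf", "gbm"), function(nm)
    mean(predict(train_model(model_spec(nm, n_estimators = 30L), tab),
                 probe) == probe$label), numeric(1))
  stack <- train_model(model_spec("ensemble_rrgraboost", n_estimators = 30L,
                                  crossfit_folds = 3L), tab)
  acc_stack <- mean(predict(stack, probe) == probe$label)
  expect_gte(acc_stack, max(accs) - 0.02)
})
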