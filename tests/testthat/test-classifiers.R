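# 2D toy with a clean margin between the classes (large enough that
# boosted trees can split: leaf hessians must clear min_child_weight)
separable_toy <- function() {
  set.seed(100)
  X <- rbind(matrix(rnorm(12, -1, 0.2), 6, 2), matrix(rnorm(12, 1, 0.2), 6, 2))
  colnames(X) <- c("u", "v")
  list(X = X, y = rep(c(0L, 1L), each = 6))
}

synth_cohort <- function(n = 200, seed = 1, signal = 1.5) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.45)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- X[, 1] + signal * y
  X[, 2] <- X[, 2] - signal * y
  list(X = X, y = y)
}

test_that("every family separates a linearly separable toy", {
  toy <- separable_toy()
  for (fam in c("svm", "gbt", "mlp")) {
    spec <- if (fam == "svm") model_spec("svm", kernel = "linear") else model_spec(fam)
    m <- train_classifier(toy$X, toy$y, spec)
    s <- predict_proba(m, toy$X)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(auc_roc(s, toy$y), 1)
  }
})

test_that("training and prediction are deterministic given the seed", {
  d <- synth_cohort(120, seed = 2)
  for (fam in c("svm", "gbt", "mlp")) {
    m1 <- train_classifier(d$X, d$y, model_spec(fam, seed = 5))
    m2 <- train_classifier(d$X, d$y, model_spec(fam, seed = 5))
    expect_identical(predict_proba(m1, d$X), predict_proba(m2, d$X))
  }
  # changing only the seed never changes the (deterministic) SVM decision values
  m3 <- train_classifier(d$X, d$y, model_spec("svm", seed = 99))
  m1 <- train_classifier(d$X, d$y, model_spec("svm", seed = 5))
  expect_equal(predict_label(m3, d$X), predict_label(m1, d$X))
})

test_that("label-permuted training yields chance-level held-out AUC", {
  d <- synth_cohort(200, seed = 3)
  set.seed(4)
  y_perm <- sample(d$y)
  tr <- 1:150; te <- 151:200
  m <- train_classifier(d$X[tr, ], y_perm[tr], model_spec("gbt", seed = 1))
  a <- auc_roc(predict_proba(m, d$X[te, ]), y_perm[te])
  expect_gt(a, 0.35)
  expect_lt(a, 0.65)
})

test_that("single-class labels and contract violations are rejected", {
  d <- synth_cohort(40, seed = 5)
  expect_error(train_classifier(d$X, rep(1L, 40), model_spec("svm")),
               "both classes")
  m <- train_classifier(d$X, d$y, model_spec("svm"))
  Xbad <- d$X
  colnames(Xbad)[3] <- "wrong"
  expect_error(predict_proba(m, Xbad), "wrong")
  expect_error(predict_proba(m, d$X[, 1:4]), "expected 6")
})

test_that("thresholding scores is consistent with predict_label", {
  d <- synth_cohort(100, seed = 6)
  m <- train_classifier(d$X, d$y, model_spec("gbt"))
  s <- predict_proba(m, d$X)
  for (cut in c(0.3, 0.5, 0.8)) {
    expect_identical(predict_label(m, d$X, cut), as.integer(s >= cut))
  }
})

test_that("scores rank cases by their true class-1 propensity", {
  set.seed(7)
  n <- 400
  eta <- rnorm(n)
  p <- plogis(2 * eta)
  y <- rbinom(n, 1, p)
  X <- cbind(x1 = eta + rnorm(n, sd = 0.3), x2 = rnorm(n))
  m <- train_classifier(X[1:300, ], y[1:300], model_spec("gbt", seed = 2))
  s <- predict_proba(m, X[301:n, ])
  expect_gt(cor(s, p[301:n], method = "spearman"), 0)
})

test_that("hyperparameter search returns the better-regularised SVM", {
  res_single <- hyperparameter_search(separable_toy()$X, separable_toy()$y,
                                      "svm", list(kernel = "linear"),
                                      budget = 3, n_folds = 2)
  expect_identical(res_single$best_spec$params$kernel, "linear")
  expect_identical(nrow(res_single$trials), 1L)

  # paired big/small clusters: with a tiny C every dual coefficient is
  # pinned at the bound, so each small cluster is swamped by the big
  # opposite-class cluster beside it and gets misranked; a large C can
  # reweight and separate the pairs locally
  set.seed(8)
  mk <- function(n, cx, cy, sd = 0.2) cbind(rnorm(n, cx, sd), rnorm(n, cy, sd))
  X <- rbind(mk(40, 0, 0), mk(10, 0.8, 0), mk(10, 5, 0), mk(40, 5.8, 0)) * 1.4
  y <- c(rep(1L, 40), rep(0L, 10), rep(1L, 10), rep(0L, 40))
  colnames(X) <- c("a", "b")
  res <- hyperparameter_search(X, y, "svm",
                               list(cost = c(0.01, 60), kernel = "radial"),
                               budget = 4, seed = 3, n_folds = 3)
  expect_identical(res$best_spec$params$cost, 60)
  expect_identical(nrow(res$trials), 2L)
  expect_error(hyperparameter_search(X, y, "svm", list(), budget = 2), "empty")
})

test_that("the packaged best SVM preset carries error tolerance 60", {
  spec <- svm_error_tolerance_60()
  expect_identical(spec$family, "svm")
  expect_identical(spec$params$cost, 60)
})

test_that("tidy and glance summarise fitted classifiers", {
  d <- synth_cohort(60, seed = 9)
  m <- train_classifier(d$X, d$y, model_spec("gbt", eta = 0.1))
  td <- tidy(m)
  expect_true("eta" %in% td$hyperparameter)
  g <- glance(m)
  expect_identical(g$family, "gbt")
  expect_identical(g$n_features, 6L)
})
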