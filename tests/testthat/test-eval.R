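test_that("AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(c(0.9, 0.3, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_roc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_roc(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(14)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_roc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }

  # independent library cross-check
  set.seed(16)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(40)
  expect_equal(auc_roc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("sensitivity and specificity follow the confusion-matrix arithmetic", {
  truth <- c(rep(1, 4), rep(0, 4))
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0)   # TP 3, FN 1, TN 4, FP 0
  ss <- sens_spec(pred, truth)
  expect_equal(ss$sensitivity, 0.75)
  expect_equal(ss$specificity, 1)
  expect_equal(unlist(sens_spec(truth, truth)), c(sensitivity = 1, specificity = 1))
  expect_equal(unlist(sens_spec(1 - truth, truth)),
               c(sensitivity = 0, specificity = 0))
  expect_true(is.na(sens_spec(c(1, 0), c(0, 0))$sensitivity))
})

test_that("split plans are stratified partitions with an isolated test set", {
  y <- rep(c(0, 1), c(120, 80))
  plan <- split_plan(y, test_fraction = 0.15, n_folds = 5, seed = 7)
  expect_identical(sum(plan$role == "test" & plan$label == 0), 18L)
  expect_identical(sum(plan$role == "test" & plan$label == 1), 12L)
  expect_true(all(is.na(plan$fold[plan$role == "test"])))
  tr <- plan[plan$role == "train", ]
  expect_true(all(tr$fold %in% 1:5))
  # each training case sits in exactly one validation fold => 4 train folds
  expect_identical(nrow(tr), sum(table(tr$fold)))
  expect_identical(split_plan(y, seed = 7), plan)
  expect_false(identical(split_plan(y, seed = 8)$role, plan$role))
})

test_that("cross-validation is deterministic and leakage-safe", {
  set.seed(15)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  X[, 1] <- X[, 1] + 2.5 * y
  feats <- dplyr::bind_cols(
    tibble::tibble(case_id = sprintf("case_%04d", 1:n), label = y),
    tibble::as_tibble(X)
  )
  plan <- split_plan(y, test_fraction = 0.15, n_folds = 5, seed = 3)

  test_rows_before <- feats[match(plan$case_id[plan$role == "test"], feats$case_id), ]
  r1 <- cross_validate(feats, plan, selection = "PCA", k = 4,
                       model = model_spec("gbt"))
  test_rows_after <- feats[match(plan$case_id[plan$role == "test"], feats$case_id), ]
  expect_identical(test_rows_before, test_rows_after)  # test data untouched

  r2 <- cross_validate(feats, plan, selection = "PCA", k = 4,
                       model = model_spec("gbt"))
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$test, r2$test)
  expect_identical(nrow(r1$per_fold), 5L)
  expect_true(all(r1$per_fold$auc_roc >= 0 & r1$per_fold$auc_roc <= 1))
  expect_gt(mean(r1$per_fold$auc_roc), 0.8)  # the planted signal is recovered

  g <- glance(r1)
  expect_identical(g$mode, "standalone")
  expect_true(is.numeric(g$cv_auc_roc))
  td <- tidy(r1)
  expect_true(all(c("cv", "test") %in% td$split))
})

test_that("stratification failures raise an error", {
  y <- c(rep(0, 30), 1, 1)
  X <- matrix(rnorm(32 * 3), 32, 3, dimnames = list(NULL, paste0("f", 1:3)))
  feats <- dplyr::bind_cols(
    tibble::tibble(case_id = sprintf("case_%04d", 1:32), label = y),
    tibble::as_tibble(X)
  )
  plan <- split_plan(y, test_fraction = 0.15, n_folds = 5, seed = 1)
  expect_error(cross_validate(feats, plan, model = model_spec("svm")),
               "single class")
})
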