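make_separable_tab <- function(n = 10, noise = 0.2, seed = 60) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * 2, 0, noise), n, 2),
               matrix(rnorm(n * 2, 3, noise), n, 2))
    colnames(X) <- c("f1", "f2")
    feature_table(X, rep(c("PC", "PE"), each = n))
  })
}

test_that("separable clusters are classified perfectly by linear models", {
  tab <- make_separable_tab()
  for (m in c("logistic_regression", "svm")) {
    r <- loocv(tab, m)
    expect_equal(r$accuracy, 1)
    expect_equal(r$auc, 1)
  }
  expect_error(loocv(tab, "boosting"), "valid models")
})

test_that("every model family runs and reports coherent LOOCV output", {
  # n large enough that rpart's default minsplit (20) can act
  tab <- make_separable_tab(n = 15)
  for (m in c("decision_tree", "random_forest", "naive_bayes", "mlp")) {
    r <- loocv(tab, m, seed = 2)
    expect_true(r$accuracy >= 0 && r$accuracy <= 1)
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_gt(r$accuracy, 0.8)   # trivially separable
    expect_equal(nrow(r$predictions), 30)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= -1e-12))
  }
})

test_that("LOOCV accuracy is bit-reproducible under a fixed seed", {
  tab <- make_separable_tab(n = 6, noise = 1.5)
  r1 <- loocv(tab, "random_forest", seed = 5)
  r2 <- loocv(tab, "random_forest", seed = 5)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$predictions$score, r2$predictions$score)
})

test_that("permuted labels give chance-level accuracy on average", {
  withr::local_seed(61)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  accs <- vapply(1:20, function(i) {
    tab <- feature_table(X, sample(rep(c("PC", "PE"), each = 10)))
    loocv(tab, "logistic_regression")$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("fold models never see the held-out sample's features", {
  tab <- make_separable_tab(n = 5, noise = 1)
  j <- 3
  tab2 <- tab
  tab2[j, c("f1", "f2")] <- c(50, -50)
  r2 <- loocv(tab2, "logistic_regression")
  # reproduce fold j by hand: train on all rows but j of the MODIFIED table;
  # identical to training on the original table minus row j
  X <- feature_matrix(tab)[-j, ]
  mu <- colMeans(X); s <- apply(X, 2, sd)
  train <- data.frame(scale(X, mu, s), .y = tab$group[-j])
  fit <- suppressWarnings(glm(.y ~ ., data = train, family = binomial()))
  xnew <- data.frame(scale(matrix(c(50, -50), 1,
                                  dimnames = list(NULL, c("f1", "f2"))), mu, s))
  expect_equal(unname(r2$predictions$score[j]),
               unname(suppressWarnings(predict(fit, xnew, type = "response"))),
               tolerance = 1e-8)
})

test_that("subject-level folds keep a subject's fragments together", {
  withr::local_seed(62)
  X <- matrix(rnorm(24 * 2), 24, 2, dimnames = list(NULL, c("f1", "f2")))
  X[seq(1, 24, 2), ] <- X[seq(2, 24, 2), ]     # two identical fragments/subject
  subj <- rep(sprintf("S%02d", 1:12), each = 2)
  tab <- feature_table(X, rep(c("PC", "PE"), each = 12),
                       sample_id = paste0(subj, "_f", 1:2), subject_id = subj)
  r <- loocv(tab, "logistic_regression", cv_unit = "subject")
  sc <- matrix(r$predictions$score, ncol = 2, byrow = TRUE)
  expect_equal(sc[, 1], sc[, 2], tolerance = 1e-12)  # same fold, same model
})

test_that("evaluate_all retains the max over the PCA variants", {
  tab <- make_separable_tab(n = 6, noise = 2)
  ev <- evaluate_all(tab, models = c("logistic_regression", "naive_bayes"),
                     seed = 3)
  expect_equal(nrow(ev), 2)
  det <- attr(ev, "details")
  for (m in ev$model) {
    expect_equal(ev$accuracy[ev$model == m],
                 max(det[[m]]$none$accuracy, det[[m]]$fold$accuracy))
    expect_equal(ev$auc[ev$model == m],
                 max(det[[m]]$none$auc, det[[m]]$fold$auc))
  }
})

test_that("compare_conditions yields conditions x models rows", {
  tab <- make_separable_tab(n = 6)
  ev <- evaluate_all(tab, models = c("logistic_regression", "svm"), seed = 1)
  attr(ev, "condition") <- c(network = "static", method = "CORR",
                             band = "Full", dataset = "original")
  rep1 <- compare_conditions(list(cond = ev))
  expect_equal(nrow(rep1), 2)
  rep2 <- compare_conditions(list(a = ev, b = ev))
  expect_equal(nrow(rep2), 4)
  expect_true(all(c("network", "method", "band", "dataset",
                    "model", "accuracy", "auc") %in% names(rep2)))
})
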