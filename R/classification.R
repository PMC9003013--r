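#' @name classifiers
#' @title The six classifier families
#' @description Models are run with their implementing package's defaults
#'   (logistic regression via `glm`, decision tree via `rpart`, SVM via
#'   `e1071::svm`, random forest via `randomForest`, naive Bayes via
#'   `e1071::naiveBayes`, and a single-hidden-layer back-propagation network
#'   via `nnet` with 5 hidden units). Scores are probabilities (or SVM
#'   decision margins) for the second group level.
NULL

classifier_names <- c("logistic_regression", "decision_tree", "svm",
                      "random_forest", "naive_bayes", "mlp")

# Fit one model; X is a data.frame of predictors, y a 2-level factor.
fit_model <- function(model, X, y) {
  dat <- cbind(X, .y = y)
  switch(model,
    logistic_regression = suppressWarnings(
      glm(.y ~ ., data = dat, family = binomial())),
    decision_tree = rpart::rpart(.y ~ ., data = dat, method = "class"),
    svm = e1071::svm(.y ~ ., data = dat),
    random_forest = randomForest::randomForest(.y ~ ., data = dat),
    naive_bayes = e1071::naiveBayes(.y ~ ., data = dat),
    mlp = nnet::nnet(.y ~ ., data = dat, size = 5, trace = FALSE),
    stop("unknown model '", model, "'; valid models: ",
         paste(classifier_names, collapse = ", "))
  )
}

# Predict class labels and a numeric score oriented toward the positive
# (second) level.
predict_model <- function(model, fit, X, levels) {
  pos <- levels[2]
  switch(model,
    logistic_regression = {
      p <- suppressWarnings(predict(fit, newdata = X, type = "response"))
      list(class = ifelse(p > 0.5, levels[2], levels[1]), score = p)
    },
    decision_tree = {
      p <- predict(fit, newdata = X, type = "prob")[, pos]
      cl <- as.character(predict(fit, newdata = X, type = "class"))
      list(class = cl, score = p)
    },
    svm = {
      pr <- predict(fit, newdata = X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- dv[, 1]
      if (!grepl(paste0("^", pos, "/"), colnames(dv)[1])) s <- -s
      list(class = as.character(pr), score = s)
    },
    random_forest = {
      p <- predict(fit, newdata = X, type = "prob")[, pos]
      list(class = as.character(predict(fit, newdata = X)), score = p)
    },
    naive_bayes = {
      p <- predict(fit, newdata = X, type = "raw")[, pos]
      list(class = as.character(predict(fit, newdata = X)), score = p)
    },
    mlp = {
      p <- as.vector(predict(fit, newdata = X, type = "raw"))
      list(class = ifelse(p > 0.5, levels[2], levels[1]), score = p)
    }
  )
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  list(mu = mu, s = s)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$s, `/`)

#' Leave-one-out cross-validation of one classifier
#'
#' Each held-out unit is predicted by a model trained on the remaining
#' units; scaling (and PCA when `pca = "fold"`) is fit on the training fold
#' only. `cv_unit = "sample"` holds out one row at a time; `"subject"` holds
#' out all fragments of one subject together, so fragments of a subject
#' never straddle the train/test split. Accuracy is the fraction of correct
#' sample-level predictions; AUC is computed from the pooled held-out
#' scores.
#'
#' @param tab A [feature_table()] with >= 3 samples per group.
#' @param model One of `r paste(classifier_names, collapse = ", ")`.
#' @param cv_unit `"sample"` or `"subject"`.
#' @param pca `"none"` or `"fold"` (PCA fit inside each training fold).
#' @param variance_target Cumulative variance for in-fold PCA.
#' @param seed Master seed; one child seed per fold for stochastic models.
#' @param select_alpha If not `NULL`, the univariate screen (normality-gated
#'   t/Wilcoxon at this level) is fit inside each training fold and only the
#'   retained features enter the model; when nothing passes, the smallest-p
#'   feature is kept so the model stays defined.
#' @return A `cv_result`: `model`, `accuracy`, `auc`, `roc_points`
#'   (fpr/tpr), `predictions`, `pca_used`.
#' @export
loocv <- function(tab, model, cv_unit = c("sample", "subject"),
                  pca = c("none", "fold"), variance_target = 0.85, seed = 1,
                  select_alpha = NULL) {
  cv_unit <- match.arg(cv_unit)
  pca <- match.arg(pca)
  if (!model %in% classifier_names)
    stop("unknown model '", model, "'; valid models: ",
         paste(classifier_names, collapse = ", "))
  if (any(table(tab$group) < 3)) stop("need at least 3 samples per group")
  lv <- levels(tab$group)
  X <- feature_matrix(tab)
  units <- if (cv_unit == "subject") tab$subject_id else tab$sample_id
  fold_ids <- unique(units)
  pred_class <- character(nrow(tab))
  pred_score <- numeric(nrow(tab))
  for (k in seq_along(fold_ids)) {
    test <- units == fold_ids[k]
    Xtr0 <- X[!test, , drop = FALSE]
    Xte0 <- X[test, , drop = FALSE]
    if (!is.null(select_alpha)) {
      p <- feature_pvalues(Xtr0, droplevels(tab$group[!test]))
      keep <- which(p <= select_alpha)
      if (!length(keep)) keep <- which.min(p)
      Xtr0 <- Xtr0[, keep, drop = FALSE]
      Xte0 <- Xte0[, keep, drop = FALSE]
    }
    sc <- scale_fit(Xtr0)
    Xtr <- scale_apply(Xtr0, sc)
    Xte <- scale_apply(Xte0, sc)
    if (pca == "fold" && ncol(Xtr) >= 2) {
      pc <- prcomp(Xtr, center = FALSE, scale. = FALSE)
      ve <- pc$sdev^2 / sum(pc$sdev^2)
      kc <- which(cumsum(ve) >= variance_target - 1e-12)[1]
      Xtr <- Xtr %*% pc$rotation[, seq_len(kc), drop = FALSE]
      Xte <- Xte %*% pc$rotation[, seq_len(kc), drop = FALSE]
    }
    dtr <- as.data.frame(Xtr); dte <- as.data.frame(Xte)
    colnames(dte) <- colnames(dtr)
    fit <- withr::with_seed(derive_seed(seed, k),
                            fit_model(model, dtr, droplevels(tab$group[!test])))
    pr <- predict_model(model, fit, dte, lv)
    pred_class[test] <- pr$class
    pred_score[test] <- pr$score
  }
  truth <- as.character(tab$group)
  accuracy <- mean(pred_class == truth)
  r <- suppressMessages(pROC::roc(response = truth, predictor = pred_score,
                                  levels = lv, direction = "<", quiet = TRUE))
  co <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  co <- co[order(co$fpr, co$tpr), ]
  structure(list(model = model, accuracy = accuracy, auc = as.numeric(r$auc),
                 roc_points = co,
                 predictions = data.frame(sample_id = tab$sample_id,
                                          truth = truth, predicted = pred_class,
                                          score = pred_score,
                                          stringsAsFactors = FALSE),
                 pca_used = pca == "fold", cv_unit = cv_unit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$model, ": accuracy = ", round(x$accuracy, 3),
      ", AUC = ", round(x$auc, 3),
      if (x$pca_used) " (PCA)", "\n", sep = "")
  invisible(x)
}

#' Evaluate all six classifiers with and without PCA
#'
#' Runs every model twice (raw features, and PCA fit inside each training
#' fold) and retains, per model, the better accuracy and the better AUC,
#' each flagged with whether PCA produced it.
#'
#' @inheritParams loocv
#' @param models Character vector of model names (default all six).
#' @return data.frame with one row per model: `model`, `accuracy`,
#'   `acc_pca`, `auc`, `auc_pca`. The full `cv_result` objects are attached
#'   as the `"details"` attribute.
#' @export
evaluate_all <- function(tab, cv_unit = c("sample", "subject"),
                         models = classifier_names, variance_target = 0.85,
                         seed = 1, select_alpha = NULL) {
  cv_unit <- match.arg(cv_unit)
  details <- list()
  rows <- lapply(models, function(m) {
    r0 <- loocv(tab, m, cv_unit, pca = "none",
                variance_target = variance_target, seed = seed,
                select_alpha = select_alpha)
    r1 <- loocv(tab, m, cv_unit, pca = "fold",
                variance_target = variance_target, seed = seed,
                select_alpha = select_alpha)
    details[[m]] <<- list(none = r0, fold = r1)
    data.frame(model = m,
               accuracy = max(r0$accuracy, r1$accuracy),
               acc_pca = r1$accuracy > r0$accuracy,
               auc = max(r0$auc, r1$auc),
               auc_pca = r1$auc > r0$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}

#' Combine evaluation results across experiment conditions
#'
#' @param results Named list; each element is the data.frame from
#'   [evaluate_all()], optionally carrying a `"condition"` attribute (named
#'   character vector such as `c(network = "dynamic", method = "iCOH",
#'   band = "Full", dataset = "original")`). Absent conditions are parsed
#'   from the element name on `"."`.
#' @return Long-format data.frame: condition columns + `model`, `accuracy`,
#'   `auc`.
#' @export
compare_conditions <- function(results) {
  if (!length(results)) stop("no conditions to compare")
  rows <- lapply(names(results), function(nm) {
    df <- results[[nm]]
    cond <- attr(df, "condition")
    if (is.null(cond)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      cond <- c(network = parts[1] %||% nm, method = parts[2] %||% NA,
                band = parts[3] %||% NA, dataset = parts[4] %||% NA)
    }
    cbind(as.data.frame(as.list(cond), stringsAsFactors = FALSE),
          df[, c("model", "accuracy", "auc")], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Grouped bar chart of accuracies across conditions
#'
#' @param report Output of [compare_conditions()].
#' @param metric Column to plot.
#' @return Invisibly, the matrix passed to [graphics::barplot()].
#' @export
plot_accuracy <- function(report, metric = "accuracy") {
  cond <- apply(report[, setdiff(names(report), c("model", "accuracy", "auc")),
                       drop = FALSE], 1, paste, collapse = ".")
  m <- tapply(report[[metric]], list(report$model, cond), mean)
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1), las = 2,
                    legend.text = rownames(m), ylab = metric)
  invisible(m)
}
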