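#' Feature table
#'
#' Samples (participants or fragments) in rows, named features in columns,
#' with sample/subject identifiers and a two-level group factor.
#'
#' @param features Numeric matrix or data.frame of features.
#' @param group Group labels, coerced to a factor with exactly 2 levels
#'   (levels ordered `PC`, `PE` when those labels are present).
#' @param sample_id,subject_id Identifier vectors (defaults generated).
#' @return A data.frame of class `feature_table` with columns `sample_id`,
#'   `subject_id`, `group`, then the features.
#' @export
feature_table <- function(features, group, sample_id = NULL, subject_id = NULL) {
  features <- as.data.frame(features)
  if (any(!vapply(features, is.numeric, TRUE))) stop("features must be numeric")
  if (anyNA(features)) stop("features contain missing values")
  lv <- unique(as.character(group))
  if (all(c("PC", "PE") %in% lv)) lv <- c("PC", "PE")
  group <- factor(as.character(group), levels = sort(lv))
  if (nlevels(group) != 2) stop("group must have exactly 2 levels; got ",
                                nlevels(group))
  n <- nrow(features)
  if (length(group) != n) stop("group length must match the number of rows")
  sample_id <- sample_id %||% sprintf("S%03d", seq_len(n))
  subject_id <- subject_id %||% sample_id
  out <- cbind(data.frame(sample_id = as.character(sample_id),
                          subject_id = as.character(subject_id),
                          group = group, stringsAsFactors = FALSE),
               features)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @rdname feature_table
#' @param tab A `feature_table`.
#' @export
feature_names <- function(tab) setdiff(names(tab), c("sample_id", "subject_id", "group"))

#' @rdname feature_table
#' @export
feature_matrix <- function(tab) as.matrix(tab[, feature_names(tab), drop = FALSE])

#' Univariate group comparison and feature selection
#'
#' Per feature, normality is assessed in both groups (Shapiro-Wilk at 0.05);
#' a Welch t-test is used if both groups pass, otherwise the Wilcoxon
#' rank-sum test. Features with `p > alpha` are removed. Raw p-values are
#' used (no multiplicity correction, mirroring common univariate screens);
#' set `adjust = "BH"` for Benjamini-Hochberg-adjusted selection.
#'
#' @param tab A [feature_table()] with >= 2 samples per group.
#' @param alpha Significance level for retention (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `selected` (retained feature names) and `results`, a
#'   data.frame with columns `Item`, per-group medians and IQRs, the test
#'   used, its statistic `W` (or `t`) and `p`.
#' @export
# Normality-gated two-sample comparison of one feature; shared by the
# reporting screen and the in-fold selection inside loocv().
compare_feature <- function(x, y, warn_name = NULL) {
  if (sd(c(x, y)) == 0) {
    if (!is.null(warn_name))
      warning("feature '", warn_name, "' is constant; assigned p = 1")
    return(list(test = "wilcoxon", stat = NA_real_, p = 1))
  }
  normal <- function(v) length(unique(v)) >= 3 &&
    length(v) >= 3 && shapiro.test(v)$p.value > 0.05
  if (normal(x) && normal(y)) {
    ht <- t.test(x, y)
    list(test = "t", stat = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
    list(test = "wilcoxon", stat = unname(ht$statistic), p = ht$p.value)
  }
}

# p-values for every column of X between the two levels of g; constants get
# p = 1 silently (used per fold, where warnings would flood).
feature_pvalues <- function(X, g) {
  lv <- levels(g)
  vapply(seq_len(ncol(X)), function(j)
    compare_feature(X[g == lv[1], j], X[g == lv[2], j])$p, numeric(1))
}

univariate_select <- function(tab, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g <- tab$group
  lv <- levels(g)
  if (any(table(g) < 2)) stop("need at least 2 samples per group")
  rows <- lapply(feature_names(tab), function(f) {
    x <- tab[[f]][g == lv[1]]
    y <- tab[[f]][g == lv[2]]
    cmp <- compare_feature(x, y, warn_name = f)
    out <- data.frame(Item = f, m1 = median(x), i1 = IQR(x), m2 = median(y),
                      i2 = IQR(y), test = cmp$test, W = cmp$stat, p = cmp$p,
                      stringsAsFactors = FALSE)
    names(out)[2:5] <- c(paste0("P50_", lv[1]), paste0("IQR_", lv[1]),
                         paste0("P50_", lv[2]), paste0("IQR_", lv[2]))
    out
  })
  results <- do.call(rbind, rows)
  p_sel <- if (adjust == "BH") p.adjust(results$p, "BH") else results$p
  list(selected = results$Item[p_sel <= alpha], results = results)
}

#' PCA dimensionality reduction of a feature table
#'
#' Features are standardized (zero mean, unit variance; constant features
#' are dropped with a warning) and projected onto the leading principal
#' components whose cumulative explained variance first reaches
#' `variance_target` -- an automated stand-in for a scree-plot choice.
#'
#' @param tab A [feature_table()] with >= 2 features and >= 2 samples.
#' @param variance_target Cumulative explained-variance fraction (default
#'   0.85).
#' @return A [feature_table()] of component scores with attributes
#'   `loadings`, `var_explained`, `n_components`.
#' @export
pca_reduce <- function(tab, variance_target = 0.85) {
  X <- feature_matrix(tab)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (ncol(X) < 2) stop("need at least 2 features")
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning("dropping constant features before PCA: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ve) >= variance_target - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out <- feature_table(scores, tab$group, tab$sample_id, tab$subject_id)
  attr(out, "loadings") <- pc$rotation[, seq_len(k), drop = FALSE]
  attr(out, "var_explained") <- ve
  attr(out, "n_components") <- k
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1, two-sided. On the gender table of
#' a 16-patient / 20-control cohort (`[[6,10],[7,13]]`) this gives
#' chi-square 0.024, p = 0.877.
#'
#' @param counts 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' U is counted for the first sample (`U = 0` when every `x` precedes every
#' `y`); `U_x + U_y = n_x * n_y`. Exact p for small untied samples,
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ht <- suppressWarnings(wilcox.test(x, y))
  list(U = unname(ht$statistic), p = ht$p.value)
}
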