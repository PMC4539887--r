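#' Correlation-adjusted t-scores (CAT-scores)
#'
#' Ranks features by class separability while accounting for feature
#' correlation: the vector of shrinkage t-statistics is decorrelated by the
#' inverse square root of the shrinkage feature correlation matrix,
#' `cat = R^(-1/2) t`. Features that merely echo a correlated neighbour are
#' down-weighted relative to ordinary t-scores.
#'
#' Both shrinkage intensities are estimated analytically from the data
#' (variances shrunk toward their median, correlations toward the identity,
#' Schafer-Strimmer-type estimators), which keeps the scores well defined
#' when features outnumber patients. With two classes the score is the
#' absolute CAT statistic of the single between-class contrast; with more
#' classes it is the root of the summed squared CAT statistics over
#' class-vs-rest contrasts. When the correlation matrix is the identity
#' (`lambda_cor = 1`) the scores reduce exactly to (shrinkage) t-scores.
#'
#' @param matrix numeric matrix, features (prototypes) x patients.
#' @param labels factor of class labels, aligned to the columns; every class
#'   needs at least 2 patients.
#' @param lambda_var,lambda_cor optional shrinkage intensities in `[0, 1]`
#'   overriding the analytic estimates.
#' @return a [RankedFeatures] with `method = "cat_score"`.
#' @references Zuber & Strimmer (2009), gene ranking by correlation-adjusted
#'   t-scores.
#' @export
catScore <- function(matrix, labels, lambda_var = NULL, lambda_cor = NULL) {
  labels <- checkLabels(matrix, labels)
  classes <- levels(labels)
  contrasts <- if (length(classes) == 2L) classes[1L] else classes
  tmat <- vapply(contrasts, function(cl)
    shrinkT(matrix, labels == cl, lambda_var = lambda_var),
    numeric(nrow(matrix)))
  R <- shrinkCor(matrix, labels, lambda_cor = lambda_cor)
  Rinvsqrt <- matPower(R, -0.5)
  cat_mat <- Rinvsqrt %*% tmat
  score <- if (length(classes) == 2L) abs(cat_mat[, 1L])
           else sqrt(rowSums(cat_mat^2))
  makeRanking(rownames(matrix), score, "cat_score")
}

checkLabels <- function(matrix, labels) {
  stopifnot(is.matrix(matrix), ncol(matrix) == length(labels))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  small <- table(labels) < 2L
  if (any(small))
    stop("class '", names(which(small))[1L], "' has fewer than 2 patients")
  labels
}

makeRanking <- function(ids, score, method, view = "view") {
  ord <- order(-score, ids)
  new("RankedFeatures", viewName = view, featureIds = ids[ord],
      scores = unname(score[ord]), method = method)
}

# Shrinkage two-sample t-statistics for the contrast `grp` vs rest:
# pooled per-feature variances are shrunk toward their median with an
# analytic intensity before entering the denominator.
shrinkT <- function(m, grp, lambda_var = NULL) {
  n1 <- sum(grp); n0 <- sum(!grp); n <- n1 + n0
  m1 <- rowMeans(m[, grp, drop = FALSE])
  m0 <- rowMeans(m[, !grp, drop = FALSE])
  xc <- m
  xc[, grp] <- xc[, grp] - m1
  xc[, !grp] <- xc[, !grp] - m0
  v <- rowSums(xc^2) / (n - 2)
  if (is.null(lambda_var)) {
    w <- xc^2
    var_v <- n / (n - 1)^3 * rowSums((w - rowMeans(w))^2)
    dev <- sum((v - stats::median(v))^2)
    lambda_var <- if (dev == 0) 1 else min(1, sum(var_v) / dev)
  }
  v_star <- lambda_var * stats::median(v) + (1 - lambda_var) * v
  (m1 - m0) / sqrt(v_star * (1 / n1 + 1 / n0))
}

# Shrinkage correlation matrix of the within-class-centered data:
# R* = lambda I + (1 - lambda) R with the analytic intensity
# lambda = sum Var(r_ij) / sum r_ij^2 over off-diagonal pairs.
shrinkCor <- function(m, labels, lambda_cor = NULL) {
  n <- ncol(m)
  xc <- m
  for (cl in levels(labels)) {
    idx <- labels == cl
    xc[, idx] <- xc[, idx] - rowMeans(m[, idx, drop = FALSE])
  }
  sds <- sqrt(rowSums(xc^2) / (n - 1))
  sds[sds == 0] <- 1
  u <- xc / sds
  R <- (u %*% t(u)) / (n - 1)
  diag(R) <- 1
  if (is.null(lambda_cor)) {
    p <- nrow(m)
    num <- 0; den <- 0
    for (i in seq_len(p - 1L)) {
      w <- u[rep(i, p - i), , drop = FALSE] * u[(i + 1L):p, , drop = FALSE]
      wbar <- rowMeans(w)
      num <- num + sum(n / (n - 1)^3 * rowSums((w - wbar)^2))
      den <- den + sum((n / (n - 1) * wbar)^2)
    }
    lambda_cor <- if (den == 0) 1 else min(1, num / den)
  }
  lambda_cor * diag(nrow(R)) + (1 - lambda_cor) * R
}

# Symmetric matrix power via eigendecomposition; eigenvalues floored to keep
# the inverse square root defined for near-singular shrinkage targets.
matPower <- function(S, power) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (vals^power * t(e$vectors))
}

#' Random-forest permutation importance
#'
#' Ranks features by mean decrease in out-of-bag accuracy when each feature
#' is permuted (a random-forest permutation importance). Negative
#' importances are floored at 0 so the scores can be cut cumulatively.
#' Deterministic given `seed`.
#'
#' @inheritParams catScore
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return a [RankedFeatures] with `method = "rf_importance"`.
#' @export
rfImportance <- function(matrix, labels, n_trees = 1000L, seed = 1L) {
  labels <- checkLabels(matrix, labels)
  fit <- withSeed(seed,
    randomForest::randomForest(x = t(matrix), y = labels,
                               ntree = n_trees, importance = TRUE))
  imp <- randomForest::importance(fit, type = 1L, scale = FALSE)[, 1L]
  makeRanking(rownames(matrix), pmax(imp, 0), "rf_importance")
}

#' Cut a ranking at a cumulative-score fraction
#'
#' Returns the shortest prefix of the ranking whose scores sum to at least
#' `fraction` of the total score. Selections are nested across fractions:
#' the 60 % cut is contained in the 70 % cut, and so on.
#'
#' @param ranking a [RankedFeatures].
#' @param fraction target cumulative fraction in `(0, 1]`; the stage uses
#'   0.6, 0.7, 0.8 and 0.9.
#' @return character vector of selected feature ids.
#' @export
cumulativeCut <- function(ranking, fraction) {
  stopifnot(is(ranking, "RankedFeatures"),
            fraction > 0, fraction <= 1)
  total <- sum(ranking@scores)
  if (total <= 0) stop("all scores are zero; nothing to cut")
  cum <- cumsum(ranking@scores)
  n <- which(cum >= fraction * total - 1e-12)[1L]
  ranking@featureIds[seq_len(n)]
}
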