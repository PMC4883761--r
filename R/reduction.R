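#' Univariate screening of features against a binary outcome
#'
#' Fits one single-covariate logistic regression per feature and keeps
#' features whose Wald p-value falls below `alpha`. Constant features are
#' excluded with a warning (the test is undefined).
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary 0/1 outcome.
#' @param alpha retention threshold on the Wald p-value (default 0.2).
#' @return character vector of selected feature names.
#' @export
univariate_screen <- function(X, y, alpha = 0.2) {
  X <- as.data.frame(X)
  keep <- character(0)
  for (nm in names(X)) {
    x <- X[[nm]]
    if (length(unique(x)) < 2) {
      warning("constant feature `", nm, "` excluded from screen")
      next
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    p <- summary(fit)$coefficients["x", "Pr(>|z|)"]
    if (!is.na(p) && p < alpha) keep <- c(keep, nm)
  }
  keep
}

#' LASSO feature selection by cross-validated penalized logistic regression
#'
#' L1-penalized logistic regression over a penalty path; the penalty is
#' chosen by cross-validated binomial deviance and the selected set is the
#' features with nonzero coefficients at that penalty. Features are
#' standardized internally by the solver.
#'
#' @param X numeric matrix of features.
#' @param y binary 0/1 outcome.
#' @param nfolds cross-validation folds for the path (default 5).
#' @param lambda `"min"` (deviance-minimizing penalty) or `"1se"`.
#' @param seed integer seed for fold assignment.
#' @return list with `selected` (feature names) and `lambda` (the chosen
#'   penalty).
#' @export
lasso_select <- function(X, y, nfolds = 5, lambda = "min", seed = 1L) {
  if (length(unique(y)) < 2) stop("degenerate outcome")
  X <- as.matrix(X)
  set.seed(child_seed(seed, 8))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = nfolds,
                          standardize = TRUE)
  lam <- if (lambda == "1se") cv$lambda.1se else cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  list(selected = names(cf)[cf != 0], lambda = lam)
}

#' Principal component extraction on standardized features
#'
#' Standardizes features to zero mean and unit variance (correlation-matrix
#' PCA) and returns the leading component scores. Scores of distinct
#' components are empirically uncorrelated and loadings are orthonormal.
#'
#' @param X numeric matrix of features.
#' @param n_components number of leading components to keep (default 5).
#' @return list with `scores` (n x n_components matrix), `loadings`,
#'   `center`, `scale`, `sdev`, usable with [pca_transform()].
#' @export
pca_extract <- function(X, n_components = 5) {
  X <- as.matrix(X)
  if (n_components > ncol(X))
    stop("n_components exceeds the number of features")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         "; drop before PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       center = pc$center, scale = pc$scale, sdev = pc$sdev)
}

#' Project new data onto fitted principal components
#'
#' @param fit result of [pca_extract()].
#' @param X numeric matrix with the same columns as at fit time.
#' @return score matrix.
#' @export
pca_transform <- function(fit, X) {
  X <- as.matrix(X)[, names(fit$center), drop = FALSE]
  scale(X, center = fit$center, scale = fit$scale) %*% fit$loadings
}
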