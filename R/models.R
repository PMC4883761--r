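#' Risk models for binary postoperative outcomes
#'
#' Four model families share the `risk_model` interface: logistic
#' regression (IRLS maximum likelihood), generalized additive models with
#' cubic-spline smooths whose degrees of freedom are selected by restricted
#' maximum likelihood and linearized when effectively straight, Gaussian /
#' Bernoulli naive Bayes, and a soft-margin support vector machine.
#' [predict_risk()] returns probabilities for the probabilistic models and
#' raw decision scores for the SVM.
#'
#' @name risk_models
NULL

new_risk_model <- function(kind, fit, schema, extra = list()) {
  structure(c(list(kind = kind, fit = fit, schema = schema), extra),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %s> %d features\n", x$kind, length(x$schema)))
  invisible(x)
}

check_schema <- function(model, X) {
  if (!all(model$schema %in% colnames(X)))
    stop("feature schema mismatch: missing ",
         paste(setdiff(model$schema, colnames(X)), collapse = ", "))
}

as_model_frame <- function(X) {
  X <- as.data.frame(X)
  names(X) <- make.names(names(X))
  X
}

#' Fit a logistic regression risk model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares; predicted risk is `1 / (1 + exp(-(b0 + sum(bi xi))))`.
#'
#' @param X numeric matrix or data.frame of features (no missing values).
#' @param y binary 0/1 outcome.
#' @return a `risk_model` of kind `"logistic"`.
#' @export
fit_logistic <- function(X, y) {
  d <- as_model_frame(X)
  schema <- names(d)
  d$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::binomial()))
  if (!fit$converged) warning("logistic fit did not converge")
  new_risk_model("logistic", fit, schema)
}

#' Fit a generalized additive risk model with spline linearization
#'
#' The logit of risk is an additive sum of per-feature terms: cubic
#' regression spline smooths for the listed continuous features and linear
#' terms otherwise. Smoothing is selected by restricted maximum likelihood.
#' After the first fit, smoothed terms whose estimated effective degrees of
#' freedom fall below `edf_linear_threshold` (effectively straight lines)
#' are demoted to linear terms and the model is refitted, so the final
#' model partitions features into a linear set and a smoothed set.
#' Smoothed features with fewer than 10 distinct values are demoted up
#' front.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary 0/1 outcome.
#' @param smooth_features names of features to smooth (subset of columns).
#' @param edf_linear_threshold edf below which a smooth is refit as linear
#'   (default 1.5).
#' @param k spline basis dimension per smoothed term (default 10).
#' @return a `risk_model` of kind `"gam"`, with a `diagnostics` element
#'   (per-term edf, which terms were linearized, smoothing parameters).
#' @export
fit_gam <- function(X, y, smooth_features = character(0),
                    edf_linear_threshold = 1.5, k = 10) {
  d <- as_model_frame(X)
  schema <- names(d)
  smooth_features <- make.names(smooth_features)
  bad <- setdiff(smooth_features, names(d))
  if (length(bad)) stop("unknown smooth feature(s): ", paste(bad, collapse = ", "))
  demoted <- character(0)
  for (nm in smooth_features) {
    if (length(unique(d[[nm]])) < 10) {
      warning("fewer than 10 distinct values in `", nm,
              "`; term demoted to linear")
      demoted <- c(demoted, nm)
    }
  }
  smooth_features <- setdiff(smooth_features, demoted)
  d$.y <- y

  gam_formula <- function(sm) {
    lin <- setdiff(schema, sm)
    rhs <- c(sprintf("s(%s, bs = \"cr\", k = %d)", sm, k), lin)
    if (length(rhs) == 0) rhs <- "1"
    stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  }
  fit <- mgcv::gam(gam_formula(smooth_features), data = d,
                   family = stats::binomial(), method = "REML")
  edf <- numeric(0)
  if (length(smooth_features)) {
    edf <- stats::setNames(
      vapply(fit$smooth, function(s) sum(fit$edf[s$first.para:s$last.para]),
             numeric(1)),
      vapply(fit$smooth, function(s) s$term, character(1)))  # per-feature edf
  }
  linearized <- names(edf)[edf < edf_linear_threshold]
  if (length(linearized)) {
    keep <- setdiff(smooth_features, linearized)
    fit <- mgcv::gam(gam_formula(keep), data = d,
                     family = stats::binomial(), method = "REML")
    smooth_features <- keep
  }
  diagnostics <- list(edf = edf,
                      linearized = union(demoted, linearized),
                      smoothed = smooth_features,
                      sp = fit$sp,
                      edf_linear_threshold = edf_linear_threshold)
  new_risk_model("gam", fit, schema, list(diagnostics = diagnostics))
}

#' Fit a naive Bayes risk model with typed conditionals
#'
#' Class priors from outcome frequencies; conditionally independent
#' features given the class, with Gaussian conditionals for continuous
#' features and Laplace-smoothed Bernoulli tables for binary (0/1)
#' features. Columns with at most two distinct values are treated as
#' Bernoulli; the posterior is normalized over both classes. Within-class
#' variances are floored at 1e-9.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary 0/1 outcome.
#' @param laplace pseudo-count for Bernoulli tables (default 1).
#' @return a `risk_model` of kind `"naive_bayes"`.
#' @export
fit_naive_bayes <- function(X, y, laplace = 1) {
  d <- as_model_frame(X)
  schema <- names(d)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  prior1 <- mean(y)
  tabs <- list()
  for (nm in schema) {
    x <- d[[nm]]
    if (all(x %in% c(0, 1))) {
      p1 <- (sum(x[y == 1]) + laplace) / (sum(y == 1) + 2 * laplace)
      p0 <- (sum(x[y == 0]) + laplace) / (sum(y == 0) + 2 * laplace)
      tabs[[nm]] <- list(type = "bernoulli", p1 = p1, p0 = p0)
    } else {
      v1 <- stats::var(x[y == 1]); v0 <- stats::var(x[y == 0])
      if (is.na(v1) || v1 < 1e-9 || is.na(v0) || v0 < 1e-9)
        warning("near-zero within-class variance in `", nm, "`; floored")
      tabs[[nm]] <- list(type = "gaussian",
                         mu1 = mean(x[y == 1]), sd1 = sqrt(max(v1, 1e-9, na.rm = TRUE)),
                         mu0 = mean(x[y == 0]), sd0 = sqrt(max(v0, 1e-9, na.rm = TRUE)))
    }
  }
  new_risk_model("naive_bayes", list(prior1 = prior1, tables = tabs,
                                     laplace = laplace), schema)
}

predict_naive_bayes <- function(model, d) {
  lp1 <- log(model$fit$prior1); lp0 <- log(1 - model$fit$prior1)
  l1 <- rep(lp1, nrow(d)); l0 <- rep(lp0, nrow(d))
  for (nm in model$schema) {
    t <- model$fit$tables[[nm]]
    x <- d[[nm]]
    if (t$type == "bernoulli") {
      l1 <- l1 + ifelse(x == 1, log(t$p1), log(1 - t$p1))
      l0 <- l0 + ifelse(x == 1, log(t$p0), log(1 - t$p0))
    } else {
      l1 <- l1 + stats::dnorm(x, t$mu1, t$sd1, log = TRUE)
      l0 <- l0 + stats::dnorm(x, t$mu0, t$sd0, log = TRUE)
    }
  }
  1 / (1 + exp(l0 - l1))
}

#' Fit a support vector machine risk model
#'
#' Soft-margin SVM on internally standardized features. Default kernel is
#' radial basis function with the package default bandwidth; class weights
#' default to inverse class frequency, which matters for the rare-outcome
#' (5% prevalence) setting. The decision score `w.x - b` is returned by
#' [predict_risk()] and is not a probability.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary 0/1 outcome.
#' @param kernel `"radial"` or `"linear"`.
#' @param cost soft-margin cost parameter.
#' @param class_weights `"inverse"` (default) for inverse-prevalence
#'   weights, or a named numeric vector over classes `"0"`, `"1"`.
#' @return a `risk_model` of kind `"svm"`.
#' @export
fit_svm <- function(X, y, kernel = "radial", cost = 1,
                    class_weights = "inverse") {
  d <- as_model_frame(X)
  schema <- names(d)
  yf <- factor(y, levels = c(0, 1))
  if (identical(class_weights, "inverse")) {
    class_weights <- c("0" = 1 / mean(y == 0), "1" = 1 / mean(y == 1))
    class_weights <- class_weights / min(class_weights)
  }
  fit <- e1071::svm(x = as.matrix(d), y = yf, kernel = kernel, cost = cost,
                    class.weights = class_weights, scale = TRUE)
  new_risk_model("svm", fit, schema)
}

#' Predict risk scores from a fitted model
#'
#' Probabilistic models (`logistic`, `gam`, `naive_bayes`) return event
#' probabilities in (0, 1); the SVM returns signed decision scores, used
#' directly for AUC and thresholded at 0 for accuracy/PPV.
#'
#' @param model a `risk_model`.
#' @param X feature matrix or data.frame matching the fitted schema.
#' @return numeric score vector of length `nrow(X)`.
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "risk_model"))
  d <- as_model_frame(X)
  check_schema(model, d)
  d <- d[model$schema]
  switch(model$kind,
    logistic = unname(stats::predict(model$fit, newdata = d,
                                     type = "response")),
    gam = unname(as.numeric(mgcv::predict.gam(model$fit, newdata = d,
                                              type = "response"))),
    naive_bayes = predict_naive_bayes(model, d),
    svm = {
      pr <- stats::predict(model$fit, newdata = as.matrix(d),
                           decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      # orient scores so larger means higher risk of class "1"
      if (grepl("^0/1", colnames(attr(pr, "decision.values"))[1])) -dv else dv
    },
    stop("unknown model kind: ", model$kind))
}

#' Decision threshold appropriate for a model's score scale
#'
#' 0.5 for probabilistic models, 0 for SVM decision scores.
#'
#' @param model a `risk_model`.
#' @return numeric threshold.
#' @export
default_threshold <- function(model) if (model$kind == "svm") 0 else 0.5

#' Serialize fitted model parameters to JSON
#'
#' Coefficient-level serialization for exact re-scoring of the logistic
#' model and the naive Bayes tables; for GAM and SVM the stored R object is
#' the canonical representation and only summary metadata is written.
#'
#' @param model a `risk_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  payload <- switch(model$kind,
    logistic = list(kind = "logistic",
                    coefficients = as.list(stats::coef(model$fit))),
    naive_bayes = list(kind = "naive_bayes", prior1 = model$fit$prior1,
                       tables = model$fit$tables),
    gam = list(kind = "gam", schema = model$schema,
               smoothed = model$diagnostics$smoothed,
               edf = as.list(model$diagnostics$edf)),
    svm = list(kind = "svm", schema = model$schema,
               n_support = model$fit$tot.nSV))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
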