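#' Stratified train/validation split
#'
#' Allocates patients to a training fold at `train_fraction` separately
#' within each outcome class, so the outcome prevalence of each partition
#' matches the cohort's.
#'
#' @param y binary 0/1 outcome.
#' @param train_fraction training fraction (default 0.7).
#' @param seed integer seed.
#' @return an object of class `split_plan` with `train` and `validation`
#'   integer index vectors.
#' @export
stratified_split <- function(y, train_fraction = 0.7, seed = 1L) {
  if (any(!y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (min(table(y)) < 2) stop("each class needs at least 2 members")
  set.seed(child_seed(seed, 5))
  train <- integer(0)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    k <- round(train_fraction * length(idx))
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  structure(list(train = train,
                 validation = setdiff(seq_along(y), train),
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted half; computed from midranks, so it agrees exactly with
#' exhaustive pair enumeration.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil standard error of an AUC estimate
auc_se <- function(a, n1, n0) {
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

#' Classification accuracy and positive predictive value at a threshold
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold (default 0.5; use 0 for SVM decision
#'   scores).
#' @return named vector `c(accuracy, ppv)`; `ppv` is `NA` when no patient
#'   is predicted positive.
#' @export
accuracy_ppv <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  acc <- mean(pred == labels)
  ppv <- if (sum(pred) == 0) NA_real_ else sum(pred == 1 & labels == 1) / sum(pred)
  c(accuracy = acc, ppv = ppv)
}

#' Percentile bootstrap confidence interval for a validation metric
#'
#' Resamples validation patients with replacement and recomputes the metric
#' `B` times; the interval is the percentile interval at the requested
#' level and the point estimate is the observed metric.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param metric function `(scores, labels) -> numeric scalar` (default
#'   [auc()]).
#' @param B bootstrap replicates (default 2000; at least 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named vector `c(point, lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auc, B = 2000,
                         level = 0.95, seed = 1L) {
  stopifnot(B >= 100)
  n <- length(scores)
  point <- metric(scores, labels)
  set.seed(child_seed(seed, 6))
  reps <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    reps[b] <- tryCatch(metric(scores[i], labels[i]), error = function(e) NA)
  }
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE)
  c(point = point, lower = q[1], upper = q[2])
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups patients into deciles of predicted risk, compares observed and
#' expected event counts per group with the chi-squared statistic
#' `sum((O - E)^2 / (n_g * p_g * (1 - p_g)))`, and refers it to a
#' chi-squared distribution with `groups - 2` degrees of freedom. Groups
#' with zero expected events (or non-events) are merged with their
#' neighbor.
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param labels binary 0/1 labels.
#' @param groups number of risk groups (default 10).
#' @return named vector `c(statistic, df, p_value)`.
#' @export
hosmer_lemeshow <- function(probabilities, labels, groups = 10) {
  stopifnot(all(probabilities >= 0), all(probabilities <= 1))
  br <- unique(stats::quantile(probabilities, seq(0, 1, length.out = groups + 1),
                               names = FALSE, type = 7))
  if (length(br) < 3) stop("probabilities too concentrated to form groups")
  g <- cut(probabilities, br, include.lowest = TRUE, labels = FALSE)
  O <- tapply(labels, g, sum)
  E <- tapply(probabilities, g, sum)
  n_g <- tapply(labels, g, length)
  # merge groups whose expected counts vanish with their lower neighbor
  while (length(n_g) > 2 && any(E < 1e-9 | (n_g - E) < 1e-9)) {
    i <- which(E < 1e-9 | (n_g - E) < 1e-9)[1]
    j <- if (i == 1) 2 else i - 1
    O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; n_g[j] <- n_g[j] + n_g[i]
    O <- O[-i]; E <- E[-i]; n_g <- n_g[-i]
  }
  pbar <- E / n_g
  stat <- sum((O - E)^2 / (n_g * pbar * (1 - pbar)))
  df <- length(n_g) - 2
  c(statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Compare two models' repeated-split AUCs
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-repetition AUC
#' differences.
#'
#' @param auc_a,auc_b numeric vectors of per-repetition AUCs, paired by
#'   repetition.
#' @return two-sided p-value (1 when all differences are zero).
#' @export
compare_models <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b))
  d <- auc_a - auc_b
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(auc_a, auc_b, paired = TRUE)$p.value)
}

#' Partial risk-function curves from a GAM and a logistic model
#'
#' Evaluates each model's partial effect for one feature over a grid, with
#' all other features held at their reference (mean) values, on the logit
#' scale and centered at the grid mean. For the GAM the feature must be
#' among its smoothed terms; its effective degrees of freedom annotate the
#' curve.
#'
#' @param gam_model a `risk_model` of kind `"gam"`.
#' @param logistic_model a `risk_model` of kind `"logistic"`.
#' @param X reference feature data (used for the held-at values).
#' @param feature feature name.
#' @param grid numeric grid of feature values (default 50 points spanning
#'   the observed range).
#' @return data.frame with one row per grid point: `feature_value`,
#'   `gam_effect`, `logistic_effect`, plus attribute `edf`.
#' @export
risk_function_curves <- function(gam_model, logistic_model, X, feature,
                                 grid = NULL) {
  d <- as_model_frame(X)
  feature <- make.names(feature)
  if (!feature %in% gam_model$schema || !feature %in% logistic_model$schema)
    stop("feature absent from one of the models")
  sm_terms <- gam_model$diagnostics$smoothed
  if (!feature %in% sm_terms)
    stop("feature `", feature, "` is not smoothed in the GAM")
  if (is.null(grid))
    grid <- seq(min(d[[feature]]), max(d[[feature]]), length.out = 50)
  ref <- d[rep(1, length(grid)), gam_model$schema, drop = FALSE]
  for (nm in names(ref)) ref[[nm]] <- mean(d[[nm]])
  ref[[feature]] <- grid
  lp_gam <- as.numeric(mgcv::predict.gam(gam_model$fit, newdata = ref,
                                         type = "link"))
  lp_log <- stats::predict(logistic_model$fit, newdata = ref, type = "link")
  out <- data.frame(feature_value = grid,
                    gam_effect = lp_gam - mean(lp_gam),
                    logistic_effect = as.numeric(lp_log - mean(lp_log)))
  attr(out, "edf") <- unname(gam_model$diagnostics$edf[feature])
  attr(out, "feature") <- feature
  out
}
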