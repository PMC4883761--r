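# shared small fixtures, built in code at load time

# minimal spec without the heavyweight default feature set
small_spec <- function(n = 2000, seed = 42, ...) {
  cohort_spec(
    n_patients = n,
    prevalence = c(aki = 0.36, sepsis = 0.05),
    continuous = data.frame(
      name = c("age", "hematocrit"), mean = c(56, 34.3), sd = c(15, 6),
      family = "normal", beta = c(0.5, -0.3), shape = "linear",
      stringsAsFactors = FALSE),
    cont_cor = 0.2,
    binary = data.frame(name = c("diabetes", "chf"), rate = c(0.2, 0.1),
                        beta = c(0.4, 0.5), cluster = c(1L, 1L),
                        stringsAsFactors = FALSE),
    nominal = data.frame(name = "surgeon", n_levels = 40L, zipf = 1.0,
                         effect_sd = 0.3, stringsAsFactors = FALSE),
    code = list(n_top_classes = 5L, children_per_class = c(2L, 3L),
                leaves_per_child = c(2L, 4L), zipf = 1.0,
                effect_sd = c(0.3, 0.2, 0.1)),
    seed = seed, ...)
}

# logistic-model data with known coefficients, for recovery tests
logistic_data <- function(n, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  y <- rbinom(n, 1, plogis(intercept + X %*% beta))
  list(X = X, y = y)
}

# exhaustive-pair AUC oracle (independent of the rank-based implementation)
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# weighted Gini impurity of a two-way split of level-count data
gini_split <- function(n1_left, n0_left, n1_right, n0_right) {
  imp <- function(a, b) {
    n <- a + b
    if (n == 0) return(0)
    p <- a / n
    2 * p * (1 - p)
  }
  nl <- n1_left + n0_left; nr <- n1_right + n0_right
  (nl * imp(n1_left, n0_left) + nr * imp(n1_right, n0_right)) / (nl + nr)
}

# best Gini over all 2^(k-1)-1 binary partitions of levels (brute force)
best_gini_partition <- function(n1, n0) {
  k <- length(n1)
  best <- Inf
  for (mask in 1:(2^(k - 1) - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    g <- gini_split(sum(n1[sel]), sum(n0[sel]),
                    sum(n1[!sel]), sum(n0[!sel]))
    if (g < best) best <- g
  }
  best
}

# best Gini over threshold splits of levels ordered by a score
best_gini_threshold <- function(n1, n0, score) {
  ord <- order(score)
  n1 <- n1[ord]; n0 <- n0[ord]
  best <- Inf
  for (cut in seq_len(length(n1) - 1)) {
    sel <- seq_len(length(n1)) <= cut
    g <- gini_split(sum(n1[sel]), sum(n0[sel]),
                    sum(n1[!sel]), sum(n0[!sel]))
    if (g < best) best <- g
  }
  best
}

zipf_probs_test <- function(k, s = 1) {
  p <- seq_len(k)^(-s)
  p / sum(p)
}
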