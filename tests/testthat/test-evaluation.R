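test_that("stratified split preserves class balance and is reproducible", {
  set.seed(41)
  y <- rbinom(100, 1, 0.36)
  while (sum(y) != 36) y <- rbinom(100, 1, 0.36)
  plan <- stratified_split(y, 0.7, seed = 1)
  expect_length(plan$train, 70)
  expect_equal(sum(y[plan$train]), round(0.7 * 36))
  expect_identical(plan, stratified_split(y, 0.7, seed = 1))
  expect_setequal(c(plan$train, plan$validation), 1:100)
  expect_error(stratified_split(c(0, 0, 0, 1), 0.7), "at least 2")

  # stratification shrinks validation-prevalence variability
  y2 <- rbinom(2000, 1, 0.05)
  strat <- vapply(1:50, function(s)
    mean(y2[stratified_split(y2, 0.7, seed = s)$validation]), numeric(1))
  unstrat <- vapply(1:50, function(s) {
    set.seed(s); mean(y2[sample(2000, 600)])
  }, numeric(1))
  expect_lt(sd(strat), sd(unstrat))
  expect_true(all(abs(strat - mean(y2)) < 0.005))
})

test_that("AUC matches exhaustive pair enumeration", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(42)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(auc(sc, lb), auc_brute(sc, lb), tolerance = 1e-12)
    expect_equal(auc(sc, 1 - lb), 1 - auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("accuracy and PPV come straight from the confusion counts", {
  sc <- c(rep(0.9, 30), rep(0.9, 10), rep(0.1, 50), rep(0.1, 10))
  lb <- c(rep(1, 30), rep(0, 10), rep(0, 50), rep(1, 10))
  out <- accuracy_ppv(sc, lb, 0.5)
  expect_equal(unname(out["accuracy"]), 0.80)
  expect_equal(unname(out["ppv"]), 0.75)
  perfect <- accuracy_ppv(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unname(perfect), c(1, 1))
  none <- accuracy_ppv(c(0.9, 0.1), c(1, 0), 1.01)
  expect_true(is.na(none["ppv"]))
})

test_that("bootstrap CI degenerates, widens, and reproduces correctly", {
  const <- bootstrap_ci(rep(1, 50), rep(c(0, 1), 25),
                        metric = function(s, l) 0.7, B = 200, seed = 2)
  expect_equal(unname(const["lower"]), unname(const["upper"]))
  set.seed(43)
  mk <- function(n) {
    lb <- rbinom(n, 1, 0.3)
    sc <- rnorm(n, lb)
    bootstrap_ci(sc, lb, B = 300, seed = 7)
  }
  small <- mk(500); big <- mk(5000)
  expect_gt(small["upper"] - small["lower"], big["upper"] - big["lower"])
})

test_that("Hosmer-Lemeshow is zero under exact group calibration", {
  p <- rep(seq(0.05, 0.95, 0.1), each = 100)
  set.seed(44)
  lb <- unlist(lapply(seq(0.05, 0.95, 0.1), function(q)
    sample(c(rep(1, round(100 * q)), rep(0, 100 - round(100 * q))))))
  out <- hosmer_lemeshow(p, lb)
  expect_equal(unname(out["statistic"]), 0, tolerance = 1e-20)
  expect_equal(unname(out["df"]), 8)
})

test_that("Hosmer-Lemeshow flags gross miscalibration", {
  set.seed(45)
  p <- runif(10000, 0.05, 0.95)
  lb <- rbinom(10000, 1, p)
  miscal <- hosmer_lemeshow(p^2, lb)
  expect_lt(miscal["p_value"], 1e-6)
  ok <- hosmer_lemeshow(p, lb)
  expect_gt(ok["p_value"], 1e-4)
})

test_that("paired Wilcoxon model comparison behaves at the extremes", {
  expect_equal(compare_models(rep(0.8, 20), rep(0.8, 20)), 1)
  set.seed(46)
  a <- 0.85 + rnorm(50, 0, 0.01)
  b <- 0.60 + rnorm(50, 0, 0.01)
  expect_lt(compare_models(a, b), 0.01)
  expect_equal(compare_models(a, b), compare_models(b, a))
})

test_that("risk-function curves expose GAM non-monotonicity", {
  set.seed(47)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.7 * (x1^2 - 1) + 0.5 * x2))
  X <- cbind(x1 = x1, x2 = x2)
  g <- fit_gam(X, y, smooth_features = "x1")
  lr <- fit_logistic(X, y)
  grid <- seq(-2, 2, length.out = 41)
  cv <- risk_function_curves(g, lr, X, "x1", grid)
  expect_equal(nrow(cv), 41)
  # logistic partial effect is a straight line; GAM dips near the truth's argmin
  expect_equal(diff(range(diff(cv$logistic_effect))), 0, tolerance = 1e-8)
  expect_lt(abs(cv$feature_value[which.min(cv$gam_effect)]), 0.5)
  expect_error(risk_function_curves(g, lr, X, "x2"), "not smoothed")
})

test_that("run_experiment produces a full factorial report", {
  sim <- simulate_cohort(small_spec(n = 1200))
  cfg <- experiment_config(models = c("logistic", "naive_bayes"),
                           arms = c("none", "pca"), repetitions = 2,
                           n_components = 3, bootstrap_B = 150, seed = 3)
  rep <- suppressWarnings(run_experiment(sim$cohort, cfg))
  expect_equal(nrow(rep$summary), 2 * 2 * 2)
  expect_true(all(rep$summary$auc >= 0 & rep$summary$auc <= 1))
  expect_true(all(rep$summary$auc_lower <= rep$summary$auc + 1e-12))
  expect_true(all(rep$summary$auc_upper >= rep$summary$auc - 1e-12))
  expect_equal(nrow(rep$per_repetition), 2 * 2 * 2 * 2)
})

test_that("whole-cohort preprocessing is optimistic for high-cardinality features", {
  sp <- small_spec(n = 3000)
  sp$nominal <- data.frame(name = "surgeon", n_levels = 400L, zipf = 0.5,
                           effect_sd = 0.4, stringsAsFactors = FALSE)
  sim <- simulate_cohort(sp)
  base <- experiment_config(models = "logistic", arms = "none",
                            outcomes = "aki", repetitions = 3,
                            bootstrap_B = 150, seed = 8)
  honest <- suppressWarnings(run_experiment(sim$cohort, base))
  paper <- base; paper$paper_mode <- TRUE
  leaky <- suppressWarnings(run_experiment(sim$cohort, paper))
  expect_gt(mean(leaky$per_repetition$auc), mean(honest$per_repetition$auc))
})

test_that("the screening arm restricts the design to retained features", {
  sim <- simulate_cohort(small_spec(n = 1500))
  cfg <- experiment_config(models = "logistic", arms = "screen",
                           outcomes = "aki", repetitions = 1,
                           bootstrap_B = 150, seed = 13)
  rep <- suppressWarnings(run_experiment(sim$cohort, cfg))
  expect_equal(nrow(rep$summary), 1)
  expect_gt(rep$summary$auc, 0.5)
})
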