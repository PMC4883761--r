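test_that("generation is deterministic given spec and seed", {
  a <- generate_cohort(small_spec(n = 500))
  b <- generate_cohort(small_spec(n = 500))
  expect_identical(a$cohort$features, b$cohort$features)
  expect_identical(a$cohort$outcomes, b$cohort$outcomes)
  expect_identical(a$true_model$intercepts, b$true_model$intercepts)
})

test_that("intercept calibration matches closed forms and hits targets", {
  eta0 <- rep(0, 1000)
  expect_equal(calibrate_intercept(eta0, 0.05), qlogis(0.05), tolerance = 1e-5)
  expect_equal(calibrate_intercept(eta0, 0.36), qlogis(0.36), tolerance = 1e-5)
  set.seed(1)
  eta <- rnorm(5000, 0, 1.3)
  for (tgt in c(0.05, 0.36, 0.7)) {
    a <- calibrate_intercept(eta, tgt)
    expect_lt(abs(mean(plogis(a + eta)) - tgt), 1e-4)
  }
  expect_error(calibrate_intercept(eta, 0), "strictly")
  expect_error(calibrate_intercept(eta, 1), "strictly")
})

test_that("realized prevalence tracks the calibrated target", {
  # symmetric null: all effects zero, intercept 0
  sp <- small_spec(n = 4000)
  sp$continuous$beta[] <- 0; sp$binary$beta[] <- 0
  sp$nominal$effect_sd[] <- 0; sp$code$effect_sd[] <- 0
  sp$prevalence <- c(aki = 0.5)
  g <- generate_cohort(sp)
  p <- mean(g$cohort$outcomes$aki)
  expect_lt(abs(p - 0.5), 3 / sqrt(4000))

  g2 <- generate_cohort(cohort_spec(n_patients = 20000, seed = 11))
  expect_gte(mean(g2$cohort$outcomes$aki), 0.35)
  expect_lte(mean(g2$cohort$outcomes$aki), 0.37)
  expect_lt(abs(mean(g2$cohort$outcomes$sepsis) - 0.05), 0.01)
})

test_that("a positive effect raises event rates in the upper tail", {
  sp <- small_spec(n = 10000)
  sp$continuous <- data.frame(name = "x", mean = 0, sd = 1,
                              family = "normal", beta = 1, shape = "linear",
                              stringsAsFactors = FALSE)
  sp$cont_cor <- 0
  sp$binary <- NULL; sp$nominal <- NULL; sp$code <- NULL
  g <- generate_cohort(sp)
  x <- g$cohort$features$x; y <- g$cohort$outcomes$aki
  top <- y[x > quantile(x, 0.9)]; bottom <- y[x < quantile(x, 0.1)]
  expect_gt(mean(top), mean(bottom))
})

test_that("missingness injection is MCAR at the requested rate", {
  g <- generate_cohort(small_spec(n = 10000))
  same <- inject_missingness(g$cohort, 0, seed = 3)
  expect_identical(same$features, g$cohort$features)
  m <- inject_missingness(g$cohort, 0.1, seed = 3)
  fr <- colMeans(is.na(m$features))
  expect_true(all(fr > 0.09 & fr < 0.11))
  expect_false(anyNA(m$outcomes))
  expect_error(inject_missingness(g$cohort, 1), "rates")
})

test_that("outlier injection records its indices and lands outside the bulk", {
  g <- generate_cohort(small_spec(n = 5000))
  same <- inject_outliers(g$cohort, 0, seed = 5)
  expect_identical(same$features, g$cohort$features)
  o <- inject_outliers(g$cohort, 0.01, magnitude = 10, seed = 5)
  idx <- attr(o, "outlier_index")
  for (nm in names(idx)) {
    expect_length(idx[[nm]], round(0.01 * 5000))
    clean <- g$cohort$features[[nm]]
    rng <- quantile(clean, c(0.01, 0.99))
    vals <- o$features[[nm]][idx[[nm]]]
    expect_true(all(vals < rng[1] | vals > rng[2]))
  }
  expect_error(inject_outliers(g$cohort, 0.01, magnitude = 1), "magnitude")
})

test_that("theoretical AUC behaves as a discrimination ceiling", {
  sp <- small_spec(n = 4000)
  sp$continuous$beta[] <- 0; sp$binary$beta[] <- 0
  sp$nominal$effect_sd[] <- 0; sp$code$effect_sd[] <- 0
  g <- generate_cohort(sp)
  a <- theoretical_auc(g$true_model, g$cohort, "aki")
  n1 <- sum(g$cohort$outcomes$aki); n0 <- 4000 - n1
  # null score: AUC near 1/2 within a few pair-count standard errors
  expect_lt(abs(a - 0.5), 3 * sqrt((n1 + n0 + 1) / (12 * n1 * n0)))

  sp2 <- small_spec(n = 4000)
  sp2$continuous$beta <- c(8, 0)  # near-deterministic single feature
  g2 <- generate_cohort(sp2)
  expect_gt(theoretical_auc(g2$true_model, g2$cohort, "aki"), 0.95)
})

test_that("nominal level frequencies follow the configured Zipf law", {
  sp <- small_spec(n = 20000)
  sp$nominal <- data.frame(name = "surgeon", n_levels = 200L, zipf = 1.0,
                           effect_sd = 0.1, stringsAsFactors = FALSE)
  g <- generate_cohort(sp)
  f <- sort(table(g$cohort$features$surgeon), decreasing = TRUE)
  r <- seq_along(f)
  use <- r <= 50  # well-observed head of the distribution
  slope <- coef(lm(log(as.numeric(f[use])) ~ log(r[use])))[2]
  expect_lt(abs(-slope - 1.0), 0.1)
})

test_that("generated codes are prefix-consistent with their universe", {
  g <- generate_cohort(small_spec(n = 2000))
  codes <- g$cohort$features$proc_code
  eff <- g$true_model$code_node_effects
  expect_true(all(substr(codes, 1, 2) %in% names(eff)))
  expect_true(all(substr(codes, 1, 3) %in% names(eff)))
  expect_true(all(codes %in% names(eff)))
})

test_that("cohort CSV round-trips through the sidecar metadata", {
  g <- generate_cohort(small_spec(n = 300))
  co <- inject_missingness(g$cohort, 0.05, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$types, co$types)
  expect_equal(back$features, co$features)
  expect_identical(back$outcomes, co$outcomes)
})
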