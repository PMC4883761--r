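test_that("log-likelihood-ratio score matches the closed form", {
  # equal conditional frequencies score zero
  expect_equal(log_likelihood_ratio(20, 20, 100, 100, smoothing = 0), 0)
  expect_equal(log_likelihood_ratio(5, 10, 50, 100, smoothing = 0), 0)
  expect_equal(log_likelihood_ratio(20, 10, 100, 100, smoothing = 0), log(2))
  # swapping outcome labels negates the score
  expect_equal(log_likelihood_ratio(7, 3, 40, 60, smoothing = 0.5),
               -log_likelihood_ratio(3, 7, 60, 40, smoothing = 0.5))
  expect_error(log_likelihood_ratio(0, 5, 10, 10, smoothing = 0), "zero cell")
  # smoothed score converges to the exact formula as the pseudo-count vanishes
  exact <- log_likelihood_ratio(20, 10, 100, 100, smoothing = 0)
  expect_equal(log_likelihood_ratio(20, 10, 100, 100, smoothing = 1e-8),
               exact, tolerance = 1e-6)
})

test_that("rare-level grouping partitions on the strict count threshold", {
  st <- data.frame(level = c("A", "B", "C"), n1 = c(50, 33, 1),
                   n0 = c(100, 66, 2))
  out <- group_rare_levels(st, 100)
  expect_identical(out$kept, "A")
  expect_setequal(out$other, c("B", "C"))
  all_kept <- group_rare_levels(st, 1)
  expect_setequal(all_kept$kept, c("A", "B", "C"))
  expect_length(all_kept$other, 0)
})

test_that("k-means subgrouping pools levels with similar event proportions", {
  same <- data.frame(level = c("a", "b", "c"), n1 = c(1, 2, 3),
                     n0 = c(1, 2, 3))
  expect_length(unique(cluster_other_pool(same, 5)), 1)

  sep <- data.frame(level = c("a", "b", "c", "d"), n1 = c(0, 0, 5, 7),
                    n0 = c(5, 8, 0, 0))
  cl <- cluster_other_pool(sep, 2, seed = 1)
  expect_identical(cl[["a"]], cl[["b"]])
  expect_identical(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])

  # 20 levels from 5 well-separated proportions: partition recovered
  set.seed(3)
  truth <- rep(1:5, each = 4)
  p <- c(0.02, 0.25, 0.5, 0.75, 0.98)[truth]
  n <- 400
  st <- data.frame(level = sprintf("L%02d", 1:20),
                   n1 = round(n * p), n0 = round(n * (1 - p)))
  cl <- cluster_other_pool(st, 5, seed = 2)
  expect_equal(length(unique(cl)), 5)
  for (g in 1:5)
    expect_length(unique(cl[truth == g]), 1)
})

test_that("fitted encoder scores are monotone in level event rates", {
  lv <- rep(c("A", "B"), each = 100)
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  map <- fit_encoder(lv, y, min_count = 1)
  expect_gt(map$score[["A"]], map$score[["B"]])
  expect_error(fit_encoder(lv, rep(1, 200)), "single class")
  # unseen level routes to the fallback without error
  expect_identical(apply_encoder(map, "Z"), map$fallback)
  expect_length(apply_encoder(map, character(0)), 0)
  expect_equal(apply_encoder(map, lv)[1], map$score[["A"]])
})

test_that("rare levels share their pooled subgroup score", {
  # 6 levels: A,B,C common; D,E rare with one event mix, F rare with another
  lv <- c(rep("A", 40), rep("B", 30), rep("C", 25),
          rep("D", 4), rep("E", 3), rep("F", 2))
  y <- c(rep(1, 12), rep(0, 28),      # A: 12/40
         rep(1, 6), rep(0, 24),       # B: 6/30
         rep(1, 5), rep(0, 20),       # C: 5/25
         1, 1, 0, 0,                  # D: p = 0.5
         0, 0, 0,                     # E: p = 0
         1, 0)                        # F: p = 0.5
  map <- fit_encoder(lv, y, min_count = 10, n_clusters = 2, smoothing = 0.5,
                     seed = 1)
  expect_identical(map$group[["D"]], map$group[["F"]])
  expect_identical(map$score[["D"]], map$score[["F"]])
  expect_false(map$group[["D"]] == map$group[["E"]])
  # pooled D+F score from first principles
  N1 <- sum(y); N0 <- sum(1 - y)
  expect_equal(map$score[["D"]],
               log(((3 + 0.5) / (N1 + 1)) / ((3 + 0.5) / (N0 + 1))))
})

test_that("encoding is equivariant under level relabeling", {
  set.seed(5)
  lv <- sample(LETTERS[1:6], 500, replace = TRUE)
  y <- rbinom(500, 1, 0.3)
  map1 <- fit_encoder(lv, y, min_count = 1)
  perm <- setNames(letters[6:1], LETTERS[1:6])
  map2 <- fit_encoder(unname(perm[lv]), y, min_count = 1)
  for (l in LETTERS[1:6])
    expect_equal(map2$score[[perm[[l]]]], map1$score[[l]])
})

test_that("encoded-score ordering matches event-rate ordering among kept levels", {
  set.seed(6)
  lv <- sample(sprintf("L%d", 1:8), 2000, replace = TRUE)
  y <- rbinom(2000, 1, 0.4)
  map <- fit_encoder(lv, y, min_count = 1, smoothing = 0)
  st <- aggregate(y, list(lv), mean)
  phat <- setNames(st$x, st$Group.1)
  sc <- map$score[names(phat)]
  expect_equal(order(sc), order(phat))
})

test_that("the encoded score supports the optimal Gini split (small case)", {
  set.seed(8)
  for (rep_i in 1:5) {
    k <- 6
    lv <- sample(LETTERS[1:k], 1500, replace = TRUE,
                 prob = zipf_probs_test(k))
    p <- runif(k, 0.05, 0.7)
    y <- rbinom(1500, 1, p[match(lv, LETTERS[1:k])])
    st <- table(lv, y)
    n0 <- st[, "0"]; n1 <- st[, "1"]
    map <- fit_encoder(lv, y, min_count = 1, smoothing = 0)
    sc <- map$score[rownames(st)]
    expect_equal(best_gini_threshold(n1, n0, sc),
                 best_gini_partition(n1, n0), tolerance = 1e-12)
  }
})
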