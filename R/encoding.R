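#' Smoothed log-likelihood-ratio score for one level (or pooled group)
#'
#' Score of a categorical level against a binary outcome:
#' `log[((n1 + s) / (N1 + 2s)) / ((n0 + s) / (N0 + 2s))]`,
#' the log ratio of the level's conditional frequency among positives to
#' that among negatives. With `smoothing = 0` and both counts positive this
#' is the exact empirical log-likelihood ratio; the pseudo-count guards
#' zero cells.
#'
#' @param n1,n0 level (or pooled-group) counts among positives / negatives.
#' @param N1,N0 total positives / negatives.
#' @param smoothing pseudo-count added to each cell (default 0.5).
#' @return real score.
#' @export
log_likelihood_ratio <- function(n1, n0, N1, N0, smoothing = 0.5) {
  stopifnot(N1 >= 1, N0 >= 1, n1 >= 0, n0 >= 0, smoothing >= 0)
  if (smoothing == 0 && (any(n1 == 0) || any(n0 == 0)))
    stop("zero cell with smoothing 0: score would be infinite; ",
         "use smoothing > 0 or group rare levels")
  log(((n1 + smoothing) / (N1 + 2 * smoothing)) /
        ((n0 + smoothing) / (N0 + 2 * smoothing)))
}

level_stats <- function(levels, outcome) {
  tab <- table(factor(levels), factor(outcome, levels = c(0, 1)))
  data.frame(level = rownames(tab),
             n0 = as.integer(tab[, 1]), n1 = as.integer(tab[, 2]),
             stringsAsFactors = FALSE)
}

#' Partition levels into individually-scored and rare ("other") pools
#'
#' Levels observed fewer than `min_count` times in total go to the "other"
#' pool (strict inequality); the partition is exhaustive and disjoint.
#'
#' @param stats data.frame with columns `level`, `n0`, `n1`.
#' @param min_count minimum total records for a level to stand alone.
#' @return list with `kept` and `other` character vectors of level names.
#' @export
group_rare_levels <- function(stats, min_count = 100) {
  stopifnot(min_count >= 1)
  total <- stats$n0 + stats$n1
  list(kept = stats$level[total >= min_count],
       other = stats$level[total < min_count])
}

#' Subgroup the "other" pool by k-means on event proportions
#'
#' One-dimensional k-means on each rare level's event proportion
#' `p = n1 / (n1 + n0)`, so that levels with similar outcome mix share a
#' pooled score. The effective cluster count is `min(n_clusters, number of
#' distinct proportions)`.
#'
#' @param stats data.frame (rows = other-pool levels) with `level`, `n0`,
#'   `n1`.
#' @param n_clusters requested clusters (default 5).
#' @param seed integer seed for the k-means restarts.
#' @return integer vector of subgroup ids (1-based), named by level.
#' @export
cluster_other_pool <- function(stats, n_clusters = 5, seed = 1L) {
  if (nrow(stats) == 0) stop("empty other pool")
  p <- stats$n1 / (stats$n1 + stats$n0)
  k <- min(n_clusters, length(unique(p)))
  if (k == 1L) {
    assign <- rep(1L, nrow(stats))
  } else {
    set.seed(child_seed(seed, 7))
    km <- stats::kmeans(matrix(p, ncol = 1), centers = k, nstart = 10)
    # relabel clusters by ascending center for determinism
    ord <- order(km$centers[, 1])
    assign <- match(km$cluster, ord)
  }
  stats::setNames(as.integer(assign), stats$level)
}

#' Fit an outcome-conditional encoder for one nominal feature
#'
#' Levels with at least `min_count` records are scored individually by their
#' smoothed log-likelihood ratio; rarer levels are pooled into an "other"
#' group, subgrouped by k-means on event proportion, and each subgroup is
#' scored on its pooled counts. Levels unseen at fit time receive the score
#' of the largest subgroup (by pooled records) of the other pool, or the
#' overall-prevalence score when no pool exists.
#'
#' @param levels character vector of level identifiers.
#' @param outcome binary 0/1 vector of the same length.
#' @param min_count rare-level threshold (default 100 records).
#' @param n_clusters k-means clusters for the other pool (default 5).
#' @param smoothing pseudo-count for the score (default 0.5).
#' @param seed integer seed.
#' @return an object of class `encoding_map`.
#' @export
fit_encoder <- function(levels, outcome, min_count = 100, n_clusters = 5,
                        smoothing = 0.5, seed = 1L) {
  stopifnot(length(levels) == length(outcome))
  if (length(unique(outcome)) < 2)
    stop("outcome has a single class; encoder undefined")
  st <- level_stats(levels, outcome)
  N1 <- sum(st$n1); N0 <- sum(st$n0)
  parts <- group_rare_levels(st, min_count)

  score <- numeric(0); group <- character(0)
  for (lv in parts$kept) {
    i <- match(lv, st$level)
    score[lv] <- log_likelihood_ratio(st$n1[i], st$n0[i], N1, N0, smoothing)
    group[lv] <- lv
  }

  cluster_assign <- NULL
  fallback <- log_likelihood_ratio(N1, N0, N1, N0, smoothing)  # 0: prior odds ratio
  if (length(parts$other)) {
    ost <- st[st$level %in% parts$other, , drop = FALSE]
    cluster_assign <- cluster_other_pool(ost, n_clusters, seed)
    pool_sizes <- integer(0)
    for (g in sort(unique(cluster_assign))) {
      members <- names(cluster_assign)[cluster_assign == g]
      i <- match(members, st$level)
      gsc <- log_likelihood_ratio(sum(st$n1[i]), sum(st$n0[i]), N1, N0,
                                  smoothing)
      gname <- paste0("__other_", g, "__")
      score[members] <- gsc
      group[members] <- gname
      pool_sizes[gname] <- sum(st$n1[i] + st$n0[i])
    }
    fallback <- unname(score[match(names(which.max(pool_sizes)), group)][1])
  }

  structure(list(score = score, group = group,
                 min_count = min_count, n_clusters = n_clusters,
                 smoothing = smoothing, seed = seed,
                 totals = c(N1 = N1, N0 = N0),
                 cluster_assign = cluster_assign,
                 fallback = fallback),
            class = "encoding_map")
}

#' Apply a fitted encoder to a vector of levels
#'
#' Elementwise score lookup; levels unseen at fit time get the fallback
#' score.
#'
#' @param map an `encoding_map` from [fit_encoder()].
#' @param levels character vector.
#' @return numeric vector of the same length.
#' @export
apply_encoder <- function(map, levels) {
  out <- unname(map$score[levels])
  out[is.na(out)] <- map$fallback
  out
}

#' Serialize an encoding map to JSON
#'
#' @param map an `encoding_map`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_encoding_map <- function(map, path) {
  jsonlite::write_json(
    list(score = as.list(map$score), group = as.list(map$group),
         min_count = map$min_count, n_clusters = map$n_clusters,
         smoothing = map$smoothing, seed = map$seed,
         totals = as.list(map$totals), fallback = map$fallback),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
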