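#' Build the prefix tree over hierarchical procedure codes
#'
#' Codes are digit strings of length 2-4 (an ICD-9-CM style hierarchy; a
#' decimal point, as in `"81.54"`, is stripped on read). Each node is a
#' digit prefix of length 2-4; a node's count is the number of patients
#' whose code starts with that prefix, so internal counts equal the sum of
#' child counts plus patients coded exactly at that prefix length. `NA`
#' entries and the reserved `"__missing__"` marker are excluded from the
#' tree (they are grouped separately downstream).
#'
#' @param codes character vector of procedure codes.
#' @return an object of class `code_tree`: data.frame of nodes (`node`,
#'   `depth`, `count`, `exact`), plus the cleaned per-patient codes.
#' @export
build_prefix_tree <- function(codes) {
  codes <- codes[!is.na(codes) & codes != "__missing__"]
  codes <- gsub(".", "", codes, fixed = TRUE)
  if (length(codes) == 0) {
    return(structure(list(nodes = data.frame(node = character(0),
                                             depth = integer(0),
                                             count = integer(0),
                                             exact = integer(0)),
                          codes = character(0)),
                     class = "code_tree"))
  }
  if (!all(grepl("^[0-9]{2,4}$", codes)))
    stop("codes must be digit strings of length 2-4 (decimal point allowed)")
  exact <- table(codes)
  node_set <- unique(unlist(lapply(2:4, function(l) {
    cs <- codes[nchar(codes) >= l]
    unique(substr(cs, 1, l))
  })))
  count <- vapply(node_set, function(nd)
    sum(startsWith(codes, nd)), integer(1))
  exact_n <- vapply(node_set, function(nd)
    if (nd %in% names(exact)) as.integer(exact[[nd]]) else 0L, integer(1))
  nodes <- data.frame(node = node_set, depth = nchar(node_set),
                      count = unname(count), exact = unname(exact_n),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), ]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, codes = codes), class = "code_tree")
}

#' Aggregate codes bottom-up until every group reaches a minimum count
#'
#' Depth-first from the leaves: a node whose count reaches `min_count`
#' and whose membership was not consumed by deeper groups becomes (or
#' contributes to) a group; under-threshold siblings merge into their
#' parent-level residual, and residuals still under threshold merge upward
#' again. Residuals reaching the 2-digit top level are retained as groups
#' even when under threshold, so every group except top-level residuals has
#' at least `min_count` patients. Groups are enumerated (lexicographic by
#' label) and the enumeration index is the discrete feature value.
#'
#' @param tree a `code_tree`.
#' @param min_count minimum patients per group (default 100).
#' @return an object of class `code_grouping`: `assignment` (code -> group
#'   label), `groups` data.frame (`group`, `count`, `index`, `top_residual`).
#' @export
aggregate_codes <- function(tree, min_count = 100) {
  stopifnot(min_count >= 1)
  nodes <- tree$nodes
  if (nrow(nodes) == 0) {
    return(structure(list(assignment = character(0),
                          groups = data.frame(group = character(0),
                                              count = integer(0),
                                              index = integer(0),
                                              top_residual = logical(0))),
                     class = "code_grouping"))
  }
  cnt <- stats::setNames(nodes$count, nodes$node)
  exact <- stats::setNames(nodes$exact, nodes$node)
  env <- new.env(parent = emptyenv())
  env$assignment <- character(0)  # observed code -> group label
  env$grp_count <- integer(0)     # group label -> patient count
  top_res <- character(0)

  children_of <- function(nd) {
    sort(nodes$node[nodes$depth == nchar(nd) + 1 &
                      startsWith(nodes$node, nd)])
  }
  settle <- function(codes, count, lab) {
    env$assignment[codes] <- lab
    env$grp_count[lab] <- sum(env$grp_count[lab], count, na.rm = TRUE)
  }

  # depth-first merge; returns the unsettled residual under `nd`
  walk <- function(nd) {
    if (nchar(nd) == 4L) {
      if (cnt[[nd]] >= min_count) {
        settle(nd, cnt[[nd]], nd)
        return(list(codes = character(0), count = 0L))
      }
      return(list(codes = nd, count = cnt[[nd]]))
    }
    res_codes <- if (exact[[nd]] > 0) nd else character(0)
    res_count <- exact[[nd]]
    for (kid in children_of(nd)) {
      sub <- walk(kid)
      res_codes <- c(res_codes, sub$codes)
      res_count <- res_count + sub$count
    }
    if (res_count >= min_count) {
      settle(res_codes, res_count, paste0(nd, "*"))
      return(list(codes = character(0), count = 0L))
    }
    list(codes = res_codes, count = res_count)
  }

  for (top in sort(nodes$node[nodes$depth == 2])) {
    left <- walk(top)
    if (left$count > 0) {  # retained even when under threshold
      lab <- paste0(top, "*")
      settle(left$codes, left$count, lab)
      top_res <- c(top_res, lab)
    }
  }
  assignment <- env$assignment
  grp_count <- env$grp_count

  labs <- sort(names(grp_count))
  groups <- data.frame(group = labs,
                       count = as.integer(grp_count[labs]),
                       index = seq_along(labs),
                       top_residual = labs %in% top_res,
                       stringsAsFactors = FALSE)
  structure(list(assignment = assignment, groups = groups),
            class = "code_grouping")
}

#' Map codes to their fitted groups
#'
#' Unseen codes route to the deepest existing ancestor group (the group of
#' their longest fit-time prefix), falling back to their 2-digit class
#' residual, then to a global `"__other__"`. Missing codes map to
#' `"__missing__"`.
#'
#' @param grouping a `code_grouping` from [aggregate_codes()].
#' @param codes character vector.
#' @return character vector of group labels.
#' @export
apply_grouping <- function(grouping, codes) {
  codes_clean <- gsub(".", "", codes, fixed = TRUE)
  labs <- grouping$groups$group
  vapply(codes_clean, function(cd) {
    if (is.na(cd) || cd == "__missing__") return("__missing__")
    g <- grouping$assignment[cd]
    if (!is.na(g)) return(unname(g))
    for (l in rev(seq(2, min(3, nchar(cd))))) {
      cand <- paste0(substr(cd, 1, l), "*")
      if (cand %in% labs) return(cand)
    }
    "__other__"
  }, character(1), USE.NAMES = FALSE)
}

#' Choose the aggregation threshold by held-out univariate AUC
#'
#' For each candidate threshold: aggregate the training codes, encode the
#' resulting groups with the outcome-conditional encoder, fit a univariate
#' logistic model on the training fold, and score AUC on the held-out fold.
#' Returns the candidate with the highest held-out AUC (ties break to the
#' smaller candidate).
#'
#' @param codes character vector of codes.
#' @param outcome binary 0/1 vector.
#' @param candidates candidate thresholds (default `c(50, 100, 150, 250,
#'   500)`).
#' @param train_fraction held-out split fraction (default 0.7).
#' @param seed integer seed for the split.
#' @return list with `min_count` (chosen), and `auc` (named vector of
#'   held-out AUCs per candidate).
#' @export
grid_search_min_count <- function(codes, outcome,
                                  candidates = c(50, 100, 150, 250, 500),
                                  train_fraction = 0.7, seed = 1L) {
  stopifnot(length(candidates) >= 1)
  plan <- stratified_split(outcome, train_fraction, seed = seed)
  tr <- plan$train; va <- plan$validation
  aucs <- stats::setNames(numeric(length(candidates)), candidates)
  for (i in seq_along(candidates)) {
    mc <- candidates[i]
    tree <- build_prefix_tree(codes[tr])
    grouping <- aggregate_codes(tree, mc)
    g_tr <- apply_grouping(grouping, codes[tr])
    g_va <- apply_grouping(grouping, codes[va])
    enc <- fit_encoder(g_tr, outcome[tr], min_count = 1, seed = seed)
    x_tr <- apply_encoder(enc, g_tr)
    x_va <- apply_encoder(enc, g_va)
    fit <- stats::glm(outcome[tr] ~ x_tr, family = stats::binomial())
    sc <- fit$coefficients[1] + fit$coefficients[2] * x_va
    aucs[i] <- auc(sc, outcome[va])
  }
  best <- candidates[which(aucs == max(aucs))]
  list(min_count = min(best), auc = aucs)
}

#' Serialize a code grouping to JSON
#'
#' @param grouping a `code_grouping`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_code_grouping <- function(grouping, path) {
  jsonlite::write_json(
    list(assignment = as.list(grouping$assignment),
         groups = grouping$groups),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
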