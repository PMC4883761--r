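#' Patient cohort container
#'
#' A `cohort` bundles a patient-by-feature table, one binary outcome vector
#' per outcome, and per-column type metadata. Feature columns are typed as
#' `"continuous"`, `"binary"`, `"nominal"` or `"code"` (hierarchical digit
#' codes stored as character strings). Missing values are `NA`; outcome
#' vectors never contain missing entries, and nominal columns store level
#' identifiers, never encoded scores.
#'
#' @param features data.frame of patient features.
#' @param outcomes data.frame of 0/1 outcome columns (e.g. `aki`, `sepsis`).
#' @param types named character vector mapping every feature column to its
#'   type.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(features, outcomes, types) {
  stopifnot(is.data.frame(features), is.data.frame(outcomes))
  if (!setequal(names(types), names(features)))
    stop("`types` must name every feature column exactly once")
  bad <- setdiff(unique(types), c("continuous", "binary", "nominal", "code"))
  if (length(bad)) stop("unknown column type(s): ", paste(bad, collapse = ", "))
  if (anyNA(outcomes)) stop("outcome columns must not contain missing values")
  for (o in names(outcomes)) {
    if (!all(outcomes[[o]] %in% c(0L, 1L)))
      stop("outcome `", o, "` must be binary 0/1")
  }
  structure(
    list(features = features,
         outcomes = outcomes,
         types = types[names(features)]),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%d %s", table(x$types)[unique(x$types)],
                            unique(x$types)), collapse = ", ")))
  for (o in names(x$outcomes))
    cat(sprintf("  outcome %-8s prevalence %.3f\n", o, mean(x$outcomes[[o]])))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$features)

#' Subset a cohort by patient index
#'
#' @param cohort a `cohort`.
#' @param idx integer or logical patient index.
#' @return the subsetted `cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  new_cohort(cohort$features[idx, , drop = FALSE],
             cohort$outcomes[idx, , drop = FALSE],
             cohort$types)
}

feature_names_of_type <- function(cohort, type) {
  names(cohort$types)[cohort$types == type]
}

#' Write a cohort to disk as CSV plus a JSON metadata sidecar
#'
#' The CSV holds features and outcome columns (missing values as empty
#' fields); the sidecar records column types and outcome names so the cohort
#' can be read back with types intact.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if absent).
#' @param name file stem, default `"cohort"`.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, name = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  meta <- file.path(dir, paste0(name, "_meta.json"))
  tab <- cbind(cohort$features, cohort$outcomes)
  utils::write.csv(tab, csv, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(types = as.list(cohort$types), outcomes = names(cohort$outcomes)),
    meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, meta = meta))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the CSV and sidecar.
#' @param name file stem, default `"cohort"`.
#' @return a `cohort`.
#' @export
read_cohort <- function(dir, name = "cohort") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  types <- unlist(meta$types)
  cls <- c(continuous = "numeric", binary = "integer",
           nominal = "character", code = "character")[types]
  names(cls) <- names(types)
  tab <- utils::read.csv(file.path(dir, paste0(name, ".csv")),
                         colClasses = c(cls, stats::setNames(
                           rep("integer", length(meta$outcomes)), meta$outcomes)),
                         na.strings = "")
  feats <- tab[names(types)]
  outs <- tab[meta$outcomes]
  # outcomes are never missing by contract; empty strings only affect features
  new_cohort(feats, outs, types)
}
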