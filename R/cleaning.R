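#' Flag distributional outliers in a continuous vector
#'
#' Entries strictly below the `lower_q` quantile or strictly above the
#' `upper_q` quantile of the non-missing values are flagged (type-7
#' linear-interpolation quantiles). Missing entries are never flagged.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param lower_q,upper_q tail quantiles; defaults trim the top and bottom
#'   1% of the distribution.
#' @return logical mask, `TRUE` where flagged.
#' @export
flag_outliers <- function(values, lower_q = 0.01, upper_q = 0.99) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stop("all-missing column: cannot flag outliers")
  if (length(obs) < 10) stop("need at least 10 non-missing values")
  b <- stats::quantile(obs, probs = c(lower_q, upper_q), names = FALSE,
                       type = 7)
  mask <- !is.na(values) & (values < b[1] | values > b[2])
  mask
}

#' Mean-impute masked entries of a continuous vector
#'
#' Masked entries (missing or flagged) are replaced by the mean of the
#' retained entries; retained entries are untouched.
#'
#' @param values numeric vector.
#' @param mask logical, `TRUE` for entries to impute (defaults to the
#'   missing entries).
#' @return imputed numeric vector.
#' @export
impute_continuous <- function(values, mask = is.na(values)) {
  keep <- !mask & !is.na(values)
  if (!any(keep)) stop("no retained values to compute the imputation mean")
  values[mask | is.na(values)] <- mean(values[keep])
  values
}

#' Replace missing nominal entries by a reserved level
#'
#' Missing entries become the reserved level `"__missing__"`, which the
#' encoder then treats as an ordinary level.
#'
#' @param levels character vector with possible `NA`.
#' @return character vector without `NA`.
#' @export
impute_nominal <- function(levels) {
  if (anyNA(levels) && any(levels == "__missing__", na.rm = TRUE))
    stop("observed level collides with the reserved `__missing__` marker")
  levels[is.na(levels)] <- "__missing__"
  levels
}

#' Fit cleaning statistics on a cohort
#'
#' Computes, per continuous feature, the 1%/99% trim bounds on the full
#' column and the mean of the retained (unflagged, non-missing) values.
#' Returned object can be applied to any cohort with the same schema, which
#' is how validation folds are cleaned without leakage.
#'
#' @param cohort a `cohort` (typically the training fold).
#' @param lower_q,upper_q tail quantiles for outlier flagging.
#' @return an object of class `cleaner`.
#' @export
fit_cleaner <- function(cohort, lower_q = 0.01, upper_q = 0.99) {
  stats_ <- list()
  for (nm in feature_names_of_type(cohort, "continuous")) {
    x <- cohort$features[[nm]]
    flag <- flag_outliers(x, lower_q, upper_q)
    keep <- !flag & !is.na(x)
    b <- stats::quantile(x[!is.na(x)], probs = c(lower_q, upper_q),
                         names = FALSE, type = 7)
    stats_[[nm]] <- list(lower = b[1], upper = b[2], mean = mean(x[keep]))
  }
  structure(list(continuous = stats_, lower_q = lower_q, upper_q = upper_q),
            class = "cleaner")
}

#' Apply fitted cleaning statistics to a cohort
#'
#' Continuous entries outside the fitted bounds are flagged and, together
#' with missing entries, replaced by the fitted retained-mean. Nominal and
#' code columns have missing entries converted to the reserved
#' `"__missing__"` level. Binary columns are mode-imputed against the
#' fitted mean rounded to \{0, 1\}.
#'
#' @param cleaner a `cleaner` from [fit_cleaner()].
#' @param cohort a `cohort`.
#' @return list with `cohort` (no missing feature values remain) and
#'   `report` (class `cleaning_report`).
#' @export
apply_cleaner <- function(cleaner, cohort) {
  rep_rows <- list()
  for (nm in names(cohort$types)) {
    type <- cohort$types[[nm]]
    x <- cohort$features[[nm]]
    if (type == "continuous") {
      st <- cleaner$continuous[[nm]]
      flag <- !is.na(x) & (x < st$lower | x > st$upper)
      n_missing <- sum(is.na(x))
      x[flag | is.na(x)] <- st$mean
      rep_rows[[nm]] <- data.frame(
        feature = nm, type = type, outliers_flagged = sum(flag),
        originally_missing = n_missing,
        imputed = sum(flag) + n_missing,
        impute_constant = st$mean, missing_category = FALSE)
    } else if (type %in% c("nominal", "code")) {
      n_missing <- sum(is.na(x))
      x <- impute_nominal(x)
      rep_rows[[nm]] <- data.frame(
        feature = nm, type = type, outliers_flagged = 0L,
        originally_missing = n_missing, imputed = n_missing,
        impute_constant = NA_real_, missing_category = n_missing > 0)
    } else { # binary: impute the rounded training mean
      n_missing <- sum(is.na(x))
      fill <- as.integer(round(mean(cohort$features[[nm]], na.rm = TRUE)))
      x[is.na(x)] <- fill
      rep_rows[[nm]] <- data.frame(
        feature = nm, type = type, outliers_flagged = 0L,
        originally_missing = n_missing, imputed = n_missing,
        impute_constant = fill, missing_category = FALSE)
    }
    cohort$features[[nm]] <- x
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  class(report) <- c("cleaning_report", "data.frame")
  list(cohort = cohort, report = report)
}

#' Clean a cohort: flag outliers, then impute
#'
#' One-shot whole-cohort cleaning (fit and apply on the same data), matching
#' a preprocess-before-split workflow. Cleaning is idempotent: bounds are
#' fitted once, so a second pass finds nothing new to flag.
#'
#' @param cohort a `cohort`.
#' @param lower_q,upper_q tail quantiles for outlier flagging.
#' @return list with `cohort` and `report` as in [apply_cleaner()].
#' @export
clean_cohort <- function(cohort, lower_q = 0.01, upper_q = 0.99) {
  if (isTRUE(attr(cohort, "cleaned"))) {
    # re-flagging disabled on an already-cleaned cohort: quantile trimming
    # would otherwise keep shaving 1% tails on every pass
    cleaner <- fit_cleaner(cohort, 0, 1)
  } else {
    cleaner <- fit_cleaner(cohort, lower_q, upper_q)
  }
  out <- apply_cleaner(cleaner, cohort)
  attr(out$cohort, "cleaned") <- TRUE
  out$cleaner <- cleaner
  out
}

#' Serialize a cleaning report to JSON
#'
#' @param report a `cleaning_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, pretty = TRUE,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
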