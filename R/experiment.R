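#' Configuration for the repeated-split experiment
#'
#' Collects every tunable of the evaluation harness. `paper_mode = FALSE`
#' (the default, "honest" mode) fits all data-dependent preprocessing —
#' cleaning statistics, categorical encoders, code grouping, reduction
#' transforms — on the training fold only and applies them to validation;
#' `paper_mode = TRUE` fits preprocessing on the whole cohort before
#' splitting, matching a preprocess-then-split workflow and giving
#' optimistic estimates for high-cardinality encoded features.
#'
#' @param models model kinds to fit (subset of `"logistic"`, `"gam"`,
#'   `"naive_bayes"`, `"svm"`).
#' @param arms reduction arms (subset of `"none"`, `"screen"`, `"lasso"`,
#'   `"pca"`).
#' @param outcomes outcome names to evaluate (default all in the cohort).
#' @param repetitions number of repeated 70/30 splits (default 50).
#' @param train_fraction training fraction (default 0.7).
#' @param paper_mode logical; see above.
#' @param min_count rare-level / code-aggregation threshold (default 100).
#' @param n_clusters k-means clusters for the encoder's other pool.
#' @param smoothing encoder pseudo-count.
#' @param alpha univariate screen threshold.
#' @param n_components principal components kept by the PCA arm.
#' @param smooth_features continuous features smoothed by the GAM (default
#'   age, eGFR, hematocrit, hemoglobin — the clinically non-monotone
#'   candidates); `NULL` smooths every continuous feature.
#' @param threshold probability threshold for accuracy/PPV.
#' @param bootstrap_B bootstrap replicates for within-split CIs.
#' @param seed master seed.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(models = c("logistic", "gam", "naive_bayes"),
                              arms = c("none", "lasso", "pca"),
                              outcomes = NULL,
                              repetitions = 50,
                              train_fraction = 0.7,
                              paper_mode = FALSE,
                              min_count = 100,
                              n_clusters = 5,
                              smoothing = 0.5,
                              alpha = 0.2,
                              n_components = 5,
                              smooth_features = c("age", "egfr",
                                                  "hematocrit", "hemoglobin"),
                              threshold = 0.5,
                              bootstrap_B = 500,
                              seed = 1L) {
  stopifnot(all(models %in% c("logistic", "gam", "naive_bayes", "svm")),
            all(arms %in% c("none", "screen", "lasso", "pca")),
            repetitions >= 1)
  structure(as.list(environment()), class = "experiment_config")
}

#' Build numeric train/validation design matrices for one outcome
#'
#' Runs the preprocessing chain — cleaning, outcome-conditional encoding of
#' nominal features, prefix-tree aggregation plus encoding of the code
#' feature — and returns aligned numeric matrices. In honest mode all
#' statistics come from the training rows; in paper mode they come from the
#' full cohort.
#'
#' @param cohort a `cohort`.
#' @param train,validation integer patient indices.
#' @param outcome outcome name.
#' @param config an [experiment_config()].
#' @return list with `X_train`, `X_val` (numeric matrices), `y_train`,
#'   `y_val`, and `prep` (fitted preprocessing objects).
#' @export
prepare_design <- function(cohort, train, validation, outcome, config) {
  y <- cohort$outcomes[[outcome]]
  fit_rows <- if (config$paper_mode) seq_len(nrow(cohort$features)) else train

  cleaner <- fit_cleaner(cohort_subset(cohort, fit_rows))
  cl_tr <- apply_cleaner(cleaner, cohort_subset(cohort, train))$cohort
  cl_va <- apply_cleaner(cleaner, cohort_subset(cohort, validation))$cohort
  cl_fit <- if (config$paper_mode)
    apply_cleaner(cleaner, cohort)$cohort else cl_tr

  num_cols <- c(feature_names_of_type(cohort, "continuous"),
                feature_names_of_type(cohort, "binary"))
  X_tr <- cl_tr$features[num_cols]
  X_va <- cl_va$features[num_cols]

  encoders <- list()
  for (nm in feature_names_of_type(cohort, "nominal")) {
    enc <- fit_encoder(cl_fit$features[[nm]], y[fit_rows],
                       min_count = config$min_count,
                       n_clusters = config$n_clusters,
                       smoothing = config$smoothing, seed = config$seed)
    X_tr[[nm]] <- apply_encoder(enc, cl_tr$features[[nm]])
    X_va[[nm]] <- apply_encoder(enc, cl_va$features[[nm]])
    encoders[[nm]] <- enc
  }

  grouping <- NULL
  for (nm in feature_names_of_type(cohort, "code")) {
    tree <- build_prefix_tree(cl_fit$features[[nm]])
    grouping <- aggregate_codes(tree, config$min_count)
    g_fit <- apply_grouping(grouping, cl_fit$features[[nm]])
    enc <- fit_encoder(g_fit, y[fit_rows], min_count = 1,
                       n_clusters = config$n_clusters,
                       smoothing = config$smoothing, seed = config$seed)
    X_tr[[nm]] <- apply_encoder(enc, apply_grouping(grouping,
                                                    cl_tr$features[[nm]]))
    X_va[[nm]] <- apply_encoder(enc, apply_grouping(grouping,
                                                    cl_va$features[[nm]]))
    encoders[[nm]] <- enc
  }

  list(X_train = as.matrix(X_tr), X_val = as.matrix(X_va),
       y_train = y[train], y_val = y[validation],
       prep = list(cleaner = cleaner, encoders = encoders,
                   grouping = grouping))
}

apply_arm <- function(arm, X_tr, X_va, y_tr, config) {
  switch(arm,
    none = list(X_train = X_tr, X_val = X_va, info = NULL),
    screen = {
      sel <- suppressWarnings(univariate_screen(X_tr, y_tr,
                                                alpha = config$alpha))
      if (length(sel) == 0) sel <- colnames(X_tr)  # never empty the design
      list(X_train = X_tr[, sel, drop = FALSE],
           X_val = X_va[, sel, drop = FALSE], info = sel)
    },
    lasso = {
      ls <- lasso_select(X_tr, y_tr, seed = config$seed)
      sel <- if (length(ls$selected)) ls$selected else colnames(X_tr)
      list(X_train = X_tr[, sel, drop = FALSE],
           X_val = X_va[, sel, drop = FALSE], info = ls)
    },
    pca = {
      keep <- apply(X_tr, 2, stats::sd) > 0
      fit <- pca_extract(X_tr[, keep, drop = FALSE],
                         n_components = min(config$n_components,
                                            sum(keep)))
      list(X_train = fit$scores,
           X_val = pca_transform(fit, X_va[, keep, drop = FALSE]),
           info = fit)
    })
}

fit_model_kind <- function(kind, X, y, config, cohort) {
  if (kind == "gam") {
    sm <- config$smooth_features
    if (is.null(sm))
      sm <- intersect(feature_names_of_type(cohort, "continuous"),
                      colnames(X))
    sm <- intersect(sm, colnames(X))  # reduction arms may drop or replace them
    # in the PCA arm the component scores are the continuous inputs
    sm <- union(sm, grep("^PC[0-9]+$", colnames(X), value = TRUE))
    fit_gam(X, y, smooth_features = sm)
  } else switch(kind,
    logistic = fit_logistic(X, y),
    naive_bayes = fit_naive_bayes(X, y),
    svm = fit_svm(X, y))
}

#' Run the full repeated-split evaluation experiment
#'
#' Full factorial over models x reduction arms x outcomes. Each repetition
#' draws a stratified 70/30 split, runs preprocessing per
#' [prepare_design()], applies the reduction arm, fits each model on the
#' training fold and scores the validation fold. Reported per cell: mean
#' validation AUC / accuracy / PPV across repetitions with across-repetition
#' percentile 95% CIs, a within-split patient bootstrap 95% CI for AUC from
#' the first repetition, and the Hosmer-Lemeshow statistic (probabilistic
#' models, first repetition).
#'
#' @param cohort a `cohort`.
#' @param config an [experiment_config()].
#' @return list of class `eval_report`: `summary` (one data.frame row per
#'   model x arm x outcome) and `per_repetition` (long data.frame of
#'   per-repetition metrics).
#' @export
run_experiment <- function(cohort, config = experiment_config()) {
  outcomes <- config$outcomes
  if (is.null(outcomes)) outcomes <- names(cohort$outcomes)
  per_rep <- list()
  extras <- list()
  for (outcome in outcomes) {
    y <- cohort$outcomes[[outcome]]
    for (rep_i in seq_len(config$repetitions)) {
      plan <- stratified_split(y, config$train_fraction,
                               seed = child_seed(config$seed, 100 + rep_i))
      des <- prepare_design(cohort, plan$train, plan$validation, outcome,
                            config)
      for (arm in config$arms) {
        red <- apply_arm(arm, des$X_train, des$X_val, des$y_train, config)
        for (kind in config$models) {
          model <- suppressWarnings(
            fit_model_kind(kind, red$X_train, des$y_train, config, cohort))
          sc <- predict_risk(model, red$X_val)
          thr <- if (kind == "svm") 0 else config$threshold
          ap <- accuracy_ppv(sc, des$y_val, thr)
          key <- paste(outcome, arm, kind, sep = ".")
          per_rep[[length(per_rep) + 1L]] <- data.frame(
            outcome = outcome, arm = arm, model = kind, repetition = rep_i,
            auc = auc(sc, des$y_val),
            accuracy = unname(ap["accuracy"]), ppv = unname(ap["ppv"]))
          if (rep_i == 1L) {
            ci <- bootstrap_ci(sc, des$y_val, B = config$bootstrap_B,
                               seed = config$seed)
            hl <- if (kind != "svm")
              hosmer_lemeshow(sc, des$y_val) else
                c(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
            extras[[key]] <- c(boot_auc_lower = unname(ci["lower"]),
                               boot_auc_upper = unname(ci["upper"]),
                               hl_statistic = unname(hl["statistic"]),
                               hl_p = unname(hl["p_value"]))
          }
        }
      }
    }
  }
  per_rep <- do.call(rbind, per_rep)

  cells <- unique(per_rep[c("outcome", "arm", "model")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- per_rep$outcome == cells$outcome[i] & per_rep$arm == cells$arm[i] &
      per_rep$model == cells$model[i]
    sub <- per_rep[sel, ]
    qs <- function(v) if (all(is.na(v))) c(NA_real_, NA_real_) else
      stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    a <- qs(sub$auc); ac <- qs(sub$accuracy); pp <- qs(sub$ppv)
    ex <- extras[[paste(cells$outcome[i], cells$arm[i], cells$model[i],
                        sep = ".")]]
    data.frame(cells[i, ],
               auc = mean(sub$auc), auc_lower = a[1], auc_upper = a[2],
               accuracy = mean(sub$accuracy),
               accuracy_lower = ac[1], accuracy_upper = ac[2],
               ppv = mean(sub$ppv, na.rm = TRUE),
               ppv_lower = pp[1], ppv_upper = pp[2],
               boot_auc_lower = ex["boot_auc_lower"],
               boot_auc_upper = ex["boot_auc_upper"],
               hl_statistic = ex["hl_statistic"], hl_p = ex["hl_p"],
               row.names = NULL)
  }))
  structure(list(summary = summ, per_repetition = per_rep, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summary[c("outcome", "arm", "model", "auc", "auc_lower",
                    "auc_upper", "accuracy", "ppv")], digits = 3)
  invisible(x)
}

#' Write an evaluation report to CSV (and optionally JSON)
#'
#' The CSV has one row per model x arm x outcome with point estimates and
#' CI bounds; numbers are written at full precision so reruns under the
#' same seed are byte-identical.
#'
#' @param report an `eval_report`.
#' @param csv_path output CSV path.
#' @param json_path optional JSON path for the full report.
#' @return invisibly, the CSV path.
#' @export
write_eval_report <- function(report, csv_path, json_path = NULL) {
  dir.create(dirname(csv_path), recursive = TRUE, showWarnings = FALSE)
  out <- report$summary
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.12g", v))
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(summary = report$summary,
                              per_repetition = report$per_repetition),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Run the whole pipeline from a spec to an evaluation report
#'
#' Synthesizes a cohort, cleans it, and runs the repeated-split experiment;
#' artifacts (cohort CSV, report CSV/JSON, manifest with config and seed)
#' are written under `out_dir` when given.
#'
#' @param spec a [cohort_spec()].
#' @param config an [experiment_config()].
#' @param out_dir optional artifact directory.
#' @return the `eval_report`.
#' @export
run_pipeline <- function(spec = cohort_spec(), config = experiment_config(),
                         out_dir = NULL) {
  sim <- simulate_cohort(spec)
  report <- run_experiment(sim$cohort, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(sim$cohort, out_dir)
    write_eval_report(report, file.path(out_dir, "eval_report.csv"),
                      file.path(out_dir, "eval_report.json"))
    jsonlite::write_json(
      list(seed = spec$seed, n_patients = spec$n_patients,
           config = unclass(config)[!vapply(unclass(config), is.function,
                                            logical(1))],
           r_version = as.character(getRversion())),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}
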