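#' Specification for a synthetic surgical cohort
#'
#' Defines the generative model for a synthetic preoperative cohort with the
#' statistical structure the downstream analysis assumes: correlated
#' continuous labs/demographics with optionally non-monotone (U-shaped) risk
#' contributions, binary comorbidity/medication indicators, high-cardinality
#' nominal features with Zipf-distributed level frequencies and i.i.d. normal
#' level effects, a 4-digit hierarchical procedure-code feature with effects
#' at every tree depth, and one or more binary outcomes at calibrated
#' prevalences. Defaults emulate a large academic-surgery cohort: ~36%
#' acute kidney injury and ~5% severe sepsis prevalence, a surgeon identifier
#' with 500 levels, and U-shaped effects for hematocrit, hemoglobin and eGFR.
#'
#' @param n_patients number of patients.
#' @param prevalence named vector of target outcome prevalences in (0,1).
#' @param continuous data.frame with columns `name`, `mean`, `sd`, `family`
#'   (`"normal"`, or `"lognormal"` for right-skewed labs such as serum
#'   creatinine, where `mean` is the median and `sd` the log-scale standard
#'   deviation), `beta` (linear coefficient on the standardized latent
#'   scale) and `shape` (`"linear"` or `"ushape"`). All true effects act on
#'   the standardized latent scale, so a lognormal feature's true effect is
#'   linear in its logarithm.
#' @param cont_cor correlation among the continuous features: either a
#'   single exchangeable pairwise correlation or a full correlation matrix
#'   (rows/columns in the order of `continuous$name`). The default matrix
#'   encodes realistic lab dependence: hematocrit-hemoglobin 0.9,
#'   eGFR-creatinine -0.7, age-eGFR -0.45.
#' @param ushape_strength curvature coefficient c of the U-shaped effect
#'   f(z) = c (z^2 - 1) on the standardized scale.
#' @param binary data.frame with columns `name`, `rate`, `beta`, `cluster`
#'   (integer label; indicators sharing a cluster are correlated through a
#'   latent Gaussian threshold model, emulating comorbidity/medication
#'   clusters such as heart failure with diuretic use).
#' @param binary_cluster_cor latent pairwise correlation within a binary
#'   cluster, in \[0, 1).
#' @param nominal data.frame with columns `name`, `n_levels`, `zipf`,
#'   `effect_sd`.
#' @param code list describing the hierarchical procedure-code feature:
#'   `n_top_classes`, `children_per_class` (range), `leaves_per_child`
#'   (range), `zipf` (leaf-frequency exponent), `effect_sd` (length-3 vector
#'   of per-depth effect standard deviations for digit lengths 2, 3, 4).
#'   `NULL` disables the code feature.
#' @param missingness_rate missing-completely-at-random rate per feature
#'   column, in \[0, 1).
#' @param outlier_rate corruption rate per continuous feature, in \[0, 1).
#' @param outlier_magnitude scale multiplier for injected outliers (> 1).
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20000,
                        prevalence = c(aki = 0.36, sepsis = 0.05),
                        continuous = default_continuous_features(),
                        cont_cor = default_continuous_correlation(),
                        ushape_strength = 0.18,
                        binary = default_binary_features(),
                        binary_cluster_cor = 0.55,
                        nominal = default_nominal_features(),
                        code = default_code_feature(),
                        missingness_rate = 0.05,
                        outlier_rate = 0.01,
                        outlier_magnitude = 8,
                        seed = 1L) {
  stopifnot(n_patients >= 1,
            all(prevalence > 0), all(prevalence < 1),
            missingness_rate >= 0, missingness_rate < 1,
            outlier_rate >= 0, outlier_rate < 1,
            outlier_magnitude > 1)
  if (!is.null(nominal) && nrow(nominal) && any(nominal$n_levels < 2))
    stop("nominal features need at least 2 levels")
  if (!is.null(code) &&
      (code$children_per_class[2] > 10 || code$leaves_per_child[2] > 10))
    stop("at most 10 children per node (one decimal digit each)")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 continuous = continuous, cont_cor = cont_cor,
                 ushape_strength = ushape_strength,
                 binary = binary, binary_cluster_cor = binary_cluster_cor,
                 nominal = nominal, code = code,
                 missingness_rate = missingness_rate,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_continuous_features <- function() {
  data.frame(
    name   = c("age", "ref_creatinine", "mdrd_creatinine", "egfr",
               "hematocrit", "hemoglobin",
               "total_population", "median_income", "prop_poverty",
               "prop_aa", "prop_hispanic", "distance_km"),
    mean   = c(56, 0.85, 0.90, 92, 34.3, 11.7,
               17000, 33000, 0.13, 0.10, 0.04, 53),
    sd     = c(15, 0.40, 0.40, 25, 6, 2.2,
               0.90, 0.30, 0.45, 0.80, 0.70, 1.00),
    family = c("normal", "lognormal", "lognormal", "normal",
               "normal", "normal",
               "lognormal", "lognormal", "lognormal",
               "lognormal", "lognormal", "lognormal"),
    beta   = c(0.45, 0.45, 0.00, 0.00, -0.35, 0.00,
               0.00, -0.25, 0.00, 0.00, 0.00, 0.10),
    shape  = c("linear", "linear", "linear", "ushape",
               "ushape", "linear",
               "linear", "linear", "linear", "linear", "linear", "linear"),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_continuous_correlation <- function() {
  nm <- default_continuous_features()$name
  # three latent factors: renal function, red-cell mass, neighborhood SES;
  # the duplicate creatinine pair shares an extra method factor
  L <- matrix(0, length(nm), 4, dimnames = list(nm, NULL))
  L["age", ]             <- c(0.30, -0.15, 0.00, 0.00)
  L["ref_creatinine", ]  <- c(0.80, 0.00, 0.00, 0.50)
  L["mdrd_creatinine", ] <- c(0.80, 0.00, 0.00, 0.50)
  L["egfr", ]            <- c(-0.80, 0.00, 0.00, 0.00)
  L["hematocrit", ]      <- c(0.00, 0.95, 0.00, 0.00)
  L["hemoglobin", ]      <- c(0.00, 0.95, 0.00, 0.00)
  L["total_population", ] <- c(0.00, 0.00, 0.35, 0.00)
  L["median_income", ]   <- c(0.00, 0.00, -0.80, 0.00)
  L["prop_poverty", ]    <- c(0.00, 0.00, 0.80, 0.00)
  L["prop_aa", ]         <- c(0.00, 0.00, 0.70, 0.00)
  L["prop_hispanic", ]   <- c(0.00, 0.00, 0.50, 0.00)
  L["distance_km", ]     <- c(0.00, 0.00, -0.30, 0.00)
  R <- L %*% t(L)
  diag(R) <- 1
  R
}

#' @rdname cohort_spec
#' @export
default_binary_features <- function() {
  # comorbidity/medication/operative indicators in latent clusters
  # (cardiac, renal, metabolic, oncologic, infection/inflammation, acuity);
  # zero-beta members are marginally informative but conditionally redundant
  data.frame(
    name = c("chf", "mi", "pvd", "betablockers", "diuretics", "pressors",
             "ckd", "ace_inhibitors", "bicarbonate",
             "diabetes", "statin", "insulin",
             "cancer", "liver_disease", "steroid",
             "vancomycin", "aminoglycosides", "antiemetic", "nsaids",
             "emergent", "transfer", "weekend", "surgical_service",
             "aspirin"),
    rate = c(0.08, 0.065, 0.12, 0.23, 0.12, 0.06,
             0.06, 0.10, 0.04,
             0.17, 0.12, 0.07,
             0.20, 0.05, 0.08,
             0.05, 0.03, 0.57, 0.06,
             0.45, 0.13, 0.14, 0.89,
             0.07),
    beta = c(0.45, 0.25, 0.20, 0.00, 0.00, 0.55,
             0.50, 0.00, 0.20,
             0.35, 0.00, 0.00,
             0.15, 0.30, 0.15,
             0.30, 0.25, 0.00, -0.10,
             0.40, 0.25, 0.00, -0.15,
             0.00),
    cluster = c(1L, 1L, 1L, 1L, 1L, 1L,
                2L, 2L, 2L,
                3L, 3L, 3L,
                4L, 4L, 4L,
                5L, 5L, 5L, 5L,
                6L, 6L, 6L, 6L,
                6L),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_nominal_features <- function() {
  data.frame(
    name      = c("surgeon", "county"),
    n_levels  = c(500L, 71L),
    zipf      = c(1.1, 1.0),
    effect_sd = c(0.30, 0.20),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_code_feature <- function() {
  list(n_top_classes = 18L, children_per_class = c(2L, 6L),
       leaves_per_child = c(1L, 8L), zipf = 1.05,
       effect_sd = c(0.25, 0.15, 0.08))
}

zipf_probs <- function(k, s) {
  p <- seq_len(k)^(-s)
  p / sum(p)
}

# sample the code universe: top classes "01".."NN", 3-digit children,
# 4-digit leaves; returns leaves, leaf probabilities, per-node effects
build_code_universe <- function(code, seed) {
  set.seed(seed)
  tops <- sprintf("%02d", seq_len(code$n_top_classes))
  leaves <- character(0)
  for (top in tops) {
    n_child <- sample(code$children_per_class[1]:code$children_per_class[2], 1)
    kids <- sample(0:9, n_child)
    for (kid in kids) {
      child <- paste0(top, kid)
      n_leaf <- sample(code$leaves_per_child[1]:code$leaves_per_child[2], 1)
      leaves <- c(leaves, paste0(child, sample(0:9, n_leaf)))
    }
  }
  leaves <- sort(leaves)
  probs <- zipf_probs(length(leaves), code$zipf)
  probs <- probs[sample.int(length(leaves))]  # decouple rank from code order
  nodes <- unique(c(substr(leaves, 1, 2), substr(leaves, 1, 3), leaves))
  eff <- stats::rnorm(length(nodes)) *
    code$effect_sd[nchar(nodes) - 1L]
  names(eff) <- nodes
  list(leaves = leaves, probs = probs, effects = eff)
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Draws covariates per the spec, builds the true additive linear predictor
#' on the logit scale, calibrates each outcome's intercept so the expected
#' prevalence matches the target, and draws outcomes Bernoulli(sigmoid(eta)).
#' The returned cohort is complete: missingness and outliers are injected
#' separately by [inject_missingness()] and [inject_outliers()] so tests can
#' hold the clean truth.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `cohort` (a [new_cohort()]) and `true_model`
#'   (class `true_model`: intercepts, linear coefficients, nonlinear
#'   functions, nominal level effects, code node effects, and the
#'   standardization constants needed to recompute the linear predictor).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  feats <- list(); types <- character(0)

  # continuous block: exchangeable correlation, then shift/scale
  set.seed(child_seed(spec$seed, 1))
  cont <- spec$continuous
  eta <- numeric(n)
  nonlinear <- list()
  if (!is.null(cont) && nrow(cont)) {
    p <- nrow(cont)
    if (is.matrix(spec$cont_cor)) {
      if (!all(dim(spec$cont_cor) == p))
        stop("correlation matrix dimension must match the continuous block")
      R <- spec$cont_cor
    } else {
      stopifnot(spec$cont_cor >= 0, spec$cont_cor < 1)
      R <- matrix(spec$cont_cor, p, p); diag(R) <- 1
    }
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
    if (is.null(cont$family)) cont$family <- "normal"
    for (j in seq_len(p)) {
      nm <- cont$name[j]
      feats[[nm]] <- if (cont$family[j] == "lognormal")
        cont$mean[j] * exp(cont$sd[j] * Z[, j])
      else cont$mean[j] + cont$sd[j] * Z[, j]
      types[nm] <- "continuous"
      if (cont$shape[j] == "ushape") {
        cs <- spec$ushape_strength
        nonlinear[[nm]] <- local({
          c0 <- cs
          function(z) c0 * (z^2 - 1)
        })
        eta <- eta + nonlinear[[nm]](Z[, j])
      }
      eta <- eta + cont$beta[j] * Z[, j]
    }
  }

  # binary indicators: latent Gaussian threshold model with within-cluster
  # correlation, emulating comorbidity/medication clusters
  set.seed(child_seed(spec$seed, 2))
  bin <- spec[["binary"]]  # exact: `binary` may be absent, avoid partial match
  if (!is.null(bin) && nrow(bin)) {
    q <- nrow(bin)
    if (is.null(bin$cluster)) bin$cluster <- seq_len(q)
    Rb <- diag(q)
    for (cl in unique(bin$cluster)) {
      i <- which(bin$cluster == cl)
      Rb[i, i] <- spec$binary_cluster_cor
    }
    diag(Rb) <- 1
    L <- MASS::mvrnorm(n, mu = rep(0, q), Sigma = Rb)
    for (j in seq_len(q)) {
      nm <- bin$name[j]
      x <- as.integer(L[, j] > stats::qnorm(1 - bin$rate[j]))
      feats[[nm]] <- x
      types[nm] <- "binary"
      eta <- eta + bin$beta[j] * x
    }
  }

  nominal_effects <- list()
  nom <- spec$nominal
  if (!is.null(nom) && nrow(nom)) {
    for (j in seq_len(nrow(nom))) {
      set.seed(child_seed(spec$seed, 10 + j))
      nm <- nom$name[j]
      k <- nom$n_levels[j]
      lv <- sprintf("%s_%04d", toupper(substr(nm, 1, 1)), seq_len(k))
      pr <- zipf_probs(k, nom$zipf[j])
      x <- sample(lv, n, replace = TRUE, prob = pr)
      eff <- stats::setNames(stats::rnorm(k, 0, nom$effect_sd[j]), lv)
      feats[[nm]] <- x
      types[nm] <- "nominal"
      nominal_effects[[nm]] <- eff
      eta <- eta + unname(eff[x])
    }
  }

  code_effects <- NULL
  if (!is.null(spec$code)) {
    uni <- build_code_universe(spec$code, child_seed(spec$seed, 30))
    set.seed(child_seed(spec$seed, 31))
    x <- sample(uni$leaves, n, replace = TRUE, prob = uni$probs)
    feats[["proc_code"]] <- x
    types["proc_code"] <- "code"
    code_effects <- uni$effects
    eta <- eta + code_node_sum(x, code_effects)
  }

  features <- as.data.frame(feats, stringsAsFactors = FALSE)

  # per-outcome intercept calibration, then independent Bernoulli draws
  intercepts <- vapply(spec$prevalence, function(tgt)
    calibrate_intercept(eta, tgt), numeric(1))
  outcomes <- list()
  for (i in seq_along(spec$prevalence)) {
    set.seed(child_seed(spec$seed, 50 + i))
    outcomes[[names(spec$prevalence)[i]]] <-
      stats::rbinom(n, 1L, sigmoid(intercepts[i] + eta))
  }
  outcomes <- as.data.frame(outcomes)

  true_model <- structure(
    list(intercepts = intercepts,
         linear_coefficients = c(
           if (!is.null(cont) && nrow(cont)) stats::setNames(cont$beta, cont$name),
           if (!is.null(bin) && nrow(bin)) stats::setNames(bin$beta, bin$name)),
         nonlinear_functions = nonlinear,
         nominal_level_effects = nominal_effects,
         code_node_effects = code_effects,
         standardize = if (!is.null(cont) && nrow(cont))
           data.frame(name = cont$name, mean = cont$mean, sd = cont$sd,
                      family = cont$family)
         else NULL),
    class = "true_model")

  list(cohort = new_cohort(features, outcomes, types),
       true_model = true_model)
}

code_node_sum <- function(codes, effects) {
  vapply(codes, function(cd) {
    s <- 0
    for (l in 2:nchar(cd)) {
      e <- effects[substr(cd, 1, l)]
      if (!is.na(e)) s <- s + e
    }
    s
  }, numeric(1), USE.NAMES = FALSE)
}

#' Recompute the true linear predictor (without intercept) for a cohort
#'
#' @param true_model a `true_model` as returned by [generate_cohort()].
#' @param cohort the matching `cohort` (complete, pre-corruption).
#' @return numeric vector, one logit-scale contribution per patient.
#' @export
true_linear_predictor <- function(true_model, cohort) {
  eta <- numeric(nrow(cohort$features))
  std <- true_model$standardize
  for (nm in names(cohort$types)) {
    x <- cohort$features[[nm]]
    type <- cohort$types[[nm]]
    if (type == "continuous") {
      i <- match(nm, std$name)
      z <- if (!is.null(std$family) && std$family[i] == "lognormal")
        log(x / std$mean[i]) / std$sd[i]
      else (x - std$mean[i]) / std$sd[i]
      b <- true_model$linear_coefficients[nm]
      if (!is.na(b)) eta <- eta + b * z
      f <- true_model$nonlinear_functions[[nm]]
      if (!is.null(f)) eta <- eta + f(z)
    } else if (type == "binary") {
      b <- true_model$linear_coefficients[nm]
      if (!is.na(b)) eta <- eta + b * x
    } else if (type == "nominal") {
      eff <- true_model$nominal_level_effects[[nm]]
      if (!is.null(eff)) eta <- eta + unname(eff[x])
    } else if (type == "code") {
      eta <- eta + code_node_sum(x, true_model$code_node_effects)
    }
  }
  eta
}

#' Calibrate the logit intercept to hit a target mean risk
#'
#' Finds alpha such that mean(sigmoid(alpha + eta)) equals the target
#' prevalence; the mean sigmoid is strictly increasing in alpha so the root
#' is unique (monotone root-finding via [stats::uniroot()]).
#'
#' @param eta linear predictor values (without intercept) over the sampled
#'   covariates.
#' @param prevalence_target fraction strictly in (0, 1).
#' @param tol absolute tolerance on the expected-prevalence scale.
#' @return the calibrated intercept (real).
#' @export
calibrate_intercept <- function(eta, prevalence_target, tol = 1e-6) {
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence target must lie strictly in (0, 1)")
  f <- function(a) mean(sigmoid(a + eta)) - prevalence_target
  lo <- logit(prevalence_target) - max(abs(eta)) - 1
  hi <- logit(prevalence_target) + max(abs(eta)) + 1
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Inject missing-completely-at-random values into feature columns
#'
#' Outcome vectors are never masked. The mask is drawn independently per
#' entry at the given rate(s).
#'
#' @param cohort a `cohort`.
#' @param rates single rate in \[0, 1) or named per-feature vector.
#' @param seed integer seed.
#' @return the corrupted `cohort`.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L) {
  if (any(rates >= 1) || any(rates < 0)) stop("rates must lie in [0, 1)")
  if (length(rates) == 1L)
    rates <- stats::setNames(rep(rates, ncol(cohort$features)),
                             names(cohort$features))
  set.seed(child_seed(seed, 3))
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r == 0) next
    mask <- stats::runif(nrow(cohort$features)) < r
    cohort$features[[nm]][mask] <- NA
  }
  cohort
}

#' Inject gross outliers into continuous feature columns
#'
#' A fraction of entries per continuous feature is replaced by values beyond
#' `magnitude` scale units from the feature's location (random sign). The
#' affected indices are recorded in `attr(, "outlier_index")` so tests can
#' verify detection.
#'
#' @param cohort a `cohort`.
#' @param rate corruption rate per continuous feature in \[0, 1).
#' @param magnitude scale multiplier (> 1).
#' @param seed integer seed.
#' @return the corrupted `cohort` with an `outlier_index` attribute
#'   (named list of integer vectors).
#' @export
inject_outliers <- function(cohort, rate, magnitude = 8, seed = 1L) {
  stopifnot(magnitude > 1, rate >= 0, rate < 1)
  set.seed(child_seed(seed, 4))
  idx_rec <- list()
  for (nm in feature_names_of_type(cohort, "continuous")) {
    x <- cohort$features[[nm]]
    k <- round(rate * length(x))
    if (k == 0) { idx_rec[[nm]] <- integer(0); next }
    loc <- mean(x, na.rm = TRUE); sc <- stats::sd(x, na.rm = TRUE)
    idx <- sample(which(!is.na(x)), k)
    sign <- sample(c(-1, 1), k, replace = TRUE)
    x[idx] <- loc + sign * sc * magnitude * (1 + stats::runif(k))
    cohort$features[[nm]] <- x
    idx_rec[[nm]] <- sort(idx)
  }
  attr(cohort, "outlier_index") <- idx_rec
  cohort
}

#' Simulate a corrupted cohort in one call
#'
#' Convenience wrapper: [generate_cohort()] followed by [inject_outliers()]
#' and [inject_missingness()] at the rates in the spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (corrupted), `clean_cohort`, `true_model`.
#' @export
simulate_cohort <- function(spec) {
  g <- generate_cohort(spec)
  corrupted <- inject_outliers(g$cohort, spec$outlier_rate,
                               spec$outlier_magnitude, seed = spec$seed)
  corrupted <- inject_missingness(corrupted, spec$missingness_rate,
                                  seed = spec$seed)
  list(cohort = corrupted, clean_cohort = g$cohort, true_model = g$true_model)
}

#' Discrimination ceiling of the true risk score on a realized cohort
#'
#' AUC of the ground-truth linear predictor against the realized outcomes;
#' by the Neyman-Pearson lemma no model can beat this score's ranking in
#' expectation, so it bounds achievable validation AUC.
#'
#' @param true_model a `true_model`.
#' @param cohort the matching complete `cohort`.
#' @param outcome outcome name.
#' @return the AUC of the true score (real in \[0, 1\]).
#' @export
theoretical_auc <- function(true_model, cohort, outcome) {
  y <- cohort$outcomes[[outcome]]
  if (length(unique(y)) < 2) stop("degenerate outcome: one class only")
  auc(true_linear_predictor(true_model, cohort), y)
}
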