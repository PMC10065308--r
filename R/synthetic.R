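# Synthetic pregnancy-cohort generator: correlated continuous risk factors,
# binary histories, count variables, a logistic outcome mechanism with a
# bisection-calibrated intercept, both missingness mechanisms (gated
# "not applicable" and covariate-driven MAR), and planted point / contextual
# outliers with recorded ground truth.

#' Specification for a synthetic cohort
#'
#' Defaults emulate the clinical shape of a high-risk obstetric trial cohort:
#' n = 2301 participants, mixed continuous measurements (age, weight, BMI,
#' blood pressures), count-style obstetric history variables, binary risk
#' factors and supplement indicators at realistic prevalences, and a binary
#' outcome (preeclampsia) at 14.1% prevalence driven by a known logistic
#' mechanism over the risk factors. A cohort-study-like variant is available
#' via `target_prevalence = 0.074`.
#'
#' @param n_rows Number of participants.
#' @param continuous_vars Data frame `(name, mean, sd)` of continuous
#'   variables, drawn jointly normal with exchangeable correlation `corr`.
#' @param count_vars Data frame `(name, lambda)` of Poisson count variables
#'   (obstetric history counts).
#' @param binary_vars Data frame `(name, prevalence)` of yes/no variables.
#' @param corr Exchangeable latent correlation among continuous variables.
#' @param gated_pairs List of gate rules: each a list with `gate` (binary
#'   variable), `gate_value` (level that makes the question applicable),
#'   `target`, `target_kind`, `fill` (sentinel used when not applicable), and
#'   for continuous targets `mean`/`sd`, for categorical targets `levels`.
#' @param outcome_name,positive_label Outcome column and event token.
#' @param outcome_coefficients Named log-odds weights: per SD for continuous
#'   and count variables, per indicator for binary (`yes`) variables.
#' @param target_prevalence Outcome prevalence the intercept is calibrated to.
#' @param mar_missing_rate Average missing-at-random rate over the MAR-eligible
#'   columns (0 disables); missingness probability is a logistic function of
#'   the two fully observed driver covariates (age and weight).
#' @param n_point_outliers,point_magnitude,point_n_features Planted point
#'   outliers: rows shifted by `point_magnitude` SDs on `point_n_features`
#'   continuous features.
#' @param n_contextual_outliers,contextual_mechanism Planted contextual
#'   outliers: `"label_flip_extreme"` flips the outcome of marginally typical
#'   rows with extreme linear predictors; `"hidden_modifier"` draws an
#'   unrecorded binary modifier that reverses the odds for carriers and
#'   resamples their outcomes.
#' @param seed Integer seed; the generator is fully reproducible from
#'   (spec, seed).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_rows = 2301L,
    continuous_vars = data.frame(
      name = c("age", "weight_kg", "bmi", "sbp_last", "dbp_last",
               "gest_age_delivery"),
      mean = c(31.4, 91.6, 34.0, 136.1, 81.5, 37.8),
      sd = c(5.3, 24.8, 11.2, 18.2, 13.0, 2.8),
      stringsAsFactors = FALSE),
    count_vars = data.frame(
      name = c("gravidity", "term_births", "preterm_births", "living_children"),
      lambda = c(2.3, 0.9, 0.3, 1.0),
      stringsAsFactors = FALSE),
    binary_vars = data.frame(
      name = c("multiple_pregnancy", "art_pregnancy", "chronic_hypertension",
               "diabetes_history", "preeclampsia_history", "smoking_history",
               "folic_acid", "aspirin", "other_medications", "alcohol_use"),
      prevalence = c(0.186, 0.093, 0.184, 0.135, 0.253, 0.399, 0.818, 0.289,
                     0.704, 0.021),
      stringsAsFactors = FALSE),
    corr = 0.3,
    gated_pairs = list(
      list(gate = "smoking_history", gate_value = "yes",
           target = "cigarettes_per_day", target_kind = "continuous",
           fill = 0, mean = 9, sd = 5),
      list(gate = "alcohol_use", gate_value = "yes",
           target = "alcohol_frequency", target_kind = "categorical",
           fill = "NOT_APPLICABLE",
           levels = c("monthly", "weekly", "daily"))),
    outcome_name = "preeclampsia",
    positive_label = "yes",
    outcome_coefficients = c(
      age = 0.3, weight_kg = 0.3, bmi = 0.8, chronic_hypertension = 1.5,
      preeclampsia_history = 2.0, multiple_pregnancy = 1.0,
      smoking_history = 0.5, folic_acid = -0.5, diabetes_history = 0.8),
    target_prevalence = 0.141,
    mar_missing_rate = 0.03,
    n_point_outliers = 0L,
    point_magnitude = 8,
    point_n_features = 3L,
    n_contextual_outliers = 0L,
    contextual_mechanism = c("label_flip_extreme", "hidden_modifier"),
    seed = 2022L) {
  stopifnot(target_prevalence > 0, target_prevalence < 1,
            n_point_outliers + n_contextual_outliers <= n_rows,
            mar_missing_rate >= 0, mar_missing_rate < 1)
  structure(list(
    n_rows = as.integer(n_rows), continuous_vars = continuous_vars,
    count_vars = count_vars, binary_vars = binary_vars, corr = corr,
    gated_pairs = gated_pairs, outcome_name = outcome_name,
    positive_label = positive_label,
    outcome_coefficients = outcome_coefficients,
    target_prevalence = target_prevalence,
    mar_missing_rate = mar_missing_rate,
    n_point_outliers = as.integer(n_point_outliers),
    point_magnitude = point_magnitude,
    point_n_features = as.integer(point_n_features),
    n_contextual_outliers = as.integer(n_contextual_outliers),
    contextual_mechanism = match.arg(contextual_mechanism),
    seed = as.integer(seed)), class = "synthetic_spec")
}

# Correlated standard normals via a Cholesky factor of an exchangeable
# correlation matrix (Gaussian copula over the continuous block).
draw_correlated_normals <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (p > 1 && rho != 0) {
    sigma <- matrix(rho, p, p)
    diag(sigma) <- 1
    z <- z %*% chol(sigma)
  }
  z
}

# Bisection on the logistic intercept so mean(plogis(lp + b)) hits target.
calibrate_intercept <- function(lp, target, tol = 1e-8, max_iter = 200L) {
  f <- function(b) mean(stats::plogis(lp + b)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence unattainable for the given coefficients")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the cohort described by the spec, calibrates the outcome intercept
#' by bisection so the expected prevalence matches `target_prevalence`,
#' plants the requested point and contextual outliers (disjoint sets), then
#' applies gated structured missingness and covariate-driven MAR gaps.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a [cohort_table()]), `metadata`, `outcome`
#'   (an [outcome_spec()]), and `truth` — a `synthetic_truth` record of the
#'   linear predictor, calibrated intercept, planted outlier ids, and any
#'   hidden-modifier values (the modifier itself is never added to the
#'   table).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_rows
    cv <- spec$continuous_vars
    z <- draw_correlated_normals(n, nrow(cv), spec$corr)
    cont <- sweep(sweep(z, 2, cv$sd, "*"), 2, cv$mean, "+")
    colnames(cont) <- cv$name

    counts <- vapply(seq_len(nrow(spec$count_vars)), function(i)
      stats::rpois(n, spec$count_vars$lambda[i]), numeric(n))
    colnames(counts) <- spec$count_vars$name

    bins <- vapply(seq_len(nrow(spec$binary_vars)), function(i)
      stats::rbinom(n, 1L, spec$binary_vars$prevalence[i]), numeric(n))
    colnames(bins) <- spec$binary_vars$name

    # linear predictor on standardized continuous/count scales
    lp <- rep(0, n)
    for (nm in names(spec$outcome_coefficients)) {
      b <- spec$outcome_coefficients[[nm]]
      if (nm %in% colnames(cont)) {
        lp <- lp + b * (cont[, nm] - cv$mean[cv$name == nm]) /
          cv$sd[cv$name == nm]
      } else if (nm %in% colnames(counts)) {
        lam <- spec$count_vars$lambda[spec$count_vars$name == nm]
        lp <- lp + b * (counts[, nm] - lam) / sqrt(lam)
      } else if (nm %in% colnames(bins)) {
        lp <- lp + b * bins[, nm]
      } else stop("outcome coefficient for unknown variable: ", nm)
    }
    intercept <- calibrate_intercept(lp, spec$target_prevalence)
    prob <- stats::plogis(lp + intercept)
    y <- stats::rbinom(n, 1L, prob)

    ids <- sprintf("P%05d", seq_len(n))
    truth <- structure(list(
      linear_predictor = lp, intercept = intercept, prob = prob,
      point_ids = character(), contextual_ids = character(),
      hidden_modifier = NULL, mechanism = spec$contextual_mechanism,
      seed = spec$seed, target_prevalence = spec$target_prevalence),
      class = "synthetic_truth")

    # contextual outliers first (they use lp and y), then point outliers on
    # the remaining rows; sets are disjoint by construction
    if (spec$n_contextual_outliers > 0L) {
      ctx <- plant_contextual(cont, cv, lp, y, prob, ids, spec)
      y <- ctx$y
      truth$contextual_ids <- ctx$ids
      truth$hidden_modifier <- ctx$modifier
    }
    if (spec$n_point_outliers > 0L) {
      pp <- plant_point(cont, cv, ids, setdiff(ids, truth$contextual_ids), spec)
      cont <- pp$cont
      truth$point_ids <- pp$ids
    }

    df <- data.frame(participant_id = ids, cont, counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (nm in colnames(bins)) df[[nm]] <- ifelse(bins[, nm] == 1, "yes", "no")
    df[[spec$outcome_name]] <- ifelse(y == 1, spec$positive_label, "no")

    # gated variables: observed only where the gate question applied
    gate_rows <- list()
    for (g in spec$gated_pairs) {
      applicable <- df[[g$gate]] == g$gate_value
      if (g$target_kind == "continuous") {
        v <- rep(NA_real_, n)
        v[applicable] <- pmax(0, stats::rnorm(sum(applicable), g$mean, g$sd))
      } else {
        v <- rep(NA_character_, n)
        v[applicable] <- sample(g$levels, sum(applicable), replace = TRUE)
      }
      df[[g$target]] <- v
    }

    md <- build_synthetic_metadata(spec)
    # MAR gaps: logistic in standardized age and weight, calibrated to rate
    if (spec$mar_missing_rate > 0) {
      drivers <- cbind((cont[, "age"] - cv$mean[cv$name == "age"]) /
                         cv$sd[cv$name == "age"],
                       (cont[, "weight_kg"] - cv$mean[cv$name == "weight_kg"]) /
                         cv$sd[cv$name == "weight_kg"])
      eta <- drivers %*% c(0.5, 0.5)
      a <- calibrate_intercept(eta, spec$mar_missing_rate)
      p_miss <- stats::plogis(eta + a)
      # gate variables stay fully observed so gate fills remain well defined
      mar_cols <- setdiff(md$name[md$role == "feature" & is.na(md$gate_variable)],
                          c("age", "weight_kg", stats::na.omit(md$gate_variable)))
      for (colnm in mar_cols) {
        hit <- stats::runif(n) < p_miss
        df[[colnm]][hit] <- NA
      }
    }
    list(table = cohort_table(df, md), metadata = md,
         outcome = outcome_spec(spec$outcome_name, spec$positive_label),
         truth = truth, spec = spec)
  })
}

#' Strongly separable outcome coefficients
#'
#' The default [synthetic_spec()] coefficients keep effect sizes in a range
#' plausible for obstetric epidemiology; for benchmarking the contextual
#' detector the planted-flip recovery conditions call for a strongly
#' separable mechanism (most outcomes near-deterministic given the features,
#' so a recorded label contradicting the mechanism is genuinely anomalous
#' rather than sampling noise). This helper returns the default coefficient
#' vector scaled up for that purpose.
#'
#' @param scale Multiplier applied to the default log-odds weights.
#' @return Named numeric vector of log-odds coefficients.
#' @export
strong_outcome_coefficients <- function(scale = 3) {
  synthetic_spec()$outcome_coefficients * scale
}

#' Plant additional point outliers into a generated cohort
#'
#' Shifts `n` rows (sampled among rows not already planted as outliers of
#' either kind) by `magnitude` standard deviations on `n_features` continuous
#' features, direction away from the population mean, and records their ids
#' in the ground truth. A magnitude of zero leaves the table numerically
#' unchanged apart from the truth bookkeeping.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param n Number of rows to plant.
#' @param magnitude Shift size in population SDs.
#' @param n_features Continuous features shifted per row.
#' @param seed Integer seed.
#' @return The cohort list with updated `table` and `truth`.
#' @export
plant_point_outliers <- function(cohort, n, magnitude = 8, n_features = 3L,
                                 seed = 1L) {
  if (n == 0L) return(cohort)
  cv <- cohort$spec$continuous_vars
  tab <- cohort$table
  ids <- participant_ids(tab)
  eligible <- setdiff(ids, c(cohort$truth$point_ids, cohort$truth$contextual_ids))
  rows <- with_seed(seed, sample(match(eligible, ids), n))
  picks <- with_seed(derive_seed(seed, "feats"), lapply(rows, function(r)
    sample(seq_len(nrow(cv)), min(n_features, nrow(cv)))))
  for (j in seq_along(rows)) {
    r <- rows[j]
    for (f in picks[[j]]) {
      nm <- cv$name[f]
      dir <- sign(tab[[nm]][r] - cv$mean[f])
      if (is.na(dir) || dir == 0) dir <- 1
      tab[[nm]][r] <- tab[[nm]][r] + dir * magnitude * cv$sd[f]
    }
  }
  cohort$table <- tab
  cohort$truth$point_ids <- c(cohort$truth$point_ids, ids[rows])
  cohort
}

#' Plant additional contextual outliers into a generated cohort
#'
#' Under `label_flip_extreme`, flips the recorded outcome of `n` marginally
#' typical rows drawn from the top decile of |linear predictor| (distance
#' from the decision boundary, intercept included — rows whose outcome is
#' near-deterministic under the mechanism); these rows look ordinary
#' variable-by-variable but contradict the outcome mechanism, which is
#' exactly the signature the extreme-misclassification detector targets.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param n Number of rows to flip.
#' @param seed Integer seed.
#' @return The cohort list with updated `table` and `truth`.
#' @export
plant_contextual_outliers <- function(cohort, n, seed = 1L) {
  if (n == 0L) return(cohort)
  spec <- cohort$spec
  cv <- spec$continuous_vars
  tab <- cohort$table
  ids <- participant_ids(tab)
  eta <- cohort$truth$linear_predictor + cohort$truth$intercept
  top <- abs(eta) >= stats::quantile(abs(eta), 0.9)
  zabs <- abs(vapply(seq_len(nrow(cv)), function(f)
    (tab[[cv$name[f]]] - cv$mean[f]) / cv$sd[f], numeric(nrow(tab))))
  typical <- rowMeans(zabs <= 2, na.rm = TRUE) >= 0.9
  taken <- ids %in% c(cohort$truth$point_ids, cohort$truth$contextual_ids)
  eligible <- which(top & typical & !taken)
  if (length(eligible) < n)
    stop(sprintf("only %d rows eligible for label flipping, need %d",
                 length(eligible), n))
  rows <- with_seed(seed, sample(eligible, n))
  oc <- spec$outcome_name
  pos <- spec$positive_label
  tab[[oc]][rows] <- ifelse(tab[[oc]][rows] == pos, "no", pos)
  cohort$table <- tab
  cohort$truth$contextual_ids <- c(cohort$truth$contextual_ids, ids[rows])
  cohort
}

build_synthetic_metadata <- function(spec) {
  nm <- c("participant_id", spec$continuous_vars$name, spec$count_vars$name,
          spec$binary_vars$name, spec$outcome_name,
          vapply(spec$gated_pairs, `[[`, "", "target"))
  kind <- c("categorical", rep("continuous", nrow(spec$continuous_vars)),
            rep("continuous", nrow(spec$count_vars)),
            rep("categorical", nrow(spec$binary_vars)), "categorical",
            vapply(spec$gated_pairs, `[[`, "", "target_kind"))
  role <- c("identifier", rep("feature", nrow(spec$continuous_vars) +
                                nrow(spec$count_vars) +
                                nrow(spec$binary_vars)), "outcome",
            rep("feature", length(spec$gated_pairs)))
  md <- variable_metadata(nm, kind = kind, role = role)
  for (g in spec$gated_pairs) {
    i <- match(g$target, md$name)
    md$gate_variable[i] <- g$gate
    md$gate_value[i] <- g$gate_value
    md$gate_fill[i] <- as.character(g$fill)
  }
  md$summary[md$name %in% spec$count_vars$name] <- "median_iqr"
  md$risk_factor[md$name %in% c("chronic_hypertension", "preeclampsia_history",
                                "diabetes_history", "multiple_pregnancy",
                                "smoking_history", "bmi", "age")] <- TRUE
  validate_metadata(md)
  md
}

# Shift point_n_features continuous features of sampled rows by
# point_magnitude SDs, direction away from the mean.
plant_point <- function(cont, cv, ids, eligible_ids, spec) {
  rows <- sample(match(eligible_ids, ids), spec$n_point_outliers)
  for (r in rows) {
    feats <- sample(seq_len(ncol(cont)), min(spec$point_n_features, ncol(cont)))
    for (f in feats) {
      dir <- sign(cont[r, f] - cv$mean[f])
      if (dir == 0) dir <- 1
      cont[r, f] <- cont[r, f] + dir * spec$point_magnitude * cv$sd[f]
    }
  }
  list(cont = cont, ids = ids[rows])
}

plant_contextual <- function(cont, cv, lp, y, prob, ids, spec) {
  k <- spec$n_contextual_outliers
  if (spec$contextual_mechanism == "label_flip_extreme") {
    # extreme = far from the decision boundary on the linear-predictor scale
    # (|eta| = |lp + intercept| large, i.e. near-deterministic outcomes)
    eta <- stats::qlogis(prob)
    top <- abs(eta) >= stats::quantile(abs(eta), 0.9)
    # marginal typicality: at least 90% of continuous features within 2 SD
    zabs <- abs(sweep(sweep(cont, 2, cv$mean, "-"), 2, cv$sd, "/"))
    typical <- rowMeans(zabs <= 2) >= 0.9
    eligible <- which(top & typical)
    if (length(eligible) < k)
      stop(sprintf("only %d rows eligible for label flipping, need %d",
                   length(eligible), k))
    rows <- sample(eligible, k)
    y[rows] <- 1L - y[rows]
    list(y = y, ids = ids[rows], modifier = NULL)
  } else { # hidden_modifier
    carrier <- stats::rbinom(length(y), 1L, min(0.5, k / length(y) * 3))
    rows <- sample(which(carrier == 1L), k)
    flipped_prob <- stats::plogis(-(lp[rows] + spec_intercept_guess(prob, lp)))
    y[rows] <- stats::rbinom(k, 1L, flipped_prob)
    list(y = y, ids = ids[rows],
         modifier = stats::setNames(as.integer(seq_along(y) %in% rows), ids))
  }
}

# Recover the calibrated intercept from prob/lp (avoids threading it through).
spec_intercept_guess <- function(prob, lp) {
  stats::qlogis(prob[1]) - lp[1]
}
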