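# Planted-outlier recovery benchmarks. These define, in one place, the
# simulation conditions under which the two detectors are validated; the
# test suite and the acceptance script both call them.

#' Benchmark cohort for point-outlier recovery
#'
#' A continuous-measurements cohort (the six default clinical variables,
#' no binary or count features) with `n_planted` rows shifted by `magnitude`
#' SDs on `n_features` features. Isolation-forest scoring is a geometric
#' procedure over feature ranges; a shift on 3 of 6 continuous dimensions is
#' a recoverable signal, whereas the same shift diluted across a large block
#' of integer-coded binaries is not (a documented limitation of the method,
#' not of the generator).
#'
#' @param n_rows Cohort size.
#' @param n_planted Planted point outliers.
#' @param magnitude Shift in SDs.
#' @param n_features Continuous features shifted per planted row.
#' @param seed Integer seed.
#' @return As [generate_cohort()], with planted truth.
#' @export
point_benchmark_cohort <- function(n_rows = 1000L, n_planted = 5L,
                                   magnitude = 8, n_features = 3L,
                                   seed = 2022L) {
  spec <- synthetic_spec(
    n_rows = n_rows, seed = seed, mar_missing_rate = 0, gated_pairs = list(),
    binary_vars = data.frame(name = character(), prevalence = numeric()),
    count_vars = data.frame(name = character(), lambda = numeric()),
    outcome_coefficients = c(age = 0.3, weight_kg = 0.3, bmi = 0.8))
  gen <- generate_cohort(spec)
  plant_point_outliers(gen, n_planted, magnitude = magnitude,
                       n_features = n_features,
                       seed = derive_seed(seed, "plant-point"))
}

#' Point-outlier recovery benchmark
#'
#' For each seed, generates a [point_benchmark_cohort()], scores it with an
#' isolation forest, and records the worst rank of a planted row by |z|.
#'
#' @param seeds Integer vector of benchmark seeds.
#' @param n_rows,n_planted,magnitude,n_features Passed to
#'   [point_benchmark_cohort()].
#' @param n_estimators,max_samples Forest size used for scoring.
#' @return Data frame with one row per seed: `seed`, `worst_rank`,
#'   `all_top_1pct` (all planted rows within the top 1% by |z|), `n_flagged`.
#' @export
benchmark_point_recovery <- function(seeds = 1:10, n_rows = 1000L,
                                     n_planted = 5L, magnitude = 8,
                                     n_features = 3L, n_estimators = 300L,
                                     max_samples = 256L) {
  rows <- lapply(seeds, function(s) {
    gen <- point_benchmark_cohort(n_rows, n_planted, magnitude, n_features,
                                  seed = derive_seed(s, "point-bench"))
    enc <- encode_features(gen$table)
    anom <- score_anomalies(
      enc$x,
      isolation_config(n_estimators = n_estimators, max_samples = max_samples,
                       random_state = derive_seed(s, "point-bench-if")),
      ids = participant_ids(gen$table))
    rk <- rank(-abs(anom$scores$z_score))
    planted <- rk[match(gen$truth$point_ids, anom$scores$participant_id)]
    data.frame(seed = s, worst_rank = max(planted),
               all_top_1pct = all(planted <= ceiling(0.01 * n_rows)),
               n_flagged = sum(anom$scores$is_outlier))
  })
  do.call(rbind, rows)
}

#' Benchmark cohort for contextual-outlier recovery
#'
#' The full mixed clinical roster at `n_rows` participants, complete-case
#' (no gates, no MAR) so the detector is measured in isolation, with a
#' strongly separable outcome mechanism ([strong_outcome_coefficients()])
#' and `n_flipped` marginally typical, extreme-linear-predictor rows whose
#' recorded outcome is flipped.
#'
#' @param n_rows Cohort size.
#' @param n_flipped Planted contextual outliers (label flips).
#' @param seed Integer seed.
#' @return As [generate_cohort()], with planted truth.
#' @export
contextual_benchmark_cohort <- function(n_rows = 3000L, n_flipped = 30L,
                                        seed = 2022L) {
  spec <- synthetic_spec(
    n_rows = n_rows, seed = seed, mar_missing_rate = 0, gated_pairs = list(),
    outcome_coefficients = strong_outcome_coefficients())
  gen <- generate_cohort(spec)
  plant_contextual_outliers(gen, n_flipped,
                            seed = derive_seed(seed, "plant-ctx"))
}

#' Contextual-outlier recovery benchmark
#'
#' For each seed: generate a [contextual_benchmark_cohort()], train the
#' outcome forest on a 50/33/17 split, flag extreme misclassifications over
#' the full cohort at the vote-fraction threshold, and score recovery of the
#' planted flips. Also runs the isolation-forest stage on the same cohort
#' and records the overlap between the two flag sets (the two detectors'
#' near-disjointness is itself a property under test).
#'
#' @param seeds Integer vector of benchmark seeds.
#' @param n_rows,n_flipped Passed to [contextual_benchmark_cohort()].
#' @param threshold Vote-fraction flagging threshold.
#' @param params Forest hyperparameters (default: 600 trees, depth 10,
#'   min bucket 2, bootstrap off).
#' @return Data frame with one row per seed: `recall`, `precision`,
#'   `n_flagged`, `n_point_flagged`, `overlap_fraction` (overlap over the
#'   smaller flag set; 0 when either set is empty).
#' @export
benchmark_contextual_recovery <- function(seeds = 1:10, n_rows = 3000L,
                                          n_flipped = 30L, threshold = 0.90,
                                          params = list(num_trees = 600L,
                                                        max_depth = 10L,
                                                        min_node_size = 2L,
                                                        min_bucket = 2L,
                                                        replace = FALSE)) {
  rows <- lapply(seeds, function(s) {
    gen <- contextual_benchmark_cohort(n_rows, n_flipped,
                                       seed = derive_seed(s, "ctx-bench"))
    tab <- gen$table
    n <- nrow(tab)
    tn <- round(0.5 * n); te <- round(1 / 3 * n)
    splits <- split_dataset(tab, tn, te, n - tn - te, gen$outcome,
                            seed = derive_seed(s, "ctx-bench-split"))
    enc <- encode_features(tab)
    enc_tr <- encode_features(splits$train, level_maps = enc$level_maps)
    model <- fit_outcome_forest(enc_tr$x,
                                factor(splits$train[[gen$outcome$column]]),
                                params, seed = derive_seed(s, "ctx-bench-rf"))
    mis <- flag_extreme_misclassification(model, tab, gen$outcome,
                                          threshold = threshold,
                                          level_maps = enc$level_maps)
    flagged <- mis$flags$participant_id[mis$flags$is_outlier]
    truth <- gen$truth$contextual_ids
    anom <- score_anomalies(
      enc$x, isolation_config(n_estimators = 100L, max_samples = 256L,
                              random_state = derive_seed(s, "ctx-bench-if")),
      ids = participant_ids(tab))
    pt <- anom$scores$participant_id[anom$scores$is_outlier]
    smaller <- min(length(pt), length(flagged))
    data.frame(
      seed = s,
      recall = length(intersect(flagged, truth)) / length(truth),
      precision = if (length(flagged))
        length(intersect(flagged, truth)) / length(flagged) else NA_real_,
      n_flagged = length(flagged), n_point_flagged = length(pt),
      overlap_fraction = if (smaller == 0) 0
        else length(intersect(pt, flagged)) / smaller)
  })
  do.call(rbind, rows)
}
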