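test_that("generation is fully reproducible from (spec, seed)", {
  spec <- synthetic_spec(n_rows = 150L, seed = 41L, n_point_outliers = 3L,
                         n_contextual_outliers = 5L,
                         outcome_coefficients = strong_outcome_coefficients())
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$point_ids, b$truth$point_ids)
  expect_identical(a$truth$contextual_ids, b$truth$contextual_ids)
  expect_identical(a$truth$intercept, b$truth$intercept)
})

test_that("empirical prevalence hits the calibrated target", {
  # single default-size draw within +/- 1.5 percentage points
  gen <- generate_cohort(synthetic_spec(seed = 43L))
  prev <- mean(gen$table$preeclampsia == "yes")
  expect_gte(prev, 0.126)
  expect_lte(prev, 0.156)

  # across 20 seeds the mean is within +/- 0.5 points (smaller cohorts)
  prevs <- vapply(1:20, function(s) {
    g <- generate_cohort(synthetic_spec(n_rows = 1500L, seed = 500L + s,
                                        mar_missing_rate = 0,
                                        gated_pairs = list()))
    mean(g$table$preeclampsia == "yes")
  }, 0)
  expect_lt(abs(mean(prevs) - 0.141), 0.005)
})

test_that("an unattainable prevalence fails after bounded bisection", {
  expect_error(outlierscreen:::calibrate_intercept(rep(0, 10), 1 - 1e-16),
               "unattainable")
  # and a reachable target converges to it
  lp <- rnorm(5000)
  b <- outlierscreen:::calibrate_intercept(lp, 0.141)
  expect_equal(mean(plogis(lp + b)), 0.141, tolerance = 1e-6)
})

test_that("switching off both missingness mechanisms yields a complete table", {
  gen <- generate_cohort(synthetic_spec(n_rows = 100L, seed = 3L,
                                        mar_missing_rate = 0,
                                        gated_pairs = list()))
  expect_identical(n_missing_cells(gen$table), 0L)
})

test_that("gated pairs produce structured missingness and MAR produces the rest", {
  gen <- generate_cohort(synthetic_spec(n_rows = 400L, seed = 4L,
                                        mar_missing_rate = 0.05))
  tab <- gen$table
  # cigarettes/day observed iff smoker (structured, not random)
  expect_true(all(is.na(tab$cigarettes_per_day[tab$smoking_history == "no"])))
  expect_true(all(!is.na(tab$cigarettes_per_day[tab$smoking_history == "yes"])))
  # MAR drivers stay fully observed
  expect_false(anyNA(tab$age))
  expect_false(anyNA(tab$weight_kg))
  # some MAR gaps exist
  expect_gt(n_missing_cells(tab), sum(tab$smoking_history == "no") +
              sum(tab$alcohol_use == "no"))
})

test_that("planted point outliers have extreme robust z on the shifted features", {
  gen <- point_benchmark_cohort(n_rows = 1000L, n_planted = 5L,
                                magnitude = 8, n_features = 3L, seed = 51L)
  tab <- gen$table
  cv <- gen$spec$continuous_vars
  rows <- match(gen$truth$point_ids, participant_ids(tab))
  extreme_per_row <- vapply(rows, function(r) {
    sum(vapply(cv$name, function(v) {
      z <- (tab[[v]][r] - median(tab[[v]])) / mad(tab[[v]])
      abs(z) >= 5
    }, TRUE))
  }, 0L)
  expect_true(all(extreme_per_row >= 3L))
})

test_that("magnitude-zero planting changes bookkeeping but not values", {
  gen <- point_benchmark_cohort(n_rows = 200L, n_planted = 0L, seed = 7L)
  planted <- plant_point_outliers(gen, 4L, magnitude = 0, seed = 2L)
  expect_identical(as.data.frame(planted$table), as.data.frame(gen$table))
  expect_length(planted$truth$point_ids, 4L)

  null_plant <- plant_point_outliers(gen, 0L)
  expect_length(null_plant$truth$point_ids, 0L)
  null_ctx <- plant_contextual_outliers(gen, 0L)
  expect_length(null_ctx$truth$contextual_ids, 0L)
})

test_that("planted contextual outliers are marginally typical", {
  gen <- contextual_benchmark_cohort(n_rows = 2000L, n_flipped = 20L,
                                     seed = 53L)
  tab <- gen$table
  cv <- gen$spec$continuous_vars
  rows <- match(gen$truth$contextual_ids, participant_ids(tab))
  frac_within_2sd <- vapply(rows, function(r) {
    mean(vapply(seq_len(nrow(cv)), function(f)
      abs((tab[[cv$name[f]]][r] - cv$mean[f]) / cv$sd[f]) <= 2, TRUE))
  }, 0)
  expect_true(all(frac_within_2sd >= 0.9))
})

test_that("point and contextual truth sets are disjoint", {
  spec <- synthetic_spec(n_rows = 500L, seed = 57L, mar_missing_rate = 0,
                         gated_pairs = list(), n_point_outliers = 10L,
                         n_contextual_outliers = 10L,
                         outcome_coefficients = strong_outcome_coefficients())
  gen <- generate_cohort(spec)
  expect_length(intersect(gen$truth$point_ids, gen$truth$contextual_ids), 0L)
})

test_that("the hidden-modifier mechanism never leaks the modifier into the table", {
  spec <- synthetic_spec(n_rows = 300L, seed = 59L, mar_missing_rate = 0,
                         gated_pairs = list(), n_contextual_outliers = 6L,
                         contextual_mechanism = "hidden_modifier",
                         outcome_coefficients = strong_outcome_coefficients())
  gen <- generate_cohort(spec)
  expect_length(gen$truth$contextual_ids, 6L)
  expect_false(is.null(gen$truth$hidden_modifier))
  expect_false(any(grepl("modifier", names(gen$table))))
})

test_that("planted flips are not enriched among isolation-forest z-scores", {
  # the |z| distribution of flipped rows should match the background
  ps <- vapply(1:3, function(s) {
    gen <- contextual_benchmark_cohort(n_rows = 1500L, n_flipped = 15L,
                                       seed = 600L + s)
    enc <- encode_features(gen$table)
    anom <- score_anomalies(enc$x,
                            isolation_config(n_estimators = 100L,
                                             max_samples = 256L,
                                             random_state = s),
                            ids = participant_ids(gen$table))
    planted <- anom$scores$participant_id %in% gen$truth$contextual_ids
    stats::wilcox.test(abs(anom$scores$z_score[planted]),
                       abs(anom$scores$z_score[!planted]))$p.value
  }, 0)
  expect_true(all(ps > 0.01))
})

test_that("requesting more flips than the eligible stratum is a hard error", {
  gen <- contextual_benchmark_cohort(n_rows = 200L, n_flipped = 0L, seed = 61L)
  expect_error(plant_contextual_outliers(gen, 150L), "eligible")
})
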