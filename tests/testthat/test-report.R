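report_fixture <- function(n = 60L, seed = 19L) {
  gen <- generate_cohort(synthetic_spec(n_rows = n, seed = seed,
                                        mar_missing_rate = 0,
                                        gated_pairs = list()))
  gen$table
}

test_that("small count cells are suppressed; zero and >= 7 are rendered", {
  tab <- report_fixture(100L)
  # choose an outlier subset of 19 so some binary levels land in [1,6]
  ids <- participant_ids(tab)[1:19]
  ct <- characterize_outliers(ids, tab)
  counts <- ct[ct$statistic == "n_percent", ]
  sub <- subset_cohort_for_test(tab, 1:19)
  for (i in seq_len(nrow(counts))) {
    v <- sub("( = .*)$", "", counts$variable[i])
    lvl <- if (grepl(" = ", counts$variable[i]))
      sub("^.* = ", "", counts$variable[i])
    else sort(unique(tab[[v]]))[2]
    n_sub <- sum(sub[[v]] == lvl)
    if (n_sub >= 1 && n_sub <= 6) {
      expect_identical(counts$outliers[i], "Suppressed")
    } else {
      expect_match(counts$outliers[i], sprintf("^%d \\(", n_sub))
    }
  }
  # the fixture must actually exercise all three regimes
  rendered_zero <- any(grepl("^0 \\(", counts$outliers))
  suppressed <- any(counts$outliers == "Suppressed")
  rendered_big <- any(grepl("^([7-9]|1[0-9]) \\(", counts$outliers))
  expect_true(rendered_zero && suppressed && rendered_big)
})

test_that("rendered comparison output never leaks a count between 1 and 6", {
  tab <- report_fixture(100L)
  ct <- characterize_outliers(participant_ids(tab)[1:15], tab)
  lines <- render_comparison(ct, 15L, nrow(tab))
  expect_length(audit_suppression(lines), 0L)
  # the audit itself catches a seeded leak
  expect_length(audit_suppression("history of X, n (%)  3 (15.8)"), 1L)
  expect_length(audit_suppression("age, mean (SD)  31.4 (5.3)"), 0L)
})

test_that("continuous, count-like, and binary variables get the right statistic", {
  tab <- report_fixture(80L)
  ct <- characterize_outliers(participant_ids(tab)[1:10], tab)
  expect_identical(ct$statistic[ct$variable == "age"], "mean_sd")
  expect_identical(ct$statistic[ct$variable == "gravidity"], "median_iqr")
  expect_identical(ct$statistic[ct$variable == "smoking_history"], "n_percent")
  expect_match(ct$outliers[ct$variable == "age"],
               "^-?[0-9.]+ \\([0-9.]+\\)$")
  expect_match(ct$cohort[ct$variable == "gravidity"],
               "^[0-9.]+ \\([0-9.]+ to [0-9.]+\\)$")
})

test_that("an empty outlier set or unknown id is rejected", {
  tab <- report_fixture(40L)
  expect_error(characterize_outliers(character(), tab), "empty")
  expect_error(characterize_outliers("nope", tab), "nope")
})

test_that("case narratives carry provenance, risk factors, and k highlights", {
  gen <- point_benchmark_cohort(n_rows = 300L, n_planted = 3L, seed = 23L)
  enc <- encode_features(gen$table)
  anom <- score_anomalies(enc$x,
                          isolation_config(n_estimators = 200L,
                                           max_samples = 128L,
                                           random_state = 2L),
                          ids = participant_ids(gen$table))
  flagged <- anom$scores$participant_id[anom$scores$is_outlier]
  expect_gt(length(flagged), 0L)
  cn <- build_case_narrative(flagged[1], gen$table, anomaly = anom, k = 4L)
  expect_identical(cn$assessment, "unreviewed")
  expect_named(cn$provenance, "isolation_forest")
  expect_identical(nrow(cn$highlights), 4L)
  txt <- render_case_narrative(cn)
  expect_true(any(grepl("Assessment: unreviewed", txt)))
  expect_true(any(grepl("Risk Factors:", txt)))
  expect_true(any(grepl("Interesting Variables:", txt)))
  # deterministic given identical inputs
  cn2 <- build_case_narrative(flagged[1], gen$table, anomaly = anom, k = 4L)
  expect_identical(cn, cn2)
})

test_that("an unflagged participant cannot get a narrative; dual flags merge", {
  fx <- make_forest_fixture(n = 200L, num_trees = 30L, seed = 29L,
                            label_noise = 0.15)
  anom <- score_anomalies(fx$enc$x,
                          isolation_config(n_estimators = 100L,
                                           max_samples = 128L,
                                           random_state = 1L),
                          ids = participant_ids(fx$table))
  mis <- flag_extreme_misclassification(fx$model, fx$table, fx$outcome,
                                        threshold = 0.90,
                                        level_maps = fx$enc$level_maps)
  unflagged <- setdiff(participant_ids(fx$table),
                       c(anom$scores$participant_id[anom$scores$is_outlier],
                         mis$flags$participant_id[mis$flags$is_outlier]))
  expect_error(build_case_narrative(unflagged[1], fx$table, anomaly = anom,
                                    misclass = mis),
               "not flagged")

  both <- intersect(anom$scores$participant_id[anom$scores$is_outlier],
                    mis$flags$participant_id[mis$flags$is_outlier])
  if (length(both)) {
    cn <- build_case_narrative(both[1], fx$table, anomaly = anom,
                               misclass = mis)
    expect_length(cn$provenance, 2L)
  }
})

test_that("run summaries format novelty rates as n (pct) over reviewed cases", {
  flagged <- sprintf("id%02d", 1:19)
  reviews <- stats::setNames(
    c(rep("potential_novelty", 3), rep("natural_deviation", 16)), flagged)
  s <- summarize_run(list(isolation_forest = flagged), reviews)
  expect_identical(s$total_flagged, 19L)
  expect_identical(s$potential_novelty, "3 (15.8)")
  expect_identical(s$natural_deviation, "16 (84.2)")

  flagged2 <- sprintf("rf%02d", 1:13)
  reviews2 <- stats::setNames(
    c(rep("potential_novelty", 10), rep("natural_deviation", 3)), flagged2)
  s2 <- summarize_run(list(extreme_misclassification = flagged2), reviews2)
  expect_identical(s2$potential_novelty, "10 (76.9)")
})

test_that("with nothing reviewed, percentages are undefined and all rows count as unreviewed", {
  s <- summarize_run(list(isolation_forest = sprintf("id%02d", 1:7)))
  expect_identical(s$unreviewed, 7L)
  expect_identical(s$potential_novelty, "0 (--)")
  expect_error(summarize_run(list()), "no detector")
})
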