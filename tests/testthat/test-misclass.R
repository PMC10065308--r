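test_that("splits have the exact requested sizes, are disjoint/exhaustive, and reproduce under a seed", {
  for (sizes in list(c(2301L, 1200L, 800L, 301L),
                     c(300L, 150L, 100L, 50L))) {
    n <- sizes[1]
    gen <- generate_cohort(synthetic_spec(n_rows = n, seed = 13L,
                                          mar_missing_rate = 0,
                                          gated_pairs = list()))
    sp <- split_dataset(gen$table, sizes[2], sizes[3], sizes[4],
                        gen$outcome, seed = 99L)
    expect_identical(vapply(sp, nrow, 0L),
                     c(train = sizes[2], test = sizes[3],
                       validation = sizes[4]))
    ids <- lapply(sp, participant_ids)
    expect_identical(sort(unname(unlist(ids))),
                     sort(participant_ids(gen$table)))
    expect_length(intersect(ids$train, ids$test), 0L)
    expect_length(intersect(ids$train, ids$validation), 0L)

    again <- split_dataset(gen$table, sizes[2], sizes[3], sizes[4],
                           gen$outcome, seed = 99L)
    expect_identical(lapply(again, participant_ids), ids)
  }
})

test_that("split sizes that do not sum to n are a hard error", {
  gen <- generate_cohort(synthetic_spec(n_rows = 100L, seed = 1L,
                                        mar_missing_rate = 0,
                                        gated_pairs = list()))
  expect_error(split_dataset(gen$table, 50L, 30L, 10L, gen$outcome),
               "50 \\+ 30 \\+ 10 != 100")
})

test_that("vote fractions equal an explicit per-tree prediction loop, exactly", {
  fx <- make_forest_fixture(n = 120L, num_trees = 15L, seed = 7L,
                            label_noise = 0.1)
  votes <- vote_confidence(fx$model, fx$enc$x)
  oracle <- brute_force_votes(fx$model, fx$enc$x)
  expect_identical(dim(votes), dim(oracle))
  expect_equal(votes[, colnames(oracle)], oracle, tolerance = 0)
  # fractions across classes sum to 1 on every row
  expect_equal(unname(rowSums(votes)), rep(1, nrow(votes)), tolerance = 0)
})

test_that("unanimous forests give vote fraction 1.0", {
  # perfectly separable outcome: one feature determines the label
  md <- variable_metadata(c("pid", "x", "status"),
                          kind = c("categorical", "continuous", "categorical"),
                          role = c("identifier", "feature", "outcome"))
  df <- data.frame(pid = as.character(1:80),
                   x = c(rnorm(40, 0), rnorm(40, 30)),
                   status = rep(c("no", "yes"), each = 40),
                   stringsAsFactors = FALSE)
  tab <- cohort_table(df, md)
  enc <- encode_features(tab)
  m <- fit_outcome_forest(enc$x, factor(tab$status),
                          list(num_trees = 10L, replace = FALSE), seed = 1L)
  v <- vote_confidence(m, enc$x)
  expect_true(all(apply(v, 1, max) == 1))
})

test_that("misclassification flags obey the strict >0.90 rule and the subset chain", {
  fx <- make_forest_fixture(n = 250L, num_trees = 50L, seed = 10L,
                            label_noise = 0.08)
  res <- flag_extreme_misclassification(fx$model, fx$table, fx$outcome,
                                        threshold = 0.90,
                                        level_maps = fx$enc$level_maps)
  fl <- res$flags
  mis <- fl$predicted_label != fl$true_label
  expect_identical(fl$is_outlier, mis & fl$vote_fraction > 0.90)
  # flagged set is a subset of the misclassified set
  expect_true(all(mis[fl$is_outlier]))
  # a correctly predicted row is never flagged, however confident
  expect_false(any(fl$is_outlier & !mis))
})

test_that("a wrong prediction at vote fraction exactly the threshold is not flagged", {
  fx <- make_forest_fixture(n = 250L, num_trees = 10L, seed = 10L,
                            label_noise = 0.2)
  # with 10 trees, fractions are multiples of 0.1; find rows mislabelled at
  # exactly 0.9 through the real scoring path
  res <- flag_extreme_misclassification(fx$model, fx$table, fx$outcome,
                                        threshold = 0.90,
                                        level_maps = fx$enc$level_maps)
  fl <- res$flags
  boundary <- fl$predicted_label != fl$true_label &
    abs(fl$vote_fraction - 0.90) < 1e-12
  expect_gt(sum(boundary), 0)              # the boundary case is exercised
  expect_false(any(fl$is_outlier[boundary]))
  above <- fl$predicted_label != fl$true_label & fl$vote_fraction > 0.90
  expect_identical(fl$is_outlier, above)
})

test_that("raising the threshold never adds a flag", {
  fx <- make_forest_fixture(n = 250L, num_trees = 50L, seed = 12L,
                            label_noise = 0.15)
  thresholds <- c(0.6, 0.7, 0.8, 0.9, 0.92, 0.98, 1)
  sets <- lapply(thresholds, function(th) {
    r <- flag_extreme_misclassification(fx$model, fx$table, fx$outcome,
                                        threshold = th,
                                        level_maps = fx$enc$level_maps)
    r$flags$participant_id[r$flags$is_outlier]
  })
  for (i in seq_len(length(sets) - 1L))
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  # threshold 1 can flag nothing (fraction cannot exceed 1)
  expect_length(sets[[length(sets)]], 0L)
})

test_that("thresholds outside (0.5, 1] are rejected", {
  fx <- make_forest_fixture(n = 60L, num_trees = 5L, seed = 3L)
  for (bad in c(0.5, 0.2, 1.2))
    expect_error(
      flag_extreme_misclassification(fx$model, fx$table, fx$outcome,
                                     threshold = bad,
                                     level_maps = fx$enc$level_maps),
      "threshold")
})

test_that("classification report matches hand arithmetic on constructed counts", {
  # TP = 3, FP = 1, FN = 2 for class 'yes' -> precision 0.75, recall 0.6
  flags <- data.frame(
    participant_id = as.character(1:10),
    true_label = c(rep("yes", 5), rep("no", 5)),
    predicted_label = c("yes", "yes", "yes", "no", "no",
                        "yes", "no", "no", "no", "no"),
    vote_fraction = rep(0.8, 10), is_outlier = FALSE,
    stringsAsFactors = FALSE)
  res <- structure(list(flags = flags, threshold = 0.9),
                   class = "misclassification_result")
  rep_ <- classification_report(res)
  yes <- rep_[rep_$class == "yes", ]
  expect_equal(yes$precision, 0.75)
  expect_equal(yes$recall, 0.6)
  no <- rep_[rep_$class == "no", ]
  expect_equal(no$precision, 4 / 6)
  expect_equal(no$recall, 0.8)
})

test_that("a perfect classifier reports precision and recall 1 for both classes", {
  flags <- data.frame(participant_id = as.character(1:6),
                      true_label = rep(c("yes", "no"), 3),
                      predicted_label = rep(c("yes", "no"), 3),
                      vote_fraction = 1, is_outlier = FALSE,
                      stringsAsFactors = FALSE)
  res <- structure(list(flags = flags, threshold = 0.9),
                   class = "misclassification_result")
  rep_ <- classification_report(res)
  expect_equal(rep_$precision, c(1, 1))
  expect_equal(rep_$recall, c(1, 1))
})

test_that("a class absent from the subset has undefined metrics, not zero", {
  flags <- data.frame(participant_id = as.character(1:6),
                      true_label = c("yes", "yes", "no", "no", "no", "no"),
                      predicted_label = c("yes", "no", "no", "no", "no", "no"),
                      vote_fraction = 1, is_outlier = FALSE,
                      stringsAsFactors = FALSE)
  res <- structure(list(flags = flags, threshold = 0.9),
                   class = "misclassification_result")
  rep_ <- classification_report(res, subset = 3:6) # only 'no' rows
  yes <- rep_[rep_$class == "yes", ]
  expect_true(is.na(yes$recall))
  expect_identical(yes$support, 0L)
  expect_error(classification_report(res, subset = rep(FALSE, 6)), "empty")
})

test_that("a degenerate single-class training outcome is a hard error", {
  md <- variable_metadata(c("pid", "x", "status"),
                          kind = c("categorical", "continuous", "categorical"),
                          role = c("identifier", "feature", "outcome"))
  df <- data.frame(pid = as.character(1:20), x = rnorm(20),
                   status = rep("no", 20), stringsAsFactors = FALSE)
  tab <- cohort_table(df, md)
  enc <- encode_features(tab)
  expect_error(fit_outcome_forest(enc$x, factor(tab$status),
                                  list(num_trees = 5L)),
               "one class")
})

test_that("a search space of size 1 returns that configuration from both phases", {
  fx <- make_forest_fixture(n = 200L, num_trees = 20L, seed = 5L)
  sp <- split_dataset(fx$table, 120L, 60L, 20L, fx$outcome, seed = 1L)
  enc_tr <- encode_features(sp$train, level_maps = fx$enc$level_maps)
  enc_te <- encode_features(sp$test, level_maps = fx$enc$level_maps)
  spec <- forest_search_spec(
    n_candidates = 5L,
    distributions = list(num_trees = 50L, max_depth = 5L, mtry = 3L,
                         min_node_size = 2L, min_bucket = 1L,
                         replace = FALSE),
    seed = 3L)
  got <- search_hyperparameters(enc_tr$x, factor(sp$train$preeclampsia),
                                enc_te$x, factor(sp$test$preeclampsia),
                                spec, positive = "yes")
  expect_identical(got$params$num_trees, 50L)
  expect_identical(got$params$max_depth, 5L)
  expect_identical(nrow(got$ledger[got$ledger$phase == "random", ]), 1L)
})

test_that("the search winner equals the argmax over the persisted ledger", {
  fx <- make_forest_fixture(n = 300L, num_trees = 20L, seed = 15L,
                            label_noise = 0.05)
  sp <- split_dataset(fx$table, 180L, 80L, 40L, fx$outcome, seed = 2L)
  enc_tr <- encode_features(sp$train, level_maps = fx$enc$level_maps)
  enc_te <- encode_features(sp$test, level_maps = fx$enc$level_maps)
  spec <- forest_search_spec(
    n_candidates = 6L,
    distributions = list(num_trees = c(50L, 100L, 200L),
                         max_depth = c(4L, 8L, 16L),
                         mtry = c(3L, 6L),
                         min_node_size = c(2L, 6L),
                         min_bucket = c(1L, 2L),
                         replace = FALSE),
    seed = 17L)
  got <- search_hyperparameters(enc_tr$x, factor(sp$train$preeclampsia),
                                enc_te$x, factor(sp$test$preeclampsia),
                                spec, positive = "yes")
  led <- got$ledger
  targeted <- led[led$phase == "targeted", ]
  best <- targeted[which.max(targeted$score), ]
  for (d in c("num_trees", "max_depth", "mtry", "min_node_size",
              "min_bucket", "replace"))
    expect_identical(got$params[[d]], best[[d]])
  # the targeted grid brackets the random-phase winner in every refined dim
  win1 <- led[led$phase == "random", ][which.max(led$score[led$phase == "random"]), ]
  for (d in c("num_trees", "max_depth", "mtry"))
    expect_true(win1[[d]] %in% targeted[[d]])
})
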