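# Fixtures are built in code; nothing is stored on disk.

# Minimal cohort: id, one continuous, one categorical, a gated continuous,
# and a binary outcome.
make_basic_cohort <- function() {
  md <- variable_metadata(
    name = c("pid", "age", "smoker", "cigs", "status"),
    kind = c("categorical", "continuous", "categorical", "continuous",
             "categorical"),
    role = c("identifier", "feature", "feature", "feature", "outcome"),
    gate_variable = c(NA, NA, NA, "smoker", NA),
    gate_value = c(NA, NA, NA, "no", NA),
    gate_fill = c(NA, NA, NA, "0", NA))
  df <- data.frame(
    pid = c("a", "b", "c", "d", "e", "f"),
    age = c(31.4, 28, 35, NA, 41, 29),
    smoker = c("no", "yes", "no", "yes", "no", "yes"),
    cigs = c(NA, 10, NA, NA, NA, 8),
    status = c("no", "yes", "no", "no", "yes", "no"),
    stringsAsFactors = FALSE)
  cohort_table(df, md)
}

# 12-variable crafted fixture exercising all five exclusion rules, n = 200.
# Expected drops: oc_derived (rule 1), mostly_missing + bmi (rule 2),
# age_group (rule 3; its source age survives), constant (rule 4),
# dominant (rule 5). Retained: pid, status, half_missing, age, bmi_group
# (its source bmi was dropped under rule 2), near_dominant.
make_filter_fixture <- function() {
  n <- 200L
  md <- variable_metadata(
    name = c("pid", "status", "oc_derived", "mostly_missing", "half_missing",
             "age", "age_group", "bmi", "bmi_group", "constant", "dominant",
             "near_dominant"),
    kind = c("categorical", "categorical", "categorical", "continuous",
             "continuous", "continuous", "categorical", "continuous",
             "categorical", "continuous", "categorical", "categorical"),
    role = c("identifier", "outcome", "outcome_derived", "feature", "feature",
             "feature", "recategorization_of:age", "feature",
             "recategorization_of:bmi", "feature", "feature", "feature"))
  mk_missing <- function(p) {
    v <- rep(1.5, n)
    v[seq_len(round(p * n))] <- NA
    v
  }
  df <- data.frame(
    pid = sprintf("p%03d", seq_len(n)),
    status = rep(c("yes", "no"), c(30, n - 30)),
    oc_derived = rep(c("early", "late", "none"), length.out = n),
    mostly_missing = mk_missing(0.60),
    half_missing = mk_missing(0.50),
    age = seq(20, 45, length.out = n),
    age_group = rep(c("lt30", "ge30"), length.out = n),
    bmi = mk_missing(0.60),
    bmi_group = rep(c("lean", "obese"), length.out = n),
    constant = rep(0, n),
    dominant = rep(c("x", "y"), c(n - 1L, 1L)),       # 199/200 = 0.995
    near_dominant = rep(c("x", "y"), c(n - 4L, 4L)),  # 196/200 = 0.98
    stringsAsFactors = FALSE)
  # keep variation inside the observed parts of partly missing columns so
  # only the intended rules fire
  df$mostly_missing[!is.na(df$mostly_missing)] <-
    seq_along(df$mostly_missing[!is.na(df$mostly_missing)])
  df$half_missing[!is.na(df$half_missing)] <-
    seq_along(df$half_missing[!is.na(df$half_missing)])
  df$bmi[!is.na(df$bmi)] <- seq_along(df$bmi[!is.na(df$bmi)])
  cohort_table(df, md)
}

subset_cohort_for_test <- function(tab, i = integer(0)) {
  outlierscreen:::subset_cohort(tab, i)
}

# Small complete cohort + fitted forest for vote/flag tests.
make_forest_fixture <- function(n = 300L, num_trees = 50L, seed = 42L,
                                label_noise = 0) {
  gen <- generate_cohort(synthetic_spec(
    n_rows = n, seed = seed, mar_missing_rate = 0, gated_pairs = list(),
    outcome_coefficients = strong_outcome_coefficients()))
  tab <- gen$table
  if (label_noise > 0) {
    flip <- withr::with_seed(seed + 1L,
                             sample.int(n, round(label_noise * n)))
    tab$preeclampsia[flip] <- ifelse(tab$preeclampsia[flip] == "yes",
                                     "no", "yes")
  }
  enc <- encode_features(tab)
  model <- fit_outcome_forest(enc$x, factor(tab$preeclampsia),
                              list(num_trees = num_trees, max_depth = 6L,
                                   min_bucket = 2L, replace = FALSE),
                              seed = seed)
  list(gen = gen, table = tab, enc = enc, model = model,
       outcome = gen$outcome)
}

# Independent per-tree prediction oracle: traverse every ranger tree by hand
# via treeInfo() and tally hard votes per class.
brute_force_votes <- function(model, x) {
  x <- as.data.frame(x)
  lev <- model$forest$levels
  votes <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
  for (t in seq_len(model$num.trees)) {
    ti <- ranger::treeInfo(model, t)
    for (i in seq_len(nrow(x))) {
      node <- 1L
      repeat {
        r <- ti[node, ]
        if (r$terminal) {
          votes[i, as.character(r$prediction)] <-
            votes[i, as.character(r$prediction)] + 1
          break
        }
        node <- if (x[i, r$splitvarName] <= r$splitval)
          r$leftChild + 1L else r$rightChild + 1L
      }
    }
  }
  votes / model$num.trees
}
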