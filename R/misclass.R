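# Contextual outliers via extreme misclassification: a random-forest outcome
# classifier is trained, and observations it mislabels while more than 90% of
# its trees agree on the (wrong) class are flagged. Confidence is the
# hard-vote fraction of the base trees, never an averaged leaf probability.

#' Split a cohort into train / test / validation sets
#'
#' Random, disjoint, exhaustive partition with exactly the requested sizes;
#' reproducible from the seed. The outcome prevalence of each split is
#' attached as the `"prevalence"` attribute.
#'
#' @param table A [cohort_table()].
#' @param train_n,test_n,validation_n Split sizes; must sum to `nrow(table)`.
#' @param outcome An [outcome_spec()] (used only to log prevalence).
#' @param seed Integer seed.
#' @return A list of three `cohort_table`s: `train`, `test`, `validation`.
#' @export
split_dataset <- function(table, train_n, test_n, validation_n, outcome,
                          seed = 2022L) {
  n <- nrow(table)
  if (train_n + test_n + validation_n != n)
    stop(sprintf("split sizes %d + %d + %d != %d rows",
                 train_n, test_n, validation_n, n))
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(train_n)],
              test = perm[train_n + seq_len(test_n)],
              validation = perm[train_n + test_n + seq_len(validation_n)])
  out <- lapply(idx, function(i) subset_cohort(table, sort(i)))
  attr(out, "prevalence") <- vapply(out, function(s)
    mean(s[[outcome$column]] == outcome$positive_label), 0)
  out
}

#' Forest hyperparameter search specification
#'
#' Phase 1 samples `n_candidates` configurations at random from the
#' per-dimension candidate lists and scores each on the held-out test set;
#' phase 2 exhaustively scores a small grid bracketing the phase-1 winner
#' (neighboring candidate values in the `targeted_dims` dimensions, the
#' winner's value elsewhere). The searched dimensions are the ensemble size,
#' tree depth, features per split, node-splitting and leaf-size minima, and
#' bootstrap resampling.
#'
#' @param n_candidates Number of random-phase configurations.
#' @param distributions Named list of candidate values per dimension:
#'   `num_trees`, `max_depth`, `mtry`, `min_node_size`, `min_bucket`,
#'   `replace`.
#' @param targeted_dims Dimensions refined in phase 2.
#' @param metric Scoring metric: `"f1"` (positive class, default) or
#'   `"accuracy"`.
#' @param seed Integer seed.
#' @return A `forest_search_spec` list.
#' @export
forest_search_spec <- function(n_candidates = 20L,
                               distributions = list(
                                 num_trees = c(100L, 200L, 400L, 600L, 800L, 1000L),
                                 max_depth = c(5L, 10L, 20L, 40L, 90L),
                                 mtry = NULL, # filled from ncol at search time
                                 min_node_size = c(2L, 6L, 10L),
                                 min_bucket = c(1L, 2L, 4L),
                                 replace = c(FALSE, TRUE)),
                               targeted_dims = c("num_trees", "max_depth", "mtry"),
                               metric = c("f1", "accuracy"),
                               seed = 2022L) {
  structure(list(n_candidates = as.integer(n_candidates),
                 distributions = distributions,
                 targeted_dims = targeted_dims,
                 metric = match.arg(metric),
                 seed = as.integer(seed)),
            class = "forest_search_spec")
}

#' Fit the outcome random forest
#'
#' @param x Numeric feature matrix (from [encode_features()]).
#' @param y Factor outcome.
#' @param params Named list: `num_trees`, `max_depth`, `mtry`,
#'   `min_node_size`, `min_bucket`, `replace`.
#' @param seed Integer seed.
#' @return A fitted `ranger` classification forest.
#' @export
fit_outcome_forest <- function(x, y, params, seed = 2022L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("degenerate training outcome: only one class present")
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = params$num_trees %||% 500L,
    mtry = min(params$mtry %||% floor(sqrt(ncol(x))), ncol(x)),
    max.depth = params$max_depth %||% 0L,
    min.node.size = params$min_node_size %||% 1L,
    min.bucket = params$min_bucket %||% 1L,
    replace = isTRUE(params$replace),
    sample.fraction = 1,
    seed = seed, num.threads = 1L
  )
}

score_forest <- function(model, x, y, positive, metric) {
  pred <- stats::predict(model, data = as.data.frame(x),
                         num.threads = 1L)$predictions
  if (metric == "accuracy") return(mean(pred == y))
  tp <- sum(pred == positive & y == positive)
  fp <- sum(pred == positive & y != positive)
  fn <- sum(pred != positive & y == positive)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Two-phase random-then-targeted hyperparameter search
#'
#' @param train_x,train_y Training features and factor outcome.
#' @param test_x,test_y Held-out features and outcome the candidates are
#'   scored on.
#' @param spec A [forest_search_spec()].
#' @param positive Positive-class label for F1 scoring.
#' @return A list with `params` (the winning configuration) and `ledger`
#'   (data frame of every configuration scored in both phases).
#' @export
search_hyperparameters <- function(train_x, train_y, test_x, test_y,
                                   spec = forest_search_spec(),
                                   positive = levels(as.factor(train_y))[2]) {
  dists <- spec$distributions
  if (is.null(dists$mtry)) {
    p <- ncol(train_x)
    dists$mtry <- sort(unique(pmax(1L, pmin(p, c(floor(sqrt(p)), floor(p / 3),
                                                 floor(p / 2), p)))))
  }
  dims <- names(dists)
  draw_one <- function() lapply(dists, function(v) v[[sample.int(length(v), 1L)]])
  space_size <- prod(vapply(dists, length, 0L))

  cands <- with_seed(spec$seed, {
    if (space_size <= spec$n_candidates) {
      grid <- expand.grid(dists, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
    } else {
      seen <- character()
      out <- list()
      while (length(out) < spec$n_candidates) {
        cand <- draw_one()
        key <- paste(unlist(cand), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- cand
      }
      out
    }
  })

  eval_cand <- function(cand, phase) {
    m <- fit_outcome_forest(train_x, train_y, cand,
                            seed = derive_seed(spec$seed, "search-fit"))
    sc <- score_forest(m, test_x, test_y, positive, spec$metric)
    cbind(data.frame(phase = phase, stringsAsFactors = FALSE),
          as.data.frame(cand), data.frame(score = sc))
  }

  ledger <- do.call(rbind, lapply(cands, eval_cand, phase = "random"))
  win1 <- as.list(ledger[which.max(ledger$score),
                         dims, drop = FALSE])

  # targeted grid: neighbors of the winner in the refined dims, winner elsewhere
  neighbors <- function(dim) {
    v <- sort(unique(dists[[dim]]))
    i <- match(win1[[dim]], v)
    unique(v[pmax(1L, pmin(length(v), c(i - 1L, i, i + 1L)))])
  }
  grid_dims <- lapply(stats::setNames(dims, dims), function(d)
    if (d %in% spec$targeted_dims) neighbors(d) else win1[[d]])
  grid <- expand.grid(grid_dims, stringsAsFactors = FALSE)
  ledger2 <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    eval_cand(as.list(grid[i, , drop = FALSE]), phase = "targeted")))

  ledger <- rbind(ledger, ledger2)
  targeted <- ledger[ledger$phase == "targeted", , drop = FALSE]
  winner <- as.list(targeted[which.max(targeted$score), dims, drop = FALSE])
  list(params = winner, ledger = ledger)
}

#' Per-class tree-vote fractions
#'
#' For each observation, the fraction of the forest's base trees whose
#' individual hard prediction is each class. This is the confidence
#' definition used for flagging; fractions across classes sum to 1.
#'
#' @param model A fitted `ranger` classification forest.
#' @param x Feature matrix or data frame to score.
#' @return Numeric matrix, one column per class (named by class label).
#' @export
vote_confidence <- function(model, x) {
  pr <- stats::predict(model, data = as.data.frame(x), predict.all = TRUE,
                       num.threads = 1L)$predictions
  lev <- model$forest$levels
  out <- vapply(seq_along(lev), function(k) rowMeans(pr == k),
                numeric(nrow(pr)))
  out <- matrix(out, nrow = nrow(pr), dimnames = list(NULL, lev))
  out
}

#' Flag contextual outliers by extreme misclassification
#'
#' Applies the fitted forest over the supplied table (by default the entire
#' dataset: train, test and validation together) and flags an observation iff
#' its predicted class differs from its recorded class AND the vote fraction
#' of the predicted class strictly exceeds `threshold`. A tie at 0.5 votes is
#' resolved to the lexicographically smaller class label; ties can never
#' exceed the threshold, so flagging is unaffected.
#'
#' @param model A fitted `ranger` classification forest.
#' @param table A complete [cohort_table()].
#' @param outcome An [outcome_spec()].
#' @param threshold Strict vote-fraction cutoff, in (0.5, 1]; default 0.90.
#' @param level_maps Level maps from [encode_features()] at training time.
#' @return A `misclassification_result`: list with `flags` (data frame with
#'   `participant_id`, `true_label`, `predicted_label`, `vote_fraction`,
#'   `is_outlier`) and the threshold used.
#' @export
flag_extreme_misclassification <- function(model, table, outcome,
                                           threshold = 0.90,
                                           level_maps = NULL) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1], got ", threshold)
  enc <- encode_features(table, level_maps = level_maps)
  votes <- vote_confidence(model, enc$x)
  votes <- votes[, order(colnames(votes)), drop = FALSE]
  pred_i <- max.col(votes, ties.method = "first") # cols sorted => lexicographic tie-break
  predicted <- colnames(votes)[pred_i]
  vf <- votes[cbind(seq_len(nrow(votes)), pred_i)]
  truth <- as.character(table[[outcome$column]])
  flag <- predicted != truth & vf > threshold
  flags <- data.frame(
    participant_id = participant_ids(table),
    true_label = truth, predicted_label = predicted,
    vote_fraction = vf, is_outlier = flag,
    stringsAsFactors = FALSE
  )
  structure(list(flags = flags, threshold = threshold,
                 positive_label = outcome$positive_label),
            class = "misclassification_result")
}

#' @export
print.misclassification_result <- function(x, ...) {
  cat(sprintf("<misclassification_result> %d observations, %d flagged (vote fraction > %g)\n",
              nrow(x$flags), sum(x$flags$is_outlier), x$threshold))
  invisible(x)
}

#' Per-class precision and recall
#'
#' Classification-report metrics over any subset of a
#' [flag_extreme_misclassification()] result. A class absent from the subset
#' has undefined (`NA`) metrics, never zero.
#'
#' @param result A `misclassification_result`.
#' @param subset Optional logical/integer row selector or character vector of
#'   participant ids; default all rows.
#' @return Data frame with `class`, `precision`, `recall`, `support`.
#' @export
classification_report <- function(result, subset = NULL) {
  fl <- result$flags
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- fl$participant_id %in% subset
    fl <- fl[subset, , drop = FALSE]
  }
  if (!nrow(fl)) stop("classification_report: empty subset")
  classes <- sort(unique(c(result$flags$true_label, result$flags$predicted_label)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(fl$predicted_label == cl & fl$true_label == cl)
    fp <- sum(fl$predicted_label == cl & fl$true_label != cl)
    fn <- sum(fl$predicted_label != cl & fl$true_label == cl)
    support <- sum(fl$true_label == cl)
    data.frame(class = cl,
               precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
               recall = if (support == 0) NA_real_ else tp / (tp + fn),
               support = support, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
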