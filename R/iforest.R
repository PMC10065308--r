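# Isolation forest: random binary partition trees on subsamples; an
# observation's anomaly score is derived from its ensemble-averaged path
# length, normalized by the expected path length c(psi) of an unsuccessful
# BST search. Short paths (easy isolation) => score near 1 => anomalous.

harmonic <- function(n) log(n) + 0.5772156649015329

# Expected path length of an unsuccessful search in a BST of n points.
c_factor <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * harmonic(n - 1) - 2 * (n - 1) / n
}

# Grow one isolation tree on rows `idx` of x, to height limit `hlim`.
grow_itree <- function(x, idx, depth, hlim) {
  n <- length(idx)
  if (n <= 1L || depth >= hlim)
    return(list(leaf = TRUE, size = n))
  rngs <- apply(x[idx, , drop = FALSE], 2, range)
  splittable <- which(rngs[2, ] > rngs[1, ])
  if (!length(splittable)) return(list(leaf = TRUE, size = n))
  q <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
  sv <- stats::runif(1, rngs[1, q], rngs[2, q])
  left <- idx[x[idx, q] < sv]
  right <- idx[x[idx, q] >= sv]
  list(leaf = FALSE, var = q, val = sv,
       left = grow_itree(x, left, depth + 1L, hlim),
       right = grow_itree(x, right, depth + 1L, hlim))
}

# Path lengths of all rows of x through one tree (vectorized recursion).
itree_paths <- function(node, x, idx, depth, out) {
  if (node$leaf) {
    out[idx] <- depth + c_factor(node$size)
    return(out)
  }
  go_left <- x[idx, node$var] < node$val
  if (any(go_left)) out <- itree_paths(node$left, x, idx[go_left], depth + 1L, out)
  if (any(!go_left)) out <- itree_paths(node$right, x, idx[!go_left], depth + 1L, out)
  out
}

#' Fit an isolation forest
#'
#' @param x Numeric feature matrix (rows = observations). Columns are
#'   canonicalized to name order internally so results do not depend on the
#'   column order of the input.
#' @param n_estimators Number of trees.
#' @param max_samples Subsample size per tree (capped at `nrow(x)`).
#' @param seed Random state.
#' @return An `isolation_forest` model object.
#' @export
isolation_forest <- function(x, n_estimators = 100L, max_samples = 256L,
                             seed = 2022L) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) x <- x[, order(colnames(x)), drop = FALSE]
  n <- nrow(x)
  psi <- min(as.integer(max_samples), n)
  hlim <- ceiling(log2(max(psi, 2)))
  trees <- with_seed(seed, lapply(seq_len(n_estimators), function(t) {
    sub <- if (psi < n) sample.int(n, psi) else seq_len(n)
    grow_itree(x, sub, 0L, hlim)
  }))
  structure(list(trees = trees, psi = psi, cn = c_factor(psi),
                 n_estimators = as.integer(n_estimators),
                 max_samples = psi, seed = as.integer(seed),
                 colnames = colnames(x)),
            class = "isolation_forest")
}

#' Anomaly scores from a fitted isolation forest
#'
#' Returns `2^(-E[h(x)] / c(psi))`, the normalized ensemble-average path
#' length, oriented so that larger scores are more anomalous.
#'
#' @param model An [isolation_forest()].
#' @param x Numeric matrix to score (same columns as at fit time).
#' @return Numeric vector of anomaly scores in (0, 1].
#' @export
anomaly_scores <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$colnames)) x <- x[, model$colnames, drop = FALSE]
  n <- nrow(x)
  total <- numeric(n)
  for (tr in model$trees)
    total <- total + itree_paths(tr, x, seq_len(n), 0L, numeric(n))
  avg_path <- total / length(model$trees)
  2^(-avg_path / model$cn)
}

#' Isolation-forest stage configuration
#'
#' Defaults follow the published analysis: contamination 0.05 (the assumption
#' that at most 5% of the sample could be outliers — recorded in the result,
#' never used to flag), random state 2022, and tuning grids that start at 100
#' trees / 256 subsamples.
#'
#' @param n_estimators,max_samples Explicit hyperparameters; `NULL` means
#'   "tune with [tune_isolation()]".
#' @param contamination Assumed upper bound on the outlier fraction, in
#'   (0, 0.5].
#' @param random_state Seed for fitting the final forest.
#' @param grid_n_estimators,grid_max_samples Strictly increasing candidate
#'   grids for tuning.
#' @param tuning_replicates Forests fitted per candidate (distinct derived
#'   seeds).
#' @param tuning_tolerance Relative-change threshold under which the score
#'   mean and SD are considered stabilized.
#' @param z_threshold Two-sided inclusive z cutoff for flagging (default 3).
#' @return An `isolation_config` list.
#' @export
isolation_config <- function(n_estimators = NULL, max_samples = NULL,
                             contamination = 0.05, random_state = 2022L,
                             grid_n_estimators = seq(100L, 1000L, by = 100L),
                             grid_max_samples = c(256L, 512L, 700L, 1024L),
                             tuning_replicates = 3L,
                             tuning_tolerance = 0.01,
                             z_threshold = 3) {
  stopifnot(contamination > 0, contamination <= 0.5,
            all(diff(grid_n_estimators) > 0), all(diff(grid_max_samples) > 0))
  structure(list(n_estimators = n_estimators, max_samples = max_samples,
                 contamination = contamination,
                 random_state = as.integer(random_state),
                 grid_n_estimators = as.integer(grid_n_estimators),
                 grid_max_samples = as.integer(grid_max_samples),
                 tuning_replicates = as.integer(tuning_replicates),
                 tuning_tolerance = tuning_tolerance,
                 z_threshold = z_threshold),
            class = "isolation_config")
}

# Mean/SD of anomaly scores for one candidate, averaged over replicates.
tuning_stats <- function(x, n_estimators, max_samples, seed, replicates) {
  ms <- vapply(seq_len(replicates), function(r) {
    m <- isolation_forest(x, n_estimators, max_samples,
                          seed = derive_seed(seed, paste0("rep", r)))
    s <- anomaly_scores(m, x)
    c(mean(s), stats::sd(s))
  }, numeric(2))
  c(mean = mean(ms[1, ]), sd = mean(ms[2, ]))
}

# First grid value whose mean AND sd change relatively less than tol vs the
# next value; falls back to the largest value (with warning) if none does.
first_stable <- function(grid, means, sds, tol) {
  if (length(grid) == 1L) {
    warning("tuning grid of size 1; returning it as-is")
    return(grid[1])
  }
  for (i in seq_len(length(grid) - 1L)) {
    dm <- abs(means[i + 1] - means[i]) / max(abs(means[i]), .Machine$double.eps)
    ds <- abs(sds[i + 1] - sds[i]) / max(abs(sds[i]), .Machine$double.eps)
    if (dm < tol && ds < tol) return(grid[i])
  }
  warning("no grid value stabilized within tolerance; using the largest")
  grid[length(grid)]
}

#' Stabilization-based isolation-forest tuning
#'
#' For each candidate value, fits `tuning_replicates` forests under distinct
#' derived seeds and records the mean and standard deviation of the anomaly
#' scores; the chosen value is the first at which both statistics show the
#' least variation beyond it (successive relative change below
#' `tuning_tolerance`). `n_estimators` is scanned first (at the 256-subsample
#' grid origin), then `max_samples` at the chosen tree count.
#'
#' @param x Numeric feature matrix.
#' @param config An [isolation_config()].
#' @return A list with `n_estimators`, `max_samples`, and `ledger` — a data
#'   frame of the per-candidate statistics the decision was made from.
#' @export
tune_isolation <- function(x, config = isolation_config()) {
  stopifnot(config$tuning_replicates >= 2L || length(config$grid_n_estimators) == 1L)
  grid_ms <- pmin(config$grid_max_samples, nrow(x))
  grid_ms <- unique(grid_ms)
  base_ms <- grid_ms[1]

  st_ne <- vapply(config$grid_n_estimators, function(ne)
    tuning_stats(x, ne, base_ms, derive_seed(config$random_state, paste0("ne", ne)),
                 config$tuning_replicates), numeric(2))
  ne <- first_stable(config$grid_n_estimators, st_ne[1, ], st_ne[2, ],
                     config$tuning_tolerance)

  st_ms <- vapply(grid_ms, function(ms)
    tuning_stats(x, ne, ms, derive_seed(config$random_state, paste0("ms", ms)),
                 config$tuning_replicates), numeric(2))
  ms <- first_stable(grid_ms, st_ms[1, ], st_ms[2, ], config$tuning_tolerance)

  ledger <- rbind(
    data.frame(parameter = "n_estimators", candidate = config$grid_n_estimators,
               score_mean = st_ne[1, ], score_sd = st_ne[2, ]),
    data.frame(parameter = "max_samples", candidate = grid_ms,
               score_mean = st_ms[1, ], score_sd = st_ms[2, ])
  )
  list(n_estimators = ne, max_samples = ms, ledger = ledger)
}

#' Score a cohort and flag point outliers by the z rule
#'
#' Fits an isolation forest (tuning first if hyperparameters are not set in
#' the config), standardizes the anomaly scores against their own mean and
#' SD, and flags observations with `z <= -3` or `z >= 3` (inclusive). The
#' contamination value is recorded but plays no part in flagging.
#'
#' @param x Numeric feature matrix from [encode_features()].
#' @param config An [isolation_config()].
#' @param ids Optional participant identifiers (row order).
#' @return An `anomaly_result`: a list with `scores` (data frame with
#'   `participant_id`, `anomaly_score`, `z_score`, `is_outlier`),
#'   `score_mean`, `score_sd`, the hyperparameters used, and the tuning
#'   ledger when tuning ran.
#' @export
score_anomalies <- function(x, config = isolation_config(), ids = NULL) {
  x <- as.matrix(x)
  tuned <- NULL
  ne <- config$n_estimators
  ms <- config$max_samples
  if (is.null(ne) || is.null(ms)) {
    tuned <- tune_isolation(x, config)
    ne <- ne %||% tuned$n_estimators
    ms <- ms %||% tuned$max_samples
  }
  model <- isolation_forest(x, ne, ms, seed = config$random_state)
  s <- anomaly_scores(model, x)
  mu <- mean(s)
  sdv <- stats::sd(s)
  if (is.na(sdv) || sdv == 0) {
    warning("anomaly-score SD is zero; no outliers can be flagged")
    z <- rep(0, length(s))
    flag <- rep(FALSE, length(s))
  } else {
    z <- (s - mu) / sdv
    flag <- z <= -config$z_threshold | z >= config$z_threshold
  }
  scores <- data.frame(
    participant_id = ids %||% as.character(seq_len(nrow(x))),
    anomaly_score = s, z_score = z, is_outlier = flag,
    stringsAsFactors = FALSE
  )
  structure(list(scores = scores, score_mean = mu,
                 score_sd = if (is.na(sdv)) 0 else sdv,
                 n_estimators = ne, max_samples = min(ms, nrow(x)),
                 contamination = config$contamination,
                 random_state = config$random_state,
                 z_threshold = config$z_threshold,
                 tuning = tuned$ledger),
            class = "anomaly_result")
}

#' @export
print.anomaly_result <- function(x, ...) {
  cat(sprintf(paste0("<anomaly_result> %d observations, %d flagged ",
                     "(|z| >= %g)\nn_estimators = %d, max_samples = %d, ",
                     "score mean %.4f sd %.4f\n"),
              nrow(x$scores), sum(x$scores$is_outlier), x$z_threshold,
              x$n_estimators, x$max_samples, x$score_mean, x$score_sd))
  invisible(x)
}
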