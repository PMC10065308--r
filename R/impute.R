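#' Fill structured "not applicable" missingness
#'
#' Missing cells that arise because an upstream exclusionary question gated
#' the variable off (e.g. cigarettes/day was never asked of non-smokers) are
#' not missing at random and must not be imputed. For every variable with a
#' gate rule, cells that are missing while `gate_variable == gate_value` are
#' replaced by the rule's fill: a numeric sentinel for continuous variables
#' (e.g. zero cigarettes) or a new category token for categorical ones. All
#' other missing cells are left untouched for the iterative imputer.
#'
#' @param table A [cohort_table()] (typically after [filter_variables()]).
#' @return The table with gated cells filled.
#' @export
apply_gate_fills <- function(table) {
  md <- cohort_metadata(table)
  for (i in which(!is.na(md$gate_variable))) {
    target <- md$name[i]
    gv <- md$gate_variable[i]
    if (!gv %in% md$name)
      stop("gate rule for '", target, "' references dropped variable '", gv, "'")
    gate_col <- table[[gv]]
    gated <- !is.na(gate_col) & as.character(gate_col) == md$gate_value[i] &
      is.na(table[[target]])
    if (!any(gated)) next
    if (md$kind[i] == "continuous") {
      fill <- suppressWarnings(as.numeric(md$gate_fill[i]))
      if (is.na(fill))
        stop("gate fill for continuous '", target, "' is not numeric: ",
             md$gate_fill[i])
      table[[target]][gated] <- fill
    } else {
      fill <- md$gate_fill[i]
      if (fill %in% unique(table[[target]][!gated]))
        stop("gate fill token '", fill, "' is an existing category of '",
             target, "'")
      table[[target]][gated] <- fill
    }
  }
  table
}

#' Imputation configuration
#'
#' @param n_iterations Number of round-robin rounds (default 10); the returned
#'   values are those of the final round.
#' @param seed Integer seed (the default regressors are deterministic, but the
#'   seed is threaded through for forward compatibility and manifests).
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(n_iterations = 10L, seed = 1L) {
  stopifnot(n_iterations >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Iterative round-robin regression imputation
#'
#' Treats each incomplete variable in turn as the dependent variable and all
#' other variables as predictors, fitting a linear regression for continuous
#' targets and a multinomial logistic regression for categorical targets on
#' the rows where the target was observed, then predicting its missing cells.
#' Missing cells are pre-filled with the column mean (continuous) or mode
#' (categorical) before round 1; variables are visited in order of increasing
#' missingness within each round; the whole sweep is repeated
#' `config$n_iterations` times (default 10) and the final round's values are
#' returned. Observed cells are never altered.
#'
#' @param table A [cohort_table()] with gate fills already applied.
#' @param config An [imputation_config()].
#' @return A complete [cohort_table()] (zero missing cells).
#' @export
impute_iterative <- function(table, config = imputation_config()) {
  md <- cohort_metadata(table)
  id <- identifier_name(md)
  vars <- setdiff(md$name, id)
  if (length(vars) < 2L) stop("need at least 2 variables to impute")
  miss <- vapply(vars, function(v) sum(is.na(table[[v]])), 0L)
  if (all(miss == 0L)) return(table)
  all_missing <- vars[vapply(vars, function(v) all(is.na(table[[v]])), TRUE)]
  if (length(all_missing))
    stop("variable(s) with zero observed values, nothing to regress on: ",
         paste(all_missing, collapse = ", "))

  kind <- stats::setNames(md$kind, md$name)
  obs_mask <- lapply(stats::setNames(vars, vars), function(v) !is.na(table[[v]]))
  # frozen level sets so factors are stable across rounds
  levels_of <- lapply(stats::setNames(vars, vars), function(v)
    if (kind[[v]] == "categorical") sort(unique(table[[v]][obs_mask[[v]]])))

  cur <- as.data.frame(table)[vars]
  for (v in vars) { # initial fill: mean / mode
    na <- !obs_mask[[v]]
    if (!any(na)) next
    cur[[v]][na] <- if (kind[[v]] == "continuous")
      mean(cur[[v]][obs_mask[[v]]]) else stat_mode(cur[[v]][obs_mask[[v]]])
  }

  incomplete <- vars[miss[vars] > 0L]
  incomplete <- incomplete[order(miss[incomplete], incomplete)]

  predictor_frame <- function(preds) {
    df <- cur[preds]
    for (p in preds)
      if (kind[[p]] == "categorical")
        df[[p]] <- factor(df[[p]], levels = unique(c(levels_of[[p]], unique(df[[p]]))))
    # constant predictors carry no information and break the fitters
    keep <- vapply(df, function(col) length(unique(col)) > 1L, TRUE)
    df[keep]
  }

  with_seed(config$seed, {
    for (round in seq_len(config$n_iterations)) {
      for (v in incomplete) {
        na <- !obs_mask[[v]]
        preds <- setdiff(vars, v)
        df <- predictor_frame(preds)
        if (!ncol(df)) next # nothing informative; keep current fill
        df[["..target"]] <- if (kind[[v]] == "continuous") cur[[v]]
          else factor(cur[[v]], levels = unique(c(levels_of[[v]], unique(cur[[v]]))))
        train <- df[obs_mask[[v]], , drop = FALSE]
        if (kind[[v]] == "continuous") {
          fit <- stats::lm(..target ~ ., data = train)
          pred <- suppressWarnings(
            stats::predict(fit, newdata = df[na, , drop = FALSE]))
          pred[!is.finite(pred)] <- mean(train[["..target"]])
          cur[[v]][na] <- as.numeric(pred)
        } else {
          if (length(unique(as.character(train[["..target"]]))) < 2L) {
            cur[[v]][na] <- as.character(train[["..target"]][1])
          } else {
            fit <- nnet::multinom(..target ~ ., data = train, trace = FALSE,
                                  maxit = 200, MaxNWts = 5000)
            pred <- stats::predict(fit, newdata = df[na, , drop = FALSE],
                                   type = "class")
            cur[[v]][na] <- as.character(pred)
          }
        }
      }
    }
  })

  out <- as.data.frame(table)
  for (v in vars) out[[v]] <- cur[[v]]
  structure(out, metadata = md, class = c("cohort_table", "data.frame"))
}
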