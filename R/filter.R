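#' Apply the five variable-exclusion rules
#'
#' Screens every variable against five exclusion criteria, applied in fixed
#' order with the first matching rule recorded per variable:
#'
#' 1. the variable is a variation or sub-categorization of the outcome
#'    (role `outcome_derived`);
#' 2. more than 50% of its cells are missing (strictly greater — a variable
#'    at exactly 50% is retained);
#' 3. it re-categorizes an existing variable that is itself retained
#'    (role `recategorization_of:<source>`);
#' 4. it has exactly one unique non-missing value (e.g. death when no deaths
#'    occurred);
#' 5. a single value accounts for >= 99% of all observations (missing cells
#'    count in the denominator, not as a level).
#'
#' The outcome and identifier variables are never dropped. Rules are evaluated
#' as ordered passes, so a recategorization is dropped under rule 3 only when
#' its source variable survived rules 1-2; sources later removed by rules 4-5
#' do not resurrect their recategorizations.
#'
#' @param table A [cohort_table()].
#' @param max_missing Missing-fraction threshold for rule 2 (default 0.5).
#' @param dominance Modal-fraction threshold for rule 5 (default 0.99).
#' @return A list with `table` (the filtered [cohort_table()]) and `log`, an
#'   exclusion-log data frame with columns `variable`, `rule` (1-5) and
#'   `diagnostic` (missing fraction for rule 2, modal fraction for rules 4-5,
#'   `NA` for the role-based rules).
#' @export
filter_variables <- function(table, max_missing = 0.5, dominance = 0.99) {
  md <- cohort_metadata(table)
  n <- nrow(table)
  protected <- c(outcome_name(md), identifier_name(md))
  log <- data.frame(variable = character(), rule = integer(),
                    diagnostic = numeric(), stringsAsFactors = FALSE)
  dropped <- character()
  mark <- function(var, rule, diag = NA_real_) {
    log[nrow(log) + 1L, ] <<- list(var, as.integer(rule), diag)
    dropped <<- c(dropped, var)
  }
  candidates <- function() setdiff(md$name, c(protected, dropped))

  # rule 1: outcome-derived
  for (v in sort(md$name[md$role == "outcome_derived"]))
    if (!v %in% protected) mark(v, 1L)
  # rule 2: missing fraction strictly > threshold
  for (v in candidates()) {
    frac <- if (n > 0) sum(is.na(table[[v]])) / n else 0
    if (frac > max_missing) mark(v, 2L, frac)
  }
  # rule 3: recategorization whose source is still retained
  src <- stats::setNames(recat_source(md), md$name)
  for (v in candidates()) {
    s <- src[[v]]
    if (!is.na(s) && !s %in% dropped) mark(v, 3L)
  }
  # rule 4: single unique non-missing value
  for (v in candidates()) {
    u <- unique(table[[v]][!is.na(table[[v]])])
    if (length(u) == 1L) mark(v, 4L, 1)
  }
  # rule 5: modal value dominance over all observations
  for (v in candidates()) {
    x <- table[[v]]
    obs <- x[!is.na(x)]
    if (!length(obs) || n == 0) next
    frac <- max(table(obs)) / n
    if (frac >= dominance) mark(v, 5L, frac)
  }

  out <- drop_variables(table, dropped)
  if (ncol(out) <= length(protected))
    message("filter_variables: no feature variables remain after exclusion")
  list(table = out, log = log)
}

#' Write an exclusion log to CSV
#'
#' @param log The `log` element returned by [filter_variables()].
#' @param path Output path.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
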