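# Reviewer-facing outputs: outlier-vs-cohort characterization tables with
# small-cell suppression, structured case narratives, and run summaries.
# Suppression rule: any rendered count cell covering 1-6 participants is
# replaced by "Suppressed" (its percentage too, since the count would be
# recoverable from it); 0 and >= 7 are rendered.

SUPPRESS_MIN <- 1L
SUPPRESS_MAX <- 6L

suppress_count <- function(n, pct) {
  if (n >= SUPPRESS_MIN && n <= SUPPRESS_MAX) "Suppressed"
  else sprintf("%d (%s)", n, fmt_num(pct))
}

#' Characterize outliers against the full cohort
#'
#' Builds a comparison table in the style of a baseline-characteristics
#' table: continuous variables as mean (SD), count-like variables as median
#' (IQR), categorical variables as n (%) per level, each computed for the
#' outlier subset and for the full cohort. Count cells covering one to six
#' participants are suppressed to protect privacy.
#'
#' @param outlier_ids Character vector of flagged participant ids (non-empty).
#' @param table A [cohort_table()].
#' @param k_median_iqr Continuous variables with at most this many unique
#'   integer values default to median (IQR) unless metadata overrides.
#' @return A `comparison_table` data frame with columns `variable`,
#'   `statistic`, `outliers`, `cohort`, `suppressed`.
#' @export
characterize_outliers <- function(outlier_ids, table, k_median_iqr = 12L) {
  if (!length(outlier_ids)) stop("outlier set is empty")
  md <- cohort_metadata(table)
  ids <- participant_ids(table)
  unknown <- setdiff(outlier_ids, ids)
  if (length(unknown))
    stop("unknown participant id(s): ", paste(unknown, collapse = ", "))
  sub <- table[ids %in% outlier_ids, , drop = FALSE]

  stat_kind <- function(i) {
    if (!is.na(md$summary[i])) return(md$summary[i])
    if (md$kind[i] == "categorical") return("n_percent")
    x <- table[[md$name[i]]]
    obs <- x[!is.na(x)]
    if (length(obs) && all(obs == round(obs)) &&
        length(unique(obs)) <= k_median_iqr) "median_iqr" else "mean_sd"
  }

  rows <- list()
  add <- function(variable, statistic, outliers, cohort, suppressed = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, statistic = statistic, outliers = outliers,
      cohort = cohort, suppressed = suppressed, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(md))) {
    nm <- md$name[i]
    if (md$role[i] == "identifier") next
    kind <- stat_kind(i)
    if (kind == "mean_sd") {
      f <- function(x) sprintf("%s (%s)", fmt_num(mean(x, na.rm = TRUE)),
                               fmt_num(stats::sd(x, na.rm = TRUE)))
      add(nm, "mean_sd", f(sub[[nm]]), f(table[[nm]]))
    } else if (kind == "median_iqr") {
      f <- function(x) {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
        sprintf("%g (%g to %g)", q[2], q[1], q[3])
      }
      add(nm, "median_iqr", f(sub[[nm]]), f(table[[nm]]))
    } else {
      lv <- sort(unique(table[[nm]][!is.na(table[[nm]])]))
      show <- if (length(lv) == 2L) lv[2] else lv # binary: report upper level
      for (l in show) {
        n_sub <- sum(!is.na(sub[[nm]]) & sub[[nm]] == l)
        n_all <- sum(!is.na(table[[nm]]) & table[[nm]] == l)
        sup_sub <- n_sub >= SUPPRESS_MIN && n_sub <= SUPPRESS_MAX
        sup_all <- n_all >= SUPPRESS_MIN && n_all <= SUPPRESS_MAX
        label <- if (length(show) > 1L) sprintf("%s = %s", nm, l) else nm
        add(label, "n_percent",
            suppress_count(n_sub, 100 * n_sub / max(nrow(sub), 1)),
            suppress_count(n_all, 100 * n_all / max(nrow(table), 1)),
            suppressed = sup_sub || sup_all)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Render a comparison table as aligned text
#'
#' @param ct A `comparison_table` from [characterize_outliers()].
#' @param n_outliers,n_cohort Optional subset/cohort sizes for the header.
#' @return Character vector of lines.
#' @export
render_comparison <- function(ct, n_outliers = NULL, n_cohort = NULL) {
  hdr <- sprintf("%-38s %-22s %-22s", "Variable",
                 if (is.null(n_outliers)) "Outliers"
                 else sprintf("Outliers (N = %d)", n_outliers),
                 if (is.null(n_cohort)) "Full cohort"
                 else sprintf("Full cohort (N = %d)", n_cohort))
  body <- sprintf("%-38s %-22s %-22s",
                  paste0(ct$variable, stat_suffix(ct$statistic)),
                  ct$outliers, ct$cohort)
  c(hdr, strrep("-", nchar(hdr)), body,
    "Cells covering fewer than seven participants are suppressed.")
}

stat_suffix <- function(s) c(mean_sd = ", mean (SD)",
                             median_iqr = ", median (IQR)",
                             n_percent = ", n (%)")[s]

#' Build a structured case narrative for a flagged participant
#'
#' Assembles, for one flagged participant, the detector provenance (which
#' stage flagged them and with what score or confidence), the values of all
#' declared risk-factor variables, and the `k` variables most deviant from
#' the cohort (by robust z against the cohort median and MAD). The clinical
#' assessment is left `"unreviewed"`: promoting a case to potential novelty
#' or natural deviation is a human reviewer's decision, never the package's.
#'
#' @param participant_id Id of a participant flagged by at least one
#'   detector (hard error otherwise).
#' @param table A complete [cohort_table()].
#' @param anomaly An `anomaly_result` from [score_anomalies()], or `NULL`.
#' @param misclass A `misclassification_result`, or `NULL`.
#' @param k Number of deviation highlights.
#' @return A `case_narrative` list.
#' @export
build_case_narrative <- function(participant_id, table, anomaly = NULL,
                                 misclass = NULL, k = 5L) {
  md <- cohort_metadata(table)
  ids <- participant_ids(table)
  r <- match(participant_id, ids)
  if (is.na(r)) stop("unknown participant id: ", participant_id)

  provenance <- list()
  if (!is.null(anomaly)) {
    row <- anomaly$scores[anomaly$scores$participant_id == participant_id, ]
    if (nrow(row) && row$is_outlier)
      provenance$isolation_forest <- list(
        detector = "isolation_forest", anomaly_score = row$anomaly_score,
        z_score = row$z_score)
  }
  if (!is.null(misclass)) {
    row <- misclass$flags[misclass$flags$participant_id == participant_id, ]
    if (nrow(row) && row$is_outlier)
      provenance$extreme_misclassification <- list(
        detector = "extreme_misclassification", true_label = row$true_label,
        predicted_label = row$predicted_label, confidence = row$vote_fraction)
  }
  if (!length(provenance))
    stop("participant ", participant_id, " was not flagged by any detector")

  cont <- md$name[md$kind == "continuous" & md$role == "feature"]
  rz <- vapply(cont, function(v) {
    x <- table[[v]]
    m <- stats::median(x, na.rm = TRUE)
    s <- stats::mad(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(0)
    (x[r] - m) / s
  }, 0)
  topk <- names(sort(abs(rz), decreasing = TRUE))[seq_len(min(k, length(rz)))]
  highlights <- data.frame(variable = topk,
                           value = vapply(topk, function(v) table[[v]][r], 0),
                           robust_z = rz[topk], stringsAsFactors = FALSE)

  rf <- md$name[md$risk_factor]
  risk <- data.frame(variable = rf,
                     value = vapply(rf, function(v) {
                       x <- table[[v]][r]
                       if (is.numeric(x)) format(signif(x, 4)) else as.character(x)
                     }, ""),
                     stringsAsFactors = FALSE)

  structure(list(participant_id = participant_id, provenance = provenance,
                 highlights = highlights, risk_factors = risk,
                 interesting_variables = topk, assessment = "unreviewed",
                 reasoning = ""),
            class = "case_narrative")
}

#' Render a case narrative as text
#'
#' Four reviewer-facing sections mirror the case-assessment worksheet:
#' Assessment, Reasoning, Risk Factors, Interesting Variables, preceded by
#' the detector provenance.
#'
#' @param cn A `case_narrative`.
#' @return Character vector of lines.
#' @export
render_case_narrative <- function(cn) {
  prov <- vapply(cn$provenance, function(p) {
    if (p$detector == "isolation_forest")
      sprintf("isolation forest: anomaly score %.4f, z %.2f",
              p$anomaly_score, p$z_score)
    else
      sprintf("extreme misclassification: recorded %s, predicted %s, confidence %.2f",
              p$true_label, p$predicted_label, p$confidence)
  }, "")
  c(sprintf("Participant %s", cn$participant_id),
    paste0("Detected by ", prov),
    sprintf("Assessment: %s", cn$assessment),
    sprintf("Reasoning: %s", ifelse(nzchar(cn$reasoning), cn$reasoning, "(pending review)")),
    sprintf("Risk Factors: %s",
            paste(sprintf("%s = %s", cn$risk_factors$variable,
                          cn$risk_factors$value), collapse = "; ")),
    sprintf("Interesting Variables: %s",
            paste(sprintf("%s = %.4g (robust z %.1f)", cn$highlights$variable,
                          cn$highlights$value, cn$highlights$robust_z),
                  collapse = "; ")))
}

#' Summarize detector runs and reviewer assessments
#'
#' Per detector: total flagged, and among reviewed cases the counts and
#' percentages assessed as potential novelty vs natural deviation, formatted
#' `"n (pct)"`. Percentages are taken over flagged-and-reviewed rows;
#' unreviewed rows are counted separately and percentages are undefined when
#' nothing was reviewed.
#'
#' @param detectors Named list mapping detector name to a character vector of
#'   flagged participant ids.
#' @param assessments Optional named character vector mapping participant id
#'   to `"potential_novelty"` or `"natural_deviation"`; ids absent from it
#'   are unreviewed.
#' @return A `run_summary` data frame.
#' @export
summarize_run <- function(detectors, assessments = NULL) {
  if (!length(detectors)) stop("no detector results supplied")
  rows <- lapply(names(detectors), function(d) {
    ids <- detectors[[d]]
    assessed <- assessments[names(assessments) %in% ids]
    n_rev <- length(assessed)
    n_nov <- sum(assessed == "potential_novelty")
    n_nat <- sum(assessed == "natural_deviation")
    fmt <- function(n) if (n_rev == 0) sprintf("%d (--)", n)
      else sprintf("%d (%s)", n, fmt_num(100 * n / n_rev))
    data.frame(detector = d, total_flagged = length(ids),
               potential_novelty = fmt(n_nov), natural_deviation = fmt(n_nat),
               unreviewed = length(ids) - n_rev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("run_summary", "data.frame")
  out
}

#' Audit rendered report lines for suppression leaks
#'
#' Scans rendered characterization output for any `n (pct)` count cell whose
#' count lies in the suppression band [1, 6]. Used by the test suite to show
#' suppression is total on the rendered artifact.
#'
#' @param lines Character vector of rendered lines.
#' @return Character vector of offending matches (empty when clean).
#' @export
audit_suppression <- function(lines) {
  hits <- regmatches(lines,
                     gregexpr("(?<![0-9.])[0-9]+ \\([0-9.]+\\)", lines,
                              perl = TRUE))
  hits <- unlist(hits)
  bad <- vapply(hits, function(h)
    as.integer(sub(" .*$", "", h)) %in% SUPPRESS_MIN:SUPPRESS_MAX, TRUE)
  unname(hits[bad])
}
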