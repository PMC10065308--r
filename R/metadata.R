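#' Variable metadata for a cohort table
#'
#' Declares, for every column of a cohort table, its measurement kind
#' (continuous or categorical), its role in the analysis, and an optional
#' structured-missingness ("not applicable") gate rule. Roles drive the
#' variable-filtering stage: `outcome_derived` variables (variations or
#' sub-categorizations of the outcome) and `recategorization_of:<source>`
#' variables (bucketed versions of a retained continuous variable) are dropped
#' before modelling; the `outcome` and `identifier` variables are never
#' dropped.
#'
#' @param name Character vector of variable names.
#' @param kind `"continuous"` or `"categorical"`, recycled as needed.
#' @param role One of `"feature"`, `"outcome"`, `"outcome_derived"`,
#'   `"identifier"`, or `"recategorization_of:<source>"`.
#' @param gate_variable,gate_value,gate_fill Optional gate rule per variable:
#'   when `gate_variable == gate_value` for a participant, a missing cell in
#'   this variable is "not applicable" and is filled with `gate_fill` (a
#'   numeric sentinel for continuous targets, a new category token for
#'   categorical ones) instead of being imputed.
#' @param summary Optional override for the characterization statistic:
#'   `"mean_sd"`, `"median_iqr"`, or `"n_percent"`.
#' @param risk_factor Logical; marks variables listed as risk factors in case
#'   narratives.
#' @return A `variable_metadata` data frame with one row per variable.
#' @export
variable_metadata <- function(name, kind = "continuous", role = "feature",
                              gate_variable = NA_character_,
                              gate_value = NA_character_,
                              gate_fill = NA_character_,
                              summary = NA_character_,
                              risk_factor = FALSE) {
  n <- length(name)
  md <- data.frame(
    name = as.character(name),
    kind = rep_len(as.character(kind), n),
    role = rep_len(as.character(role), n),
    gate_variable = rep_len(as.character(gate_variable), n),
    gate_value = rep_len(as.character(gate_value), n),
    gate_fill = rep_len(as.character(gate_fill), n),
    summary = rep_len(as.character(summary), n),
    risk_factor = rep_len(as.logical(risk_factor), n),
    stringsAsFactors = FALSE
  )
  class(md) <- c("variable_metadata", "data.frame")
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  stopifnot(inherits(md, "variable_metadata"))
  if (anyDuplicated(md$name))
    stop("duplicate variable names in metadata: ",
         paste(unique(md$name[duplicated(md$name)]), collapse = ", "))
  bad_kind <- setdiff(unique(md$kind), c("continuous", "categorical"))
  if (length(bad_kind)) stop("unknown variable kind: ", paste(bad_kind, collapse = ", "))
  base_role <- sub(":.*$", "", md$role)
  bad_role <- setdiff(unique(base_role),
                      c("feature", "outcome", "outcome_derived",
                        "recategorization_of", "identifier"))
  if (length(bad_role)) stop("unknown variable role: ", paste(bad_role, collapse = ", "))
  if (sum(md$role == "outcome") != 1L)
    stop("metadata must declare exactly one variable with role 'outcome'")
  src <- recat_source(md)
  missing_src <- setdiff(stats::na.omit(src), md$name)
  if (length(missing_src))
    stop("recategorization_of targets unknown variable(s): ",
         paste(missing_src, collapse = ", "))
  gate_has <- !is.na(md$gate_variable)
  if (any(gate_has & (is.na(md$gate_value) | is.na(md$gate_fill))))
    stop("gate rules need gate_variable, gate_value and gate_fill together")
  missing_gate <- setdiff(md$gate_variable[gate_has], md$name)
  if (length(missing_gate))
    stop("gate_variable references unknown variable(s): ",
         paste(missing_gate, collapse = ", "))
  invisible(md)
}

# Source variable name for recategorization_of:<source> roles; NA otherwise.
recat_source <- function(md) {
  ifelse(startsWith(md$role, "recategorization_of:"),
         sub("^recategorization_of:", "", md$role), NA_character_)
}

outcome_name <- function(md) md$name[md$role == "outcome"]

identifier_name <- function(md) {
  id <- md$name[md$role == "identifier"]
  if (length(id)) id[1] else NA_character_
}

#' Outcome specification
#'
#' Names the binary outcome column and which category token counts as the
#' positive (event) class, e.g. presence of preeclampsia or of a hypertensive
#' disorder of pregnancy.
#'
#' @param column Outcome column name.
#' @param positive_label Token of the positive class.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(column, positive_label) {
  stopifnot(is.character(column), length(column) == 1L,
            is.character(positive_label), length(positive_label) == 1L)
  structure(list(column = column, positive_label = positive_label),
            class = "outcome_spec")
}

#' Read variable metadata from a YAML file
#'
#' The file maps variable names to entries with keys `kind`, `role`, and an
#' optional nested `gate:` block (`variable`, `value`, `fill`), plus optional
#' `summary` and `risk_factor`.
#'
#' @param path Path to the YAML metadata file.
#' @return A [variable_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty metadata file: ", path)
  rows <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    g <- e$gate
    data.frame(
      name = nm,
      kind = e$kind %||% "continuous",
      role = e$role %||% "feature",
      gate_variable = g$variable %||% NA_character_,
      gate_value = as.character(g$value %||% NA_character_),
      gate_fill = as.character(g$fill %||% NA_character_),
      summary = e$summary %||% NA_character_,
      risk_factor = isTRUE(e$risk_factor),
      stringsAsFactors = FALSE
    )
  })
  md <- do.call(rbind, rows)
  class(md) <- c("variable_metadata", "data.frame")
  validate_metadata(md)
  md
}

#' Write variable metadata to YAML
#'
#' Inverse of [read_metadata()].
#'
#' @param md A [variable_metadata()] data frame.
#' @param path Output path.
#' @export
write_metadata <- function(md, path) {
  validate_metadata(md)
  out <- lapply(seq_len(nrow(md)), function(i) {
    e <- list(kind = md$kind[i], role = md$role[i])
    if (!is.na(md$gate_variable[i]))
      e$gate <- list(variable = md$gate_variable[i],
                     value = md$gate_value[i],
                     fill = md$gate_fill[i])
    if (!is.na(md$summary[i])) e$summary <- md$summary[i]
    if (isTRUE(md$risk_factor[i])) e$risk_factor <- TRUE
    e
  })
  names(out) <- md$name
  yaml::write_yaml(out, path)
  invisible(path)
}
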