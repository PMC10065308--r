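#' Construct a cohort table
#'
#' The shared data model of the pipeline: one row per participant, typed
#' columns (numeric for continuous variables, character tokens for categorical
#' ones), `NA` for missing cells, and an attached [variable_metadata()]
#' describing every column. All stages consume and return this object.
#'
#' @param data A data frame with a participant identifier column and one
#'   column per declared variable.
#' @param metadata A [variable_metadata()] covering exactly the columns of
#'   `data`.
#' @return A `cohort_table` (a data frame subclass).
#' @export
cohort_table <- function(data, metadata) {
  validate_metadata(metadata)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  extra <- setdiff(names(data), metadata$name)
  absent <- setdiff(metadata$name, names(data))
  if (length(extra) || length(absent))
    stop("metadata/column mismatch; columns without metadata: [",
         paste(extra, collapse = ", "), "]; metadata without column: [",
         paste(absent, collapse = ", "), "]")
  data <- data[, metadata$name, drop = FALSE]
  id <- identifier_name(metadata)
  if (is.na(id)) stop("metadata declares no identifier variable")
  ids <- as.character(data[[id]])
  if (anyNA(ids) || any(ids == "")) stop("missing participant identifiers")
  if (anyDuplicated(ids))
    stop("duplicate participant_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data[[id]] <- ids
  for (i in seq_len(nrow(metadata))) {
    nm <- metadata$name[i]
    if (nm == id) next
    if (metadata$kind[i] == "continuous") {
      data[[nm]] <- as.numeric(data[[nm]])
    } else {
      v <- as.character(data[[nm]])
      v[!is.na(v) & v == ""] <- NA_character_
      data[[nm]] <- v
    }
  }
  structure(data, metadata = metadata, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  md <- cohort_metadata(x)
  cat(sprintf("<cohort_table> %d participants x %d variables (%d missing cells)\n",
              nrow(x), ncol(x), n_missing_cells(x)))
  cat("outcome:", outcome_name(md), " identifier:", identifier_name(md), "\n")
  NextMethod()
}

#' Metadata attached to a cohort table
#' @param table A `cohort_table`.
#' @return The [variable_metadata()] of the table.
#' @export
cohort_metadata <- function(table) {
  md <- attr(table, "metadata")
  if (is.null(md)) stop("not a cohort_table: no metadata attribute")
  md
}

#' Participant identifiers of a cohort table
#' @param table A `cohort_table`.
#' @return Character vector of participant ids, in row order.
#' @export
participant_ids <- function(table) {
  table[[identifier_name(cohort_metadata(table))]]
}

#' Count of missing cells
#' @param table A `cohort_table`.
#' @return Integer number of `NA` cells across all variables.
#' @export
n_missing_cells <- function(table) sum(vapply(table, function(c) sum(is.na(c)), 0L))

# Subset rows, keeping class and metadata.
subset_cohort <- function(table, i) {
  md <- cohort_metadata(table)
  out <- as.data.frame(table)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, metadata = md, class = c("cohort_table", "data.frame"))
}

# Drop columns by name, pruning metadata to match.
drop_variables <- function(table, vars) {
  md <- cohort_metadata(table)
  keep <- setdiff(md$name, vars)
  md2 <- md[md$name %in% keep, , drop = FALSE]
  rownames(md2) <- NULL
  class(md2) <- c("variable_metadata", "data.frame")
  out <- as.data.frame(table)[, keep, drop = FALSE]
  structure(out, metadata = md2, class = c("cohort_table", "data.frame"))
}
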