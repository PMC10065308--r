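#' Read a cohort table from CSV plus metadata
#'
#' Reads an RFC-4180 CSV with a header row and types each column according to
#' the metadata: continuous columns are parsed as numbers, categorical columns
#' as opaque tokens. Empty fields and the token `"NA"` both parse to missing.
#' A cell in a continuous column that does not parse as a number becomes
#' missing, with a single warning reporting how many cells were affected.
#'
#' If the metadata declares no identifier variable, the row index is promoted
#' to a `participant_id` column with a warning.
#'
#' @param table_path Path to the CSV file.
#' @param metadata_path Path to the YAML metadata file (see [read_metadata()]),
#'   or a [variable_metadata()] object.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(table_path, metadata_path) {
  md <- if (inherits(metadata_path, "variable_metadata")) metadata_path
        else read_metadata(metadata_path)
  hdr <- strsplit(readLines(table_path, n = 1L), ",", fixed = TRUE)[[1]]
  hdr <- gsub('^"|"$', "", hdr)
  if (anyDuplicated(hdr))
    stop("duplicate column name in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  raw <- utils::read.csv(table_path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  if (is.na(identifier_name(md))) {
    warning("no identifier variable declared; promoting row index to participant_id")
    raw$participant_id <- as.character(seq_len(nrow(raw)))
    id_row <- md[1, ]
    id_row[1, ] <- list("participant_id", "categorical", "identifier",
                        NA_character_, NA_character_, NA_character_,
                        NA_character_, FALSE)
    md <- rbind(md, id_row)
    class(md) <- c("variable_metadata", "data.frame")
    rownames(md) <- NULL
  }
  n_bad <- 0L
  for (i in seq_len(nrow(md))) {
    nm <- md$name[i]
    if (!nm %in% names(raw) || md$kind[i] != "continuous") next
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(raw[[nm]]))
  }
  if (n_bad > 0L)
    warning(sprintf("%d unparseable numeric cell(s) set to missing", n_bad))
  suppressWarnings(cohort_table(raw, md))
}

#' Write a cohort table to CSV
#'
#' Missing cells are written as empty fields. Numeric cells are serialized at
#' full precision so that `read_cohort(write_cohort(t))` reproduces `t`
#' cell-for-cell, and repeated writes of the same table are byte-identical.
#'
#' @param table A [cohort_table()].
#' @param path Output path.
#' @export
write_cohort <- function(table, path) {
  md <- cohort_metadata(table)
  out <- as.data.frame(table)
  for (i in seq_len(nrow(md))) {
    nm <- md$name[i]
    if (md$kind[i] == "continuous" && nm != identifier_name(md)) {
      v <- out[[nm]]
      s <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
      # trim to the shortest representation that round-trips exactly
      short <- ifelse(is.na(v), NA_character_, sprintf("%.15g", v))
      use_short <- !is.na(v) & suppressWarnings(as.numeric(short)) == v
      out[[nm]] <- ifelse(is.na(v), NA_character_, ifelse(use_short, short, s))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   eol = "\n")
  invisible(path)
}
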