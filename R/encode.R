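#' Encode a complete cohort table as a numeric feature matrix
#'
#' Builds the model matrix both detector stages consume. The outcome and
#' identifier columns are excluded; categorical variables are integer-coded
#' `0, 1, 2, ...` by lexicographic level order (so a `{no, yes}` variable maps
#' to `{0, 1}`). The level map is returned and can be passed back in to encode
#' further tables consistently; an unseen level at transform time is an error.
#'
#' @param table A complete [cohort_table()] (no missing cells).
#' @param level_maps Optional level map from a previous call, to reuse.
#' @return A list with `x` (numeric matrix, one column per feature) and
#'   `level_maps` (named list of sorted level vectors for the categorical
#'   features).
#' @export
encode_features <- function(table, level_maps = NULL) {
  md <- cohort_metadata(table)
  if (n_missing_cells(table) > 0)
    stop("encode_features requires a complete table; run imputation first")
  feats <- setdiff(md$name, c(outcome_name(md), identifier_name(md)))
  feats <- feats[md$role[match(feats, md$name)] != "outcome_derived"]
  maps <- level_maps %||% list()
  cols <- lapply(feats, function(v) {
    k <- md$kind[match(v, md$name)]
    if (k == "continuous") return(as.numeric(table[[v]]))
    vals <- as.character(table[[v]])
    if (is.null(maps[[v]])) maps[[v]] <<- sort(unique(vals))
    code <- match(vals, maps[[v]]) - 1L
    if (anyNA(code)) {
      bad <- setdiff(unique(vals), maps[[v]])
      stop("unseen categorical level(s) in '", v, "': ",
           paste(bad, collapse = ", "))
    }
    as.numeric(code)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- feats
  list(x = x, level_maps = maps)
}
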