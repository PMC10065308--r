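#' Run the full screening pipeline
#'
#' Chains the stages end to end on a single dataset: acquire the cohort
#' (synthetic generation, or a CSV + metadata pair), filter variables, apply
#' gated fills, impute, detect point outliers (isolation forest) and
#' contextual outliers (random-forest extreme misclassification), and write
#' the reviewer-facing reports plus a JSON run manifest. Each dataset is
#' analyzed separately; a config naming more than one dataset is rejected.
#'
#' All randomness derives from the single master `seed` via stage keys, so
#' two runs with the same config and seed produce byte-identical outputs.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Keys (all optional unless noted): `out_dir` (required), `seed`,
#'   `dataset` (`csv` + `metadata` paths + `outcome` + `positive_label`) or
#'   `synthetic` (overrides for [synthetic_spec()] fields), `imputation`
#'   (`n_iterations`), `iforest` (`n_estimators`, `max_samples`, `tune`),
#'   `forest` (`train_n`, `test_n`, `validation_n`, `search`, fixed `params`,
#'   `threshold`), `report` (`k`).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(cfg$datasets) && length(cfg$datasets) > 1)
    stop("config names multiple datasets; each dataset must be analyzed separately")
  if (is.null(cfg$out_dir)) stop("config field missing: out_dir")
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 2022L)
  manifest <- list(config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion("outlierscreen")),
                   stages = list(), seeds = list(), files = list())
  outp <- function(f) file.path(out_dir, f)

  # --- acquire -------------------------------------------------------------
  if (!is.null(cfg$dataset)) {
    ds <- cfg$dataset
    if (is.null(ds$csv) || !file.exists(ds$csv))
      stop("dataset csv missing: ", ds$csv %||% "(unset)")
    table <- read_cohort(ds$csv, ds$metadata)
    md <- cohort_metadata(table)
    outcome <- outcome_spec(ds$outcome %||% outcome_name(md),
                            ds$positive_label %||% "yes")
    truth <- NULL
  } else {
    syn <- cfg$synthetic %||% list()
    syn$seed <- derive_seed(seed, "synthetic")
    spec <- do.call(synthetic_spec, syn)
    gen <- generate_cohort(spec)
    table <- gen$table
    outcome <- gen$outcome
    truth <- gen$truth
    manifest$seeds$synthetic <- spec$seed
    write_cohort(table, outp("cohort.csv"))
    write_metadata(gen$metadata, outp("metadata.yml"))
  }
  manifest$stages$input <- list(rows = nrow(table), cols = ncol(table),
                                missing_cells = n_missing_cells(table))
  message(sprintf("[input] %d rows x %d variables, %d missing cells",
                  nrow(table), ncol(table), n_missing_cells(table)))

  # --- preprocess ----------------------------------------------------------
  filt <- filter_variables(table)
  write_exclusion_log(filt$log, outp("exclusion_log.csv"))
  table <- apply_gate_fills(filt$table)
  imp_seed <- derive_seed(seed, "imputation")
  table <- impute_iterative(table, imputation_config(
    n_iterations = cfg$imputation$n_iterations %||% 10L, seed = imp_seed))
  manifest$seeds$imputation <- imp_seed
  manifest$stages$preprocess <- list(
    dropped = filt$log$variable, rows = nrow(table), cols = ncol(table))
  write_cohort(table, outp("imputed.csv"))
  message(sprintf("[preprocess] dropped %d variable(s); table now complete (%d cols)",
                  nrow(filt$log), ncol(table)))

  enc <- encode_features(table)
  ids <- participant_ids(table)

  # --- point outliers ------------------------------------------------------
  ifc <- cfg$iforest %||% list()
  icfg <- isolation_config(
    n_estimators = if (isTRUE(ifc$tune)) NULL else ifc$n_estimators %||% 300L,
    max_samples = if (isTRUE(ifc$tune)) NULL else ifc$max_samples %||% 256L,
    random_state = derive_seed(seed, "iforest"))
  anom <- score_anomalies(enc$x, icfg, ids = ids)
  utils::write.csv(anom$scores, outp("anomalies.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest$seeds$iforest <- icfg$random_state
  manifest$stages$point_outliers <- list(
    n_estimators = anom$n_estimators, max_samples = anom$max_samples,
    contamination = anom$contamination, score_mean = anom$score_mean,
    score_sd = anom$score_sd, flagged = sum(anom$scores$is_outlier))
  message(sprintf("[iforest] %d point outlier(s) flagged (|z| >= %g)",
                  sum(anom$scores$is_outlier), icfg$z_threshold))

  # --- contextual outliers -------------------------------------------------
  fo <- cfg$forest %||% list()
  n <- nrow(table)
  tn <- fo$train_n %||% round(0.52 * n)
  te <- fo$test_n %||% round(0.35 * n)
  vn <- fo$validation_n %||% (n - tn - te)
  split_seed <- derive_seed(seed, "split")
  splits <- split_dataset(table, tn, te, vn, outcome, seed = split_seed)
  y_of <- function(s) factor(s[[outcome$column]])
  enc_tr <- encode_features(splits$train, level_maps = enc$level_maps)
  if (isTRUE(fo$search)) {
    enc_te <- encode_features(splits$test, level_maps = enc$level_maps)
    sr <- search_hyperparameters(
      enc_tr$x, y_of(splits$train), enc_te$x, y_of(splits$test),
      forest_search_spec(seed = derive_seed(seed, "search")),
      positive = outcome$positive_label)
    params <- sr$params
    utils::write.csv(sr$ledger, outp("search_ledger.csv"), row.names = FALSE)
  } else {
    params <- fo$params %||% list(num_trees = 600L, max_depth = 10L,
                                  min_node_size = 2L, min_bucket = 2L,
                                  replace = FALSE)
  }
  rf_seed <- derive_seed(seed, "forest")
  model <- fit_outcome_forest(enc_tr$x, y_of(splits$train), params,
                              seed = rf_seed)
  mis <- flag_extreme_misclassification(model, table, outcome,
                                        threshold = fo$threshold %||% 0.90,
                                        level_maps = enc$level_maps)
  utils::write.csv(mis$flags, outp("misclass.csv"), row.names = FALSE,
                   quote = FALSE)
  report_full <- classification_report(mis)
  manifest$seeds$split <- split_seed
  manifest$seeds$forest <- rf_seed
  manifest$stages$contextual_outliers <- list(
    split = c(train = tn, test = te, validation = vn),
    split_prevalence = as.list(attr(splits, "prevalence")),
    params = params, threshold = mis$threshold,
    flagged = sum(mis$flags$is_outlier),
    classification_report = report_full)
  message(sprintf("[forest] %d contextual outlier(s) flagged (vote fraction > %g)",
                  sum(mis$flags$is_outlier), mis$threshold))

  # --- reporting -----------------------------------------------------------
  point_ids <- anom$scores$participant_id[anom$scores$is_outlier]
  ctx_ids <- mis$flags$participant_id[mis$flags$is_outlier]
  all_flagged <- union(point_ids, ctx_ids)
  report_lines <- character()
  for (set in list(list(name = "isolation_forest", ids = point_ids),
                   list(name = "extreme_misclassification", ids = ctx_ids))) {
    if (!length(set$ids)) next
    ct <- characterize_outliers(set$ids, table)
    utils::write.csv(ct, outp(sprintf("comparison_%s.csv", set$name)),
                     row.names = FALSE)
    report_lines <- c(report_lines, sprintf("== %s outliers ==", set$name),
                      render_comparison(ct, length(set$ids), nrow(table)), "")
  }
  k <- cfg$report$k %||% 5L
  narr_lines <- unlist(lapply(all_flagged, function(pid)
    c(render_case_narrative(
        build_case_narrative(pid, table, anomaly = anom, misclass = mis, k = k)),
      "")))
  writeLines(c(report_lines,
               "== case narratives ==", narr_lines %||% character()),
             outp("report.txt"))
  summ <- summarize_run(list(isolation_forest = point_ids,
                             extreme_misclassification = ctx_ids))
  utils::write.csv(summ, outp("summary.csv"), row.names = FALSE)
  manifest$stages$reporting <- list(
    narratives = length(all_flagged),
    overlap = length(intersect(point_ids, ctx_ids)))

  files <- c("exclusion_log.csv", "imputed.csv", "anomalies.csv",
             "misclass.csv", "report.txt", "summary.csv")
  files <- files[file.exists(outp(files))]
  manifest$files <- as.list(tools::md5sum(outp(files)))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  message(sprintf("[done] %d point + %d contextual outliers (%d overlap); outputs in %s",
                  length(point_ids), length(ctx_ids),
                  length(intersect(point_ids, ctx_ids)), out_dir))
  invisible(list(table = table, anomaly = anom, misclass = mis,
                 summary = summ, truth = truth, manifest = manifest))
}
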