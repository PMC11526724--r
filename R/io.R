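#' Read a feature table from CSV
#'
#' Expects a header with `sample_id`, `label` (0/1) and feature columns; an
#' optional `source` column defaults to `"real"`. Validation errors name the
#' offending column.
#'
#' @param path CSV path.
#' @return Tibble feature table.
#' @export
read_feature_table <- function(path) {
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"label" %in% names(df)) stop_invalid("label", "column is missing")
  if (!all(df$label %in% c(0, 1))) stop_invalid("label", "must contain only 0/1")
  if ("sample_id" %in% names(df) && anyDuplicated(df$sample_id)) {
    stop_invalid("sample_id", "contains duplicates")
  }
  if (!"source" %in% names(df)) df$source <- "real"
  df$label <- as.integer(df$label)
  df
}

#' Write a feature table to CSV
#'
#' Full-precision CSV so a write/read round trip is value-identical to within
#' 1e-12.
#'
#' @param table Feature table tibble.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full workflow on a directory of images or a feature table
#'
#' Executes the pipeline stages in order -- simulate/ingest, preprocess,
#' extract, select, augment, quality, evaluate, interpret -- and writes the
#' six artifacts (`features.csv`, `selected.json`, `augmented.csv`,
#' `report.json`, `results.json`, `interpret.json`) plus a machine-readable
#' run log to `out_dir`. Tabular entry (a `table` instead of `lesions`)
#' skips the image stages, which is recorded in the log.
#'
#' @param lesions Optional list of `dermaug_lesion` objects (or NULL).
#' @param table Optional feature table (used when `lesions` is NULL).
#' @param out_dir Output directory (created if needed).
#' @param models Models for the sweep.
#' @param r_values Balance ratios for the sweep.
#' @param repeats Repeated splits.
#' @param cv_k Cross-validation folds in the grid search.
#' @param k_final Features kept by ensemble selection.
#' @param fs_m Bootstrap subsets in ensemble selection.
#' @param boot_m Bootstrap resamples in the CI tests.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Invisibly, a list with the artifacts and the run log tibble.
#' @export
run_pipeline <- function(lesions = NULL, table = NULL, out_dir,
                         models = "lasso", r_values = c(0.5, 1.0),
                         repeats = 3L, cv_k = 5L, k_final = 35L, fs_m = 25L,
                         boot_m = 1000L, seed = 1L) {
  if (is.null(lesions) && is.null(table)) {
    stop_invalid("lesions", "provide lesions or a feature table")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_rows <- list()
  log_stage <- function(stage, rows_in, rows_out, note = "") {
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage,
      rows_in = rows_in, rows_out = rows_out, note = note)
  }

  if (!is.null(lesions)) {
    feats <- purrr::map_dfr(seq_along(lesions), function(i) {
      les <- lesions[[i]]
      img <- les$image
      if (dim(img)[1] != 224) img <- resize_image(img)
      hr <- remove_hair(img)
      mask <- if (dim(les$image)[1] == 224) les$mask else
        resize_mask(les$mask, 224L)
      if (!any(mask > 0)) mask <- segment_fallback(hr$clean_image)
      dplyr::bind_cols(tibble(sample_id = sprintf("img_%04d", i),
                              label = les$label, source = "real"),
                       extract_all(hr$clean_image, mask))
    })
    table <- feats
    log_stage("preprocess+extract", length(lesions), nrow(table))
  } else {
    log_stage("extract", 0L, nrow(table), "tabular entry: image stages skipped")
  }
  write_feature_table(table, file.path(out_dir, "features.csv"))

  xy <- table_xy(table)
  es <- ensemble_select(xy$X, xy$y, M = fs_m, k_final = min(k_final, ncol(xy$X)),
                        seed = seed + 1L)
  jsonlite::write_json(list(selected = es$selected,
                            ranking = es$ranking, seed = seed),
                       file.path(out_dir, "selected.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage("select", ncol(xy$X), length(es$selected))

  sel_tbl <- dplyr::bind_cols(table[, intersect(c("sample_id", "label", "source"),
                                                names(table))],
                              table[, es$selected, drop = FALSE])
  aug <- augment_to_ratio(sel_tbl, method = "smote", r = max(r_values),
                          seed = seed + 2L)
  write_feature_table(aug, file.path(out_dir, "augmented.csv"))
  log_stage("augment", nrow(sel_tbl), nrow(aug),
            sprintf("n_synthetic=%d", sum(aug$source == "synthetic")))

  syn <- aug[aug$source == "synthetic", es$selected, drop = FALSE]
  real_min <- aug[aug$source == "real" & aug$label == 1, es$selected, drop = FALSE]
  qr <- if (nrow(syn) >= 3) quality_report(real_min, syn) else NULL
  if (!is.null(qr)) {
    jsonlite::write_json(list(mean_hd = qr$mean_hd, mean_maep = qr$mean_maep,
                              pcd = qr$pcd, rsvr = qr$rsvr,
                              per_feature = qr$per_feature, seed = seed),
                         file.path(out_dir, "report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  log_stage("quality", nrow(syn), nrow(syn))

  exp_res <- ir_sweep_experiment(sel_tbl, models = models, r_values = r_values,
                                 repeats = repeats, cv_k = cv_k, seed = seed + 3L)
  jsonlite::write_json(list(summary = exp_res$summary, seed = seed),
                       file.path(out_dir, "results.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage("evaluate", nrow(sel_tbl), nrow(exp_res$summary))

  tests <- run_all_feature_tests(sel_tbl, M = boot_m, seed = seed + 4L)
  jsonlite::write_json(list(tests = tests, seed = seed),
                       file.path(out_dir, "interpret.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage("interpret", ncol(xy$X), nrow(tests))

  log <- dplyr::bind_rows(log_rows)
  log$seed <- seed
  utils::write.csv(log, file.path(out_dir, "run_log.csv"), row.names = FALSE)
  invisible(list(features = table, selected = es, augmented = aug,
                 quality = qr, experiment = exp_res, tests = tests, log = log))
}
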