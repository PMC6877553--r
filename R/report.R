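# Result serialization: confusion-matrix CSVs, summary JSON, best-combination
# table and a rendered text summary.

CLASS_NAMES <- c("dorsiflexion", "foot_flat", "plantarflexion",
                 "eversion", "inversion")

#' Best-performing approach/classifier combination per data set and condition
#'
#' One row per (data set, electrode condition) pair, six rows total. Exact
#' accuracy ties resolve in approach order (generic, biased, walking style)
#' then classifier order (LDA, tree, deterministic, voting).
#'
#' @param result An `emg_experiment`.
#' @return Data frame with columns `dataset`, `condition`, `approach`,
#'   `classifier`, `accuracy`.
#' @export
best_combinations <- function(result) {
  g <- result$grid
  rows <- lapply(CONDITIONS, function(cond) {
    do.call(rbind, lapply(DATASETS, function(ds) {
      sub <- g[g$condition == cond & g$dataset == ds, , drop = FALSE]
      sub <- sub[order(match(sub$approach, APPROACHES),
                       match(sub$classifier, CLASSIFIERS)), , drop = FALSE]
      best <- sub[which.max(sub$accuracy), , drop = FALSE]
      data.frame(dataset = ds, condition = cond, approach = best$approach,
                 classifier = best$classifier, accuracy = best$accuracy,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ttest_to_list <- function(tt) {
  if (inherits(tt, "emg_ttest")) return(unclass(tt))
  lapply(tt, ttest_to_list)
}

#' Write experiment results to disk
#'
#' Produces, under `dir`: one CSV per grid cell with the 5x5 confusion matrix
#' (rows = true class, columns = predicted class), `summary.json` (seed,
#' accuracy grid, t-tests, best combinations, identified styles) and
#' `summary.md`, a human-readable digest.
#'
#' @param result An `emg_experiment`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
report <- function(result, dir) {
  if (!inherits(result, "emg_experiment") || !nrow(result$grid)) {
    stop_config("result must be a non-empty emg_experiment")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm_dir <- file.path(dir, "confusions")
  dir.create(cm_dir, showWarnings = FALSE)
  cm_paths <- vapply(names(result$confusions), function(key) {
    cm <- as.data.frame.matrix(result$confusions[[key]])
    dimnames(cm) <- list(CLASS_NAMES, CLASS_NAMES)
    path <- file.path(cm_dir, paste0(key, ".csv"))
    utils::write.csv(cm, path)
    path
  }, character(1))

  best <- best_combinations(result)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(seed = result$seed, grid = result$grid,
         best_combinations = best, ttests = ttest_to_list(result$ttests),
         styles = result$styles),
    summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE)

  md_path <- file.path(dir, "summary.md")
  g <- result$grid
  lines <- c("# Intent-prediction experiment summary", "",
             sprintf("Seed: %d. Cells: %d. Test participants: %d.",
                     result$seed, nrow(g),
                     length(unique(result$per_participant$participant))), "",
             "## Best combinations (dataset x electrode condition)", "",
             "| dataset | condition | approach | classifier | accuracy |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %.1f%% |", best$dataset,
                     best$condition, best$approach, best$classifier,
                     100 * best$accuracy), "",
             "## Mean accuracy by condition", "",
             sprintf("- %s: %.1f%%", CONDITIONS,
                     vapply(CONDITIONS, function(cc) {
                       100 * mean(g$accuracy[g$condition == cc])
                     }, numeric(1))))
  writeLines(lines, md_path)
  invisible(list(summary = summary_path, markdown = md_path,
                 confusions = cm_paths))
}
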