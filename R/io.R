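#' Write a cohort to disk (TSV time series, manifest CSV, truth JSON)
#'
#' Each subject's time series goes to `<dir>/<subject_id>.tsv` (rows =
#' timepoints, columns = region indices); `manifest.csv` lists
#' `subject_id,label,path`; when `spec` is given, `ground_truth.json` records
#' the planted pairs and the full specification.
#'
#' @param subjects List of subject records from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param spec Optional [cohort_spec()] recorded as ground truth.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(subjects, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(subjects, function(s) {
    p <- file.path(dir, paste0(s$subject_id, ".tsv"))
    utils::write.table(s$timeseries, p, sep = "\t", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    p
  }, "")
  manifest <- data.frame(
    subject_id = vapply(subjects, function(s) s$subject_id, ""),
    label = vapply(subjects, function(s) as.character(s$label), ""),
    path = basename(paths), stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(
      list(planted_pairs = spec$planted_pairs, seed = spec$seed,
           spec = unclass(spec)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the per-subject TSVs.
#' @return List of subject records.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lev <- if (all(manifest$label %in% c("control", "case")))
    c("control", "case") else unique(manifest$label)
  lapply(seq_len(nrow(manifest)), function(i) {
    ts <- as.matrix(read.csv(file.path(dir, manifest$path[i]), sep = "\t"))
    list(subject_id = manifest$subject_id[i],
         label = factor(manifest$label[i], levels = lev),
         timeseries = ts)
  })
}

#' Write an ensemble run report as JSON
#'
#' Records the configuration, per-member accuracies, ensemble accuracy,
#' significant-member count, failed-member count and tie flags — everything
#' needed to audit a run.
#'
#' @param cluster A trained `nn_cluster`.
#' @param test Test [feature_table()].
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_cluster_report <- function(cluster, test, path) {
  pred <- predict(cluster, test)
  acc <- member_accuracies(cluster, test)
  sig <- select_significant(cluster, test)
  report <- list(
    config = unclass(cluster$config)[c("k", "n_sub", "m_feat", "base_kind",
                                       "split_ratio", "sig_threshold",
                                       "seed")],
    nn_config = unclass(cluster$config$nn),
    ensemble_accuracy = mean(as.character(pred) ==
                               as.character(test$labels)),
    member_accuracies = acc,
    mean_member_accuracy = mean(acc, na.rm = TRUE),
    significant_members = length(sig$indices),
    failed_members = cluster$n_failed,
    ties = sum(attr(pred, "ties")))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(report)
}

#' Write feature frequencies with their region annotation
#'
#' @param counts Counts from [feature_frequencies()].
#' @param layout Layout map (or `NULL` for anonymous features).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(counts, layout, path) {
  df <- if (is.null(layout)) {
    data.frame(index = seq_along(counts), count = counts)
  } else {
    data.frame(index = layout$index, indicator = layout$indicator,
               region1 = layout$region1, region2 = layout$region2,
               count = counts)
  }
  df <- df[order(-df$count, df$index), ]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
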