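#' Subjects-by-features table with class labels
#'
#' The common container handed between the feature-extraction and ensemble
#' stages: a numeric matrix (one row per subject), class labels, and — when
#' the features come from a connectome — the layout map linking every column
#' to its graph indicator and region(s).
#'
#' @param x Numeric matrix, subjects in rows.
#' @param labels Factor (or coercible) of class labels, one per row.
#' @param layout Optional layout data frame from [feature_layout()].
#' @param subject_ids Optional character vector of subject identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, labels, layout = NULL, subject_ids = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nrow(x) != length(labels) && nrow(x) > 0)
    stop_ctx("labels length (%d) does not match rows (%d)",
             length(labels), nrow(x))
  if (is.null(subject_ids)) subject_ids <- rownames(x)
  if (is.null(subject_ids) && nrow(x) > 0)
    subject_ids <- sprintf("S%03d", seq_len(nrow(x)))
  rownames(x) <- subject_ids
  if (!is.null(layout) && ncol(x) > 0 && nrow(layout) != ncol(x))
    stop_ctx("layout has %d rows but table has %d features",
             nrow(layout), ncol(x))
  structure(list(x = x, labels = labels, layout = layout,
                 subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features\n",
              nrow(x$x), ncol(x$x)))
  if (length(x$labels)) print(table(x$labels))
  if (!is.null(x$layout))
    cat("layout:", paste(unique(x$layout$indicator), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

# Row/column subset keeping labels and layout consistent.
subset_table <- function(ft, rows = NULL, cols = NULL) {
  x <- ft$x
  labels <- ft$labels
  layout <- ft$layout
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]
    labels <- labels[rows]
  }
  if (!is.null(cols)) {
    x <- x[, cols, drop = FALSE]
    if (!is.null(layout)) layout <- layout[cols, , drop = FALSE]
  }
  feature_table(x, labels, layout, rownames(x))
}

#' Write / read a feature table as CSV plus a sidecar JSON layout map
#'
#' The CSV holds `subject_id`, `label`, then one column per feature; the
#' sidecar (`<path>.layout.json`) records the indicator and region indices of
#' every feature so that importance results remain interpretable.
#'
#' @param ft A [feature_table()].
#' @param path CSV output path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(subject_id = ft$subject_ids, label = as.character(ft$labels),
                   ft$x, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(ft$layout)) {
    jsonlite::write_json(ft$layout, paste0(path, ".layout.json"),
                         dataframe = "columns", na = "null", digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  layout_path <- paste0(path, ".layout.json")
  layout <- NULL
  if (file.exists(layout_path)) {
    l <- jsonlite::read_json(layout_path, simplifyVector = TRUE)
    layout <- as.data.frame(l, stringsAsFactors = FALSE)
  }
  x <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")), drop = FALSE])
  feature_table(x, factor(df$label, levels = unique(df$label)),
                layout, df$subject_id)
}
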