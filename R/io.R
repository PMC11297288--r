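#' Read a well-level profile table from disk
#'
#' Reads either delimited text (CSV, header row, metadata columns then
#' numeric feature columns) or the columnar binary format (Parquet, lossless
#' for doubles). All columns that are not recognized metadata are treated as
#' features and must be numeric; non-numeric feature cells are an error, not
#' silently dropped, and missing values are rejected rather than imputed
#' because every downstream formula assumes complete vectors.
#'
#' @param path Path to an existing file.
#' @param format `"auto"` (by extension), `"csv"` or `"parquet"`.
#' @param column_map Optional named character vector mapping canonical
#'   metadata names to the headers used in the file, e.g.
#'   `c(batch_id = "Metadata_Batch")`, for ingesting externally produced
#'   tables.
#' @return A validated [profile_table].
#' @export
read_profiles <- function(path, format = c("auto", "csv", "parquet"),
                          column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  format <- resolve_format(path, format)
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE),
    parquet = as.data.frame(arrow::read_parquet(path))
  )
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      ext <- column_map[[canon]]
      if (!ext %in% names(df)) {
        stop("column_map refers to absent column: ", ext)
      }
      names(df)[names(df) == ext] <- canon
    }
  }
  meta_cols <- intersect(c(META_COLUMNS, "microscope_type"), names(df))
  missing_cols <- setdiff(META_COLUMNS, meta_cols)
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  feat_cols <- setdiff(names(df), meta_cols)
  if (length(feat_cols) == 0) stop("no feature columns found")
  non_num <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  }
  meta <- df[meta_cols]
  for (cc in meta_cols) meta[[cc]] <- as.character(meta[[cc]])
  profile_table(as.matrix(df[feat_cols]), meta)
}

#' Write a well-level profile table to disk
#'
#' The CSV writer emits metadata columns first, then features. The Parquet
#' writer stores doubles at full precision so `read_profiles()` on the result
#' reproduces the table exactly.
#'
#' @param x A non-empty [profile_table].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, format = c("auto", "csv", "parquet")) {
  validate_profile_table(x)
  if (n_wells(x) == 0) stop("refusing to write an empty (0-well) table")
  format <- resolve_format(path, match.arg(format))
  meta_cols <- intersect(c(META_COLUMNS, "microscope_type"),
                         names(x$metadata))
  df <- cbind(x$metadata[meta_cols], as.data.frame(x$features))
  switch(format,
    csv = utils::write.csv(df, path, row.names = FALSE),
    parquet = arrow::write_parquet(df, path)
  )
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt")) return("csv")
  if (ext %in% c("parquet", "pq")) return("parquet")
  stop("cannot infer format from extension '.", ext,
       "'; pass format explicitly")
}

#' Write a tidy metric table
#'
#' All quantitative outputs of the benchmark are tidy delimited text with
#' columns `scenario`, `method`, `metric`, `category`, `raw_value`,
#' `normalized_value`.
#'
#' @param metrics data.frame of metric results (see [evaluate_metrics()]).
#' @param path Output CSV path.
#' @param scenario Scenario name recorded in the `scenario` column.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, scenario = "scenario") {
  need <- c("method", "metric", "category", "raw_value", "normalized_value")
  if (!all(need %in% names(metrics))) {
    stop("metrics table must contain columns: ", paste(need, collapse = ", "))
  }
  out <- cbind(scenario = scenario, metrics[need])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
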