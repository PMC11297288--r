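#' Well-level morphological profile table
#'
#' `profile_table` pairs a numeric feature matrix (wells x features) with
#' per-well metadata describing the experimental hierarchy of image-based
#' profiling: data-producing source (laboratory), experimental batch, plate,
#' and well. It is the common currency of every stage of the benchmark:
#' preprocessing, batch correction and metric evaluation all consume and
#' return `profile_table` objects.
#'
#' Mandatory metadata columns are `source_id`, `batch_id`, `plate_id`,
#' `well_position`, `compound_id` and `control_type`
#' (`"negative"` for DMSO vehicle wells, `"positive"`, or `"treatment"`);
#' `microscope_type` is optional. Plate identifiers are namespaced internally
#' by source and batch, so a plate can never straddle two batches.
#'
#' @param features Numeric matrix (wells x features) of finite values with
#'   unique, non-empty column names.
#' @param metadata data.frame with one row per well containing the mandatory
#'   metadata columns described above.
#' @return An object of class `profile_table`: a list with elements
#'   `features` (matrix) and `metadata` (data.frame).
#' @examples
#' tab <- profile_table(
#'   matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("f1", "f2", "f3"))),
#'   data.frame(
#'     source_id = "s1", batch_id = "b1", plate_id = "p1",
#'     well_position = c("A01", "A02", "A03", "A04"),
#'     compound_id = c("DMSO", "DMSO", "cmpdA", "cmpdB"),
#'     control_type = c("negative", "negative", "treatment", "treatment")
#'   )
#' )
#' n_wells(tab)
#' @export
profile_table <- function(features, metadata) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix (wells x features)")
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  rownames(metadata) <- NULL
  rownames(features) <- NULL
  x <- structure(list(features = features, metadata = metadata),
                 class = "profile_table")
  validate_profile_table(x)
}

#' @rdname profile_table
#' @export
META_COLUMNS <- c("source_id", "batch_id", "plate_id", "well_position",
                  "compound_id", "control_type")

CONTROL_TYPES <- c("negative", "positive", "treatment")

#' Validate a profile table
#'
#' Checks the structural invariants: one metadata record per feature row,
#' unique non-empty feature names, finite values, known control types, and
#' uniqueness of the (source, batch, plate, well) address.
#'
#' @param x A [profile_table].
#' @return `x` invisibly unchanged if valid; otherwise an error.
#' @export
validate_profile_table <- function(x) {
  stopifnot(inherits(x, "profile_table"))
  f <- x$features
  m <- x$metadata
  missing_cols <- setdiff(META_COLUMNS, names(m))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(f) != nrow(m)) {
    stop("integrity error: ", nrow(f), " feature rows but ",
         nrow(m), " metadata records")
  }
  fn <- colnames(f)
  if (ncol(f) > 0 && (is.null(fn) || anyNA(fn) || any(fn == ""))) {
    stop("features must have non-empty column names")
  }
  if (anyDuplicated(fn)) {
    stop("duplicate feature names: ",
         paste(unique(fn[duplicated(fn)]), collapse = ", "))
  }
  if (length(f) > 0 && !all(is.finite(f))) {
    stop("features must be finite real numbers; found NA/NaN/Inf")
  }
  bad_ct <- setdiff(unique(m$control_type), CONTROL_TYPES)
  if (length(bad_ct) > 0) {
    stop("unknown control_type value(s): ", paste(bad_ct, collapse = ", "),
         " (expected negative/positive/treatment)")
  }
  addr <- well_address(x)
  if (anyDuplicated(addr)) {
    stop("integrity error: duplicated well address(es): ",
         paste(unique(addr[duplicated(addr)]), collapse = "; "))
  }
  invisible(x)
}

#' @rdname profile_table
#' @export
n_wells <- function(x) nrow(x$features)

#' @rdname profile_table
#' @export
n_features <- function(x) ncol(x$features)

#' @rdname profile_table
#' @export
feature_names <- function(x) colnames(x$features)

#' Unique well address strings (source/batch/plate/well)
#' @param x A [profile_table].
#' @return Character vector, one address per well.
#' @export
well_address <- function(x) {
  m <- x$metadata
  paste(m$source_id, m$batch_id, m$plate_id, m$well_position, sep = "/")
}

#' Namespaced plate keys (source/batch/plate)
#' @param x A [profile_table].
#' @return Character vector, one key per well.
#' @export
plate_key <- function(x) {
  m <- x$metadata
  paste(m$source_id, m$batch_id, m$plate_id, sep = "/")
}

#' @export
dim.profile_table <- function(x) dim(x$features)

#' @export
print.profile_table <- function(x, ...) {
  m <- x$metadata
  cat("profile_table: ", n_wells(x), " wells x ", n_features(x),
      " features\n", sep = "")
  if (n_wells(x) > 0) {
    cat("  sources: ", length(unique(m$source_id)),
        " | batches: ", length(unique(m$batch_id)),
        " | plates: ", length(unique(plate_key(x))),
        " | compounds: ", length(unique(m$compound_id)), "\n", sep = "")
    ct <- table(m$control_type)
    cat("  control types:",
        paste(names(ct), ct, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Row/column subsetting of a profile table
#'
#' @param x A [profile_table].
#' @param i Well (row) index.
#' @param j Feature (column) index or names.
#' @param ... Ignored.
#' @return A [profile_table].
#' @export
`[.profile_table` <- function(x, i, j, ...) {
  f <- x$features
  m <- x$metadata
  if (!missing(i)) {
    f <- f[i, , drop = FALSE]
    m <- m[i, , drop = FALSE]
  }
  if (!missing(j)) f <- f[, j, drop = FALSE]
  profile_table(f, m)
}

#' Subset wells of a profile table by a metadata predicate
#'
#' Filters rows using an expression evaluated in the metadata, in the spirit
#' of [base::subset()]. Features are carried along untouched. An empty result
#' is allowed (with a warning) so that scenario filters can legitimately
#' select nothing.
#'
#' @param x A [profile_table].
#' @param subset Logical expression over metadata columns
#'   (e.g. `control_type == "negative"`).
#' @param ... Ignored.
#' @return A [profile_table] with the selected wells.
#' @examples
#' \dontrun{subset(tab, control_type == "negative")}
#' @export
subset.profile_table <- function(x, subset, ...) {
  e <- substitute(subset)
  keep <- eval(e, x$metadata, parent.frame())
  subset_profiles(x, keep)
}

#' @rdname subset.profile_table
#' @param keep Logical vector of length `n_wells(x)` (NA treated as FALSE).
#' @export
subset_profiles <- function(x, keep) {
  if (!is.logical(keep)) stop("subset predicate must be logical")
  if (length(keep) != n_wells(x)) {
    stop("predicate length ", length(keep), " != number of wells ", n_wells(x))
  }
  keep <- keep & !is.na(keep)
  out <- profile_table(x$features[keep, , drop = FALSE],
                       x$metadata[keep, , drop = FALSE])
  if (n_wells(out) == 0) warning("subset selected no wells")
  out
}

#' Aggregate single-cell features to well-level profiles
#'
#' Population-averaged (pseudo-bulk) profiles are the unit of analysis of the
#' benchmark: each well's profile is the arithmetic mean of the feature
#' vectors of all cells measured in that well.
#'
#' @param cell_features Numeric matrix (cells x features).
#' @param cell_metadata data.frame with one row per cell carrying the well's
#'   metadata (the mandatory [profile_table] columns).
#' @return A [profile_table] with one row per distinct well, in order of
#'   first appearance.
#' @export
aggregate_cells_to_wells <- function(cell_features, cell_metadata) {
  if (is.data.frame(cell_features)) cell_features <- as.matrix(cell_features)
  cell_metadata <- as.data.frame(cell_metadata, stringsAsFactors = FALSE)
  if (nrow(cell_features) != nrow(cell_metadata)) {
    stop("one metadata record required per cell")
  }
  if (nrow(cell_features) == 0) stop("no cells to aggregate")
  addr <- paste(cell_metadata$source_id, cell_metadata$batch_id,
                cell_metadata$plate_id, cell_metadata$well_position,
                sep = "/")
  addr <- factor(addr, levels = unique(addr))
  sums <- rowsum(cell_features, addr, reorder = FALSE)
  counts <- as.vector(table(addr)[levels(addr)])
  means <- sums / counts
  first <- !duplicated(addr)
  profile_table(means, cell_metadata[first, , drop = FALSE])
}
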