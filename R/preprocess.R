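#' Preprocessing parameters
#'
#' Tunable knobs of the four-step baseline pipeline.
#'
#' @param cvar_threshold Features whose robust coefficient of variation on
#'   any plate falls below this value are discarded. Default `1e-3`.
#' @param int_c Blom offset of the rank-based inverse normal transform,
#'   `0 <= c < 0.5`. Default `3/8`.
#' @param corr_threshold Absolute Pearson correlation above which one member
#'   of a feature pair is dropped, `0 < threshold < 1`. Default `0.9`.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(cvar_threshold = 1e-3, int_c = 3 / 8,
                              corr_threshold = 0.9) {
  stopifnot(is.numeric(cvar_threshold), cvar_threshold >= 0)
  if (!(int_c >= 0 && int_c < 0.5)) stop("int_c must be in [0, 0.5)")
  if (!(corr_threshold > 0 && corr_threshold < 1)) {
    stop("corr_threshold must be in (0, 1)")
  }
  structure(list(cvar_threshold = cvar_threshold, int_c = int_c,
                 corr_threshold = corr_threshold),
            class = "preprocess_params")
}

#' Per-plate robust feature statistics from negative controls
#'
#' For every plate and feature, computes the median (location), the raw
#' median absolute deviation (scale, no consistency constant), and the
#' absolute robust coefficient of variation
#' \eqn{C_{var} = | \tilde{\sigma} / \tilde{X} |}, all over that plate's
#' negative-control (DMSO) wells only. `C_var` is defined as 0 when the MAD
#' is 0 and as `Inf` when the median is 0 with positive MAD (such features
#' are never mistaken for low-variation ones).
#'
#' @param x A [profile_table]; every plate must carry at least 2
#'   negative-control wells.
#' @return An object of class `feature_stats`: list with `plates`,
#'   `features`, and plates x features matrices `median`, `mad`, `cvar`.
#' @export
compute_feature_stats <- function(x) {
  validate_profile_table(x)
  pk <- plate_key(x)
  plates <- unique(pk)
  neg <- x$metadata$control_type == "negative"
  p <- n_features(x)
  med <- mad <- matrix(NA_real_, length(plates), p,
                       dimnames = list(plates, feature_names(x)))
  for (pl in plates) {
    idx <- which(pk == pl & neg)
    if (length(idx) < 2) {
      stop("plate '", pl, "' has ", length(idx),
           " negative-control wells (>= 2 required)")
    }
    sub <- x$features[idx, , drop = FALSE]
    m <- matrixStats::colMedians(sub)
    med[pl, ] <- m
    mad[pl, ] <- matrixStats::colMedians(abs(sweep(sub, 2, m)))
  }
  cvar <- abs(mad / med)
  cvar[mad == 0] <- 0
  cvar[mad > 0 & med == 0] <- Inf
  structure(list(plates = plates, features = feature_names(x),
                 median = med, mad = mad, cvar = cvar),
            class = "feature_stats")
}

#' @export
print.feature_stats <- function(x, ...) {
  cat("feature_stats: ", length(x$plates), " plates x ",
      length(x$features), " features (negative-control medians/MADs)\n",
      sep = "")
  invisible(x)
}

stats_for <- function(stats, x) {
  stopifnot(inherits(stats, "feature_stats"))
  plates <- unique(plate_key(x))
  miss_p <- setdiff(plates, stats$plates)
  if (length(miss_p) > 0) {
    stop("feature_stats missing plate(s): ", paste(miss_p, collapse = ", "))
  }
  miss_f <- setdiff(feature_names(x), stats$features)
  if (length(miss_f) > 0) {
    stop("feature_stats missing feature(s): ",
         paste(utils::head(miss_f, 5), collapse = ", "))
  }
  stats
}

#' Remove low-variation features
#'
#' A feature is discarded iff its `C_var` falls below `cvar_threshold` on at
#' least one plate ("any" quantifier), so a feature that is constant on a
#' single plate is removed everywhere. Feature order is otherwise preserved.
#'
#' @param x A [profile_table].
#' @param stats Optional precomputed [compute_feature_stats()] result.
#' @param params A [preprocess_params()] list.
#' @return A [profile_table] with the surviving features.
#' @export
filter_low_variance <- function(x, stats = NULL,
                                params = preprocess_params()) {
  if (is.null(stats)) stats <- compute_feature_stats(x)
  stats <- stats_for(stats, x)
  cv <- stats$cvar[unique(plate_key(x)), feature_names(x), drop = FALSE]
  drop <- matrixStats::colAnys(cv < params$cvar_threshold)
  if (all(drop)) stop("all features removed by variance filtering")
  x[, !drop]
}

#' Plate-wise robust (MAD) normalization
#'
#' Every well on a plate is transformed feature-wise with that plate's
#' negative-control median and MAD:
#' \eqn{\hat{X}_i = (X_i - \tilde{X}) / \tilde{\sigma}}. Afterwards the
#' negative controls of each plate have median 0 and MAD 1 per feature.
#'
#' @inheritParams filter_low_variance
#' @return A [profile_table] of normalized features.
#' @export
mad_normalize <- function(x, stats = NULL) {
  if (is.null(stats)) stats <- compute_feature_stats(x)
  stats <- stats_for(stats, x)
  pk <- plate_key(x)
  fn <- feature_names(x)
  if (any(stats$mad[unique(pk), fn] == 0)) {
    stop("zero MAD encountered; run filter_low_variance() first")
  }
  out <- x$features
  for (pl in unique(pk)) {
    idx <- pk == pl
    out[idx, ] <- sweep(sweep(out[idx, , drop = FALSE], 2,
                              stats$median[pl, fn]),
                        2, stats$mad[pl, fn], "/")
  }
  profile_table(out, x$metadata)
}

#' Rank-based inverse normal transform (Blom scores)
#'
#' Maps a vector to normal quantiles of its ranks,
#' \eqn{Y_i = \Phi^{-1}\left(\frac{r_i - c}{N - 2c + 1}\right)},
#' with offset `c = 3/8` by default. Ties receive average (mid-) ranks.
#' For distinct inputs the transform is strictly monotone, and negating the
#' input negates the output.
#'
#' @param values Finite numeric vector, length `N >= 1`.
#' @param c Blom offset in `[0, 0.5)`.
#' @return Numeric vector of the same length.
#' @export
inverse_normal_transform <- function(values, c = 3 / 8) {
  if (length(values) < 1) stop("need at least one value")
  if (!all(is.finite(values))) stop("values must be finite")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - c) / (n - 2 * c + 1))
}

#' Apply the inverse normal transform feature-wise
#'
#' Each feature is transformed jointly over all wells of the table (a single
#' `N` per feature); plate-level location/scale differences are assumed to be
#' already handled by [mad_normalize()].
#'
#' @param x A [profile_table].
#' @param c Blom offset.
#' @return A [profile_table].
#' @export
int_transform <- function(x, c = 3 / 8) {
  profile_table(apply(x$features, 2, inverse_normal_transform, c = c),
                x$metadata)
}

#' Correlation-threshold feature selection
#'
#' Iteratively removes redundant features: while any pair of surviving
#' features has absolute Pearson correlation above the threshold, the member
#' involved in a violating pair that shows the largest total absolute
#' correlation with all current features is dropped. The procedure is
#' idempotent and guarantees no surviving pair exceeds the threshold.
#'
#' @inheritParams filter_low_variance
#' @return A [profile_table] with the surviving features, original order.
#' @export
select_features_correlation <- function(x, params = preprocess_params()) {
  if (n_features(x) < 2) stop("need at least 2 features")
  sds <- matrixStats::colSds(x$features)
  if (any(sds == 0)) {
    stop("zero-variance feature(s) at selection stage: ",
         paste(utils::head(feature_names(x)[sds == 0], 5), collapse = ", "))
  }
  cm <- abs(stats::cor(x$features))
  diag(cm) <- 0
  keep <- seq_len(ncol(cm))
  repeat {
    viol <- which(cm > params$corr_threshold, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    involved <- unique(as.vector(viol))
    tot <- colSums(cm)
    worst <- involved[which.max(tot[involved])]
    cm <- cm[-worst, -worst, drop = FALSE]
    keep <- keep[-worst]
  }
  x[, keep]
}

#' The four-step baseline preprocessing pipeline
#'
#' Composes, in order: low-variance feature removal, plate-wise MAD
#' normalization on negative controls, rank-based inverse normal transform,
#' and correlation-threshold feature selection. The result is the "Baseline"
#' representation that every batch-correction method receives (and that also
#' serves as the no-correction reference).
#'
#' @param x A raw well-level [profile_table].
#' @param params A [preprocess_params()] list.
#' @return A preprocessed [profile_table].
#' @export
run_baseline <- function(x, params = preprocess_params()) {
  stats <- compute_feature_stats(x)
  x <- filter_low_variance(x, stats, params)
  x <- mad_normalize(x, stats)
  x <- int_transform(x, c = params$int_c)
  select_features_correlation(x, params)
}
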