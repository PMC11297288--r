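#' Batch design of a profile table
#'
#' Extracts and validates the per-well batch labels used by label-aware
#' correction methods.
#'
#' @param x A [profile_table].
#' @param batch_key Metadata column holding the batch variable
#'   (e.g. `"batch_id"` or `"source_id"`).
#' @return List of class `batch_design` with `labels` (character vector) and
#'   `n_batches`.
#' @export
batch_design <- function(x, batch_key = "batch_id") {
  if (!batch_key %in% names(x$metadata)) {
    stop("unknown batch key: ", batch_key)
  }
  labels <- as.character(x$metadata[[batch_key]])
  if (length(labels) == 0 || anyNA(labels) || any(labels == "")) {
    stop("every well must carry a non-empty batch label under '",
         batch_key, "'")
  }
  structure(list(labels = labels, n_batches = length(unique(labels)),
                 batch_key = batch_key),
            class = "batch_design")
}

#' The no-correction reference
#'
#' Returns the preprocessed representation unchanged; every correction
#' method is compared against this baseline. Batch labels are still
#' validated so that misconfigured scenarios fail early.
#'
#' @inheritParams batch_design
#' @return `x`, unchanged (output space: feature).
#' @export
baseline_identity <- function(x, batch_key = "batch_id") {
  batch_design(x, batch_key)
  x
}

#' Fit a sphering (ZCA whitening) correction on negative controls
#'
#' Sphering assumes that negative controls from different batches should look
#' alike, so any covariance structure they exhibit is technical. It computes
#' the ZCA whitening matrix \eqn{W = V (D + \lambda I)^{-1/2} V^T} from the
#' eigendecomposition \eqn{V D V^T} of the negative-control covariance and
#' applies it (after centering on the control mean) to all wells. It is the
#' only built-in method that needs no batch labels.
#'
#' @param x A [profile_table] with at least 2 negative-control wells.
#' @param lambda Nonnegative eigenvalue regularization. With `lambda = 0`
#'   the control covariance must be full rank (more controls than features).
#' @return An object of class `sphering_model` with `predict()` and
#'   `print()` methods.
#' @seealso [predict.sphering_model()]
#' @export
fit_sphering <- function(x, lambda = 1) {
  validate_profile_table(x)
  if (lambda < 0) stop("lambda must be >= 0")
  ctrl <- x$features[x$metadata$control_type == "negative", , drop = FALSE]
  if (nrow(ctrl) < 2) stop("need >= 2 negative-control wells")
  mu <- colMeans(ctrl)
  S <- stats::cov(ctrl)
  eig <- eigen(S, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  if (lambda == 0 && min(d) < 1e-10 * max(d, 1e-300)) {
    stop("negative-control covariance is (near-)singular with lambda = 0; ",
         "supply lambda > 0 or more control wells")
  }
  W <- eig$vectors %*% (t(eig$vectors) / sqrt(d + lambda))
  structure(list(method_name = "sphering", center = mu, W = W,
                 lambda = lambda, eigenvalues = d,
                 feature_names = feature_names(x),
                 n_controls = nrow(ctrl), output_space = "feature"),
            class = c("sphering_model", "correction_model"))
}

#' Apply a fitted sphering model
#'
#' @param object A [fit_sphering()] model.
#' @param newdata A [profile_table] with the model's features.
#' @param ... Ignored.
#' @return A [profile_table] of whitened features.
#' @export
predict.sphering_model <- function(object, newdata, ...) {
  if (!identical(feature_names(newdata), object$feature_names)) {
    stop("newdata features do not match the fitted sphering model")
  }
  f <- sweep(newdata$features, 2, object$center) %*% object$W
  colnames(f) <- object$feature_names
  profile_table(f, newdata$metadata)
}

#' @export
print.sphering_model <- function(x, ...) {
  cat("sphering_model: ZCA whitening on ", x$n_controls,
      " negative controls, ", length(x$feature_names),
      " features, lambda = ", format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Sphering correction (fit + apply)
#'
#' @inheritParams fit_sphering
#' @param batch_key Ignored (sphering needs no batch labels); accepted for
#'   contract uniformity.
#' @return A [profile_table].
#' @export
sphering_correct <- function(x, batch_key = "batch_id", lambda = 1) {
  predict(fit_sphering(x, lambda = lambda), x)
}

#' ComBat batch correction
#'
#' Models batch effects as additive and multiplicative per-feature noise and
#' removes empirical-Bayes shrunken per-batch location/scale estimates,
#' restoring the grand location/scale. Delegates to the canonical
#' implementation in the sva package.
#'
#' @inheritParams batch_design
#' @param parametric Use the parametric form of the empirical-Bayes priors.
#' @return A [profile_table] (output space: feature).
#' @export
combat_correct <- function(x, batch_key = "batch_id", parametric = TRUE) {
  design <- batch_design(x, batch_key)
  if (design$n_batches < 2) stop("ComBat requires >= 2 batches")
  sizes <- table(design$labels)
  if (any(sizes < 2)) {
    stop("batch(es) with a single well: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (any(matrixStats::colVars(x$features) == 0)) {
    stop("zero-variance feature(s); filter before ComBat")
  }
  dat <- t(x$features)
  corrected <- suppressMessages(
    sva::ComBat(dat = dat, batch = factor(design$labels), mod = NULL,
                par.prior = parametric)
  )
  profile_table(t(corrected), x$metadata)
}

#' Mutual nearest neighbours (MNN) batch correction
#'
#' Assumes batch effects are orthogonal to biology: wells of the same
#' biological state in two batches are mutual nearest neighbours across the
#' batch boundary, and the displacement between such pairs estimates the
#' batch effect. Batches are merged sequentially onto a reference (largest
#' first, which stabilizes the reference); for each incoming batch, mutual
#' k-nearest-neighbour pairs define per-pair correction vectors that are
#' smoothed over the batch's wells with a Gaussian kernel before being
#' applied.
#'
#' @inheritParams batch_design
#' @param k Neighbour count used on both sides of the mutual search; every
#'   batch must contain at least `k` wells.
#' @param sigma Gaussian smoothing bandwidth in feature-space distance units.
#'   `NULL` (default) uses the median distance between the incoming batch's
#'   wells and the paired anchor wells, a broad bandwidth that regularizes
#'   the per-pair vectors toward the batch-level consensus correction.
#' @return A [profile_table] in the original well order (output space:
#'   feature).
#' @export
mnn_correct <- function(x, batch_key = "batch_id", k = 20, sigma = NULL) {
  design <- batch_design(x, batch_key)
  if (design$n_batches < 2) stop("MNN requires >= 2 batches")
  if (k < 1) stop("k must be >= 1")
  sizes <- sort(table(design$labels), decreasing = TRUE)
  if (min(sizes) < k) {
    stop("k = ", k, " exceeds the smallest batch (",
         names(sizes)[length(sizes)], ", ", min(sizes), " wells)")
  }
  feats <- x$features
  order_b <- names(sizes)
  ref_idx <- which(design$labels == order_b[1])
  corrected <- feats
  for (b in order_b[-1]) {
    new_idx <- which(design$labels == b)
    ref <- corrected[ref_idx, , drop = FALSE]
    new <- corrected[new_idx, , drop = FALSE]
    kk <- min(k, nrow(ref), nrow(new))
    nn_rn <- FNN::get.knnx(new, ref, k = kk)$nn.index  # for each ref well
    nn_nr <- FNN::get.knnx(ref, new, k = kk)$nn.index  # for each new well
    pairs <- mutual_pairs(nn_rn, nn_nr)
    if (nrow(pairs) == 0) {
      stop("no mutual nearest neighbours between reference and batch '",
           b, "'")
    }
    vecs <- ref[pairs[, 1], , drop = FALSE] - new[pairs[, 2], , drop = FALSE]
    anchors <- new[pairs[, 2], , drop = FALSE]
    d2 <- outer(rowSums(new^2), rowSums(anchors^2), "+") -
      2 * new %*% t(anchors)
    d2[d2 < 0] <- 0
    sig <- if (is.null(sigma)) stats::median(sqrt(d2)) else sigma
    sig <- max(sig, 1e-8)
    w <- exp(-d2 / (2 * sig^2))
    # guard against all-zero rows when anchors are very far away
    w <- w / pmax(rowSums(w), 1e-300)
    corrected[new_idx, ] <- new + w %*% vecs
    ref_idx <- c(ref_idx, new_idx)
  }
  profile_table(corrected, x$metadata)
}

mutual_pairs <- function(nn_rn, nn_nr) {
  # nn_rn: ref x k indices into new; nn_nr: new x k indices into ref
  r_edges <- cbind(rep(seq_len(nrow(nn_rn)), ncol(nn_rn)),
                   as.vector(nn_rn))
  n_edges <- cbind(as.vector(nn_nr),
                   rep(seq_len(nrow(nn_nr)), ncol(nn_nr)))
  key_r <- paste(r_edges[, 1], r_edges[, 2])
  key_n <- paste(n_edges[, 1], n_edges[, 2])
  r_edges[key_r %in% key_n, , drop = FALSE]
}

#' Harmony-style iterative cluster-based correction ("harmony_lite")
#'
#' A faithful-in-spirit, desk-scale rendition of the Harmony idea rather
#' than a line-by-line port: in a PCA embedding, soft k-means clustering
#' with a batch-diversity penalty alternates with a linear per-cluster,
#' per-batch centroid correction, until the correction magnitude stabilizes.
#' Clustering distances use cosine geometry (rows L2-normalized), as in
#' Harmony; corrections are applied in the raw embedding.
#'
#' @inheritParams batch_design
#' @param n_clusters Number of soft clusters; default
#'   `max(2, min(20, floor(n/30)))`.
#' @param theta Diversity penalty; `0` disables batch awareness.
#' @param n_pcs Dimensionality of the PCA embedding.
#' @param sigma Soft k-means bandwidth on cosine distances.
#' @param max_iter Maximum outer iterations; non-convergence returns the last
#'   iterate with a warning.
#' @param tol Convergence threshold on the relative change of the applied
#'   correction.
#' @param seed RNG seed (k-means initialization).
#' @return A [profile_table] whose "features" are the corrected embedding
#'   coordinates (output space: embedding).
#' @export
harmony_lite <- function(x, batch_key = "batch_id", n_clusters = NULL,
                         theta = 2, n_pcs = 20, sigma = 0.1,
                         max_iter = 20, tol = 1e-3, seed = 1) {
  design <- batch_design(x, batch_key)
  n <- n_wells(x)
  if (is.null(n_clusters)) n_clusters <- max(2, min(20, floor(n / 30)))
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  d <- min(n_pcs, n_features(x), n - 1)
  Z <- stats::prcomp(x$features, center = TRUE, scale. = FALSE)$x[,
    seq_len(d), drop = FALSE]
  batch <- factor(design$labels)
  B <- nlevels(batch)
  pi_b <- as.vector(table(batch)) / n
  onehot <- stats::model.matrix(~ 0 + batch)
  old_seed <- save_rng()
  on.exit(restore_rng(old_seed))
  set.seed(seed)
  Y0 <- l2_normalize(Z)
  centers <- stats::kmeans(Y0, centers = min(n_clusters, n - 1),
                           nstart = 5, iter.max = 50)$centers
  Zc <- Z
  prev_mag <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Y <- l2_normalize(Zc)
    mu <- l2_normalize(centers)
    # soft assignment with diversity penalty (E/O)^theta for each well's batch
    R <- exp(tcrossprod(Y, mu) / sigma)          # n x K, cosine affinity
    if (theta > 0 && B > 1) {
      O <- crossprod(onehot, R)                  # B x K observed soft counts
      E <- pi_b %o% colSums(R)                   # B x K expected under mixing
      pen <- ((E + 1) / (O + 1))^theta          # B x K
      R <- R * pen[as.integer(batch), , drop = FALSE]
    }
    R <- R / pmax(rowSums(R), 1e-300)
    Rsum <- colSums(R)
    centers <- crossprod(R, Zc) / pmax(Rsum, 1e-300)
    # per-cluster per-batch linear correction
    corr <- matrix(0, n, d)
    for (kk in seq_len(nrow(centers))) {
      rk <- R[, kk]
      mk <- colSums(Zc * rk) / max(sum(rk), 1e-300)
      for (bb in levels(batch)) {
        ib <- batch == bb
        wb <- rk[ib]
        sb <- sum(wb)
        if (sb < 1e-8) next
        mkb <- colSums(Zc[ib, , drop = FALSE] * wb) / sb
        corr[ib, ] <- corr[ib, ] + outer(wb, mkb - mk)
      }
    }
    Zc <- Zc - corr
    mag <- sqrt(mean(corr^2)) / max(sqrt(mean(Z^2)), 1e-300)
    if (abs(prev_mag - mag) < tol || mag < tol) {
      converged <- TRUE
      break
    }
    prev_mag <- mag
  }
  if (!converged) {
    warning("harmony_lite did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  colnames(Zc) <- paste0("HDIM", seq_len(d))
  out <- profile_table(Zc, x$metadata)
  attr(out, "output_space") <- "embedding"
  out
}

l2_normalize <- function(M) {
  M / pmax(sqrt(rowSums(M^2)), 1e-300)
}

save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(seed) {
  if (!is.null(seed)) {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
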