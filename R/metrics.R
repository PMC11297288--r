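#' @title Integration metrics for corrected profiles
#' @description The benchmark scores each correction with four batch-removal
#' metrics (batch silhouette, graph connectivity, iLISI, kBET) and six
#' bio-conservation metrics (label silhouette, cLISI, Leiden ARI, Leiden
#' NMI, mAP-nonrep, mAP-control), each normalized to `[0, 1]` with 1 best.
#' @name metrics
NULL

metric_result <- function(metric, category, raw, normalized) {
  data.frame(metric = metric, category = category,
             raw_value = raw,
             normalized_value = min(1, max(0, normalized)),
             stringsAsFactors = FALSE)
}

get_labels <- function(x, key) {
  if (!key %in% names(x$metadata)) stop("unknown metadata key: ", key)
  as.character(x$metadata[[key]])
}

metric_rep <- function(x, rep) if (is.null(rep)) x$features else rep

#' Label (compound) average silhouette width
#'
#' Treats the compound as the cluster label; the mean silhouette width over
#' wells measures how compactly replicates group relative to other
#' compounds. Raw value in `[-1, 1]`; normalized as `(raw + 1) / 2`.
#' Labels with a single member are excluded with a warning; wells with
#' undefined silhouette (identical coordinates) contribute 0.
#'
#' @param x A [profile_table].
#' @param label_key Metadata column with the biological label.
#' @param rep Optional representation matrix overriding the features.
#' @return One-row data.frame (see [metrics]).
#' @export
silhouette_label <- function(x, label_key = "compound_id", rep = NULL) {
  M <- metric_rep(x, rep)
  labels <- get_labels(x, label_key)
  counts <- table(labels)
  singletons <- names(counts)[counts < 2]
  if (length(singletons) > 0) {
    warning(length(singletons), " label(s) with a single member excluded ",
            "from silhouette")
    keep <- !labels %in% singletons
    M <- M[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop("need >= 2 labels with >= 2 members")
  s <- silhouette_widths(M, labels)
  raw <- mean(s)
  metric_result("silhouette_label", "bio", raw, (raw + 1) / 2)
}

#' Batch average silhouette width (within label groups)
#'
#' Within each biological label group, the batch is treated as the cluster
#' label and each well scores `1 - |s|`: a well whose neighbourhood mixes
#' batches (silhouette near 0) scores near 1. Per-label means are averaged
#' over labels. Labels present in only one batch are skipped with a warning.
#'
#' @inheritParams silhouette_label
#' @param batch_key Metadata column with the batch variable.
#' @return One-row data.frame (see [metrics]).
#' @export
silhouette_batch <- function(x, batch_key = "batch_id",
                             label_key = "compound_id", rep = NULL) {
  M <- metric_rep(x, rep)
  batch <- get_labels(x, batch_key)
  labels <- get_labels(x, label_key)
  if (length(unique(batch)) < 2) stop("need >= 2 batches")
  per_label <- c()
  skipped <- 0
  for (lab in unique(labels)) {
    idx <- labels == lab
    b <- batch[idx]
    if (length(unique(b)) < 2 || sum(idx) < 3) {
      skipped <- skipped + 1
      next
    }
    s <- silhouette_widths(M[idx, , drop = FALSE], b)
    per_label <- c(per_label, mean(1 - abs(s)))
  }
  if (skipped > 0) {
    warning(skipped, " label(s) present in a single batch (or too small) ",
            "skipped in batch silhouette")
  }
  if (length(per_label) == 0) stop("no label spans >= 2 batches")
  raw <- mean(per_label)
  metric_result("silhouette_batch", "batch", raw, raw)
}

silhouette_widths <- function(M, labels) {
  cl <- as.integer(factor(labels))
  sil <- cluster::silhouette(cl, stats::dist(M))
  s <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(cl))
  s[!is.finite(s)] <- 0  # degenerate (identical coordinates) convention
  s
}

#' Graph connectivity
#'
#' For each biological label, the fraction of its wells contained in the
#' largest connected component of the label-induced subgraph of the kNN
#' graph. If batch effects are removed, replicates of a compound sit close
#' together and each label's subgraph is a single component (score 1).
#' Labels of size 1 contribute 1.
#'
#' @param graph A [build_knn_graph()] result.
#' @param labels Character vector of per-well labels (or a [profile_table]
#'   plus `label_key`).
#' @param label_key Used when `labels` is a [profile_table].
#' @return One-row data.frame (see [metrics]).
#' @export
graph_connectivity <- function(graph, labels, label_key = "compound_id") {
  if (inherits(labels, "profile_table")) {
    labels <- get_labels(labels, label_key)
  }
  stopifnot(inherits(graph, "knn_graph"), length(labels) == graph$n)
  g <- knn_igraph(graph)
  fracs <- vapply(unique(labels), function(lab) {
    idx <- which(labels == lab)
    if (length(idx) == 1) return(1)
    sub <- igraph::induced_subgraph(g, idx)
    max(igraph::components(sub)$csize) / length(idx)
  }, numeric(1))
  raw <- mean(fracs)
  metric_result("graph_connectivity", "batch", raw, raw)
}

#' Local inverse Simpson's index (LISI)
#'
#' Measures the effective number of categories in each well's local
#' neighbourhood, with Gaussian kernel weights calibrated to a perplexity
#' (as in t-SNE). For the batch variable (iLISI) higher is better; raw
#' values in `[1, B]` are normalized as `(raw - 1) / (B - 1)`. For the
#' biological label (cLISI) lower diversity is better; normalized as
#' `(L - raw) / (L - 1)`.
#'
#' @inheritParams silhouette_label
#' @param key Metadata column whose diversity is measured.
#' @param type `"batch"` (iLISI) or `"label"` (cLISI).
#' @param perplexity Neighbourhood size parameter; must be `< n_wells / 3`.
#' @return One-row data.frame (see [metrics]).
#' @export
lisi_score <- function(x, key, type = c("batch", "label"),
                       perplexity = 30, rep = NULL) {
  type <- match.arg(type)
  M <- metric_rep(x, rep)
  g <- factor(get_labels(x, key))
  C <- nlevels(g)
  if (C < 2) stop("LISI undefined for a single category under '", key, "'")
  n <- nrow(M)
  if (perplexity >= n / 3) {
    stop("perplexity must be < n_wells / 3 (= ", n / 3, ")")
  }
  k <- min(n - 1, max(15, ceiling(3 * perplexity)))
  nn <- FNN::get.knn(M, k = k)
  isi <- vapply(seq_len(n), function(i) {
    p <- perplexity_weights(nn$nn.dist[i, ]^2, perplexity)
    pb <- rowsum(p, as.integer(g[nn$nn.index[i, ]]))
    1 / sum(pb^2)
  }, numeric(1))
  raw <- mean(isi)
  if (type == "batch") {
    metric_result("ilisi", "batch", raw, (raw - 1) / (C - 1))
  } else {
    metric_result("clisi", "bio", raw, (C - raw) / (C - 1))
  }
}

perplexity_weights <- function(d2, perplexity, tol = 1e-5, max_iter = 64) {
  # binary search the Gaussian precision so that entropy = log(perplexity)
  target <- log(min(perplexity, length(d2)))
  beta <- 1
  lo <- -Inf
  hi <- Inf
  d2 <- d2 - min(d2)
  for (iter in seq_len(max_iter)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    if (sw == 0) {
      h <- 0
      p <- rep(0, length(d2))
      p[which.min(d2)] <- 1
    } else {
      p <- w / sw
      h <- -sum(ifelse(p > 0, p * log(p), 0))
    }
    if (abs(h - target) < tol) break
    if (h > target) {
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
    }
  }
  p
}

#' k-nearest-neighbour batch effect test (kBET)
#'
#' For each well, a Pearson chi-square test compares the batch composition
#' of its `k0`-neighbourhood (including itself) against the global batch
#' composition; the raw value is the rejection rate at `alpha`, computed per
#' biological label group and averaged over groups, and the score is
#' `1 - rejection rate`. Well-mixed data rejects at roughly the nominal
#' `alpha`; fully separated batches reject everywhere (score 0).
#'
#' @inheritParams silhouette_batch
#' @param k0 Neighbourhood size; default is a quarter of the mean batch size
#'   within the group, capped at 50. Must be at least the number of batches.
#' @param alpha Significance level of the per-well test.
#' @param per_label Compute within label groups then average (default), or
#'   globally when `FALSE`.
#' @return One-row data.frame (see [metrics]).
#' @export
kbet_score <- function(x, batch_key = "batch_id",
                       label_key = "compound_id", k0 = NULL, alpha = 0.05,
                       per_label = TRUE, rep = NULL) {
  M <- metric_rep(x, rep)
  batch <- get_labels(x, batch_key)
  if (length(unique(batch)) < 2) stop("kBET requires >= 2 batches")
  groups <- if (per_label) get_labels(x, label_key) else
    rep("all", nrow(M))
  rates <- c()
  for (gr in unique(groups)) {
    idx <- which(groups == gr)
    b <- factor(batch[idx])
    if (nlevels(b) < 2) next
    nb <- as.vector(table(b))
    ng <- length(idx)
    if (!is.null(k0) && k0 < nlevels(b)) {
      stop("kBET neighbourhood (", k0, ") smaller than the number of ",
           "batches (", nlevels(b), ")")
    }
    kk <- if (is.null(k0)) min(50, max(10, floor(mean(nb) / 4))) else k0
    kk <- min(kk, ng - 1)
    # groups too small to hold a testable neighbourhood are skipped
    if (kk < nlevels(b)) next
    nn <- FNN::get.knn(M[idx, , drop = FALSE], k = kk)$nn.index
    expected <- (kk + 1) * nb / ng
    rej <- vapply(seq_len(ng), function(i) {
      obs <- tabulate(as.integer(b[c(i, nn[i, ])]), nbins = nlevels(b))
      stat <- sum((obs - expected)^2 / expected)
      stats::pchisq(stat, df = nlevels(b) - 1, lower.tail = FALSE) < alpha
    }, logical(1))
    rates <- c(rates, mean(rej))
  }
  if (length(rates) == 0) stop("no group spans >= 2 batches")
  raw <- mean(rates)
  metric_result("kbet", "batch", raw, 1 - raw)
}

#' Leiden clustering agreement (ARI and NMI)
#'
#' Runs Leiden community detection on the kNN graph over a grid of
#' resolutions, selects the resolution maximizing NMI against the biological
#' labels, and reports the ARI and NMI of that clustering. ARI raw values
#' can be slightly negative under the null and are clipped at 0 for the
#' normalized score.
#'
#' @inheritParams silhouette_label
#' @param resolutions Resolution grid scanned.
#' @param k kNN graph neighbour count.
#' @param seed RNG seed (Leiden is stochastic).
#' @return Two-row data.frame: `leiden_ari` and `leiden_nmi` (see
#'   [metrics]).
#' @export
leiden_cluster_scores <- function(x, label_key = "compound_id",
                                  resolutions = c(0.1, 0.25, 0.5, 1, 2),
                                  k = 15, seed = 1, rep = NULL) {
  M <- metric_rep(x, rep)
  labels <- as.integer(factor(get_labels(x, label_key)))
  graph <- build_knn_graph(M, k = min(k, nrow(M) - 1))
  g <- knn_igraph(graph)
  old_seed <- save_rng()
  on.exit(restore_rng(old_seed))
  best <- list(nmi = -Inf, ari = NA_real_, single = TRUE)
  for (res in resolutions) {
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res, n_iterations = 5)
    mem <- igraph::membership(cl)
    single <- length(unique(mem)) == 1
    nmi <- if (single) 0 else igraph::compare(mem, labels, method = "nmi")
    ari <- igraph::compare(mem, labels, method = "adjusted.rand")
    if (nmi > best$nmi) best <- list(nmi = nmi, ari = ari, single = single)
    if (!single) best$any_multi <- TRUE
  }
  if (is.null(best$any_multi)) {
    warning("Leiden produced a single community at every resolution")
  }
  rbind(
    metric_result("leiden_ari", "bio", best$ari, max(0, best$ari)),
    metric_result("leiden_nmi", "bio", best$nmi, best$nmi)
  )
}

#' Average precision of one retrieval query
#'
#' Candidates (positives and negatives) are ranked by descending cosine
#' similarity to the query; average precision accumulates precision at each
#' rank weighted by the recall increment, which equals the mean of precision
#' at the positives' ranks. Ties are broken by stable candidate order.
#'
#' @param query Numeric query vector (nonzero).
#' @param positives Matrix of positive candidate rows (nonzero).
#' @param negatives Matrix of negative candidate rows (nonzero).
#' @param similarity Only `"cosine"` is implemented.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(query, positives, negatives,
                              similarity = "cosine") {
  similarity <- match.arg(similarity)
  positives <- rbind(positives)
  negatives <- rbind(negatives)
  if (nrow(positives) < 1 || nrow(negatives) < 1) {
    stop("need >= 1 positive and >= 1 negative candidate")
  }
  cand <- rbind(positives, negatives)
  if (!all(is.finite(query)) || !all(is.finite(cand))) {
    stop("vectors must be finite")
  }
  norms <- c(sqrt(sum(query^2)), sqrt(rowSums(cand^2)))
  if (any(norms == 0)) stop("zero-norm vector in query or candidates")
  sims <- as.vector(cand %*% query) / (sqrt(sum(query^2)) *
                                         sqrt(rowSums(cand^2)))
  is_pos <- c(rep(TRUE, nrow(positives)), rep(FALSE, nrow(negatives)))
  ap_from_ranking(is_pos[order(-sims)])
}

ap_from_ranking <- function(is_pos_ranked) {
  tp <- cumsum(is_pos_ranked)
  P <- sum(is_pos_ranked)
  sum((tp / seq_along(is_pos_ranked))[is_pos_ranked]) / P
}

#' Replicate-retrieval mean average precision (mAP)
#'
#' Every eligible well serves as a query; the `M - 1` other wells treated
#' with the same compound are the positives, and the negatives are either
#' same-plate wells treated with a different (non-DMSO) compound
#' (`"nonrep"`) or the same plate's negative controls (`"control"`).
#' Rankings use cosine similarity. Per-compound mAP is the mean AP over its
#' replicates and the metric's raw value is the mean over compounds
#' (already in `[0, 1]`).
#'
#' Negative-control wells are not used as queries; compounds with a single
#' replicate are excluded with a warning; in control mode, queries on plates
#' without negative controls are skipped with a warning.
#'
#' @inheritParams silhouette_label
#' @param negatives_mode `"nonrep"` or `"control"`.
#' @return One-row data.frame (see [metrics]).
#' @export
mean_average_precision <- function(x, label_key = "compound_id",
                                   negatives_mode = c("nonrep", "control"),
                                   rep = NULL) {
  negatives_mode <- match.arg(negatives_mode)
  M <- metric_rep(x, rep)
  labels <- get_labels(x, label_key)
  ctype <- x$metadata$control_type
  plates <- plate_key(x)
  Mn <- l2_normalize(M)
  counts <- table(labels)
  eligible <- which(ctype != "negative" & counts[labels] >= 2)
  if (any(ctype != "negative" & counts[labels] < 2)) {
    warning("compound(s) with a single replicate excluded from mAP")
  }
  if (length(eligible) == 0) stop("no compound with >= 2 replicates")
  ap <- rep(NA_real_, length(eligible))
  skipped_plates <- FALSE
  for (j in seq_along(eligible)) {
    i <- eligible[j]
    pos <- which(labels == labels[i])
    pos <- pos[pos != i]
    neg <- if (negatives_mode == "nonrep") {
      which(plates == plates[i] & labels != labels[i] & ctype != "negative")
    } else {
      which(plates == plates[i] & ctype == "negative")
    }
    if (length(neg) == 0) {
      skipped_plates <- TRUE
      next
    }
    sims <- as.vector(Mn[c(pos, neg), , drop = FALSE] %*% Mn[i, ])
    is_pos <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
    ap[j] <- ap_from_ranking(is_pos[order(-sims)])
  }
  if (skipped_plates) {
    warning("queries on plates without eligible negatives skipped")
  }
  ok <- !is.na(ap)
  if (!any(ok)) stop("no scorable query")
  per_compound <- tapply(ap[ok], labels[eligible][ok], mean)
  raw <- mean(per_compound)
  metric_result(paste0("map_", negatives_mode), "bio", raw, raw)
}

#' Evaluate the full metric panel on a corrected representation
#'
#' Computes the four batch-removal and six bio-conservation metrics on a
#' method's output. Feature-space outputs are PCA-reduced (default 50
#' components) before the graph-based metrics for parity with
#' embedding-space methods; silhouettes and mAP use the representation
#' as-is.
#'
#' @param x A corrected [profile_table] (possibly with
#'   `attr(, "output_space") = "embedding"`).
#' @param batch_key,label_key Metadata columns for the confounder and the
#'   biological label.
#' @param params A [metric_params()] list.
#' @return data.frame with 10 rows: `metric`, `category`, `raw_value`,
#'   `normalized_value`.
#' @export
evaluate_metrics <- function(x, batch_key = "batch_id",
                             label_key = "compound_id",
                             params = metric_params()) {
  validate_profile_table(x)
  space <- attr(x, "output_space") %||% "feature"
  graph_rep <- x$features
  if (space == "feature" && params$pca_dim > 0 &&
      params$pca_dim < ncol(graph_rep)) {
    d <- min(params$pca_dim, nrow(graph_rep) - 1)
    graph_rep <- stats::prcomp(graph_rep, center = TRUE)$x[, seq_len(d),
                                                           drop = FALSE]
  }
  graph <- build_knn_graph(graph_rep, k = min(params$knn_k,
                                              nrow(graph_rep) - 1))
  res <- rbind(
    silhouette_batch(x, batch_key, label_key),
    graph_connectivity(graph, x, label_key),
    lisi_score(x, batch_key, "batch", params$lisi_perplexity,
               rep = graph_rep),
    kbet_score(x, batch_key, label_key, k0 = params$kbet_k0,
               alpha = params$alpha, per_label = params$kbet_per_label,
               rep = graph_rep),
    silhouette_label(x, label_key),
    lisi_score(x, label_key, "label", params$lisi_perplexity,
               rep = graph_rep),
    leiden_cluster_scores(x, label_key, params$leiden_resolutions,
                          k = params$knn_k, seed = params$seed,
                          rep = graph_rep),
    mean_average_precision(x, label_key, "nonrep"),
    mean_average_precision(x, label_key, "control")
  )
  rownames(res) <- NULL
  res
}

#' Metric parameters
#'
#' @param knn_k kNN graph neighbour count (graph connectivity, Leiden).
#' @param lisi_perplexity LISI perplexity.
#' @param kbet_k0 kBET neighbourhood size (`NULL` = quarter of mean batch
#'   size, capped at 50).
#' @param kbet_per_label Compute kBET within label groups then average.
#' @param leiden_resolutions Leiden resolution grid.
#' @param pca_dim PCA components applied to feature-space outputs before
#'   graph metrics (0 disables).
#' @param alpha kBET significance level.
#' @param seed Seed for stochastic metrics (Leiden).
#' @return A list of class `metric_params`.
#' @export
metric_params <- function(knn_k = 15, lisi_perplexity = 30, kbet_k0 = NULL,
                          kbet_per_label = TRUE,
                          leiden_resolutions = c(0.1, 0.25, 0.5, 1, 2),
                          pca_dim = 50, alpha = 0.05, seed = 1) {
  structure(list(knn_k = knn_k, lisi_perplexity = lisi_perplexity,
                 kbet_k0 = kbet_k0, kbet_per_label = kbet_per_label,
                 leiden_resolutions = leiden_resolutions,
                 pca_dim = pca_dim, alpha = alpha, seed = seed),
            class = "metric_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
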