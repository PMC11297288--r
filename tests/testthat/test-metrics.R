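test_that("knn graph matches the brute-force all-pairs oracle", {
  set.seed(20)
  M <- matrix(rnorm(50 * 10), 50, 10)
  g <- build_knn_graph(M, k = 5)
  D <- as.matrix(stats::dist(M))
  for (i in c(1, 17, 50)) {
    oracle <- order(D[i, -i])[1:5]
    oracle_idx <- seq_len(50)[-i][oracle]
    expect_setequal(g$index[i, ], oracle_idx)
  }
  # collinear points, k = 1: nearest on the line
  line <- cbind(c(0, 1, 3, 10), 0)
  g1 <- build_knn_graph(line, k = 1)
  expect_equal(as.vector(g1$index), c(2, 1, 2, 3))
  expect_error(build_knn_graph(M, k = 50), "smaller than")
})

test_that("label silhouette separates tight clusters and is 0.5 under null", {
  set.seed(21)
  n <- 40
  p <- 5
  f <- rbind(matrix(rnorm(n * p, 0, 0.05), n, p),
             matrix(rnorm(n * p, 8, 0.05), n, p))
  tab <- make_table(f, compound = rep(c("a", "b"), each = n))
  res <- silhouette_label(tab)
  expect_gt(res$normalized_value, 0.95)
  # random labels on one blob: normalized ~ 0.5
  null_tab <- make_table(matrix(rnorm(200 * 6), 200, 6),
                         compound = sample(letters[1:4], 200, TRUE))
  res_null <- silhouette_label(null_tab)
  expect_equal(res_null$normalized_value, 0.5, tolerance = 0.05)
  # identical coordinates: degenerate silhouette -> 0 -> normalized 0.5
  flat <- make_table(matrix(1, 12, 3), compound = rep(c("a", "b"), 6))
  expect_equal(silhouette_label(flat)$normalized_value, 0.5)
  # mirror-image invariance
  mirr <- make_table(-f, compound = rep(c("a", "b"), each = n))
  expect_equal(silhouette_label(mirr)$normalized_value,
               res$normalized_value)
  # singleton labels are excluded with a warning
  tab_s <- make_table(f, compound = c("solo", rep(c("a", "b"), c(n - 1, n))))
  expect_warning(silhouette_label(tab_s), "single member")
})

test_that("batch silhouette scores mixing within compounds", {
  mixed <- two_batch_blobs(n_per_batch = 60, shift = 0, seed = 22)
  expect_gt(silhouette_batch(mixed)$normalized_value, 0.9)
  apart <- two_batch_blobs(n_per_batch = 60, shift = 20, seed = 22)
  expect_lt(silhouette_batch(apart)$normalized_value, 0.1)
  one_batch <- random_table(plates = 1)
  expect_error(silhouette_batch(one_batch), ">= 2 batches")
})

test_that("graph connectivity reflects label components", {
  # tight label clusters: fully connected -> 1
  mixed <- two_batch_blobs(n_per_batch = 30, shift = 0, seed = 23)
  g <- build_knn_graph(mixed, k = 10)
  expect_equal(graph_connectivity(g, mixed)$normalized_value, 1)
  # one label split into two far blobs -> 0.5 for that label
  set.seed(23)
  f <- rbind(matrix(rnorm(10 * 4, 0, 0.1), 10, 4),
             matrix(rnorm(10 * 4, 50, 0.1), 10, 4),
             matrix(rnorm(10 * 4, 100, 0.1), 10, 4))
  tab <- make_table(f, compound = rep(c("split", "split", "whole"),
                                      each = 10))
  gg <- build_knn_graph(tab, k = 3)
  labs <- tab$metadata$compound_id
  res <- graph_connectivity(gg, tab)
  # split label contributes 0.5, whole contributes 1 -> mean 0.75
  expect_equal(res$normalized_value, 0.75)
  # all-singleton labels: every label contributes 1
  sing <- make_table(matrix(rnorm(20), 10, 2),
                     compound = paste0("c", 1:10))
  gs <- build_knn_graph(sing, k = 2)
  expect_equal(graph_connectivity(gs, sing)$normalized_value, 1)
})

test_that("lisi scores diversity of local neighbourhoods", {
  mixed <- two_batch_blobs(n_per_batch = 100, shift = 0, seed = 24)
  # finite perplexity caps attainable iLISI: ~30 effective neighbours give
  # binomial composition noise of ~0.06 on the normalized scale
  il <- lisi_score(mixed, "batch_id", "batch", perplexity = 30)
  expect_gte(il$normalized_value, 0.85)
  il_wide <- lisi_score(mixed, "batch_id", "batch", perplexity = 60)
  expect_gte(il_wide$normalized_value, il$normalized_value - 0.01)
  apart <- two_batch_blobs(n_per_batch = 100, shift = 30, seed = 24)
  il2 <- lisi_score(apart, "batch_id", "batch", perplexity = 30)
  expect_lt(il2$normalized_value, 0.02)
  # compounds in pure tight clusters: cLISI ~ 1
  set.seed(24)
  f <- rbind(matrix(rnorm(40 * 4, 0, 0.05), 40, 4),
             matrix(rnorm(40 * 4, 30, 0.05), 40, 4))
  tabc <- make_table(f, compound = rep(c("a", "b"), each = 40))
  cl <- lisi_score(tabc, "compound_id", "label", perplexity = 20)
  expect_gt(cl$normalized_value, 0.98)
  # batch-label permutation invariance
  perm <- mixed
  relabel <- c(b1 = "x2", b2 = "x1")
  perm$metadata$batch_id <- unname(relabel[perm$metadata$batch_id])
  expect_equal(lisi_score(perm, "batch_id", "batch")$raw_value,
               lisi_score(mixed, "batch_id", "batch")$raw_value)
  expect_error(lisi_score(mixed, "batch_id", "batch", perplexity = 100),
               "perplexity")
  one <- random_table(plates = 1)
  expect_error(lisi_score(one, "batch_id", "batch", perplexity = 2),
               "single category")
})

test_that("kbet rejects when neighbourhoods are batch-pure", {
  mixed <- two_batch_blobs(n_per_batch = 150, shift = 0, n_cmpd = 2,
                           seed = 25)
  kb <- kbet_score(mixed)
  expect_gte(kb$normalized_value, 0.9)
  apart <- two_batch_blobs(n_per_batch = 150, shift = 30, n_cmpd = 2,
                           seed = 25)
  kb2 <- kbet_score(apart)
  expect_lt(kb2$normalized_value, 0.05)
  expect_error(kbet_score(mixed, k0 = 1), "smaller than the number")
  one <- random_table(plates = 1)
  expect_error(kbet_score(one), ">= 2 batches")
})

test_that("leiden scores recover planted clusters and are seeded", {
  set.seed(26)
  n <- 30
  p <- 6
  f <- do.call(rbind, lapply(c(0, 20, 40), function(mu) {
    matrix(rnorm(n * p, mu, 0.3), n, p)
  }))
  tab <- make_table(f, compound = rep(c("a", "b", "c"), each = n))
  res <- leiden_cluster_scores(tab, seed = 2)
  expect_equal(res$normalized_value[res$metric == "leiden_ari"], 1)
  expect_equal(res$normalized_value[res$metric == "leiden_nmi"], 1)
  # identical under the same seed and graph
  res2 <- leiden_cluster_scores(tab, seed = 2)
  expect_identical(res, res2)
  # shuffled labels: ARI near zero (clipped at 0 for the normalized value)
  set.seed(27)
  null_tab <- make_table(matrix(rnorm(120 * 5), 120, 5),
                         compound = sample(c("a", "b", "c"), 120, TRUE))
  res_null <- leiden_cluster_scores(null_tab, seed = 2)
  ari_raw <- res_null$raw_value[res_null$metric == "leiden_ari"]
  expect_lt(abs(ari_raw), 0.06)
  expect_gte(res_null$normalized_value[res_null$metric == "leiden_ari"], 0)
})

test_that("average precision reproduces enumeration oracles", {
  # positives at all top ranks -> AP = 1
  q <- c(1, 0)
  pos <- rbind(c(1, 0.01), c(1, -0.01))
  neg <- rbind(c(-1, 0.2), c(-1, -0.2))
  expect_equal(average_precision(q, pos, neg), 1)
  # 2 positives at ranks 1 and 3 of 4 -> (1 + 2/3)/2 = 5/6
  pos2 <- rbind(c(1, 0), c(0.6, 0.8))
  neg2 <- rbind(c(0.8, 0.6), c(-1, 0))
  expect_equal(average_precision(q, pos2, neg2), 5 / 6)
  # positives ranked last (2 pos, 2 neg) -> (1/3 + 2/4)/2 = 5/12
  pos3 <- rbind(c(-1, 0.1), c(-1, -0.1))
  neg3 <- rbind(c(1, 0.1), c(1, -0.1))
  expect_equal(average_precision(q, pos3, neg3), 5 / 12)
  expect_error(average_precision(c(0, 0), pos, neg), "zero-norm")
})

test_that("map equals hand-enumerated values on a toy plate", {
  # 2 compounds x 2 replicates + 2 DMSO on one plate; identical replicates
  f <- rbind(c(1, 0), c(1, 0.001), c(0, 1), c(0.001, 1),
             c(0.5, 0.5), c(0.45, 0.55))
  colnames(f) <- c("f1", "f2")
  m <- make_meta(6, compound = c("a", "a", "b", "b", "DMSO", "DMSO"),
                 control = c(rep("treatment", 4), rep("negative", 2)))
  tab <- profile_table(f, m)
  res_c <- mean_average_precision(tab, negatives_mode = "control")
  expect_equal(res_c$raw_value, 1)  # replicate always outranks DMSO
  res_n <- mean_average_precision(tab, negatives_mode = "nonrep")
  expect_equal(res_n$raw_value, 1)  # replicate outranks other compound
  # planted inversion: degrade one replicate so DMSO can outrank it,
  # then compare with a per-query enumeration oracle
  f2 <- f
  f2[2, ] <- c(0.4, 0.6)
  tab2 <- profile_table(f2, m)
  res2 <- mean_average_precision(tab2, negatives_mode = "control")
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  ap_query <- function(qi, pos, neg) {
    cand <- c(pos, neg)
    sims <- vapply(cand, function(j) cosv(f2[qi, ], f2[j, ]), numeric(1))
    ap_oracle((cand %in% pos)[order(-sims)])
  }
  expected <- mean(c(
    mean(c(ap_query(1, 2, c(5, 6)), ap_query(2, 1, c(5, 6)))),
    mean(c(ap_query(3, 4, c(5, 6)), ap_query(4, 3, c(5, 6))))
  ))
  expect_equal(res2$raw_value, expected)
  expect_lt(res2$raw_value, 1)
})

test_that("map handles singleton compounds and missing negatives", {
  f <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, paste0("f", 1:3)))
  m <- make_meta(10, compound = c(rep("a", 4), rep("b", 4), "solo", "DMSO"),
                 control = c(rep("treatment", 9), "negative"))
  tab <- profile_table(f, m)
  expect_warning(mean_average_precision(tab, negatives_mode = "nonrep"),
                 "single replicate")
  # control mode without negatives on the plate: all queries skipped
  no_ctrl <- subset(tab, control_type != "negative")
  expect_error(suppressWarnings(
    mean_average_precision(no_ctrl, negatives_mode = "control")),
    "no scorable query")
})

test_that("ap implementation matches recall-increment oracle on rankings", {
  set.seed(30)
  for (i in 1:200) {
    P <- sample(1:5, 1)
    N <- sample(1:10, 1)
    ranking <- sample(c(rep(TRUE, P), rep(FALSE, N)))
    expect_equal(cpbench:::ap_from_ranking(ranking), ap_oracle(ranking),
                 tolerance = 1e-12)
  }
})

test_that("the metric panel returns 10 results in [0,1]", {
  tab <- random_table(plates = 3, n_ctrl = 6, n_treat = 18, n_cmpd = 6,
                      p = 30, seed = 31)
  m <- suppressWarnings(evaluate_metrics(tab, params = metric_params(
    knn_k = 8, lisi_perplexity = 5, pca_dim = 10)))
  expect_equal(nrow(m), 10)
  expect_equal(sum(m$category == "batch"), 4)
  expect_equal(sum(m$category == "bio"), 6)
  expect_true(all(m$normalized_value >= 0 & m$normalized_value <= 1))
})

test_that("batch metrics degrade monotonically with injected effect size", {
  scores <- vapply(c(0, 1, 2.5), function(ms) {
    cfg <- simulation_config(
      n_sources = 2, batches_per_source = 2, wells_per_plate = 36,
      n_compounds = 8, replicates_per_compound = 12,
      n_negative_controls_per_plate = 6, n_positive_controls = 2,
      n_features = 60, batch_additive_scale = 0.2,
      batch_multiplicative_scale = ms, seed = 42)
    tab <- run_baseline(simulate_profiles(cfg)$table)
    m <- suppressWarnings(evaluate_metrics(tab, params = metric_params(
      lisi_perplexity = 15)))
    batch_mean_score(m)
  }, numeric(1))
  expect_true(all(diff(scores) < 0.02))  # nonincreasing within tolerance
  expect_lt(scores[3], scores[1])
})
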