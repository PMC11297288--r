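test_that("feature stats reproduce hand-computed robust statistics", {
  # controls [1,2,3,4,100]: median 3, MAD (raw) 1, C_var 1/3
  f <- cbind(f1 = c(1, 2, 3, 4, 100, 7),
             f2 = c(5, 5, 5, 5, 5, 9),      # constant controls -> C_var 0
             f3 = c(-1, 0, 1, 0, -1, 2))    # median 0, MAD > 0 -> C_var Inf
  m <- make_meta(6)
  m$control_type <- c(rep("negative", 5), "treatment")
  st <- compute_feature_stats(profile_table(f, m))
  expect_equal(unname(st$median[1, ]), c(3, 5, 0))
  expect_equal(unname(st$mad[1, ]), c(1, 0, 1))
  expect_equal(unname(st$cvar[1, ]), c(1 / 3, 0, Inf))

  m2 <- make_meta(3, control = "treatment")
  expect_error(compute_feature_stats(profile_table(f[1:3, ], m2)),
               "negative-control")
})

test_that("low-variance filter uses the any-plate quantifier", {
  set.seed(2)
  tab <- random_table(plates = 2, n_ctrl = 5, n_treat = 5, p = 4)
  # plant a feature constant on plate 2 controls only
  idx_p2_ctrl <- tab$metadata$plate_id == "p2" &
    tab$metadata$control_type == "negative"
  tab$features[idx_p2_ctrl, 3] <- 42
  st <- compute_feature_stats(tab)
  out <- filter_low_variance(tab, st)
  expect_equal(feature_names(out), c("f001", "f002", "f004"))
  # brute-force oracle over plates x features
  keep_oracle <- apply(st$cvar >= 1e-3, 2, all)
  expect_equal(feature_names(out), names(keep_oracle)[keep_oracle])
  # nothing filtered when all C_var clear the threshold
  out2 <- filter_low_variance(tab[, c(1, 2, 4)], st)
  expect_identical(out2$features, tab$features[, c(1, 2, 4)])
  tab$features[, ] <- 1
  expect_error(filter_low_variance(tab, compute_feature_stats(tab)),
               "all features")
})

test_that("MAD normalization centers and scales by plate controls", {
  # plate controls [1,2,3]: treated 5 -> (5-2)/1 = 3; control median -> 0
  f <- cbind(f1 = c(1, 2, 3, 5, 2))
  m <- make_meta(5)
  m$control_type <- c("negative", "negative", "negative", "treatment",
                      "treatment")
  out <- mad_normalize(profile_table(f, m))
  expect_equal(unname(out$features[4, 1]), 3)
  expect_equal(unname(out$features[5, 1]), 0)

  # randomized fixture: post-hoc control median 0 and MAD 1 per plate
  tab <- random_table(plates = 3, n_ctrl = 7, n_treat = 9, p = 5, seed = 9)
  norm <- mad_normalize(tab)
  for (pl in unique(plate_key(norm))) {
    ctrl <- norm$features[plate_key(norm) == pl &
                            norm$metadata$control_type == "negative", ]
    expect_equal(unname(matrixStats::colMedians(ctrl)), rep(0, 5),
                 tolerance = 1e-12)
    med <- matrixStats::colMedians(ctrl)
    expect_equal(unname(matrixStats::colMedians(abs(sweep(ctrl, 2, med)))),
                 rep(1, 5), tolerance = 1e-12)
  }
  # affine equivariance: shifting a plate shifts nothing after recentring
  shifted <- tab
  idx <- plate_key(tab) == unique(plate_key(tab))[1]
  shifted$features[idx, ] <- shifted$features[idx, ] + 100
  expect_equal(mad_normalize(shifted)$features, norm$features,
               tolerance = 1e-9)

  f0 <- cbind(f1 = c(1, 1, 1, 4))
  m0 <- make_meta(4)
  m0$control_type <- c(rep("negative", 3), "treatment")
  expect_error(mad_normalize(profile_table(f0, m0)), "filter_low_variance")
})

test_that("inverse normal transform produces Blom scores", {
  expect_equal(inverse_normal_transform(7), 0)          # N = 1 -> qnorm(1/2)
  expect_equal(inverse_normal_transform(c(9, 4, 17))[1], 0)  # middle rank
  # rank 1 of 3: qnorm((1 - 3/8) / (3 - 3/4 + 1)) via independent oracle
  y <- inverse_normal_transform(c(9, 4, 17))
  expect_equal(y[2], qnorm(0.625 / 3.25), tolerance = 1e-9)
  expect_equal(y[3], qnorm(2.625 / 3.25), tolerance = 1e-9)

  # strict monotonicity and negation symmetry on random vectors
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(37)
    out <- inverse_normal_transform(v)
    expect_equal(order(out), order(v))
    expect_equal(inverse_normal_transform(-v), -out, tolerance = 1e-12)
  }
  # ties get mid-ranks: equal values map to equal scores
  out_t <- inverse_normal_transform(c(1, 1, 5))
  expect_equal(out_t[1], out_t[2])
  expect_error(inverse_normal_transform(c(1, NA)), "finite")
})

test_that("correlation selection drops the highest-total-correlation member", {
  set.seed(4)
  n <- 200
  base <- rnorm(n)
  f <- cbind(a = base + rnorm(n, 0, 0.2),   # corr(a,b) > 0.9
             b = base + rnorm(n, 0, 0.2),
             c = rnorm(n))
  tab <- make_table(f)
  cm <- abs(cor(f))
  diag(cm) <- 0
  expect_gt(cm["a", "b"], 0.9)
  out <- select_features_correlation(tab)
  # greedy oracle: of the violating pair, the larger column sum goes
  drop_oracle <- c("a", "b")[which.max(colSums(cm)[c("a", "b")])]
  expect_setequal(feature_names(out), setdiff(colnames(f), drop_oracle))
  # no surviving pair above the threshold; idempotent
  expect_identical(select_features_correlation(out)$features, out$features)
  # all-below-threshold input is untouched
  set.seed(5)
  indep <- make_table(matrix(rnorm(200 * 4), 200, 4))
  expect_identical(select_features_correlation(indep)$features,
                   indep$features)
  # exact duplicate: exactly one copy removed
  dup <- make_table(cbind(x = base, y = base, z = rnorm(n)))
  out_dup <- select_features_correlation(dup)
  expect_equal(n_features(out_dup), 2)
  expect_true("z" %in% feature_names(out_dup))
  expect_error(select_features_correlation(make_table(cbind(k = rep(1, 5),
                                                            l = 1:5))),
               "zero-variance")
})

test_that("baseline pipeline composes the four stages in order", {
  tab <- random_table(plates = 3, n_ctrl = 6, n_treat = 18, n_cmpd = 6,
                      p = 8, seed = 11)
  # plant a constant feature: must be absent from the output
  tab$features[, 2] <- 5
  params <- preprocess_params()
  out <- run_baseline(tab, params)
  expect_false("f002" %in% feature_names(out))
  # manual composition equals the pipeline
  st <- compute_feature_stats(tab)
  manual <- select_features_correlation(
    int_transform(mad_normalize(filter_low_variance(tab, st, params), st),
                  params$int_c), params)
  expect_identical(out$features, manual$features)
  # post-hoc scan: no surviving pair beyond the correlation threshold
  cm <- abs(cor(out$features))
  diag(cm) <- 0
  expect_lte(max(cm), params$corr_threshold)
})

test_that("baseline keeps i.i.d. features when no structure is planted", {
  set.seed(21)
  tab <- random_table(plates = 2, n_ctrl = 12, n_treat = 36, n_cmpd = 6,
                      p = 20, seed = 21)
  out <- run_baseline(tab)
  expect_equal(n_features(out), 20)
})

test_that("preprocess parameter validation enforces documented ranges", {
  expect_error(preprocess_params(int_c = 0.5), "int_c")
  expect_error(preprocess_params(corr_threshold = 1), "corr_threshold")
  expect_silent(preprocess_params(cvar_threshold = 0))
})
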