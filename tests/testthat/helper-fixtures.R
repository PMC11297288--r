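# Shared fixture builders: tables are always generated in code.

make_meta <- function(n, source = "s1", batch = "b1", plate = "p1",
                      compound = "cmpdA", control = "treatment") {
  data.frame(
    source_id = rep_len(source, n),
    batch_id = rep_len(batch, n),
    plate_id = rep_len(plate, n),
    well_position = sprintf("W%03d", seq_len(n)),
    compound_id = rep_len(compound, n),
    control_type = rep_len(control, n),
    stringsAsFactors = FALSE
  )
}

make_table <- function(features, ...) {
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  profile_table(features, make_meta(nrow(features), ...))
}

# random table with a valid plate/control layout: `plates` plates, each with
# `n_ctrl` DMSO wells and `n_treat` treated wells over `n_cmpd` compounds
random_table <- function(plates = 2, n_ctrl = 4, n_treat = 8, n_cmpd = 4,
                         p = 6, seed = 1, batch_of_plate = NULL) {
  set.seed(seed)
  metas <- lapply(seq_len(plates), function(i) {
    n <- n_ctrl + n_treat
    m <- make_meta(n,
                   batch = if (is.null(batch_of_plate)) paste0("b", i) else
                     batch_of_plate[i],
                   plate = paste0("p", i))
    m$compound_id <- c(rep("DMSO", n_ctrl),
                       paste0("cmpd", rep_len(seq_len(n_cmpd), n_treat)))
    m$control_type <- c(rep("negative", n_ctrl), rep("treatment", n_treat))
    m
  })
  meta <- do.call(rbind, metas)
  f <- matrix(stats::rnorm(nrow(meta) * p), nrow(meta), p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  profile_table(f, meta)
}

# two-batch gaussian mixture used by several metric fixtures: equal batches,
# optional mean shift between batches, `n_cmpd` compound labels assigned
# independently of batch
two_batch_blobs <- function(n_per_batch = 60, p = 10, shift = 0,
                            n_cmpd = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_batch
  f <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  f[seq_len(n_per_batch), ] <- f[seq_len(n_per_batch), ] + shift
  meta <- make_meta(n)
  meta$batch_id <- rep(c("b1", "b2"), each = n_per_batch)
  meta$plate_id <- meta$batch_id
  meta$compound_id <- paste0("cmpd", rep_len(seq_len(n_cmpd), n))
  profile_table(f, meta)
}

# independent AP oracle: explicit recall-increment formula over the ranking
ap_oracle <- function(is_pos_ranked) {
  P <- sum(is_pos_ranked)
  tp <- 0
  r_prev <- 0
  ap <- 0
  for (k in seq_along(is_pos_ranked)) {
    tp <- tp + is_pos_ranked[k]
    r_k <- tp / P
    ap <- ap + (r_k - r_prev) * (tp / k)
    r_prev <- r_k
  }
  ap
}

# exact expectation of AP under a uniformly random ranking
expected_ap_random <- function(P, N) {
  T <- P + N
  k <- seq_len(T)
  sum((1 + (k - 1) * (P - 1) / (T - 1)) / k) / T
}

batch_mean_score <- function(metrics) {
  mean(metrics$normalized_value[metrics$category == "batch"])
}
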