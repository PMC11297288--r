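#' Simulation configuration for hierarchical well-level profiles
#'
#' The generator emulates the hierarchy of multi-site Cell Painting style
#' campaigns: sources (laboratories, each with a microscope type) contain
#' experimental batches, batches contain plates, plates contain wells. Every
#' plate carries DMSO negative controls, each positive-control compound once
#' (so positive controls accumulate one replicate per plate, mirroring the
#' heavy replication of landmark positive controls), and treatment wells
#' cycled over the compound list so replicates spread across plates and
#' batches.
#'
#' The observation model is additive + multiplicative technical noise on a
#' per-compound biological signal:
#' `observed = biology * batch_multiplicative * microscope_gain +
#'  batch_additive + well_noise`, with all random draws Gaussian
#' (multiplicative factors and microscope gains log-normal around 1).
#' Per-batch effect vectors are constant within a batch, making the batch
#' the true confounder level. The multiplicative terms are response gains
#' acting on the biological signal: batches and imaging systems differ in
#' how strongly they express each feature. Additive offsets are fully
#' visible on (biologically null) negative controls and are therefore
#' removed by plate-wise control normalization, whereas response gains
#' cannot be estimated from controls and persist into the preprocessed
#' representation -- they are what the batch-correction methods compete
#' on.
#'
#' @param n_features Number of morphological features.
#' @param n_sources Number of data-producing sources (laboratories).
#' @param microscope_types Character vector recycled over sources.
#' @param batches_per_source,plates_per_batch,wells_per_plate Layout counts.
#' @param n_compounds Number of treatment compounds.
#' @param replicates_per_compound Treatment replicates per compound; the
#'   total demand must fit the treatment capacity of the layout.
#' @param n_negative_controls_per_plate DMSO wells per plate (>= 2).
#' @param n_positive_controls Distinct positive-control compounds, each
#'   appearing once per plate.
#' @param compound_effect_scale,positive_effect_scale SD of per-compound
#'   biological effect vectors (positives are drawn with the larger scale,
#'   reflecting their deliberately strong phenotypes).
#' @param batch_additive_scale SD of per-batch additive effect vectors.
#' @param batch_multiplicative_scale SD (log scale) of per-batch
#'   multiplicative factors.
#' @param microscope_effect_scale SD (log scale) of per-microscope-type
#'   feature gains.
#' @param well_noise_scale SD of i.i.d. per-well noise.
#' @param heavy_tails Draw well noise from a scaled t(3) instead of a
#'   Gaussian (robustness stress variant).
#' @param seed RNG seed; the generator is deterministic given the config.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 300,
                              n_sources = 1,
                              microscope_types = "scope_A",
                              batches_per_source = 3,
                              plates_per_batch = 1,
                              wells_per_plate = 48,
                              n_compounds = 12,
                              replicates_per_compound = 9,
                              n_negative_controls_per_plate = 8,
                              n_positive_controls = 4,
                              compound_effect_scale = 1,
                              positive_effect_scale = 3,
                              batch_additive_scale = 0.3,
                              batch_multiplicative_scale = 0.05,
                              microscope_effect_scale = 0,
                              well_noise_scale = 0.5,
                              heavy_tails = FALSE,
                              seed = 1) {
  cfg <- list(n_features = n_features, n_sources = n_sources,
              microscope_types = microscope_types,
              batches_per_source = batches_per_source,
              plates_per_batch = plates_per_batch,
              wells_per_plate = wells_per_plate,
              n_compounds = n_compounds,
              replicates_per_compound = replicates_per_compound,
              n_negative_controls_per_plate = n_negative_controls_per_plate,
              n_positive_controls = n_positive_controls,
              compound_effect_scale = compound_effect_scale,
              positive_effect_scale = positive_effect_scale,
              batch_additive_scale = batch_additive_scale,
              batch_multiplicative_scale = batch_multiplicative_scale,
              microscope_effect_scale = microscope_effect_scale,
              well_noise_scale = well_noise_scale,
              heavy_tails = isTRUE(heavy_tails), seed = seed)
  counts <- c("n_features", "n_sources", "batches_per_source",
              "plates_per_batch", "wells_per_plate", "n_compounds",
              "replicates_per_compound", "n_negative_controls_per_plate")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) stop(nm, " must be >= 1")
  }
  if (cfg$n_positive_controls < 0) stop("n_positive_controls must be >= 0")
  if (cfg$n_negative_controls_per_plate < 2) {
    stop("need >= 2 negative controls per plate")
  }
  scales <- c("compound_effect_scale", "positive_effect_scale",
              "batch_additive_scale", "batch_multiplicative_scale",
              "microscope_effect_scale", "well_noise_scale")
  for (nm in scales) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) stop(nm, " must be >= 0")
  }
  slots <- cfg$wells_per_plate - cfg$n_negative_controls_per_plate -
    cfg$n_positive_controls
  if (slots < 1) {
    stop("wells_per_plate leaves no treatment slots after controls")
  }
  n_plates <- cfg$n_sources * cfg$batches_per_source * cfg$plates_per_batch
  if (cfg$n_compounds * cfg$replicates_per_compound > slots * n_plates) {
    stop("replicate demand (", cfg$n_compounds * cfg$replicates_per_compound,
         ") exceeds treatment capacity (", slots * n_plates, ")")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a hierarchical well-level profile table with ground truth
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a [profile_table]) and `truth` (a
#'   `ground_truth` object holding the per-well biology, microscope shift,
#'   batch additive vector, batch multiplicative factor and well noise
#'   matrices, from which the observed table is exactly reconstructible).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  old_seed <- save_rng()
  on.exit(restore_rng(old_seed))
  set.seed(cfg$seed)
  p <- cfg$n_features
  fnames <- sprintf("feat_%03d", seq_len(p))

  cmpd_ids <- sprintf("cmpd_%04d", seq_len(cfg$n_compounds))
  pos_ids <- if (cfg$n_positive_controls > 0) {
    sprintf("poscon_%02d", seq_len(cfg$n_positive_controls))
  } else {
    character(0)
  }
  effects <- rbind(
    matrix(stats::rnorm(cfg$n_compounds * p, 0, cfg$compound_effect_scale),
           ncol = p, dimnames = list(cmpd_ids, fnames)),
    matrix(stats::rnorm(length(pos_ids) * p, 0, cfg$positive_effect_scale),
           ncol = p, dimnames = list(pos_ids, fnames))
  )
  effects <- rbind(effects, DMSO = rep(0, p))

  scopes <- rep_len(cfg$microscope_types, cfg$n_sources)
  scope_gain <- matrix(exp(stats::rnorm(length(unique(scopes)) * p, 0,
                                        cfg$microscope_effect_scale)),
                       ncol = p, dimnames = list(unique(scopes), fnames))

  # plate layout: negatives, positives once each, treatments cycled
  slots <- cfg$wells_per_plate - cfg$n_negative_controls_per_plate -
    cfg$n_positive_controls
  n_plates <- cfg$n_sources * cfg$batches_per_source * cfg$plates_per_batch
  # cycling the compound list spreads replicates across plates and batches;
  # leftover capacity becomes extra DMSO wells
  demand <- rep(cmpd_ids, times = cfg$replicates_per_compound)
  treat_assign <- c(demand, rep("DMSO", slots * n_plates - length(demand)))

  n_cols <- min(12, cfg$wells_per_plate)
  meta <- list()
  rows_bio <- rows_micro <- rows_add <- rows_mult <- list()
  slot_cursor <- 0
  for (s in seq_len(cfg$n_sources)) {
    source_id <- sprintf("source_%d", s)
    for (b in seq_len(cfg$batches_per_source)) {
      batch_id <- sprintf("%s_batch_%d", source_id, b)
      add_b <- stats::rnorm(p, 0, cfg$batch_additive_scale)
      mult_b <- exp(stats::rnorm(p, 0, cfg$batch_multiplicative_scale))
      for (pl in seq_len(cfg$plates_per_batch)) {
        plate_id <- sprintf("%s_plate_%d", batch_id, pl)
        treat <- treat_assign[slot_cursor + seq_len(slots)]
        slot_cursor <- slot_cursor + slots
        compounds <- c(rep("DMSO", cfg$n_negative_controls_per_plate),
                       pos_ids, treat)
        ctype <- c(rep("negative", cfg$n_negative_controls_per_plate),
                   rep("positive", length(pos_ids)),
                   ifelse(treat == "DMSO", "negative", "treatment"))
        ord <- sample.int(length(compounds))
        compounds <- compounds[ord]
        ctype <- ctype[ord]
        idx <- seq_along(compounds) - 1
        pos_str <- paste0(LETTERS[idx %/% n_cols + 1],
                          sprintf("%02d", idx %% n_cols + 1))
        meta[[plate_id]] <- data.frame(
          source_id = source_id, batch_id = batch_id, plate_id = plate_id,
          well_position = pos_str, compound_id = compounds,
          control_type = ctype, microscope_type = scopes[s],
          stringsAsFactors = FALSE)
        nw <- length(compounds)
        rows_bio[[plate_id]] <- effects[compounds, , drop = FALSE]
        rows_micro[[plate_id]] <- scope_gain[rep(scopes[s], nw), ,
                                             drop = FALSE]
        rows_add[[plate_id]] <- matrix(add_b, nw, p, byrow = TRUE)
        rows_mult[[plate_id]] <- matrix(mult_b, nw, p, byrow = TRUE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  bio <- do.call(rbind, rows_bio)
  micro <- do.call(rbind, rows_micro)
  add <- do.call(rbind, rows_add)
  mult <- do.call(rbind, rows_mult)
  dimnames(bio) <- dimnames(micro) <- dimnames(add) <- dimnames(mult) <-
    list(NULL, fnames)
  n <- nrow(metadata)
  noise <- if (cfg$heavy_tails) {
    matrix(stats::rt(n * p, df = 3) * cfg$well_noise_scale / sqrt(3), n, p)
  } else {
    matrix(stats::rnorm(n * p, 0, cfg$well_noise_scale), n, p)
  }
  colnames(noise) <- fnames
  observed <- bio * mult * micro + add + noise
  table <- profile_table(observed, metadata)
  truth <- structure(
    list(biology = bio, microscope_gain = micro, additive = add,
         multiplicative = mult, noise = noise,
         well_address = well_address(table), config = cfg),
    class = "ground_truth")
  list(table = table, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth: ", nrow(x$biology), " wells x ", ncol(x$biology),
      " features (biology + technical components)\n", sep = "")
  invisible(x)
}

#' Oracle correction using simulation ground truth
#'
#' Inverts the injected technical components exactly:
#' `observed - additive - biology * (multiplicative * microscope_gain - 1)`,
#' leaving exactly biology + well noise. It upper-bounds what any
#' correction method can achieve on simulated data and is used to validate
#' the metrics.
#'
#' @param x The [profile_table] produced by [simulate_profiles()] (or a
#'   row-subset of it).
#' @param truth The matching `ground_truth`.
#' @return A corrected [profile_table].
#' @export
oracle_correct <- function(x, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  idx <- match(well_address(x), truth$well_address)
  if (anyNA(idx)) stop("table does not match the supplied ground truth")
  fcols <- match(feature_names(x), colnames(truth$biology))
  if (anyNA(fcols)) stop("table features do not match the ground truth")
  obs <- x$features
  gain <- truth$multiplicative[idx, fcols, drop = FALSE] *
    truth$microscope_gain[idx, fcols, drop = FALSE]
  corrected <- obs - truth$additive[idx, fcols, drop = FALSE] -
    truth$biology[idx, fcols, drop = FALSE] * (gain - 1)
  profile_table(corrected, x$metadata)
}

#' Oracle correction followed by the preprocessing pipeline
#'
#' Plate-wise MAD normalization estimates (and removes) exactly the class
#' of per-batch affine effects the simulator injects, and rescaling each
#' plate by its control MAD reintroduces the inverse gains into
#' already-corrected data; running the standard pipeline after
#' [oracle_correct()] therefore reproduces the baseline identically. The
#' oracle pipeline instead normalizes with pooled negative controls (a
#' single global median/MAD per feature), which is unbiased because
#' oracle-corrected data has no plate effects left, then applies the same
#' INT and feature-selection steps.
#'
#' @param raw The raw simulated [profile_table].
#' @param truth Matching ground truth.
#' @param params A [preprocess_params()] list.
#' @return A preprocessed, oracle-corrected [profile_table].
#' @export
run_oracle_baseline <- function(raw, truth, params = preprocess_params()) {
  stats <- compute_feature_stats(raw)
  x <- filter_low_variance(raw, stats, params)
  x <- oracle_correct(x, truth)
  ctrl <- x$features[x$metadata$control_type == "negative", , drop = FALSE]
  med <- matrixStats::colMedians(ctrl)
  mad <- matrixStats::colMedians(abs(sweep(ctrl, 2, med)))
  if (any(mad == 0)) stop("zero pooled-control MAD after oracle correction")
  f <- sweep(sweep(x$features, 2, med), 2, mad, "/")
  x <- profile_table(f, x$metadata)
  x <- int_transform(x, c = params$int_c)
  select_features_correlation(x, params)
}

#' Desk-scale scenario presets
#'
#' Five presets mirror benchmark scenarios of increasing technical
#' heterogeneity: `s1` one laboratory with several batches, few compounds,
#' many replicates; `s2` three laboratories sharing a microscope type;
#' `s3` three laboratories, many compounds with 1-3 replicates and heavily
#' replicated positive controls; `s4` five laboratories spanning three
#' microscope types, few compounds; `s5` five laboratories, three
#' microscope types, many compounds. Effect scales increase with scenario
#' complexity so the presets bracket easy-to-hard integration regimes.
#'
#' @param name One of `"s1" ... "s5"`.
#' @param seed RNG seed stored in the config.
#' @return A [simulation_config()].
#' @export
scenario_preset <- function(name = c("s1", "s2", "s3", "s4", "s5"),
                            seed = 1) {
  name <- match.arg(name)
  switch(name,
    s1 = simulation_config(
      n_sources = 1, microscope_types = "scope_A",
      batches_per_source = 6, plates_per_batch = 1, wells_per_plate = 48,
      n_compounds = 12, replicates_per_compound = 18,
      n_negative_controls_per_plate = 8, n_positive_controls = 4,
      batch_additive_scale = 0.3, batch_multiplicative_scale = 0.3,
      microscope_effect_scale = 0, seed = seed),
    s2 = simulation_config(
      n_sources = 3, microscope_types = "scope_A",
      batches_per_source = 3, plates_per_batch = 1, wells_per_plate = 48,
      n_compounds = 12, replicates_per_compound = 27,
      n_negative_controls_per_plate = 8, n_positive_controls = 4,
      batch_additive_scale = 0.6, batch_multiplicative_scale = 1.0,
      microscope_effect_scale = 0, seed = seed),
    s3 = simulation_config(
      n_sources = 3, microscope_types = "scope_A",
      batches_per_source = 3, plates_per_batch = 2, wells_per_plate = 48,
      n_compounds = 250, replicates_per_compound = 2,
      n_negative_controls_per_plate = 8, n_positive_controls = 8,
      batch_additive_scale = 0.8, batch_multiplicative_scale = 1.1,
      microscope_effect_scale = 0, seed = seed),
    s4 = simulation_config(
      n_sources = 5,
      microscope_types = c("scope_A", "scope_A", "scope_A",
                           "scope_B", "scope_C"),
      batches_per_source = 2, plates_per_batch = 1, wells_per_plate = 48,
      n_compounds = 12, replicates_per_compound = 30,
      n_negative_controls_per_plate = 8, n_positive_controls = 4,
      batch_additive_scale = 1.0, batch_multiplicative_scale = 1.2,
      microscope_effect_scale = 0.6, seed = seed),
    s5 = simulation_config(
      n_sources = 5,
      microscope_types = c("scope_A", "scope_A", "scope_A",
                           "scope_B", "scope_C"),
      batches_per_source = 2, plates_per_batch = 2, wells_per_plate = 48,
      n_compounds = 300, replicates_per_compound = 2,
      n_negative_controls_per_plate = 8, n_positive_controls = 8,
      batch_additive_scale = 1.2, batch_multiplicative_scale = 1.3,
      microscope_effect_scale = 0.6, seed = seed)
  )
}
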