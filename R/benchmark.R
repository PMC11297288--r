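#' Scenario configuration
#'
#' One config fully determines a benchmark run: the input (a
#' [profile_table], a simulator preset name, or a file path), the batch and
#' label variables, the method list with per-method parameters, metric
#' parameters, and the category weights of the overall score.
#'
#' @param input A [profile_table], a preset name (`"s1"`..`"s5"`), or a
#'   path readable by [read_profiles()].
#' @param batch_key,label_key Metadata columns for the confounder and the
#'   biological label.
#' @param methods Named list: method name -> list of extra parameters
#'   passed to the registered method (may be empty lists). `"oracle"` is
#'   available when the input is a simulator preset.
#' @param metric_params A [metric_params()] list.
#' @param weights Numeric `c(batch = , bio = )` summing to 1; the overall
#'   score is `w_batch * mean(batch metrics) + w_bio * mean(bio metrics)`.
#' @param preprocess Run the four-step baseline pipeline on the input first.
#' @param preprocess_params A [preprocess_params()] list.
#' @param seed Seed forwarded to the simulator and the methods.
#' @param name Scenario name used in reports.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(input, batch_key = "batch_id",
                            label_key = "compound_id",
                            methods = list(baseline = list()),
                            metric_params = NULL,
                            weights = c(batch = 0.4, bio = 0.6),
                            preprocess = TRUE,
                            preprocess_params = NULL,
                            seed = 1, name = "scenario") {
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("`methods` must be a named list")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (!all(c("batch", "bio") %in% names(weights))) {
    stop("weights must be named c(batch = , bio = )")
  }
  # namespaced: the argument names shadow the constructor functions here
  if (is.null(metric_params)) metric_params <- cpbench::metric_params()
  if (is.null(preprocess_params)) {
    preprocess_params <- cpbench::preprocess_params()
  }
  structure(list(input = input, batch_key = batch_key,
                 label_key = label_key, methods = methods,
                 metric_params = metric_params, weights = weights,
                 preprocess = preprocess,
                 preprocess_params = preprocess_params,
                 seed = seed, name = name),
            class = "scenario_config")
}

#' Run a benchmark scenario
#'
#' Resolves the input (simulating if a preset name was given), preprocesses
#' it with the baseline pipeline, applies every configured correction
#' method, evaluates the 10-metric panel on each method's output
#' representation, and aggregates weighted scores. A method that errors
#' mid-run is recorded as failed without aborting the others. The returned
#' manifest (seed, parameters, package version) makes the run reproducible.
#'
#' The `"oracle"` pseudo-method subtracts the simulator's injected technical
#' components from the raw table and then preprocesses; it is only
#' available for simulated inputs and upper-bounds attainable performance.
#'
#' @param config A [scenario_config()].
#' @return Object of class `benchmark_report`: list with `metrics` (tidy
#'   data.frame), `scores` (per-method batch/bio/overall + rank), `failed`
#'   (named character vector of error messages), `manifest`, `name`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  truth <- NULL
  input <- config$input
  if (is.character(input) && length(input) == 1) {
    if (input %in% c("s1", "s2", "s3", "s4", "s5")) {
      sim <- simulate_profiles(scenario_preset(input, seed = config$seed))
      raw <- sim$table
      truth <- sim$truth
    } else {
      raw <- read_profiles(input)
    }
  } else if (inherits(input, "profile_table")) {
    raw <- input
  } else {
    stop("config$input must be a profile_table, preset name, or file path")
  }
  for (key in c(config$batch_key, config$label_key)) {
    if (!key %in% names(raw$metadata)) {
      stop("unknown metadata key in config: ", key)
    }
  }
  base <- if (config$preprocess) {
    run_baseline(raw, config$preprocess_params)
  } else {
    raw
  }
  metrics <- list()
  failed <- character(0)
  for (mname in names(config$methods)) {
    pars <- config$methods[[mname]]
    res <- tryCatch({
      corrected <- if (mname == "oracle") {
        if (is.null(truth)) stop("oracle requires a simulated input")
        run_oracle_baseline(raw, truth, config$preprocess_params)
      } else {
        entry <- get_method(mname)
        out <- do.call(entry$fn, c(list(table = base,
                                        batch_key = config$batch_key,
                                        seed = config$seed), pars))
        if (is.null(attr(out, "output_space"))) {
          attr(out, "output_space") <- entry$output_space
        }
        out
      }
      m <- suppressWarnings(
        evaluate_metrics(corrected, config$batch_key, config$label_key,
                         config$metric_params))
      cbind(method = mname, m, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[mname] <- conditionMessage(res)
    } else {
      metrics[[mname]] <- res
    }
  }
  metrics_df <- if (length(metrics) > 0) {
    do.call(rbind, c(metrics, list(make.row.names = FALSE)))
  } else {
    data.frame(method = character(0), metric = character(0),
               category = character(0), raw_value = numeric(0),
               normalized_value = numeric(0))
  }
  scores <- aggregate_scores(metrics_df,
                             w_batch = config$weights[["batch"]],
                             w_bio = config$weights[["bio"]])
  structure(list(
    name = config$name, metrics = metrics_df, scores = scores,
    failed = failed,
    manifest = list(
      scenario = config$name, seed = config$seed,
      batch_key = config$batch_key, label_key = config$label_key,
      methods = names(config$methods),
      weights = as.list(config$weights),
      metric_params = unclass(config$metric_params),
      preprocess_params = unclass(config$preprocess_params),
      package_version = as.character(utils::packageVersion("cpbench")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report '", x$name, "'\n", sep = "")
  if (nrow(x$scores) > 0) {
    print(x$scores[order(x$scores$rank), ], row.names = FALSE, digits = 3)
  }
  if (length(x$failed) > 0) {
    cat("failed methods:\n")
    for (m in names(x$failed)) cat("  ", m, ": ", x$failed[m], "\n", sep = "")
  }
  invisible(x)
}

#' Aggregate metric results into per-method scores
#'
#' The batch score is the mean of the four normalized batch-removal
#' metrics, the bio score the mean of the six normalized bio-conservation
#' metrics, and the overall score the weighted sum (defaults 0.4 / 0.6).
#' Methods missing part of the panel are excluded with a warning.
#'
#' @param metrics data.frame with columns `method`, `metric`, `category`,
#'   `normalized_value`.
#' @param w_batch,w_bio Category weights; must sum to 1.
#' @return data.frame with columns `method`, `batch_score`, `bio_score`,
#'   `overall_score`, `rank` (1 = best, average ranks on ties).
#' @export
aggregate_scores <- function(metrics, w_batch = 0.4, w_bio = 0.6) {
  if (abs(w_batch + w_bio - 1) > 1e-8) stop("weights must sum to 1")
  if (nrow(metrics) == 0) {
    return(data.frame(method = character(0), batch_score = numeric(0),
                      bio_score = numeric(0), overall_score = numeric(0),
                      rank = numeric(0)))
  }
  full_panel <- max(table(metrics$method))
  rows <- lapply(unique(metrics$method), function(m) {
    sub <- metrics[metrics$method == m, ]
    if (nrow(sub) < full_panel) {
      warning("method '", m, "' is missing metrics; excluded from scores")
      return(NULL)
    }
    batch <- mean(sub$normalized_value[sub$category == "batch"])
    bio <- mean(sub$normalized_value[sub$category == "bio"])
    data.frame(method = m, batch_score = batch, bio_score = bio,
               overall_score = w_batch * batch + w_bio * bio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(method = character(0), batch_score = numeric(0),
                      bio_score = numeric(0), overall_score = numeric(0),
                      rank = numeric(0)))
  }
  out$rank <- rank(-out$overall_score, ties.method = "average")
  out
}

#' Mean rank of methods across scenarios
#'
#' Ranks methods by overall score within each scenario (1 = best, average
#' ranks on ties) and averages ranks across scenarios. Methods absent from
#' some scenarios are ranked only where present and flagged.
#'
#' @param reports List of [run_benchmark()] reports (or of their `scores`
#'   data.frames).
#' @return data.frame with `method`, `mean_rank`, `n_scenarios`,
#'   `in_all_scenarios`, sorted by mean rank.
#' @export
rank_methods <- function(reports) {
  if (inherits(reports, "benchmark_report")) reports <- list(reports)
  if (length(reports) == 0) stop("need >= 1 scenario report")
  score_tabs <- lapply(reports, function(r) {
    if (inherits(r, "benchmark_report")) r$scores else r
  })
  ranks <- lapply(score_tabs, function(s) {
    stats::setNames(rank(-s$overall_score, ties.method = "average"),
                    s$method)
  })
  all_methods <- unique(unlist(lapply(ranks, names)))
  out <- do.call(rbind, lapply(all_methods, function(m) {
    rs <- unlist(lapply(ranks, function(r) {
      if (m %in% names(r)) r[[m]] else NULL
    }))
    data.frame(method = m, mean_rank = mean(rs), n_scenarios = length(rs),
               in_all_scenarios = length(rs) == length(ranks),
               stringsAsFactors = FALSE)
  }))
  out[order(out$mean_rank), ]
}

#' Write benchmark outputs (tidy metrics, summary, manifest)
#'
#' @param report A [run_benchmark()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics(report$metrics, file.path(dir, "metrics.csv"),
                scenario = report$name)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  md <- c(paste0("# Benchmark report: ", report$name), "",
          "| method | batch | bio | overall | rank |",
          "|---|---|---|---|---|")
  s <- report$scores[order(report$scores$rank), ]
  for (i in seq_len(nrow(s))) {
    md <- c(md, sprintf("| %s | %.3f | %.3f | %.3f | %.1f |",
                        s$method[i], s$batch_score[i], s$bio_score[i],
                        s$overall_score[i], s$rank[i]))
  }
  if (length(report$failed) > 0) {
    md <- c(md, "", "Failed methods:",
            paste0("- ", names(report$failed), ": ", report$failed))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' UMAP embedding panels for qualitative assessment
#'
#' Computes a 2-D UMAP embedding of the representation and draws one panel
#' per metadata color key (e.g. compound, batch, microscope). Clusters
#' aligned with batch variables indicate residual batch effects; clusters
#' aligned with compounds indicate preserved biology. Deterministic given
#' the seed.
#'
#' @param x A [profile_table] with at least 10 wells.
#' @param color_keys Metadata columns to color by, one panel each.
#' @param seed RNG seed.
#' @param n_neighbors UMAP neighbourhood size (must be below `n_wells`).
#' @param file Optional output file; `.svg` or `.pdf` vector graphics.
#' @return Invisibly, a list with `coords` (n x 2) and `file`.
#' @export
plot_embedding <- function(x, color_keys = c("batch_id", "compound_id"),
                           seed = 1, n_neighbors = 15, file = NULL) {
  validate_profile_table(x)
  if (n_wells(x) < 10) stop("need >= 10 wells to embed")
  if (n_neighbors >= n_wells(x)) {
    stop("fewer wells than embedding neighbours")
  }
  for (key in color_keys) {
    if (!key %in% names(x$metadata)) stop("unknown metadata key: ", key)
  }
  old_seed <- save_rng()
  on.exit(restore_rng(old_seed))
  set.seed(seed)
  coords <- uwot::umap(x$features, n_neighbors = n_neighbors,
                       n_threads = 1, n_sgd_threads = 0)
  colnames(coords) <- c("UMAP1", "UMAP2")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = grDevices::svg(file, width = 5 * length(color_keys),
                                height = 5),
           pdf = grDevices::pdf(file, width = 5 * length(color_keys),
                                height = 5),
           stop("file must end in .svg or .pdf"))
    on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
    graphics::par(mfrow = c(1, length(color_keys)), mar = c(4, 4, 2, 1))
    for (key in color_keys) {
      g <- factor(x$metadata[[key]])
      graphics::plot(coords, col = grDevices::rainbow(nlevels(g))[g],
                     pch = 19, cex = 0.6, main = key,
                     xlab = "UMAP1", ylab = "UMAP2")
    }
  }
  invisible(list(coords = coords, file = file))
}
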