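#' Default pipeline configuration
#'
#' One nested list holding every stage's tunables plus the global seed and
#' output directory. `run_pipeline()` derives an independent seed per
#' stage from the global one, so reruns with the same configuration are
#' bitwise-reproducible. Configurations round-trip losslessly through
#' JSON via [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param seed global integer seed.
#' @param out_dir directory for all pipeline artifacts.
#' @return nested configuration list with sections `simulate`, `metrics`,
#'   `tensor`, `decompose`, `select`, `splithalf`, `bootstrap`, `pca`.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "trisync-run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(background_rate = 20, injection_rate = 2,
                    deactivation_multiplier = 0.3, jitter_sd = 0.001,
                    osc_depth = 0, osc_freq = 40),
    metrics = list(metrics = "sync", bin_width = 0.002, max_lag = 50,
                   t_jitter = 0.006, t_sync = 0.005,
                   f_min = 30, f_max = 50),
    tensor = list(metric = "kappa_sync", center_modes = c(1, 2, 3),
                  subset = "all"),
    decompose = list(n_components = 3, n_starts = 10, tol = 1e-8,
                     max_iter = 2000),
    select = list(f_max = 6, congruence_threshold = 0.85, n_starts = 10),
    splithalf = list(n_components = NULL, n_starts = 10),
    bootstrap = list(n_reps = 20, mode = "parametric", n_starts = 3),
    pca = list(mode = 3, threshold = 70)
  )
}

#' @rdname default_pipeline_config
#' @param path JSON file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_pipeline_config(), cfg)
}

#' @rdname default_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order — `simulate` ->
#' `metrics` -> `tensor` -> `decompose`, with `select`, `splithalf`,
#' `bootstrap` (all needing the tensor; `bootstrap` also the fitted
#' model) and `pca` available downstream — writing every intermediate
#' artifact under `config$out_dir` and returning a manifest that records
#' the configuration, per-stage seeds, artifact paths and their MD5
#' content hashes, and the numerical conventions applied (jitter kernel,
#' centering order, loading normalization). A stage whose upstream
#' artifact is neither being produced in this run nor present on disk
#' from an earlier one raises an error naming the missing artifact.
#'
#' @param config configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param stages character vector of stage names to run.
#' @return the manifest (invisibly written to `manifest.json` as well).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("simulate", "metrics", "tensor",
                                    "decompose")) {
  all_stages <- c("simulate", "metrics", "tensor", "decompose", "select",
                  "splithalf", "bootstrap", "pca")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max, length(all_stages)), all_stages)
  log_msg <- function(...) message("[trisync] ", sprintf(...))
  artifacts <- list()
  note <- function(stage, files) {
    files <- files[file.exists(files)]
    artifacts[[stage]] <<- data.frame(
      path = files, md5 = unname(tools::md5sum(files)))
  }
  dataset <- NULL; metrics_tab <- NULL; tensor <- NULL; model <- NULL
  ds_dir <- file.path(out, "dataset")
  metrics_path <- file.path(out, "metrics.tsv")
  tensor_path <- file.path(out, "tensor.tsv")
  model_dir <- file.path(out, "model")

  need <- function(obj, loader, what, artifact) {
    if (!is.null(obj)) return(obj)
    loaded <- tryCatch(loader(), error = function(e) NULL)
    if (is.null(loaded))
      stop(sprintf("stage needs %s but artifact '%s' is missing",
                   what, artifact))
    loaded
  }

  if ("simulate" %in% stages) {
    log_msg("simulate: generating spike dataset (seed %d)",
            stage_seeds[["simulate"]])
    sim <- config$simulate
    dataset <- simulate_experiment(
      background_rate = sim$background_rate,
      injection_rate = sim$injection_rate,
      phase_multipliers = c(warm = 1,
                            deactivation = sim$deactivation_multiplier,
                            rewarm = 1),
      jitter_sd = sim$jitter_sd, osc_depth = sim$osc_depth,
      osc_freq = sim$osc_freq, seed = stage_seeds[["simulate"]])
    write_dataset(dataset, ds_dir)
    gt <- attr(dataset, "ground_truth")
    gt_path <- file.path(out, "ground_truth.json")
    jsonlite::write_json(
      list(n_components = gt$truth$n_components,
           A = gt$truth$A, B = gt$truth$B, C = gt$truth$C,
           phase_multipliers = as.list(gt$phase_multipliers),
           injection_rate = gt$injection_rate),
      gt_path, digits = NA, auto_unbox = TRUE)
    note("simulate", c(list.files(ds_dir, full.names = TRUE), gt_path))
  }

  if ("metrics" %in% stages) {
    dataset <- need(dataset, function() read_dataset(ds_dir),
                    "a spike dataset", ds_dir)
    m <- config$metrics
    log_msg("metrics: %s over %d live channels",
            paste(m$metrics, collapse = "+"),
            length(live_channels(dataset$grid)))
    metrics_tab <- synchrony_table(
      dataset, metrics = m$metrics, bin_width = m$bin_width,
      max_lag = m$max_lag, t_jitter = m$t_jitter, t_sync = m$t_sync,
      f_min = m$f_min, f_max = m$f_max)
    write.table(metrics_tab, metrics_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("metrics", metrics_path)
  }

  if ("tensor" %in% stages) {
    metrics_tab <- need(metrics_tab, function() read.delim(metrics_path),
                        "a metric table", metrics_path)
    tc <- config$tensor
    tensor <- build_tensor(metrics_tab, metric = tc$metric)
    if (!identical(tc$subset, "all")) {
      dataset <- need(dataset, function() read_dataset(ds_dir),
                      "a spike dataset (for pair classification)", ds_dir)
      cls <- classify_pairs(dataset$grid)
      tensor <- subset_tensor(tensor, cls[[tc$subset]])
    }
    if (length(tc$center_modes))
      tensor <- center_tensor(tensor, tc$center_modes)
    log_msg("tensor: %s", paste(dim(tensor), collapse = " x "))
    write.table(flatten_tensor(tensor), tensor_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("tensor", tensor_path)
  }

  reload_tensor <- function() {
    tab <- read.delim(tensor_path)
    tt <- build_tensor(tab, metric = names(tab)[4])
    if (length(config$tensor$center_modes) &&
        !length(attr(tt, "centered")))
      tt <- center_tensor(tt, config$tensor$center_modes)
    tt
  }

  if ("decompose" %in% stages) {
    tensor <- need(tensor, reload_tensor, "a synchrony tensor",
                   tensor_path)
    dc <- config$decompose
    model <- als_fit(tensor, dc$n_components, n_starts = dc$n_starts,
                     tol = dc$tol, max_iter = dc$max_iter,
                     seed = stage_seeds[["decompose"]])
    log_msg("decompose: F = %d, %.2f%% explained variance",
            model$n_components, model$explained_variance)
    write_parafac(model, model_dir)
    note("decompose", list.files(model_dir, full.names = TRUE))
  }

  if ("select" %in% stages) {
    tensor <- need(tensor, reload_tensor, "a synchrony tensor",
                   tensor_path)
    sc <- config$select
    report <- select_components(
      tensor, f_max = sc$f_max,
      congruence_threshold = sc$congruence_threshold,
      n_starts = sc$n_starts, seed = stage_seeds[["select"]])
    log_msg("select: chosen F = %d", report$chosen_f)
    sel_path <- file.path(out, "selection.tsv")
    write_selection(report, sel_path)
    note("select", sel_path)
  }

  if ("splithalf" %in% stages) {
    tensor <- need(tensor, reload_tensor, "a synchrony tensor",
                   tensor_path)
    sh <- config$splithalf
    f_use <- if (is.null(sh$n_components))
      config$decompose$n_components else sh$n_components
    res <- split_half(tensor, f_use, n_starts = sh$n_starts,
                      seed = stage_seeds[["splithalf"]])
    log_msg("splithalf: match %.4f, variance %.2f%% / %.2f%%",
            res$match$score, res$explained_variance["odd"],
            res$explained_variance["even"])
    sh_path <- file.path(out, "splithalf.json")
    jsonlite::write_json(
      list(factor_match = res$match$score,
           per_component = res$match$per_component,
           explained_variance = as.list(res$explained_variance)),
      sh_path, digits = NA, auto_unbox = TRUE)
    note("splithalf", sh_path)
  }

  if ("bootstrap" %in% stages) {
    tensor <- need(tensor, reload_tensor, "a synchrony tensor",
                   tensor_path)
    if (is.null(model))
      stop("stage needs a fitted model but artifact '", model_dir,
           "' was not produced in this run; include 'decompose'")
    bt <- config$bootstrap
    res <- residual_bootstrap(tensor, model, n_reps = bt$n_reps,
                              seed = stage_seeds[["bootstrap"]],
                              mode = bt$mode, n_starts = bt$n_starts)
    log_msg("bootstrap: empirical %.4f vs gaussian %.4f",
            mean(res$scores_empirical), mean(res$scores_gaussian))
    bt_path <- file.path(out, "bootstrap.json")
    jsonlite::write_json(
      list(scores_empirical = res$scores_empirical,
           scores_gaussian = res$scores_gaussian, mode = res$mode),
      bt_path, digits = NA, auto_unbox = TRUE)
    note("bootstrap", bt_path)
  }

  if ("pca" %in% stages) {
    tensor <- need(tensor, reload_tensor, "a synchrony tensor",
                   tensor_path)
    pc <- config$pca
    pm <- pca_on_tensor(tensor, mode = pc$mode)
    needed <- components_needed(pm, pc$threshold)
    log_msg("pca: %d components for %.0f%% cumulative variance",
            needed, pc$threshold)
    pca_path <- file.path(out, "pca.json")
    jsonlite::write_json(
      list(mode = pm$mode, variance = pm$variance,
           cumulative_variance = pm$cumulative_variance,
           threshold = pc$threshold,
           components_needed = as.integer(needed),
           threshold_reached = attr(needed, "reached")),
      pca_path, digits = NA, auto_unbox = TRUE)
    note("pca", pca_path)
  }

  manifest <- list(
    package = "trisync",
    version = as.character(utils::packageVersion("trisync")),
    seed = config$seed,
    stage_seeds = as.list(stage_seeds[stages]),
    stages = stages,
    config = config,
    conventions = list(
      jitter = "both trains convolved with homogeneous kernel at binned resolution",
      convolution_edges = "zero padded, same length",
      centering = paste0("sequential single-mode centering, order ",
                         paste(config$tensor$center_modes, collapse = ",")),
      scaling = "none",
      normalization = "unit-norm B and C columns, magnitude and sign in A",
      component_order = "explained-variance contribution, descending"),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
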