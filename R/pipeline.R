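#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with defaults
#' matching the reference protocol: 60-130 Hz band in 1 Hz bins, 4-cycle
#' Gabor atoms, 0.5 s smoothing, 2 s epochs, 10-fold cross-validation,
#' 10000 selection permutations at alpha 0.05 (FDR), 5000 random-search
#' iterations and an r-squared inclusion threshold of 0.2 for the
#' winner-takes-all map. `profile = "test"` scales the two expensive
#' Monte-Carlo loops down (1000 permutations, 500 iterations) for quick runs;
#' reported analyses use the full profile.
#'
#' @param sim A [sim_config()] describing the run to simulate, or `NULL`
#'   when an existing run is supplied to [run_pipeline()].
#' @param f_lo,f_hi,bin_hz,fwhm_cycles,hop See [gabor_power()].
#' @param line_freq_hz,n_harmonics,bandwidth_hz See [notch_filter()].
#' @param flat_var_tol,noisy_var_factor,noisy_line_factor See
#'   [detect_bad_channels()].
#' @param smoothing_s,epoch_s See [smooth_zscore_epoch()].
#' @param k Cross-validation folds.
#' @param n_perm Selection permutations.
#' @param alpha FDR level.
#' @param fdr_family FDR family, see [permutation_fdr()].
#' @param n_iter Random-search iterations.
#' @param r2_threshold Winner-takes-all inclusion threshold.
#' @param seed Master seed of the analysis stages.
#' @param profile `"full"` or `"test"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            f_lo = 60, f_hi = 130, bin_hz = 1,
                            fwhm_cycles = 4, hop = 1L,
                            line_freq_hz = 50, n_harmonics = 3,
                            bandwidth_hz = 1,
                            flat_var_tol = 1e-8, noisy_var_factor = 10,
                            noisy_line_factor = 10,
                            smoothing_s = 0.5, epoch_s = 2.0,
                            k = 10L, n_perm = 10000L, alpha = 0.05,
                            fdr_family = "within_movement",
                            n_iter = 5000L, r2_threshold = 0.2,
                            seed = 1L, profile = c("full", "test")) {
  profile <- match.arg(profile)
  if (profile == "test") {
    n_perm <- min(n_perm, 1000L)
    n_iter <- min(n_iter, 500L)
  }
  cfg <- list(sim = sim, f_lo = f_lo, f_hi = f_hi, bin_hz = bin_hz,
              fwhm_cycles = fwhm_cycles, hop = as.integer(hop),
              line_freq_hz = line_freq_hz, n_harmonics = n_harmonics,
              bandwidth_hz = bandwidth_hz, flat_var_tol = flat_var_tol,
              noisy_var_factor = noisy_var_factor,
              noisy_line_factor = noisy_line_factor,
              smoothing_s = smoothing_s, epoch_s = epoch_s, k = as.integer(k),
              n_perm = as.integer(n_perm), alpha = alpha,
              fdr_family = fdr_family, n_iter = as.integer(n_iter),
              r2_threshold = r2_threshold, seed = as.integer(seed),
              profile = profile)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' The round-trip `read_config(write_config(cfg, f))` reproduces the
#' configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) {
    sim <- unclass(cfg$sim)
    sim$layout <- unclass(sim$layout)
    cfg$sim <- sim
  }
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$layout <- grid_layout(sim$layout$n_rows, sim$layout$n_cols,
                              sim$layout$spacing_mm)
    cfg$sim <- do.call(sim_config, sim)
  }
  do.call(pipeline_config, cfg)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulate (or take) a run, then: bad-channel detection, notch filtering,
#' common-average re-referencing, HFB envelope extraction, whole-run
#' electrode responsiveness and winner-takes-all map, spatial and
#' spatio-temporal 10-fold template-matching classification, random-search
#' electrode importance and the searchlight accuracy-by-grid-size analysis.
#' All tabular outputs are written as TSV, structured results as JSON, plus
#' a manifest (`manifest.json`) with the configuration, seed, package
#' version and the MD5 of every output file, so a bundle is exactly
#' reproducible: the same configuration and seed give byte-identical
#' manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param run Optional `ecog_run` (skips simulation); otherwise
#'   `config$sim` is simulated.
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, out_dir, run = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(run)) {
    if (is.null(config$sim)) stop("no run given and no sim config", call. = FALSE)
    run <- generate_run(config$sim)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  mask <- stage("detect_bad_channels",
                detect_bad_channels(run, config$flat_var_tol,
                                    config$noisy_var_factor,
                                    config$noisy_line_factor,
                                    config$line_freq_hz))
  run <- stage("notch_filter",
               notch_filter(run, config$line_freq_hz, config$n_harmonics,
                            config$bandwidth_hz))
  run <- stage("common_average_rereference",
               common_average_rereference(run, mask))
  env <- stage("gabor_power",
               gabor_power(run, config$f_lo, config$f_hi, config$bin_hz,
                           config$fwhm_cycles, config$hop))
  included <- which(mask$included)

  tm <- stage("trial_means", trial_means(env))
  sel <- stage("permutation_fdr",
               permutation_fdr(tm$means[, included, drop = FALSE], tm$labels,
                               n_perm = config$n_perm, alpha = config$alpha,
                               seed = config$seed,
                               fdr_family = config$fdr_family))
  topo <- stage("winner_takes_all",
                winner_takes_all(sel, config$r2_threshold))

  cv_sp <- stage("crossvalidate_spatial",
                 crossvalidate(env, "spatial", config$k, config$seed,
                               electrodes = included,
                               n_perm = config$n_perm, alpha = config$alpha,
                               fdr_family = config$fdr_family,
                               smoothing_s = config$smoothing_s,
                               epoch_s = config$epoch_s))
  cv_st <- stage("crossvalidate_spatiotemporal",
                 crossvalidate(env, "spatiotemporal", config$k, config$seed,
                               electrodes = included,
                               n_perm = config$n_perm, alpha = config$alpha,
                               fdr_family = config$fdr_family,
                               smoothing_s = config$smoothing_s,
                               epoch_s = config$epoch_s))

  tensor <- stage("smooth_zscore_epoch",
                  smooth_zscore_epoch(env, included, config$smoothing_s,
                                      config$epoch_s))
  imp <- stage("random_search_importance",
               random_search_importance(tensor, config$n_iter,
                                        seed = config$seed))
  sl <- stage("searchlight", searchlight(tensor, run$layout))

  write_channel_mask(mask, file.path(out_dir, "channel_mask.tsv"))
  write_selection(sel, file.path(out_dir, "selection.tsv"))
  write_topo_map(structure(c(topo[names(topo) != "layout"],
                             list(layout = run$layout)), class = "topo_map"),
                 file.path(out_dir, "winner_takes_all.tsv"))
  write_cv_result(cv_sp, file.path(out_dir, "cv_spatial.json"))
  write_cv_result(cv_st, file.path(out_dir, "cv_spatiotemporal.json"))
  imp_df <- data.frame(electrode = imp$electrodes,
                       mean_acc = sprintf("%.6f", imp$mean_acc),
                       z = sprintf("%.6f", imp$z),
                       inclusions = imp$inclusion_counts)
  utils::write.table(imp_df, file.path(out_dir, "importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sl$summary, file.path(out_dir, "searchlight_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- c("channel_mask.tsv", "selection.tsv", "winner_takes_all.tsv",
               "cv_spatial.json", "cv_spatiotemporal.json", "importance.tsv",
               "searchlight_summary.tsv")
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_file)
  manifest <- list(
    package = "hfbdecode",
    version = as.character(utils::packageVersion("hfbdecode")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(run = run, mask = mask, envelope = env, selection = sel,
                 topo = topo, cv_spatial = cv_sp, cv_spatiotemporal = cv_st,
                 importance = imp, searchlight = sl,
                 manifest = file.path(out_dir, "manifest.json")))
}
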