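## -------------------------------------------------------------------------
## End-to-end orchestration: synthetic scenes -> maps -> insertion points ->
## simulated experiment -> psychometric (and optional EEG) analysis.
## -------------------------------------------------------------------------

#' Pipeline manifest
#'
#' A manifest fixes every input of a full synthetic-experiment run: the
#' generator configurations, stage list, and master seed. Re-running the
#' same manifest reproduces all outputs bit-exactly.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param n_scenes number of synthetic scenes.
#' @param scene_config a [scene_generator_config].
#' @param cohort a [cohort_config].
#' @param erp_config an [erp_cohort_config], or NULL to skip the EEG stage.
#' @param stages character subset of
#'   \code{c("scenes", "simulate", "analyze", "eeg")}.
#' @return object of class \code{run_manifest}.
#' @export
run_manifest <- function(seed = 1L, n_scenes = 12,
                         scene_config = scene_generator_config(),
                         cohort = cohort_config(),
                         erp_config = NULL,
                         stages = c("scenes", "simulate", "analyze")) {
  structure(list(seed = as.integer(seed), n_scenes = n_scenes,
                 scene_config = scene_config, cohort = cohort,
                 erp_config = erp_config, stages = stages,
                 version = as.character(utils::packageVersion("sceneprobe"))),
            class = "run_manifest")
}

#' Run the full pipeline
#'
#' Executes the manifest's stages: scene synthesis + map building +
#' insertion-point selection; experiment simulation; psychometric analysis
#' (2x2 effect table, tuning functions, retuning indices, double-pass
#' internal noise when double-pass blocks exist); and, when configured,
#' the synthetic-EEG stage with pooled occipital modulations.
#'
#' @param manifest a [run_manifest].
#' @param out_dir optional directory; when given, the trial table,
#'   insertion CSV and summary JSON are written there.
#' @param quiet suppress per-stage messages.
#' @return result bundle (list) with elements per stage and a
#'   \code{summary} list mirroring the JSON output.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(manifest = manifest)
  seed <- manifest$seed

  if ("scenes" %in% manifest$stages) {
    say("stage scenes: generating %d synthetic scenes", manifest$n_scenes)
    pts <- list(); kept <- 0; excluded <- 0
    for (i in seq_len(manifest$n_scenes)) {
      gen <- generate_scene(manifest$scene_config, seed = seed + i)
      sel <- scene_to_points(gen)
      if (is_scene_excluded(sel$points)) { excluded <- excluded + 1; next }
      kept <- kept + 1
      pts[[kept]] <- insertion_points_df(sel$points, scene_id = i)
    }
    if (kept == 0)
      sp_stop("all scenes excluded", "sceneprobe_exclusion_only")
    res$points <- do.call(rbind, pts)
    res$n_scenes_kept <- kept
    res$n_scenes_excluded <- excluded
    say("stage scenes: kept %d, excluded %d", kept, excluded)
  }

  if ("simulate" %in% manifest$stages) {
    if (is.null(res$points)) sp_input_error("simulate stage needs insertion points")
    say("stage simulate: %d subjects x %d insertion points",
        manifest$cohort$n_subjects, nrow(res$points))
    res$trials <- simulate_experiment(res$points, manifest$cohort,
                                      seed = seed + 10000L)
  }

  if ("analyze" %in% manifest$stages) {
    if (is.null(res$trials)) sp_input_error("analyze stage needs a trial table")
    say("stage analyze: %d trials", nrow(res$trials))
    main <- res$trials[res$trials$pass_id == "none", ]
    res$summary_table <- summarize_experiment(main)
    tf_rich <- reverse_correlation(main[main$td_label == "rich", ])
    tf_poor <- reverse_correlation(main[main$td_label == "poor", ])
    res$tuning <- list(td_rich = tf_rich, td_poor = tf_poor)
    res$retuning <- c(td_rich = retuning_index(symmetrize(tf_rich)),
                      td_poor = retuning_index(symmetrize(tf_poor)))
    if (manifest$cohort$double_pass_blocks > 0) {
      dps <- double_pass_stats(res$trials)
      res$internal_noise <- estimate_internal_noise(dps$pc, dps$pa, dps$p_yes)
    }
  }

  if ("eeg" %in% manifest$stages) {
    if (is.null(manifest$erp_config)) sp_input_error("eeg stage needs erp_config")
    say("stage eeg: %d subjects", manifest$erp_config$n_subjects)
    mm <- erp_cohort_modulation(manifest$erp_config, c("td", "bu"),
                                seed = seed + 20000L)
    mm_td <- mm$td; mm_bu <- mm$bu
    zpool <- function(mm) {
      pooled <- pool_window(mm, "occipital", c(0, 0.1))
      mean(pooled) / (stats::sd(pooled) / sqrt(length(pooled)))
    }
    res$eeg <- list(td = mm_td, bu = mm_bu,
                    occipital_z = c(td = zpool(mm_td), bu = zpool(mm_bu)))
  }

  res$summary <- pipeline_summary(res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$points))
      write_insertion_csv(res$points, file.path(out_dir, "insertions.csv"))
    if (!is.null(res$trials))
      write_trial_table(res$trials, file.path(out_dir, "trials.csv"))
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

pipeline_summary <- function(res) {
  s <- list(seed = res$manifest$seed)
  if (!is.null(res$n_scenes_kept))
    s$scenes <- list(kept = res$n_scenes_kept,
                     excluded = res$n_scenes_excluded)
  if (!is.null(res$summary_table)) {
    st <- res$summary_table
    s$effects <- list(
      td_log_ratio_median = st$td$median, td_wilcoxon_p = st$td$p,
      td_ci = st$td$ci,
      bu_log_ratio_median = st$bu$median, bu_wilcoxon_p = st$bu$p,
      bu_ci = st$bu$ci)
    s$per_observer <- res$summary_table$observers
  }
  if (!is.null(res$retuning)) s$retuning_index <- as.list(res$retuning)
  if (!is.null(res$tuning))
    s$tuning <- lapply(res$tuning, function(tf) tf$p)
  if (!is.null(res$internal_noise))
    s$internal_noise <- list(sigma_int = res$internal_noise$sigma_int,
                             pc = res$internal_noise$pc,
                             pa = res$internal_noise$pa)
  if (!is.null(res$eeg)) s$eeg_occipital_z <- as.list(res$eeg$occipital_z)
  s
}
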