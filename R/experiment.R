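#' Configuration for an end-to-end simulation experiment
#'
#' Defines a cohort of synthetic subjects per class-separability contrast
#' and the pipelines, cross-validation schemes and statistics to run on
#' them. The default contrasts realize "high" and "low" class separability
#' as oscillator modulation depths of 0.8 (gain ratio 1.8) and 0.2 (gain
#' ratio 1.2).
#'
#' @param n_subjects subjects per contrast (default 15).
#' @param layout_preset block layout, see [make_layout()].
#' @param contrasts named numeric vector of `class_effect` values.
#' @param block_effect,noise,run_duration_overrides forwarded to
#'   [synth_params()].
#' @param pipelines pipeline names (default all four).
#' @param schemes scheme names (default all four).
#' @param k folds for the k-fold schemes.
#' @param alpha significance level.
#' @param n_boot,n_boot_subj bootstrap iterations and units per iteration.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param write_recordings also write the generated recordings.
#' @return an `ncv_experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 15,
                              layout_preset = c("shin_like",
                                                "schroeder_like",
                                                "hinss_multiday_like"),
                              contrasts = c(low_separability = 0.2,
                                            high_separability = 0.8),
                              block_effect = c(channel_gain_sd = 0.08,
                                               drift_sd = 0.12,
                                               aperiodic_shift_sd = 0.12),
                              noise = c(pink_slope = 1, white_sd = 0.5),
                              run_duration_overrides = NULL,
                              pipelines = c("broad_rmdm", "narrow_rmdm",
                                            "psd_lda", "fbcsp"),
                              schemes = c("pseudo_online",
                                          "leave_one_block_out",
                                          "sequential_kfold",
                                          "randomized_kfold"),
                              k = 10, alpha = 0.05, n_boot = 10000,
                              n_boot_subj = 15, seed = 1L, out_dir = NULL,
                              write_recordings = FALSE) {
  stopifnot(all(layout_preset %in% layout_presets),
            all(pipelines %in% c("broad_rmdm", "narrow_rmdm", "psd_lda",
                                 "fbcsp")),
            all(schemes %in% c("pseudo_online", "leave_one_block_out",
                               "sequential_kfold", "randomized_kfold")),
            !is.null(names(contrasts)))
  structure(as.list(environment()), class = "ncv_experiment_config")
}

make_plan <- function(scheme, meta, k, seed) {
  switch(scheme,
         pseudo_online = plan_pseudo_online(meta),
         leave_one_block_out = plan_leave_one_block_out(meta),
         sequential_kfold = plan_sequential_kfold(meta, k),
         randomized_kfold = plan_randomized_kfold(meta, k, seed))
}

#' Run a full simulated cross-validation experiment
#'
#' For every contrast, generates a cohort, preprocesses each subject,
#' prepares each pipeline once per subject and executes all requested
#' fold plans; then computes the summary accuracy table with bootstrap
#' confidence intervals of scheme differences against pseudo-online, and
#' Friedman / Durbin-Conover comparisons of the pipelines per scheme and
#' contrast. All outputs are returned and, if `out_dir` is set, written as
#' CSV/JSON together with a run manifest.
#'
#' @param config an `ncv_experiment_config`.
#' @param verbose print per-stage progress.
#' @return list with `results` (fold-level table), `subject_accuracy`,
#'   `summary` (mean accuracy per pipeline x scheme), `bootstrap_ci`,
#'   `rank_tests` and `manifest`.
#' @export
run_experiment <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "ncv_experiment_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 2L)
  cohort_seeds <- derive_seeds(seeds[1], length(cfg$contrasts))
  cv_seed_root <- seeds[2]
  rows <- list()
  subj_rows <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (ci in seq_along(cfg$contrasts)) {
    contrast <- names(cfg$contrasts)[ci]
    subj_seeds <- derive_seeds(cohort_seeds[ci], cfg$n_subjects)
    cv_seeds <- derive_seeds(cv_seed_root + ci, cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      t0 <- Sys.time()
      # several layouts act as distinct "datasets": subjects are assigned
      # round-robin so each contrast covers every layout
      layout <- cfg$layout_preset[(s - 1) %% length(cfg$layout_preset) + 1]
      params <- synth_params(layout_preset = layout,
                             class_effect = unname(cfg$contrasts[ci]),
                             block_effect = cfg$block_effect,
                             noise = cfg$noise,
                             run_duration_overrides = cfg$run_duration_overrides)
      params$seed <- subj_seeds[s]
      sid <- sprintf("S%02d", s)
      rec <- generate_subject(params, subject_id = sid)
      rec <- preprocess_recording(rec)$recording
      for (pl_name in cfg$pipelines) {
        pl <- build_pipeline(pl_name)
        prep <- pl$prepare(rec)
        for (scheme in cfg$schemes) {
          plan <- make_plan(scheme, prep$meta, cfg$k, cv_seeds[s])
          acc <- run_cv(pl, prep, plan, alpha = cfg$alpha)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, dataset_layout = layout,
            contrast = contrast, pipeline = pl_name, cv_scheme = scheme,
            fold = seq_along(acc$fold_accuracy),
            accuracy = acc$fold_accuracy, n_test = acc$n_test,
            stringsAsFactors = FALSE)
          subj_rows[[length(subj_rows) + 1L]] <- data.frame(
            subject = sid, dataset_layout = layout,
            contrast = contrast, pipeline = pl_name, cv_scheme = scheme,
            accuracy = acc$mean_accuracy,
            pooled_accuracy = acc$pooled_accuracy,
            adjusted_chance = acc$adjusted_chance,
            stringsAsFactors = FALSE)
        }
      }
      say("[%s] %s subject %s done (%.1f s)", contrast, layout,
          sid, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
  }
  results <- results_table(do.call(rbind, rows))
  subject_accuracy <- do.call(rbind, subj_rows)
  summary_tab <- aggregate(accuracy ~ pipeline + cv_scheme, subject_accuracy,
                           mean)
  ci_tab <- bootstrap_scheme_differences(subject_accuracy, n_iter = cfg$n_boot,
                                         n_subj = cfg$n_boot_subj,
                                         seed = cv_seed_root)
  rank_tests <- list()
  for (contrast in names(cfg$contrasts)) {
    for (scheme in cfg$schemes) {
      sub <- subject_accuracy[subject_accuracy$contrast == contrast &
                                subject_accuracy$cv_scheme == scheme, ]
      wide <- tapply(sub$accuracy, list(sub$subject, sub$pipeline), mean)
      fr <- friedman(wide)
      dc <- durbin_conover(wide)
      dc$contrast <- contrast
      dc$cv_scheme <- scheme
      dc$friedman_chi2 <- fr$chi2
      dc$friedman_p <- fr$p
      rank_tests[[length(rank_tests) + 1L]] <- dc
    }
  }
  rank_tests <- do.call(rbind, rank_tests)
  manifest <- list(package_version = as.character(utils::packageVersion("neurocv")),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "out_dir")])
  out <- list(results = results, subject_accuracy = subject_accuracy,
              summary = summary_tab, bootstrap_ci = ci_tab,
              rank_tests = rank_tests, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_results(results, file.path(cfg$out_dir, "results.csv"))
    write.csv(subject_accuracy,
              file.path(cfg$out_dir, "subject_accuracy.csv"),
              row.names = FALSE)
    write.csv(summary_tab, file.path(cfg$out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(ci_tab, file.path(cfg$out_dir, "bootstrap_ci.csv"),
              row.names = FALSE)
    write.csv(rank_tests, file.path(cfg$out_dir, "pairwise_tests.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' Label/block reassignment leakage diagnostic
#'
#' Reassigns condition labels at the run level — half of each class's runs
#' are flipped to the other class — and re-evaluates a pipeline with a
#' randomized k-fold and a leave-one-block-out plan. On data whose blocks
#' carry temporal dependencies, the k-fold accuracy stays above the
#' adjusted chance level even though the labels are now half wrong, while
#' the block-wise accuracy falls to chance: a large gap flags leakage.
#'
#' @param rec a preprocessed `ncv_recording`.
#' @param pipeline an `ncv_pipeline` (default `psd_lda`).
#' @param k folds (default 10).
#' @param seed seed controlling which runs flip and the k-fold shuffle.
#' @return list with the reassigned-label accuracies of both schemes,
#'   their adjusted chance levels and the flipped run ids.
#' @export
label_block_reassignment_diagnostic <- function(rec,
                                                pipeline = build_pipeline("psd_lda"),
                                                k = 10, seed = 1L) {
  ann <- rec$annotations
  classes <- sort(unique(ann$condition))
  stopifnot(length(classes) == 2)
  if (nrow(ann) < 4) stop("too few runs to flip half of each class")
  flipped <- with_seed(seed, unlist(lapply(classes, function(cl) {
    runs <- ann$run_id[ann$condition == cl]
    sample(runs, floor(length(runs) / 2))
  })))
  prep <- pipeline$prepare(rec)
  flip <- prep$meta$run_id %in% flipped
  prep$meta$condition[flip] <-
    ifelse(prep$meta$condition[flip] == classes[1], classes[2], classes[1])
  kf <- run_cv(pipeline, prep, plan_randomized_kfold(prep$meta, k, seed))
  bw <- run_cv(pipeline, prep, plan_leave_one_block_out(prep$meta))
  list(flipped_runs = sort(flipped),
       kfold_accuracy = kf$pooled_accuracy,
       kfold_chance = kf$adjusted_chance,
       blockwise_accuracy = bw$pooled_accuracy,
       blockwise_chance = bw$adjusted_chance,
       leakage_gap = kf$pooled_accuracy - bw$pooled_accuracy)
}
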