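# Shared fixtures: everything is generated in code at test time.

# Random SPD matrix with eigenvalues bounded away from zero
rand_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(d) * 0.5 * scale
}

# Small synthetic subject: scaled-down run durations keep unit tests fast.
small_params <- function(layout = "shin_like", run_dur = 10,
                         class_effect = 0.8, seed = 1,
                         block_effect = c(channel_gain_sd = 0.08,
                                          drift_sd = 0.12,
                                          aperiodic_shift_sd = 0.12),
                         ...) {
  synth_params(layout_preset = layout, class_effect = class_effect,
               block_effect = block_effect,
               run_duration_overrides = run_dur, seed = seed, ...)
}

# Deterministic miniature recording for IO/filter tests (2 runs, 2 sets)
toy_recording <- function(fs = 250, n_ch = 6, run_dur = 4) {
  channels <- default_montage()[seq_len(n_ch)]
  n <- 2 * run_dur * fs
  tt <- seq_len(n) / fs
  data <- t(vapply(seq_len(n_ch), function(i) {
    sin(2 * pi * (4 + i) * tt) + 0.1 * cos(2 * pi * 0.7 * i * tt)
  }, numeric(n)))
  ann <- block_annotations(onset = c(0, run_dur), duration = rep(run_dur, 2),
                           condition = c("low", "high"), run_id = 1:2,
                           set_id = 1:2)
  new_recording(data, fs, channels, ann, subject_id = "TOY")
}

# A preprocessed small subject shared by several expensive tests
cached_small_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_subject(small_params(run_dur = 20, seed = 7))
      cache <<- preprocess_recording(rec)$recording
    }
    cache
  }
})

scheme_plan <- function(scheme, meta, k = 10, seed = 1) {
  switch(scheme,
         pseudo_online = plan_pseudo_online(meta),
         leave_one_block_out = plan_leave_one_block_out(meta),
         sequential_kfold = plan_sequential_kfold(meta, k),
         randomized_kfold = plan_randomized_kfold(meta, k, seed))
}
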