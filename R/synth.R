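#' Parameters of the synthetic block-structured EEG generator
#'
#' The generator superimposes three ingredient classes on a per-subject
#' random orthonormal source mixing:
#' * class-linked band-limited oscillators (a 6 Hz "theta" and a 10 Hz
#'   "alpha" source) whose gain depends on the condition label;
#' * block-specific confounds ("temporal dependencies"): per-block
#'   multiplicative channel gains (sensor-shift analog), a within-block
#'   random-walk amplitude drift on the sources (drowsiness analog) and a
#'   per-block offset of the aperiodic 1/f slope (arousal analog);
#' * stationary pink + white sensor noise.
#'
#' `class_effect` is the relative modulation depth of the class-linked
#' oscillators: the high-workload condition multiplies the theta source
#' amplitude by `1 + class_effect` and the alpha source by
#' `1 / (1 + class_effect)` (workload raises frontal theta and suppresses
#' alpha). `class_effect = 0` makes labels statistically independent of the
#' signal given block identity.
#'
#' Block confounds are drawn hierarchically, once per set and once per
#' block (run, or grouped condition repetition), each with standard
#' deviation `sd / sqrt(2)`, so windows within a set are more similar than
#' windows across sets.
#'
#' @param n_channels number of channels (default 28,
#'   [default_montage()]).
#' @param fs_raw raw sampling rate in Hz (default 500).
#' @param layout_preset one of the four study layouts, see [make_layout()].
#' @param n_conditions number of classes (default 2).
#' @param class_effect oscillator modulation depth (>= 0).
#' @param block_effect named numeric vector
#'   `c(channel_gain_sd=, drift_sd=, aperiodic_shift_sd=)`.
#' @param noise named numeric vector `c(pink_slope=, white_sd=)`;
#'   amplitudes in microvolts.
#' @param source_amp amplitudes (microvolts) of the theta and alpha sources.
#' @param pink_sd standard deviation (microvolts) of the pink-noise floor.
#' @param spatial_rho length scale (head-radius units) of the Gaussian
#'   spatial kernel mixing the pink background across channels
#'   (volume-conduction analog; larger = more correlated neighbours).
#' @param subject_var named numeric vector `c(amp_sd=, block_sd=)`:
#'   standard deviations of the per-subject lognormal factors scaling the
#'   oscillator amplitudes and the block-confound magnitudes, emulating
#'   between-subject differences in signal-to-noise and non-stationarity.
#' @param run_duration_overrides optional run duration override (seconds).
#' @param seed integer seed; the generated recording is a pure function of
#'   the full parameter set including the seed.
#' @return a `ncv_synth_params` list.
#' @export
synth_params <- function(n_channels = 28L, fs_raw = 500,
                         layout_preset = "shin_like", n_conditions = 2L,
                         class_effect = 0.5,
                         block_effect = c(channel_gain_sd = 0.08,
                                          drift_sd = 0.12,
                                          aperiodic_shift_sd = 0.12),
                         noise = c(pink_slope = 1, white_sd = 0.5),
                         source_amp = c(theta = 20, alpha = 28),
                         pink_sd = 6, spatial_rho = 0.55,
                         subject_var = c(amp_sd = 0.25, block_sd = 0.35),
                         run_duration_overrides = NULL, seed = 1L) {
  p <- list(n_channels = as.integer(n_channels), fs_raw = fs_raw,
            layout_preset = match.arg(layout_preset, layout_presets),
            n_conditions = as.integer(n_conditions),
            class_effect = class_effect,
            block_effect = block_effect, noise = noise,
            source_freq = c(theta = 6, alpha = 10),
            source_bw = c(theta = 2, alpha = 3),
            source_amp = source_amp, pink_sd = pink_sd,
            spatial_rho = spatial_rho, subject_var = subject_var,
            run_duration_overrides = run_duration_overrides,
            seed = as.integer(seed))
  stopifnot(p$class_effect >= 0, all(p$block_effect >= 0),
            all(p$subject_var >= 0),
            p$noise[["pink_slope"]] >= 0, p$noise[["white_sd"]] >= 0,
            p$fs_raw > 2 * max(p$source_freq + p$source_bw))
  class(p) <- "ncv_synth_params"
  p
}

#' Pink (1/f^slope) noise
#'
#' Spectrally shaped Gaussian noise: the Fourier coefficients of white
#' noise are scaled by `f^(-slope/2)`, giving a power spectrum proportional
#' to `f^-slope`; the DC term is zeroed, so the series is zero-mean, and
#' the output is scaled to unit expected variance.
#'
#' @param n_samples series length (> 64).
#' @param slope aperiodic exponent (>= 0; 0 gives white noise).
#' @param fs sampling rate in Hz (sets the frequency axis only).
#' @param seed optional integer seed.
#' @return numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, slope = 1, fs = 500, seed = NULL) {
  if (slope < 0) stop("slope must be >= 0")
  stopifnot(n_samples > 64)
  with_seed(seed, drop(pink_noise_matrix(n_samples, 1L, slope, fs)))
}

# n x m matrix of independent pink-noise columns (vectorized via mvfft).
# The 1/f shaping plateaus below 1 Hz so the series' variance lives in the
# physiological band rather than in subsonic drift (which the 1 Hz
# highpass of the preprocessing chain would remove anyway).
pink_noise_matrix <- function(n, m, slope, fs) {
  w <- matrix(rnorm(n * m), n, m)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  g <- pmax(f, 1)^(-slope / 2)
  g[1] <- 0 # zero-mean
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n
  # scale by the filter's analytic output sd (not the realized one, which
  # would constrain every segment's total power and break exchangeability)
  x / sqrt(mean(g^2))
}

# Band-limited Gaussian noise carrier: white noise shaped by a Gaussian
# spectral envelope centred at f0 with sd bw/2; unit variance.
band_noise <- function(n, f0, bw, fs) {
  w <- rnorm(n)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  g <- exp(-(f - f0)^2 / (2 * (bw / 2)^2))
  g[1] <- 0
  x <- Re(fft(fft(w) * g, inverse = TRUE)) / n
  x / sqrt(mean(g^2))
}

#' Generate one synthetic subject
#'
#' Realizes the signal model of [synth_params()] on the block layout of the
#' chosen preset and returns a continuous recording at the raw sampling
#' rate, annotated with the layout's run/set/block structure.
#'
#' @param params a `ncv_synth_params` object.
#' @param subject_id subject identifier.
#' @return an `ncv_recording` (reference `"average"`).
#' @export
generate_subject <- function(params, subject_id = "S01") {
  stopifnot(inherits(params, "ncv_synth_params"))
  p <- params
  with_seed(p$seed, {
    ann <- make_layout(p$layout_preset, p$run_duration_overrides,
                       p$n_conditions, seed = NULL)
    channels <- default_montage()[seq_len(p$n_channels)]
    n_src <- length(p$source_freq)
    # between-subject heterogeneity: lognormal factors on signal-to-noise
    # and on the strength of the block confounds
    amp_factor <- exp(rnorm(1, 0, p$subject_var[["amp_sd"]]))
    block_factor <- exp(rnorm(1, 0, p$subject_var[["block_sd"]]))
    p$source_amp <- p$source_amp * amp_factor
    p$block_effect <- p$block_effect * block_factor
    # volume-conduction analog: the pink background mixes as many pink
    # sources as channels through the symmetric square root of a Gaussian
    # spatial kernel over the 2-D layout, so the background has exactly
    # the kernel's smooth cross-channel correlation (as in real EEG);
    # only the white sensor noise is channel-independent
    pos <- as.matrix(channel_positions(channels)[, c("x", "y")])
    G <- exp(-as.matrix(dist(pos))^2 / (2 * p$spatial_rho^2))
    eG <- eigen(G, symmetric = TRUE)
    B <- eG$vectors %*% (t(eG$vectors) * sqrt(pmax(eG$values, 1e-10)))
    B <- B / sqrt(rowSums(B^2))
    # oscillator topographies: random but spatially smoothed (cortical
    # patches blurred by volume conduction), orthonormalized
    Gn <- G / sqrt(rowSums(G^2))
    mix <- qr.Q(qr(Gn %*% matrix(rnorm(p$n_channels * n_src), p$n_channels)))
    # block gains are spatially smooth as well (a cap shift perturbs
    # neighbouring sensors coherently); rows scaled to unit norm so the
    # per-channel gain sd is exactly the requested one
    smooth_gain <- function(sd) drop(Gn %*% rnorm(p$n_channels, 0, sd))
    # the sensor-shift analog also rotates the projection of the sources
    # onto the cap (a displaced electrode sees a re-projected field, not
    # just a rescaled one); small random rotation via a Cayley transform
    rand_rotation <- function(theta) {
      A <- matrix(rnorm(p$n_channels^2), p$n_channels)
      A <- (A - t(A)) / 2
      A <- A * (theta / norm(A, "2"))
      solve(diag(p$n_channels) - A / 2, diag(p$n_channels) + A / 2)
    }
    # hierarchical confound split: the set-level component carries most of
    # the weight (sessions/sets differ more than adjacent runs), the
    # block-level remainder keeps individual runs identifiable
    set_share <- 0.8
    cg_sd <- p$block_effect[["channel_gain_sd"]] * set_share
    cg_sd_blk <- p$block_effect[["channel_gain_sd"]] * sqrt(1 - set_share^2)
    ap_sd <- p$block_effect[["aperiodic_shift_sd"]] * set_share
    ap_sd_blk <- p$block_effect[["aperiodic_shift_sd"]] * sqrt(1 - set_share^2)
    drift_sd <- p$block_effect[["drift_sd"]]
    rot_scale <- 0.3 # rotation angle (rad) per unit channel_gain_sd
    sets <- sort(unique(ann$set_id))
    set_gain <- lapply(sets, function(s) smooth_gain(cg_sd))
    set_rot <- lapply(sets, function(s) rand_rotation(cg_sd * rot_scale))
    set_slope <- rnorm(length(sets), 0, ap_sd)
    names(set_gain) <- names(set_rot) <- names(set_slope) <-
      as.character(sets)
    blocks <- sort(unique(ann$block_id))
    blk_gain <- lapply(blocks, function(b) smooth_gain(cg_sd_blk))
    blk_rot <- lapply(blocks, function(b) rand_rotation(cg_sd_blk * rot_scale))
    blk_slope <- rnorm(length(blocks), 0, ap_sd_blk)
    names(blk_gain) <- names(blk_rot) <- names(blk_slope) <-
      as.character(blocks)
    # drift state carries over between runs of the same block
    drift_state <- setNames(rep(0, n_src * length(blocks)),
                            paste(rep(blocks, each = n_src),
                                  rep(seq_len(n_src), length(blocks))))
    total <- round(sum(ann$duration) * p$fs_raw)
    data <- matrix(0, p$n_channels, total)
    ann <- ann[order(ann$chrono_index), , drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      a <- ann[i, ]
      L <- round(a$duration * p$fs_raw)
      idx <- round(a$onset * p$fs_raw) + seq_len(L)
      conds <- sort(unique(ann$condition))
      boosted <- if ("high" %in% conds) "high" else conds[length(conds)]
      ratio <- 1 + p$class_effect
      hi <- a$condition == boosted # workload: theta up, alpha down
      gains <- p$source_amp * c(if (hi) ratio else 1,
                                if (hi) 1 / ratio else 1)
      src <- matrix(0, n_src, L)
      for (s in seq_len(n_src)) {
        key <- paste(a$block_id, s)
        walk <- drift_state[key] +
          cumsum(rnorm(L, 0, drift_sd / sqrt(a$duration * p$fs_raw)))
        drift_state[key] <- walk[L]
        src[s, ] <- gains[s] * exp(walk) *
          band_noise(L, p$source_freq[s], p$source_bw[s], p$fs_raw)
      }
      slope_b <- max(0, p$noise[["pink_slope"]] +
                       set_slope[as.character(a$set_id)] +
                       blk_slope[as.character(a$block_id)])
      R <- blk_rot[[as.character(a$block_id)]] %*%
        set_rot[[as.character(a$set_id)]]
      neural <- mix %*% src +
        p$pink_sd * (B %*% t(pink_noise_matrix(L, p$n_channels, slope_b,
                                               p$fs_raw)))
      seg <- R %*% neural +
        p$noise[["white_sd"]] * matrix(rnorm(p$n_channels * L), p$n_channels)
      g <- pmax(0.1, 1 + set_gain[[as.character(a$set_id)]] +
                  blk_gain[[as.character(a$block_id)]])
      data[, idx] <- seg * g
    }
    new_recording(data, fs = p$fs_raw, channels = channels, annotations = ann,
                  subject_id = subject_id, reference = "average")
  })
}

#' Generate a cohort of independent synthetic subjects
#'
#' Subject k is exactly `generate_subject` run with the k-th seed of the
#' stable sequence derived from `seed` (so cohorts are reproducible and
#' individual subjects can be regenerated in isolation).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param params shared `ncv_synth_params`; the per-subject seed is
#'   replaced by the derived sequence.
#' @param seed master seed for the cohort.
#' @return list of `ncv_recording` objects.
#' @export
generate_cohort <- function(n_subjects, params, seed = 1L) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(k) {
    pk <- params
    pk$seed <- seeds[k]
    generate_subject(pk, subject_id = sprintf("S%02d", k))
  })
}

#' Write a cohort to disk with a manifest
#'
#' @param recordings list of recordings (e.g. from [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(recordings, function(rec) {
    base <- file.path(dir, rec$subject_id)
    write_recording(rec, paste0(base, ".f32.gz"), paste0(base, ".json"))
    list(subject_id = rec$subject_id,
         data = paste0(rec$subject_id, ".f32.gz"),
         sidecar = paste0(rec$subject_id, ".json"))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format = "neurocv-cohort-v1", subjects = entries),
                       manifest, auto_unbox = TRUE)
  invisible(manifest)
}
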