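test_that("notch filter hits the stated -6 dB edges and kills 50 Hz", {
  taps <- notch_design(fs = 500)
  expect_lt(abs(fir_response_db(taps, 49.25, 500) - (-6)), 0.5)
  expect_lt(abs(fir_response_db(taps, 50.75, 500) - (-6)), 0.5)
  expect_lte(fir_response_db(taps, 50, 500), -20)
  # passband identity at 10 Hz on an applied signal
  fs <- 500
  tt <- seq_len(10 * fs) / fs
  rec <- toy_recording(fs = fs, run_dur = 5)
  rec$data[1, ] <- sin(2 * pi * 10 * tt)
  out <- notch_filter(rec)$data[1, ]
  mid <- seq(fs, 9 * fs)
  expect_lt(max(abs(out[mid] - rec$data[1, mid])), 0.01)
})

test_that("highpass filter has -6 dB at 0.5 Hz and removes DC", {
  taps <- highpass_design(fs = 500)
  expect_lt(abs(fir_response_db(taps, 0.5, 500) - (-6)), 0.5)
  expect_lt(abs(fir_response_db(taps, 10, 500)), 0.1)
  rec <- toy_recording(fs = 500, run_dur = 5)
  rec$data[2, ] <- rec$data[2, ] + 100 # 100 uV DC offset
  out <- highpass_filter(rec)$data[2, ]
  mid <- seq(2 * 500, 8 * 500)
  expect_lt(abs(mean(out[mid])), 100 / 10^(40 / 20)) # >= 40 dB DC reduction
})

test_that("broadband FIR bandpass matches its stated edges", {
  taps <- neurocv:::design_fir_bandpass(1, 25, 128)
  expect_lt(abs(fir_response_db(taps, 0.5, 128) - (-6)), 0.5)
  expect_lt(abs(fir_response_db(taps, 28, 128) - (-6)), 1.0)
  expect_lt(abs(fir_response_db(taps, 10, 128)), 0.1)
  expect_lte(fir_response_db(taps, 45, 128), -20)
})

test_that("applied filters are zero-phase", {
  fs <- 250
  tt <- seq_len(8 * fs) / fs
  x <- matrix(sin(2 * pi * 8 * tt), 1)
  for (taps in list(neurocv:::design_fir_bandpass(1, 25, fs),
                    neurocv:::design_fir_highpass(1, fs))) {
    y <- neurocv:::fir_apply(x, taps)
    cc <- ccf(drop(y), drop(x), lag.max = 20, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("FFT resampling preserves amplitude, duration and annotations", {
  fs <- 500
  rec <- toy_recording(fs = fs, run_dur = 5)
  tt <- seq_len(ncol(rec$data)) / fs
  rec$data[1, ] <- sin(2 * pi * 10 * tt)
  out <- resample_recording(rec, 128)
  expect_equal(out$fs, 128)
  expect_lt(abs(ncol(out$data) / 128 - ncol(rec$data) / fs), 1 / 128)
  expect_identical(out$annotations, rec$annotations)
  # sample i of the output sits at the time of input sample 1 plus i/128
  t2 <- 1 / fs + (seq_len(ncol(out$data)) - 1) / 128
  mid <- seq(128, length(t2) - 128)
  expect_lt(max(abs(out$data[1, mid] - sin(2 * pi * 10 * t2[mid]))), 0.02)
  expect_error(resample_recording(out, 500), "upsampling")
})

test_that("reference recovery and re-referencing behave as declared", {
  # simulate data referenced to a known FCz on a montage including it
  set.seed(5)
  chans <- c(default_montage(), "FCz")
  n <- 5000
  field <- neurocv:::channel_positions(chans)
  K <- exp(-as.matrix(dist(as.matrix(field[, c("x", "y")])))^2 / (2 * 0.5^2))
  eK <- eigen(K, symmetric = TRUE)
  B <- eK$vectors %*% (t(eK$vectors) * sqrt(pmax(eK$values, 1e-9)))
  truth <- B %*% matrix(rnorm(length(chans) * n), length(chans))
  truth <- truth - rep(colMeans(truth), each = length(chans)) # zero common mode
  fcz <- match("FCz", chans)
  referenced <- sweep(truth, 2, truth[fcz, ])[-fcz, ]
  ann <- block_annotations(0, n / 250, "low", 1L, 1L)
  rec <- new_recording(referenced, 250, chans[-fcz], ann, reference = "FCz")
  out <- recover_reference_then_rereference(rec, online_ref = "FCz",
                                            new_ref = "Pz")
  expect_false("Pz" %in% out$channels)
  expect_identical(out$reference, "Pz")
  # CAR recovery: compare a recovered channel against its true
  # Pz-referenced counterpart
  i <- match("Cz", out$channels)
  truth_pz <- truth[match("Cz", chans), ] - truth[match("Pz", chans), ]
  expect_gt(cor(out$data[i, ], truth_pz), 0.99)
  # a second re-referencing to the same reference is a no-op
  rec2 <- out
  rec2$data <- rbind(rec2$data, 0)
  rec2$channels <- c(rec2$channels, "Pz")
  rec2$positions <- neurocv:::channel_positions(rec2$channels)
  out2 <- recover_reference_then_rereference(rec2, new_ref = "Pz")
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  expect_error(recover_reference_then_rereference(rec, new_ref = "POz"),
               "missing")
})

test_that("bad-channel rule removes noise channels and spares clean data", {
  rec <- generate_subject(small_params(run_dur = 10, seed = 51))
  rec$data[4, ] <- rnorm(ncol(rec$data), sd = sd(rec$data[4, ]))
  res <- remove_bad_channels(rec)
  expect_true(rec$channels[4] %in% res$removed)
  expect_identical(remove_bad_channels(rec, threshold = 0)$removed,
                   character(0))
  removals <- vapply(1:10, function(s) {
    # clean data with strong mixing: no block confounds, oscillators at
    # background scale so volume conduction dominates the correlations
    p <- small_params(run_dur = 10, seed = 500 + s, class_effect = 0.5,
                      block_effect = c(channel_gain_sd = 0, drift_sd = 0,
                                       aperiodic_shift_sd = 0),
                      source_amp = c(theta = 5, alpha = 7),
                      subject_var = c(amp_sd = 0, block_sd = 0))
    pp <- preprocess_recording(generate_subject(p))
    length(pp$removed)
  }, numeric(1))
  expect_gte(sum(removals == 0), 9)
  small <- toy_recording(n_ch = 4)
  expect_error(remove_bad_channels(small, n_neighbors = 4), "channels")
})

test_that("butterworth filter bank meets its design constraints", {
  rec <- toy_recording(fs = 128, run_dur = 8)
  tt <- seq_len(ncol(rec$data)) / 128
  rec$data[1, ] <- sin(2 * pi * 10 * tt)
  bank <- butter_filterbank(rec, canonical_bands())
  expect_length(bank, 4)
  mid <- seq(2 * 128, 14 * 128)
  alpha_amp <- max(abs(bank$alpha$data[1, mid]))
  delta_amp <- max(abs(bank$delta$data[1, mid]))
  expect_gt(alpha_amp, 10^(-3 / 20)) # within single-pass passband ripple
  expect_lt(delta_amp, 10^(-20 / 20)) # two-pass stopband: >= 20 dB down
  # analytic responses: butter_response2 is the applied (two-pass)
  # magnitude-squared transfer, so its dB value is 20 log10
  d <- neurocv:::butter_bandpass_design(4, 7, 128)
  expect_gte(20 * log10(neurocv:::butter_response2(d, 4)), -6.03)
  expect_lte(20 * log10(neurocv:::butter_response2(d, 3)), -20)
  expect_lte(20 * log10(neurocv:::butter_response2(d, 8)), -20)
  expect_length(fbcsp_bands(), 10)
  expect_error(neurocv:::butter_bandpass_design(60, 63.95, 128), "infeasible")
  expect_error(neurocv:::butter_bandpass_design(7, 4, 128), "edges")
})

test_that("window extraction follows the floor rule and inherits metadata", {
  mk <- function(dur) {
    fs <- 128
    n <- round(dur * fs)
    ann <- block_annotations(0, dur, "high", 1L, 1L)
    new_recording(matrix(rnorm(2 * n), 2), fs, c("Cz", "Pz"), ann)
  }
  expect_equal(dim(extract_windows(mk(140))$x)[3], 70)
  expect_equal(dim(extract_windows(mk(40))$x)[3], 20)
  ws <- extract_windows(mk(41))
  expect_equal(dim(ws$x)[3], 20) # trailing second dropped
  expect_equal(dim(ws$x)[2], 256) # 2 s x 128 Hz exactly
  expect_error(extract_windows(mk(1.5)), "shorter")
  # each sample belongs to at most one window and metadata partitions
  rec <- toy_recording(fs = 128, run_dur = 5)
  ws <- extract_windows(rec)
  expect_equal(dim(ws$x)[3], 4)
  expect_equal(ws$meta$condition, rep(c("low", "high"), each = 2))
  expect_equal(ws$meta$chrono_index, 1:4)
  expect_equal(ws$x[, , 2], rec$data[, 128 * 2 + seq_len(256)],
               ignore_attr = TRUE)
})

test_that("the preprocessing chain runs in its fixed order", {
  rec <- generate_subject(small_params(run_dur = 10, seed = 61))
  pp <- preprocess_recording(rec)
  expect_identical(attr(pp$recording, "proc_history"),
                   c("notch", "highpass", "resample", "rereference",
                     "bad_channels"))
  expect_equal(pp$recording$fs, 128)
  expect_false("Pz" %in% pp$recording$channels)
})

test_that("the fused filter+resample path matches the sequential chain", {
  rec <- toy_recording(fs = 500, run_dur = 5)
  taps <- list(neurocv:::design_fir_notch(50, 500),
               neurocv:::design_fir_highpass(1, 500))
  fused <- neurocv:::fused_fir_resample(rec$data, 500, taps, 128)
  seq_path <- resample_recording(
    neurocv:::rec_update(rec, data = neurocv:::fir_apply(rec$data, taps)),
    128)$data
  expect_equal(dim(fused), dim(seq_path))
  mid <- seq(129, ncol(fused) - 128)
  scale <- sd(seq_path[, mid])
  expect_lt(max(abs(fused[, mid] - seq_path[, mid])), 1e-3 * scale)
})
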