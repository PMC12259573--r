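#' Recover the online reference and re-reference
#'
#' If the recording declares an online reference channel (e.g. FCz) that is
#' absent from the data, the channel is appended as a flat zero trace and a
#' common average reference is computed, which recovers the online
#' reference's signal up to the (assumed small) common mode. All channels
#' are then re-referenced to `new_ref`, whose residual zero trace is
#' dropped from the data used downstream.
#'
#' @param rec an `ncv_recording`.
#' @param online_ref name of the online reference channel to recover when
#'   it is the declared reference and missing from the montage.
#' @param new_ref channel to re-reference to (must be present).
#' @return re-referenced recording (reference set to `new_ref`).
#' @export
recover_reference_then_rereference <- function(rec, online_ref = "FCz",
                                               new_ref = "Pz") {
  data <- rec$data
  channels <- rec$channels
  if (identical(rec$reference, online_ref) && !(online_ref %in% channels)) {
    data <- rbind(data, 0)
    channels <- c(channels, online_ref)
    data <- sweep(data, 2, colMeans(data)) # CAR recovers the online ref
  }
  if (!(new_ref %in% channels)) stop("new reference channel missing: ", new_ref)
  data <- sweep(data, 2, data[match(new_ref, channels), ])
  keep <- channels != new_ref
  rec$data <- data[keep, , drop = FALSE]
  rec$channels <- channels[keep]
  rec$positions <- channel_positions(rec$channels)
  rec$reference <- new_ref
  attr(rec, "proc_history") <- c(attr(rec, "proc_history"), "rereference")
  rec
}

#' Remove channels poorly correlated with their neighbours
#'
#' A channel is removed when the absolute Pearson correlation between its
#' trace and the average of its `n_neighbors` nearest channels (Euclidean
#' distance in the 2-D 10-20 layout) falls below `threshold`, computed over
#' the whole recording.
#'
#' @param rec an `ncv_recording`.
#' @param threshold correlation threshold (default 0.8).
#' @param n_neighbors number of nearest neighbours to average (default 4).
#' @return list with elements `recording` (channels removed) and `removed`
#'   (character vector of removed channel names).
#' @export
remove_bad_channels <- function(rec, threshold = 0.8, n_neighbors = 4) {
  n_ch <- nrow(rec$data)
  if (n_ch < n_neighbors + 1) stop("need more channels than n_neighbors")
  pos <- as.matrix(rec$positions[, c("x", "y")])
  D <- as.matrix(dist(pos))
  bad <- logical(n_ch)
  for (i in seq_len(n_ch)) {
    nb <- order(D[i, ])[2:(n_neighbors + 1)]
    ref <- colMeans(rec$data[nb, , drop = FALSE])
    bad[i] <- abs(cor(rec$data[i, ], ref)) < threshold
  }
  removed <- rec$channels[bad]
  rec$data <- rec$data[!bad, , drop = FALSE]
  rec$channels <- rec$channels[!bad]
  rec$positions <- channel_positions(rec$channels)
  attr(rec, "proc_history") <- c(attr(rec, "proc_history"), "bad_channels")
  list(recording = rec, removed = removed)
}

#' Extract non-overlapping labelled windows
#'
#' Cuts each annotated run into `floor(duration / length)` contiguous
#' non-overlapping windows aligned to the run onset (partial trailing
#' segments are discarded). Each window inherits the run's condition, set,
#' run, day and block identity, plus a global chronological index.
#'
#' @param rec an `ncv_recording`.
#' @param length window length in seconds (default 2).
#' @param overlap overlap in seconds; only 0 is supported (the evaluation
#'   design relies on disjoint windows).
#' @return an `ncv_window_set`: list with `x` (channels x samples x windows
#'   array), `fs`, `channels` and `meta` (one row per window).
#' @export
extract_windows <- function(rec, length = 2, overlap = 0) {
  stopifnot(overlap == 0)
  wlen <- round(length * rec$fs)
  ann <- rec$annotations[order(rec$annotations$chrono_index), , drop = FALSE]
  if (any(ann$duration < length)) stop("run shorter than one window")
  per_run <- floor(ann$duration / length)
  n_win <- sum(per_run)
  x <- array(0, dim = c(nrow(rec$data), wlen, n_win))
  meta <- vector("list", nrow(ann))
  w <- 0L
  for (i in seq_len(nrow(ann))) {
    start <- round(ann$onset[i] * rec$fs)
    for (j in seq_len(per_run[i])) {
      w <- w + 1L
      x[, , w] <- rec$data[, start + (j - 1) * wlen + seq_len(wlen),
                           drop = FALSE]
    }
    meta[[i]] <- data.frame(
      condition = ann$condition[i], run_id = ann$run_id[i],
      set_id = ann$set_id[i], day_id = ann$day_id[i],
      block_id = ann$block_id[i], stringsAsFactors = FALSE
    )[rep(1, per_run[i]), , drop = FALSE]
  }
  meta <- do.call(rbind, meta)
  meta$chrono_index <- seq_len(n_win)
  rownames(meta) <- NULL
  structure(list(x = x, fs = rec$fs, channels = rec$channels, meta = meta),
            class = "ncv_window_set")
}

#' @export
print.ncv_window_set <- function(x, ...) {
  cat(sprintf("<ncv_window_set> %d windows x %d ch x %d samples @ %g Hz\n",
              dim(x$x)[3], dim(x$x)[1], dim(x$x)[2], x$fs))
  print(table(condition = x$meta$condition, set = x$meta$set_id))
  invisible(x)
}

preprocess_order <- c("notch", "highpass", "resample", "rereference",
                      "bad_channels")

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Fused zero-phase FIR filtering + FFT resampling: both operators are
# diagonal in the frequency domain, so they are applied in one forward /
# one inverse transform on a reflection-padded signal. Exactly equivalent
# to applying the FIR filters and the spectral resampler in sequence on
# the padded signal. Returns NULL when the rate ratio does not divide the
# signal length (caller falls back to the sequential path).
fused_fir_resample <- function(x, fs, taps_list, fs_new) {
  n <- ncol(x)
  g <- gcd2(fs, fs_new)
  p <- fs_new / g
  q <- fs / g
  if (p != round(p) || q != round(q) || (n * p) %% q != 0) return(NULL)
  minpad <- max(vapply(taps_list, length, 1L))
  k <- ceiling(minpad / q)
  for (tries in 1:500) {
    Lp <- n + 2 * k * q
    f <- Lp
    for (d in c(2, 3, 5)) while (f %% d == 0) f <- f / d
    if (f <= 13) break # FFT-friendly length
    k <- k + 1
  }
  pad <- k * q
  if (pad >= n) return(NULL)
  xp <- cbind(x[, pad:1, drop = FALSE], x, x[, n:(n - pad + 1), drop = FALSE])
  X <- stats::mvfft(t(xp))
  key <- paste("prefir", fs, Lp, paste(vapply(taps_list, length, 1L),
                                       collapse = "_"))
  A <- response_cache[[key]]
  if (is.null(A)) {
    # real amplitude response of each delay-compensated symmetric FIR
    w <- 2 * pi * (seq_len(Lp) - 1) / Lp
    A <- rep(1, Lp)
    for (taps in taps_list) {
      H <- fft(c(taps, rep(0, Lp - length(taps))))
      A <- A * Re(H * exp(1i * w * (length(taps) - 1) / 2))
    }
    response_cache[[key]] <- A
  }
  X <- X * A
  m <- Lp * p / q
  Y <- matrix(0i, m, nrow(x))
  half <- floor((m - 1) / 2)
  Y[1, ] <- X[1, ]
  if (half >= 1) {
    ks <- seq_len(half)
    Y[1 + ks, ] <- X[1 + ks, , drop = FALSE]
    Y[m + 1 - ks, ] <- X[Lp + 1 - ks, , drop = FALSE]
  }
  if (m %% 2 == 0) Y[m / 2 + 1, ] <- Re(X[m / 2 + 1, , drop = FALSE])
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / Lp
  t(y)[, pad * p / q + seq_len(n * p / q), drop = FALSE]
}

#' Harmonization preprocessing chain
#'
#' Applies, in this fixed order: 50 Hz notch -> 1 Hz highpass -> resampling
#' to 128 Hz -> reference recovery / re-referencing to Pz -> correlation
#' based bad-channel removal. The order is recorded on the recording and
#' asserted, so downstream classifier-specific filtering cannot run on an
#' unharmonized recording by accident.
#'
#' @param rec an `ncv_recording`.
#' @param notch_f0,highpass_fc,fs_new,new_ref,bad_threshold,n_neighbors
#'   stage parameters (defaults as described).
#' @return list with `recording` and `removed` (bad channels).
#' @export
preprocess_recording <- function(rec, notch_f0 = 50, highpass_fc = 1,
                                 fs_new = 128, new_ref = "Pz",
                                 bad_threshold = 0.8, n_neighbors = 4) {
  # notch + highpass are zero-phase FIRs and the resampler is spectral:
  # all three are diagonal in frequency and are applied in one FFT pass,
  # logged as their three chain steps
  taps <- list(design_fir_notch(notch_f0, rec$fs),
               design_fir_highpass(highpass_fc, rec$fs))
  fused <- fused_fir_resample(rec$data, rec$fs, taps, fs_new)
  if (is.null(fused)) {
    rec <- rec_update(rec, data = fir_apply(rec$data, taps), step = "notch")
    attr(rec, "proc_history") <- c(attr(rec, "proc_history"), "highpass")
    rec <- resample_recording(rec, fs_new)
  } else {
    rec <- rec_update(rec, data = fused, fs = fs_new, step = "notch")
    attr(rec, "proc_history") <- c(attr(rec, "proc_history"),
                                   c("highpass", "resample"))
  }
  rec <- recover_reference_then_rereference(rec, new_ref = new_ref)
  res <- remove_bad_channels(rec, bad_threshold, n_neighbors)
  hist <- attr(res$recording, "proc_history")
  stopifnot(identical(hist, preprocess_order))
  res
}
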