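## FIR designs are Hamming-windowed sincs whose single-applied-pass
## magnitude response is -6 dB at the stated edge frequencies; they are
## linear-phase and applied with group-delay compensation, so the applied
## filter is zero-phase. Filter length follows the 3.3/transition-bandwidth
## rule for Hamming windows.

fir_length <- function(tbw, fs) {
  n <- ceiling(3.3 / tbw * fs)
  n + (n %% 2L) + 1L # odd length, symmetric (type I) impulse response
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Hamming-windowed sinc lowpass, unit DC gain; the magnitude response
# passes through 1/2 (-6.02 dB) at the cutoff frequency.
windowed_lowpass <- function(fc, fs, L) {
  M <- (L - 1) / 2
  n <- 0:(L - 1)
  h <- 2 * fc / fs * sinc(2 * fc / fs * (n - M))
  h <- h * (0.54 - 0.46 * cos(2 * pi * n / (L - 1)))
  h / sum(h)
}

# Highpass / bandpass / band-stop by spectral subtraction of lowpasses of
# the same (odd, linear-phase) length: the -6 dB points land exactly on
# the requested edge frequencies.
design_fir_highpass <- function(fc = 1, fs = 500, tbw = fc) {
  if (fc >= fs / 2) stop("highpass cutoff must lie below Nyquist")
  L <- fir_length(tbw, fs)
  h <- -windowed_lowpass(fc - tbw / 2, fs, L)
  h[(L + 1) / 2] <- h[(L + 1) / 2] + 1
  h
}

design_fir_notch <- function(f0 = 50, fs = 500, edges = f0 + c(-0.75, 0.75),
                             tbw = 0.75) {
  if (f0 >= fs / 2) stop("notch frequency must lie below Nyquist")
  L <- fir_length(tbw, fs)
  h <- windowed_lowpass(edges[1], fs, L) - windowed_lowpass(edges[2], fs, L)
  h[(L + 1) / 2] <- h[(L + 1) / 2] + 1
  h
}

design_fir_bandpass <- function(lo = 1, hi = 25, fs = 128,
                                edge_lo = lo / 2,
                                edge_hi = min(hi + 3, (hi + fs / 2) / 2)) {
  # -6 dB points sit below/above the passband (half the low edge; 3 Hz
  # above the high edge): a 1-25 Hz request yields -6 dB at 0.5 and 28 Hz
  if (hi >= fs / 2) stop("bandpass upper edge must lie below Nyquist")
  L <- fir_length(min(lo, 2 * (edge_hi - hi), 2), fs)
  windowed_lowpass(edge_hi, fs, L) - windowed_lowpass(edge_lo, fs, L)
}

#' Frequency response of an FIR design, in dB
#'
#' Evaluates the single-applied-pass magnitude response of a linear-phase
#' FIR filter at the requested frequencies. Because the package applies FIR
#' filters once with group-delay compensation, this *is* the applied
#' (zero-phase) response.
#'
#' @param taps FIR coefficients.
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return magnitude response in dB.
#' @export
fir_response_db <- function(taps, f, fs) {
  k <- seq_along(taps) - 1
  H <- vapply(f, function(fi) {
    abs(sum(taps * exp(-2i * pi * fi * k / fs)))
  }, numeric(1))
  20 * log10(H)
}

#' Design the preprocessing notch / highpass filters
#'
#' Exposed so the applied responses can be inspected directly; the filters
#' are the ones `notch_filter()` and `highpass_filter()` apply.
#'
#' @param fs sampling rate (Hz).
#' @param f0 notch centre frequency (Hz); -6 dB edges at `f0 +- 0.75` Hz.
#' @param fc highpass cutoff (Hz); -6 dB point at `fc / 2`.
#' @return numeric vector of FIR taps.
#' @export
notch_design <- function(fs, f0 = 50) design_fir_notch(f0, fs)

#' @rdname notch_design
#' @export
highpass_design <- function(fs, fc = 1) design_fir_highpass(fc, fs)

# Zero-phase application of one or more linear-phase FIR filters to a
# channels x samples matrix: one FFT pass per channel, responses multiplied
# together, group delay compensated exactly; reflection padding suppresses
# boundary transients.
fir_apply <- function(x, taps_list) {
  if (!is.list(taps_list)) taps_list <- list(taps_list)
  n <- ncol(x)
  pad <- max(vapply(taps_list, length, 1L))
  stopifnot(pad < n)
  xp <- cbind(x[, pad:1, drop = FALSE], x, x[, n:(n - pad + 1), drop = FALSE])
  np <- ncol(xp)
  nfft <- stats::nextn(np + pad, factors = c(2, 3))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
  H <- rep(1 + 0i, nfft)
  delay <- 0
  for (taps in taps_list) {
    Hi <- fft(c(taps, rep(0, nfft - length(taps))))
    H <- H * Hi
    delay <- delay + (length(taps) - 1) / 2
  }
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  t(y)[, pad + delay + seq_len(n), drop = FALSE]
}

rec_update <- function(rec, data = rec$data, fs = rec$fs, step = NULL) {
  rec$data <- data
  rec$fs <- fs
  if (!is.null(step)) {
    attr(rec, "proc_history") <- c(attr(rec, "proc_history"), step)
  }
  rec
}

#' Zero-phase FIR notch filter
#'
#' Windowed-sinc band-stop at `f0` whose applied magnitude response is
#' -6 dB at `f0 - 0.75` and `f0 + 0.75` Hz (for the default 50 Hz mains
#' notch: 49.25 and 50.75 Hz).
#'
#' @param rec an `ncv_recording`.
#' @param f0 notch frequency in Hz (default 50).
#' @return the filtered recording.
#' @export
notch_filter <- function(rec, f0 = 50) {
  taps <- design_fir_notch(f0, rec$fs)
  rec_update(rec, data = fir_apply(rec$data, taps), step = "notch")
}

#' Zero-phase FIR highpass filter
#'
#' Windowed-sinc highpass at `fc` with the applied -6 dB point at `fc / 2`
#' (default: 1 Hz highpass, -6 dB at 0.5 Hz).
#'
#' @param rec an `ncv_recording`.
#' @param fc cutoff in Hz (default 1).
#' @return the filtered recording.
#' @export
highpass_filter <- function(rec, fc = 1) {
  taps <- design_fir_highpass(fc, rec$fs)
  rec_update(rec, data = fir_apply(rec$data, taps), step = "highpass")
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc bandpass; for the default 1-25 Hz band the applied -6 dB
#' points sit at 0.5 Hz and ~28 Hz (25% transition bandwidth above, full
#' octave below), matching common EEG broadband defaults.
#'
#' @param rec an `ncv_recording`.
#' @param lo,hi passband edges in Hz.
#' @return the filtered recording.
#' @export
bandpass_fir <- function(rec, lo = 1, hi = 25) {
  taps <- design_fir_bandpass(lo, hi, rec$fs)
  rec_update(rec, data = fir_apply(rec$data, taps), step = "bandpass_fir")
}

## Butterworth filter bank ---------------------------------------------------

# Minimal Butterworth bandpass order meeting <= rp dB passband ripple at the
# band edges and >= rs dB attenuation at the edges +- tbw, for a SINGLE
# forward pass; the zero-phase application doubles both in dB.
butter_bandpass_design <- function(lo, hi, fs, rp = 3, rs = 10, tbw = 1) {
  nyq <- fs / 2
  if (!(lo > 0 && hi > lo && hi < nyq)) stop("band edges must satisfy 0 < lo < hi < Nyquist")
  ws_lo <- max(lo - tbw, 0.05)
  ws_hi <- min(hi + tbw, 0.999 * nyq)
  if (ws_hi <= hi || hi - lo <= 0) stop("infeasible band after transitions")
  warp <- function(f) tan(pi * f / fs)
  wl <- warp(lo); wh <- warp(hi); w0sq <- wl * wh; bw <- wh - wl
  omega <- function(f) abs((warp(f)^2 - w0sq) / (warp(f) * bw))
  num <- log10((10^(rs / 10) - 1) / (10^(rp / 10) - 1))
  ord_for <- function(f) {
    om <- omega(f)
    if (om <= 1) Inf else num / (2 * log10(om))
  }
  ords <- c(ord_for(ws_lo), ord_for(ws_hi))
  if (any(!is.finite(ords)) || max(ords) > 50) {
    stop("infeasible band (width <= 0 after transitions)")
  }
  n <- max(1, ceiling(max(ords)))
  flt <- signal::butter(n, c(lo, hi) / nyq, type = "pass")
  list(b = flt$b, a = flt$a, order = n, band = c(lo, hi), fs = fs)
}

butter_response2 <- function(design, f) {
  # magnitude-squared response of the forward-backward (zero-phase) filter;
  # polynomial evaluation vectorized over the frequency grid
  z <- exp(-2i * pi * f / design$fs)
  num <- 0i
  for (bk in rev(design$b)) num <- num * z + bk
  den <- 0i
  for (ak in rev(design$a)) den <- den * z + ak
  Mod(num / den)^2
}

# responses on an FFT grid are identical across subjects: memoize
response_cache <- new.env(parent = emptyenv())

butter_response2_grid <- function(design, nfft, fs) {
  key <- paste(nfft, fs, design$order, paste(design$band, collapse = "-"))
  got <- response_cache[[key]]
  if (!is.null(got)) return(got)
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  fgrid <- pmin(fgrid, fs - fgrid)
  H2 <- butter_response2(design, fgrid)
  response_cache[[key]] <- H2
  H2
}

# Zero-phase Butterworth application in the frequency domain: the two-pass
# (forward-backward) filter has exactly the magnitude-squared response and
# zero phase, which is applied spectrally (no startup transients). The
# forward FFT of the (reflection-padded) signal can be shared across the
# bands of a filter bank.
butter_forward_fft <- function(x, fs) {
  n <- ncol(x)
  pad <- min(n, round(3 * fs))
  xp <- cbind(x[, pad:1, drop = FALSE], x, x[, n:(n - pad + 1), drop = FALSE])
  np <- ncol(xp)
  nfft <- stats::nextn(np, factors = c(2, 3))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
  list(X = X, n = n, pad = pad, nfft = nfft, fs = fs)
}

butter_apply_fft <- function(fwd, design) {
  H2 <- butter_response2_grid(design, fwd$nfft, fwd$fs)
  y <- Re(stats::mvfft(fwd$X * H2, inverse = TRUE)) / fwd$nfft
  t(y)[, fwd$pad + seq_len(fwd$n), drop = FALSE]
}

butter_apply_zerophase <- function(x, design) {
  butter_apply_fft(butter_forward_fft(x, design$fs), design)
}

#' Zero-phase Butterworth filter bank
#'
#' For each band, designs the minimal-order Butterworth bandpass meeting a
#' 3 dB passband ripple and 10 dB stopband attenuation constraint with 1 Hz
#' transition bands for the single forward pass, then applies it
#' forward-backward (zero phase; effective constraints double to 6/20 dB).
#'
#' @param rec an `ncv_recording`.
#' @param bands list (or 2-column matrix) of `c(lo, hi)` passbands in Hz.
#' @param rp,rs,tbw single-pass passband ripple (dB), stopband attenuation
#'   (dB) and transition bandwidth (Hz).
#' @return list of filtered recordings, one per band, named `"lo-hi"`.
#' @export
butter_filterbank <- function(rec, bands, rp = 3, rs = 10, tbw = 1) {
  if (is.matrix(bands)) bands <- split(bands, seq_len(nrow(bands)))
  fwd <- butter_forward_fft(rec$data, rec$fs) # shared across bands
  out <- lapply(bands, function(band) {
    d <- butter_bandpass_design(band[1], band[2], rec$fs, rp, rs, tbw)
    rec_update(rec, data = butter_apply_fft(fwd, d),
               step = sprintf("butter_%g_%g", band[1], band[2]))
  })
  names(out) <- names(bands) %||%
    vapply(bands, function(b) paste0(b[1], "-", b[2]), "")
  out
}

#' Canonical EEG frequency bands
#'
#' Delta (1-4), theta (4-7), alpha (8-12) and beta (13-25) Hz.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
canonical_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 7), alpha = c(8, 12), beta = c(13, 25))
}

#' Filter-bank CSP band grid
#'
#' Ten 4-Hz-wide bins spanning 3-25 Hz in steps of 2 Hz.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
fbcsp_bands <- function() {
  lo <- seq(3, 21, by = 2)
  out <- lapply(lo, function(l) c(l, l + 4))
  names(out) <- vapply(out, function(b) paste0(b[1], "-", b[2]), "")
  out
}

#' Resample a recording (FFT method)
#'
#' Downsamples by Fourier-domain truncation (ideal anti-alias filtering for
#' periodic extension); annotation onsets are expressed in seconds and are
#' unchanged.
#'
#' @param rec an `ncv_recording`.
#' @param fs_new target sampling rate in Hz (must be below `rec$fs`).
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, fs_new = 128) {
  if (fs_new >= rec$fs) stop("upsampling requested; fs_new must be < fs")
  n <- ncol(rec$data)
  m <- round(n * fs_new / rec$fs)
  X <- stats::mvfft(t(rec$data))
  Y <- matrix(0i, m, nrow(rec$data))
  half <- floor((m - 1) / 2)
  Y[1, ] <- X[1, ]
  if (half >= 1) {
    ks <- seq_len(half)
    Y[1 + ks, ] <- X[1 + ks, , drop = FALSE]
    Y[m + 1 - ks, ] <- X[n + 1 - ks, , drop = FALSE]
  }
  if (m %% 2 == 0) Y[m / 2 + 1, ] <- Re(X[m / 2 + 1, , drop = FALSE])
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  rec_update(rec, data = t(y), fs = fs_new, step = "resample")
}
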