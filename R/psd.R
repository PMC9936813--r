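#' Welch power spectral density estimate
#'
#' Segment-averaged windowed periodogram (Hann window, 50% overlap,
#' one-sided, density scaling): the standard Welch estimator for discrete
#' series, matching the common scientific-computing conventions.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length; `x` must be at least this long.
#' @param noverlap samples of overlap (default `nperseg/2`).
#' @param demean subtract each segment's mean before windowing.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 10000),
                      noverlap = nperseg %/% 2, demean = TRUE) {
  n <- length(x)
  if (n < nperseg) stop("series shorter than nperseg")
  w <- hann_window(nperseg)
  step <- nperseg - noverlap
  starts <- seq(1, n - nperseg + 1, by = step)
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * sum(w^2))
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]       # one-sided doubling (not DC/Nyquist)
    if (nperseg %% 2 == 1) p[nf] <- 2 * p[nf]
    acc <- acc + p
  }
  list(freq = seq(0, by = fs / nperseg, length.out = nf),
       psd = acc / length(starts))
}

hann_window <- function(n) {
  i <- seq_len(n) - 1
  0.5 - 0.5 * cos(2 * pi * i / n)            # periodic Hann
}

#' Binary spike-train signal from spike times
#'
#' Bins spike onsets at `bin_ms` resolution: 1 in a bin containing an onset,
#' 0 elsewhere.
#'
#' @param spikes a `spike_record` or numeric onset times (ms).
#' @param duration train length (ms).
#' @param bin_ms bin width (ms); the train's sampling rate is `1000/bin_ms` Hz.
#' @return list with binary `train` and sampling rate `fs`.
#' @export
spike_train_signal <- function(spikes, duration, bin_ms = 1) {
  times <- if (is.numeric(spikes)) spikes else spikes$onset_times
  n <- round(duration / bin_ms)
  train <- integer(n)
  idx <- pmin(n, floor(times / bin_ms) + 1L)
  train[idx] <- 1L
  list(train = train, fs = 1000 / bin_ms)
}

#' PSD of a spike train
#'
#' @param train list from [spike_train_signal()] (or a binary vector with
#'   attribute-free `fs` given).
#' @param fs sampling rate (Hz) if `train` is a plain vector.
#' @param nperseg Welch segment length.
#' @return list with `freq` and `psd`.
#' @export
spike_psd <- function(train, fs = NULL, nperseg = NULL) {
  if (is.list(train)) { fs <- train$fs; train <- train$train }
  if (is.null(fs)) stop("sampling rate required")
  if (is.null(nperseg)) nperseg <- min(length(train), 10000)
  welch_psd(as.numeric(train), fs, nperseg)
}
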