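# Neural feature extraction from broadband signal: spike-band filtering,
# threshold-crossing counts (TC), and spike-band power (SBP) per 20-ms bin.

#' Zero-phase spike-band filter
#'
#' Band-pass filters a broadband signal to the spike band (250-5000 Hz by
#' default) with a 4th-order Butterworth filter applied forward and backward
#' (zero phase).
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param fs Sampling rate in Hz (30 kHz for the recordings emulated here).
#' @param band Passband edges in Hz.
#' @param order Butterworth order (of the one-pass prototype).
#' @return Filtered signal with the same shape as `x`.
#' @export
spike_band_filter <- function(x, fs = 30000, band = c(250, 5000), order = 4) {
  stopifnot(is.numeric(fs), fs > 0, length(band) == 2L,
            band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  warmup <- max(300, 10 * order)
  if (n < warmup)
    stop("segment too short for filter warm-up: need >= ", warmup, " samples")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt1 <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

.channel_rms <- function(x) sqrt(mean(x^2))

#' Threshold-crossing counts per bin
#'
#' Counts negative-going crossings of a channel-specific noise threshold in
#' non-overlapping bins.  The threshold defaults to `multiplier` times the
#' RMS of a reference segment of the filtered signal (the signal itself if no
#' reference is supplied), following standard intracortical practice of
#' -4.5 x RMS with negative-going detection.
#'
#' @param x Filtered signal, numeric vector (one channel).
#' @param fs Sampling rate in Hz.
#' @param bin_ms Bin width in milliseconds.
#' @param multiplier RMS multiplier defining the threshold (negative).
#' @param threshold Optional explicit threshold (overrides `multiplier`).
#' @param reference Optional signal segment whose RMS sets the threshold
#'   (e.g. the first 30 s of a block).
#' @return Integer vector of counts, one per complete bin (a trailing partial
#'   bin is dropped).
#' @export
extract_tc <- function(x, fs = 30000, bin_ms = 20, multiplier = -4.5,
                       threshold = NULL, reference = NULL) {
  stopifnot(is.numeric(x), fs > 0, bin_ms > 0)
  if (is.null(threshold)) {
    ref <- if (is.null(reference)) x else reference
    rms <- .channel_rms(ref)
    if (rms == 0) stop("zero-variance channel: threshold undefined")
    threshold <- multiplier * rms
  }
  spb <- round(fs * bin_ms / 1000)
  n_bins <- length(x) %/% spb
  if (n_bins < 1) stop("signal shorter than one bin")
  n_use <- n_bins * spb
  cross <- which(x[-1] <= threshold & x[-length(x)] > threshold)
  cross <- cross[cross < n_use]  # crossing at sample cross+1
  counts <- tabulate(((cross) %/% spb) + 1L, nbins = n_bins)
  as.integer(counts)
}

#' Spike-band power per bin
#'
#' Root-mean-square amplitude of the (spike-band filtered) signal in
#' non-overlapping bins.
#'
#' @inheritParams extract_tc
#' @return Numeric vector of per-bin RMS values (trailing partial bin
#'   dropped).
#' @export
extract_sbp <- function(x, fs = 30000, bin_ms = 20) {
  stopifnot(is.numeric(x), fs > 0, bin_ms > 0)
  spb <- round(fs * bin_ms / 1000)
  n_bins <- length(x) %/% spb
  if (n_bins < 1) stop("signal shorter than one bin")
  m <- matrix(x[seq_len(n_bins * spb)]^2, nrow = spb)
  sqrt(colMeans(m))
}

#' Extract a feature tensor from broadband trials
#'
#' Runs the full desk-scale feature chain on a [generate_broadband()] session
#' (or any list of channels x samples matrices): spike-band filtering, then
#' TC counts and SBP per bin for each channel.  Features 1..C are TC by
#' channel and C+1..2C are SBP by channel, mirroring the 1-192 / 193-384
#' numbering of the recordings.
#'
#' Channel thresholds are fixed from a reference window (the first
#' `reference_s` seconds of the concatenated filtered trials), then applied
#' unchanged to every trial, as a real-time system would.
#'
#' @param bb A `"broadband_session"` or list of channels x samples matrices.
#' @param fs Sampling rate (taken from `bb` when available).
#' @param bin_ms Bin width in milliseconds.
#' @param multiplier Threshold multiplier for TC extraction.
#' @param reference_s Length of the threshold reference window in seconds.
#' @return A [feature_tensor()] with 2 x channels features.
#' @export
extract_features <- function(bb, fs = NULL, bin_ms = 20, multiplier = -4.5,
                             reference_s = 30) {
  if (inherits(bb, "broadband_session")) {
    fs <- bb$fs
    trials <- bb$trials
  } else {
    trials <- bb
    if (is.null(fs)) stop("fs required when bb is a plain list")
  }
  stopifnot(length(trials) >= 1, is.matrix(trials[[1]]))
  ncha <- nrow(trials[[1]])
  filt <- lapply(trials, spike_band_filter, fs = fs)

  # channel thresholds from the leading reference window
  nref <- round(reference_s * fs)
  thr <- numeric(ncha)
  for (ch in seq_len(ncha)) {
    ref <- unlist(lapply(filt, function(m) m[ch, ]), use.names = FALSE)
    ref <- ref[seq_len(min(nref, length(ref)))]
    rms <- .channel_rms(ref)
    if (rms == 0) stop("zero-variance channel ", ch, ": threshold undefined")
    thr[ch] <- multiplier * rms
  }

  spb <- as.integer(round(fs * bin_ms / 1000))
  n_bins <- vapply(filt, function(m) ncol(m) %/% spb, 0L)
  nbmax <- max(n_bins)
  nf <- 2L * ncha
  values <- array(NA_real_, c(nf, nbmax, length(filt)))
  for (i in seq_along(filt)) {
    for (ch in seq_len(ncha)) {
      v <- filt[[i]][ch, ]
      values[ch, seq_len(n_bins[i]), i] <-
        extract_tc(v, fs, bin_ms, threshold = thr[ch])
      values[ncha + ch, seq_len(n_bins[i]), i] <- extract_sbp(v, fs, bin_ms)
    }
  }
  feature_tensor(values, kind = rep(c("TC", "SBP"), each = ncha),
                 bin_ms = bin_ms, n_bins = n_bins)
}
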