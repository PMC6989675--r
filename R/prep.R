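# Pre-processing: Gaussian temporal smoothing, PSTHs, baseline-deviation
# modulation depths, SNR ranking, and trial-averaged time-course correlations.

#' Gaussian smoothing kernel matrix
#'
#' Column `j` holds the (edge-renormalized) weights producing smoothed bin
#' `j` from the raw bins: a unit-mass discrete Gaussian of the stated SD,
#' truncated at +/- 3 SD, renormalized where the window hangs over an edge so
#' that constant traces are preserved exactly.
#'
#' @param n_bins Trace length in bins.
#' @param sd_bins Kernel SD in bins.
#' @return `n_bins` x `n_bins` matrix `K` with `colSums(K) == 1`.
#' @keywords internal
gaussian_kernel_matrix <- function(n_bins, sd_bins) {
  stopifnot(n_bins >= 1, sd_bins > 0)
  L <- ceiling(3 * sd_bins)
  off <- -L:L
  w <- stats::dnorm(off, sd = sd_bins)
  w <- w / sum(w)
  K <- matrix(0, n_bins, n_bins)
  for (j in seq_len(n_bins)) {
    src <- j + off
    ok <- src >= 1 & src <= n_bins
    K[src[ok], j] <- w[ok] / sum(w[ok])
  }
  K
}

#' Temporal Gaussian smoothing
#'
#' Convolves each feature trace with a unit-mass Gaussian kernel of the given
#' SD (in milliseconds), truncated at +/- 3 SD and renormalized at the edges.
#' For a [feature_tensor()], each trial is smoothed over its own valid bins.
#'
#' @param x Numeric vector, features x bins matrix, or [feature_tensor()].
#' @param sd_ms Kernel SD in milliseconds (must be positive).
#' @param bin_ms Bin width in milliseconds (taken from the tensor when `x`
#'   is one).
#' @return Smoothed object of the same shape/class as `x`.
#' @export
smooth_gaussian <- function(x, sd_ms, bin_ms = 20) {
  if (!is.numeric(sd_ms) || length(sd_ms) != 1L || sd_ms <= 0)
    stop("sd_ms must be a single positive number")
  if (inherits(x, "feature_tensor")) {
    out <- x
    for (i in seq_along(x$n_bins)) {
      nb <- x$n_bins[i]
      K <- gaussian_kernel_matrix(nb, sd_ms / x$bin_ms)
      out$values[, seq_len(nb), i] <-
        x$values[, seq_len(nb), i, drop = FALSE][, , 1] %*% K
    }
    return(out)
  }
  if (is.matrix(x)) {
    K <- gaussian_kernel_matrix(ncol(x), sd_ms / bin_ms)
    return(x %*% K)
  }
  K <- gaussian_kernel_matrix(length(x), sd_ms / bin_ms)
  drop(matrix(x, 1) %*% K)
}

# bin indices covering [start_ms, start_ms + len_ms) relative to go onset;
# errors if any selected trial cannot supply the window
.window_bins <- function(tensor, trials, start_ms, len_ms,
                         idx = seq_len(nrow(trials))) {
  bin_ms <- tensor$bin_ms
  n_w <- as.integer(round(len_ms / bin_ms))
  if (n_w < 1) stop("window shorter than one bin")
  start_bin <- as.integer(floor((trials$go_onset * 1000 + start_ms) / bin_ms)) + 1L
  if (any(start_bin[idx] < 1) ||
      any(start_bin[idx] + n_w - 1L > tensor$n_bins[idx]))
    stop("window [", start_ms, ", ", start_ms + len_ms,
         ") ms around go onset falls outside some trial's extent")
  list(start = start_bin, n = n_w)
}

# default go-phase window length: the shortest go phase, floored to whole bins
.min_go_ms <- function(tensor, trials) {
  floor(min((trials$stop_onset - trials$go_onset) * 1000 / tensor$bin_ms)) *
    tensor$bin_ms
}

#' Peristimulus time histogram (PSTH)
#'
#' Go-aligned mean feature trace over a set of trials.  Supports the two
#' marginalizations used to characterize tuning: averaging over states
#' within a force level, or over forces within a state, via `select`.
#'
#' @param tensor A [feature_tensor()].
#' @param trials Matching trial table.
#' @param select Logical or integer vector choosing the trials to average
#'   (default: all).
#' @param start_ms Window start relative to go onset (ms; may be negative).
#' @param len_ms Window length (ms; default: the shortest go phase).
#' @param smooth_sd_ms Optional Gaussian SD (ms) applied to each trial's
#'   trace before averaging (100 ms in the tuning figures; visualization
#'   only -- statistics use unsmoothed depths).
#' @return A features x bins matrix of class `"psth"` with attributes
#'   `n_trials`, `start_ms`, `bin_ms`.
#' @export
compute_psth <- function(tensor, trials, select = NULL, start_ms = 0,
                         len_ms = NULL, smooth_sd_ms = NULL) {
  stopifnot(inherits(tensor, "feature_tensor"), nrow(trials) == dim(tensor)[3])
  idx <- if (is.null(select)) seq_len(nrow(trials)) else which(
    if (is.logical(select)) select else seq_len(nrow(trials)) %in% select)
  if (length(idx) == 0) stop("no trials selected")
  if (is.null(len_ms)) len_ms <- .min_go_ms(tensor, trials)
  w <- .window_bins(tensor, trials, start_ms, len_ms, idx)
  nf <- dim(tensor)[1]
  acc <- matrix(0, nf, w$n)
  for (i in idx) {
    sl <- tensor$values[, w$start[i]:(w$start[i] + w$n - 1L), i, drop = FALSE][, , 1]
    if (!is.null(smooth_sd_ms))
      sl <- smooth_gaussian(sl, smooth_sd_ms, tensor$bin_ms)
    acc <- acc + sl
  }
  structure(acc / length(idx), class = c("psth", "matrix"),
            n_trials = length(idx), start_ms = start_ms, bin_ms = tensor$bin_ms)
}

#' Go-phase modulation depths relative to rest baseline
#'
#' For each feature: baseline is the mean go-phase activity over rest trials;
#' each trial's modulation depth is the mean over go-phase bins of activity
#' minus baseline.  The go-phase window runs from go onset for the length of
#' the shortest go phase, so every trial contributes the same number of bins.
#'
#' @param tensor A [feature_tensor()].
#' @param trials Matching trial table (must contain rest trials).
#' @param start_ms,len_ms Depth window relative to go onset (defaults: 0 and
#'   the shortest go phase).
#' @param rest_loo If `TRUE`, each rest trial's own depth is computed against
#'   a baseline from the *other* rest trials (leave-one-out); used for
#'   diagnostics.
#' @return List of class `"modulation_depths"`: `depths` (features x trials
#'   matrix), `baseline` (per-feature), `window`, and the trial table.
#' @export
baseline_deviation <- function(tensor, trials, start_ms = 0, len_ms = NULL,
                               rest_loo = FALSE) {
  stopifnot(inherits(tensor, "feature_tensor"), nrow(trials) == dim(tensor)[3])
  rest <- which(trials$condition == "rest")
  if (length(rest) == 0) stop("no rest trials: baseline undefined")
  if (is.null(len_ms)) len_ms <- .min_go_ms(tensor, trials)
  w <- .window_bins(tensor, trials, start_ms, len_ms)
  nf <- dim(tensor)[1]
  nt <- nrow(trials)
  gm <- matrix(NA_real_, nf, nt)  # per-trial go-phase mean
  for (i in seq_len(nt)) {
    gm[, i] <- rowMeans(tensor$values[, w$start[i]:(w$start[i] + w$n - 1L), i,
                                      drop = FALSE][, , 1, drop = FALSE])
  }
  baseline <- rowMeans(gm[, rest, drop = FALSE])
  depths <- gm - baseline
  if (rest_loo && length(rest) > 1) {
    rs <- rowSums(gm[, rest, drop = FALSE])
    for (j in rest) depths[, j] <- gm[, j] - (rs - gm[, j]) / (length(rest) - 1)
  }
  structure(list(depths = depths, baseline = baseline,
                 window = c(start_ms = start_ms, len_ms = len_ms),
                 trials = trials),
            class = "modulation_depths")
}

#' Condition-mean depths with confidence intervals, normalized per feature
#'
#' Averages per-trial modulation depths within each force x state condition
#' and attaches 95% t-intervals; each feature's means are also divided by its
#' maximum absolute condition mean, the normalization used to display simple
#' main effects.
#'
#' @param md A [baseline_deviation()] result.
#' @param conf Confidence level for the t-intervals.
#' @return Long data.frame: `feature`, `force`, `state`, `n`, `mean`, `lo`,
#'   `hi`, `norm_mean`, `norm_lo`, `norm_hi`.
#' @export
normalized_depths <- function(md, conf = 0.95) {
  stopifnot(inherits(md, "modulation_depths"))
  trials <- md$trials
  idx <- which(trials$condition %in% force_levels())
  f <- factor(trials$condition[idx], force_levels())
  s <- factor(trials$state[idx], vos_levels())
  D <- md$depths[, idx, drop = FALSE]
  grid <- expand.grid(force = force_levels(), state = vos_levels(),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  nf <- nrow(D)
  for (g in seq_len(nrow(grid))) {
    sel <- f == grid$force[g] & s == grid$state[g]
    n <- sum(sel)
    m <- rowMeans(D[, sel, drop = FALSE])
    se <- sqrt(apply(D[, sel, drop = FALSE], 1, stats::var) / n)
    tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    out[[g]] <- data.frame(feature = seq_len(nf), force = grid$force[g],
                           state = grid$state[g], n = n, mean = m,
                           lo = m - tcrit * se, hi = m + tcrit * se)
  }
  res <- do.call(rbind, out)
  nrm <- tapply(abs(res$mean), res$feature, max)[as.character(res$feature)]
  nrm[nrm == 0] <- 1  # all-zero feature: leave values at 0
  res$norm_mean <- res$mean / nrm
  res$norm_lo <- res$lo / nrm
  res$norm_hi <- res$hi / nrm
  rownames(res) <- NULL
  res
}

#' Rank features by signal-to-noise ratio
#'
#' SNR per feature is the absolute mean go-phase deviation across non-rest
#' trials divided by the SD of rest-trial depths (the SD is unaffected by the
#' shared baseline shift).  Scale-free; ties broken by feature index.
#'
#' @param md A [baseline_deviation()] result.
#' @param n_top Optionally return only the top `n_top` features (the
#'   correlation analyses use the 120 highest-SNR features).
#' @return Data.frame ordered by decreasing SNR: `feature`, `snr`.
#' @export
snr_rank <- function(md, n_top = NULL) {
  stopifnot(inherits(md, "modulation_depths"))
  trials <- md$trials
  active <- trials$condition != "rest"
  rest <- which(trials$condition == "rest")
  if (length(rest) < 2) stop("need >= 2 rest trials to estimate noise")
  sig <- abs(rowMeans(md$depths[, active, drop = FALSE]))
  noise <- apply(md$depths[, rest, drop = FALSE], 1, stats::sd)
  snr <- ifelse(noise > 0, sig / noise, 0)
  ord <- order(-snr, seq_along(snr))
  out <- data.frame(feature = ord, snr = snr[ord])
  if (!is.null(n_top)) out <- out[seq_len(min(n_top, nrow(out))), ]
  rownames(out) <- NULL
  out
}

#' Correlation of trial-averaged feature time courses
#'
#' Pearson correlation, per feature, between two PSTHs over their (shared)
#' window -- e.g. force vs finger-wiggle traces within a volitional state for
#' the kinetic-vs-kinematic comparison.  Features whose trace is constant in
#' either PSTH yield `NA`.
#'
#' @param psth_a,psth_b Two [compute_psth()] results with matching dimensions.
#' @return Numeric vector of per-feature correlation coefficients.
#' @export
timecourse_correlation <- function(psth_a, psth_b) {
  stopifnot(inherits(psth_a, "psth"), inherits(psth_b, "psth"),
            all(dim(psth_a) == dim(psth_b)))
  a <- unclass(psth_a); b <- unclass(psth_b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  r <- rep(NA_real_, nrow(a))
  ok <- va > 0 & vb > 0
  if (any(!ok)) warning(sum(!ok), " feature(s) with zero-variance trace: r = NA")
  for (i in which(ok)) r[i] <- stats::cor(a[i, ], b[i, ])
  r
}
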