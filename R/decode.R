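# LDA decoding in CSIM space: stratified k-fold cross-validation,
# permutation (label-shuffle) chance distributions, sliding/growing-window
# decoding series, and go-phase confusion matrices.

# Fit LDA with a shared within-class covariance shrunk toward a scaled
# identity (Ledoit-Wolf-style regularization with fixed intensity lambda):
# with ~20-60 trials per class in 10 dimensions the pooled covariance is
# otherwise ill-conditioned.
.lda_fit <- function(X, y, K, lambda) {
  nk <- tabulate(y, K)
  if (any(nk == 0)) stop("a class is absent from a training fold")
  M <- rowsum(X, y) / nk
  Xc <- X - M[y, , drop = FALSE]
  S <- crossprod(Xc) / max(1L, nrow(X) - K)
  p <- ncol(X)
  if (lambda > 0)
    S <- (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  Si <- tryCatch(chol2inv(chol(S)), error = function(e)
    stop("singular pooled covariance; increase lambda"))
  W <- Si %*% t(M)
  b <- -0.5 * colSums(t(M) * W) + log(nk / sum(nk))
  list(W = W, b = b)
}

.lda_predict <- function(fit, X) {
  max.col(X %*% fit$W + rep(fit$b, each = nrow(X)), ties.method = "first")
}

# stratified fold assignment: within each class, fold ids 1..k dealt as
# evenly as possible in random order
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

.cv_lda <- function(X, y, folds, K, lambda) {
  pred <- integer(length(y))
  for (f in seq_len(max(folds))) {
    te <- folds == f
    fit <- .lda_fit(X[!te, , drop = FALSE], y[!te], K, lambda)
    pred[te] <- .lda_predict(fit, X[te, , drop = FALSE])
  }
  pred
}

#' Cross-validated LDA accuracy
#'
#' Stratified k-fold cross-validation of a shrinkage-regularized LDA
#' classifier: per fold the classifier is fit on the training trials and
#' evaluated on the held-out trials; accuracy is the pooled fraction correct
#' over all held-out trials.
#'
#' @param x Trials x dimensions matrix (e.g. a 10-D CSIM embedding).
#' @param labels Class label per trial (>= `k` trials per class).
#' @param k Number of folds (10).
#' @param lambda Covariance shrinkage intensity in `[0, 1]`.
#' @param seed Integer seed for the fold assignment (`NULL`: current RNG
#'   state).
#' @param predictions If `TRUE`, also return the held-out predictions.
#' @return Accuracy (fraction correct), or a list with `accuracy`,
#'   `predicted`, `truth` when `predictions = TRUE`.
#' @export
crossval_accuracy <- function(x, labels, k = 10, lambda = 0.1, seed = NULL,
                              predictions = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  yf <- factor(labels)
  y <- as.integer(yf)
  K <- nlevels(yf)
  if (K < 2) stop("need >= 2 classes")
  if (min(tabulate(y, K)) < k)
    stop("need >= k trials per class for stratified ", k, "-fold CV")
  if (!is.null(seed)) set.seed(as.integer(seed))
  folds <- .stratified_folds(y, k)
  pred <- .cv_lda(x, y, folds, K, lambda)
  acc <- mean(pred == y)
  if (!predictions) return(acc)
  list(accuracy = acc,
       predicted = factor(levels(yf)[pred], levels(yf)),
       truth = yf)
}

#' Empirical chance distribution by label shuffling
#'
#' Estimates the decoding chance level by re-running the cross-validated LDA
#' under uniform random permutations of the trial labels, with the embedding
#' held fixed (the embedding is label-blind, so permuting labels after
#' embedding gives an exact null).  Reports the distribution mean and its
#' central 95% interval (2.5th / 97.5th percentiles).
#'
#' @inheritParams crossval_accuracy
#' @param n_shuffles Number of label permutations (10000 in the full
#'   analysis; a warning is issued below 100, where the interval is
#'   unstable).
#' @param seed Integer seed (shuffles and folds).
#' @return List of class `"chance_distribution"`: `mean`, `lo`, `hi`
#'   (2.5th / 97.5th percentiles), `samples`, `n_trials`, `n_shuffles`.
#' @export
chance_distribution <- function(x, labels, n_shuffles = 10000, k = 10,
                                lambda = 0.1, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (n_shuffles < 100)
    warning("n_shuffles < 100: percentile interval will be unstable")
  yf <- factor(labels)
  y <- as.integer(yf)
  K <- nlevels(yf)
  if (min(tabulate(y, K)) < k)
    stop("need >= k trials per class for stratified ", k, "-fold CV")
  if (!is.null(seed)) set.seed(as.integer(seed))
  acc <- numeric(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    yp <- sample(y)
    folds <- .stratified_folds(yp, k)
    acc[i] <- mean(.cv_lda(x, yp, folds, K, lambda) == yp)
  }
  qs <- stats::quantile(acc, c(0.025, 0.975), names = FALSE)
  structure(list(mean = mean(acc), lo = qs[1], hi = qs[2], samples = acc,
                 n_trials = length(y), n_shuffles = n_shuffles),
            class = "chance_distribution")
}

# trials and labels entering a decode: VoS decoding uses force trials
# labeled by state; force decoding uses one state's force trials labeled by
# force level
.decode_selection <- function(trials, factor = c("state", "force"),
                              state = NULL) {
  what <- match.arg(factor)
  if (what == "state") {
    idx <- which(trials$condition %in% force_levels())
    labels <- base::factor(trials$state[idx], vos_levels())
  } else {
    if (is.null(state) || !state %in% vos_levels())
      stop("force decoding requires state in ", paste(vos_levels(), collapse = "/"))
    idx <- which(trials$condition %in% force_levels() & trials$state == state)
    labels <- base::factor(trials$condition[idx], force_levels())
  }
  list(idx = idx, labels = labels)
}

# latest window end (ms after go onset) available in every selected trial
.span_limit_ms <- function(tensor, trials, idx = seq_len(nrow(trials))) {
  floor(min(tensor$n_bins[idx] * tensor$bin_ms / 1000 - trials$go_onset[idx]) *
          1000 / tensor$bin_ms) * tensor$bin_ms
}

# one window's decode: vectors -> cosine -> 10-D embedding -> CV (+ chance)
.window_decode <- function(tensor, trials, sel, start_ms, len_ms, dims,
                           perplexity, n_iter, k, lambda, n_shuffles, seed) {
  V <- trial_vectors(tensor, trials, start_ms = start_ms, len_ms = len_ms,
                     select = sel$idx)
  Dm <- cosine_dissimilarity(V)
  Y <- csim_embed(Dm, dims = dims, perplexity = perplexity, n_iter = n_iter,
                  seed = seed)
  acc <- crossval_accuracy(Y, sel$labels, k = k, lambda = lambda,
                           seed = seed + 1L)
  ch <- if (n_shuffles > 0)
    chance_distribution(Y, sel$labels, n_shuffles = n_shuffles, k = k,
                        lambda = lambda, seed = seed + 2L)
  else NULL
  data.frame(window_start_ms = start_ms, window_len_ms = len_ms,
             accuracy = acc,
             chance_mean = if (is.null(ch)) NA_real_ else ch$mean,
             chance_lo = if (is.null(ch)) NA_real_ else ch$lo,
             chance_hi = if (is.null(ch)) NA_real_ else ch$hi)
}

#' Sliding-window decoding series
#'
#' Time-resolved decoding: for each position of a 400-ms window stepped in
#' 100-ms increments (aligned to go onset, spanning from `start_ms` through
#' the stop phase), trial vectors are built, embedded into a `dims`-D CSIM
#' space, and classified with cross-validated LDA; each window also carries
#' its label-shuffle chance summary.  Windows extending past the shortest
#' trial are truncated from the series.  VoS decoding uses all force trials;
#' force decoding is computed within one volitional state via `state`.
#'
#' @param tensor A [feature_tensor()].
#' @param trials Matching trial table.
#' @param factor `"state"` or `"force"`.
#' @param state Volitional state for force decoding.
#' @param win_ms,step_ms Window length and step (400 / 100 ms).
#' @param start_ms First window start relative to go onset (default -1000,
#'   clipped to what the shortest prep phase allows).
#' @param end_ms Last allowed window end (default: shortest trial).
#' @param dims Embedding dimension (10).
#' @param perplexity,n_iter t-SNE settings (see [csim_embed()]).
#' @param k,lambda Cross-validation folds and LDA shrinkage.
#' @param n_shuffles Label shuffles per window for the chance band (0 to
#'   skip; the full analysis uses 10000 -- scale to taste).
#' @param seed Integer seed.
#' @return Data.frame of class `"decoding_series"`: one row per window with
#'   `window_start_ms`, `window_len_ms`, `accuracy`, `chance_mean`,
#'   `chance_lo`, `chance_hi`, plus `factor` / `state` attributes.
#' @export
sliding_window_decode <- function(tensor, trials, factor = c("state", "force"),
                                  state = NULL, win_ms = 400, step_ms = 100,
                                  start_ms = -1000, end_ms = NULL, dims = 10,
                                  perplexity = NULL, n_iter = 1000, k = 10,
                                  lambda = 0.1, n_shuffles = 200, seed = 1L) {
  factor <- match.arg(factor)
  sel <- .decode_selection(trials, factor, state)
  lo <- -floor(min(trials$go_onset[sel$idx]) * 1000 / tensor$bin_ms) *
    tensor$bin_ms
  hi <- .span_limit_ms(tensor, trials, sel$idx)
  if (is.null(end_ms)) end_ms <- hi
  end_ms <- min(end_ms, hi)
  starts <- seq(max(start_ms, lo), end_ms - win_ms, by = step_ms)
  if (length(starts) == 0) stop("no window fits the configured span")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    out[[i]] <- .window_decode(tensor, trials, sel, starts[i], win_ms, dims,
                               perplexity, n_iter, k, lambda, n_shuffles,
                               seed + 10L * i)
  }
  res <- do.call(rbind, out)
  attr(res, "factor") <- factor
  attr(res, "state") <- state
  class(res) <- c("decoding_series", "data.frame")
  res
}

#' Growing-window decoding series
#'
#' As [sliding_window_decode()], but every window is anchored at go onset and
#' grows in length (100 ms to 3000 ms in 100-ms increments by default),
#' probing how much go-phase data the classifier needs.  Lengths exceeding
#' the shortest trial are truncated from the series.
#'
#' @inheritParams sliding_window_decode
#' @param lengths_ms Vector of window lengths in ms.
#' @return A `"decoding_series"` data.frame (window start fixed at 0).
#' @export
growing_window_decode <- function(tensor, trials, factor = c("state", "force"),
                                  state = NULL,
                                  lengths_ms = seq(100, 3000, by = 100),
                                  dims = 10, perplexity = NULL, n_iter = 1000,
                                  k = 10, lambda = 0.1, n_shuffles = 200,
                                  seed = 1L) {
  factor <- match.arg(factor)
  sel <- .decode_selection(trials, factor, state)
  hi <- .span_limit_ms(tensor, trials, sel$idx)
  lengths_ms <- lengths_ms[lengths_ms <= hi]
  if (length(lengths_ms) == 0) stop("no window fits the configured span")
  out <- vector("list", length(lengths_ms))
  for (i in seq_along(lengths_ms)) {
    out[[i]] <- .window_decode(tensor, trials, sel, 0, lengths_ms[i], dims,
                               perplexity, n_iter, k, lambda, n_shuffles,
                               seed + 10L * i)
  }
  res <- do.call(rbind, out)
  attr(res, "factor") <- factor
  attr(res, "state") <- state
  class(res) <- c("decoding_series", "data.frame")
  res
}

#' Go-phase confusion matrix
#'
#' Accumulates cross-validated predictions from a 400-ms window stepped
#' across the go phase into a true x predicted confusion matrix per window,
#' row-normalizes each, and averages the matrices over windows.
#'
#' @inheritParams sliding_window_decode
#' @return K x K matrix (rows = true classes, columns = predicted; rows sum
#'   to 1) with attribute `n_windows`.
#' @export
confusion_go <- function(tensor, trials, factor = c("state", "force"),
                         state = NULL, win_ms = 400, step_ms = 100,
                         dims = 10, perplexity = NULL, n_iter = 1000,
                         k = 10, lambda = 0.1, seed = 1L) {
  factor <- match.arg(factor)
  sel <- .decode_selection(trials, factor, state)
  go_ms <- .min_go_ms(tensor, trials[sel$idx, , drop = FALSE])
  starts <- seq(0, go_ms - win_ms, by = step_ms)
  if (length(starts) == 0) stop("go phase shorter than one window")
  lev <- levels(sel$labels)
  K <- length(lev)
  acc <- matrix(0, K, K, dimnames = list(true = lev, predicted = lev))
  for (i in seq_along(starts)) {
    V <- trial_vectors(tensor, trials, start_ms = starts[i], len_ms = win_ms,
                       select = sel$idx)
    Y <- csim_embed(cosine_dissimilarity(V), dims = dims,
                    perplexity = perplexity, n_iter = n_iter,
                    seed = seed + 10L * i)
    cv <- crossval_accuracy(Y, sel$labels, k = k, lambda = lambda,
                            seed = seed + 10L * i + 1L, predictions = TRUE)
    cm <- table(cv$truth, cv$predicted)
    acc <- acc + cm / rowSums(cm)
  }
  out <- acc / length(starts)
  attr(out, "n_windows") <- length(starts)
  out
}
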