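# Continuous similarity (CSIM) analysis: smoothed trial vectors, cosine
# dissimilarity, exact-gradient t-SNE embedding of the precomputed
# dissimilarities, and within/between-condition distance statistics.

#' Smoothed per-trial feature vectors
#'
#' Extracts, for each selected trial, the feature activity in a window
#' relative to go onset, smooths it with a Gaussian kernel (400 ms / 20 bins
#' by default), and flattens it feature-major (all bins of feature 1, then
#' all bins of feature 2, ...).  Smoothing is applied on the window extended
#' by 3 kernel SDs on each side (clipped to the trial extent) so interior
#' bins see the same kernel mass as a whole-trial smooth.
#'
#' By default only force trials enter the similarity analysis (wiggle and
#' rest excluded).
#'
#' @param tensor A [feature_tensor()].
#' @param trials Matching trial table.
#' @param start_ms Window start relative to go onset (ms).
#' @param len_ms Window length (ms; default: the shortest go phase).
#' @param smooth_sd_ms Gaussian SD in ms (`NULL` to skip smoothing).
#' @param select `"force"` (default), `"all"`, or a logical/integer trial
#'   selector.
#' @return Trials x (features * bins) numeric matrix with attributes
#'   `trial_idx`, `n_features`, `n_bins_window`, `layout = "feature-major"`.
#' @export
trial_vectors <- function(tensor, trials, start_ms = 0, len_ms = NULL,
                          smooth_sd_ms = 400, select = "force") {
  stopifnot(inherits(tensor, "feature_tensor"), nrow(trials) == dim(tensor)[3])
  idx <- if (identical(select, "force")) {
    which(trials$condition %in% force_levels())
  } else if (identical(select, "all")) {
    seq_len(nrow(trials))
  } else if (is.logical(select)) {
    which(select)
  } else {
    as.integer(select)
  }
  if (length(idx) == 0) stop("no trials selected")
  if (is.null(len_ms)) len_ms <- .min_go_ms(tensor, trials)
  w <- .window_bins(tensor, trials, start_ms, len_ms, idx)
  nf <- dim(tensor)[1]
  bin_ms <- tensor$bin_ms
  margin <- if (is.null(smooth_sd_ms)) 0L else
    as.integer(ceiling(3 * smooth_sd_ms / bin_ms))
  V <- matrix(NA_real_, length(idx), nf * w$n)
  for (k in seq_along(idx)) {
    i <- idx[k]
    a <- max(1L, w$start[i] - margin)
    b <- min(tensor$n_bins[i], w$start[i] + w$n - 1L + margin)
    sl <- tensor$values[, a:b, i, drop = FALSE][, , 1, drop = FALSE]
    dim(sl) <- dim(sl)[1:2]
    if (!is.null(smooth_sd_ms)) sl <- smooth_gaussian(sl, smooth_sd_ms, bin_ms)
    keep <- (w$start[i] - a + 1L):(w$start[i] - a + w$n)
    V[k, ] <- as.vector(t(sl[, keep, drop = FALSE]))
  }
  structure(V, trial_idx = idx, n_features = nf, n_bins_window = w$n,
            layout = "feature-major")
}

#' Cosine dissimilarity matrix
#'
#' `d(u, v) = 1 - cos(angle(u, v))`: 0 for identical directions, 1 for
#' orthogonal vectors, 2 for antipodal vectors.  Invariant to positive
#' rescaling of either vector, which makes the similarity analysis robust to
#' overall amplitude non-stationarities.
#'
#' @param vectors Trials x dimensions numeric matrix (rows are trial
#'   vectors; no zero rows).
#' @return Symmetric trials x trials matrix with zero diagonal, entries in
#'   `[0, 2]`.
#' @export
cosine_dissimilarity <- function(vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0))
    stop("zero vector for trial(s) ", paste(which(nrm == 0), collapse = ", "),
         ": cosine dissimilarity undefined")
  U <- vectors / nrm
  D <- 1 - tcrossprod(U)
  D[D < 0] <- 0
  D[D > 2] <- 2
  diag(D) <- 0
  (D + t(D)) / 2
}

# Per-row conditional probabilities at a fixed perplexity via binary search
# on the Gaussian precision; `d2` plays the role of squared distances.
.perplexity_probs <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 10; next }
      p <- w / sw
      H <- -sum(ifelse(p > 0, p * log(p), 0))
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P
}

#' t-SNE embedding of a precomputed dissimilarity matrix
#'
#' Exact-gradient t-distributed stochastic neighbor embedding run directly on
#' pairwise dissimilarities (never on raw vectors).  The cosine
#' dissimilarity is used as the squared-distance input of the Gaussian
#' neighborhood kernel -- principled, since for unit vectors
#' `||u - v||^2 = 2 (1 - cos)`.  The exact gradient supports any output
#' dimension; the similarity-space analyses use D = 2 for visualization and
#' D = 10 for decoding.  Random (PCA-free) initialization from `seed`;
#' standard early exaggeration and adaptive gains.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal) or `dist`.
#' @param dims Output dimension (2 or 10 in the analyses here).
#' @param perplexity Gaussian neighborhood size; default
#'   `min(30, floor((n - 1) / 3))`.  Must be `< n / 3`.
#' @param n_iter Gradient iterations (1000).
#' @param learning_rate,exaggeration,exag_iter Optimizer settings.
#' @param seed Integer seed (embedding is deterministic given the seed).
#' @return Trials x `dims` coordinate matrix with attribute `kl`
#'   (final KL divergence).
#' @export
csim_embed <- function(d, dims = 2, perplexity = NULL, n_iter = 1000,
                       learning_rate = 200, exaggeration = 12,
                       exag_iter = 250, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 4, ncol(d) == n, dims >= 1)
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0)) stop("dissimilarity matrix must have zero diagonal")
  if (is.null(perplexity)) perplexity <- min(30, floor((n - 1) / 3))
  if (perplexity >= n / 3)
    stop("perplexity must be < n_trials / 3 (n = ", n, ")")
  if (perplexity < 1) stop("perplexity must be >= 1")

  P <- .perplexity_probs(d, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)
  # early exaggeration must end well before the run does, or the embedding
  # is returned mid-optimization
  exag_iter <- min(exag_iter, floor(n_iter / 4))

  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  G <- matrix(0, n, dims)        # update (momentum) term
  gains <- matrix(1, n, dims)
  for (it in seq_len(n_iter)) {
    ex <- if (it <= exag_iter) exaggeration else 1
    mom <- if (it <= exag_iter) 0.5 else 0.8
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.xmin)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - learning_rate * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sq <- rowSums(Y^2)
  num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
  diag(num) <- 0
  Q <- pmax(num / sum(num), .Machine$double.xmin)
  kl <- sum(P * log(P / Q))
  attr(Y, "kl") <- kl
  Y
}

#' Within- vs between-condition distance statistics
#'
#' Splits all pairwise distances among trials into pairs sharing the factor
#' level ("within") and pairs differing ("between"), reports both samples and
#' their medians, and compares them with a Kruskal-Wallis test.  Distances
#' are Euclidean in the supplied embedding by default; pass a `dissimilarity`
#' matrix to use raw dissimilarities instead.
#'
#' @param coords Trials x D embedding coordinates (ignored when
#'   `dissimilarity` is given).
#' @param labels Factor level per trial.
#' @param dissimilarity Optional precomputed trial x trial distance matrix.
#' @return List of class `"distance_stats"`: `within`, `between`
#'   (distance samples), `median_within`, `median_between`, `statistic`
#'   (Kruskal-Wallis H), `p.value`, `degenerate`.
#' @export
distance_cluster_stats <- function(coords = NULL, labels,
                                   dissimilarity = NULL) {
  labels <- factor(labels)
  n_lab <- table(labels)
  if (any(n_lab < 2)) {
    skip <- names(n_lab)[n_lab < 2]
    warning("skipping factor level(s) with < 2 trials: ",
            paste(skip, collapse = ", "))
    keep <- !(labels %in% skip)
    labels <- droplevels(labels[keep])
    if (!is.null(coords)) coords <- coords[keep, , drop = FALSE]
    if (!is.null(dissimilarity))
      dissimilarity <- dissimilarity[keep, keep, drop = FALSE]
  }
  n <- length(labels)
  if (n < 3 || nlevels(labels) < 2)
    stop("need >= 2 factor levels with >= 2 trials each")
  Dm <- if (!is.null(dissimilarity)) as.matrix(dissimilarity)
        else as.matrix(stats::dist(coords))
  stopifnot(nrow(Dm) == n)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(Dm)
  within <- Dm[ut & same]
  between <- Dm[ut & !same]
  degenerate <- all(c(within, between) == 0) ||
    stats::var(c(within, between)) == 0
  if (degenerate) {
    warning("all pairwise distances identical: test degenerate")
    kw <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    kw <- stats::kruskal.test(list(within, between))
  }
  structure(list(within = within, between = between,
                 median_within = stats::median(within),
                 median_between = stats::median(between),
                 statistic = unname(kw$statistic),
                 p.value = unname(kw$p.value),
                 degenerate = degenerate),
            class = "distance_stats")
}

#' Normalize and pool distance statistics across sessions
#'
#' Divides each session's distances by that session's median off-diagonal
#' distance (a robust per-session scale), concatenates the normalized
#' within/between samples, and re-tests the pooled samples.
#'
#' @param stats_list List of [distance_cluster_stats()] results.
#' @return A pooled `"distance_stats"` object (with `normalizers`
#'   attribute).
#' @export
normalize_and_pool <- function(stats_list) {
  stopifnot(length(stats_list) >= 1,
            all(vapply(stats_list, inherits, TRUE, "distance_stats")))
  wl <- list(); bl <- list(); nrm <- numeric(length(stats_list))
  for (i in seq_along(stats_list)) {
    s <- stats_list[[i]]
    nrm[i] <- stats::median(c(s$within, s$between))
    if (nrm[i] == 0) stop("session ", i, " has zero median distance")
    wl[[i]] <- s$within / nrm[i]
    bl[[i]] <- s$between / nrm[i]
  }
  within <- unlist(wl); between <- unlist(bl)
  kw <- stats::kruskal.test(list(within, between))
  out <- structure(list(within = within, between = between,
                        median_within = stats::median(within),
                        median_between = stats::median(between),
                        statistic = unname(kw$statistic),
                        p.value = unname(kw$p.value),
                        degenerate = FALSE),
                   class = "distance_stats")
  attr(out, "normalizers") <- nrm
  out
}
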