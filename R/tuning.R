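# Per-feature tuning statistics: heteroskedastic one-way (Welch) and
# factorial (Johansen) ANOVA, Benjamini-Hochberg correction, marginalization
# categories, interaction follow-up, and assumption checks.

#' Welch's heteroskedastic one-way ANOVA
#'
#' One-way ANOVA that does not assume equal group variances (Welch 1951),
#' applied to untrimmed means.  For two groups the statistic equals the
#' square of Welch's two-sample t.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with n >= 2 and positive variance).
#' @return List with `statistic` (F*), `df1`, `df2`
#'   (Welch-Satterthwaite), and `p.value`.
#' @export
welch_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs n >= 2")
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v <= 0)) stop("zero-variance group: Welch ANOVA undefined")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), n))
  ht <- stats::oneway.test(y ~ g, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
       p.value = unname(ht$p.value))
}

# (J-1) x J successive-difference contrast matrix
.diffmat <- function(J) {
  m <- matrix(0, J - 1L, J)
  m[cbind(seq_len(J - 1L), seq_len(J - 1L))] <- 1
  m[cbind(seq_len(J - 1L), seq_len(J - 1L) + 1L)] <- -1
  m
}

# Johansen-type heteroskedastic test of contrast C on cell means m with
# squared standard errors on the diagonal of V and cell sizes n.
# Q = (Cm)' (C V C')^{-1} (Cm); second-order F approximation:
# F = Q / c with c = q + 2A - 6A/(q+2), df2 = q(q+2)/(3A),
# A = sum_k R_kk^2 / (n_k - 1), R = V C'(C V C')^{-1} C.
# The one-factor case reduces exactly to Welch's ANOVA.
.johansen_stat <- function(C, m, V, n) {
  W <- C %*% V %*% t(C)
  Wi <- tryCatch(solve(W), error = function(e)
    stop("singular contrast covariance"))
  Cm <- C %*% m
  Q <- drop(t(Cm) %*% Wi %*% Cm)
  R <- V %*% t(C) %*% Wi %*% C
  A <- sum(diag(R)^2 / (n - 1))
  q <- nrow(C)
  cc <- q + 2 * A - 6 * A / (q + 2)
  Fs <- Q / cc
  df2 <- if (A > 0) q * (q + 2) / (3 * A) else Inf
  list(statistic = Fs, df1 = q, df2 = df2,
       p.value = stats::pf(Fs, q, df2, lower.tail = FALSE))
}

#' Johansen's heteroskedastic two-way ANOVA (untrimmed means)
#'
#' Robust factorial test of the two main effects and their interaction that
#' allows unequal cell variances: cell means are weighted by
#' `n_jk / s^2_jk`, each effect is tested through its contrast matrix with
#' the quadratic form `Q = (Cm)' (C V C')^{-1} (Cm)`,
#' `V = diag(s^2_jk / n_jk)`, and `Q` is referred to Johansen's
#' second-order F approximation.  With a single-level second factor the
#' first-factor test reduces exactly to Welch's one-way ANOVA.
#'
#' @param y Numeric response (per-trial modulation depths).
#' @param f First factor (force level).
#' @param s Second factor (volitional state).
#' @return List with one element per testable effect (`force`, `state`,
#'   `interaction`), each a list of `statistic`, `df1`, `df2`, `p.value`.
#' @export
johansen_twoway <- function(y, f, s) {
  f <- droplevels(factor(f)); s <- droplevels(factor(s))
  stopifnot(length(y) == length(f), length(y) == length(s))
  J <- nlevels(f); K <- nlevels(s)
  if (J < 2L) stop("first factor needs >= 2 levels")
  n <- tapply(y, list(f, s), length)
  if (any(is.na(n)) || any(n < 2L))
    stop("every factor cell needs n >= 2")
  m <- tapply(y, list(f, s), mean)
  v <- tapply(y, list(f, s), stats::var)
  if (any(v <= 0)) stop("zero-variance cell")
  # vectorize cells with the first factor slowest (row-major)
  mv <- as.vector(t(m)); vv <- as.vector(t(v)); nv <- as.vector(t(n))
  V <- diag(vv / nv, J * K)
  cJ <- .diffmat(J)
  oK <- matrix(1, 1, K)
  out <- list(force = .johansen_stat(cJ %x% oK, mv, V, nv))
  if (K >= 2L) {
    cK <- .diffmat(K)
    oJ <- matrix(1, 1, J)
    out$state <- .johansen_stat(oJ %x% cK, mv, V, nv)
    out$interaction <- .johansen_stat(cJ %x% cK, mv, V, nv)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1).
#' Thin wrapper over [stats::p.adjust()] so the correction applied across
#' feature families is explicit and testable.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Map adjusted p-values to a tuning category
#'
#' A significant interaction takes precedence; otherwise the significance
#' pattern of the two main effects maps to force_only / state_only / both /
#' neither.  Vectorized.
#'
#' @param p_force,p_state,p_interaction BH-adjusted p-values.
#' @param alpha Significance level (0.05).
#' @return Character vector of categories.
#' @export
classify_tuning <- function(p_force, p_state, p_interaction, alpha = 0.05) {
  n <- length(p_force)
  stopifnot(length(p_state) == n, length(p_interaction) == n)
  out <- rep("neither", n)
  out[p_force < alpha & p_state >= alpha] <- "force_only"
  out[p_force >= alpha & p_state < alpha] <- "state_only"
  out[p_force < alpha & p_state < alpha] <- "both"
  out[p_interaction < alpha] <- "interaction"
  out[is.na(p_force) | is.na(p_state) | is.na(p_interaction)] <- "degenerate"
  out
}

#' Within-state force tuning for interacting features
#'
#' For each requested feature, runs a one-way Welch ANOVA on force within
#' each volitional state, then BH-adjusts across the whole follow-up family
#' (all features x states jointly).
#'
#' @param depths Features x trials matrix of modulation depths (force trials).
#' @param f Force labels per trial.
#' @param s State labels per trial.
#' @param features Integer indices of the features to follow up.
#' @param adjust If `TRUE` (default) BH-adjust across the family.
#' @return Data.frame: `feature`, `state`, `p` (raw), `p_adj`.
#' @export
interaction_followup <- function(depths, f, s, features = seq_len(nrow(depths)),
                                 adjust = TRUE) {
  if (is.vector(depths)) depths <- matrix(depths, nrow = 1)
  f <- factor(f); s <- factor(s)
  rows <- list(); k <- 0L
  for (ft in features) {
    for (st in levels(s)) {
      sel <- s == st
      groups <- split(depths[ft, sel], droplevels(f[sel]))
      p <- tryCatch(welch_oneway(groups)$p.value, error = function(e) NA_real_)
      k <- k + 1L
      rows[[k]] <- data.frame(feature = ft, state = st, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust) bh_adjust(out$p) else out$p
  out
}

#' Distributional assumption checks for one feature
#'
#' Shapiro-Wilk normality per factor cell and Levene's test (classical,
#' mean-centered) for homogeneity of variance across cells, each flagged at
#' `alpha`.  Constant cells make the tests undefined and are flagged as
#' degenerate.
#'
#' @param y Numeric response.
#' @param f,s Factors defining the cells.
#' @param alpha Flagging level.
#' @return List: `normality_p` (per-cell vector), `levene_p`,
#'   `normal` (no cell rejected), `heteroskedastic`, `degenerate`.
#' @export
assumption_checks <- function(y, f, s, alpha = 0.05) {
  f <- factor(f); s <- factor(s)
  cell <- interaction(f, s, drop = TRUE)
  vs <- tapply(y, cell, stats::var)
  if (any(is.na(vs)) || any(vs == 0)) {
    return(list(normality_p = NULL, levene_p = NA_real_, normal = NA,
                heteroskedastic = NA, degenerate = TRUE))
  }
  np <- vapply(split(y, cell), function(g) {
    if (length(g) < 3 || length(g) > 5000) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  lev <- car::leveneTest(y ~ cell, center = mean)
  lp <- lev[["Pr(>F)"]][1]
  list(normality_p = np, levene_p = lp,
       normal = all(np >= alpha, na.rm = TRUE),
       heteroskedastic = lp < alpha, degenerate = FALSE)
}

#' Classify the tuning of every feature in a session
#'
#' The full single-feature pipeline: for each feature, a two-way Johansen
#' (heteroskedastic Welch-type) ANOVA of force, volitional state, and their
#' interaction on go-phase modulation depths; BH correction across the
#' feature population separately per test; category assignment at `alpha`;
#' and, for features with a significant interaction, a within-state one-way
#' Welch follow-up (BH-adjusted across the follow-up family).
#'
#' @param md A [baseline_deviation()] result.
#' @param alpha Significance level applied to adjusted p-values.
#' @param checks If `TRUE`, run per-feature assumption checks (adds
#'   `normal` / `heteroskedastic` flags).
#' @return Data.frame of class `"tuning_result"`, one row per feature:
#'   raw and BH-adjusted p-values for force, state, and interaction;
#'   `category`; follow-up adjusted p-values `p_obs`, `p_imag`, `p_att`
#'   (NA unless the interaction is significant); assumption flags.
#' @export
feature_tuning <- function(md, alpha = 0.05, checks = TRUE) {
  stopifnot(inherits(md, "modulation_depths"))
  trials <- md$trials
  idx <- which(trials$condition %in% force_levels())
  f <- factor(trials$condition[idx], force_levels())
  s <- factor(trials$state[idx], vos_levels())
  D <- md$depths[, idx, drop = FALSE]
  nf <- nrow(D)

  p_force <- p_state <- p_int <- rep(NA_real_, nf)
  normal <- hetero <- rep(NA, nf)
  for (i in seq_len(nf)) {
    jt <- tryCatch(johansen_twoway(D[i, ], f, s), error = function(e) NULL)
    if (!is.null(jt)) {
      p_force[i] <- jt$force$p.value
      p_state[i] <- jt$state$p.value
      p_int[i] <- jt$interaction$p.value
    }
    if (checks) {
      ac <- assumption_checks(D[i, ], f, s, alpha)
      normal[i] <- ac$normal
      hetero[i] <- ac$heteroskedastic
    }
  }
  q_force <- bh_adjust(p_force)
  q_state <- bh_adjust(p_state)
  q_int <- bh_adjust(p_int)
  category <- classify_tuning(q_force, q_state, q_int, alpha)

  res <- data.frame(feature = seq_len(nf), kind = NA_character_,
                    p_force = p_force, p_state = p_state,
                    p_interaction = p_int,
                    q_force = q_force, q_state = q_state,
                    q_interaction = q_int, category = category,
                    p_obs = NA_real_, p_imag = NA_real_, p_att = NA_real_,
                    normal = normal, heteroskedastic = hetero,
                    stringsAsFactors = FALSE)
  inter <- which(category == "interaction")
  if (length(inter) > 0) {
    fu <- interaction_followup(D, f, s, features = inter)
    for (st in vos_levels()) {
      col <- c(observe = "p_obs", imagine = "p_imag", attempt = "p_att")[[st]]
      sub <- fu[fu$state == st, ]
      res[[col]][sub$feature] <- sub$p_adj
    }
  }
  class(res) <- c("tuning_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

#' Category fractions over the feature population
#'
#' @param tr A [feature_tuning()] result.
#' @return Named numeric vector of fractions over the five categories
#'   (plus `degenerate` if present); sums to 1.
#' @export
tuning_fractions <- function(tr) {
  stopifnot(inherits(tr, "tuning_result"))
  cats <- c("force_only", "state_only", "both", "interaction", "neither")
  if (any(tr$category == "degenerate")) cats <- c(cats, "degenerate")
  tab <- table(factor(tr$category, cats))
  fr <- as.vector(tab) / nrow(tr)
  names(fr) <- cats
  fr
}
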