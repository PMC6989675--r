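# Smoothing, PSTHs, modulation depths, SNR ranking, time-course correlation.

test_that("Gaussian smoothing preserves DC, mass, and matches brute force", {
  # constant trace unchanged (edge renormalization)
  expect_equal(smooth_gaussian(rep(3.7, 40), sd_ms = 100), rep(3.7, 40))
  # unit impulse far from the edges -> discrete Gaussian of mass exactly 1
  # (all touched output bins see the full +-3 SD kernel)
  x <- numeric(80); x[40] <- 1
  sm <- smooth_gaussian(x, sd_ms = 100)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(which.max(sm), 40)
  # brute-force convolution oracle (truncated +-3 SD, edge renormalized)
  set.seed(8)
  tr <- rnorm(50)
  sd_bins <- 100 / 20
  L <- ceiling(3 * sd_bins)
  w <- dnorm(-L:L, sd = sd_bins); w <- w / sum(w)
  oracle <- sapply(seq_len(50), function(j) {
    src <- j + (-L:L)
    ok <- src >= 1 & src <= 50
    sum(w[ok] * tr[src[ok]]) / sum(w[ok])
  })
  expect_equal(smooth_gaussian(tr, 100), oracle, tolerance = 1e-12)
  expect_error(smooth_gaussian(tr, 0), "positive")
})

test_that("smoothing commutes with trial averaging (linearity)", {
  set.seed(9)
  trials <- replicate(6, matrix(rnorm(4 * 30), 4, 30), simplify = FALSE)
  avg_then_smooth <- smooth_gaussian(Reduce(`+`, trials) / 6, 100)
  smooth_then_avg <- Reduce(`+`, lapply(trials, smooth_gaussian, sd_ms = 100)) / 6
  expect_equal(avg_then_smooth, smooth_then_avg, tolerance = 1e-12)
})

test_that("PSTH equals single-trial trace / two-trial mean and recovers ordering", {
  ss <- small_session(seed = 12, n_channels = 3)
  ft <- ss$tensor; sch <- ss$schedule
  p1 <- compute_psth(ft, sch, select = 4, len_ms = 1000)
  w <- floor(sch$go_onset[4] * 1000 / 20) + 1
  expect_equal(unclass(p1), ft$values[, w:(w + 49), 4],
               ignore_attr = TRUE)
  p2 <- compute_psth(ft, sch, select = c(4, 9), len_ms = 1000)
  w9 <- floor(sch$go_onset[9] * 1000 / 20) + 1
  expect_equal(unclass(p2),
               (ft$values[, w:(w + 49), 4] + ft$values[, w9:(w9 + 49), 9]) / 2,
               ignore_attr = TRUE)
  # force-tuned synthetic feature: PSTH ordering matches the generating gains
  sc <- session_config(n_blocks = 9, trials_per_block = 20, n_channels = 2,
                       prep_s = c(0.9, 1.1), go_s = c(1.5, 2),
                       stop_s = c(0.8, 1.2), seed = 13)
  sch2 <- make_schedule(sc)
  gt <- ground_truth(sc, categories = c(force_only = 1, state_only = 0,
                                        both = 0, interaction = 0, neither = 0),
                     force_snr = 6, random_sign = FALSE)
  ft2 <- generate_features(sch2, gt)
  means <- sapply(force_levels(), function(fl)
    mean(compute_psth(ft2, sch2, select = sch2$condition == fl)[1, ]))
  expect_true(means["light"] < means["medium"] &&
                means["medium"] < means["hard"])
})

test_that("baseline deviations satisfy exact identities and recover gains", {
  # constructed tensor: feature 1 constant at baseline, feature 2 carries +c
  # in the go phase of every non-rest trial
  sc <- session_config(n_blocks = 3, trials_per_block = 10, n_channels = 1,
                       prep_s = c(0.9, 1.1), go_s = c(1.5, 2),
                       stop_s = c(0.8, 1.2), seed = 14)
  sch <- make_schedule(sc)
  nb <- pmax(1L, as.integer(floor(sch$end / 0.02 + 1e-9)))
  vals <- array(NA_real_, c(2, max(nb), nrow(sch)))
  cc <- 1.4
  for (i in seq_len(nrow(sch))) {
    vals[1, seq_len(nb[i]), i] <- 5
    tr <- rep(2, nb[i])
    if (sch$condition[i] != "rest") {
      g0 <- floor(sch$go_onset[i] / 0.02) + 1
      g1 <- floor(sch$stop_onset[i] / 0.02)
      tr[g0:g1] <- 2 + cc
    }
    vals[2, seq_len(nb[i]), i] <- tr
  }
  ft <- feature_tensor(vals, kind = c("TC", "SBP"), n_bins = nb)
  md <- baseline_deviation(ft, sch)
  expect_equal(unname(md$depths[1, ]), rep(0, nrow(sch)))
  active <- sch$condition != "rest"
  expect_equal(unname(md$depths[2, active]), rep(cc, sum(active)),
               tolerance = 1e-9)
  expect_error(baseline_deviation(ft, transform(sch, condition = "light")),
               "rest")

  # parameter recovery: condition-mean depth ~ gate-weighted generating gain
  sc2 <- session_config(n_blocks = 15, trials_per_block = 20, n_channels = 4,
                        prep_s = c(0.9, 1.1), go_s = c(1.5, 2),
                        stop_s = c(0.8, 1.2), seed = 15)
  sch2 <- make_schedule(sc2)
  gt <- ground_truth(sc2, categories = c(force_only = 0, state_only = 0,
                                         both = 1, interaction = 0, neither = 0),
                     force_snr = 2, state_snr = 4, random_sign = FALSE)
  ft2 <- generate_features(sch2, gt)
  md2 <- baseline_deviation(ft2, sch2)
  len_s <- .001 * graspforce:::.min_go_ms(ft2, sch2)
  idx <- which(sch2$condition == "hard" & sch2$state == "attempt")
  # mean gate over the depth window, bin-center exact, per selected trial
  gate_mean <- sapply(idx, function(i) {
    t0 <- (floor(sch2$go_onset[i] * 1000 / 20)) * 0.02
    tt <- t0 + (seq_len(len_s / 0.02) - 0.5) * 0.02
    mean(graspforce:::.go_gate(tt, sch2$go_onset[i], sch2$stop_onset[i], 0.15))
  })
  for (f in 1:8) {
    g <- gt$force_gain[f, "hard"] + gt$state_gain[f, "attempt"]
    expected <- g * mean(gate_mean)
    obs <- md2$depths[f, idx]
    sem <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - expected), 3 * sem + 0.02 * abs(g))
  }
})

test_that("rest-trial depths are mean-zero under leave-one-out baselines", {
  ss <- small_session(seed = 16, n_blocks = 9, n_channels = 20,
                      scenario = "null")
  md <- baseline_deviation(ss$tensor, ss$schedule, rest_loo = TRUE)
  rest <- which(ss$schedule$condition == "rest")
  m <- rowMeans(md$depths[, rest])
  sem <- apply(md$depths[, rest], 1, sd) / sqrt(length(rest))
  expect_gt(mean(abs(m) < 3 * sem), 0.95)
})

test_that("normalized condition means behave and raw t-intervals cover", {
  # single nonzero condition normalizes to +-1; all-equal conditions stay equal
  trials <- expand.grid(condition = c(force_levels(), "rest"),
                        state = vos_levels(), rep = 1:8,
                        stringsAsFactors = FALSE)
  trials$condition[trials$state != "observe" & trials$condition == "rest"] <- "light"
  nt <- nrow(trials)
  dep <- matrix(0, 2, nt)
  hard_att <- trials$condition == "hard" & trials$state == "attempt"
  set.seed(17)
  dep[1, ] <- rnorm(nt, ifelse(hard_att, -2, 0), 0.01)
  dep[2, ] <- rnorm(nt, 1, 0.01)
  md <- structure(list(depths = dep, baseline = c(0, 0),
                       window = c(0, 1000), trials = trials),
                  class = "modulation_depths")
  nd <- normalized_depths(md)
  f1 <- nd[nd$feature == 1, ]
  expect_equal(f1$norm_mean[f1$force == "hard" & f1$state == "attempt"], -1,
               tolerance = 0.02)
  expect_true(all(abs(f1$norm_mean[!(f1$force == "hard" & f1$state == "attempt")])
                  < 0.05))
  f2 <- nd[nd$feature == 2, ]
  expect_lt(diff(range(f2$norm_mean)), 0.05)

  # 95% t-interval coverage on simulated Gaussian depths (1000 intervals)
  set.seed(18)
  cover <- logical(0)
  for (r in 1:125) {
    depr <- matrix(rnorm(1 * nt, 0.5, 1), 1, nt)
    mdr <- structure(list(depths = depr, baseline = 0,
                          window = c(0, 1000), trials = trials),
                     class = "modulation_depths")
    ndr <- normalized_depths(mdr)
    cover <- c(cover, ndr$lo <= 0.5 & ndr$hi >= 0.5)
  }
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("SNR ranking is ordered, tie-broken by index, and scale-free", {
  trials <- data.frame(condition = rep(c("light", "rest"), each = 10),
                       state = "attempt")
  set.seed(19)
  dep <- rbind(rnorm(20, rep(c(2, 0), each = 10), 0.5),   # strong
               rnorm(20, rep(c(1, 0), each = 10), 0.5),   # half the deviation
               c(rnorm(10, 0, 1e-12), rnorm(10, 0, 0.5))) # ~zero deviation
  dep[3, 1:10] <- 0
  md <- structure(list(depths = dep, baseline = rep(0, 3),
                       window = c(0, 1000), trials = trials),
                  class = "modulation_depths")
  r <- snr_rank(md)
  expect_equal(r$feature[1:2], c(1, 2))
  expect_equal(r$feature[3], 3)
  # scaling a feature leaves the ranking unchanged
  md2 <- md; md2$depths[2, ] <- md2$depths[2, ] * 100
  expect_equal(snr_rank(md2)$feature, r$feature)
  expect_equal(snr_rank(md2)$snr[r$feature == 2], r$snr[r$feature == 2])
  expect_equal(nrow(snr_rank(md, n_top = 2)), 2)
})

test_that("time-course correlations hit the closed-form cases", {
  set.seed(20)
  a <- matrix(rnorm(5 * 40), 5, 40)
  pa <- structure(a, class = c("psth", "matrix"))
  pb <- structure(-a, class = c("psth", "matrix"))
  expect_equal(timecourse_correlation(pa, pa), rep(1, 5))
  expect_equal(timecourse_correlation(pa, pb), rep(-1, 5))
  # zero-variance trace reported as missing, with a warning
  a2 <- a; a2[3, ] <- 2
  pa2 <- structure(a2, class = c("psth", "matrix"))
  expect_warning(r <- timecourse_correlation(pa2, pb), "zero-variance")
  expect_true(is.na(r[3]))
  # independently drawn gain profiles: correlations centered near zero
  set.seed(21)
  b <- matrix(rnorm(300 * 40), 300, 40)
  cc <- timecourse_correlation(structure(matrix(rnorm(300 * 40), 300, 40),
                                         class = c("psth", "matrix")),
                               structure(b, class = c("psth", "matrix")))
  # per-feature r has SD ~ 1/sqrt(39); 3 SEM bound over 300 features
  expect_lt(abs(mean(cc)), 3 / sqrt(39) / sqrt(300) * 1.2)
})
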