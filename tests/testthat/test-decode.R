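# LDA decoding, chance distributions, windowed decoders, confusion matrices.

test_that("cross-validated LDA is exact in the separable limit and at chance", {
  # three classes, each concentrated at its own point, well separated
  Y <- rbind(matrix(rnorm(30 * 3, 0, 0.01), 30),
             matrix(rnorm(30 * 3, 10, 0.01), 30),
             matrix(rnorm(30 * 3, -10, 0.01), 30))
  lab <- rep(letters[1:3], each = 30)
  expect_equal(crossval_accuracy(Y, lab, seed = 1), 1.0)
  # labels independent of position: accuracy ~ 1/3 within 3 SE over reps
  set.seed(50)
  accs <- replicate(60, {
    X <- matrix(rnorm(90 * 5), 90)
    crossval_accuracy(X, sample(lab))
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 0.005)
  # contract: too few trials per class for stratified 10-fold
  expect_error(crossval_accuracy(Y[1:35, ], lab[1:35]), "k trials per class")
})

test_that("accuracy approaches the closed-form Bayes rate for 2-class Gaussians", {
  set.seed(51)
  n <- 150
  delta <- 1.5                       # class means 0 and delta on dim 1
  X <- rbind(matrix(rnorm(n * 4), n), cbind(rnorm(n, delta), matrix(rnorm(n * 3), n)))
  lab <- rep(0:1, each = n)
  bayes <- 1 - pnorm(-delta / 2)     # optimal accuracy
  acc <- mean(replicate(10, crossval_accuracy(X, lab, lambda = 0.02)))
  expect_lt(abs(acc - bayes), 0.03)
})

test_that("shrinkage-off LDA agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(52)
  X <- rbind(matrix(rnorm(40 * 4, 0), 40), matrix(rnorm(40 * 4, 1.2), 40))
  lab <- rep(c("p", "q"), each = 40)
  tr <- c(1:30, 41:70); te <- setdiff(1:80, tr)
  fit <- graspforce:::.lda_fit(X[tr, ], as.integer(factor(lab[tr])), 2, lambda = 0)
  mine <- graspforce:::.lda_predict(fit, X[te, ])
  ref <- as.integer(predict(MASS::lda(X[tr, ], grouping = lab[tr]),
                            X[te, ])$class)
  expect_equal(mine, ref)
})

test_that("chance distribution is centered, scales with n, and flags controls", {
  set.seed(53)
  # balanced 3-class labels: mean ~ 1/3
  X <- matrix(rnorm(90 * 6), 90)
  lab <- rep(1:3, each = 30)
  ch <- chance_distribution(X, lab, n_shuffles = 600, seed = 2)
  expect_lt(abs(ch$mean - 1 / 3), 0.02)
  expect_lt(ch$lo, 1 / 3); expect_gt(ch$hi, 1 / 3)
  # interval width shrinks ~ 1/sqrt(n) across n in {90, 180, 360}
  widths <- sapply(c(90, 180, 360), function(n) {
    Xn <- matrix(rnorm(n * 6), n)
    chn <- chance_distribution(Xn, rep(1:3, each = n / 3), n_shuffles = 800,
                               seed = 3)
    chn$hi - chn$lo
  })
  expect_lt(abs(widths[1] / widths[2] - sqrt(2)), 0.45)
  expect_lt(abs(widths[2] / widths[3] - sqrt(2)), 0.45)
  expect_true(all(diff(widths) < 0))
  # positive control: strongly tuned data exceeds the 97.5th percentile
  Ys <- rbind(matrix(rnorm(30 * 4, 0), 30), matrix(rnorm(30 * 4, 3), 30),
              matrix(rnorm(30 * 4, -3), 30))
  labs <- rep(1:3, each = 30)
  obs <- crossval_accuracy(Ys, labs, seed = 4)
  chs <- chance_distribution(Ys, labs, n_shuffles = 400, seed = 5)
  expect_gt(obs, chs$hi)
  # shuffle distribution is invariant to relabeling class names
  ch_a <- chance_distribution(X, lab, n_shuffles = 200, seed = 7)
  ch_b <- chance_distribution(X, c(3, 1, 2)[lab], n_shuffles = 200, seed = 7)
  expect_identical(ch_a$samples, ch_b$samples)
  # small shuffle counts warn
  expect_warning(chance_distribution(X, lab, n_shuffles = 50, seed = 8),
                 "unstable")
})

test_that("label-shuffled decodes fall inside their own chance band ~95% of the time", {
  set.seed(54)
  X <- matrix(rnorm(60 * 5), 60)
  lab <- rep(1:3, each = 20)
  ch <- chance_distribution(X, lab, n_shuffles = 2000, seed = 9)
  inside <- mean(ch$samples >= ch$lo & ch$samples <= ch$hi)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("windowed decoders honor their arithmetic and time-locking", {
  ss <- small_session(seed = 55, n_blocks = 9, trials_per_block = 20,
                      n_channels = 12)
  ft <- ss$tensor; sch <- ss$schedule
  # step = win: non-overlapping windows, series length = floor(span / win)
  ser <- sliding_window_decode(ft, sch, "state", win_ms = 400, step_ms = 400,
                               start_ms = 0, dims = 3, n_iter = 120,
                               n_shuffles = 0, seed = 10)
  sel <- graspforce:::.decode_selection(sch, "state")
  span <- graspforce:::.span_limit_ms(ft, sch, sel$idx)
  expect_equal(nrow(ser), floor(span / 400))
  expect_equal(diff(ser$window_start_ms), rep(400, nrow(ser) - 1))
  # growing series truncates lengths beyond the shortest trial
  gro <- growing_window_decode(ft, sch, "state",
                               lengths_ms = seq(200, 60000, by = 400),
                               dims = 3, n_iter = 120, n_shuffles = 0,
                               seed = 11)
  expect_true(all(gro$window_len_ms <= span))
  expect_equal(gro$window_start_ms, rep(0, nrow(gro)))
  # single-length growing decode equals the one-window decode it wraps
  one <- growing_window_decode(ft, sch, "state", lengths_ms = 600, dims = 3,
                               n_iter = 120, n_shuffles = 0, seed = 12)
  direct <- graspforce:::.window_decode(ft, sch, sel, 0, 600, 3, NULL, 120,
                                        10, 0.1, 0, seed = 12 + 10L)
  expect_equal(one$accuracy, direct$accuracy)

  # time-locking: go-gated signal raises go-phase windows above prep windows
  ser2 <- sliding_window_decode(ft, sch, "state", win_ms = 400, step_ms = 200,
                                start_ms = -800, end_ms = 1400, dims = 5,
                                n_iter = 600, n_shuffles = 0, seed = 13)
  prep_acc <- mean(ser2$accuracy[ser2$window_start_ms <= -400])
  go_acc <- mean(ser2$accuracy[ser2$window_start_ms >= 200])
  expect_gt(go_acc, prep_acc + 0.15)
})

test_that("null sessions decode within their empirical chance bands", {
  ss <- small_session(seed = 56, n_blocks = 9, trials_per_block = 20,
                      n_channels = 12, scenario = "null")
  ser <- sliding_window_decode(ss$tensor, ss$schedule, "state", win_ms = 400,
                               step_ms = 400, start_ms = 0, dims = 5,
                               n_iter = 600, n_shuffles = 300, seed = 14)
  # per-window exceedances of the 97.5th percentile happen ~2.5% of the
  # time by construction; with a handful of windows allow at most one
  expect_lte(sum(ser$accuracy > ser$chance_hi), 1)
  expect_lt(abs(mean(ser$accuracy) - 1 / 3), 0.07)
})

test_that("confusion matrices are exact for perfect/random classifiers and expose shared structure", {
  # perfect separation: identity; labels shuffled: ~uniform 1/3
  ss <- small_session(seed = 57, n_blocks = 9, trials_per_block = 20,
                      n_channels = 12)
  cm <- confusion_go(ss$tensor, ss$schedule, "state", step_ms = 400, dims = 5,
                     n_iter = 600, seed = 15)
  expect_equal(rowSums(cm), rep(1, 3), ignore_attr = TRUE)
  expect_gt(mean(diag(cm)), 0.6)            # strong state tuning separates
  expect_true(all(apply(cm, 1, which.max) == 1:3))  # diagonal dominates
  # exact identity in the separable limit, via the same prediction path
  Ysep <- rbind(matrix(rnorm(30 * 3, 0, 0.01), 30),
                matrix(rnorm(30 * 3, 10, 0.01), 30),
                matrix(rnorm(30 * 3, -10, 0.01), 30))
  cv <- crossval_accuracy(Ysep, rep(c("a", "b", "c"), each = 30), seed = 3,
                          predictions = TRUE)
  tab <- table(cv$truth, cv$predicted)
  expect_equal(unclass(tab / rowSums(tab)), diag(3), ignore_attr = TRUE)
  ssn <- small_session(seed = 58, n_blocks = 9, trials_per_block = 20,
                       n_channels = 12, scenario = "null")
  cmn <- confusion_go(ssn$tensor, ssn$schedule, "state", step_ms = 400,
                      dims = 5, n_iter = 600, seed = 16)
  expect_true(all(abs(cmn - 1 / 3) < 0.2))
  expect_equal(rowSums(cmn), rep(1, 3), ignore_attr = TRUE)

  # observe and imagine sharing a latent pattern are confused with each
  # other more than with attempt
  sc <- ssn$config
  gt <- ground_truth(sc, categories = c(force_only = 0, state_only = 1,
                                        both = 0, interaction = 0, neither = 0),
                     state_snr = 3, random_sign = FALSE, seed = 77)
  gt$state_gain[, "imagine"] <- gt$state_gain[, "observe"] +
    0.15 * gt$state_gain[, "attempt"]
  ft <- generate_features(ssn$schedule, gt, seed = 78)
  cms <- confusion_go(ft, ssn$schedule, "state", step_ms = 400, dims = 5,
                      n_iter = 600, seed = 17)
  oi <- cms["observe", "imagine"] + cms["imagine", "observe"]
  oa <- cms["observe", "attempt"] + cms["attempt", "observe"]
  ia <- cms["imagine", "attempt"] + cms["attempt", "imagine"]
  expect_gt(oi, oa)
  expect_gt(oi, ia)
})
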