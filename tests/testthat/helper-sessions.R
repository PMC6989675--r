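# Shared fixtures, generated in code.  The full-size sessions used by the
# acceptance checks are expensive (192 channels, 300 trials), so they are
# built once per test run and cached.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .session_cache)) {
    assign(key, build(), envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# small session for unit tests: few channels, abbreviated phases
small_session <- function(seed = 5, n_blocks = 6, trials_per_block = 10,
                          n_channels = 6, scenario = c("headline", "null"),
                          ...) {
  scenario <- match.arg(scenario)
  sc <- session_config(n_blocks = n_blocks,
                       trials_per_block = trials_per_block,
                       n_channels = n_channels,
                       prep_s = c(0.9, 1.1), go_s = c(1.5, 2),
                       stop_s = c(0.8, 1.2), seed = seed, ...)
  sch <- make_schedule(sc)
  gt <- if (scenario == "null") ground_truth_null(sc) else ground_truth(sc)
  list(config = sc, schedule = sch, truth = gt,
       tensor = generate_features(sch, gt))
}

# full study-condition sessions shared by the acceptance checks
null_session_full <- function() cached("null_full", function() {
  sc <- session_config(seed = 7001L)
  sch <- make_schedule(sc)
  gt <- ground_truth_null(sc)
  list(config = sc, schedule = sch, truth = gt,
       tensor = generate_features(sch, gt))
})

headline_session_full <- function() cached("headline_full", function() {
  sc <- session_config(seed = 7002L)
  sch <- make_schedule(sc)
  gt <- ground_truth(sc)
  list(config = sc, schedule = sch, truth = gt,
       tensor = generate_features(sch, gt))
})

# 10-D CSIM embedding of a session's go-phase force-trial vectors
embed_session <- function(ss, dims = 10, seed = 99L) {
  V <- trial_vectors(ss$tensor, ss$schedule)
  Y <- csim_embed(cosine_dissimilarity(V), dims = dims, seed = seed)
  idx <- attr(V, "trial_idx")
  list(embedding = Y, labels_state = ss$schedule$state[idx],
       labels_force = ss$schedule$condition[idx], idx = idx)
}

# three tight direction-clusters in feature space (for embedding checks):
# cluster k points along axis k with small angular noise
direction_clusters <- function(n_per = 25, dims = 12, spread = 0.05,
                               seed = 4) {
  set.seed(seed)
  X <- matrix(rnorm(3 * n_per * dims, sd = spread), 3 * n_per, dims)
  for (k in 1:3) X[(k - 1) * n_per + seq_len(n_per), k] <-
    X[(k - 1) * n_per + seq_len(n_per), k] + 1
  list(x = X, labels = rep(1:3, each = n_per))
}
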