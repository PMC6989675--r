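# Orchestration: one reproducible run tying together simulation,
# pre-processing, tuning, similarity-space analysis, and decoding, with all
# stage outputs and a manifest written to an output directory.

#' Default run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: the session
#' layout, ground-truth scenario, significance level, analysis window, and
#' decoding settings.  All randomness derives from `seed`.
#'
#' @param seed Master integer seed.
#' @param n_blocks,trials_per_block,n_channels,grasp Session layout (see
#'   [session_config()]).
#' @param scenario `"headline"` (state gains exceeding force gains with an
#'   attempt-only interaction subset) or `"null"` (no tuning anywhere).
#' @param alpha Significance level for tuning classification.
#' @param n_shuffles Label shuffles for decoding chance bands.
#' @param dims Embedding dimension for decoding.
#' @param tsne_iter t-SNE iterations.
#' @param stages Character vector of stages to run, in order, from
#'   `c("synth", "prep", "tuning", "csim", "decode")`.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_blocks = 15L, trials_per_block = 20L,
                       n_channels = 192L, grasp = "power",
                       scenario = c("headline", "null"), alpha = 0.05,
                       n_shuffles = 1000L, dims = 10L, tsne_iter = 1000L,
                       stages = c("synth", "prep", "tuning", "csim",
                                  "decode")) {
  scenario <- match.arg(scenario)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = as.integer(seed), n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 n_channels = as.integer(n_channels), grasp = grasp,
                 scenario = scenario, alpha = alpha,
                 n_shuffles = as.integer(n_shuffles), dims = as.integer(dims),
                 tsne_iter = as.integer(tsne_iter), stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic session generation (schedule + feature
#' tensor), go-phase modulation depths, per-feature tuning classification,
#' similarity-space analysis (2-D embedding and within/between distance
#' statistics for state and for force within each state), and go-window
#' decoding (state, and force within each state) with label-shuffle chance
#' summaries.  Every stage writes CSV/JSON outputs under `out_dir`, and a
#' manifest records the config, per-stage seeds, and row counts.  Idempotent
#' given the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory not empty; pass overwrite = TRUE to replace")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  sc <- session_config(n_blocks = config$n_blocks,
                       trials_per_block = config$trials_per_block,
                       grasp = config$grasp, n_channels = config$n_channels,
                       seed = config$seed)
  truth <- if (config$scenario == "null") ground_truth_null(sc)
           else ground_truth(sc)
  schedule <- make_schedule(sc)
  tensor <- generate_features(schedule, truth)
  write_trial_table(schedule, file.path(out_dir, "trials.csv"))
  utils::write.csv(data.frame(feature = seq_len(truth$n_features),
                              kind = truth$kind, category = truth$category),
                   file.path(out_dir, "ground_truth_categories.csv"),
                   row.names = FALSE)
  tick("synth")

  md <- baseline_deviation(tensor, schedule)
  dep <- data.frame(trial = rep(seq_len(ncol(md$depths)), each = nrow(md$depths)),
                    feature = rep(seq_len(nrow(md$depths)), ncol(md$depths)),
                    depth = as.vector(md$depths))
  data.table::fwrite(dep, file.path(out_dir, "depths.csv"))
  tick("prep")

  results <- list(schedule = schedule, truth = truth)
  if ("tuning" %in% config$stages) {
    tune <- feature_tuning(md, alpha = config$alpha, checks = FALSE)
    tune$kind <- truth$kind
    utils::write.csv(as.data.frame(tune),
                     file.path(out_dir, "tuning.csv"), row.names = FALSE)
    fr <- tuning_fractions(tune)
    jsonlite::write_json(as.list(fr), file.path(out_dir, "tuning_fractions.json"),
                         auto_unbox = TRUE, digits = NA)
    results$tuning <- tune
    tick("tuning")
  }

  if ("csim" %in% config$stages) {
    sel <- .decode_selection(schedule, "state")
    V <- trial_vectors(tensor, schedule, select = sel$idx)
    Dm <- cosine_dissimilarity(V)
    Y2 <- csim_embed(Dm, dims = 2, n_iter = config$tsne_iter,
                     seed = config$seed + 11L)
    emb <- data.frame(trial = sel$idx, x = Y2[, 1], y = Y2[, 2],
                      state = schedule$state[sel$idx],
                      force = schedule$condition[sel$idx])
    utils::write.csv(emb, file.path(out_dir, "csim_embedding_2d.csv"),
                     row.names = FALSE)
    ds_state <- distance_cluster_stats(Y2, emb$state)
    stats_rows <- data.frame(factor = "state", state = NA_character_,
                             median_within = ds_state$median_within,
                             median_between = ds_state$median_between,
                             statistic = ds_state$statistic,
                             p.value = ds_state$p.value)
    for (st in vos_levels()) {
      in_st <- emb$state == st
      ds <- distance_cluster_stats(Y2[in_st, , drop = FALSE], emb$force[in_st])
      stats_rows <- rbind(stats_rows,
                          data.frame(factor = "force", state = st,
                                     median_within = ds$median_within,
                                     median_between = ds$median_between,
                                     statistic = ds$statistic,
                                     p.value = ds$p.value))
    }
    utils::write.csv(stats_rows, file.path(out_dir, "distance_stats.csv"),
                     row.names = FALSE)
    results$csim <- list(embedding = emb, distance_stats = stats_rows)
    tick("csim")
  }

  if ("decode" %in% config$stages) {
    go_ms <- .min_go_ms(tensor, schedule)
    dec_rows <- list()
    run_one <- function(what, st, seed_off) {
      sel <- .decode_selection(schedule, what, st)
      V <- trial_vectors(tensor, schedule, start_ms = 0, len_ms = go_ms,
                         select = sel$idx)
      Y <- csim_embed(cosine_dissimilarity(V), dims = config$dims,
                      n_iter = config$tsne_iter,
                      seed = config$seed + seed_off)
      acc <- crossval_accuracy(Y, sel$labels, seed = config$seed + seed_off + 1L)
      ch <- chance_distribution(Y, sel$labels, n_shuffles = config$n_shuffles,
                                seed = config$seed + seed_off + 2L)
      data.frame(factor = what, state = if (is.null(st)) NA_character_ else st,
                 window_start_ms = 0, window_len_ms = go_ms, accuracy = acc,
                 chance_mean = ch$mean, chance_lo = ch$lo, chance_hi = ch$hi)
    }
    dec_rows[[1]] <- run_one("state", NULL, 100L)
    for (j in seq_along(vos_levels()))
      dec_rows[[1 + j]] <- run_one("force", vos_levels()[j], 100L + 10L * j)
    dec <- do.call(rbind, dec_rows)
    utils::write.csv(dec, file.path(out_dir, "decoding.csv"), row.names = FALSE)
    results$decoding <- dec
    tick("decode")
  }

  manifest <- list(package_version = as.character(utils::packageVersion("graspforce")),
                   r_version = R.version.string,
                   config = unclass(config),
                   timings_s = timings,
                   n_trials = nrow(schedule),
                   n_features = truth$n_features)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Summarize a pipeline run directory
#'
#' Regenerates the report tables from a [run_pipeline()] output directory:
#' tuning category fractions, within/between median distance gaps, decoding
#' accuracies with chance bands.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return List with `tuning_fractions`, `distance_stats`, `decoding`
#'   (elements `NULL` when the stage did not run).
#' @export
summarize_run <- function(out_dir) {
  out <- list(tuning_fractions = NULL, distance_stats = NULL, decoding = NULL)
  fj <- file.path(out_dir, "tuning_fractions.json")
  if (file.exists(fj))
    out$tuning_fractions <- unlist(jsonlite::read_json(fj))
  fd <- file.path(out_dir, "distance_stats.csv")
  if (file.exists(fd))
    out$distance_stats <- utils::read.csv(fd)
  fc <- file.path(out_dir, "decoding.csv")
  if (file.exists(fc))
    out$decoding <- utils::read.csv(fc)
  out
}
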