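# Plain-text serialization: trial tables and stats as CSV, feature tensors
# as wide CSV (one row per trial x feature), configs as YAML.

#' Write / read a trial table
#'
#' One CSV row per trial with the documented columns (`session`, `block`,
#' `trial`, `state`, `condition`, `grasp`, `prep_onset`, `go_onset`,
#' `stop_onset`, `end`).
#'
#' @param schedule A [make_schedule()] trial table.
#' @param path File path.
#' @return `read_trial_table` returns a `"trial_schedule"` data.frame.
#' @export
write_trial_table <- function(schedule, path) {
  data.table::fwrite(as.data.frame(schedule), path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  need <- c("session", "block", "trial", "state", "condition", "grasp",
            "prep_onset", "go_onset", "stop_onset", "end")
  if (!all(need %in% names(out)))
    stop("trial table missing column(s): ",
         paste(setdiff(need, names(out)), collapse = ", "))
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Write / read a feature tensor
#'
#' Wide CSV layout: metadata columns `trial`, `feature`, `kind`, `n_bins`
#' followed by one column per bin (`b1`, `b2`, ...; `NA` past each trial's
#' end).  Intended for desk-scale tensors and analysis windows; full-session
#' tensors are large and are normally regenerated from config + seed instead.
#'
#' @param tensor A [feature_tensor()].
#' @param path File path.
#' @return `read_feature_tensor` returns a [feature_tensor()].
#' @export
write_feature_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "feature_tensor"))
  d <- dim(tensor$values)
  flat <- matrix(aperm(tensor$values, c(1, 3, 2)), d[1] * d[3], d[2])
  df <- data.frame(trial = rep(seq_len(d[3]), each = d[1]),
                   feature = rep(seq_len(d[1]), d[3]),
                   kind = rep(tensor$kind, d[3]),
                   n_bins = rep(tensor$n_bins, each = d[1]))
  colnames(flat) <- paste0("b", seq_len(d[2]))
  df <- cbind(df, as.data.frame(flat))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_tensor
#' @param bin_ms Bin width in milliseconds of the stored tensor.
#' @export
read_feature_tensor <- function(path, bin_ms = 20) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("trial", "feature", "kind", "n_bins")
  if (!all(need %in% names(df)))
    stop("feature tensor file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  nt <- max(df$trial); nf <- max(df$feature); nb <- length(bcols)
  values <- array(NA_real_, c(nf, nb, nt))
  m <- as.matrix(df[bcols])
  values[cbind(rep(df$feature, nb),
               rep(seq_len(nb), each = nrow(df)),
               rep(df$trial, nb))] <- as.vector(m)
  kind <- df$kind[match(seq_len(nf), df$feature)]
  n_bins <- df$n_bins[match(seq_len(nt), df$trial)]
  feature_tensor(values, kind = kind, bin_ms = bin_ms, n_bins = n_bins)
}

#' Write / read a session configuration as YAML
#'
#' @param config A [session_config()].
#' @param path File path.
#' @return `read_session_config` returns a `"session_config"`.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(session_config, x)
}
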