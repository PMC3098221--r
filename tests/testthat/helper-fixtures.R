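# In-code fixtures shared across test files.

# Bare rate matrix from a numeric matrix (bypasses spike smoothing).
mk_rates <- function(values, bin_width = 0.2, trial_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("u", seq_len(ncol(values)))
  if (is.null(trial_ids)) trial_ids <- rep("trial1", nrow(values))
  starts <- unlist(lapply(split(seq_along(trial_ids), trial_ids)[
    unique(trial_ids)], function(i) (seq_along(i) - 1) * bin_width))
  structure(list(values = values, bin_width = bin_width, sigma = 0.05,
                 bin_starts = as.numeric(starts),
                 unit_ids = colnames(values), trial_ids = trial_ids,
                 normalized_to_trial = FALSE),
            class = "rate_matrix")
}

mk_timeline <- function(labels) {
  structure(list(labels = labels,
                 event_windows = data.frame(label = character(0),
                                            start_s = numeric(0),
                                            end_s = numeric(0),
                                            trial_id = character(0))),
            class = "epoch_timeline")
}

# Small spike table file on disk; returns its path.
write_spike_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A small synthetic dataset reused by several files (cached per session).
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- synth_params(n_units = 10L, n_trials = 2L, seed = 42L)
      cache <<- generate_dataset(p)
    }
    cache
  }
})
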