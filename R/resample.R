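# Surrogate/null datasets preserving within-epoch autocorrelations, and
# nonparametric bootstrap comparisons against them.

# Runs of constant label define the blocks of the timeline.
.label_blocks <- function(labels, trial_ids = NULL) {
  n <- length(labels)
  if (is.null(trial_ids)) trial_ids <- rep("trial1", n)
  brk <- c(TRUE, labels[-1L] != labels[-n] | trial_ids[-1L] != trial_ids[-n])
  id <- cumsum(brk)
  split(seq_len(n), id)
}

#' Epoch-block shuffle surrogate
#'
#' Cuts the vector time series at epoch boundaries into blocks and permutes
#' the block order uniformly at random while the epoch-label timeline stays
#' fixed in place, so the vector-to-label assignment is randomized while all
#' temporal autocorrelations up to the relevant block length are preserved
#' (blocks keep their internal order).  To keep the fixed label timeline
#' well defined, permutation is restricted to blocks of compatible length
#' (within +/-10%).
#'
#' @param values T x n matrix of state vectors (or a [rate_matrix] /
#'   `dc_matrix`, in which case the same object is returned with shuffled
#'   rows).
#' @param labels per-bin epoch labels defining the blocks.
#' @param trial_ids optional per-bin trial ids (blocks never span trials).
#' @param seed RNG seed for reproducibility.
#' @return Object of the same shape as `values` with rows permuted
#'   block-wise; the label timeline is unchanged by construction.
#' @export
epoch_block_shuffle <- function(values, labels, trial_ids = NULL,
                                seed = NULL) {
  container <- NULL
  if (inherits(values, c("rate_matrix", "dc_matrix"))) {
    container <- values
    trial_ids <- trial_ids %||% container$trial_ids
    values <- container$values
  }
  stopifnot(nrow(values) == length(labels))
  blocks <- .label_blocks(labels, trial_ids)
  if (length(blocks) < 2L) stop("need at least 2 labeled blocks to shuffle")
  if (!is.null(seed)) set.seed(seed)

  # group blocks of compatible length (within 10% of the group's first)
  len <- lengths(blocks)
  ord <- order(len)
  group <- integer(length(blocks))
  g <- 0L; ref_len <- -Inf
  for (b in ord) {
    if (len[b] > 1.1 * ref_len) { g <- g + 1L; ref_len <- len[b] }
    group[b] <- g
  }
  assign_to <- seq_along(blocks)
  for (gg in unique(group)) {
    members <- which(group == gg)
    if (length(members) > 1L)
      assign_to[members] <- sample(members)
  }
  new_rows <- unlist(blocks[assign_to], use.names = FALSE)
  out <- values[new_rows, , drop = FALSE]
  if (!is.null(container)) { container$values <- out; return(container) }
  out
}

#' Time inversion within task epochs
#'
#' Reverses the bin order for all units simultaneously within each labeled
#' epoch block; unlabeled stretches are left untouched.  Epoch-specific
#' lengths and marginal distributions are preserved while causal temporal
#' relations are destroyed.  The operation is an involution.
#'
#' @inheritParams epoch_block_shuffle
#' @return Object of the same shape as `values` with rows reversed within
#'   labeled blocks.
#' @export
time_invert_epochs <- function(values, labels, trial_ids = NULL) {
  container <- NULL
  if (inherits(values, c("rate_matrix", "dc_matrix"))) {
    container <- values
    trial_ids <- trial_ids %||% container$trial_ids
    values <- container$values
  }
  stopifnot(nrow(values) == length(labels))
  blocks <- .label_blocks(labels, trial_ids)
  new_rows <- seq_len(nrow(values))
  for (b in blocks) {
    if (labels[b[1]] != "unlabeled") new_rows[b] <- rev(b)
  }
  out <- values[new_rows, , drop = FALSE]
  if (!is.null(container)) { container$values <- out; return(container) }
  out
}

#' Augment or decimate a dataset within epochs
#'
#' Augmentation resamples vectors with replacement within each epoch to
#' reach `factor` times the original count; decimation drops vectors
#' uniformly at random down to fraction `factor`.  A per-unit
#' Kolmogorov-Smirnov distance between original and surrogate marginals is
#' computed per epoch and attached as attribute `ks_distance` (the process
#' is meant not to alter the original distributions).
#'
#' @param values T x n matrix of state vectors.
#' @param labels per-bin epoch labels.
#' @param mode `"augment"` or `"decimate"`.
#' @param factor augmentation multiple (> 1) or decimation fraction in
#'   (0, 1].
#' @param seed RNG seed.
#' @return List with `values` (resampled matrix), `labels` (matching), and
#'   attribute `ks_distance` (max per-unit KS distance across epochs).
#' @export
augment_decimate <- function(values, labels, mode = c("augment", "decimate"),
                             factor = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(values) == length(labels))
  if (factor < 0.5 || factor > 20)
    warning("factor ", factor, " outside the usual range [0.5, 20]")
  if (mode == "decimate" && (factor <= 0 || factor > 1))
    stop("decimation fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  idx_out <- integer(0); lab_out <- character(0)
  for (ep in unique(labels)) {
    idx <- which(labels == ep)
    take <- if (mode == "augment") {
      if (factor == 1) idx else sample(idx, round(factor * length(idx)),
                                       replace = TRUE)
    } else {
      if (factor == 1) idx else sort(sample(idx, round(factor * length(idx))))
    }
    idx_out <- c(idx_out, take)
    lab_out <- c(lab_out, rep(ep, length(take)))
  }
  ks <- 0
  for (ep in unique(labels)) {
    a <- which(labels == ep); b <- which(lab_out == ep)
    for (j in seq_len(ncol(values))) {
      orig <- values[a, j]; new <- values[idx_out[b], j]
      if (sd(orig) == 0) next
      d <- suppressWarnings(stats::ks.test(orig, new)$statistic)
      ks <- max(ks, unname(d))
    }
  }
  structure(list(values = values[idx_out, , drop = FALSE], labels = lab_out),
            ks_distance = ks)
}

#' One-sided bootstrap test against surrogate data
#'
#' Evaluates a statistic on the original dataset and on `n_replications`
#' surrogates built by `surrogate_fn`, and reports the add-one exceedance
#' probability `p = (1 + #extreme) / (n + 1)`.  Surrogate seeds are derived
#' deterministically from `seed`.
#'
#' @param statistic function `dataset -> scalar`, deterministic given the
#'   dataset.
#' @param data the original dataset object.
#' @param surrogate_fn function `(dataset, seed) -> surrogate dataset`.
#' @param n_replications number of surrogates; default 100 (one-sided
#'   comparisons at p = 0.01).
#' @param seed master seed.
#' @param alternative `"less"` if small statistics are extreme (e.g.
#'   prediction error below the null), `"greater"` otherwise.
#' @return A `bootstrap_ensemble`: `observed`, `statistics` (per
#'   replication), `p_value`, `n_failed`.
#' @export
bootstrap_test <- function(statistic, data, surrogate_fn,
                           n_replications = 100L, seed = 1L,
                           alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  observed <- statistic(data)
  stats_r <- rep(NA_real_, n_replications)
  for (r in seq_len(n_replications)) {
    stats_r[r] <- tryCatch(statistic(surrogate_fn(data, seed + r)),
                           error = function(e) NA_real_)
  }
  failed <- sum(is.na(stats_r))
  if (failed > 0.1 * n_replications)
    stop("statistic failed on ", failed, " of ", n_replications,
         " replications")
  okv <- stats_r[!is.na(stats_r)]
  extreme <- if (alternative == "less") sum(okv <= observed)
  else sum(okv >= observed)
  structure(list(observed = observed, statistics = okv,
                 p_value = (1 + extreme) / (length(okv) + 1),
                 n_failed = failed, alternative = alternative),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(
    "bootstrap_ensemble: observed %.4f vs %d surrogates [%.4f, %.4f] | p = %.4f (%s)\n",
    x$observed, length(x$statistics), min(x$statistics), max(x$statistics),
    x$p_value, x$alternative))
  invisible(x)
}
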