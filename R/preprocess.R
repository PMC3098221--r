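# Spike-table ingestion, unit quality control, Gaussian rate estimation and
# epoch-label timelines.

#' Construct a spike train set
#'
#' A `spike_train_set` holds the spike times of all simultaneously recorded
#' units for one trial.  Spike times are in seconds, strictly within the trial
#' span, and non-decreasing per unit.
#'
#' @param units named list; one sorted numeric vector of spike times per unit.
#' @param trial_span numeric length-2, `(t_start, t_end)` in seconds.
#' @param trial_id identifier for the trial.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(units, trial_span, trial_id = "trial1") {
  stopifnot(is.list(units), length(trial_span) == 2L,
            trial_span[2] > trial_span[1])
  if (is.null(names(units)) && length(units) > 0L)
    names(units) <- paste0("u", seq_along(units))
  units <- lapply(units, function(tt) sort(as.numeric(tt)))
  bad <- vapply(units, function(tt)
    any(tt < trial_span[1] | tt > trial_span[2]), logical(1))
  if (any(bad))
    stop("spike times outside trial span for unit(s): ",
         paste(names(units)[bad], collapse = ", "))
  structure(list(trial_id = trial_id, units = units,
                 trial_span = as.numeric(trial_span)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("spike_train_set:", x$trial_id, "|", length(x$units), "units |",
      sum(lengths(x$units)), "spikes | span",
      sprintf("[%.1f, %.1f] s\n", x$trial_span[1], x$trial_span[2]))
  invisible(x)
}

#' Read a delimited spike-time table
#'
#' Expects columns `unit_id` and `time_s` (comma- or tab-separated; extra
#' columns are ignored).  An optional `trial_id` column splits the file into
#' several trials, in which case a named list of [spike_train_set] objects is
#' returned.
#'
#' @param path path to the CSV/TSV file.
#' @param trial_span `(t_start, t_end)` in seconds applied to every trial.
#' @param units optional character vector declaring the expected unit ids, so
#'   that units with zero spikes are still represented.
#' @return A [spike_train_set], or a named list of them when the table
#'   contains several `trial_id` values.
#' @export
load_spike_table <- function(path, trial_span, units = NULL) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("unit_id", "time_s")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("spike table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  times <- suppressWarnings(as.numeric(tab$time_s))
  if (nrow(tab) && anyNA(times))
    stop("non-numeric time_s in ", path, " at line(s): ",
         paste(which(is.na(times)) + 1L, collapse = ", "))
  out_of_span <- times < trial_span[1] | times > trial_span[2]
  if (nrow(tab) && any(out_of_span))
    stop("time_s outside trial span in ", path, " at line(s): ",
         paste(which(out_of_span) + 1L, collapse = ", "))
  build_one <- function(sub, id) {
    uu <- split(times[sub], as.character(tab$unit_id[sub]))
    if (!is.null(units))
      for (u in setdiff(as.character(units), names(uu))) uu[[u]] <- numeric(0)
    uu <- uu[order(names(uu))]
    spike_train_set(uu, trial_span, trial_id = id)
  }
  if ("trial_id" %in% names(tab) && nrow(tab) &&
      length(unique(tab$trial_id)) > 1L) {
    ids <- unique(as.character(tab$trial_id))
    sets <- lapply(ids, function(id) build_one(tab$trial_id == id, id))
    names(sets) <- ids
    sets
  } else {
    id <- if ("trial_id" %in% names(tab) && nrow(tab))
      as.character(tab$trial_id[1]) else "trial1"
    build_one(rep(TRUE, nrow(tab)), id)
  }
}

#' Unit quality control
#'
#' Applies, in order: (1) removal of the second spike of any pair with an
#' inter-spike interval at or below `isi_floor` (duplicate threshold
#' crossings); (2) removal of the lower-rate unit of any pair whose 1-ms
#' binned spike indicators correlate above `dup_corr_max` at zero lag (the
#' same neuron captured on two channels); (3) exclusion of units whose mean
#' rate is below `low_rate_frac` of the most responsive unit's mean rate.
#'
#' @param s a [spike_train_set].
#' @param rates optional [rate_matrix]; if supplied, mean rates for step (3)
#'   are taken from its column means instead of raw spike counts.
#' @param isi_floor seconds; default 0.010.
#' @param dup_corr_max zero-lag correlation threshold; default 0.9.
#' @param low_rate_frac fraction of the maximum mean rate; default 0.02.
#' @return A list with elements `spikes` (filtered [spike_train_set]) and
#'   `report` (a `unit_qc_report`).
#' @export
qc_filter_units <- function(s, rates = NULL, isi_floor = 0.010,
                            dup_corr_max = 0.9, low_rate_frac = 0.02) {
  stopifnot(inherits(s, "spike_train_set"))
  span <- s$trial_span
  dur <- diff(span)

  # (1) ISI floor: greedy forward pass, second spike of the offending pair
  removed_isi <- integer(length(s$units))
  names(removed_isi) <- names(s$units)
  units <- lapply(names(s$units), function(u) {
    tt <- s$units[[u]]
    if (length(tt) < 2L) return(tt)
    keep <- logical(length(tt)); keep[1] <- TRUE
    last <- tt[1]
    for (i in 2:length(tt)) {
      if (tt[i] - last > isi_floor) { keep[i] <- TRUE; last <- tt[i] }
    }
    removed_isi[u] <<- sum(!keep)
    tt[keep]
  })
  names(units) <- names(s$units)

  # (2) duplicate units: zero-lag correlation of 1-ms spike indicators
  dup_df <- data.frame(kept = character(0), dropped = character(0),
                       correlation = numeric(0), stringsAsFactors = FALSE)
  ids <- names(units)
  if (length(ids) > 1L) {
    nbin <- max(1L, ceiling(dur / 0.001))
    ind <- vapply(units, function(tt) {
      v <- integer(nbin)
      if (length(tt)) {
        b <- pmin(nbin, pmax(1L, ceiling((tt - span[1]) / 0.001)))
        v <- as.integer(tabulate(b, nbin) > 0L)
      }
      v
    }, integer(nbin))
    drop <- character(0)
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      a <- ids[i]; b <- ids[j]
      if (a %in% drop || b %in% drop) next
      if (sd(ind[, a]) == 0 || sd(ind[, b]) == 0) next
      r <- stats::cor(ind[, a], ind[, b])
      if (is.finite(r) && r > dup_corr_max) {
        lo <- if (length(units[[a]]) <= length(units[[b]])) a else b
        hi <- setdiff(c(a, b), lo)
        drop <- c(drop, lo)
        dup_df <- rbind(dup_df, data.frame(kept = hi, dropped = lo,
                                           correlation = r))
      }
    }
    units <- units[setdiff(ids, drop)]
  }

  # (3) low-rate exclusion, on rates surviving (1)+(2)
  mean_rate <- if (!is.null(rates)) {
    mr <- colMeans(rates$values)[names(units)]
    ifelse(is.na(mr), lengths(units) / dur, mr)
  } else lengths(units) / dur
  low_df <- data.frame(unit_id = character(0), rate_ratio = numeric(0),
                       stringsAsFactors = FALSE)
  if (length(units)) {
    ratio <- mean_rate / max(mean_rate)
    low <- names(units)[ratio < low_rate_frac]
    if (length(low))
      low_df <- data.frame(unit_id = low, rate_ratio = ratio[low])
    units <- units[setdiff(names(units), low)]
  }
  if (!length(units)) stop("no responsive units")

  report <- structure(list(removed_isi_spikes = removed_isi,
                           removed_duplicate_units = dup_df,
                           removed_low_rate_units = low_df),
                      class = "unit_qc_report")
  list(spikes = spike_train_set(units, span, s$trial_id), report = report)
}

#' @export
print.unit_qc_report <- function(x, ...) {
  cat("unit_qc_report:", sum(x$removed_isi_spikes), "ISI spikes removed;",
      nrow(x$removed_duplicate_units), "duplicate unit(s);",
      nrow(x$removed_low_rate_units), "low-rate unit(s)\n")
  invisible(x)
}

#' Smoothed, binned population firing rates
#'
#' Each spike contributes a unit-area Gaussian of width `sigma`; the bin value
#' is the mean spike density over the half-open bin `[t, t+Delta)` in
#' spikes/s, so the integral of each unit's density over the trial
#' approximates its spike count (mass outside the trial is truncated, not
#' reflected).  With `normalize_to_trial = TRUE` each unit's density is
#' additionally divided by its integral over the trial, yielding a per-trial
#' probability density.
#'
#' @param s a [spike_train_set] or list of them (trials are stacked in list
#'   order; all trials must share the same unit set).
#' @param sigma Gaussian SD in seconds (default 0.05; useful range
#'   0.005-0.200).
#' @param bin_width bin width Delta in seconds (default 0.200).
#' @param normalize_to_trial divide each unit's density by its trial
#'   integral.
#' @return A `rate_matrix`: list with `values` (T x n), `bin_width`, `sigma`,
#'   `bin_starts` (s, relative to each trial start), `unit_ids`, `trial_ids`
#'   (per bin), `normalized_to_trial`.
#' @export
estimate_rates <- function(s, sigma = 0.05, bin_width = 0.2,
                           normalize_to_trial = FALSE) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (bin_width <= 0) stop("bin_width must be > 0")
  trials <- if (inherits(s, "spike_train_set")) list(s) else s
  stopifnot(all(vapply(trials, inherits, logical(1), "spike_train_set")))
  unit_ids <- names(trials[[1]]$units)
  vals <- list(); starts <- list(); tids <- list()
  for (tr in trials) {
    if (!identical(names(tr$units), unit_ids))
      stop("trials must share the same unit set")
    span <- tr$trial_span
    T_tr <- floor(diff(span) / bin_width)
    if (T_tr < 1L) stop("trial shorter than one bin")
    edges <- span[1] + bin_width * (0:T_tr)
    m <- matrix(0, T_tr, length(unit_ids),
                dimnames = list(NULL, unit_ids))
    for (u in unit_ids) {
      sp <- tr$units[[u]]
      if (!length(sp)) next
      # Gaussian CDF at bin edges for every spike; bin mass = cdf difference
      cdf <- outer(edges, sp, function(e, mu) stats::pnorm(e, mu, sigma))
      mass <- rowSums(cdf[-1L, , drop = FALSE] -
                        cdf[-nrow(cdf), , drop = FALSE])
      dens <- mass / bin_width
      if (normalize_to_trial) {
        tot <- sum(stats::pnorm(span[2], sp, sigma) -
                     stats::pnorm(span[1], sp, sigma))
        if (tot > 0) dens <- dens / tot
      }
      m[, u] <- dens
    }
    vals[[length(vals) + 1L]] <- m
    starts[[length(starts) + 1L]] <- edges[-length(edges)] - span[1]
    tids[[length(tids) + 1L]] <- rep(tr$trial_id, T_tr)
  }
  structure(list(values = do.call(rbind, vals),
                 bin_width = bin_width, sigma = sigma,
                 bin_starts = unlist(starts),
                 unit_ids = unit_ids,
                 trial_ids = unlist(tids),
                 normalized_to_trial = normalize_to_trial),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix:", nrow(x$values), "bins x", ncol(x$values), "units |",
      "Delta =", x$bin_width, "s, sigma =", x$sigma, "s |",
      length(unique(x$trial_ids)), "trial(s)",
      if (x$normalized_to_trial) "| trial-normalized" else "", "\n")
  invisible(x)
}

# window precedence when overlapping windows of different kinds collide
.label_kind <- function(label) {
  ifelse(grepl("reward|food_cup", label), "reward",
         ifelse(grepl("choice", label), "choice", "other"))
}
.kind_rank <- c(reward = 3, choice = 2, other = 1)

#' Build the per-bin epoch-label timeline
#'
#' Event tables give either explicit windows (`end_s` present) or point
#' events from which windows are derived: reward-type events (label matching
#' "reward"/"food_cup") span `[t - 0.2, t + 0.8)` s; choice-type events span
#' `[t - 1.5, min(t + 0.5, next reward start))` s.  Per-bin labels are
#' assigned by majority temporal overlap (at least half the bin); overlapping
#' windows of different kinds are resolved by precedence reward > choice >
#' other, with a warning.
#'
#' @param events path to a CSV with columns
#'   `trial_id,label_or_event,start_s[,end_s]`, or an equivalent data frame.
#' @param rates the [rate_matrix] whose bins are to be labeled.
#' @return An `epoch_timeline`: list with `labels` (per bin; `"unlabeled"`
#'   outside windows) and `event_windows` (data frame).
#' @export
build_epoch_timeline <- function(events, rates) {
  ev <- if (is.character(events)) {
    utils::read.csv(events, stringsAsFactors = FALSE)
  } else as.data.frame(events)
  if (!nrow(ev)) {
    return(structure(list(labels = rep("unlabeled", nrow(rates$values)),
                          event_windows = data.frame(label = character(0),
                                                     start_s = numeric(0),
                                                     end_s = numeric(0),
                                                     trial_id = character(0))),
                     class = "epoch_timeline"))
  }
  need <- c("trial_id", "label_or_event", "start_s")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"end_s" %in% names(ev)) ev$end_s <- NA_real_
  ev$trial_id <- as.character(ev$trial_id)
  ev <- ev[order(ev$trial_id, ev$start_s, ev$label_or_event), , drop = FALSE]

  windows <- do.call(rbind, lapply(split(ev, ev$trial_id), function(sub) {
    kind <- .label_kind(sub$label_or_event)
    explicit <- !is.na(sub$end_s)
    start <- sub$start_s; end <- sub$end_s
    # point events: derive windows
    reward_starts <- c(start[explicit & kind == "reward"],
                       sub$start_s[!explicit & kind == "reward"] - 0.2)
    for (i in which(!explicit)) {
      if (kind[i] == "reward") {
        start[i] <- sub$start_s[i] - 0.2
        end[i] <- sub$start_s[i] + 0.8
      } else if (kind[i] == "choice") {
        start[i] <- sub$start_s[i] - 1.5
        nxt <- reward_starts[reward_starts > sub$start_s[i]]
        end[i] <- min(sub$start_s[i] + 0.5,
                      if (length(nxt)) min(nxt) else Inf)
      } else {
        stop("point event with non-reward/non-choice label '",
             sub$label_or_event[i], "' needs an explicit end_s")
      }
    }
    data.frame(label = sub$label_or_event, start_s = start, end_s = end,
               trial_id = sub$trial_id, stringsAsFactors = FALSE)
  }))
  rownames(windows) <- NULL
  windows <- windows[order(windows$trial_id, windows$start_s, windows$label), ,
                     drop = FALSE]

  dt <- rates$bin_width
  T_all <- nrow(rates$values)
  labels <- rep("unlabeled", T_all)
  warned <- FALSE
  for (tid in unique(rates$trial_ids)) {
    rows <- which(rates$trial_ids == tid)
    win <- windows[windows$trial_id == tid, , drop = FALSE]
    if (!nrow(win)) next
    # clip windows at trial boundaries
    tr_len <- (max(rates$bin_starts[rows]) + dt)
    win$start_s <- pmax(win$start_s, 0)
    win$end_s <- pmin(win$end_s, tr_len)
    for (r in rows) {
      b0 <- rates$bin_starts[r]; b1 <- b0 + dt
      ov <- pmin(win$end_s, b1) - pmax(win$start_s, b0)
      ov[ov < 0] <- 0
      by_label <- tapply(ov, win$label, sum)
      best <- max(by_label)
      if (best < dt / 2) next
      cand <- names(by_label)[by_label == best]
      if (length(cand) > 1L) {
        cand <- cand[order(-.kind_rank[.label_kind(cand)], cand)]
        if (!warned) {
          warning("overlapping windows of different labels; resolved by ",
                  "precedence reward > choice > other")
          warned <- TRUE
        }
      }
      labels[r] <- cand[1]
    }
  }
  structure(list(labels = labels, event_windows = windows),
            class = "epoch_timeline")
}

#' @export
print.epoch_timeline <- function(x, ...) {
  tab <- table(x$labels)
  cat("epoch_timeline:", length(x$labels), "bins |",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
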