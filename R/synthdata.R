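# Synthetic multistable-ensemble spike simulator: a latent
# Ornstein-Uhlenbeck process pulled towards epoch-specific attracting states
# drives inhomogeneous-Poisson spiking, so every pipeline stage can be
# exercised with known ground truth.

#' Default epoch schedule mimicking a delayed win-shift maze trial
#'
#' Four training choice/reward pairs, a 60-s delay, eight test choice/reward
#' pairs, separated by unlabeled locomotion stretches; total about 154 s
#' (matching the scale of real trials of roughly 160 s).
#'
#' @return Data frame with columns `label`, `duration` (s).
#' @export
default_epoch_schedule <- function() {
  blocks <- list(c("unlabeled", 5))
  for (i in 1:4)
    blocks <- c(blocks, list(c("train_choice", 2), c("train_reward", 1),
                             c("unlabeled", 4)))
  blocks <- c(blocks, list(c("delay", 60)))
  for (i in 1:8)
    blocks <- c(blocks, list(c("test_choice", 2), c("test_reward", 1),
                             c("unlabeled", 4)))
  blocks <- c(blocks, list(c("unlabeled", 5)))
  data.frame(label = vapply(blocks, `[`, character(1), 1L),
             duration = as.numeric(vapply(blocks, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

# Fixed latent fixed points: task epochs are successive states along a 1-D
# task-progression axis (training phase at one end, test phase at the
# other, the delay as a resting state at the origin, where unlabeled time
# also relaxes).  Interior states on this axis are deliberately not
# linearly separable from the mixture of the remaining epoch states, so
# that carving any single state out of the ongoing dynamics requires
# nonlinear (higher-order) boundaries -- the regime the expansion targets.
# Error choices sit off-axis.
.default_centers <- function(latent_dim, spacing = 1.5) {
  base <- rbind(train_choice = c(-2, 0, 0),
                train_reward = c(-1, 0, 0),
                delay        = c(0, 0, 0),
                test_reward  = c(1, 0, 0),
                test_choice  = c(2, 0, 0),
                error_choice = c(0, 4 / 3, 0))
  if (latent_dim < 3L)
    base <- base[, seq_len(latent_dim), drop = FALSE]
  if (latent_dim > 3L)
    base <- cbind(base, matrix(0, nrow(base), latent_dim - 3L))
  spacing * base
}

#' Parameters of the synthetic attractor-ensemble simulator
#'
#' @param n_units number of simulated units; default 20.
#' @param n_trials number of trials; default 1.
#' @param epoch_schedule data frame `(label, duration)` per trial; default
#'   [default_epoch_schedule()].
#' @param latent_dim latent state dimension; default 3.
#' @param attractor_centers matrix (labels x latent_dim) of epoch fixed
#'   points; by default the epochs form a 1-D task-progression axis
#'   (training states at one end, test states at the other, delay at the
#'   origin where unlabeled time also relaxes) with 1.5 units between
#'   neighboring states.
#' @param convergence_rate OU pull rate lambda in 1/s; default 2.
#' @param noise_sd latent diffusion scale; default 1.5 (stationary latent
#'   SD 0.75, i.e. half the separation of neighboring epoch states --
#'   heavily overlapping, noise-dominated trajectories).
#' @param loading n_units x latent_dim gain matrix; default standard-normal
#'   entries drawn from `seed`.
#' @param baseline_rate baseline firing rate in spikes/s; default 2
#'   (sparse cortical firing; rectification of the rate link is then a
#'   substantial nonlinearity).
#' @param dt simulation step in s; default 0.001 (1-ms spike resolution).
#' @param seed RNG seed; the full dataset is bit-reproducible given the
#'   seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_units = 20L, n_trials = 1L,
                         epoch_schedule = default_epoch_schedule(),
                         latent_dim = 3L, attractor_centers = NULL,
                         convergence_rate = 2, noise_sd = 1.5,
                         loading = NULL, baseline_rate = 2,
                         dt = 0.001, seed = 1L) {
  if (any(epoch_schedule$duration <= 0)) stop("durations must be > 0")
  if (convergence_rate < 0) stop("convergence_rate must be >= 0")
  centers <- attractor_centers %||% .default_centers(latent_dim)
  if (!all(is.finite(centers))) stop("non-finite attractor centers")
  structure(list(n_units = as.integer(n_units),
                 n_trials = as.integer(n_trials),
                 epoch_schedule = epoch_schedule,
                 latent_dim = as.integer(latent_dim),
                 attractor_centers = centers,
                 convergence_rate = convergence_rate,
                 noise_sd = noise_sd, loading = loading,
                 baseline_rate = baseline_rate, dt = dt,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic multistable-ensemble dataset
#'
#' The latent state follows `dz = lambda (c_epoch - z) dt + noise_sd dW`,
#' with the fixed point `c_epoch` switching at epoch boundaries (unlabeled
#' stretches relax towards the origin).  Unit rates are
#' `max(0, baseline + loading %*% z)` and spikes are drawn from an
#' inhomogeneous Poisson process at `dt` resolution.
#'
#' @param params a [synth_params()] object.
#' @return A `synthetic_dataset`: `spikes` (list of [spike_train_set] per
#'   trial), `latents` (per-trial latent trajectories at `dt` resolution,
#'   stored every 10 steps), `events` (window table in the dialect of
#'   [build_epoch_timeline()]), `params`.
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  loading <- p$loading %||% matrix(stats::rnorm(p$n_units * p$latent_dim),
                                   p$n_units, p$latent_dim)
  sched <- p$epoch_schedule
  trial_len <- sum(sched$duration)
  nsteps <- round(trial_len / p$dt)
  # per-step epoch label index
  step_label <- rep.int(seq_len(nrow(sched)),
                        round(sched$duration / p$dt))
  length(step_label) <- nsteps   # guard rounding
  step_label[is.na(step_label)] <- nrow(sched)

  centers <- matrix(0, nrow(sched), p$latent_dim)
  known <- rownames(p$attractor_centers)
  for (i in seq_len(nrow(sched))) {
    lb <- sched$label[i]
    if (lb %in% known) centers[i, ] <- p$attractor_centers[lb, ]
  }

  spikes <- list(); latents <- list()
  events <- list()
  sq_dt <- sqrt(p$dt)
  for (tr in seq_len(p$n_trials)) {
    tid <- paste0("trial", tr)
    # Euler-Maruyama as a linear recursion z_s = a z_{s-1} + drive_s with
    # a = 1 - lambda dt, solved by the recursive filter per dimension
    a_coef <- 1 - p$convergence_rate * p$dt
    z0 <- centers[step_label[1], ]  # start on the first epoch's fixed point
    noise <- matrix(stats::rnorm(nsteps * p$latent_dim), nsteps)
    z <- vapply(seq_len(p$latent_dim), function(j) {
      drive <- p$convergence_rate * centers[step_label, j] * p$dt +
        p$noise_sd * sq_dt * noise[, j]
      as.numeric(stats::filter(drive, a_coef, method = "recursive",
                               init = z0[j]))
    }, numeric(nsteps))
    rates <- pmax(0, p$baseline_rate +
                    z %*% t(loading))           # nsteps x n_units
    counts <- matrix(stats::rpois(length(rates), rates * p$dt),
                     nrow = nsteps)
    units <- lapply(seq_len(p$n_units), function(u) {
      reps <- counts[, u]
      if (!sum(reps)) return(numeric(0))
      tt <- rep((which(reps > 0) - 1L) * p$dt, reps[reps > 0]) +
        stats::runif(sum(reps), 0, p$dt)
      sort(tt)
    })
    names(units) <- sprintf("u%02d", seq_len(p$n_units))
    spikes[[tid]] <- spike_train_set(units, c(0, trial_len), trial_id = tid)
    latents[[tid]] <- z[seq(1L, nsteps, by = 10L), , drop = FALSE]
    off <- cumsum(c(0, sched$duration))
    lab <- which(sched$label != "unlabeled")
    events[[tid]] <- data.frame(trial_id = rep(tid, length(lab)),
                                label_or_event = sched$label[lab],
                                start_s = off[lab],
                                end_s = off[lab + 1L],
                                stringsAsFactors = FALSE)
  }
  structure(list(spikes = spikes, latents = latents,
                 events = do.call(rbind, events), params = p,
                 loading = loading),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$spikes), "trial(s) x",
      x$params$n_units, "units |",
      sum(vapply(x$spikes, function(s) sum(lengths(s$units)), numeric(1))),
      "spikes\n")
  invisible(x)
}

#' Matched null variants of a synthetic dataset
#'
#' `single_center`: regenerate with all epoch fixed points collapsed onto
#' their mean, so epoch structure disappears while autocorrelations are
#' preserved.  `label_shuffle`: permute the epoch labels over the event
#' windows (multiset of labels preserved).  `time_invert`: reverse spike
#' times within each labeled window for all units simultaneously (the
#' spike-level analog of [time_invert_epochs()]; an involution).
#'
#' @param d a [generate_dataset()] result.
#' @param mode one of `"single_center"`, `"label_shuffle"`,
#'   `"time_invert"`.
#' @param seed RNG seed for the label shuffle.
#' @return A `synthetic_dataset`.
#' @export
make_null_variant <- function(d, mode = c("single_center", "label_shuffle",
                                          "time_invert"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(d, "synthetic_dataset"))
  if (mode == "single_center") {
    p <- d$params
    ctr <- p$attractor_centers
    used <- intersect(rownames(ctr), unique(p$epoch_schedule$label))
    mean_ctr <- colMeans(ctr[used, , drop = FALSE])
    ctr[] <- rep(mean_ctr, each = nrow(ctr))
    p$attractor_centers <- ctr
    # unlabeled stretches must share the same fixed point: re-label rows
    # of the center table is enough since .default_centers covers labels;
    # the origin used for unlabeled time is replaced by the mean center too
    extra <- matrix(mean_ctr, 1L, p$latent_dim,
                    dimnames = list("unlabeled", NULL))
    p$attractor_centers <- rbind(p$attractor_centers, extra)
    p$loading <- d$loading  # keep the same gains
    return(generate_dataset(p))
  }
  if (mode == "label_shuffle") {
    if (!is.null(seed)) set.seed(seed)
    ev <- d$events
    ev$label_or_event <- ave(ev$label_or_event, ev$trial_id,
                             FUN = function(v) sample(v))
    d$events <- ev
    return(d)
  }
  # time_invert: reflect spike times within each labeled window
  ev <- d$events
  for (tid in names(d$spikes)) {
    win <- ev[ev$trial_id == tid, , drop = FALSE]
    st <- d$spikes[[tid]]
    st$units <- lapply(st$units, function(tt) {
      for (i in seq_len(nrow(win))) {
        inw <- tt >= win$start_s[i] & tt < win$end_s[i]
        tt[inw] <- win$start_s[i] + win$end_s[i] - tt[inw]
      }
      sort(tt)
    })
    d$spikes[[tid]] <- st
  }
  d
}

#' Write a synthetic dataset to spike/event CSV files
#'
#' Emits the same dialects [load_spike_table()] and
#' [build_epoch_timeline()] read, so datasets round-trip through the
#' preprocessing module.
#'
#' @param d a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths of `spikes.csv` and `events.csv`.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(names(d$spikes), function(tid) {
    st <- d$spikes[[tid]]
    do.call(rbind, lapply(names(st$units), function(u) {
      tt <- st$units[[u]]
      if (!length(tt)) return(NULL)
      data.frame(trial_id = tid, unit_id = u, time_s = tt,
                 stringsAsFactors = FALSE)
    }))
  }))
  spike_path <- file.path(dir, "spikes.csv")
  event_path <- file.path(dir, "events.csv")
  utils::write.csv(rows, spike_path, row.names = FALSE)
  utils::write.csv(d$events, event_path, row.names = FALSE)
  invisible(c(spikes = spike_path, events = event_path))
}
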