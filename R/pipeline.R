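# End-to-end orchestration: YAML config, staged execution, reproducible
# manifest.  A thin command-line wrapper over run_pipeline() is installed
# under exec/ensembleflow.

#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults; any subset can be
#' overridden by a YAML file or a named list.  One global `seed` fans out to
#' per-stage seeds as `seed + stage offset` (simulate +0, splits +100,
#' surrogates +200).
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sigma = 0.05, bin_width = 0.2, normalize_to_trial = FALSE,
    isi_floor = 0.010, dup_corr_max = 0.9, low_rate_frac = 0.02,
    max_lag_frac = 0.05,
    O_list = c(1, 2, 3, 5, 7), eta = 0.05, n_components = 3L,
    n_ref_trials = NULL, n_pred_trials = NULL,
    exclude_rewards = TRUE, min_per_class = 10L, max_per_class = Inf,
    escape_k = 2L, escape_rho = 1.5,
    n_replications = 100L,
    n_units = 20L, n_trials = 2L,
    spikes_csv = NULL, events_csv = NULL, trial_span = NULL
  )
}

#' Load and validate a pipeline configuration
#'
#' @param config path to a YAML file, a named list of overrides, or `NULL`
#'   for pure defaults.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  base <- default_config()
  over <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else as.list(config)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  base[names(over)] <- over
  numeric_pos <- c("sigma", "bin_width", "isi_floor", "max_lag_frac", "eta")
  for (f in numeric_pos)
    if (!is.numeric(base[[f]]) || base[[f]] < 0)
      stop("config field '", f, "' must be a non-negative number")
  for (f in c("spikes_csv", "events_csv"))
    if (!is.null(base[[f]]) && !file.exists(base[[f]]))
      stop("config field '", f, "': path does not exist: ", base[[f]])
  structure(base, class = "pipeline_config")
}

.md5_of <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(utils::capture.output(dput(obj)), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

.log_stage <- function(level, ...) {
  if (identical(Sys.getenv("ENSEMBLEFLOW_QUIET"), "1")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the analysis pipeline
#'
#' Executes (a subset of) the stages `simulate`, `preprocess`, `sweep`,
#' `flow`, `escape`, `bootstrap` from a configuration, writing CSV/JSON
#' artifacts plus a run manifest (config hash, per-output checksums,
#' per-stage wall-clock) to `out_dir`.  When `spikes_csv`/`events_csv` are
#' not configured, the `simulate` stage generates a synthetic dataset and
#' feeds its files forward.
#'
#' @param config a [pipeline_config()], YAML path, or named list.
#' @param out_dir output directory.
#' @param stages which stages to run, in pipeline order.
#' @return A `run_manifest` (invisibly written as `manifest.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = "ensembleflow_run",
                         stages = c("simulate", "preprocess", "sweep",
                                    "flow", "escape", "bootstrap")) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = .md5_of(unclass(cfg)),
                   package_version =
                     as.character(utils::packageVersion("ensembleflow")),
                   stages = list(), outputs = list(), warnings = character(0))
  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)
  timing <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    .log_stage("info", "stage ", stage, " done (",
               manifest$stages[[stage]], " s)")
    res
  }

  spikes_csv <- cfg$spikes_csv; events_csv <- cfg$events_csv
  if ("simulate" %in% stages) {
    timing("simulate", {
      params <- synth_params(n_units = cfg$n_units, n_trials = cfg$n_trials,
                             seed = cfg$seed)
      d <- generate_dataset(params)
      paths <- write_dataset(d, file.path(out_dir, "synth"))
      spikes_csv <- paths[["spikes"]]; events_csv <- paths[["events"]]
      note(spikes_csv); note(events_csv)
      d
    })
  }
  if (!any(c("preprocess", "sweep", "flow", "escape", "bootstrap") %in%
           stages)) return(.finish_manifest(manifest, outputs, out_dir))
  if (is.null(spikes_csv) || is.null(events_csv))
    stop("no input data: configure spikes_csv/events_csv or run 'simulate'")

  # preprocess ------------------------------------------------------------
  state <- timing("preprocess", {
    ev <- utils::read.csv(events_csv, stringsAsFactors = FALSE)
    sp_times <- utils::read.csv(spikes_csv, stringsAsFactors = FALSE)$time_s
    span <- cfg$trial_span %||%
      c(0, ceiling(max(c(sp_times, ev$end_s), na.rm = TRUE)))
    sets <- load_spike_table(spikes_csv, span)
    if (inherits(sets, "spike_train_set")) sets <- list(sets)
    sets <- lapply(sets, function(s)
      qc_filter_units(s, isi_floor = cfg$isi_floor,
                      dup_corr_max = cfg$dup_corr_max,
                      low_rate_frac = cfg$low_rate_frac)$spikes)
    rates <- estimate_rates(sets, sigma = cfg$sigma,
                            bin_width = cfg$bin_width,
                            normalize_to_trial = cfg$normalize_to_trial)
    timeline <- build_epoch_timeline(events_csv, rates)
    rate_path <- file.path(out_dir, "rates.csv")
    utils::write.csv(data.frame(trial_id = rates$trial_ids,
                                bin_start = rates$bin_starts,
                                label = timeline$labels,
                                rates$values, check.names = FALSE),
                     rate_path, row.names = FALSE)
    note(rate_path)
    list(rates = rates, timeline = timeline)
  })
  if (!any(c("sweep", "flow", "escape", "bootstrap") %in% stages))
    return(.finish_manifest(manifest, outputs, out_dir))

  rates <- state$rates; timeline <- state$timeline
  delays <- select_delays(rates, timeline, cfg$max_lag_frac)
  dc <- build_dc_msua(rates, delays)
  trials <- unique(rates$trial_ids)
  n_ref <- cfg$n_ref_trials %||% floor(length(trials) / 2)
  if (n_ref < 1L || n_ref >= length(trials))
    stop("need at least 2 trials to form disjoint reference/prediction sets")
  ref_trials <- trials[seq_len(n_ref)]
  pred_trials <- setdiff(trials, ref_trials)
  if (!is.null(cfg$n_pred_trials))
    pred_trials <- utils::tail(pred_trials, cfg$n_pred_trials)

  sweep_df <- NULL
  if (any(c("sweep", "flow", "escape", "bootstrap") %in% stages)) {
    sweep_df <- timing("sweep", {
      s <- pairwise_epoch_sweep(dc, timeline, ref_trials, pred_trials,
                                O_list = cfg$O_list, eta = cfg$eta,
                                exclude_rewards = cfg$exclude_rewards,
                                min_per_class = cfg$min_per_class,
                                max_per_class = cfg$max_per_class)
      p1 <- file.path(out_dir, "sweep.csv")
      utils::write.csv(s, p1, row.names = FALSE); note(p1)
      p2 <- file.path(out_dir, "sweep_summary.csv")
      utils::write.csv(summarize_sweep(s), p2, row.names = FALSE); note(p2)
      s
    })
  }

  labels_dc <- timeline$labels[dc$keep_idx]
  lab_idx <- which(labels_dc != "unlabeled")
  O_top <- max(cfg$O_list)
  if ("flow" %in% stages) {
    timing("flow", {
      fl <- flow_convergence(dc, labels_dc, ref_trials, pred_trials,
                             O = O_top, eta = cfg$eta)
      p <- file.path(out_dir, "flow.json")
      jsonlite::write_json(list(slope = fl$fit$slope,
                                slope_surrogate = fl$fit_surr$slope,
                                p_value = fl$comparison$p_value),
                           p, auto_unbox = TRUE, digits = NA)
      note(p)
      fl
    })
  }
  if ("escape" %in% stages) {
    timing("escape", {
      er <- escape_sweep(dc, labels_dc, ref_trials, pred_trials,
                         O = O_top, eta = cfg$eta, k = cfg$escape_k,
                         rho = cfg$escape_rho)
      p <- file.path(out_dir, "escape.csv")
      utils::write.csv(er$per_epoch, p, row.names = FALSE); note(p)
      er
    })
  }
  if ("bootstrap" %in% stages) {
    timing("bootstrap", {
      stat <- function(d)
        mean(pairwise_epoch_sweep(d, timeline, ref_trials, pred_trials,
                                  O_list = O_top, eta = cfg$eta,
                                  exclude_rewards = cfg$exclude_rewards,
                                  min_per_class = cfg$min_per_class,
                                  max_per_class = cfg$max_per_class,
                                  directions = "forward")$SE_predic)
      surro <- function(d, s) epoch_block_shuffle(d, labels_dc, seed = s)
      ens <- bootstrap_test(stat, dc, surro,
                            n_replications = cfg$n_replications,
                            seed = cfg$seed + 200L, alternative = "less")
      p <- file.path(out_dir, "bootstrap.json")
      jsonlite::write_json(list(observed = ens$observed,
                                p_value = ens$p_value,
                                n_replications = length(ens$statistics)),
                           p, auto_unbox = TRUE, digits = NA)
      note(p)
      ens
    })
  }
  .finish_manifest(manifest, outputs, out_dir)
}

.finish_manifest <- function(manifest, outputs, out_dir) {
  manifest$outputs <- as.list(tools::md5sum(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(structure(manifest, class = "run_manifest"))
}

#' Out-of-sample flow-convergence analysis
#'
#' Fits the pairwise classifier machinery once at order `O` on the
#' reference trials (one-vs-rest per epoch), projects the prediction trials
#' into a 3-D kernel-PCA space, computes the flow field there, and fits the
#' likelihood-velocity curve for the original and the time-inverted
#' surrogate data.
#'
#' @param dc a `dc_matrix`.
#' @param labels per-row epoch labels of `dc`.
#' @param ref_trials,pred_trials disjoint trial-id sets.
#' @param O expansion order for likelihoods (full space).
#' @param eta regularization fraction.
#' @param n_bins speed bins; default 20.
#' @return List with `fit`, `fit_surr` ([likelihood_velocity_curve()]
#'   results), `comparison` ([compare_slopes()]), `flow`, `projection`.
#' @export
flow_convergence <- function(dc, labels, ref_trials, pred_trials, O = 5,
                             eta = 0.05, n_bins = 20L) {
  prep <- .fit_reference_space(dc, labels, ref_trials, O, eta)
  pred_rows <- prep$pred_rows
  seg <- .contiguous_segments(dc$trial_ids[pred_rows],
                              dc$bin_starts[pred_rows],
                              dc$bin_width %||% 0.2)
  curve_for <- function(vals_pred) {
    pr <- .predict_epochs(prep, vals_pred)
    proj <- project_kpca(prep$kpca,
                         poly_kernel(vals_pred, prep$A, O = O))
    fl <- velocity_field(proj, trial_ids = seg)
    lik <- pr$correct_likelihood[fl$from_idx]
    keep <- is.finite(lik)
    likelihood_velocity_curve(fl$speeds[keep], lik[keep], n_bins = n_bins)
  }
  fit <- curve_for(prep$B)
  inv <- time_invert_epochs(prep$B, labels[pred_rows], seg)
  fit_surr <- curve_for(inv)
  proj <- project_kpca(prep$kpca, poly_kernel(prep$B, prep$A, O = O))
  list(fit = fit, fit_surr = fit_surr,
       comparison = compare_slopes(fit, fit_surr),
       flow = velocity_field(proj, trial_ids = seg),
       projection = proj)
}

# Contiguity segments: bins belong to the same segment only when they are
# temporally adjacent within one trial.  Subsetting labeled bins leaves
# gaps; velocity pairs and trajectory runs must never straddle them.
.contiguous_segments <- function(trial_ids, bin_starts, bin_width) {
  n <- length(trial_ids)
  if (!n) return(integer(0))
  brk <- c(TRUE, trial_ids[-1L] != trial_ids[-n] |
             abs(bin_starts[-1L] - bin_starts[-n] - bin_width) >
             bin_width / 100)
  cumsum(brk)
}

# Shared reference-space fit: one-vs-rest kernel-FDA classifiers per epoch
# plus a kernel-PCA of the reference set at order O.
.fit_reference_space <- function(dc, labels, ref_trials, O, eta,
                                 max_ref = 600L) {
  ref_rows <- which(dc$trial_ids %in% ref_trials & labels != "unlabeled")
  if (length(ref_rows) > max_ref)
    ref_rows <- ref_rows[seq(1L, length(ref_rows),
                             length.out = max_ref)]
  pred_rows <- which(!(dc$trial_ids %in% ref_trials) &
                       labels != "unlabeled")
  sc <- .vector_scale(dc$values, ref_rows)
  A <- dc$values[ref_rows, , drop = FALSE] / sc
  B <- dc$values[pred_rows, , drop = FALSE] / sc
  K <- poly_kernel(A, O = O)
  lab_ref <- labels[ref_rows]
  epochs <- sort(unique(lab_ref))
  # one-vs-rest training sets are class-balanced: all bins of the target
  # epoch against a stratified sample of the others (at most 3x the target
  # size), so that data-rich epochs do not drown data-poor ones
  models <- lapply(epochs, function(ep) {
    own <- which(lab_ref == ep)
    if (length(own) < 2L) return(NULL)
    rest <- unlist(lapply(setdiff(epochs, ep), function(o) {
      i <- which(lab_ref == o)
      n <- max(2L, ceiling(3 * length(own) / (length(epochs) - 1L)))
      if (length(i) > n) i[round(seq(1L, length(i), length.out = n))] else i
    }))
    sub <- c(own, rest)
    ovr <- ifelse(lab_ref[sub] == ep, ep, ".rest")
    m <- fit_kfda(K[sub, sub, drop = FALSE], ovr, eta = eta,
                  equal_variance = TRUE)
    m$train_subset <- sub
    m
  })
  names(models) <- epochs
  list(A = A, B = B, K = K, scale = sc, O = O,
       ref_rows = ref_rows, pred_rows = pred_rows,
       lab_ref = lab_ref, labels_pred = labels[pred_rows],
       models = models[!vapply(models, is.null, logical(1))],
       kpca = kernel_pca(K, d = 3L))
}

# Per-bin epoch decision and correct-class likelihood for prediction
# vectors, via the one-vs-rest models.
.predict_epochs <- function(prep, vals_pred) {
  epochs <- names(prep$models)
  post <- matrix(NA_real_, nrow(vals_pred), length(epochs),
                 dimnames = list(NULL, epochs))
  lik <- post
  Kx <- poly_kernel(vals_pred, prep$A, O = prep$O)
  for (ep in epochs) {
    sub <- prep$models[[ep]]$train_subset
    cr <- classify(prep$models[[ep]], Kx[, sub, drop = FALSE])
    post[, ep] <- cr$posteriors[, ep]
    lik[, ep] <- cr$likelihoods[, ep]
  }
  decision <- epochs[max.col(post, ties.method = "first")]
  truth <- prep$labels_pred
  correct <- vapply(seq_len(nrow(lik)), function(i)
    if (truth[i] %in% epochs) lik[i, truth[i]] else NA_real_, numeric(1))
  # binary membership in the true epoch's state: the epoch's own
  # one-vs-rest classifier assigns the epoch (posterior > 0.5)
  member <- vapply(seq_len(nrow(post)), function(i)
    if (truth[i] %in% epochs) post[i, truth[i]] > 0.5 else NA, logical(1))
  list(decision = decision, posteriors = post,
       correct_likelihood = correct, member = member)
}

#' Escape-fraction analysis across trials
#'
#' Fits one-vs-rest epoch classifiers at order `O` on the reference trials,
#' predicts per-bin epoch membership on the prediction trials, and runs
#' [escape_analysis()] with the reference-set kernel-PCA coordinates
#' defining the trapping regions.
#'
#' @inheritParams flow_convergence
#' @param k,rho escape parameters (see [escape_analysis()]).
#' @return An `escape_report`.
#' @export
escape_sweep <- function(dc, labels, ref_trials, pred_trials, O = 5,
                         eta = 0.05, k = 2L, rho = 1.5) {
  prep <- .fit_reference_space(dc, labels, ref_trials, O, eta)
  pr <- .predict_epochs(prep, prep$B)
  proj_pred <- project_kpca(prep$kpca,
                            poly_kernel(prep$B, prep$A, O = O))
  ref_coords <- lapply(split(seq_along(prep$lab_ref), prep$lab_ref),
                       function(i) prep$kpca$coords[i, , drop = FALSE])
  seg <- .contiguous_segments(dc$trial_ids[prep$pred_rows],
                              dc$bin_starts[prep$pred_rows],
                              dc$bin_width %||% 0.2)
  escape_analysis(prep$labels_pred, pr$member, seg, k = k,
                  coords = proj_pred, ref_coords = ref_coords, rho = rho)
}
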