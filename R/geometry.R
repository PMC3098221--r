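# Kernel-PCA projections, flow fields, likelihood-velocity convergence
# statistics, escape/trapping-region quantification, and
# correlation-dimension diagnostics.

#' Kernel principal component analysis
#'
#' Double-centers the training kernel matrix in feature space,
#' eigendecomposes it, and returns the top-`d` scores scaled so the score
#' variance of component `i` equals `lambda_i / m`.  For order-1 kernels
#' this reproduces conventional PCA scores up to sign.
#'
#' @param K symmetric training [poly_kernel()] matrix.
#' @param d number of components (default 3, for visualization and velocity
#'   fields).
#' @return A `kernel_projection`: `coords` (m x d scores),
#'   `explained_variance`, plus the eigenvectors/centering statistics needed
#'   for out-of-sample projection with [project_kpca()].
#' @export
kernel_pca <- function(K, d = 3L) {
  K <- unclass(K)
  m <- ncol(K)
  stopifnot(nrow(K) == m)
  cen <- .center_kernel(K)
  ev <- eigen(cen$Kc, symmetric = TRUE)
  pos <- which(ev$values > max(ev$values) * 1e-12)
  if (d > length(pos)) {
    warning("requested ", d, " components but rank is ", length(pos),
            "; truncating")
    d <- length(pos)
  }
  idx <- pos[seq_len(d)]
  lambda <- ev$values[idx]
  V <- ev$vectors[, idx, drop = FALSE]
  coords <- sweep(V, 2L, sqrt(lambda), `*`)
  structure(list(coords = coords,
                 explained_variance = lambda / sum(ev$values[pos]),
                 eigenvalues = lambda, vectors = V,
                 center = list(colmu = cen$colmu, mu = cen$mu)),
            class = "kernel_projection")
}

#' Project new vectors into a fitted kernel-PCA space
#'
#' @param p a [kernel_pca()] result.
#' @param K_cross kernel between new vectors (rows) and the training vectors
#'   (columns).
#' @return Matrix of out-of-sample scores.
#' @export
project_kpca <- function(p, K_cross) {
  K_cross <- unclass(K_cross)
  Kc <- .center_cross(K_cross, p$center$colmu, p$center$mu)
  Kc %*% sweep(p$vectors, 2L, sqrt(p$eigenvalues), `/`)
}

#' @export
print.kernel_projection <- function(x, ...) {
  cat("kernel_projection:", nrow(x$coords), "points x", ncol(x$coords),
      "components | var explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Flow field of a projected trajectory
#'
#' Velocity at bin `t` is the forward difference `coords(t+1) - coords(t)`;
#' pairs straddling a trial boundary are excluded.  Speeds are the vector
#' magnitudes, optionally normalized to `[0, 1]` across all vectors.
#'
#' @param coords T x d matrix of projected coordinates (or a
#'   `kernel_projection`).
#' @param trial_ids optional per-bin trial ids; consecutive-bin pairs are
#'   only formed within a trial.
#' @param bin_width bin width in seconds (metadata only).
#' @param normalize normalize speeds to `[0, 1]`; default TRUE.
#' @return A `flow_field`: `velocities`, `speeds`, `from_idx` (bin index of
#'   each velocity's origin), `bin_width`, `normalized`.
#' @export
velocity_field <- function(coords, trial_ids = NULL, bin_width = 0.2,
                           normalize = TRUE) {
  if (inherits(coords, "kernel_projection")) coords <- coords$coords
  coords <- as.matrix(coords)
  Tn <- nrow(coords)
  if (Tn < 2L)
    return(structure(list(velocities = coords[0, , drop = FALSE],
                          speeds = numeric(0), from_idx = integer(0),
                          bin_width = bin_width, normalized = normalize),
                     class = "flow_field"))
  if (is.null(trial_ids)) trial_ids <- rep("trial1", Tn)
  keep <- which(trial_ids[-Tn] == trial_ids[-1L])
  vel <- coords[keep + 1L, , drop = FALSE] - coords[keep, , drop = FALSE]
  speeds <- sqrt(rowSums(vel^2))
  if (normalize && length(speeds) && max(speeds) > 0)
    speeds <- speeds / max(speeds)
  structure(list(velocities = vel, speeds = speeds, from_idx = keep,
                 bin_width = bin_width, normalized = normalize),
            class = "flow_field")
}

#' Likelihood-velocity convergence curve
#'
#' Bins normalized speeds into `n_bins` equal-width bins, takes the mean log
#' correct-class likelihood per bin, and fits an ordinary least-squares line
#' through (bin center, mean log-likelihood).  A negative slope indicates
#' that the dynamics slows down where classification confidence is high,
#' i.e. near the putative attracting states.  The RMS fit error is reported
#' relative to the (log of the) geometric-mean likelihood.
#'
#' @param speeds per-vector speeds (from [velocity_field()]).
#' @param likelihoods per-vector correct-class likelihoods (out-of-sample
#'   Bayes classifier), aligned with `speeds`.
#' @param n_bins number of speed bins; default 20.
#' @param floor probability floor applied to the likelihoods before taking
#'   logs (default 1e-12, as in the KL discretization); Gaussian tail
#'   likelihoods decay quadratically in log and would otherwise hand single
#'   far-out vectors unbounded leverage over the bin means.
#' @return A `slope_fit`: `slope`, `intercept`, `bin_centers`, `bin_means`,
#'   `n_bins`, `rms_error` (relative), `slope_se`.
#' @export
likelihood_velocity_curve <- function(speeds, likelihoods, n_bins = 20L,
                                      floor = 1e-12) {
  stopifnot(length(speeds) == length(likelihoods))
  ok <- is.finite(speeds) & is.finite(likelihoods)
  speeds <- speeds[ok]; likelihoods <- pmax(likelihoods[ok], floor)
  rng <- range(speeds)
  if (diff(rng) <= 0) stop("speeds are constant; no curve to fit")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(speeds, edges,
                                            rightmost.closed = TRUE)))
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  means <- tapply(log(likelihoods), factor(bin, seq_len(n_bins)), mean)
  nonempty <- which(!is.na(means))
  if (length(nonempty) < length(means))
    message(length(means) - length(nonempty), " empty speed bin(s) dropped")
  if (length(nonempty) < 5L) stop("fewer than 5 nonempty speed bins")
  xx <- centers[nonempty]; yy <- as.numeric(means[nonempty])
  fit <- stats::lm(yy ~ xx)
  rms <- sqrt(mean(resid(fit)^2))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 slope_se = summary(fit)$coefficients[2L, 2L],
                 bin_centers = xx, bin_means = yy, bin_index = nonempty,
                 n_bins = n_bins, rms_error = rms / abs(mean(yy))),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope_fit: b = %.3f (SE %.3f) over %d bins | rel. RMS %.3f\n",
              x$slope, x$slope_se, length(x$bin_centers), x$rms_error))
  invisible(x)
}

#' Compare likelihood-velocity slopes against a surrogate
#'
#' Paired comparison across the shared speed bins: the per-bin differences
#' `original - surrogate` of mean log-likelihood are regressed on the bin
#' centers; the t statistic of that slope tests whether the original curve
#' falls off more steeply than the surrogate's.
#'
#' @param fit_orig,fit_surr two [likelihood_velocity_curve()] fits on the
#'   same binning.
#' @return List with `slope_diff`, `t`, `df`, `p_value` (one-sided, original
#'   steeper i.e. more negative).
#' @export
compare_slopes <- function(fit_orig, fit_surr) {
  if (fit_orig$n_bins != fit_surr$n_bins)
    stop("fits must share the same binning")
  common <- intersect(fit_orig$bin_index, fit_surr$bin_index)
  if (length(common) < 5L) stop("fewer than 5 shared bins")
  d <- fit_orig$bin_means[match(common, fit_orig$bin_index)] -
    fit_surr$bin_means[match(common, fit_surr$bin_index)]
  centers <- fit_orig$bin_centers[match(common, fit_orig$bin_index)]
  fit <- stats::lm(d ~ centers)
  sm <- summary(fit)$coefficients
  tval <- sm[2L, 1L] / sm[2L, 2L]
  df <- length(common) - 2L
  list(slope_diff = unname(sm[2L, 1L]), t = unname(tval), df = df,
       p_value = stats::pt(tval, df))
}

# Collapse non-member runs shorter than k into membership, then type the
# trajectory.  Returns one of "a", "b", "c", "escaped".
.type_trajectory <- function(member, k) {
  r <- rle(member)
  r$values[!r$values & r$lengths < k] <- TRUE
  m <- inverse.rle(r)
  r <- rle(m)
  v <- r$values
  if (all(v)) return("a")
  if (!any(v)) return("escaped")          # never converged
  if (!v[1] && length(v) == 2L) return("c")  # leading excursion only
  if (!v[length(v)]) return("escaped")    # left and never re-entered
  "b"                                      # left but re-entered
}

#' Escape-trajectory and trapping-region analysis
#'
#' A trajectory is a maximal run of consecutive bins sharing the same true
#' epoch label (within one trial); a bin is a *member* of the epoch state
#' when the full-space classifier assigns that epoch.  Trajectories are
#' typed: `a` confined (all bins members), `b` departing for at least `k`
#' consecutive non-member bins but re-entering, `c` starting outside and
#' converging into the state for good, `escaped` leaving without return
#' (including trajectories that never converge).  Optionally, escaped
#' trajectories are checked against a trapping region: a violation occurs
#' when any of their projected points lies farther from the epoch's
#' reference centroid than `rho` times the reference set's maximum member
#' distance.
#'
#' @param true_labels per-bin epoch labels (`"unlabeled"` bins separate
#'   trajectories).
#' @param predicted_labels per-bin classifier decisions in the full
#'   order-O space, or a logical vector of per-bin membership in the true
#'   epoch's state.
#' @param trial_ids per-bin trial ids.
#' @param k consecutive non-member bins counting as a departure; default 2.
#' @param coords optional per-bin projection coordinates for the trapping
#'   check.
#' @param ref_coords optional named list of reference-set coordinate
#'   matrices per epoch (members only).
#' @param rho trapping-radius multiplier; default 1.5.
#' @return An `escape_report`: per-epoch type counts, escape fractions (%),
#'   overall escape fraction, and trapping violations (% of escaped).
#' @export
escape_analysis <- function(true_labels, predicted_labels, trial_ids,
                            k = 2L, coords = NULL, ref_coords = NULL,
                            rho = 1.5) {
  stopifnot(length(true_labels) == length(predicted_labels),
            length(true_labels) == length(trial_ids))
  n <- length(true_labels)
  run_id <- cumsum(c(TRUE, true_labels[-1L] != true_labels[-n] |
                       trial_ids[-1L] != trial_ids[-n]))
  types <- list(); epochs_of <- character(0); viol <- logical(0)
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    ep <- true_labels[idx[1]]
    if (ep == "unlabeled") next
    member <- if (is.logical(predicted_labels)) {
      m <- predicted_labels[idx]
      m[is.na(m)] <- FALSE
      m
    } else predicted_labels[idx] == ep
    ty <- .type_trajectory(member, k)
    types[[length(types) + 1L]] <- ty
    epochs_of <- c(epochs_of, ep)
    v <- NA
    if (ty == "escaped" && !is.null(coords) && !is.null(ref_coords) &&
        ep %in% names(ref_coords)) {
      refc <- ref_coords[[ep]]
      ctr <- colMeans(refc)
      rmax <- max(sqrt(rowSums(sweep(refc, 2L, ctr)^2)))
      dd <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L, ctr)^2))
      v <- any(dd > rho * rmax)
    }
    viol <- c(viol, v)
  }
  if (!length(types)) stop("no labeled trajectories")
  types <- unlist(types)
  eps <- sort(unique(epochs_of))
  per_epoch <- do.call(rbind, lapply(eps, function(ep) {
    tt <- types[epochs_of == ep]
    data.frame(epoch = ep,
               a = sum(tt == "a"), b = sum(tt == "b"), c = sum(tt == "c"),
               escaped = sum(tt == "escaped"), n = length(tt),
               escape_fraction = 100 * mean(tt == "escaped"),
               stringsAsFactors = FALSE)
  }))
  esc <- types == "escaped"
  trap <- if (any(esc) && any(!is.na(viol[esc])))
    100 * mean(viol[esc], na.rm = TRUE) else NA_real_
  structure(list(per_epoch = per_epoch,
                 overall_escape_fraction = 100 * mean(esc),
                 trapping_violations = trap,
                 k = k, rho = rho),
            class = "escape_report")
}

#' @export
print.escape_report <- function(x, ...) {
  cat(sprintf("escape_report: %.1f%% escaped overall (k=%d)\n",
              x$overall_escape_fraction, x$k))
  print(x$per_epoch, row.names = FALSE)
  invisible(x)
}

#' Correlation dimension with temporal (Theiler) exclusion
#'
#' Computes the correlation sum `S(eps)` (fraction of point pairs within
#' `eps`, excluding pairs closer than `theiler_window` in time), estimates
#' `d2` as the slope of `log S` vs `log eps` over an automatically selected
#' scaling region (longest window of at least half a decade maximizing the
#' linear-fit R^2), cross-checks with the Takens maximum-likelihood
#' estimator, and derives the minimum temporal exclusion `b_min` from a
#' time-space separation criterion (variation of `S(eps)` across temporal
#' separations below 5% for all `eps`).
#'
#' @param x point-set matrix (N x d) or `kernel_projection`.
#' @param theiler_window minimum temporal separation of counted pairs;
#'   default taken from the `b_min` estimate.
#' @param n_eps number of radius values (log-spaced); default 40.
#' @return A `corrdim_result`: `epsilons`, `correlation_sums`, `d2_slope`,
#'   `takens_ml_d2`, `b_min`, `embedding_dim_needed`, `scaling_region`,
#'   `reliable`.
#' @export
correlation_dimension <- function(x, theiler_window = NULL, n_eps = 40L) {
  if (inherits(x, "kernel_projection")) x <- x$coords
  x <- as.matrix(x)
  N <- nrow(x)
  if (N < 200L) stop("need >= 200 points")
  D <- as.matrix(stats::dist(x))
  sep <- abs(outer(seq_len(N), seq_len(N), `-`))
  upper <- upper.tri(D)
  dpos <- D[upper & D > 0]
  eps <- exp(seq(log(stats::quantile(dpos, 0.01)),
                 log(max(dpos)), length.out = n_eps))

  S_at <- function(w) {
    keep <- upper & sep > w
    dd <- D[keep]
    vapply(eps, function(e) mean(dd <= e), numeric(1))
  }

  # time-space separation: smallest exclusion beyond which S(eps) is stable
  w_grid <- unique(pmin(N - 2L, c(0L, 1L, 2L, 4L, 8L, 16L, 32L)))
  S_ref <- S_at(max(w_grid))
  b_min <- max(w_grid)
  for (w in w_grid) {
    Sw <- S_at(w)
    ok <- S_ref > 0
    if (all(abs(Sw[ok] - S_ref[ok]) / S_ref[ok] < 0.05)) { b_min <- w; break }
  }
  w <- theiler_window %||% b_min
  S <- S_at(w)

  # scaling region: longest contiguous log-eps window (>= half a decade)
  # maximizing linear R^2
  ok <- which(S > 0)
  le <- log(eps[ok]); lS <- log(S[ok])
  best <- NULL; best_r2 <- -Inf
  half_decade <- log(10) / 2
  for (i in seq_along(le)) for (j in seq_along(le)) {
    if (j - i < 4L || le[j] - le[i] < half_decade) next
    seg <- i:j
    f <- stats::lm(lS[seg] ~ le[seg])
    r2 <- summary(f)$r.squared
    span_bonus <- 1e-6 * (le[j] - le[i])   # prefer longer regions on ties
    if (r2 + span_bonus > best_r2) { best_r2 <- r2 + span_bonus; best <- seg }
  }
  reliable <- !is.null(best) && best_r2 > 0.98
  if (is.null(best)) {
    warning("no scaling region detected; result flagged unreliable")
    best <- seq_along(le)
  }
  f <- stats::lm(lS[best] ~ le[best])
  d2 <- unname(coef(f)[2L])

  # Takens ML estimator over eps <= upper end of the scaling region
  eps_max <- eps[ok][max(best)]
  keep <- upper & sep > w
  dd <- D[keep]
  dd <- dd[dd > 0 & dd < eps_max]
  takens <- if (length(dd)) -length(dd) / sum(log(dd / eps_max)) else NA_real_

  structure(list(epsilons = eps, correlation_sums = S,
                 d2_slope = d2, takens_ml_d2 = takens,
                 b_min = b_min, theiler_window = w,
                 embedding_dim_needed = ceiling(2 * d2 + 1),
                 scaling_region = range(eps[ok][best]),
                 reliable = reliable),
            class = "corrdim_result")
}

#' @export
print.corrdim_result <- function(x, ...) {
  cat(sprintf(
    "corrdim_result: d2 = %.2f (Takens %.2f) | b_min = %d | 2D+1 = %d%s\n",
    x$d2_slope, x$takens_ml_d2, x$b_min, x$embedding_dim_needed,
    if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}
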