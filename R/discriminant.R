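# Regularized kernel Fisher discriminant analysis, Gaussian Bayes
# classification on the discriminant axis, segregation error (SE), predicted
# SE across trials, and epoch Kullback-Leibler divergence.

# Double-center a training kernel matrix in feature space and return the
# statistics needed to center cross-kernels consistently.
.center_kernel <- function(K) {
  m <- ncol(K)
  colmu <- colMeans(K)
  mu <- mean(K)
  Kc <- sweep(sweep(K, 2L, colmu), 1L, rowMeans(K)) + mu
  list(Kc = Kc, colmu = colmu, mu = mu)
}

# Center a cross-kernel K2 (new x train) with training statistics.
.center_cross <- function(K2, colmu, mu) {
  sweep(K2, 2L, colmu) - (rowMeans(K2) - mu)
}

#' Fit a regularized kernel Fisher discriminant
#'
#' Solves the Fisher criterion in its dual (kernel) form: feature-space
#' centering of the kernel matrix, between-class and within-class scatter
#' operators built from class-wise kernel means, and a ridge `eta * mean(K)`
#' added to the within-class scatter (the penalty is expressed as a fraction
#' of the mean kernel value).  For two classes with `n_components = 1` the
#' direction is the classical closed-form solution; the general path solves
#' the generalized eigenproblem for multi-class 2-3D visualization solves.
#' Class-conditional Gaussians (per-class mean and SD, unequal variances)
#' are fitted to the training projections on the first component.
#'
#' @param K training [poly_kernel()] matrix (m x m).
#' @param labels class label per training vector (2 or more classes).
#' @param eta regularization penalty as a fraction of `mean(K)`; default
#'   0.05 (well inside the flat plateau of out-of-sample error).
#' @param n_components number of discriminant directions (1 for pairwise
#'   classification, 3 for visualization).
#' @param priors per-class prior probabilities; default equal (0.5/0.5 for a
#'   pair) so that results are not biased towards longer epochs.
#' @param equal_variance fit a single pooled SD for all classes instead of
#'   per-class SDs (useful when one "class" is a heterogeneous rest
#'   mixture, e.g. in one-vs-rest membership classifiers).
#' @return A `kfda_model`.
#' @export
fit_kfda <- function(K, labels, eta = 0.05, n_components = 1L,
                     priors = NULL, equal_variance = FALSE) {
  K <- unclass(K)
  m <- ncol(K)
  stopifnot(nrow(K) == m, length(labels) == m, eta >= 0)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  cnt <- table(factor(labels, classes))
  if (any(cnt < 2L)) stop("need >= 2 vectors per class")
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  names(priors) <- classes

  cen <- .center_kernel(K)
  Kc <- cen$Kc
  Mstar <- rowMeans(Kc)
  Mc <- vapply(classes, function(cl)
    rowMeans(Kc[, labels == cl, drop = FALSE]), numeric(m))
  # within-class scatter N = sum_c Kc_c Kc_c' - m_c M_c M_c'
  N <- matrix(0, m, m)
  for (cl in classes) {
    Kci <- Kc[, labels == cl, drop = FALSE]
    N <- N + tcrossprod(Kci) - as.numeric(cnt[cl]) * tcrossprod(Mc[, cl])
  }
  # Ridge scaled to the scatter's own spectrum (eta as a fraction of the
  # mean eigenvalue tr(N)/m); a penalty tied to the raw kernel scale has no
  # leverage on N, whose entries grow like m * K^2, and would let the
  # discriminant interpolate the training set at high expansion orders.
  reg <- eta * sum(diag(N)) / m
  if (reg <= 0 && eta > 0) reg <- eta * 1e-8
  diag(N) <- diag(N) + max(reg, 1e-12 * sum(diag(N)) / m)

  alpha <- if (length(classes) == 2L && n_components == 1L) {
    a <- tryCatch(solve(N, Mc[, 1L] - Mc[, 2L]),
                  error = function(e)
                    stop("singular within-class system; increase eta"))
    matrix(a, ncol = 1L)
  } else {
    B <- matrix(0, m, m)
    for (cl in classes) {
      d <- Mc[, cl] - Mstar
      B <- B + as.numeric(cnt[cl]) * tcrossprod(d)
    }
    W <- tryCatch(solve(N, B),
                  error = function(e)
                    stop("singular within-class system; increase eta"))
    ev <- eigen(W)
    q <- min(n_components, length(classes) - 1L, m)
    matrix(Re(ev$vectors[, seq_len(q), drop = FALSE]), nrow = m)
  }
  # scale each direction so training projections have unit pooled SD
  proj <- Kc %*% alpha
  for (j in seq_len(ncol(alpha))) {
    s <- sd(proj[, j])
    if (s > 0) { alpha[, j] <- alpha[, j] / s; proj[, j] <- proj[, j] / s }
  }
  x1 <- proj[, 1L]
  class_stats <- t(vapply(classes, function(cl)
    c(mean = mean(x1[labels == cl]), sd = sd(x1[labels == cl])),
    numeric(2)))
  if (equal_variance)
    class_stats[, "sd"] <- sqrt(mean(class_stats[, "sd"]^2))
  if (any(class_stats[, "sd"] <= 0))
    stop("degenerate class SD on the discriminant axis")

  structure(list(alpha = alpha, eta = eta, reg = reg,
                 classes = classes, priors = priors,
                 class_stats = class_stats,
                 train_labels = labels,
                 projections = proj,
                 center = list(colmu = cen$colmu, mu = cen$mu),
                 mean_K = mean(K)),
            class = "kfda_model")
}

#' @export
print.kfda_model <- function(x, ...) {
  cat("kfda_model:", length(x$train_labels), "training vectors |",
      "classes:", paste(x$classes, collapse = " vs "),
      "| eta =", x$eta, "\n")
  invisible(x)
}

#' Gaussian Bayes classification of discriminant-axis projections
#'
#' The classification core used by [classify()]: class-conditional Gaussian
#' likelihoods, posteriors under the given priors, and argmax labels for
#' 1-D projections.  Exposed so that the classifier can be checked directly
#' against closed-form normal error rates.
#'
#' @param x numeric vector of projections.
#' @param class_stats matrix with rownames = classes and columns `mean`,
#'   `sd`.
#' @param priors named per-class prior probabilities.
#' @return List with `likelihoods`, `posteriors` (rows sum to 1) and
#'   `predicted` labels (ties go to the first class).
#' @export
bayes_classify_projections <- function(x, class_stats, priors) {
  classes <- rownames(class_stats)
  lik <- vapply(classes, function(cl)
    stats::dnorm(x, class_stats[cl, "mean"], class_stats[cl, "sd"]),
    numeric(length(x)))
  lik <- matrix(lik, ncol = length(classes),
                dimnames = list(NULL, classes))
  joint <- sweep(lik, 2L, priors[classes], `*`)
  post <- joint / pmax(rowSums(joint), .Machine$double.xmin)
  pred <- classes[max.col(post, ties.method = "first")]
  list(likelihoods = lik, posteriors = post, predicted = pred)
}

#' Classify vectors with a fitted discriminant model
#'
#' Projects vectors onto the frozen discriminant axis via the cross-kernel
#' (`x(t_i) = sum_j alpha_j k(nu(t_j), nu(t_i))`, after feature-space
#' centering with the training statistics), evaluates class-conditional
#' Gaussian likelihoods, posteriors under the model priors, and the argmax
#' label (ties go to the first class).  When true labels are supplied the
#' segregation error SE (fraction misclassified) is reported.
#'
#' @param model a [fit_kfda()] model.
#' @param K_new cross-kernel, rows = new vectors, columns = training
#'   vectors.
#' @param labels optional true labels of the new vectors.
#' @return A `classifier_result`: projections, likelihoods, posteriors,
#'   predicted labels and `se`.
#' @export
classify <- function(model, K_new, labels = NULL) {
  K_new <- unclass(K_new)
  if (is.null(dim(K_new))) K_new <- matrix(K_new, nrow = 1L)
  if (ncol(K_new) != length(model$train_labels))
    stop("cross-kernel columns must index the training vectors")
  Kc <- .center_cross(K_new, model$center$colmu, model$center$mu)
  proj <- Kc %*% model$alpha
  bc <- bayes_classify_projections(proj[, 1L], model$class_stats,
                                   model$priors)
  se <- NA_real_
  if (!is.null(labels)) {
    keep <- labels %in% model$classes
    se <- mean(bc$predicted[keep] != labels[keep])
  }
  structure(list(projections = proj, likelihoods = bc$likelihoods,
                 posteriors = bc$posteriors, predicted_labels = bc$predicted,
                 se = se),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat("classifier_result:", nrow(x$posteriors), "vectors | SE =",
      if (is.na(x$se)) "NA" else sprintf("%.3f", x$se), "\n")
  invisible(x)
}

#' Out-of-sample predicted segregation error
#'
#' Projects prediction-set vectors into the reference-trial discriminant
#' space with the frozen dual coefficients and frozen class Gaussians, and
#' returns the predicted SE.  Reference and prediction sets must be
#' disjoint; when both kernels carry time indices (attribute `row_idx` /
#' training indices stored in the model via `ref_idx`) the overlap is
#' checked.
#'
#' @param ref_model [fit_kfda()] model fitted exclusively on reference
#'   trials.
#' @param K_cross kernel between prediction vectors (rows) and reference
#'   vectors (columns).
#' @param pred_labels true epoch labels of the prediction vectors.
#' @param ref_idx,pred_idx optional global time indices of the reference and
#'   prediction vectors, used to enforce disjointness.
#' @return A `classifier_result` with `se` = SE_predic.
#' @export
se_predic <- function(ref_model, K_cross, pred_labels,
                      ref_idx = NULL, pred_idx = NULL) {
  if (!is.null(ref_idx) && !is.null(pred_idx) &&
      length(intersect(ref_idx, pred_idx)))
    stop("sets must be disjoint")
  classify(ref_model, K_cross, labels = pred_labels)
}

#' Discretized Kullback-Leibler divergence between epoch Gaussians
#'
#' KL divergence between the two fitted class-conditional Gaussians on the
#' discriminant axis, discretized on a grid spanning +/- 6 pooled SD around
#' the grand mean (1000 cells, probability floor 1e-12, renormalized).
#' Direction is class 1 -> class 2; `symmetric = TRUE` averages both
#' directions.
#'
#' @param model a two-class [fit_kfda()] model.
#' @param n_cells grid resolution; default 1000.
#' @param symmetric report the symmetrized average.
#' @return A `kl_result` with fields `kl` and `grid`.
#' @export
kl_divergence <- function(model, n_cells = 1000L, symmetric = FALSE) {
  cs <- model$class_stats
  if (nrow(cs) != 2L) stop("kl_divergence needs a two-class model")
  if (any(cs[, "sd"] <= 0)) stop("degenerate class SD")
  pooled <- sqrt(mean(cs[, "sd"]^2))
  # span must cover both class supports even when the means are far apart,
  # otherwise both discretized densities collapse onto the floor
  lo <- min(cs[, "mean"]) - 6 * pooled
  hi <- max(cs[, "mean"]) + 6 * pooled
  edges <- seq(lo, hi, length.out = n_cells + 1L)
  cellp <- function(mu, s) {
    p <- diff(stats::pnorm(edges, mu, s))
    p <- pmax(p, 1e-12)
    p / sum(p)
  }
  p <- cellp(cs[1L, "mean"], cs[1L, "sd"])
  q <- cellp(cs[2L, "mean"], cs[2L, "sd"])
  kl12 <- sum(p * log(p / q))
  kl <- if (symmetric) (kl12 + sum(q * log(q / p))) / 2 else kl12
  structure(list(kl = kl,
                 grid = list(lo = lo, hi = hi, n_cells = n_cells),
                 symmetric = symmetric),
            class = "kl_result")
}

# Rescale state vectors by the mean L2 norm of the reference rows so that
# kernel entries stay O(1)-conditioned at high expansion orders.
.vector_scale <- function(x, ref_rows) {
  nrm <- sqrt(rowSums(x[ref_rows, , drop = FALSE]^2))
  s <- mean(nrm)
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Pairwise epoch discrimination sweep across expansion orders
#'
#' For every pair of task epochs and every order in `O_list`, fits the
#' regularized kernel-FDA on the reference trials and evaluates the
#' predicted SE on the disjoint prediction trials (forward direction), and
#' vice versa (backward).  Per epoch, reference and prediction series are
#' truncated to equal length; reward epochs can be excluded (too few data
#' points).  State vectors are rescaled by the mean reference-vector norm
#' before kernel evaluation (numerical conditioning at high O).
#'
#' @param x a `dc_matrix` (or [rate_matrix]) of state vectors.
#' @param timeline [build_epoch_timeline()] result aligned with the parent
#'   rate matrix (for a `dc_matrix` the mapping uses its `keep_idx`).
#' @param ref_trials,pred_trials disjoint trial-id sets.
#' @param O_list expansion orders to sweep, e.g. `c(1, 2, 3, 5, 7)`.
#' @param eta regularization fraction; default 0.05.
#' @param exclude_rewards drop reward epochs from the pairing; default TRUE.
#' @param min_per_class minimum vectors per class; default 10.
#' @param max_per_class optional cap on vectors per class (first `n` bins);
#'   default `Inf`.
#' @param directions subset of `c("forward", "backward")`.
#' @return A data frame with one row per (epoch pair, O, direction):
#'   `epoch_pair, O, direction, SE, SE_predic, KL, n_ref, n_pred`.
#' @export
pairwise_epoch_sweep <- function(x, timeline, ref_trials, pred_trials,
                                 O_list = c(1, 2, 3, 5, 7), eta = 0.05,
                                 exclude_rewards = TRUE,
                                 min_per_class = 10L, max_per_class = Inf,
                                 directions = c("forward", "backward")) {
  if (length(intersect(ref_trials, pred_trials)))
    stop("sets must be disjoint")
  labels <- if (inherits(x, "dc_matrix"))
    timeline$labels[x$keep_idx] else timeline$labels
  vals <- x$values
  tids <- x$trial_ids
  stopifnot(length(labels) == nrow(vals))

  epochs <- setdiff(unique(labels), "unlabeled")
  if (exclude_rewards) epochs <- epochs[!grepl("reward", epochs)]
  epochs <- sort(epochs)
  if (length(epochs) < 2L) stop("no eligible epoch pairs")

  take <- function(trials, ep, n_cap) {
    idx <- which(tids %in% trials & labels == ep)
    utils::head(idx, n_cap)
  }
  out <- list()
  for (i in seq_len(length(epochs) - 1L)) for (j in (i + 1L):length(epochs)) {
    e1 <- epochs[i]; e2 <- epochs[j]
    # equal-length truncation per epoch between the two sets
    sets <- lapply(c(e1, e2), function(ep) {
      r <- which(tids %in% ref_trials & labels == ep)
      p <- which(tids %in% pred_trials & labels == ep)
      n <- min(length(r), length(p), max_per_class)
      list(ref = utils::head(r, n), pred = utils::head(p, n))
    })
    ref_idx <- c(sets[[1]]$ref, sets[[2]]$ref)
    pred_idx <- c(sets[[1]]$pred, sets[[2]]$pred)
    if (min(lengths(lapply(sets, `[[`, "ref"))) < min_per_class) next
    for (dir in directions) {
      fit_idx <- if (dir == "forward") ref_idx else pred_idx
      eval_idx <- if (dir == "forward") pred_idx else ref_idx
      sc <- .vector_scale(vals, fit_idx)
      A <- vals[fit_idx, , drop = FALSE] / sc
      B <- vals[eval_idx, , drop = FALSE] / sc
      for (O in O_list) {
        K <- poly_kernel(A, O = O)
        model <- fit_kfda(K, labels[fit_idx], eta = eta)
        cr_in <- classify(model, K, labels = labels[fit_idx])
        Kx <- poly_kernel(B, A, O = O)
        cr_out <- se_predic(model, Kx, labels[eval_idx],
                            ref_idx = fit_idx, pred_idx = eval_idx)
        klr <- kl_divergence(model)
        out[[length(out) + 1L]] <- data.frame(
          epoch_pair = paste(e1, e2, sep = ":"), O = O, direction = dir,
          SE = cr_in$se, SE_predic = cr_out$se, KL = klr$kl,
          n_ref = length(fit_idx), n_pred = length(eval_idx),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) stop("no eligible epoch pairs")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a sweep table across epoch pairs
#'
#' @param sweep result of [pairwise_epoch_sweep()].
#' @return Data frame of mean and SEM of `SE_predic` (and `SE`, `KL`) per
#'   order and direction.
#' @export
summarize_sweep <- function(sweep) {
  agg <- function(v) c(mean = mean(v), sem = sd(v) / sqrt(length(v)))
  sp <- split(sweep, list(sweep$O, sweep$direction), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(s) {
    a <- agg(s$SE_predic)
    data.frame(O = s$O[1], direction = s$direction[1],
               SE_predic_mean = a["mean"], SE_predic_sem = a["sem"],
               SE_mean = mean(s$SE), KL_mean = mean(s$KL),
               n_pairs = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$direction, out$O), ]
}
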