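# Delay-coordinate augmentation of the population rate space and the
# polynomial-kernel representation of its multinomial expansion.

#' Select one delay per unit from average cross-correlations
#'
#' For each unit i the average over partner units j != i of the absolute
#' Pearson cross-correlation `|cor(nu_i(t), nu_j(t - tau))|` is scanned over
#' lags `tau = 0..L_max`, where `L_max = floor(max_lag_frac * shortest
#' task-phase length in bins)` (phase length = total bins carrying a given
#' epoch label).  The lag chosen is the smallest interior local minimum of
#' the average curve; if none exists the lag defaults to 1 bin.
#'
#' @param r a [rate_matrix].
#' @param timeline an [build_epoch_timeline()] result aligned with `r`.
#' @param max_lag_frac cap on lags relative to the shortest phase; default
#'   0.05.
#' @return A `delay_spec`: list with `lags` (named, in bins) and `max_lag`.
#' @export
select_delays <- function(r, timeline, max_lag_frac = 0.05) {
  x <- r$values
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 units for delay selection")
  lab <- timeline$labels
  per_label <- table(lab[lab != "unlabeled"])
  if (!length(per_label)) stop("phases too short for delay selection")
  L_max <- floor(max_lag_frac * min(per_label))
  if (L_max < 1L) stop("phases too short for delay selection")
  Tn <- nrow(x)
  if (L_max + 1L >= Tn) stop("phases too short for delay selection")

  xc <- function(i, j, tau) {
    a <- x[(1L + tau):Tn, i]; b <- x[1L:(Tn - tau), j]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    abs(stats::cor(a, b))
  }
  lags <- integer(n)
  for (i in seq_len(n)) {
    avg <- vapply(0:L_max, function(tau)
      mean(vapply(setdiff(seq_len(n), i), function(j) xc(i, j, tau),
                  numeric(1))), numeric(1))
    tau_i <- 1L
    if (L_max >= 2L) {
      for (tau in 1:(L_max - 1L)) {
        if (avg[tau + 1L] < avg[tau] && avg[tau + 1L] < avg[tau + 2L]) {
          tau_i <- tau; break
        }
      }
    }
    lags[i] <- tau_i
  }
  names(lags) <- colnames(x)
  structure(list(lags = lags, max_lag = L_max,
                 max_lag_frac = max_lag_frac),
            class = "delay_spec")
}

#' Build the delay-coordinate state matrix
#'
#' Row `t` is `(nu_1(t), ..., nu_n(t), nu_1(t - tau_1), ..., nu_n(t -
#' tau_n))`; the leading `max(tau)` bins of each trial, which lack history,
#' are dropped.  `keep_idx` maps retained rows back into the parent rate
#' matrix so epoch labels can be carried over.
#'
#' @param r a [rate_matrix].
#' @param d a `delay_spec` from [select_delays()], or a named/plain integer
#'   vector of per-unit lags (bins, all >= 1).
#' @return A `dc_matrix`: list with `values` (T' x 2n), `lags`, `keep_idx`,
#'   `trial_ids`, `bin_starts`, `unit_ids` (base then lagged).
#' @export
build_dc_msua <- function(r, d) {
  lags <- if (inherits(d, "delay_spec")) d$lags else as.integer(d)
  n <- ncol(r$values)
  if (length(lags) != n) stop("need one lag per unit")
  if (any(lags < 1L)) stop("lags must be >= 1 bin")
  rows <- list(); kept <- list()
  max_lag <- max(lags)
  for (tid in unique(r$trial_ids)) {
    idx <- which(r$trial_ids == tid)
    if (max_lag >= length(idx)) stop("lag >= trial length for trial ", tid)
    tt <- idx[(max_lag + 1L):length(idx)]
    lagged <- vapply(seq_len(n), function(i)
      r$values[tt - lags[i], i], numeric(length(tt)))
    rows[[length(rows) + 1L]] <-
      cbind(r$values[tt, , drop = FALSE],
            matrix(lagged, nrow = length(tt)))
    kept[[length(kept) + 1L]] <- tt
  }
  keep_idx <- unlist(kept)
  vals <- do.call(rbind, rows)
  colnames(vals) <- c(r$unit_ids, paste0(r$unit_ids, "_lag"))
  structure(list(values = vals, lags = lags, keep_idx = keep_idx,
                 trial_ids = r$trial_ids[keep_idx],
                 bin_starts = r$bin_starts[keep_idx],
                 bin_width = r$bin_width,
                 unit_ids = colnames(vals)),
            class = "dc_matrix")
}

#' Dimensionality of the order-O multinomial expansion
#'
#' Number of monomials of total degree 1..O with repetition over `base_dim`
#' variables: `choose(base_dim + O, O) - 1`.
#'
#' @param base_dim number of base variables (2n for a delay-coordinate
#'   space).
#' @param order expansion order O >= 1.
#' @return An `expansion_spec` with fields `order`, `base_dim`,
#'   `ambient_dim`.
#' @export
expansion_spec <- function(base_dim, order) {
  stopifnot(base_dim >= 1L, order >= 1L)
  structure(list(order = as.integer(order), base_dim = as.integer(base_dim),
                 ambient_dim = choose(base_dim + order, order) - 1),
            class = "expansion_spec")
}

# graded-lexicographic enumeration of exponent vectors with |a| = k over d
# variables (lexicographic within a degree)
.compositions <- function(k, d) {
  if (d == 1L) return(matrix(k, 1L, 1L))
  out <- list()
  for (first in k:0) {
    rest <- .compositions(k - first, d - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Explicit feature map of the polynomial expansion (oracle path)
#'
#' Returns all monomials `x^a` of total degree 1..O in graded-lexicographic
#' order, each scaled by `sqrt(choose(O, |a|) * multinomial(|a|; a))`, so
#' that dot products of outputs equal [poly_kernel()] values exactly.
#' Guarded to small problems (`base_dim <= 12`, `O <= 4`); larger spaces are
#' only accessed implicitly through the kernel.
#'
#' @param x numeric vector of base variables.
#' @param spec an [expansion_spec()].
#' @return Numeric vector of length `spec$ambient_dim`.
#' @export
explicit_expand <- function(x, spec) {
  stopifnot(inherits(spec, "expansion_spec"), length(x) == spec$base_dim)
  if (spec$base_dim > 12L || spec$order > 4L)
    stop("explicit expansion guarded to base_dim <= 12, O <= 4; ",
         "use poly_kernel for larger spaces")
  O <- spec$order
  feats <- numeric(0)
  for (k in 1:O) {
    expo <- .compositions(k, spec$base_dim)
    w <- sqrt(choose(O, k) * exp(lfactorial(k) -
                                   rowSums(lfactorial(expo))))
    mono <- apply(expo, 1L, function(a) prod(x^a))
    feats <- c(feats, w * as.numeric(mono))
  }
  feats
}

#' Polynomial kernel of the order-O expansion
#'
#' `k(x, y) = (1 + x . y)^O - 1`, evaluated entrywise between the rows of
#' `a` and `b`.  For `O = 1` this is the plain dot product (Gram matrix).
#' The implied feature space is exactly the degree-1..O monomial expansion
#' with square-root multinomial weights (see [explicit_expand()]).
#'
#' @param a matrix (rows = vectors) or single vector.
#' @param b matrix or vector sharing `a`'s base dimension; default `a`.
#' @param O expansion order, integer >= 1.
#' @return A `kernel_matrix`: numeric matrix with attributes `order`.
#' @export
poly_kernel <- function(a, b = NULL, O = 1L) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(b)) b <- a else if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (ncol(a) != ncol(b)) stop("a and b must share base dimension")
  if (O < 1L) stop("O must be >= 1")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite inputs to poly_kernel")
  K <- (1 + tcrossprod(a, b))^O - 1
  structure(K, order = as.integer(O), class = c("kernel_matrix", "matrix"))
}
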