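# Reference validation protocols run by the acceptance script and the test
# suite.

#' Held-out segregation error on label-uninformative data
#'
#' The chance-level protocol: a stationary homogeneous-Poisson ensemble
#' (zero loading, so epoch structure is absent by construction) is binned
#' into population vectors, split into two arbitrary "classes", and the
#' regularized kernel-FDA Bayes classifier (equal priors) is fitted on half
#' the vectors and evaluated on the held-out half.  Since the labels carry
#' no information, held-out SE should average 50%.
#'
#' @param seeds integer vector of replicate seeds (default `1:20`).
#' @param n_units ensemble size; default 20.
#' @param per_class vectors per class; default 400.
#' @param O expansion order; default 5.
#' @param eta regularization fraction; default 0.05.
#' @return Numeric vector of held-out SE values (one per seed), fractions
#'   in `[0, 1]`.
#' @export
chance_level_se <- function(seeds = 1:20, n_units = 20L, per_class = 400L,
                            O = 5, eta = 0.05) {
  vapply(seeds, function(s) {
    dur <- ceiling(2 * per_class * 0.2) + 2
    p <- synth_params(n_units = n_units, n_trials = 1L,
                      epoch_schedule = data.frame(label = "unlabeled",
                                                  duration = dur),
                      loading = matrix(0, n_units, 3L),
                      seed = s)
    d <- generate_dataset(p)
    r <- estimate_rates(d$spikes)
    T2 <- 2L * per_class
    X <- r$values[seq_len(T2), , drop = FALSE]
    set.seed(s + 10000L)
    lab <- sample(rep(c("A", "B"), per_class))
    train <- seq(1L, T2, by = 2L)
    test <- setdiff(seq_len(T2), train)
    sc <- .vector_scale(X, train)
    A <- X[train, , drop = FALSE] / sc
    B <- X[test, , drop = FALSE] / sc
    model <- fit_kfda(poly_kernel(A, O = O), lab[train], eta = eta)
    classify(model, poly_kernel(B, A, O = O), labels = lab[test])$se
  }, numeric(1))
}
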