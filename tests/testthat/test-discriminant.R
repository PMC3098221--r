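# Two-class toy set in 2-D with controllable separation.
toy_classes <- function(n = 100, sep = 4, sd = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0, sd), n),
             matrix(rnorm(2 * n, sep / sqrt(2), sd), n))
  list(X = X, labels = rep(c("A", "B"), each = n))
}

test_that("kernel FDA separates separable classes and matches the primal
           solution at O = 1", {
  # widely separated 1-D classes: training SE below 1%
  set.seed(2)
  x <- matrix(c(rnorm(50, -5, 0.1), rnorm(50, 5, 0.1)), ncol = 1)
  lab <- rep(c("A", "B"), each = 50)
  K <- poly_kernel(x, O = 1)
  m <- fit_kfda(K, lab, eta = 0.01)
  expect_lt(classify(m, K, labels = lab)$se, 0.01)

  # O = 1 kernel solution vs explicit-space regularized Fisher discriminant
  tc <- toy_classes(n = 80, sep = 3)
  Xc <- scale(tc$X, scale = FALSE)
  Sw <- crossprod(Xc[tc$labels == "A", , drop = FALSE] |> scale(scale = FALSE)) +
    crossprod(Xc[tc$labels == "B", , drop = FALSE] |> scale(scale = FALSE))
  w <- solve(Sw + 1e-6 * diag(2),
             colMeans(Xc[tc$labels == "A", ]) -
               colMeans(Xc[tc$labels == "B", ]))
  proj_primal <- as.numeric(Xc %*% w)
  mk <- fit_kfda(poly_kernel(tc$X, O = 1), tc$labels, eta = 0.01)
  expect_gt(abs(cor(proj_primal, mk$projections[, 1])), 0.999)

  # identical class distributions: no spurious separation on held-out data
  tc0 <- toy_classes(n = 200, sep = 0, seed = 3)
  train <- c(1:100, 201:300); test <- setdiff(1:400, train)
  m0 <- fit_kfda(poly_kernel(tc0$X[train, ], O = 1), tc0$labels[train])
  pr <- classify(m0, poly_kernel(tc0$X[test, ], tc0$X[train, ], O = 1))
  d <- abs(mean(pr$projections[tc0$labels[test] == "A", 1]) -
             mean(pr$projections[tc0$labels[test] == "B", 1]))
  expect_lt(d / sd(pr$projections[, 1]), 0.5)

  expect_error(fit_kfda(poly_kernel(x, O = 1), rep("A", 100)), "2 classes")
})

test_that("Bayes classifier on the axis reproduces closed-form normal
           error rates and equal priors", {
  # N(0,1) vs N(2,1), priors 0.5: Bayes error = pnorm(-1) ~ 0.1587
  set.seed(6)
  n <- 1e5
  x <- c(rnorm(n / 2, 0, 1), rnorm(n / 2, 2, 1))
  truth <- rep(c("A", "B"), each = n / 2)
  cs <- rbind(A = c(mean = 0, sd = 1), B = c(mean = 2, sd = 1))
  colnames(cs) <- c("mean", "sd")
  bc <- bayes_classify_projections(x, cs, c(A = 0.5, B = 0.5))
  expect_equal(mean(bc$predicted != truth), pnorm(-1), tolerance = 0.01)
  # posteriors sum to one
  expect_equal(rowSums(bc$posteriors), rep(1, n), tolerance = 1e-12)
  # a point at the class-1 mean is assigned to class 1
  one <- bayes_classify_projections(0, cs, c(A = 0.5, B = 0.5))
  expect_gt(one$posteriors[1, "A"], 0.5)

  # priors stay 0.5 regardless of class sizes
  set.seed(7)
  X <- matrix(c(rnorm(150, -2), rnorm(30, 2)), ncol = 1)
  lab <- rep(c("A", "B"), c(150, 30))
  m <- fit_kfda(poly_kernel(X, O = 1), lab)
  expect_equal(unname(m$priors), c(0.5, 0.5))
})

test_that("cross-trial prediction uses frozen directions and detects nulls", {
  tc <- toy_classes(n = 300, sep = 2.5, seed = 8)
  ref <- c(1:150, 301:450); pred <- setdiff(1:600, ref)
  K <- poly_kernel(tc$X[ref, ], O = 2)
  m <- fit_kfda(K, tc$labels[ref])
  se_in <- classify(m, K, labels = tc$labels[ref])$se
  Kx <- poly_kernel(tc$X[pred, ], tc$X[ref, ], O = 2)
  # exchangeable prediction set: SE_predic ~ training SE
  out <- se_predic(m, Kx, tc$labels[pred], ref_idx = ref, pred_idx = pred)
  expect_lt(abs(out$se - se_in), 0.05)
  # permuted labels: SE_predic ~ chance (50%)
  set.seed(9)
  out_perm <- se_predic(m, Kx, sample(tc$labels[pred]))
  expect_lt(abs(out_perm$se - 0.5), 0.06)
  # disjointness is enforced
  expect_error(se_predic(m, Kx, tc$labels[pred],
                         ref_idx = ref, pred_idx = ref[1]),
               "disjoint")

  # normal-oracle SE_predic: two unit-variance classes 2 apart -> 0.1587
  tcn <- toy_classes(n = 2000, sep = 2, sd = 1, seed = 10)
  ref2 <- c(1:1000, 2001:3000); pred2 <- setdiff(1:4000, ref2)
  mn <- fit_kfda(poly_kernel(tcn$X[ref2, ], O = 1), tcn$labels[ref2])
  on <- se_predic(mn, poly_kernel(tcn$X[pred2, ], tcn$X[ref2, ], O = 1),
                  tcn$labels[pred2])
  expect_equal(on$se, pnorm(-1), tolerance = 0.02)
})

test_that("held-out SE is at chance for label-randomized data", {
  se <- chance_level_se(seeds = 1:20, n_units = 10L, per_class = 100L)
  ci <- mean(se) + c(-1, 1) * qt(0.975, 19) * sd(se) / sqrt(20)
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("in-sample SE stays positive for noisy classes in expanded
           spaces under the default penalty", {
  tc <- toy_classes(n = 150, sep = 1.5, sd = 1, seed = 12)
  K <- poly_kernel(tc$X / mean(sqrt(rowSums(tc$X^2))), O = 5)
  m <- fit_kfda(K, tc$labels, eta = 0.05)
  expect_gt(classify(m, K, labels = tc$labels)$se, 0)
})

test_that("projections are invariant to a constant kernel offset", {
  tc <- toy_classes(n = 60, sep = 2, seed = 13)
  K <- poly_kernel(tc$X, O = 2)
  m1 <- fit_kfda(K, tc$labels)
  m2 <- fit_kfda(K + 7, tc$labels)
  expect_equal(abs(cor(m1$projections[, 1], m2$projections[, 1])), 1,
               tolerance = 1e-6)
})

test_that("discretized KL matches the closed form for Gaussians", {
  mk_model <- function(m1, s1, m2, s2) {
    structure(list(class_stats = matrix(c(m1, m2, s1, s2), 2,
                                        dimnames = list(c("A", "B"),
                                                        c("mean", "sd")))),
              class = "kfda_model")
  }
  # identical Gaussians: KL ~ 0
  expect_lt(kl_divergence(mk_model(0, 1, 0, 1))$kl, 1e-6)
  # N(0,1) vs N(1,1): closed form 0.5, discretization within 1%
  expect_equal(kl_divergence(mk_model(0, 1, 1, 1))$kl, 0.5,
               tolerance = 0.005)
  # non-negativity across random parameter draws (Gibbs inequality)
  set.seed(14)
  for (i in 1:20) {
    kl <- kl_divergence(mk_model(rnorm(1), runif(1, 0.5, 2),
                                 rnorm(1), runif(1, 0.5, 2)))$kl
    expect_gte(kl, 0)
  }
  # well-separated classes still yield a large finite KL
  expect_gt(kl_divergence(mk_model(-10, 0.5, 10, 0.5))$kl, 10)
  expect_error(kl_divergence(mk_model(0, 0, 1, 1)), "degenerate")
})

test_that("the pairwise epoch sweep honors its shape contract", {
  d <- small_synth()
  r <- estimate_rates(d$spikes)
  tl <- build_epoch_timeline(d$events, r)
  dc <- build_dc_msua(r, select_delays(r, tl))
  sw <- pairwise_epoch_sweep(dc, tl, "trial1", "trial2",
                             O_list = c(1, 2, 3), max_per_class = 60)
  pairs <- unique(sw$epoch_pair)
  expect_equal(nrow(sw), length(pairs) * 3 * 2)  # pair x O x direction
  expect_true(all(c("epoch_pair", "O", "direction", "SE", "SE_predic",
                    "KL", "n_ref", "n_pred") %in% names(sw)))
  expect_true(all(sw$SE >= 0 & sw$SE <= 1))
  expect_true(all(sw$SE_predic >= 0 & sw$SE_predic <= 1))
  # reward epochs excluded by default
  expect_false(any(grepl("reward", sw$epoch_pair)))
  # overlapping trial sets are rejected; single-epoch data has no pairs
  expect_error(pairwise_epoch_sweep(dc, tl, "trial1", "trial1"), "disjoint")
  tl_one <- mk_timeline(rep(c("delay", "unlabeled"),
                            c(100, length(tl$labels) - 100)))
  expect_error(pairwise_epoch_sweep(dc, tl_one, "trial1", "trial2"),
               "no eligible")
})
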