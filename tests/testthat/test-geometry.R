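test_that("kernel PCA reduces to ordinary PCA at O = 1 and matches the
           explicit feature-map oracle at O = 2", {
  set.seed(21)
  X <- matrix(rnorm(60 * 4), 60, 4) %*% diag(c(3, 2, 1, 0.5))
  kp <- kernel_pca(poly_kernel(X, O = 1), d = 3)
  pc <- prcomp(X, center = TRUE)
  for (j in 1:3)
    expect_gt(abs(cor(kp$coords[, j], pc$x[, j])), 0.999)
  # variance ordering
  expect_true(all(diff(kp$eigenvalues) <= 0))

  # collinear data: one component explains > 99.9% of the variance
  s <- rnorm(100)
  line <- outer(s, c(1, -2, 0.5, 3, 1))
  kl <- suppressWarnings(kernel_pca(poly_kernel(line, O = 1), d = 2))
  expect_gt(kl$explained_variance[1], 0.999)

  # tiny set, explicit O = 2 feature map as the oracle
  Y <- matrix(rnorm(18), 6, 3)
  spec <- expansion_spec(3, 2)
  feats <- t(apply(Y, 1, explicit_expand, spec = spec))
  pc2 <- prcomp(feats, center = TRUE)
  kp2 <- kernel_pca(poly_kernel(Y, O = 2), d = 3)
  for (j in 1:3)
    expect_gt(abs(cor(kp2$coords[, j], pc2$x[, j])), 1 - 1e-6)

  # full-rank reconstruction of the centered kernel from scores
  K <- poly_kernel(Y, O = 2)
  kp_full <- kernel_pca(K, d = 5)
  Kc <- ensembleflow:::.center_kernel(unclass(K))$Kc
  expect_equal(tcrossprod(kp_full$coords), Kc, tolerance = 1e-8,
               ignore_attr = TRUE)

  # out-of-sample projection agrees with in-sample scores
  proj <- project_kpca(kp2, poly_kernel(Y, Y, O = 2))
  expect_equal(proj, kp2$coords, tolerance = 1e-8)
})

test_that("velocity fields are forward differences that respect trial
           boundaries", {
  # constant trajectory: zero velocities
  fl0 <- velocity_field(matrix(1, 10, 3), normalize = FALSE)
  expect_true(all(fl0$speeds == 0))
  # affine trajectory: constant velocity u
  u <- c(0.5, -1, 2)
  coords <- outer(1:20, u)
  fl <- velocity_field(coords, normalize = FALSE)
  expect_equal(unname(fl$velocities),
               matrix(u, 19, 3, byrow = TRUE), ignore_attr = TRUE)
  # two concatenated trials of lengths 10 and 8: 9 + 7 = 16 vectors
  fl2 <- velocity_field(matrix(rnorm(18 * 2), 18),
                        trial_ids = rep(c("a", "b"), c(10, 8)))
  expect_equal(nrow(fl2$velocities), 16L)
  # single point: empty field
  expect_length(velocity_field(matrix(1, 1, 2))$speeds, 0L)
  # normalization maps speeds into [0, 1]
  fl3 <- velocity_field(matrix(rnorm(40), 20))
  expect_true(all(fl3$speeds >= 0 & fl3$speeds <= 1))
})

test_that("likelihood-velocity fits recover constructed slopes", {
  set.seed(22)
  speeds <- runif(4000)
  # null: likelihood independent of speed -> slope within 2 SE of zero
  lik0 <- exp(rnorm(4000, -2, 0.3))
  f0 <- likelihood_velocity_curve(speeds, lik0)
  expect_lt(abs(f0$slope), 2 * f0$slope_se)
  # constructed log-likelihood = -2 * speed + noise -> slope ~ -2
  lik <- exp(-2 * speeds + rnorm(4000, 0, 0.2))
  f <- likelihood_velocity_curve(speeds, lik)
  expect_lt(abs(f$slope - (-2)), 3 * f$slope_se)
  expect_lt(f$rms_error, 0.05)
  expect_equal(f$n_bins, 20L)
  # too few populated bins
  expect_error(likelihood_velocity_curve(rep(c(0, 1), 50), runif(100),
                                         n_bins = 20),
               "nonempty")

  # paired slope comparison flags a steeper original
  likb <- exp(-0.5 * speeds + rnorm(4000, 0, 0.2))
  cmp <- compare_slopes(f, likelihood_velocity_curve(speeds, likb))
  expect_lt(cmp$slope_diff, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("escape typing is exhaustive and matches hand-built fixtures", {
  # all bins correctly classified: type a, 0% escaped
  lab <- rep("delay", 10)
  r <- escape_analysis(lab, rep("delay", 10), rep(1, 10))
  expect_equal(r$per_epoch$a, 1L)
  expect_equal(r$overall_escape_fraction, 0)

  # misclassified only in the final 3 bins with k = 2: escaped
  pred <- c(rep("delay", 7), rep("other", 3))
  r2 <- escape_analysis(lab, pred, rep(1, 10), k = 2)
  expect_equal(r2$per_epoch$escaped, 1L)

  # short blip below k does not count as a departure
  pred3 <- c("delay", "other", rep("delay", 8))
  r3 <- escape_analysis(lab, pred3, rep(1, 10), k = 2)
  expect_equal(r3$per_epoch$a, 1L)

  # leave-and-return is type b; converge-from-outside is type c
  predb <- c("delay", "delay", "other", "other", rep("delay", 6))
  expect_equal(escape_analysis(lab, predb, rep(1, 10))$per_epoch$b, 1L)
  predc <- c("other", "other", rep("delay", 8))
  expect_equal(escape_analysis(lab, predc, rep(1, 10))$per_epoch$c, 1L)

  # 10 trajectories, 2 built to escape: 20% escape fraction; counts conserve
  labs <- rep(rep("delay", 6), 10)
  trial <- rep(1:10, each = 6)
  preds <- rep("delay", 60)
  preds[trial %in% c(3, 7)] <- "other"
  preds[trial %in% c(3, 7)][c(1, 7)] <- "delay"  # keep some member bins
  r4 <- escape_analysis(labs, preds, trial, k = 2)
  expect_equal(r4$overall_escape_fraction, 20)
  expect_equal(sum(r4$per_epoch[, c("a", "b", "c", "escaped")]), 10)

  # trapping-region violation: escaped trajectory far outside the
  # reference cloud
  coords <- matrix(0, 10, 2); coords[8:10, 1] <- 5
  ref <- list(delay = matrix(rnorm(40, 0, 0.3), 20, 2))
  r5 <- escape_analysis(lab, pred, rep(1, 10), k = 2,
                        coords = coords, ref_coords = ref, rho = 1.5)
  expect_equal(r5$trapping_violations, 100)
  expect_error(escape_analysis(rep("unlabeled", 5), rep("x", 5), rep(1, 5)),
               "no labeled")
})

test_that("correlation dimension recovers known dimensions", {
  set.seed(23)
  # 1000 points on a segment in 3-D (shuffled so time decouples from space)
  s <- runif(1000)
  line <- outer(s, c(1, 2, -1)) + rnorm(3000, sd = 1e-4)
  cd1 <- correlation_dimension(line)
  expect_gt(cd1$d2_slope, 0.9); expect_lt(cd1$d2_slope, 1.1)

  # 2000 points on a planar patch
  uv <- cbind(runif(2000), runif(2000))
  plane <- uv %*% rbind(c(1, 0, 1), c(0, 1, -1)) + rnorm(6000, sd = 1e-4)
  cd2 <- correlation_dimension(plane)
  expect_gt(cd2$d2_slope, 1.8); expect_lt(cd2$d2_slope, 2.2)
  expect_equal(cd2$embedding_dim_needed, ceiling(2 * cd2$d2_slope + 1))

  # invariance under rigid rotation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cd1r <- correlation_dimension(line %*% R)
  expect_equal(cd1$d2_slope, cd1r$d2_slope, tolerance = 0.02)

  # Takens cross-check lands in the same range on the line
  expect_gt(cd1$takens_ml_d2, 0.8); expect_lt(cd1$takens_ml_d2, 1.2)
  expect_error(correlation_dimension(line[1:50, ]), "200")
})
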