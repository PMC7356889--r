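test_that("data in an exact k-dimensional subspace give full variance and zero OD", {
  set.seed(71)
  basis <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  x <- matrix(rnorm(40 * 2), 40, 2) %*% t(basis) +
    matrix(2, 40, 6)
  fit <- robpca(x, k = 2, seed = 1)
  expect_equal(fit$explained_variance_fraction, 1, tolerance = 1e-8)
  expect_lt(max(fit$od), 1e-8)
  expect_equal(crossprod(fit$loadings), diag(2), tolerance = 1e-8)
})

test_that("the fitted h-subset matches exhaustive MCD search on tiny instances", {
  for (sd in 1:8) {
    set.seed(500 + sd)
    x <- matrix(rnorm(16), 8, 2)
    x[1, ] <- x[1, ] + 6    # one gross lot
    fit <- robpca(x, k = 1, seed = sd)
    sc <- distances(fit, x)$scores[, 1]
    subsets <- combn(8, fit$h)
    spread <- apply(subsets, 2, function(ix) var(sc[ix]))
    oracle <- sort(subsets[, which.min(spread)])
    expect_identical(fit$best_subset, oracle)
  }
})

test_that("on clean Gaussian data the robust subspace agrees with classical PCA", {
  set.seed(72)
  x <- matrix(rnorm(200 * 10), 200, 10) %*% diag(c(5, 4, 3, rep(1, 7)))
  fit <- robpca(x, k = 3, seed = 7)
  cls <- prcomp(x)$rotation[, 1:3]
  expect_lt(principal_angle(fit$loadings, cls), 5)
})

test_that("score and orthogonal distances have their closed forms", {
  set.seed(73)
  x <- matrix(rnorm(60 * 5), 60, 5)
  fit <- robpca(x, k = 2, seed = 1)
  mu <- fit$center
  P <- fit$loadings
  d0 <- distances(fit, matrix(mu, 1))
  expect_equal(d0$sd, 0, tolerance = 1e-10)
  expect_equal(d0$od, 0, tolerance = 1e-10)

  c1 <- 3.7
  d1 <- distances(fit, matrix(mu + c1 * P[, 1], 1))
  expect_equal(d1$sd, abs(c1) / sqrt(fit$eigenvalues[1]), tolerance = 1e-8)
  expect_equal(d1$od, 0, tolerance = 1e-8)

  v <- rnorm(5)
  v <- v - P %*% crossprod(P, v)          # orthogonal complement
  d2 <- distances(fit, matrix(mu + as.numeric(v), 1))
  expect_equal(d2$sd, 0, tolerance = 1e-8)
  expect_equal(d2$od, sqrt(sum(v^2)), tolerance = 1e-8)
})

test_that("cutoffs follow the chi-squared and Wilson-Hilferty recipes", {
  set.seed(74)
  x <- matrix(rnorm(80 * 6), 80, 6)
  fit <- robpca(x, k = 2, seed = 2)
  expect_equal(unname(fit$cutoffs["sd_cut"]), sqrt(qchisq(0.975, 2)),
               tolerance = 1e-12)
  expect_equal(unname(fit$cutoffs["sd_cut"]), 2.7162, tolerance = 1e-4)
  u <- fit$od^(2 / 3)
  expect_equal(unname(fit$cutoffs["od_cut"]),
               (median(u) + mad(u) * qnorm(0.975))^(3 / 2), tolerance = 1e-10)
  # quantile -> 1: both cutoffs diverge, nothing is flagged
  far <- cutoffs(fit, quantile = 1 - 1e-12)
  expect_gt(far["sd_cut"], 7)
  expect_gt(far["od_cut"], max(fit$od))
})

test_that("quadrant classification is strict at the cutoffs", {
  cuts <- c(sd_cut = 2, od_cut = 3)
  expect_identical(as.character(classify_quadrant(0, 0, cuts)), "regular")
  expect_identical(as.character(classify_quadrant(2, 3, cuts)), "regular")
  expect_identical(as.character(classify_quadrant(4, 0, cuts)),
                   "score_outlier")
  expect_identical(as.character(classify_quadrant(0, 4, cuts)),
                   "orthogonal_outlier")
  expect_identical(as.character(classify_quadrant(4, 4, cuts)), "both")
})

test_that("score contributions decompose SD^2 additively", {
  set.seed(75)
  x <- matrix(rnorm(50 * 8), 50, 8)
  colnames(x) <- paste0("v", 1:8)
  fit <- robpca(x, k = 3, seed = 3)
  ctr <- score_contributions(fit, x)
  d <- distances(fit, x)
  expect_equal(rowSums(ctr), d$sd^2, tolerance = 1e-6)
  expect_equal(unname(score_contributions(fit, fit$center)[1, ]),
               rep(0, 8), tolerance = 1e-10)
  # a single-variable perturbation is attributed to that variable
  j <- which.max(abs(fit$loadings[, 1]))
  xi <- fit$center
  xi[j] <- xi[j] + 5
  ctr1 <- score_contributions(fit, xi)
  expect_gt(abs(ctr1[1, j]) / sum(abs(ctr1)), 0.99)
})

test_that("distances are equivariant under column rotations", {
  set.seed(76)
  x <- matrix(rnorm(60 * 6), 60, 6) %*% diag(c(4, 3, 2, 1, 1, 1))
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  f1 <- robpca(x, k = 3, seed = 4)
  f2 <- robpca(x %*% q, k = 3, seed = 4)
  expect_equal(f1$sd, f2$sd, tolerance = 1e-6)
  expect_equal(f1$od, f2$od, tolerance = 1e-6)
})

test_that("20% gross contamination barely moves the robust subspace", {
  set.seed(77)
  x <- matrix(rnorm(100 * 8), 100, 8) %*% diag(c(4, 3, 2, rep(0.5, 5)))
  xc <- x
  xc[1:20, ] <- xc[1:20, ] + matrix(rnorm(20 * 8, mean = 8), 20, 8)
  f_clean <- robpca(x, k = 3, seed = 5)
  f_cont <- robpca(xc, k = 3, seed = 5)
  expect_lt(principal_angle(f_clean$loadings, f_cont$loadings), 10)
  p_clean <- prcomp(x)$rotation[, 1:3]
  p_cont <- prcomp(xc)$rotation[, 1:3]
  expect_gt(principal_angle(p_clean, p_cont), 30)
})

test_that("classical diagnostics behave at their nominal level and degenerate cases", {
  set.seed(78)
  basis <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))
  x_flat <- matrix(rnorm(30 * 2), 30, 2) %*% t(basis)
  d <- fit_cpca_diagnostics(x_flat, k = 2)
  expect_lt(max(d$dmodx), 1e-8)

  rates <- vapply(1:4, function(sd) {
    set.seed(900 + sd)
    x <- matrix(rnorm(150 * 10), 150, 10)
    mean(fit_cpca_diagnostics(x, k = 3)$t2_outlier)
  }, numeric(1))
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.10)

  expect_error(fit_cpca_diagnostics(matrix(rnorm(40), 10, 4), k = 4), "k")
})

test_that("model guards reject impossible requests", {
  set.seed(79)
  x <- matrix(rnorm(12), 4, 3)
  expect_error(robpca(matrix(rnorm(9), 3, 3)), "at least 4")
  expect_error(robpca(x, k = 5, seed = 1), "rank")
  x[1, 1] <- NA
  expect_error(robpca(x, k = 1, seed = 1), "complete")
})

test_that("the internal MCD agrees with an independent MCD implementation", {
  set.seed(80)
  y <- matrix(rnorm(100 * 3), 100, 3)
  y[1:15, ] <- y[1:15, ] + 10         # 15% gross contamination
  h <- floor(0.75 * 100)
  ours <- fffmon:::mcd_fit(y, h)
  set.seed(80)
  ref <- MASS::cov.rob(y, method = "mcd", quantile.used = h)
  # both robust centers must sit at the clean bulk, far from the raw mean
  expect_lt(sqrt(sum((ours$center - ref$center)^2)), 0.5)
  expect_gt(sqrt(sum((colMeans(y) - ref$center)^2)), 1)
})
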