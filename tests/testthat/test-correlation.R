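test_that("linear correlation handles exact and degenerate cases", {
  x <- 1:10
  r <- linear_correlation(cbind(x, 2 * x + 1))
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-12)
  expect_equal(r$slope, 2)
  expect_equal(r$r2, r$r^2)
  # symmetry under axis swap
  set.seed(101)
  pts <- cbind(rnorm(50), rnorm(50))
  expect_equal(linear_correlation(pts)$r,
               linear_correlation(pts[, 2:1])$r)
  expect_error(linear_correlation(pts[1:2, ]), "3 points")
  expect_error(linear_correlation(cbind(rep(1, 5), rnorm(5))),
               "zero variance")
})

test_that("the slope test holds its nominal size", {
  set.seed(102)
  hits <- 0
  reps <- 2000
  for (b in seq_len(reps)) {
    if (linear_correlation(cbind(rnorm(200), rnorm(200)))$p < 0.005)
      hits <- hits + 1
  }
  expect_gt(binom.test(hits, reps, 0.005)$p.value, 0.001)
})

test_that("Fisher's combination follows its closed form", {
  n <- 7
  fc <- fisher_combine(rep(0.5, n))
  expect_equal(fc$chi2, -2 * n * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 2L * n)
  expect_equal(fisher_combine(rep(1, 4))$chi2, 0)
  expect_equal(fisher_combine(rep(0.2, 3929))$df, 7858L)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
})

test_that("bootstrap angles are exact on collinear clouds", {
  x <- seq(1, 10, length.out = 20)
  est45 <- bootstrap_angle(cbind(x, x), n_boot = 500, seed = 1)
  expect_equal(est45$theta, 45, tolerance = 1e-9)
  expect_equal(est45$theta45, 45, tolerance = 1e-9)
  expect_lt(est45$ci_high - est45$ci_low, 1e-9)
  est2 <- bootstrap_angle(cbind(x, 2 * x), n_boot = 500, seed = 1)
  expect_equal(est2$theta, atan(2) * 180 / pi, tolerance = 1e-9)
  expect_equal(est2$theta45, 90 - atan(2) * 180 / pi, tolerance = 1e-9)
  expect_error(bootstrap_angle(cbind(x[1:2], x[1:2])), "3 points")
})

test_that("angle estimates transform correctly under axis swap", {
  pts <- rotated_cloud(100, 30, seed = 103)
  a <- bootstrap_angle(pts, n_boot = 2000, seed = 7)
  b <- bootstrap_angle(pts[, 2:1], n_boot = 2000, seed = 7)
  expect_equal(b$theta, 90 - a$theta, tolerance = 0.5)
  expect_equal(b$theta45, a$theta45, tolerance = 0.5)
})

test_that("doubled-angle averaging has no discontinuity artefacts", {
  for (g in seq(5, 85, by = 10)) {
    pts <- rotated_cloud(500, g, sds = c(3, 0.3), seed = 104 + g)
    est <- bootstrap_angle(pts, n_boot = 1000, seed = g)
    expect_lt(abs(est$theta - g), 1)
  }
  # near-zero angles fold around 0/180 without artefacts
  pts <- rotated_cloud(500, 1, sds = c(3, 0.3), seed = 105)
  est <- bootstrap_angle(pts, n_boot = 1000, seed = 1)
  expect_lt(min(abs(est$theta - 1), abs(est$theta - 181)), 1)
})

test_that("angle significance behaves at and away from the boundaries", {
  pts <- rotated_cloud(300, 25, sds = c(3, 0.4), seed = 106)
  est <- bootstrap_angle(pts, n_boot = 2000, seed = 2)
  expect_equal(angle_significance(est, 0), 0)
  expect_equal(angle_significance(est, 45), 0)
  # clouds on exactly 45 degrees: the tail fraction behaves like a
  # p-value, uniform across replicates with mean 1/2
  p45s <- vapply(1:40, function(b) {
    pts45 <- rotated_cloud(100, 45, sds = c(3, 0.8), seed = 2000 + b)
    angle_significance(bootstrap_angle(pts45, n_boot = 500, seed = b),
                       45, side = "below")
  }, numeric(1))
  expect_gt(mean(p45s), 0.3)
  expect_lt(mean(p45s), 0.7)
  # a 1-degree cloud with wide scatter is not distinguishable from 0
  pts1 <- rotated_cloud(40, 3, sds = c(1.2, 0.8), seed = 108)
  est1 <- bootstrap_angle(pts1, n_boot = 2000, seed = 4)
  expect_gt(angle_significance(est1, 0), 0.025)
  neg <- bootstrap_angle(cbind(1:20, -(1:20)), n_boot = 200, seed = 1)
  expect_error(angle_significance(neg, 45), "positively correlated")
})

test_that("Henze-Zirkler matches an independent reference implementation", {
  # reference values computed with pingouin.multivariate_normality
  i <- 1:60
  x <- sin(i * 1.1) + 0.5 * cos(i * 2.7)
  y <- cos(i * 0.8) + 0.4 * sin(i * 3.3)
  hz <- henze_zirkler(cbind(x, y))
  expect_equal(hz$hz, 1.17179456, tolerance = 1e-7)
  expect_equal(hz$p, 0.00909906, tolerance = 1e-6)
  x2 <- c(x[1:30], x[31:60] + 8)
  hz2 <- henze_zirkler(cbind(x2, y))
  expect_equal(hz2$hz, 3.0692336, tolerance = 1e-6)
  expect_equal(hz2$p, 2.9568708e-07, tolerance = 1e-5)
  expect_error(henze_zirkler(cbind(rnorm(5), rnorm(5))), "n = 10")
  dup <- matrix(rep(c(1, 2), each = 20), 20, 2)
  expect_error(henze_zirkler(dup), "degenerate")
})

test_that("Henze-Zirkler is calibrated under the null and powered on mixtures", {
  set.seed(109)
  hits <- 0
  reps <- 400
  for (b in seq_len(reps)) {
    if (henze_zirkler(cbind(rnorm(100), rnorm(100)))$p < 0.05)
      hits <- hits + 1
  }
  expect_gt(binom.test(hits, reps, 0.05)$p.value, 0.001)
  power <- 0
  for (b in 1:100) {
    pts <- rbind(cbind(rnorm(50, 0), rnorm(50, 0)),
                 cbind(rnorm(50, 6), rnorm(50, 6)))
    if (henze_zirkler(pts)$p < 0.05) power <- power + 1
  }
  expect_gt(power / 100, 0.9)
})

test_that("trial regressions separate drift from flat series", {
  set.seed(110)
  trials <- 0:99
  flat <- cbind(rnorm(100, 15), rnorm(100, 20))
  tr <- trial_regressions(flat, trials)
  expect_lt(tr$multi_r2, 0.08)
  exact <- cbind(2 + 0.1 * trials, 5 - 0.2 * trials)
  expect_equal(trial_regressions(exact, trials)$multi_r2, 1)
  expect_error(trial_regressions(flat, rep(1, 100)), "constant")
  # multi-output r2 grows with the drift amplitude
  r2s <- vapply(c(0, 1, 2.5, 5), function(a) {
    set.seed(111)
    pts <- cbind(rnorm(100, 15) + a * trials / 100,
                 rnorm(100, 20) + a * trials / 100)
    trial_regressions(pts, trials)$multi_r2
  }, numeric(1))
  expect_true(all(diff(r2s) > 0))
})

test_that("difference-vs-first-spike regression matches its null model", {
  s0 <- rnorm(50, 15)
  fixed <- diff_vs_first_spike(cbind(s0, s0 + 3))
  expect_equal(fixed$r, 0)
  expect_equal(fixed$p, 1)
  prop <- diff_vs_first_spike(cbind(s0, 2 * s0))
  expect_equal(prop$r, 1)
  # under the fixed-difference null (noise independent of s0) the
  # regression rejects at the nominal rate only
  hits <- 0
  for (b in 1:200) {
    set.seed(5000 + b)
    a <- rnorm(60, 15, 1)
    if (diff_vs_first_spike(cbind(a, a + 3 + rnorm(60, 0, 0.5)))$p < 0.05)
      hits <- hits + 1
  }
  expect_gt(binom.test(hits, 200, 0.05)$p.value, 0.001)
})

test_that("trial-lagged cross-correlation aligns series correctly", {
  x <- rnorm(50)
  expect_equal(cross_correlation(x, x, 0:49, 0:49, lag = 0)$r, 1)
  expect_error(cross_correlation(x[1:3], x[1:3], 0:2, 10:12, lag = 1),
               "overlapping")
  # independent series: lag-1 significant at the nominal rate
  set.seed(113)
  hits <- 0
  for (b in 1:200) {
    a <- rnorm(100); b2 <- rnorm(100)
    if (cross_correlation(a, b2, 0:99, 0:99, lag = 1)$p < 0.05)
      hits <- hits + 1
  }
  expect_gt(binom.test(hits, 200, 0.05)$p.value, 0.001)
  # shared latent state appears at lag 0
  lc <- latent_cluster(200, c(1.5, 1), c(0.5, 0.5), seed = 114)
  cc <- cross_correlation(lc$points[, 1], lc$points[, 2], 0:199, 0:199,
                          lag = 0)
  expect_gt(cc$r, 0.5)
})

test_that("Bartlett sphericity rejects correlated clusters only", {
  set.seed(115)
  lc <- latent_cluster(80, c(1.5, 1), c(0.4, 0.4), seed = 116)
  expect_lt(bartlett_sphericity(lc$points)$p, 1e-6)
  ind <- cbind(rnorm(80), rnorm(80))
  expect_gt(bartlett_sphericity(ind)$p, 0.001)
})
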