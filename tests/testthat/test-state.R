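test_that("the single-factor fit recovers generative parameters", {
  ok_lambda <- 0; ok_sigma <- 0
  reps <- 60
  for (b in seq_len(reps)) {
    lc <- latent_cluster(300, c(2, 1), c(0.5, 0.5), seed = 9000 + b)
    fm <- fit_single_factor(lc$points)
    lam <- c(fm$lambda0, fm$lambda1)
    if (all(abs(lam - c(2, 1)) / c(2, 1) < 0.15)) ok_lambda <- ok_lambda + 1
    if (all(abs(c(fm$sigma0, fm$sigma1) - 0.5) / 0.5 < 0.2))
      ok_sigma <- ok_sigma + 1
  }
  expect_gte(ok_lambda / reps, 0.9)
  expect_gte(ok_sigma / reps, 0.9)
})

test_that("factor-model identities and gates hold", {
  lc <- latent_cluster(200, c(1.5, 0.9), c(0.4, 0.4), seed = 131)
  fm <- fit_single_factor(lc$points)
  expect_equal(fm$sigma_diff, sqrt(fm$sigma0^2 + fm$sigma1^2),
               tolerance = 1e-12)
  expect_lt(abs(mean(fm$eta)), 1e-9)
  expect_true(fm$lambda0 >= 0 && fm$lambda1 >= 0)
  # a tight symmetric cluster loads at 45 degrees
  lc45 <- latent_cluster(300, c(1, 1), c(0.01, 0.01), seed = 132)
  expect_equal(loading_angle(fit_single_factor(lc45$points)), 45,
               tolerance = 0.5)
  # gates: independent noise is rejected
  set.seed(133)
  ind <- cbind(rnorm(100, 15), rnorm(100, 20))
  expect_error(fit_single_factor(ind), "gate failed")
  expect_silent(fit_single_factor(ind, check_gates = FALSE))
})

test_that("sigma_diff is invariant under neuron order swap", {
  lc <- latent_cluster(150, c(2, 0.8), c(0.6, 0.6), seed = 134)
  a <- fit_single_factor(lc$points)
  b <- fit_single_factor(lc$points[, 2:1])
  expect_equal(a$sigma_diff, b$sigma_diff, tolerance = 1e-12)
})

test_that("factor loading angle agrees with the bootstrap PCA angle", {
  lc <- latent_cluster(200, c(2, 1), c(0.3, 0.3), seed = 135)
  fm <- fit_single_factor(lc$points)
  est <- factor_angle(lc$points, n_boot = 1000, seed = 1)
  expect_lt(abs(loading_angle(fm) - est$theta), 5)
  zero <- list(lambda0 = 0, lambda1 = 0)
  expect_error(loading_angle(zero), "zero")
})

test_that("RDR spreads order as the coding regimes predict", {
  # a tight cluster plus far outlier mass: RDR1 > RDR2
  lc <- latent_cluster(100, c(1.5, 0.8), c(0.4, 0.4), seed = 136)
  outliers <- cbind(rnorm(30, 35, 1), rnorm(30, 8, 1))
  allpts <- rbind(lc$points, outliers)
  d <- as_dist(allpts)
  fm <- fit_single_factor(lc$points)
  rdr <- rdr_summary(d, lc$points, fm)
  expect_gt(rdr$rdr1_sigma_diff, rdr$rdr2_sigma_diff)
  # unequal loadings: conditioning reduces the difference spread
  better <- 0
  reps <- 40
  for (b in seq_len(reps)) {
    lc2 <- latent_cluster(150, c(2, 1), c(0.3, 0.3), seed = 9500 + b)
    fm2 <- fit_single_factor(lc2$points)
    r2 <- rdr_summary(as_dist(lc2$points), lc2$points, fm2)
    if (r2$rdr3_sigma_diff < r2$rdr2_sigma_diff) better <- better + 1
  }
  expect_gte(better / reps, 0.9)
  # equal loadings: the state carries no difference information
  lc3 <- latent_cluster(4000, c(1.2, 1.2), c(0.5, 0.5), seed = 137)
  fm3 <- fit_single_factor(lc3$points)
  r3 <- rdr_summary(as_dist(lc3$points), lc3$points, fm3)
  expect_equal(r3$rdr3_sigma_diff, r3$rdr2_sigma_diff, tolerance = 0.05)
  expect_equal(r3$rdr2_sigma_diff, sqrt(0.5), tolerance = 0.1)
  expect_error(rdr_summary(as_dist(lc$points[1:5, ]), lc$points[1:5, ],
                           fm), "minimum size")
})

test_that("improvement of RDR3 over RDR2 grows with loading asymmetry", {
  gaps <- vapply(c(1, 1.5, 2.5, 4), function(ratio) {
    lc <- latent_cluster(3000, c(ratio, 1), c(0.3, 0.3),
                         seed = 140 + ratio * 10)
    fm <- fit_single_factor(lc$points)
    r <- rdr_summary(as_dist(lc$points), lc$points, fm)
    r$rdr2_sigma_diff - r$rdr3_sigma_diff
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("state predictions project onto the oriented first component", {
  lc <- latent_cluster(200, c(1.5, 1), c(0.4, 0.4), seed = 138)
  sp <- predict_state(lc$points, 0:199)
  ctr_pt <- colMeans(lc$points)
  at_mean <- predict_state(rbind(lc$points, ctr_pt), 0:200)
  expect_lt(abs(at_mean$state[201]), 0.05)
  expect_gt(cor(sp$state, lc$points[, 1]), 0)
  expect_gt(cor(sp$state, lc$points[, 2]), 0)
  expect_gt(cor(sp$state, lc$eta), 0.7)
})

test_that("state correlations require 15 common trials and 4 neurons' worth of data", {
  lc_a <- latent_cluster(50, c(1, 1), c(0.3, 0.3), seed = 139)
  lc_b <- latent_cluster(50, c(1, 1), c(0.3, 0.3), seed = 140)
  pa <- predict_state(lc_a$points, 0:49)
  pb <- predict_state(lc_b$points, 0:49)
  expect_s3_class(state_correlation(pa, pb), "correlation_result")
  pb14 <- predict_state(lc_b$points[1:14, , drop = FALSE], 0:13)
  expect_null(state_correlation(pa, pb14))
})

test_that("shared-state pairs have positively correlated predicted states", {
  pos <- 0; n_done <- 0
  reps <- 30
  for (b in seq_len(reps)) {
    rec <- generate_session(four_neuron_config(seed = 10000 + b))
    dists <- build_distributions(rec)
    ids <- vapply(dists, function(d) paste(d$neuron_ids, collapse = "-"),
                  character(1))
    da <- dists[[which(ids == "1-2")]]
    db <- dists[[which(ids == "3-4")]]
    pa <- predict_state(dist_points_of(da), da$trials)
    pb <- predict_state(dist_points_of(db), db$trials)
    sc <- state_correlation(pa, pb)
    if (is.null(sc)) next
    n_done <- n_done + 1
    if (sc$r > 0) pos <- pos + 1
  }
  expect_gte(n_done, reps * 0.9)
  expect_gte(pos / n_done, 0.9)
})

test_that("independent states correlate at the nominal rate only", {
  hits <- 0
  reps <- 100
  for (b in seq_len(reps)) {
    lc_a <- latent_cluster(60, c(1, 0.8), c(0.3, 0.3), seed = 11000 + b)
    lc_b <- latent_cluster(60, c(1, 0.8), c(0.3, 0.3), seed = 12000 + b)
    sc <- state_correlation(predict_state(lc_a$points, 0:59),
                            predict_state(lc_b$points, 0:59))
    if (sc$p < 0.05) hits <- hits + 1
  }
  expect_gt(binom.test(hits, reps, 0.05)$p.value, 0.001)
})

test_that("four-neuron PCA reflects the shared-state dimensionality", {
  rec <- generate_session(four_neuron_config(seed = 141))
  dists <- build_distributions(rec)
  ids <- vapply(dists, function(d) paste(d$neuron_ids, collapse = "-"),
                character(1))
  da <- dists[[which(ids == "1-2")]]
  db <- dists[[which(ids == "3-4")]]
  fr <- four_neuron_pca(dist_points_of(da), da$trials,
                        dist_points_of(db), db$trials)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_gt(fr[1], 0.7)
  # independent neurons: fractions near 1/4 each
  set.seed(142)
  ind_a <- cbind(rnorm(100), rnorm(100))
  ind_b <- cbind(rnorm(100), rnorm(100))
  fr_i <- four_neuron_pca(ind_a, 0:99, ind_b, 0:99)
  expect_true(all(abs(fr_i - 0.25) < 0.15))
  expect_error(four_neuron_pca(ind_a[1:3, ], 0:2, ind_b[1:3, ], 10:12),
               "common trials")
})

test_that("state conditioning reduces variability only for shared states", {
  reduced <- 0
  reps <- 40
  for (b in seq_len(reps)) {
    lc <- latent_cluster(80, c(1.5, 1), c(0.3, 0.3), seed = 13000 + b)
    # an independent pair observing the same eta
    set.seed(20000 + b)
    target <- 18 + 1.2 * lc$eta + rnorm(80, 0, 0.4)
    sp <- predict_state(lc$points, 0:79)
    sv <- state_conditioned_variability(target, 0:79, sp)
    if (sv$conditioned_sd < sv$unconditioned_sd) reduced <- reduced + 1
  }
  expect_gte(reduced / reps, 0.9)
  # independent predictor: no reduction beyond fitting noise
  ratios <- vapply(1:40, function(b) {
    lc <- latent_cluster(100, c(1.5, 1), c(0.3, 0.3), seed = 14000 + b)
    set.seed(21000 + b)
    target <- rnorm(100, 18, 1)
    sv <- state_conditioned_variability(target, 0:99,
                                        predict_state(lc$points, 0:99))
    sv$conditioned_sd / sv$unconditioned_sd
  }, numeric(1))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.05)
  # exactly linear target
  lc <- latent_cluster(50, c(1, 1), c(0.3, 0.3), seed = 143)
  sp <- predict_state(lc$points, 0:49)
  sv <- state_conditioned_variability(2 * sp$state + 1, 0:49, sp)
  expect_lt(sv$conditioned_sd, 1e-10)
})

test_that("pooling keeps one entry per distribution, preferring clusters", {
  s2 <- list(list(distribution_id = "A"), list(distribution_id = "B"))
  un <- list(list(distribution_id = "A"), list(distribution_id = "C"))
  pool <- pool_examples(s2, un)
  ids <- vapply(pool, function(x) x$distribution_id, character(1))
  expect_setequal(ids, c("A", "B", "C"))
  src <- vapply(pool, function(x) attr(x, "source"), character(1))
  expect_identical(src[ids == "A"], "cluster")
  expect_length(pool_examples(list(), list()), 0)
  disjoint <- pool_examples(s2, list(list(distribution_id = "D")))
  expect_length(disjoint, 3)
})
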