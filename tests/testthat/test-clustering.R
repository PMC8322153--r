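# Frozen reference labels computed with an independent density-based
# implementation (sklearn.cluster.DBSCAN, euclidean metric, min_samples 5)
# on the deterministic two-blob + stragglers fixture below.
dbscan_fixture <- function() {
  i <- 1:80
  x <- ifelse(i <= 40, 10 + sin(i * 1.7) * 0.8, 25 + cos(i * 2.3) * 1.1)
  y <- ifelse(i <= 40, 20 + cos(i * 0.9) * 0.7, 12 + sin(i * 1.3) * 0.9)
  cbind(c(x, 40, 45, 3), c(y, 40, 2, 45))
}

sklearn_labels <- list(
  "0.5" = c(0, 1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 1, 0,
            0, 0, 1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 0,
            3, 2, 2, 3, -1, 2, 4, 2, 3, -1, 2, 4, 2, -1, 3, 2, 4, 2, -1,
            3, 2, 2, 3, -1, 2, 4, 2, 3, -1, 2, 4, 2, -1, 3, 2, 4, 2, -1,
            3, 2, -1, -1, -1),
  "1" = c(rep(0, 40), rep(1, 40), -1, -1, -1),
  "2" = c(rep(0, 40), rep(1, 40), -1, -1, -1))

canonical <- function(labels) {
  noise <- labels <= 0
  out <- integer(length(labels))
  u <- unique(labels[!noise])
  out[!noise] <- match(labels[!noise], u)
  out
}

test_that("density-based labels match the reference implementation", {
  pts <- dbscan_fixture()
  D <- as.matrix(dist(pts))
  for (eps in c(0.5, 1, 2)) {
    ours <- statewarp:::dbscan_labels(D, eps, 5)
    ref <- sklearn_labels[[as.character(eps)]]
    expect_identical(canonical(ours), canonical(ref + 1L))
  }
})

test_that("the epsilon sweep finds separated blobs and applies size rules", {
  set.seed(81)
  blob <- function(n, cx, cy) cbind(rnorm(n, cx, 0.5), rnorm(n, cy, 0.5))
  pts <- rbind(blob(60, 10, 10), blob(60, 30, 30))
  d <- as_dist(pts)
  cand <- dbscan_sweep(d, epsilons = 1.5, min_cluster_size = 30)
  expect_length(cand, 2)
  expect_setequal(lengths(lapply(cand, `[[`, "members")), c(60, 60))
  # a 25-point blob is below the minimum size
  d25 <- as_dist(blob(25, 10, 10))
  expect_length(dbscan_sweep(d25, epsilons = 1.5), 0)
  expect_error(dbscan_sweep(as_dist(pts[0, , drop = FALSE])), "empty")
})

test_that("clusterings identical to the previous epsilon are discarded", {
  set.seed(82)
  pts <- cbind(rnorm(60, 10, 0.3), rnorm(60, 10, 0.3))
  d <- as_dist(pts)
  # far beyond the blob diameter every epsilon yields the same partition
  cand <- dbscan_sweep(d, epsilons = c(3, 3.05, 3.1, 3.15))
  expect_length(cand, 1)
  expect_equal(cand[[1]]$epsilon, 3)
})

test_that("intersection ellipses use the 3 * max(0.5, sd) width rule", {
  set.seed(83)
  pts <- cbind(rnorm(200, 10, 0.3), rnorm(200, 12, 0.3))
  pts[, 1] <- 10 + (pts[, 1] - 10) * 0.3 / sd(pts[, 1])
  pts[, 2] <- 12 + (pts[, 2] - 12) * 0.3 / sd(pts[, 2])
  ell <- statewarp:::intersection_ellipse(1:200, pts)
  expect_equal(ell$semi_axes, c(1.5, 1.5), tolerance = 1e-9)
})

test_that("isolation keeps disjoint candidates and drops contained ones", {
  set.seed(84)
  far_a <- cbind(rnorm(40, 10, 1), rnorm(40, 10, 1))
  far_b <- cbind(rnorm(40, 45, 1), rnorm(40, 45, 1))
  pts <- rbind(far_a, far_b)
  d <- as_dist(pts)
  cand <- list(list(members = 1:40, epsilon = 1),
               list(members = 41:80, epsilon = 1))
  expect_length(isolation_test(cand, d), 2)
  # a small candidate inside a wide one: the contained one is excluded
  inner <- cbind(rnorm(35, 10, 0.2), rnorm(35, 10, 0.2))
  outer <- cbind(rnorm(60, 10, 4), rnorm(60, 10, 4))
  d2 <- as_dist(rbind(inner, outer))
  cand2 <- list(list(members = 1:35, epsilon = 1),
                list(members = 36:95, epsilon = 1))
  kept <- isolation_test(cand2, d2)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$members, 36:95)
  # partially overlapping candidates are both excluded
  left <- cbind(rnorm(40, 10, 1.5), rnorm(40, 10, 1.5))
  right <- cbind(rnorm(40, 13, 1.5), rnorm(40, 10, 1.5))
  d3 <- as_dist(rbind(left, right))
  cand3 <- list(list(members = 1:40, epsilon = 1),
                list(members = 41:80, epsilon = 1))
  expect_length(isolation_test(cand3, d3), 0)
})

test_that("Stage 1 expansion uses the exact 4-sigma boundary", {
  # construct members with exact sds (2, 1) around (10, 12)
  base <- c(scale(rnorm(50))) * 2 + 10
  base2 <- c(scale(rnorm(50))) * 1 + 12
  pts <- rbind(cbind(base, base2), c(18, 12), c(18.01, 12), c(30, 30))
  d <- as_dist(pts)
  s1 <- expand_stage1(list(members = 1:50, epsilon = 1), d)
  expect_true(51 %in% s1$members)    # on the boundary
  expect_false(52 %in% s1$members)   # just outside
  expect_false(53 %in% s1$members)
  expect_true(all(1:50 %in% s1$members))
  degen <- as_dist(cbind(rep(10, 30), rnorm(30, 10)))
  expect_error(expand_stage1(list(members = 1:30, epsilon = 1), degen),
               "zero variance")
})

test_that("Stage 1 expansion absorbs stragglers inside the ellipse", {
  set.seed(86)
  core <- cbind(rnorm(60, 20, 1), rnorm(60, 20, 1))
  strag <- c(20 + 2.5, 20 - 2.5)   # inside 4 sigma, planted
  d <- as_dist(rbind(core, strag))
  s1 <- expand_stage1(list(members = 1:60, epsilon = 1), d)
  expect_true(61 %in% s1$members)
})

test_that("bootstrap moments are consistent and deterministic", {
  set.seed(87)
  pts <- cbind(rnorm(500, 10, 1), rnorm(500, 10, 1))
  be1 <- bootstrap_ellipse(pts, n_boot = 3000, seed = 5)
  be2 <- bootstrap_ellipse(pts, n_boot = 3000, seed = 5)
  expect_identical(be1, be2)
  sc <- cov(pts) * 499 / 500
  expect_true(all(abs(diag(be1$cov) - diag(sc)) / diag(sc) < 0.1))
  # rank-1 input: one (near-)zero eigenvalue
  line <- cbind(1:50, 1:50)
  bl <- bootstrap_ellipse(line, n_boot = 500, seed = 1)
  ev <- eigen(bl$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-10)
})

test_that("Stage 2 refinement recovers the generative rotation", {
  pts <- rotated_cloud(120, 30, sds = c(2.5, 0.6), seed = 88)
  d <- as_dist(pts)
  s1 <- extract_stage1(d)
  expect_gt(length(s1), 0)
  s2 <- stage2_cluster(s1[[1]], d, seed = 2, n_boot = 3000)
  expect_gte(30, s2$angle$ci_low)
  expect_lte(30, s2$angle$ci_high)
  # semi-axes are 4 * sqrt(averaged eigenvalues)
  ev <- eigen(s2$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(s2$ellipse$semi_axes, 4 * sqrt(ev), tolerance = 1e-9)
  # members all lie inside the reported ellipse
  expect_true(all(in_ellipse(pts[s2$members, , drop = FALSE],
                             s2$ellipse)))
})

test_that("an isolated cluster gains no members in Stage 2", {
  set.seed(89)
  pts <- cbind(rnorm(80, 15, 0.8), rnorm(80, 15, 0.8))
  pts[, 2] <- pts[, 1] * 0.5 + pts[, 2] * 0.5  # correlate
  d <- as_dist(pts)
  s1 <- extract_stage1(d)
  s2 <- stage2_cluster(s1[[1]], d, seed = 3, n_boot = 2000)
  expect_setequal(s2$members, s1[[1]]$members)
})

test_that("similarity filtering enforces the shared-member rules", {
  mk <- function(members, eps) structure(
    list(members = members, epsilon = eps), class = "cluster_stage2")
  a <- mk(1:40, 0.5); b <- mk(26:70, 0.8)     # share 15
  expect_length(similarity_filter(list(a, b), enforce_unique = FALSE), 1)
  c2 <- mk(27:70, 0.8)                          # share 14
  both <- similarity_filter(list(a, c2), enforce_unique = FALSE)
  expect_length(both, 2)
  expect_length(similarity_filter(list(a, c2), enforce_unique = TRUE), 1)
  expect_length(similarity_filter(list(a)), 1)
})

test_that("pipeline output is invariant to trial storage order", {
  cfg <- two_neuron_config(seed = 90, reliability = 0.9)
  rec <- generate_session(cfg)
  rec_perm <- rec[sample(nrow(rec)), ]
  d1 <- build_distributions(rec)[[1]]
  d2 <- build_distributions(rec_perm)[[1]]
  expect_identical(d1$s0, d2$s0)
  s1a <- extract_stage1(d1)
  s1b <- extract_stage1(d2)
  expect_identical(lapply(s1a, `[[`, "members"),
                   lapply(s1b, `[[`, "members"))
})

test_that("mixture-model clustering picks component counts by BIC", {
  set.seed(91)
  one <- as_dist(cbind(rnorm(150, 15, 1), rnorm(150, 20, 1)))
  std <- gmm_cluster(one, "standard", seed = 1)
  expect_equal(attr(std, "G"), 1)
  two <- as_dist(rbind(cbind(rnorm(80, 10, 0.8), rnorm(80, 10, 0.8)),
                       cbind(rnorm(80, 30, 0.8), rnorm(80, 30, 0.8))))
  std2 <- gmm_cluster(two, "standard", seed = 1)
  expect_equal(attr(std2, "G"), 2)
})

test_that("the custom mixture variant obeys per-distribution uniqueness", {
  lc <- latent_cluster(120, c(1.5, 0.8), c(0.5, 0.5), seed = 92)
  d <- as_dist(lc$points)
  out <- gmm_cluster(d, "custom", seed = 2, n_boot = 1000)
  expect_lte(length(out), 1)
  if (length(out)) expect_s3_class(out[[1]], "cluster_stage2")
})
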