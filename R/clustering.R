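#' Epsilon sweep of density-based clustering over a response distribution
#'
#' Runs DBSCAN at each epsilon of the sweep; a clustering that is identical
#' (as a set partition of the points, ignoring labels) to the previous
#' epsilon's is discarded, as are clusters with fewer than
#' `min_cluster_size` members.
#'
#' @param dist A [pair_distribution()].
#' @param epsilons Epsilon grid (ms); default `seq(0.4, 5.0, by = 0.05)`.
#' @param min_cluster_size Minimum cluster membership (default 30).
#' @param min_pts DBSCAN `minPts` (core threshold, counting the point
#'   itself; default 5).
#' @return List of candidate clusters, each a list with `members` (point
#'   indices into the distribution) and `epsilon`.
#' @export
dbscan_sweep <- function(dist, epsilons = seq(0.4, 5.0, by = 0.05),
                         min_cluster_size = 30, min_pts = 5) {
  n <- n_conjunctive(dist)
  if (n == 0) stop("empty distribution")
  if (n < min_cluster_size) return(list())
  D <- dist_matrix(dist_points(dist))
  lab <- dbscan_sweep_cpp(D, as.numeric(epsilons), as.integer(min_pts))
  out <- list()
  prev <- NULL
  for (e in seq_along(epsilons)) {
    labels <- lab[, e]
    sig <- canonical_partition(labels)
    if (!is.null(prev) && identical(sig, prev)) next
    prev <- sig
    for (cl in setdiff(unique(labels), 0L)) {
      members <- which(labels == cl)
      if (length(members) < min_cluster_size) next
      out[[length(out) + 1L]] <- list(members = members,
                                      epsilon = epsilons[e])
    }
  }
  out
}

# Canonical label vector: clusters renumbered by first occurrence so two
# clusterings compare as partitions.
canonical_partition <- function(labels) {
  pos <- labels != 0L
  u <- unique(labels[pos])
  labels[pos] <- match(labels[pos], u)
  labels
}

# Axis-aligned intersection ellipse of a candidate: centre at the member
# mean, semi-axes 3 * max(0.5, sd_i).
intersection_ellipse <- function(members, points) {
  p <- points[members, , drop = FALSE]
  ellipse(colMeans(p), 3 * pmax(0.5, apply(p, 2, sd)))
}

#' Isolation test over candidate clusters
#'
#' Candidates produced by the same epsilon are compared pairwise through
#' their intersection ellipses (centre = member mean, semi-axes
#' `3 * max(0.5, sd)` per axis). A candidate whose ellipse lies within
#' another's, or whose ellipse partially overlaps another's, is excluded;
#' an ellipse that strictly contains another survives.
#'
#' @param candidates Output of [dbscan_sweep()].
#' @param dist The originating [pair_distribution()].
#' @return The retained candidates.
#' @export
isolation_test <- function(candidates, dist) {
  if (!length(candidates)) return(candidates)
  pts <- dist_points(dist)
  eps_of <- vapply(candidates, function(cc) cc$epsilon, numeric(1))
  ells <- lapply(candidates, function(cc)
    intersection_ellipse(cc$members, pts))
  drop <- rep(FALSE, length(candidates))
  for (e in unique(eps_of)) {
    grp <- which(eps_of == e)
    if (length(grp) < 2) next
    for (ii in seq_along(grp)) for (jj in seq_along(grp)) {
      if (ii == jj) next
      rel <- ellipse_relation(ells[[grp[ii]]], ells[[grp[jj]]])
      if (rel == "a_in_b" || rel == "crossing") drop[grp[ii]] <- TRUE
    }
  }
  candidates[!drop]
}

#' Expand a candidate to a Stage 1 cluster
#'
#' Builds a flat (axis-aligned) bounding ellipse with centre at the
#' candidate mean and semi-axes `4 * sd` per axis, and assigns every
#' distribution point inside the ellipse to the Stage 1 cluster. The flat
#' ellipse keeps the subsequent correlation test unbiased.
#'
#' @param candidate A candidate from [dbscan_sweep()].
#' @param dist The originating [pair_distribution()].
#' @return List of class `"cluster_stage1"` with `members`, `ellipse`,
#'   `epsilon` and `core_members`.
#' @export
expand_stage1 <- function(candidate, dist) {
  pts <- dist_points(dist)
  p <- pts[candidate$members, , drop = FALSE]
  sds <- apply(p, 2, sd)
  if (any(sds == 0)) stop("zero variance on an axis: cluster rejected")
  ell <- ellipse(colMeans(p), 4 * sds)
  structure(list(members = which(in_ellipse(pts, ell)), ellipse = ell,
                 epsilon = candidate$epsilon,
                 core_members = candidate$members),
            class = "cluster_stage1")
}

#' Bootstrap-averaged mean and covariance of a point cloud
#'
#' Each resample draws n points with replacement and computes the sample
#' mean and covariance (principal-axis form); the per-resample moments are
#' averaged element-wise. Deterministic for a fixed seed.
#'
#' @param points n x 2 matrix, n >= 3.
#' @param n_boot Number of resamples (default 10000).
#' @param seed Integer seed.
#' @return List with `mean` (length 2), `cov` (2 x 2) and `samples` (the
#'   per-resample moments, for angle estimation).
#' @export
bootstrap_ellipse <- function(points, n_boot = 10000, seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  bs <- with_seed(seed, boot_moments(points, n_boot))
  cv <- matrix(c(mean(bs$cxx), mean(bs$cxy), mean(bs$cxy), mean(bs$cyy)),
               2, 2)
  if (max(abs(cv)) <= 0) stop("degenerate averaged covariance")
  list(mean = c(mean(bs$mx), mean(bs$my)), cov = cv, samples = bs)
}

# Angle estimate from stored bootstrap moments (doubled-angle convention).
angle_from_samples <- function(bs) {
  dbl <- (2 * pc1_angle_deg(bs$cxx, bs$cyy, bs$cxy)) %% 360
  est <- circular_summary(dbl)
  theta <- (est$mean / 2) %% 180
  structure(list(theta = theta, theta45 = fold45(theta),
                 ci_low = est$lo / 2, ci_high = est$hi / 2,
                 n_boot = length(dbl), boot_theta = dbl / 2),
            class = "angle_estimate")
}

#' Refine a Stage 1 cluster into an angled Stage 2 cluster
#'
#' Three successive rounds of [bootstrap_ellipse()]: each round's averaged
#' mean and covariance define an angled ellipse (rotation = first principal
#' axis, semi-axes `4 * sqrt(eigenvalue)`); membership is re-selected from
#' the full distribution inside the intermediate ellipse before the next
#' round. The final (round 3) ellipse defines the Stage 2 membership, and
#' the round-3 bootstrap samples give the cluster's angle estimate.
#' Intended for Stage 1 clusters already found correlated at p < 0.005.
#'
#' @param stage1 A [expand_stage1()] result.
#' @param dist The originating [pair_distribution()].
#' @param seed Integer seed (rounds use `seed`, `seed + 1`, `seed + 2`).
#' @param n_boot Resamples per round (default 10000).
#' @return List of class `"cluster_stage2"` with `members`, `ellipse`,
#'   `angle` (an angle estimate), `mean`, `cov`, `epsilon` and provenance.
#' @export
stage2_cluster <- function(stage1, dist, seed = 1, n_boot = 10000) {
  pts <- dist_points(dist)
  members <- stage1$members
  be <- NULL
  for (round in 1:3) {
    if (length(members) < 3) stop("intermediate membership below 3")
    be <- bootstrap_ellipse(pts[members, , drop = FALSE], n_boot,
                            seed + round - 1L)
    ell <- ellipse_from_moments(be$mean, be$cov, scale = 4)
    members <- which(in_ellipse(pts, ell))
  }
  structure(list(members = members,
                 ellipse = ellipse_from_moments(be$mean, be$cov, 4),
                 angle = angle_from_samples(be$samples),
                 mean = be$mean, cov = be$cov,
                 epsilon = stage1$epsilon,
                 stage1_members = stage1$members,
                 distribution_id = dist$id),
            class = "cluster_stage2")
}

#' Similarity filter over Stage 2 clusters of one distribution
#'
#' Working in order of increasing originating epsilon, drops any angled
#' cluster sharing at least `min_shared` members with an earlier kept one.
#' With `enforce_unique = TRUE` (the pipeline default) at most one Stage 2
#' cluster survives per distribution (the earliest).
#'
#' @param clusters List of [stage2_cluster()] results from one
#'   distribution.
#' @param min_shared Shared-member threshold (default 15).
#' @param enforce_unique Keep only the earliest survivor (default TRUE).
#' @return The retained clusters.
#' @export
similarity_filter <- function(clusters, min_shared = 15,
                              enforce_unique = TRUE) {
  if (length(clusters) <= 1)
    return(clusters)
  ord <- order(vapply(clusters, function(cl) cl$epsilon, numeric(1)))
  clusters <- clusters[ord]
  kept <- list()
  for (cl in clusters) {
    dup <- any(vapply(kept, function(k)
      length(intersect(k$members, cl$members)) >= min_shared, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- cl
  }
  if (enforce_unique && length(kept) > 1) kept <- kept[1]
  kept
}

#' Gaussian-mixture clustering of a response distribution
#'
#' Comparison variant of the density-based pipeline. The standard variant
#' fits Gaussian mixtures with 1-10 components (full covariance) and picks
#' the component count by BIC; each component is returned as a cluster. The
#' custom variant additionally applies the main pipeline's isolation test,
#' Stage 1 expansion, correlation gate (p < 0.005) and Stage 2 refinement,
#' so that its output obeys the same per-distribution uniqueness.
#'
#' @param dist A [pair_distribution()].
#' @param variant `"standard"` or `"custom"`.
#' @param seed Integer seed (used by the Stage 2 bootstrap in the custom
#'   variant).
#' @param n_boot Stage 2 bootstrap resamples (custom variant).
#' @param max_components Maximum mixture size (default 10).
#' @return For `"standard"`: list of candidate clusters (`members`,
#'   `epsilon = NA`) with attribute `G` (chosen component count). For
#'   `"custom"`: list of [stage2_cluster()] results (possibly empty).
#' @export
gmm_cluster <- function(dist, variant = c("standard", "custom"), seed = 1,
                        n_boot = 10000, max_components = 10) {
  variant <- match.arg(variant)
  pts <- dist_points(dist)
  fit <- with_seed(seed, {
    bic <- mclust::mclustBIC(pts, G = 1:max_components,
                             modelNames = "VVV", verbose = FALSE)
    mclust::summaryMclustBIC(bic, pts)
  })
  if (is.null(fit$G)) stop("mixture fit failed at all component counts")
  cand <- lapply(seq_len(fit$G), function(g)
    list(members = which(fit$classification == g), epsilon = NA_real_))
  cand <- Filter(function(cc) length(cc$members) >= 3, cand)
  if (variant == "standard") {
    attr(cand, "G") <- fit$G
    return(cand)
  }
  cand <- isolation_test(cand, dist)
  out <- list()
  for (cc in cand) {
    s1 <- tryCatch(expand_stage1(cc, dist), error = function(e) NULL)
    if (is.null(s1) || length(s1$members) < 3) next
    ct <- tryCatch(linear_correlation(pts[s1$members, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(ct) || ct$p >= 0.005) next
    s2 <- tryCatch(stage2_cluster(s1, dist, seed, n_boot),
                   error = function(e) NULL)
    if (!is.null(s2)) out[[length(out) + 1L]] <- s2
  }
  similarity_filter(out)
}

#' Extract Stage 1 clusters from one response distribution
#'
#' Convenience wrapper chaining [dbscan_sweep()], [isolation_test()] and
#' [expand_stage1()], attaching each cluster's correlation test.
#'
#' @inheritParams dbscan_sweep
#' @return List of Stage 1 clusters; each carries a `correlation` element
#'   (a [linear_correlation()] result over its members).
#' @export
extract_stage1 <- function(dist, epsilons = seq(0.4, 5.0, by = 0.05),
                           min_cluster_size = 30, min_pts = 5) {
  cand <- dbscan_sweep(dist, epsilons, min_cluster_size, min_pts)
  cand <- isolation_test(cand, dist)
  pts <- dist_points(dist)
  out <- list()
  for (cc in cand) {
    s1 <- tryCatch(expand_stage1(cc, dist), error = function(e) NULL)
    if (is.null(s1)) next
    s1$correlation <- tryCatch(
      linear_correlation(pts[s1$members, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(s1$correlation)) next
    out[[length(out) + 1L]] <- s1
  }
  out
}

#' Extract the unique Stage 2 cluster of a response distribution
#'
#' Runs the full two-stage pipeline on one distribution: Stage 1
#' extraction, the p < 0.005 correlation gate, Stage 2 bootstrap
#' refinement, and the similarity filter.
#'
#' @inheritParams dbscan_sweep
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples per round (default 10000).
#' @param first_only Stop at the first surviving cluster (default TRUE).
#'   Under the per-distribution uniqueness rule the survivor is the
#'   correlated Stage 1 cluster of lowest epsilon whose refinement
#'   succeeds, so later refinements need not be computed; set FALSE to
#'   refine every correlated Stage 1 cluster and apply the
#'   shared-membership filter explicitly.
#' @return List of surviving [stage2_cluster()] objects (length 0 or 1
#'   when unique).
#' @export
extract_stage2 <- function(dist, epsilons = seq(0.4, 5.0, by = 0.05),
                           min_cluster_size = 30, min_pts = 5, seed = 1,
                           n_boot = 10000, first_only = TRUE) {
  s1 <- extract_stage1(dist, epsilons, min_cluster_size, min_pts)
  s2 <- list()
  for (i in seq_along(s1)) {
    if (s1[[i]]$correlation$p >= 0.005) next
    cl <- tryCatch(stage2_cluster(s1[[i]], dist, seed + i, n_boot),
                   error = function(e) NULL)
    if (!is.null(cl)) {
      s2[[length(s2) + 1L]] <- cl
      if (first_only) break
    }
  }
  similarity_filter(s2)
}
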