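#' Shuffled-pairs surrogate (derangement)
#'
#' Destroys the within-trial pairing of a response distribution while
#' preserving both marginal latency multisets exactly: the y-axis margin is
#' permuted by a random derangement, so every spike time of one neuron is
#' matched with a *different* trial's spike time of the other neuron.
#'
#' @param dist A [pair_distribution()] with at least 2 conjunctive trials.
#' @param seed Integer seed.
#' @return A new [pair_distribution()].
#' @export
shuffle_pairs <- function(dist, seed) {
  n <- n_conjunctive(dist)
  if (n < 2) stop("a derangement needs at least 2 conjunctive trials")
  perm <- with_seed(seed, random_derangement(n))
  pair_distribution(dist$neuron_ids, dist$condition, dist$trials,
                    dist$s0, dist$s1[perm], meta = dist$meta,
                    id = paste0(dist$id, "#shuffled"))
}

# Uniform random derangement by rejection sampling (expected ~e tries).
random_derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Independent-Gaussian surrogate
#'
#' Replaces the distribution by the same number of samples drawn from an
#' independent bivariate normal with each margin's mean and standard
#' deviation matching the source. Off-diagonal covariance is zero by
#' construction.
#'
#' @param dist A [pair_distribution()] with at least 2 points.
#' @param seed Integer seed.
#' @return A new [pair_distribution()] on the same trial indices.
#' @export
gaussian_surrogate <- function(dist, seed) {
  n <- n_conjunctive(dist)
  if (n < 2) stop("need at least 2 source points")
  m0 <- mean(dist$s0); m1 <- mean(dist$s1)
  sd0 <- sd(dist$s0); sd1 <- sd(dist$s1)
  xy <- with_seed(seed, cbind(draw_windowed(rep(m0, n), max(sd0, 1e-9)),
                              draw_windowed(rep(m1, n), max(sd1, 1e-9))))
  ok <- complete.cases(xy)
  pair_distribution(dist$neuron_ids, dist$condition, dist$trials[ok],
                    xy[ok, 1], xy[ok, 2], meta = dist$meta,
                    id = paste0(dist$id, "#gaussian"))
}

# Correlated bivariate normal with equal marginal sds => PC1 at exactly 45
# degrees. Draws are clipped to the analysis window by redraw-then-drop.
draw_45_gaussian <- function(n, centre, sd_marg, rho = 0.7) {
  rho <- min(max(rho, 0.05), 0.95)
  a <- sd_marg * sqrt(rho)        # shared-component gain
  e <- sd_marg * sqrt(1 - rho)    # independent residual sd
  eta <- rnorm(n)
  x <- draw_windowed(centre[1] + a * eta, e)
  y <- draw_windowed(centre[2] + a * eta, e)
  cbind(x, y)
}

#' 45-degree replacement surrogate
#'
#' Removes every sample within a circle of radius `6 * sigma_bar` of the
#' Stage 2 cluster mean (`sigma_bar` = mean of the two neurons' cluster
#' latency standard deviations) and inserts the same number of samples drawn
#' from a bivariate Gaussian whose first principal component lies at exactly
#' 45 degrees (equal marginal sds `sigma_bar`, positive correlation).
#' Used to calibrate the rate at which the pipeline finds angles
#' significantly different from 45 degrees when the truth is 45 degrees.
#'
#' @param cluster A Stage 2 cluster (see [stage2_cluster()]).
#' @param dist The originating [pair_distribution()].
#' @param seed Integer seed.
#' @param rho Correlation of the replacement Gaussian (default: the
#'   cluster's own Pearson r, clamped to (0.05, 0.95)).
#' @return A new [pair_distribution()].
#' @export
forty_five_control <- function(cluster, dist, seed, rho = NULL) {
  mem <- cluster$members
  if (!length(mem)) stop("empty cluster")
  pts <- dist_points(dist)
  ctr <- colMeans(pts[mem, , drop = FALSE])
  sds <- apply(pts[mem, , drop = FALSE], 2, sd)
  sigma_bar <- mean(sds)
  radius <- 6 * sigma_bar
  inside <- which(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
                  <= radius)
  if (is.null(rho)) {
    rho <- suppressWarnings(cor(pts[mem, 1], pts[mem, 2]))
    if (!is.finite(rho)) rho <- 0.7
  }
  repl <- with_seed(seed,
                    draw_45_gaussian(length(inside), ctr, sigma_bar, rho))
  keep <- setdiff(seq_len(nrow(pts)), inside)
  ok <- complete.cases(repl)
  # Replacement samples take over the removed trials' indices.
  trials <- c(dist$trials[keep], dist$trials[inside][ok])
  s0 <- c(pts[keep, 1], repl[ok, 1])
  s1 <- c(pts[keep, 2], repl[ok, 2])
  o <- order(trials)
  out <- pair_distribution(dist$neuron_ids, dist$condition, trials[o],
                           s0[o], s1[o], meta = dist$meta,
                           id = paste0(dist$id, "#45"))
  attr(out, "radius") <- radius
  attr(out, "n_replaced") <- sum(ok)
  attr(out, "n_removed") <- length(inside)
  out
}

#' Distractor-cluster surrogate
#'
#' Builds a fresh two-cluster response distribution from a Stage 2 cluster:
#' a 45-degree Gaussian at the original cluster mean (marginal sds equal to
#' the mean of the two neurons' original sds), plus an uncorrelated Gaussian
#' of the original per-axis sds centred to the right on a 15-degree ray,
#' with x offset `10 * sd_x`. Each cloud has as many samples as the original
#' cluster. Calibrates angle estimation in the presence of a second,
#' uncorrelated cluster.
#'
#' @param cluster A Stage 2 cluster.
#' @param dist The originating [pair_distribution()].
#' @param seed Integer seed.
#' @param rho Correlation of the 45-degree cloud (default 0.7).
#' @return A new [pair_distribution()] with `2 * n` points on synthetic
#'   trial indices.
#' @export
distractor_control <- function(cluster, dist, seed, rho = 0.7) {
  mem <- cluster$members
  if (!length(mem)) stop("empty cluster")
  pts <- dist_points(dist)[mem, , drop = FALSE]
  ctr <- colMeans(pts)
  sds <- apply(pts, 2, sd)
  if (sds[1] <= 0) stop("zero x-variance cluster")
  n <- nrow(pts)
  off_x <- 10 * sds[1]
  d_ctr <- c(ctr[1] + off_x, ctr[2] + off_x * tan(15 * pi / 180))
  xy <- with_seed(seed, {
    first <- draw_45_gaussian(n, ctr, mean(sds), rho)
    second <- cbind(draw_windowed(rep(d_ctr[1], n), sds[1]),
                    draw_windowed(rep(d_ctr[2], n), sds[2]))
    rbind(first, second)
  })
  ok <- complete.cases(xy)
  pair_distribution(dist$neuron_ids, dist$condition,
                    seq_len(sum(ok)) - 1L, xy[ok, 1], xy[ok, 2],
                    meta = dist$meta, id = paste0(dist$id, "#distractor"))
}
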