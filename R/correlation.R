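#' Linear correlation of a point cloud
#'
#' Pearson r, r-squared and the two-sided p-value of the slope t-test from a
#' least-squares fit of `s1` on `s0` (equal to the Pearson correlation
#' test).
#'
#' @param points n x 2 matrix of (s0, s1) points, n >= 3.
#' @return A list of class `"correlation_result"` with `r`, `r2`, `p`,
#'   `slope` and `n`.
#' @export
linear_correlation <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  if (var(x) == 0) stop("zero variance on x")
  if (var(y) == 0)
    return(correlation_result(0, 1, n, slope = 0))
  ct <- cor.test(x, y)
  correlation_result(unname(ct$estimate), ct$p.value, n,
                     slope = cov(x, y) / var(x))
}

correlation_result <- function(r, p, n, slope = NA_real_) {
  structure(list(r = r, r2 = r * r, p = p, n = n, slope = slope),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f (r2 = %.4f), p = %.3g, n = %d\n",
              x$r, x$r2, x$p, x$n))
  invisible(x)
}

#' Fisher's combination of independent p-values
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return List with `chi2 = -2 * sum(log(p))`, `df = 2 * N` and the
#'   combined `p`.
#' @export
fisher_combine <- function(p_values) {
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

# First-principal-component angle of a 2 x 2 covariance, in degrees within
# [0, 180). For an isotropic matrix the angle is undefined (NA).
pc1_angle_deg <- function(cxx, cyy, cxy, tol = 0) {
  num <- 2 * cxy
  den <- cxx - cyy
  ang <- 0.5 * atan2(num, den) * 180 / pi   # in (-90, 90]
  ang <- ang %% 180
  if (tol > 0) ang[abs(num) <= tol & abs(den) <= tol] <- NA_real_
  ang
}

#' Bootstrap estimate of a point cloud's first-principal-component angle
#'
#' Per bootstrap resample (with replacement, same n) the first principal
#' component of the sample covariance is computed; components with negative
#' y are negated so all angles lie in `[0, 180)`. Angles are doubled into
#' `[0, 360)` to remove the 0/180 discontinuity, the resultant (circular)
#' mean vector is taken, and the mean is halved back. The 95% empirical
#' confidence interval is formed from the 2.5% and 97.5% order statistics of
#' the doubled angles (expressed as deviations from the circular mean so the
#' interval is well-defined near the discontinuity), halved back to angle
#' scale.
#'
#' @param points n x 2 matrix, n >= 3.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return A list of class `"angle_estimate"`: `theta` (deg in `[0,180)`),
#'   `theta45 = min(theta, 90 - theta)`, `ci_low`, `ci_high`, `n_boot`, and
#'   the bootstrap angle samples (`boot_theta`, deg).
#' @export
bootstrap_angle <- function(points, n_boot = 10000, seed = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  cv <- cov(points)
  if (abs(cv[1, 1] - cv[2, 2]) < 1e-12 && abs(cv[1, 2]) < 1e-12)
    stop("isotropic covariance: angle undefined")
  bs <- with_seed(seed, boot_moments(points, n_boot))
  dbl <- (2 * pc1_angle_deg(bs$cxx, bs$cyy, bs$cxy)) %% 360
  est <- circular_summary(dbl)
  theta <- (est$mean / 2) %% 180
  structure(list(theta = theta, theta45 = fold45(theta),
                 ci_low = est$lo / 2, ci_high = est$hi / 2,
                 n_boot = n_boot, boot_theta = dbl / 2),
            class = "angle_estimate")
}

# Vectorised bootstrap first and second moments of a 2-column matrix.
boot_moments <- function(points, n_boot) {
  n <- nrow(points)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  x <- matrix(points[, 1][idx], n_boot, n)
  y <- matrix(points[, 2][idx], n_boot, n)
  mx <- rowMeans(x); my <- rowMeans(y)
  # ML (1/n) covariances; the scale cancels in the angle.
  list(mx = mx, my = my,
       cxx = rowMeans(x * x) - mx * mx,
       cyy = rowMeans(y * y) - my * my,
       cxy = rowMeans(x * y) - mx * my)
}

# Circular mean and 95% deviation quantiles of angles given in degrees on a
# 360-degree circle.
circular_summary <- function(deg, probs = c(0.025, 0.975)) {
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  m <- m %% 360
  dev <- ((deg - m + 180) %% 360) - 180
  q <- quantile(dev, probs, names = FALSE, type = 1)
  list(mean = m, lo = m + q[1], hi = m + q[2])
}

fold45 <- function(theta) {
  th <- theta %% 180
  pmin(th, 90 - th)
}

#' @export
print.angle_estimate <- function(x, ...) {
  cat(sprintf("theta = %.2f deg (theta45 = %.2f), 95%% CI [%.2f, %.2f], %d bootstrap samples\n",
              x$theta, x$theta45, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' One-sided empirical angle significance against 0 or 45 degrees
#'
#' For a positively correlated cluster (`theta` in (0, 90)):
#' the 0-degree test counts bootstrap samples whose folded angle
#' `min(theta, 90 - theta)` is at or below 0 (i.e. the sample crossed the
#' 0/90-degree boundary); the 45-degree test counts samples on the far side
#' of 45 degrees from the estimate.
#'
#' @param estimate An [bootstrap_angle()] result.
#' @param boundary 0 or 45 (degrees).
#' @param side For the 45-degree test: `"auto"` (default) counts bootstrap
#'   samples on the far side of 45 from the estimate, so either neuron
#'   ordering can reach significance (the folded statistic makes both
#'   crossing directions equivalent; the chance rate for an exactly-45
#'   cloud is then about twice the threshold); `"below"` is the
#'   fixed-direction test counting samples at or above 45 only, whose
#'   chance rate at threshold 0.025 is the nominal 2.5% — the variant used
#'   for surrogate calibration.
#' @return One-sided empirical p (fraction of bootstrap samples at or
#'   beyond the boundary).
#' @export
angle_significance <- function(estimate, boundary = c(0, 45),
                               side = c("auto", "below")) {
  boundary <- match.arg(as.character(boundary[1]), c("0", "45"))
  side <- match.arg(side)
  theta_hat <- estimate$theta
  if (!(theta_hat > 0 && theta_hat < 90))
    stop("theta45 significance defined for positively correlated clusters only")
  bt <- estimate$boot_theta %% 180
  if (boundary == "0") {
    mean(fold45(bt) <= 0)
  } else if (side == "below") {
    mean(bt >= 45 & bt < 135)
  } else {
    if (theta_hat <= 45) mean(bt >= 45 & bt < 135) else
      mean(bt <= 45 | bt >= 135)
  }
}

#' Henze-Zirkler test of multivariate normality
#'
#' Standard Henze-Zirkler statistic with the usual data-driven bandwidth and
#' a log-normal approximation to its null distribution.
#'
#' @param points n x p data matrix, n >= 10.
#' @return List with `hz` (statistic) and `p`.
#' @export
henze_zirkler <- function(points) {
  x <- as.matrix(points)
  n <- nrow(x); p <- ncol(x)
  if (n < 10) stop("Henze-Zirkler not assessable below n = 10")
  S <- cov(x) * (n - 1) / n
  if (det(S) <= .Machine$double.eps) stop("degenerate covariance")
  Si <- solve(S)
  ctr <- sweep(x, 2, colMeans(x))
  G <- ctr %*% Si %*% t(ctr)            # cross Mahalanobis products
  d <- diag(G)
  Dij <- outer(d, d, "+") - 2 * G       # squared pairwise distances
  Dij[Dij < 0] <- 0
  b <- (n * (2 * p + 1) / 4)^(1 / (p + 4)) / sqrt(2)
  b2 <- b^2
  t1 <- sum(exp(-b2 / 2 * Dij)) / n
  t2 <- 2 * (1 + b2)^(-p / 2) * sum(exp(-b2 / (2 * (1 + b2)) * d))
  hz <- t1 - t2 + n * (1 + 2 * b2)^(-p / 2)
  # Log-normal approximation of the null distribution.
  wb <- (1 + b2) * (1 + 3 * b2)
  a <- 1 + 2 * b2
  mu <- 1 - a^(-p / 2) * (1 + p * b2 / a + p * (p + 2) * b2^2 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b2^2 / a^2 + 3 * p * (p + 2) * b2^4 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b2^2 / (2 * wb) +
                         p * (p + 2) * b2^4 / (2 * wb^2))
  pmu <- sqrt(mu^4 / (si2 + mu^2))
  psi <- sqrt(log((si2 + mu^2) / mu^2))
  pval <- plnorm(hz, log(pmu), psi, lower.tail = FALSE)
  list(hz = hz, p = pval)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity; the
#' standard pre-test before fitting a factor model.
#'
#' @param points n x p data matrix.
#' @return List with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(points) {
  x <- as.matrix(points)
  n <- nrow(x); p <- ncol(x)
  R <- cor(x)
  detR <- det(R)
  if (detR <= 0) detR <- .Machine$double.xmin
  chi2 <- -((n - 1) - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Trial-index regressions of a cluster's latencies
#'
#' Per-neuron linear regression of latency on trial index, plus the
#' multi-output r-squared of predicting both latencies jointly from trial
#' index (1 - pooled SSE / pooled SST).
#'
#' @param points n x 2 latency matrix.
#' @param trials Trial indices (same length).
#' @return List with `per_neuron` (list of two
#'   [linear_correlation()]-style results of latency vs trial) and
#'   `multi_r2`.
#' @export
trial_regressions <- function(points, trials) {
  points <- as.matrix(points)
  if (var(trials) == 0) stop("constant trial vector")
  per <- lapply(1:2, function(i)
    linear_correlation(cbind(trials, points[, i])))
  sse <- 0; sst <- 0
  for (i in 1:2) {
    fit <- lm(points[, i] ~ trials)
    sse <- sse + sum(residuals(fit)^2)
    sst <- sst + sum((points[, i] - mean(points[, i]))^2)
  }
  list(per_neuron = per, multi_r2 = 1 - sse / sst)
}

#' Correlation of the first neuron's latency with the pair difference
#'
#' Regresses `s1 - s0` on `s0`. Under a fixed-difference model
#' (`s1 = s0 + d + independent noise` with the difference constant) there is
#' no correlation; a 45-degree cluster produces rejections at the nominal
#' rate only.
#'
#' @param points n x 2 latency matrix, n >= 3.
#' @return A [linear_correlation()] result (r set to 0 with p = 1 when the
#'   difference has zero variance).
#' @export
diff_vs_first_spike <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  d <- points[, 2] - points[, 1]
  # a numerically constant difference is the fixed-difference null itself
  if (sd(d) <= 1e-8 * max(1, sd(points[, 1])))
    return(correlation_result(0, 1, nrow(points), slope = 0))
  linear_correlation(cbind(points[, 1], d))
}

#' Trial-lagged cross-correlation of two latency series
#'
#' Aligns series `a` on trials `t` with series `b` on trials `t + lag` over
#' the trials present in both, and reports the Pearson correlation.
#'
#' @param series_a,series_b Numeric vectors indexed by `trials_a`,
#'   `trials_b`.
#' @param trials_a,trials_b Trial indices of the two series.
#' @param lag Integer trial lag (default 1).
#' @return A [linear_correlation()] result.
#' @export
cross_correlation <- function(series_a, series_b, trials_a, trials_b,
                              lag = 1) {
  target <- trials_a + lag
  i <- match(target, trials_b)
  ok <- !is.na(i)
  if (sum(ok) < 3) stop("fewer than 3 overlapping lagged trials")
  linear_correlation(cbind(series_a[ok], series_b[i[ok]]))
}
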