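#' Fit the single-factor model of shared excitability to a cluster
#'
#' Models the zero-centred cluster latencies as `s_i = lambda_i * eta +
#' noise_i` with a standard-normal per-trial state `eta` shared by the two
#' neurons. With only two indicators the model with free residual variances
#' is not identified (four parameters against three second moments), so the
#' fit imposes equal residual variances, which gives the closed-form
#' maximum-likelihood solution: residual variance = smaller eigenvalue of
#' the sample covariance, loadings along the first principal axis with
#' squared length equal to the eigenvalue gap. The implied covariance
#' reproduces the sample covariance exactly. Per-trial state scores use the
#' regression method. The model-predicted spread of state-conditioned
#' latency differences is `sigma_diff = sqrt(sigma0^2 + sigma1^2)`.
#'
#' @param points n x 2 latency matrix of the cluster members.
#' @param trials Optional trial indices attached to the scores.
#' @param check_gates Require the factor-analysis gates (Bartlett
#'   sphericity rejected at p < 0.05; exactly one correlation-matrix
#'   eigenvalue > 1) before fitting (default TRUE).
#' @return List of class `"factor_model"`: `lambda0`, `lambda1` (ms per
#'   state unit, both non-negative for positively correlated clusters),
#'   `sigma0`, `sigma1` (ms), `sigma_diff`, `eta` (per-trial scores,
#'   mean approximately 0), `trials`, `centre`, `score_method`.
#' @export
fit_single_factor <- function(points, trials = NULL, check_gates = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points")
  if (check_gates) {
    bs <- bartlett_sphericity(points)
    if (!is.finite(bs$p) || bs$p >= 0.05)
      stop("factor-analysis gate failed: sphericity not rejected")
    ev <- eigen(cor(points), symmetric = TRUE, only.values = TRUE)$values
    if (sum(ev > 1) != 1)
      stop("factor-analysis gate failed: not a single dominant factor")
  }
  ctr <- colMeans(points)
  cv <- cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  e1 <- eg$values[1]; e2 <- eg$values[2]
  if (e2 < 0) stop("Heywood case: negative residual variance")
  v1 <- eg$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1        # orient loadings non-negative
  lambda <- v1 * sqrt(max(e1 - e2, 0))
  sigma <- sqrt(e2)
  centred <- sweep(points, 2, ctr)
  # Regression-method factor scores: eta = lambda' Sigma^-1 (s - mean).
  eta <- as.numeric(centred %*% solve(cv, lambda))
  structure(list(lambda0 = lambda[1], lambda1 = lambda[2],
                 sigma0 = sigma, sigma1 = sigma,
                 sigma_diff = sqrt(2) * sigma, eta = eta,
                 trials = trials, centre = ctr, cov = cv,
                 score_method = "regression"),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Single-factor model: lambda = (%.3f, %.3f) ms/state, sigma = (%.3f, %.3f) ms, sigma_diff = %.3f ms\n",
              x$lambda0, x$lambda1, x$sigma0, x$sigma1, x$sigma_diff))
  invisible(x)
}

#' Bootstrap angle of the factor loading direction
#'
#' Angle of the fitted loading vector `(lambda0, lambda1)` with the +x
#' axis, bootstrapped over cluster resamples with the same doubled-angle
#' convention as [bootstrap_angle()]. For this two-indicator fit the
#' loading direction coincides with the first principal axis.
#'
#' @param points Cluster latency matrix the model was fitted to.
#' @param n_boot Resamples (default 10000).
#' @param seed Integer seed.
#' @return An angle estimate (see [bootstrap_angle()]).
#' @export
factor_angle <- function(points, n_boot = 10000, seed = 1) {
  bootstrap_angle(points, n_boot = n_boot, seed = seed)
}

#' Loading angle of a fitted factor model
#'
#' @param model A [fit_single_factor()] result.
#' @return Angle in degrees in `[0, 180)`.
#' @export
loading_angle <- function(model) {
  if (abs(model$lambda0) < 1e-12 && abs(model$lambda1) < 1e-12)
    stop("both loadings are zero: angle undefined")
  (atan2(model$lambda1, model$lambda0) * 180 / pi) %% 180
}

#' Relative-difference spread under the three coding regimes
#'
#' RDR 1: sd of `s1 - s0` over all conjunctive pairs of the response
#' distribution. RDR 2: sd of `s1 - s0` within the (stationary or
#' detrended) cluster. RDR 3: the factor-model prediction of the
#' state-conditioned difference spread, `sqrt(sigma0^2 + sigma1^2)`.
#'
#' @param dist The originating [pair_distribution()].
#' @param cluster_points n x 2 latency matrix of the cluster (detrended
#'   values when the cluster was made stationary).
#' @param model A [fit_single_factor()] fitted to `cluster_points`.
#' @param min_size Minimum cluster size (default 10).
#' @return List of class `"rdr_summary"` with `rdr1_sigma_diff`,
#'   `rdr2_sigma_diff`, `rdr3_sigma_diff`.
#' @export
rdr_summary <- function(dist, cluster_points, model, min_size = 10) {
  cluster_points <- as.matrix(cluster_points)
  if (nrow(cluster_points) < min_size)
    stop("cluster below minimum size")
  structure(list(
    rdr1_sigma_diff = sd(dist$s1 - dist$s0),
    rdr2_sigma_diff = sd(cluster_points[, 2] - cluster_points[, 1]),
    rdr3_sigma_diff = model$sigma_diff), class = "rdr_summary")
}

#' Predict per-trial cortical state from a cluster
#'
#' Signed scalar projection of each zero-centred spike pair onto the
#' cluster's first principal component, oriented so that both component
#' loadings are non-negative (state then correlates positively with both
#' neurons' latencies for positively correlated clusters).
#'
#' @param points n x 2 latency matrix (cluster members).
#' @param trials Trial indices of the rows.
#' @return List of class `"state_prediction"` with `trials` and `state`.
#' @export
predict_state <- function(points, trials) {
  points <- as.matrix(points)
  cv <- cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 0) stop("degenerate covariance")
  v1 <- eg$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  ctr <- sweep(points, 2, colMeans(points))
  structure(list(trials = as.integer(trials),
                 state = as.numeric(ctr %*% v1)),
            class = "state_prediction")
}

#' Correlation of predicted states of two clusters
#'
#' Pearson correlation of the two clusters' predicted per-trial states
#' over their common trials. Intended for clusters sharing no neuron (4
#' distinct neurons); pairs with fewer than `min_conjunctive` common
#' trials are excluded.
#'
#' @param pred_a,pred_b [predict_state()] results.
#' @param min_conjunctive Inclusion threshold on common trials (default
#'   15).
#' @return A [linear_correlation()] result, or `NULL` when excluded.
#' @export
state_correlation <- function(pred_a, pred_b, min_conjunctive = 15) {
  common <- intersect(pred_a$trials, pred_b$trials)
  if (length(common) < min_conjunctive) return(NULL)
  a <- pred_a$state[match(common, pred_a$trials)]
  b <- pred_b$state[match(common, pred_b$trials)]
  linear_correlation(cbind(a, b))
}

#' Variance explained per component across two disjoint clusters
#'
#' Principal-component decomposition of the 4-dimensional latency matrix
#' of two clusters sharing no neuron, over the trials on which all four
#' neurons spiked. Fractions sum to 1.
#'
#' @param points_a,points_b n x 2 latency matrices of the two clusters.
#' @param trials_a,trials_b Their trial indices.
#' @param min_common Minimum number of common trials (default 5).
#' @return Numeric vector of 4 variance-explained fractions.
#' @export
four_neuron_pca <- function(points_a, trials_a, points_b, trials_b,
                            min_common = 5) {
  common <- intersect(trials_a, trials_b)
  if (length(common) < min_common) stop("fewer than 5 common trials")
  m <- cbind(as.matrix(points_a)[match(common, trials_a), , drop = FALSE],
             as.matrix(points_b)[match(common, trials_b), , drop = FALSE])
  ev <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

#' Spread of a target conditioned on a predicted state
#'
#' Compares the unconditioned standard deviation of a target quantity
#' (single-neuron latencies or pair differences) with the residual sd
#' after least-squares regression of the target on another pair's
#' predicted state over common trials.
#'
#' @param target Numeric target values.
#' @param target_trials Trial indices of the target.
#' @param predictor A [predict_state()] result from a different neuron
#'   pair.
#' @param min_common Minimum common trials (default 10).
#' @return List with `unconditioned_sd`, `conditioned_sd`, `n`.
#' @export
state_conditioned_variability <- function(target, target_trials,
                                          predictor, min_common = 10) {
  common <- intersect(target_trials, predictor$trials)
  if (length(common) < min_common) stop("fewer than 10 common trials")
  y <- target[match(common, target_trials)]
  x <- predictor$state[match(common, predictor$trials)]
  fit <- lm(y ~ x)
  n <- length(common)
  list(unconditioned_sd = sd(y),
       conditioned_sd = sqrt(sum(residuals(fit)^2) / (n - 1)),
       n = n)
}

#' Pool clustered and unclustered correlated examples
#'
#' Builds the analysis pool with exactly one entry per response
#' distribution: when a Stage 2 cluster and a correlated unclustered
#' distribution originate from the same response distribution, the cluster
#' is kept and the unclustered entry removed.
#'
#' @param stage2 List of entries with a `distribution_id` field (Stage 2
#'   clusters).
#' @param unclustered List of entries with a `distribution_id` field.
#' @return Combined list with a `source` attribute per entry
#'   (`"cluster"` or `"unclustered"`).
#' @export
pool_examples <- function(stage2, unclustered) {
  ids <- vapply(stage2, function(x) x$distribution_id, character(1))
  out <- lapply(stage2, function(x) { attr(x, "source") <- "cluster"; x })
  for (u in unclustered) {
    if (u$distribution_id %in% ids) next
    attr(u, "source") <- "unclustered"
    out[[length(out) + 1L]] <- u
  }
  out
}
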