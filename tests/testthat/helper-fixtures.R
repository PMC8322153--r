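# Shared fixtures: all synthetic, built in code at test time.

# Minimal two-neuron session config around a single latent-state cluster.
two_neuron_config <- function(seed, lambda = c(2, 1), sigma = c(0.4, 0.4),
                              mean = c(12, 20), prob = 0.9,
                              reliability = 1, n_trials = 200,
                              frequencies = 1, latency_amp = 0,
                              count_rate = 0, extra_clusters = list()) {
  synthetic_config(
    n_trials = n_trials, frequencies = frequencies,
    neurons = list(neuron_meta(1), neuron_meta(2, "I", "L5A")),
    cluster_specs = list(pair_spec(c(1, 2), c(
      list(list(prob = prob, mean = mean, lambda = lambda,
                sigma = sigma)),
      extra_clusters))),
    adaptation = list(latency_amp = latency_amp, count_rate = count_rate,
                      trials_to_saturation = 20,
                      latency_freq_threshold = 1,
                      count_freq_threshold = 5),
    reliability = reliability, seed = seed)
}

# Two disjoint pairs (4 neurons) driven by the same per-trial state.
four_neuron_config <- function(seed, lambda = c(1, 1), sigma_over_lambda =
                                 0.2, reliability = 0.85,
                               n_trials = 200) {
  mk <- function(ids, means) pair_spec(ids, list(list(
    prob = 0.9, mean = means, lambda = lambda,
    sigma = pmax(lambda * sigma_over_lambda, 1e-3))))
  synthetic_config(
    n_trials = n_trials, frequencies = 1,
    neurons = list(neuron_meta(1), neuron_meta(2, "I", "L5A"),
                   neuron_meta(3, "E", "L5B/6"), neuron_meta(4)),
    cluster_specs = list(mk(c(1, 2), c(12, 18)), mk(c(3, 4), c(15, 22))),
    adaptation = list(latency_amp = 0, count_rate = 0,
                      trials_to_saturation = 20,
                      latency_freq_threshold = 1,
                      count_freq_threshold = 5),
    reliability = reliability, seed = seed)
}

# Elongated Gaussian cloud rotated to a given first-principal-axis angle.
rotated_cloud <- function(n, angle_deg, sds = c(2.5, 0.8),
                          centre = c(20, 20), seed = 1) {
  set.seed(seed)
  th <- angle_deg * pi / 180
  u <- rnorm(n, 0, sds[1])
  v <- rnorm(n, 0, sds[2])
  cbind(centre[1] + u * cos(th) - v * sin(th),
        centre[2] + u * sin(th) + v * cos(th))
}

# Latent single-factor cluster: s_i = mean_i + lambda_i * eta + noise.
latent_cluster <- function(n, lambda, sigma, mean = c(15, 20), seed = 1) {
  set.seed(seed)
  eta <- rnorm(n)
  pts <- cbind(mean[1] + lambda[1] * eta + rnorm(n, 0, sigma[1]),
               mean[2] + lambda[2] * eta + rnorm(n, 0, sigma[2]))
  list(points = pts, eta = eta)
}

# Wrap a point matrix as a pair distribution on consecutive trials.
as_dist <- function(points, trials = seq_len(nrow(points)) - 1L) {
  pair_distribution(c(1, 2), "fixture", trials, points[, 1], points[, 2])
}

first_distribution <- function(config) {
  build_distributions(generate_session(config))[[1]]
}

dist_points_of <- function(d) cbind(d$s0, d$s1)
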