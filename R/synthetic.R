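#' Neuron metadata entry
#'
#' Describes one recorded unit: its identifier, putative excitatory/inhibitory
#' type, cortical layer, barrel-column identifier and whether it lies in a
#' septum (between barrels).
#'
#' @param neuron_id Integer or character unit identifier.
#' @param ei_type `"E"` (excitatory) or `"I"` (inhibitory).
#' @param layer One of `"L2/3"`, `"L4"`, `"L5A"`, `"L5B/6"`.
#' @param column Barrel-column label (e.g. `"C2"`).
#' @param septum Logical; `TRUE` if the unit lies between barrels.
#' @return A list of class `"neuron_meta"`.
#' @export
neuron_meta <- function(neuron_id, ei_type = "E", layer = "L4",
                        column = "C2", septum = FALSE) {
  ei_type <- match.arg(ei_type, c("E", "I"))
  layer <- match.arg(layer, c("L2/3", "L4", "L5A", "L5B/6"))
  structure(list(neuron_id = neuron_id, ei_type = ei_type, layer = layer,
                 column = column, septum = isTRUE(septum)),
            class = "neuron_meta")
}

#' Cluster specification for one neuron pair
#'
#' One pair of neurons responds from a mixture of latency clusters. Each
#' cluster has a per-trial membership probability, mean latencies (ms), gains
#' `lambda` (ms per unit of the shared latent state) and residual standard
#' deviations `sigma` (ms) for the two neurons.
#'
#' @param neurons Length-2 vector of neuron ids (order fixes the x/y axes;
#'   the lower id is plotted on x).
#' @param clusters List of cluster components, each a list with elements
#'   `prob`, `mean` (length 2, ms), `lambda` (length 2, ms/state unit) and
#'   `sigma` (length 2, ms, strictly positive).
#' @return A list of class `"pair_spec"`.
#' @export
pair_spec <- function(neurons, clusters) {
  stopifnot(length(neurons) == 2, length(clusters) >= 1)
  for (cl in clusters) {
    stopifnot(is.numeric(cl$prob), cl$prob >= 0, cl$prob <= 1,
              length(cl$mean) == 2, length(cl$lambda) == 2,
              length(cl$sigma) == 2)
    if (any(cl$sigma <= 0)) stop("all cluster residual sds must be > 0")
  }
  p <- sum(vapply(clusters, function(cl) cl$prob, numeric(1)))
  if (p > 1 + 1e-12)
    stop("cluster membership probabilities must sum to <= 1")
  structure(list(neurons = neurons, clusters = clusters), class = "pair_spec")
}

#' Synthetic session configuration
#'
#' Defines the generative model for a synthetic recording session: blocks of
#' repeated single-whisker deflections at each configured frequency, a shared
#' per-trial latent excitability state modulating both neurons of every
#' configured pair, depressive adaptation concentrated in early trials, and
#' unreliable (0/1 spikes per trial) responses.
#'
#' @param n_trials Trials per stimulus condition (default 200).
#' @param frequencies Stimulation frequencies in Hz (within 0.066-10).
#' @param neurons List of [neuron_meta()] entries.
#' @param cluster_specs List of [pair_spec()] entries; a neuron may appear in
#'   at most one pair.
#' @param adaptation List with `latency_amp` (ms, drift amplitude),
#'   `count_rate` (maximal proportional spike-probability depression),
#'   `trials_to_saturation` (trials by which ~90% of the drift has occurred),
#'   `latency_freq_threshold` and `count_freq_threshold` (Hz; adaptation of
#'   each kind is active only at frequencies at or above its threshold).
#' @param reliability Per-neuron spike probability in (0, 1]; a single value
#'   is recycled, or a vector named by neuron id.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param session Session label.
#' @param whisker Stimulated whisker label.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_trials = 200,
                             frequencies = c(0.1, 1, 4),
                             neurons,
                             cluster_specs,
                             adaptation = list(latency_amp = 2,
                                               count_rate = 0.3,
                                               trials_to_saturation = 20,
                                               latency_freq_threshold = 1,
                                               count_freq_threshold = 5),
                             reliability = 0.8,
                             seed,
                             session = "synthetic-01",
                             whisker = "C2") {
  if (missing(seed)) stop("a seed is mandatory")
  if (length(cluster_specs) == 0) stop("cluster_specs must be non-empty")
  stopifnot(all(frequencies >= 0.066 - 1e-9), all(frequencies <= 10 + 1e-9))
  ids <- vapply(neurons, function(n) as.character(n$neuron_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate neuron ids")
  used <- unlist(lapply(cluster_specs, function(ps) as.character(ps$neurons)))
  if (anyDuplicated(used))
    stop("a neuron may appear in at most one pair spec")
  if (!all(used %in% ids)) stop("pair spec references unknown neuron id")
  rel <- reliability
  if (length(rel) == 1) rel <- setNames(rep(rel, length(ids)), ids)
  if (any(rel <= 0) || any(rel > 1)) stop("reliability must be in (0, 1]")
  ad <- adaptation
  for (f in c("latency_amp", "count_rate", "trials_to_saturation",
              "latency_freq_threshold", "count_freq_threshold"))
    if (is.null(ad[[f]])) stop("adaptation is missing field: ", f)
  structure(list(n_trials = n_trials, frequencies = frequencies,
                 neurons = neurons, cluster_specs = cluster_specs,
                 adaptation = ad, reliability = rel,
                 seed = as.integer(seed), session = session,
                 whisker = whisker),
            class = "synthetic_config")
}

# Evaluate code under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# Saturating-exponential adaptation kernel on 0-based trial index.
# ~90% of the drift occurs within `trials_to_saturation` trials.
adaptation_kernel <- function(trial, trials_to_saturation) {
  tau <- trials_to_saturation / log(10)
  1 - exp(-trial / tau)
}

#' Generate a synthetic session of first-spike records
#'
#' Per trial, a shared standard-normal latent state `eta` modulates both
#' neurons of every configured pair through their gains; cluster membership
#' is drawn per trial from the pair's mixture; latencies outside the
#' analysis window `[0, 50)` ms are re-drawn (noise only) up to 10 times and
#' then dropped; spikes are thinned per neuron by its reliability and, at
#' frequencies at or above the count threshold, by depressive count
#' adaptation. Latency adaptation adds a saturating drift to both neurons at
#' frequencies at or above the latency threshold.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame of spike records with columns `session`, `whisker`,
#'   `frequency_hz`, `trial`, `neuron_id`, `layer`, `ei_type`, `column`,
#'   `septum`, `first_spike_ms`; at most one row per (condition, trial,
#'   neuron). Attributes: `n_trials`, and `eta` (a data.frame of the true
#'   per-trial latent state by condition, for diagnostics).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_session_impl(config))
}

generate_session_impl <- function(config) {
  meta <- do.call(rbind, lapply(config$neurons, function(n)
    data.frame(neuron_id = as.character(n$neuron_id), layer = n$layer,
               ei_type = n$ei_type, column = n$column, septum = n$septum,
               stringsAsFactors = FALSE)))
  rownames(meta) <- meta$neuron_id
  ad <- config$adaptation
  nt <- config$n_trials
  out <- vector("list", 0L)
  eta_log <- vector("list", 0L)
  for (freq in config$frequencies) {
    eta <- rnorm(nt)
    eta_log[[length(eta_log) + 1L]] <-
      data.frame(frequency_hz = freq, trial = seq_len(nt) - 1L, eta = eta)
    lat_adapt <- if (freq >= ad$latency_freq_threshold)
      ad$latency_amp * adaptation_kernel(seq_len(nt) - 1L,
                                         ad$trials_to_saturation)
    else rep(0, nt)
    keep_adapt <- if (freq >= ad$count_freq_threshold)
      1 - ad$count_rate * adaptation_kernel(seq_len(nt) - 1L,
                                            ad$trials_to_saturation)
    else rep(1, nt)
    for (ps in config$cluster_specs) {
      probs <- vapply(ps$clusters, function(cl) cl$prob, numeric(1))
      member <- draw_membership(nt, probs)
      for (i in 1:2) {
        nid <- as.character(ps$neurons[i])
        lat <- rep(NA_real_, nt)
        for (k in seq_along(ps$clusters)) {
          idx <- which(member == k)
          if (!length(idx)) next
          cl <- ps$clusters[[k]]
          lat[idx] <- draw_windowed(
            cl$mean[i] + cl$lambda[i] * eta[idx] + lat_adapt[idx],
            cl$sigma[i])
        }
        keep <- runif(nt) < config$reliability[[nid]] * keep_adapt
        lat[!keep] <- NA_real_
        idx <- which(!is.na(lat))
        if (!length(idx)) next
        out[[length(out) + 1L]] <- data.frame(
          session = config$session, whisker = config$whisker,
          frequency_hz = freq, trial = idx - 1L, neuron_id = nid,
          layer = meta[nid, "layer"], ei_type = meta[nid, "ei_type"],
          column = meta[nid, "column"], septum = meta[nid, "septum"],
          first_spike_ms = lat[idx], stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (length(out)) do.call(rbind, out) else
    data.frame(session = character(), whisker = character(),
               frequency_hz = numeric(), trial = integer(),
               neuron_id = character(), layer = character(),
               ei_type = character(), column = character(),
               septum = logical(), first_spike_ms = numeric())
  rec <- rec[order(rec$frequency_hz, rec$neuron_id, rec$trial), ]
  rownames(rec) <- NULL
  attr(rec, "n_trials") <- nt
  attr(rec, "eta") <- do.call(rbind, eta_log)
  rec
}

# Mixture membership per trial: integer 1..K, or 0 for a non-spiking trial.
draw_membership <- function(n, probs) {
  u <- runif(n)
  edges <- cumsum(probs)
  member <- integer(n)
  for (k in rev(seq_along(probs))) member[u < edges[k]] <- k
  member
}

# Draw latencies mu + N(0, sigma), re-drawing values outside [0, 50) up to
# 10 times, then dropping (NA). Keeps the window rule without distorting
# marginals of well-placed clusters.
draw_windowed <- function(mu, sigma, lo = 0, hi = 50, max_redraw = 10) {
  x <- mu + rnorm(length(mu), sd = sigma)
  for (r in seq_len(max_redraw)) {
    bad <- which(x < lo | x >= hi)
    if (!length(bad)) break
    x[bad] <- mu[bad] + rnorm(length(bad), sd = sigma)
  }
  x[x < lo | x >= hi] <- NA_real_
  x
}

#' Write spike records to a tidy CSV
#'
#' @param records Spike-record data.frame (see [generate_session()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read spike records from CSV
#'
#' @param path CSV with the schema written by [write_session_csv()].
#' @param onset_shift_ms Shift (ms) subtracted from `first_spike_ms` when
#'   the input latencies are stimulus-referenced rather than referenced to
#'   cortical activation onset (conventionally 5.4 ms); default 0.
#' @return Spike-record data.frame restricted to latencies in `[0, 50)` ms.
#' @export
read_session_csv <- function(path, onset_shift_ms = 0) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  rec$neuron_id <- as.character(rec$neuron_id)
  rec$first_spike_ms <- rec$first_spike_ms - onset_shift_ms
  rec <- rec[rec$first_spike_ms >= 0 & rec$first_spike_ms < 50, ]
  rownames(rec) <- NULL
  rec
}

#' Read a synthetic-session configuration from YAML
#'
#' The file holds the fields of [synthetic_config()]; `neurons` is a list of
#' neuron-meta mappings and `cluster_specs` a list of pair mappings. A seed
#' is mandatory.
#'
#' @param path YAML file path.
#' @return A [synthetic_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config file must set a seed")
  neurons <- lapply(y$neurons, function(n)
    neuron_meta(n$neuron_id, n$ei_type %||% "E", n$layer %||% "L4",
                n$column %||% "C2", n$septum %||% FALSE))
  specs <- lapply(y$cluster_specs, function(ps)
    pair_spec(unlist(ps$neurons), lapply(ps$clusters, function(cl)
      list(prob = cl$prob, mean = unlist(cl$mean),
           lambda = unlist(cl$lambda), sigma = unlist(cl$sigma)))))
  args <- list(neurons = neurons, cluster_specs = specs, seed = y$seed)
  for (f in c("n_trials", "frequencies", "adaptation", "reliability",
              "session", "whisker"))
    if (!is.null(y[[f]])) args[[f]] <- if (f == "frequencies" ||
                                           f == "reliability")
      unlist(y[[f]]) else y[[f]]
  do.call(synthetic_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Representative session configuration for calibration ensembles
#'
#' Draws one synthetic two-neuron session configuration from ranges that
#' emulate the heterogeneity of recorded pairwise response distributions:
#' spiking reliability 0.5-0.85 per neuron, one or two latency clusters
#' with residual sds 0.5-1.5 ms, shared-state gains 0.5-1.5 ms per state
#' unit (equal sign, so pairs are positively co-modulated), cluster means
#' spread over the 8-32 ms latency range with at least 6 ms separation, and
#' total spiking probability 0.55-0.9. Blocks of 200 trials at 1 Hz, no
#' adaptation (the stationary baseline); deterministic given the seed.
#'
#' @param seed Integer seed (also the seed of the returned config).
#' @param n_trials Trials per condition (default 200).
#' @param frequency Stimulation frequency in Hz (default 1).
#' @return A [synthetic_config()].
#' @export
random_session_config <- function(seed, n_trials = 200, frequency = 1) {
  draw <- with_seed(seed, {
    k <- sample(1:2, 1)
    total_p <- runif(1, 0.55, 0.9)
    probs <- if (k == 1) total_p else total_p * c(0.6, 0.4)
    m1 <- runif(2, 8, 22)
    m2 <- m1 + sample(c(-1, 1), 2, replace = TRUE) * runif(2, 6, 12)
    m2 <- pmin(pmax(m2, 6), 42)
    clusters <- lapply(seq_len(k), function(j) list(
      prob = probs[j],
      mean = if (j == 1) m1 else m2,
      lambda = runif(2, 0.5, 1.5),
      sigma = runif(2, 0.5, 1.5)))
    list(clusters = clusters, rel = runif(2, 0.5, 0.85))
  })
  synthetic_config(
    n_trials = n_trials, frequencies = frequency,
    neurons = list(neuron_meta(1), neuron_meta(2, "I", "L5A")),
    cluster_specs = list(pair_spec(c(1, 2), draw$clusters)),
    adaptation = list(latency_amp = 0, count_rate = 0,
                      trials_to_saturation = 20,
                      latency_freq_threshold = 1,
                      count_freq_threshold = 5),
    reliability = setNames(draw$rel, c("1", "2")),
    seed = seed)
}
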