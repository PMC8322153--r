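#' Max-normalised post-stimulus time histogram
#'
#' Histogram of first-spike latencies over the `[0, 50)` ms window,
#' smoothed with a Gaussian kernel and divided by its maximum so the peak
#' is exactly 1.
#'
#' @param records Spike-record data.frame.
#' @param neuron_ids Optional subset of neuron ids to pool (default: all).
#' @param bin_width_ms Histogram bin width (default 0.5 ms).
#' @param smoothing_sd_ms Gaussian kernel sd (default 1.5 ms); 0 disables
#'   smoothing.
#' @return Data.frame with `time_ms` (bin centres), `density`
#'   (max-normalised) and `count` (raw per-bin spike count).
#' @export
psth <- function(records, neuron_ids = NULL, bin_width_ms = 0.5,
                 smoothing_sd_ms = 1.5) {
  if (!is.null(neuron_ids))
    records <- records[records$neuron_id %in% neuron_ids, ]
  if (!nrow(records)) stop("empty neuron group")
  edges <- seq(0, 50, by = bin_width_ms)
  centres <- edges[-length(edges)] + bin_width_ms / 2
  counts <- tabulate(findInterval(records$first_spike_ms, edges,
                                  rightmost.closed = FALSE),
                     nbins = length(centres))
  y <- as.numeric(counts)
  if (smoothing_sd_ms > 0) {
    half <- ceiling(4 * smoothing_sd_ms / bin_width_ms)
    kern <- dnorm(seq(-half, half) * bin_width_ms, sd = smoothing_sd_ms)
    kern <- kern / sum(kern)
    padded <- c(rep(0, half), y, rep(0, half))
    y <- vapply(seq_along(y), function(i)
      sum(padded[i:(i + 2 * half)] * kern), numeric(1))
  }
  data.frame(time_ms = centres, density = y / max(y), count = counts)
}

#' Spiking reliability per neuron and stimulus condition
#'
#' Proportion of trials of a stimulus condition on which a neuron spiked at
#' least once.
#'
#' @param records Spike-record data.frame.
#' @param n_trials Trials per condition; if `NULL`, taken from the records'
#'   `n_trials` attribute or inferred as `max(trial) + 1`.
#' @return Data.frame with `neuron_id`, `whisker`, `frequency_hz`,
#'   `n_spiking`, `n_trials`, `reliability` in `[0, 1]`.
#' @export
reliability_histogram <- function(records, n_trials = NULL) {
  if (is.null(n_trials))
    n_trials <- attr(records, "n_trials") %||%
      (max(records$trial, 0L) + 1L)
  if (!nrow(records))
    return(data.frame(neuron_id = character(), whisker = character(),
                      frequency_hz = numeric(), n_spiking = integer(),
                      n_trials = integer(), reliability = numeric()))
  key <- interaction(records$neuron_id, records$whisker,
                     records$frequency_hz, drop = TRUE)
  agg <- aggregate(records$trial, by = list(key = key),
                   FUN = function(t) length(unique(t)))
  info <- records[!duplicated(key),
                  c("neuron_id", "whisker", "frequency_hz")]
  info <- info[match(agg$key, unique(key)), ]
  out <- data.frame(info, n_spiking = agg$x, n_trials = n_trials,
                    reliability = agg$x / n_trials, row.names = NULL)
  out[order(out$neuron_id, out$frequency_hz), ]
}

# z-score a series; returns NULL for zero variance.
zscore_or_null <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

# Frequency group label: all frequencies <= 0.2 Hz pool into "0-0.2";
# others are labelled by their integer frequency.
frequency_group <- function(f) {
  ifelse(f <= 0.2, "0-0.2", as.character(f))
}

#' Adaptation profile over trial bins
#'
#' For each (neuron, condition) series the chosen quantity (per-trial spike
#' count, or first-spike latency on spiking trials) is z-scored, then the
#' normalised values are pooled by stimulation-frequency group and 10-trial
#' bin (trials 0-9, ..., 90-99). Zero-variance series are excluded with a
#' warning.
#'
#' @param records Spike-record data.frame.
#' @param quantity `"count"` or `"first_spike"`.
#' @param n_trials Trials per condition (see [reliability_histogram()]).
#' @return Data.frame with `frequency_group`, `bin_start`, `bin_end`,
#'   `mean_normalised`, `band_halfwidth` (2 * SEM of the bin's normalised
#'   values) and `n`.
#' @export
adaptation_profile <- function(records, quantity = c("count",
                                                     "first_spike"),
                               n_trials = NULL) {
  quantity <- match.arg(quantity)
  if (is.null(n_trials))
    n_trials <- attr(records, "n_trials") %||%
      (max(records$trial, 0L) + 1L)
  key <- paste(records$neuron_id, records$whisker, records$frequency_hz,
               sep = "|")
  rows <- list()
  n_excluded <- 0L
  for (k in unique(key)) {
    rc <- records[key == k, ]
    if (quantity == "count") {
      v <- tabulate(rc$trial + 1L, nbins = n_trials)
      tr <- seq_len(n_trials) - 1L
    } else {
      if (nrow(rc) < 2) next
      v <- rc$first_spike_ms
      tr <- rc$trial
    }
    z <- zscore_or_null(v)
    if (is.null(z)) {
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frequency_group = frequency_group(rc$frequency_hz[1]),
      trial = tr, z = z)
  }
  if (n_excluded > 0)
    warning(n_excluded, " zero-variance series excluded")
  if (!length(rows))
    return(data.frame(frequency_group = character(),
                      bin_start = integer(), bin_end = integer(),
                      mean_normalised = numeric(),
                      band_halfwidth = numeric(), n = integer()))
  d <- do.call(rbind, rows)
  d$bin_start <- (d$trial %/% 10L) * 10L
  out <- list()
  for (g in unique(d$frequency_group)) for (b in sort(unique(
    d$bin_start[d$frequency_group == g]))) {
    z <- d$z[d$frequency_group == g & d$bin_start == b]
    out[[length(out) + 1L]] <- data.frame(
      frequency_group = g, bin_start = b, bin_end = b + 10L,
      mean_normalised = mean(z),
      band_halfwidth = 2 * sd(z) / sqrt(length(z)), n = length(z))
  }
  do.call(rbind, out)
}

#' Autocorrelation / partial autocorrelation of a trial series
#'
#' Per-lag (partial) autocorrelation with two-sided p-values from the
#' large-sample normal approximation (`r * sqrt(n)` standard normal under
#' the null).
#'
#' @param series Numeric series (trial-ordered).
#' @param max_lag Maximum lag.
#' @param partial Compute partial autocorrelations instead.
#' @return Data.frame with `lag`, `r`, `p`, `significant` (alpha = 0.05).
#'   With `partial = FALSE` the lag-0 row has r = 1.
#' @export
series_acf_pacf <- function(series, max_lag = 20, partial = FALSE) {
  n <- length(series)
  if (n < max_lag + 2) stop("series shorter than max_lag + 2")
  if (partial) {
    r <- as.numeric(pacf(series, lag.max = max_lag, plot = FALSE)$acf)
    lag <- seq_len(max_lag)
  } else {
    r <- as.numeric(acf(series, lag.max = max_lag, plot = FALSE)$acf)
    lag <- 0:max_lag
  }
  p <- 2 * pnorm(abs(r) * sqrt(n), lower.tail = FALSE)
  p[lag == 0] <- 0
  data.frame(lag = lag, r = r, p = p, significant = p < 0.05)
}

# Lag-k autocorrelation of a series with its normal-approximation p-value.
lag_autocorrelation <- function(series, lag = 1) {
  n <- length(series)
  if (n < lag + 3) return(list(r = NA_real_, p = NA_real_))
  r <- suppressWarnings(cor(series[1:(n - lag)],
                            series[(1 + lag):n]))
  if (!is.finite(r)) return(list(r = NA_real_, p = NA_real_))
  list(r = r, p = 2 * pnorm(abs(r) * sqrt(n), lower.tail = FALSE))
}
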