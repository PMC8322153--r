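#' KPSS stationarity test
#'
#' Kwiatkowski-Phillips-Schmidt-Shin test of the null of stationarity
#' (around a level, or around a deterministic linear trend). The long-run
#' variance uses a Bartlett window with the short truncation lag
#' `trunc(4 * (n/100)^0.25)`; the p-value is interpolated in the standard
#' critical-value table and clamped to `[0.01, 0.1]`.
#'
#' @param series Numeric series.
#' @param null `"level"` (default) or `"trend"`.
#' @return List with `statistic`, `p`, `lags`.
#' @export
kpss_test <- function(series, null = c("level", "trend")) {
  null <- match.arg(null)
  x <- as.numeric(series)
  n <- length(x)
  if (n < 8) stop("series too short for KPSS")
  if (null == "level") {
    e <- x - mean(x)
    table_stat <- c(0.347, 0.463, 0.574, 0.739)
  } else {
    t <- seq_len(n)
    e <- residuals(lm(x ~ t))
    table_stat <- c(0.119, 0.146, 0.176, 0.216)
  }
  table_p <- c(0.10, 0.05, 0.025, 0.01)
  l <- trunc(4 * (n / 100)^0.25)
  s2 <- sum(e^2) / n
  if (l > 0) for (k in seq_len(l))
    s2 <- s2 + 2 * (1 - k / (l + 1)) * sum(e[1:(n - k)] * e[(k + 1):n]) / n
  if (s2 <= 0) s2 <- .Machine$double.eps
  stat <- sum(cumsum(e)^2) / (n^2 * s2)
  p <- stats::approx(table_stat, table_p, stat, rule = 2)$y
  list(statistic = stat, p = p, lags = l)
}

#' Per-neuron trial-latency series with processing provenance
#'
#' @param values Latencies (ms) in cluster-trial order.
#' @param trials 0-based trial indices of the values.
#' @param neuron_id Neuron identifier.
#' @param differenced Logical flag.
#' @param rescale Rescale factor applied after differencing (1 or
#'   `1/sqrt(2)`).
#' @param ar_order,ma_order ARIMA orders applied (0 = none).
#' @return List of class `"processed_series"`.
#' @export
processed_series <- function(values, trials, neuron_id = NA,
                             differenced = FALSE, rescale = 1,
                             ar_order = 0L, ma_order = 0L) {
  stopifnot(length(values) == length(trials))
  structure(list(values = as.numeric(values), trials = as.integer(trials),
                 neuron_id = neuron_id, differenced = differenced,
                 rescale = rescale, ar_order = as.integer(ar_order),
                 ma_order = as.integer(ma_order)),
            class = "processed_series")
}

# The three single-neuron differencing triggers: trial regression, KPSS,
# lag-1 autocorrelation. Differencing is applied when any fails (p <= 0.05).
differencing_triggers <- function(values, trials) {
  tr <- tryCatch(linear_correlation(cbind(trials, values))$p,
                 error = function(e) 0)
  kp <- tryCatch(kpss_test(values)$p, error = function(e) 0)
  l1 <- lag_autocorrelation(values)$p
  if (is.na(l1)) l1 <- 0
  c(trial_regression = tr, kpss = kp, lag1 = l1)
}

#' First-difference a latency series with sqrt(2) rescaling
#'
#' Differencing over consecutive cluster trials removes slow adaptative
#' trends but inflates the standard deviation by approximately `sqrt(2)`
#' for near-independent samples, so the differences are divided by
#' `sqrt(2)` to return them to the original latency scale.
#'
#' @param series A [processed_series()] (raw), length >= 3.
#' @param rescale Apply the `1/sqrt(2)` rescale (default TRUE; the ARIMA
#'   path works on unrescaled differences).
#' @return A differenced [processed_series()] of length n - 1, indexed by
#'   the later trial of each difference.
#' @export
difference_series <- function(series, rescale = TRUE) {
  v <- series$values
  if (length(v) < 3) stop("series too short to difference")
  d <- diff(v)
  f <- if (rescale) 1 / sqrt(2) else 1
  processed_series(d * f, series$trials[-1], series$neuron_id,
                   differenced = TRUE, rescale = f)
}

#' Automated Box-Jenkins order selection
#'
#' Simplified automation of the classical Box-Jenkins inspection. MA
#' branch: if the lag-1 autocorrelation is negative (`r < -0.1`) and
#' significant (the series looks slightly over-differenced), scan the
#' autocorrelation p-values at lags 1-5 for a sudden increase from below
#' 0.05 by more than 0.15 between consecutive lags; the last significant
#' lag before the jump is the MA order. AR branch: if the lag-1
#' autocorrelation is positive (`r > 0.1`) and significant, the analogous
#' scan on partial autocorrelations gives the AR order. Otherwise orders
#' are 0.
#'
#' @param series Numeric series (or [processed_series()]).
#' @return Integer vector `c(ar_order, ma_order)`.
#' @export
box_jenkins_orders <- function(series) {
  v <- if (inherits(series, "processed_series")) series$values
       else as.numeric(series)
  if (length(v) < 8) {
    warning("series shorter than 8: orders (0, 0)")
    return(c(ar_order = 0L, ma_order = 0L))
  }
  l1 <- lag_autocorrelation(v)
  ar <- 0L; ma <- 0L
  if (is.finite(l1$r) && l1$p < 0.05) {
    if (l1$r < -0.1) {
      ma <- cutoff_order(acf_pvalues(v, partial = FALSE))
    } else if (l1$r > 0.1) {
      ar <- cutoff_order(acf_pvalues(v, partial = TRUE))
    }
  }
  c(ar_order = ar, ma_order = ma)
}

# p-values of (partial) autocorrelations at lags 1..5.
acf_pvalues <- function(v, partial = FALSE) {
  n <- length(v)
  max_lag <- min(5L, n - 3L)
  if (partial) {
    r <- as.numeric(pacf(v, lag.max = max_lag, plot = FALSE)$acf)
  } else {
    r <- as.numeric(acf(v, lag.max = max_lag, plot = FALSE)$acf)[-1]
  }
  2 * pnorm(abs(r) * sqrt(n), lower.tail = FALSE)
}

# Last significant lag before a jump in p-value of > 0.15 from below 0.05.
cutoff_order <- function(p) {
  for (k in seq_along(p)) {
    if (p[k] >= 0.05) return(0L)
    nxt <- if (k < length(p)) p[k + 1] else 1
    if (nxt - p[k] > 0.15) return(as.integer(k))
  }
  0L
}

#' ARIMA detrending of a differenced latency series
#'
#' Fits an ARMA model of the given orders to the (unrescaled) differenced
#' series and returns the residuals recentred by the pre-differencing
#' series mean, so the output is on the original millisecond latency scale.
#' With orders (0, 0) the input series is returned unchanged. A
#' non-convergent fit falls back to orders (0, 0) with a warning.
#'
#' @param series A [processed_series()] (the unrescaled differenced
#'   series; or a raw series when no differencing was triggered).
#' @param orders Integer vector `c(ar_order, ma_order)`.
#' @param recentre_mean Mean of the raw (pre-differencing) series, added to
#'   the residuals; defaults to 0 for already-centred input.
#' @return A [processed_series()] of the detrended values.
#' @export
arima_detrend <- function(series, orders, recentre_mean = 0) {
  ar <- orders[[1]]; ma <- orders[[2]]
  if (ar == 0 && ma == 0) return(series)
  v <- series$values
  fit <- tryCatch(
    arima(v, order = c(ar, 0L, ma), include.mean = TRUE,
          method = "CSS-ML"),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(arima(v, order = c(ar, 0L, ma), include.mean = TRUE,
                          method = "CSS"),
                    error = function(e) NULL)
  if (is.null(fit)) {
    warning("ARIMA fit failed to converge: falling back to orders (0, 0)")
    return(series)
  }
  processed_series(as.numeric(residuals(fit)) + recentre_mean,
                   series$trials, series$neuron_id,
                   differenced = series$differenced,
                   rescale = series$rescale,
                   ar_order = ar, ma_order = ma)
}

#' Evaluate the stationarity and factor-analysis criteria for a cluster
#'
#' Applies the criteria battery to a cluster's two latency series:
#' correlation (p < 0.005 and r > 0.3), per-neuron trial regression
#' (p > 0.05), multi-output trial r-squared (< 0.05), per-neuron KPSS
#' stationarity (p > 0.05), per-neuron lag-1 autocorrelation (p > 0.05;
#' waived in `differenced` mode but not in `arima` mode), Bartlett
#' sphericity (the factor-analysis pre-test: the correlation matrix must
#' differ from the identity, p < 0.05), and a single dominant factor
#' (exactly one correlation-matrix eigenvalue > 1, which for a 2 x 2
#' correlation matrix with eigenvalues `1 +/- r` reduces to r > 0).
#'
#' `stationary` collects the five stationarity criteria;
#' `criteria_fulfilling` additionally requires the two factor-analysis
#' gates. Raw p-values are reported for every criterion so alternative
#' groupings can be reconstructed.
#'
#' @param points n x 2 latency matrix (cluster members), n >= 10.
#' @param trials Trial indices of the rows.
#' @param mode `"raw"`, `"differenced"` or `"arima"`.
#' @return List of class `"stationarity_report"`.
#' @export
evaluate_criteria <- function(points, trials,
                              mode = c("raw", "differenced", "arima")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 10) stop("need at least 10 cluster trials")
  fail <- function(reason) list(pass = FALSE, reason = reason)
  degenerate <- apply(points, 2, function(v) var(v) == 0)
  if (any(degenerate)) {
    rep0 <- list(mode = mode, n = n,
                 c1_correlated = fail("degenerate series"),
                 stationary = FALSE, criteria_fulfilling = FALSE)
    class(rep0) <- "stationarity_report"
    return(rep0)
  }
  ct <- linear_correlation(points)
  c1 <- list(pass = ct$p < 0.005 && ct$r > 0.3, p = ct$p, r = ct$r)
  tr <- trial_regressions(points, trials)
  c2p <- vapply(tr$per_neuron, function(x) x$p, numeric(1))
  c2 <- list(pass = all(c2p > 0.05), p = c2p)
  c3 <- list(pass = tr$multi_r2 < 0.05, r2 = tr$multi_r2)
  kp <- apply(points, 2, function(v) kpss_test(v)$p)
  c4 <- list(pass = all(kp > 0.05), p = kp)
  l1 <- apply(points, 2, function(v) lag_autocorrelation(v)$p)
  c5_pass <- all(l1 > 0.05, na.rm = TRUE) && !anyNA(l1)
  c5 <- list(pass = c5_pass, p = l1, waived = mode == "differenced")
  bs <- bartlett_sphericity(points)
  c6 <- list(pass = bs$p < 0.05, p = bs$p)
  ev <- eigen(cor(points), symmetric = TRUE, only.values = TRUE)$values
  c7 <- list(pass = sum(ev > 1) == 1, eigenvalues = ev)
  stationary <- c1$pass && c2$pass && c3$pass && c4$pass &&
    (c5$pass || c5$waived)
  out <- list(mode = mode, n = n, c1_correlated = c1,
              c2_trial_regression = c2, c3_multi_r2 = c3, c4_kpss = c4,
              c5_lag1 = c5, c6_bartlett = c6, c7_one_factor = c7,
              stationary = stationary,
              criteria_fulfilling = stationary && c6$pass && c7$pass)
  class(out) <- "stationarity_report"
  out
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat(sprintf("Stationarity report (mode %s, n = %d): %s\n", x$mode, x$n,
              if (isTRUE(x$criteria_fulfilling)) "criteria fulfilling"
              else if (isTRUE(x$stationary)) "stationary"
              else "non-stationary"))
  invisible(x)
}

#' Detrend a cluster's latency pair by differencing and/or ARIMA
#'
#' Applies the battery of adaptation controls to one cluster. Each
#' neuron's series is differenced iff any of its differencing triggers
#' fails (trial regression, KPSS, or lag-1 autocorrelation at p <= 0.05).
#' When exactly one neuron is differenced, the partner series drops its
#' first sample so trial alignment holds. The `differenced` path rescales
#' by `1/sqrt(2)`; the `arima` path instead selects Box-Jenkins orders on
#' the unrescaled differences, fits the ARMA model, and recentres by the
#' raw series mean.
#'
#' @param points n x 2 latency matrix.
#' @param trials Trial indices.
#' @param method `"differenced"` or `"arima"`.
#' @return List with `points` (processed n' x 2 matrix), `trials`,
#'   `series` (the two [processed_series()]), `any_differenced`, `orders`
#'   (2 x 2 matrix of per-neuron AR/MA orders, arima method only) and
#'   `mode` suitable for [evaluate_criteria()].
#' @export
detrend_cluster <- function(points, trials,
                            method = c("differenced", "arima")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  raw <- lapply(1:2, function(i)
    processed_series(points[, i], trials, neuron_id = i))
  needs <- vapply(1:2, function(i)
    any(differencing_triggers(points[, i], trials) <= 0.05), logical(1))
  ser <- raw
  orders <- matrix(0L, 2, 2, dimnames = list(NULL, c("ar", "ma")))
  for (i in 1:2) {
    if (needs[i]) {
      ser[[i]] <- difference_series(raw[[i]],
                                    rescale = method == "differenced")
    }
  }
  # Align: a differenced neuron loses its first trial; the undifferenced
  # partner drops its first sample to match.
  if (any(needs)) {
    for (i in 1:2) if (!needs[i])
      ser[[i]] <- processed_series(ser[[i]]$values[-1],
                                   ser[[i]]$trials[-1], i)
  }
  if (method == "arima") {
    for (i in 1:2) {
      o <- box_jenkins_orders(ser[[i]])
      orders[i, ] <- o
      ser[[i]] <- arima_detrend(ser[[i]], o,
                                recentre_mean = mean(points[, i]))
      if (needs[i] && all(o == 0))  # no ARMA applied: recentre only
        ser[[i]]$values <- ser[[i]]$values + mean(points[, i])
    }
  }
  list(points = cbind(ser[[1]]$values, ser[[2]]$values),
       trials = ser[[1]]$trials, series = ser,
       any_differenced = any(needs), differenced = needs,
       orders = orders,
       mode = if (method == "differenced") "differenced" else "arima")
}
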