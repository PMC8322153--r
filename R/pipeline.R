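#' Default pipeline settings
#'
#' @param epsilons DBSCAN epsilon sweep (ms).
#' @param min_cluster_size Minimum cluster membership.
#' @param min_pts DBSCAN core threshold.
#' @param n_boot Bootstrap resamples per round.
#' @param min_conjunctive_state Inclusion threshold for cross-cluster
#'   state correlations.
#' @return List of settings for [run_pipeline()].
#' @export
pipeline_settings <- function(epsilons = seq(0.4, 5.0, by = 0.05),
                              min_cluster_size = 30, min_pts = 5,
                              n_boot = 10000,
                              min_conjunctive_state = 15) {
  list(epsilons = epsilons, min_cluster_size = min_cluster_size,
       min_pts = min_pts, n_boot = n_boot,
       min_conjunctive_state = min_conjunctive_state)
}

# Analyse one Stage 2 cluster (or an unclustered distribution treated as a
# cluster with membership = all points): angles, criteria, detrending
# fall-backs, factor model and RDR.
analyse_cluster <- function(dist, members, angle, distribution_id,
                            seed = 1, n_boot = 10000) {
  pts <- dist_points(dist)[members, , drop = FALSE]
  trials <- dist$trials[members]
  if (nrow(pts) < 10) return(NULL)
  res <- list(distribution_id = distribution_id, n = nrow(pts),
              angle = angle,
              correlation = tryCatch(linear_correlation(pts),
                                     error = function(e) NULL),
              hz_p = tryCatch(henze_zirkler(pts)$p,
                              error = function(e) NA_real_))
  report <- tryCatch(evaluate_criteria(pts, trials, "raw"),
                     error = function(e) NULL)
  if (is.null(report)) return(NULL)
  res$report_raw <- report
  res$used_mode <- "raw"
  res$points_used <- pts
  res$trials_used <- trials
  if (!report$stationary) {
    for (method in c("differenced", "arima")) {
      det <- tryCatch(detrend_cluster(pts, trials, method),
                      error = function(e) NULL)
      if (is.null(det) || nrow(det$points) < 10) next
      rep2 <- tryCatch(evaluate_criteria(det$points, det$trials,
                                         det$mode),
                       error = function(e) NULL)
      res[[paste0("report_", method)]] <- rep2
      if (!is.null(rep2) && rep2$criteria_fulfilling &&
          res$used_mode == "raw") {
        res$used_mode <- method
        res$points_used <- det$points
        res$trials_used <- det$trials
        res$orders <- det$orders
      }
    }
  }
  rep_used <- res[[paste0("report_", if (res$used_mode == "raw") "raw"
                          else res$used_mode)]]
  res$stationary <- isTRUE(res$report_raw$stationary)
  res$criteria_fulfilling <- isTRUE(rep_used$criteria_fulfilling) ||
    (res$used_mode == "raw" && isTRUE(res$report_raw$criteria_fulfilling))
  if (res$criteria_fulfilling) {
    res$factor_model <- tryCatch(
      fit_single_factor(res$points_used, res$trials_used),
      error = function(e) NULL)
    if (!is.null(res$factor_model)) {
      res$rdr <- tryCatch(
        rdr_summary(dist, res$points_used, res$factor_model),
        error = function(e) NULL)
      res$factor_theta <- loading_angle(res$factor_model)
    }
    res$state <- tryCatch(predict_state(res$points_used, res$trials_used),
                          error = function(e) NULL)
    res$neuron_ids <- dist$neuron_ids
    res$condition <- dist$condition
  }
  res
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) spike records, builds pairwise response
#' distributions, extracts Stage 1 and Stage 2 clusters, estimates angles,
#' applies the stationarity criteria with differencing and ARIMA
#' fall-backs, fits factor models with RDR summaries, predicts per-trial
#' states and correlates them across clusters sharing no neuron. Results
#' are deterministic given the seed.
#'
#' @param records Spike-record data.frame, or `NULL` to generate from
#'   `config`.
#' @param config Optional [synthetic_config()] used when `records` is
#'   `NULL`.
#' @param seed Integer seed for the bootstrap stages.
#' @param settings A [pipeline_settings()] list.
#' @param out_dir Optional output directory for CSV tables and the JSON
#'   manifest.
#' @return List with `manifest` (per-stage counts), `stage1`, `stage2`,
#'   `cluster_results`, `unclustered_results`, `pooled`,
#'   `state_correlations` (data.frame edge list) and `distributions`.
#' @export
run_pipeline <- function(records = NULL, config = NULL, seed = 1,
                         settings = pipeline_settings(),
                         out_dir = NULL) {
  if (is.null(records)) {
    if (is.null(config)) stop("either records or config is required")
    records <- generate_session(config)
  }
  dists <- build_distributions(records)
  stage1_all <- list(); stage2_all <- list()
  cluster_results <- list(); unclustered_results <- list()
  failures <- character()
  for (k in seq_along(dists)) {
    dist <- dists[[k]]
    ok <- tryCatch({
      s1 <- extract_stage1(dist, settings$epsilons,
                           settings$min_cluster_size, settings$min_pts)
      stage1_all <- c(stage1_all, s1)
      s2 <- list()
      for (i in seq_along(s1)) {
        if (s1[[i]]$correlation$p >= 0.005) next
        cl <- tryCatch(stage2_cluster(s1[[i]], dist, seed + 31L * k + i,
                                      settings$n_boot),
                       error = function(e) NULL)
        if (!is.null(cl)) {
          s2[[length(s2) + 1L]] <- cl
          break  # uniqueness rule keeps the lowest-epsilon survivor
        }
      }
      s2 <- similarity_filter(s2)
      stage2_all <- c(stage2_all, s2)
      for (cl in s2) {
        r <- analyse_cluster(dist, cl$members, cl$angle, dist$id,
                             seed = seed + k, n_boot = settings$n_boot)
        if (!is.null(r)) {
          r$kind <- "cluster"
          cluster_results[[length(cluster_results) + 1L]] <- r
        }
      }
      # Unclustered case: same analyses with membership = all points.
      if (n_conjunctive(dist) >= 10) {
        ct <- tryCatch(linear_correlation(dist_points(dist)),
                       error = function(e) NULL)
        if (!is.null(ct) && ct$p < 0.005) {
          ang <- tryCatch(bootstrap_angle(dist_points(dist),
                                          settings$n_boot,
                                          seed + 17L * k),
                          error = function(e) NULL)
          r <- analyse_cluster(dist, seq_len(n_conjunctive(dist)), ang,
                               dist$id, seed = seed + k,
                               n_boot = settings$n_boot)
          if (!is.null(r)) {
            r$kind <- "unclustered"
            unclustered_results[[length(unclustered_results) + 1L]] <- r
          }
        }
      }
      TRUE
    }, error = function(e) {
      failures <<- c(failures, paste0(dist$id, ": ", conditionMessage(e)))
      FALSE
    })
  }
  fulfilling_cl <- Filter(function(r) isTRUE(r$criteria_fulfilling),
                          cluster_results)
  fulfilling_un <- Filter(function(r) isTRUE(r$criteria_fulfilling),
                          unclustered_results)
  pooled <- pool_examples(fulfilling_cl, fulfilling_un)
  state_edges <- correlate_pooled_states(
    pooled, min_conjunctive = settings$min_conjunctive_state)
  manifest <- list(
    seed = seed,
    n_records = nrow(records),
    n_distributions = length(dists),
    n_stage1 = length(stage1_all),
    n_stage1_correlated = sum(vapply(stage1_all, function(s)
      s$correlation$p < 0.005, logical(1))),
    n_stage2 = length(stage2_all),
    n_stationary = sum(vapply(cluster_results, function(r)
      isTRUE(r$stationary), logical(1))),
    n_criteria_fulfilling = length(fulfilling_cl),
    n_unclustered_correlated = length(unclustered_results),
    n_pooled = length(pooled),
    n_state_edges = nrow(state_edges),
    n_failures = length(failures))
  out <- list(manifest = manifest, stage1 = stage1_all,
              stage2 = stage2_all, cluster_results = cluster_results,
              unclustered_results = unclustered_results, pooled = pooled,
              state_correlations = state_edges, failures = failures,
              distributions = dists)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Cross-cluster predicted-state correlations over pooled entries whose
# neuron pairs are disjoint and whose conditions match.
correlate_pooled_states <- function(pooled, min_conjunctive = 15) {
  edges <- data.frame(a = character(), b = character(), n_common =
                        integer(), r = numeric(), p = numeric())
  if (length(pooled) < 2) return(edges)
  for (i in seq_len(length(pooled) - 1)) for (j in (i + 1):length(pooled)) {
    a <- pooled[[i]]; b <- pooled[[j]]
    if (is.null(a$state) || is.null(b$state)) next
    if (length(intersect(a$neuron_ids, b$neuron_ids))) next
    if (!identical(format_condition(a$condition),
                   format_condition(b$condition))) next
    sc <- state_correlation(a$state, b$state, min_conjunctive)
    if (is.null(sc)) next
    edges <- rbind(edges, data.frame(
      a = a$distribution_id, b = b$distribution_id, n_common = sc$n,
      r = sc$r, p = sc$p))
  }
  edges
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cl_rows <- lapply(c(out$cluster_results, out$unclustered_results),
                    function(r) data.frame(
    distribution_id = r$distribution_id, kind = r$kind, n = r$n,
    r = r$correlation$r %||% NA_real_, p = r$correlation$p %||% NA_real_,
    theta = if (!is.null(r$angle)) r$angle$theta else NA_real_,
    theta45 = if (!is.null(r$angle)) r$angle$theta45 else NA_real_,
    ci_low = if (!is.null(r$angle)) r$angle$ci_low else NA_real_,
    ci_high = if (!is.null(r$angle)) r$angle$ci_high else NA_real_,
    hz_p = r$hz_p, mode = r$used_mode,
    stationary = isTRUE(r$stationary),
    criteria_fulfilling = isTRUE(r$criteria_fulfilling),
    rdr1 = if (!is.null(r$rdr)) r$rdr$rdr1_sigma_diff else NA_real_,
    rdr2 = if (!is.null(r$rdr)) r$rdr$rdr2_sigma_diff else NA_real_,
    rdr3 = if (!is.null(r$rdr)) r$rdr$rdr3_sigma_diff else NA_real_))
  if (length(cl_rows))
    write.csv(do.call(rbind, cl_rows),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
  write.csv(out$state_correlations,
            file.path(out_dir, "state_correlations.csv"),
            row.names = FALSE)
  jsonlite::write_json(out$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
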