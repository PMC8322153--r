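#' Pairwise first-spike response distribution
#'
#' The atomic input of the pipeline: the conjunctive-trial first-spike pairs
#' of one neuron pair under one stimulus condition. The neuron with the
#' lower id is placed on the x axis (`s0`).
#'
#' @param neuron_ids Length-2 vector of neuron ids.
#' @param condition List or character describing the stimulus condition
#'   (whisker + frequency).
#' @param trials Integer vector of 0-based trial indices (strictly
#'   increasing).
#' @param s0,s1 First-spike latencies (ms) of the x- and y-axis neuron on
#'   those trials; both in `[0, 50)`.
#' @param meta Optional per-neuron metadata (data.frame with 2 rows).
#' @param id Optional distribution identifier.
#' @return An object of class `"pair_distribution"`.
#' @export
pair_distribution <- function(neuron_ids, condition, trials, s0, s1,
                              meta = NULL, id = NULL) {
  stopifnot(length(neuron_ids) == 2,
            length(trials) == length(s0), length(s0) == length(s1))
  ord <- order(as_neuron_key(neuron_ids))
  if (!identical(ord, 1:2)) {
    neuron_ids <- neuron_ids[ord]
    tmp <- s0; s0 <- s1; s1 <- tmp
    if (!is.null(meta)) meta <- meta[ord, , drop = FALSE]
  }
  o <- order(trials)
  trials <- as.integer(trials[o]); s0 <- s0[o]; s1 <- s1[o]
  if (anyDuplicated(trials)) stop("duplicate trial indices")
  if (any(s0 < 0 | s0 >= 50 | s1 < 0 | s1 >= 50))
    stop("latencies must lie in [0, 50) ms")
  structure(list(neuron_ids = neuron_ids, condition = condition,
                 trials = trials, s0 = s0, s1 = s1, meta = meta,
                 id = id %||% paste(neuron_ids[1], neuron_ids[2],
                                    format_condition(condition), sep = "|")),
            class = "pair_distribution")
}

as_neuron_key <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) num else as.character(ids)
}

format_condition <- function(condition) {
  if (is.list(condition))
    paste(condition$whisker %||% "", condition$frequency_hz %||% "",
          sep = "@")
  else as.character(condition)
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat("Pair distribution", x$id, ":", length(x$trials),
      "conjunctive trials\n")
  invisible(x)
}

#' Number of conjunctive trials
#' @param dist A [pair_distribution()].
#' @return Integer count.
#' @export
n_conjunctive <- function(dist) length(dist$trials)

# Points of a pair distribution as an n x 2 matrix (s0, s1).
dist_points <- function(dist) cbind(s0 = dist$s0, s1 = dist$s1)

#' Build pairwise response distributions from spike records
#'
#' One distribution is created per ordered neuron pair and stimulus
#' condition, over the conjunctive trials (trials on which both neurons
#' spiked). Records must already be referenced to cortical activation onset
#' and windowed to `[0, 50)` ms (see [read_session_csv()] for the onset
#' shift applied at load).
#'
#' @param records Spike-record data.frame.
#' @param min_trials Minimum number of conjunctive trials for a
#'   distribution to be emitted (default 1).
#' @return List of [pair_distribution()] objects.
#' @export
build_distributions <- function(records, min_trials = 1) {
  if (!nrow(records)) return(list())
  records$.cond <- paste(records$whisker, records$frequency_hz, sep = "@")
  out <- list()
  for (cond in unique(records$.cond)) {
    rc <- records[records$.cond == cond, ]
    ids <- sort(unique(rc$neuron_id))
    if (length(ids) < 2) next
    per <- split(rc, rc$neuron_id)
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- per[[ids[i]]]; b <- per[[ids[j]]]
      common <- intersect(a$trial, b$trial)
      if (length(common) < min_trials) next
      a <- a[match(sort(common), a$trial), ]
      b <- b[match(sort(common), b$trial), ]
      meta <- rbind(a[1, c("neuron_id", "layer", "ei_type", "column",
                           "septum")],
                    b[1, c("neuron_id", "layer", "ei_type", "column",
                           "septum")])
      out[[length(out) + 1L]] <- pair_distribution(
        neuron_ids = c(ids[i], ids[j]),
        condition = list(whisker = a$whisker[1],
                         frequency_hz = a$frequency_hz[1]),
        trials = sort(common), s0 = a$first_spike_ms,
        s1 = b$first_spike_ms, meta = meta)
    }
  }
  out
}
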