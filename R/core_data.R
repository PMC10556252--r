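#' Spike-event set
#'
#' Validates a columnar table of spike events: one row per spike, with the
#' neuron it came from, the cortical area label (MIo, SIo, or CMA), the trial,
#' and the spike time in seconds relative to trial start. Spike times must be
#' strictly increasing within each (neuron, trial); by default violations are
#' rejected, or sorted when `sort = TRUE`.
#'
#' @param df data.frame with columns `neuron_id`, `area`, `trial_id`,
#'   `spike_time_s`.
#' @param sort sort spike times within (neuron, trial) instead of rejecting
#'   unsorted input.
#' @return the validated data.frame with class `spike_train_set` prepended.
#' @export
spike_train_set <- function(df, sort = FALSE) {
  need <- c("neuron_id", "area", "trial_id", "spike_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_gf("spike table is missing column(s): %s", paste(miss, collapse = ", "))
  bad_area <- setdiff(unique(as.character(df$area)), c("MIo", "SIo", "CMA"))
  if (length(bad_area))
    stop_gf("unknown area label(s): %s", paste(bad_area, collapse = ", "))
  if (!sort) {
    # spike times must be strictly increasing within (neuron, trial) as given
    key <- paste(df$neuron_id, df$trial_id, sep = "\r")
    viol <- vapply(split(df$spike_time_s, key),
                   function(x) any(diff(x) <= 0), logical(1))
    if (any(viol))
      stop_gf("spike times are not strictly increasing within (neuron, trial) %s",
              gsub("\r", ", trial ", names(viol)[which(viol)[1]]))
  }
  df <- df[order(df$neuron_id, df$trial_id, df$spike_time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_train_set", class(df))
  df
}

#' Trial table
#'
#' Validates the per-trial task parameters of the biting task: the static
#' gape (jaw depression distance, mm, exactly three distinct values across
#' the session), its rank `gape_index` (1..3), the required bite-force level
#' (1..3), the detected force-onset time, and the trial outcome. The nine
#' (gape_index, force_level) combinations are the nine trial types.
#'
#' @param df data.frame with columns `trial_id`, `gape_mm`, `gape_index`,
#'   `force_level`, `fo_time_s`, `success`.
#' @return validated data.frame with class `trial_table` prepended.
#' @export
trial_table <- function(df) {
  need <- c("trial_id", "gape_mm", "gape_index", "force_level", "fo_time_s",
            "success")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_gf("trial table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$trial_id))
    stop_gf("duplicated trial_id: %s", df$trial_id[anyDuplicated(df$trial_id)])
  gapes <- sort(unique(df$gape_mm))
  if (length(gapes) != 3L)
    stop_gf("trial table must contain exactly 3 distinct gape values, found %d",
            length(gapes))
  if (!all(df$gape_index %in% 1:3) || !all(df$force_level %in% 1:3))
    stop_gf("gape_index and force_level must be in 1..3")
  if (!all(df$gape_index == match(df$gape_mm, gapes)))
    stop_gf("gape_index must rank gape_mm (1 = smallest gape)")
  rownames(df) <- NULL
  class(df) <- c("trial_table", class(df))
  df
}

#' Align spikes to force onset and bin
#'
#' Counts spikes in fixed-width bins aligned to each trial's force onset
#' (FO). Bins are half-open `[left, right)`, left-aligned to the window
#' start; a spike exactly at the right window edge is excluded. Spike `s` in
#' trial `t` lands in bin `floor((s - fo_t - window[1]) / bin_width) + 1`.
#'
#' @param spikes a [spike_train_set].
#' @param trials a [trial_table].
#' @param window two-element window around FO, seconds (default +/- 500 ms).
#' @param bin_width bin width in seconds (default 4 ms).
#' @param include_failed include unsuccessful trials (default drops them).
#' @return object of class `aligned_binned`: list with `counts` (integer
#'   array `[neuron, trial, bin]`), `neurons` (data.frame `neuron_id`,
#'   `area`), `trials` (the trial rows used), `bin_edges`, `time` (bin
#'   centers relative to FO), `window`, `bin_width`.
#' @export
align_and_bin <- function(spikes, trials, window = c(-0.5, 0.5),
                          bin_width = 0.004, include_failed = FALSE) {
  span <- diff(window)
  n_bins <- span / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop_gf("window span (%g s) is not divisible by bin width (%g s)",
            span, bin_width)
  n_bins <- as.integer(round(n_bins))
  if (!include_failed) trials <- trials[trials$success, , drop = FALSE]
  unknown <- !(spikes$trial_id %in% trials$trial_id)
  if (!include_failed) {
    # spikes from excluded (failed) trials are silently dropped; only truly
    # unknown trial ids are an error
    all_ids <- attr(trials, "all_trial_ids") %||% trials$trial_id
    unknown <- unknown & !(spikes$trial_id %in% all_ids)
  }
  if (any(unknown)) {
    bad <- spikes[which(unknown)[1], ]
    stop_gf("spike references unknown trial_id %s (neuron %s, t = %g s)",
            bad$trial_id, bad$neuron_id, bad$spike_time_s)
  }
  spikes <- spikes[spikes$trial_id %in% trials$trial_id, , drop = FALSE]
  neurons <- unique(data.frame(neuron_id = spikes$neuron_id,
                               area = as.character(spikes$area)))
  neurons <- neurons[order(neurons$neuron_id), , drop = FALSE]
  rownames(neurons) <- NULL
  n_neu <- nrow(neurons)
  n_tr <- nrow(trials)
  fo <- trials$fo_time_s[match(spikes$trial_id, trials$trial_id)]
  rel <- spikes$spike_time_s - fo - window[1]
  bin <- floor(rel / bin_width) + 1
  ok <- bin >= 1 & bin <= n_bins
  ni <- match(spikes$neuron_id, neurons$neuron_id)
  ti <- match(spikes$trial_id, trials$trial_id)
  idx <- ni[ok] + (ti[ok] - 1L) * n_neu + (bin[ok] - 1L) * n_neu * n_tr
  counts <- array(0L, dim = c(n_neu, n_tr, n_bins))
  tab <- tabulate(idx, nbins = n_neu * n_tr * n_bins)
  counts[] <- tab
  edges <- window[1] + bin_width * (0:n_bins)
  structure(
    list(counts = counts, neurons = neurons, trials = trials,
         bin_edges = edges, time = edges[-1] - bin_width / 2,
         window = window, bin_width = bin_width),
    class = "aligned_binned"
  )
}

#' Peri-event time histograms
#'
#' Trial-averaged firing rates aligned to force onset, per group of trials.
#' Each trial's spike counts are converted to rates (counts / bin width),
#' smoothed with a truncated (+/- 3 sigma, edge-renormalized) Gaussian
#' kernel, then averaged within the group; the SEM is computed across trials.
#'
#' @param binned an [align_and_bin] result.
#' @param grouping factor of length `n_trials` partitioning trials into
#'   condition groups (e.g. by gape, pooling over force levels).
#' @param kernel_sigma Gaussian kernel sd in seconds (default 50 ms).
#' @return object of class `peth`: list with `rate` and `sem` (arrays
#'   `[neuron, group, bin]`, spikes/s), `groups`, `time`, `n_trials` per
#'   group.
#' @export
compute_peth <- function(binned, grouping, kernel_sigma = 0.05) {
  grouping <- as.factor(grouping)
  if (length(grouping) != dim(binned$counts)[2])
    stop_gf("grouping length (%d) does not match trial count (%d)",
            length(grouping), dim(binned$counts)[2])
  n_per <- table(grouping)
  if (any(n_per == 0))
    stop_gf("empty trial group: %s", names(n_per)[which(n_per == 0)[1]])
  d <- dim(binned$counts)
  W <- smoothing_matrix(d[3], kernel_sigma, binned$bin_width)
  lev <- levels(grouping)
  rate <- array(0, dim = c(d[1], length(lev), d[3]))
  sem <- array(0, dim = c(d[1], length(lev), d[3]))
  for (n in seq_len(d[1])) {
    r <- smooth_rows(matrix(binned$counts[n, , ], d[2], d[3]) / binned$bin_width, W)
    for (g in seq_along(lev)) {
      rows <- r[grouping == lev[g], , drop = FALSE]
      rate[n, g, ] <- colMeans(rows)
      sem[n, g, ] <- if (nrow(rows) > 1)
        apply(rows, 2, stats::sd) / sqrt(nrow(rows)) else 0
    }
  }
  structure(
    list(rate = rate, sem = sem, groups = lev, time = binned$time,
         n_trials = as.integer(n_per)),
    class = "peth"
  )
}
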