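# Plain-text dataset I/O. A dataset directory holds three CSV files:
#   spikes.csv  neuron_id, area, trial_id, spike_time_s
#   trials.csv  trial_id, gape_mm, gape_index, force_level, fo_time_s, success
#   force.csv   trial_id, time_s, force_v   (long format, common sample grid)

#' Force-trace container
#'
#' Holds one uniformly sampled bite-force trace per trial on a common time
#' grid relative to trial start.
#'
#' @param time_s sample times in seconds (uniform grid).
#' @param traces matrix `[trial, sample]` of force values (V).
#' @param trial_id trial identifier per row of `traces`.
#' @return object of class `force_traces` (also stores `sample_rate_hz`).
#' @export
force_traces <- function(time_s, traces, trial_id) {
  traces <- as.matrix(traces)
  if (length(time_s) != ncol(traces))
    stop_gf("time grid length (%d) does not match trace samples (%d)",
            length(time_s), ncol(traces))
  if (length(trial_id) != nrow(traces))
    stop_gf("trial_id length does not match number of traces")
  dt <- diff(time_s)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop_gf("force traces must be uniformly sampled")
  structure(
    list(time_s = as.numeric(time_s), traces = traces,
         trial_id = trial_id, sample_rate_hz = 1 / dt[1]),
    class = "force_traces"
  )
}

#' Evaluate force traces at arbitrary times
#'
#' Linear interpolation of a trial's force trace; times outside the sampled
#' span are an error (the encoding model's lagged covariates require the
#' trace to cover the full lag range).
#'
#' @param forces a [force_traces] object.
#' @param trial_id a single trial id.
#' @param times times (s, relative to trial start) at which to evaluate.
#' @return numeric vector of force values.
#' @export
force_at <- function(forces, trial_id, times) {
  i <- match(trial_id, forces$trial_id)
  if (is.na(i)) stop_gf("no force trace for trial %s", trial_id)
  rng <- range(forces$time_s)
  if (any(times < rng[1] - 1e-9 | times > rng[2] + 1e-9))
    stop_gf("force trace for trial %s is too short for the requested times (needs [%.3f, %.3f] s, has [%.3f, %.3f] s)",
            trial_id, min(times), max(times), rng[1], rng[2])
  stats::approx(forces$time_s, forces$traces[i, ], xout = times, rule = 1)$y
}

#' @rdname read_dataset
#' @export
write_dataset <- function(spikes, trials, forces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(unclass(spikes))[, c("neuron_id", "area", "trial_id", "spike_time_s")],
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(trials))[, c("trial_id", "gape_mm", "gape_index",
                                                      "force_level", "fo_time_s", "success")],
                   file.path(dir, "trials.csv"), row.names = FALSE)
  long <- data.frame(
    trial_id = rep(forces$trial_id, each = length(forces$time_s)),
    time_s = rep(forces$time_s, length(forces$trial_id)),
    force_v = as.vector(t(forces$traces))
  )
  utils::write.csv(long, file.path(dir, "force.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read / write a dataset directory
#'
#' Losslessly round-trips the three columnar files (spike events, trial
#' table, force traces) that make up a dataset. Schema violations are
#' rejected with the offending file and column named.
#'
#' @param dir dataset directory.
#' @param spikes,trials,forces components to write.
#' @param sort passed to [spike_train_set()].
#' @return `read_dataset`: list with `spikes`, `trials`, `forces`.
#' @export
read_dataset <- function(dir, sort = FALSE) {
  req <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_gf("%s: missing column(s) %s", file, paste(miss, collapse = ", "))
    df
  }
  sp <- req(utils::read.csv(file.path(dir, "spikes.csv")),
            c("neuron_id", "area", "trial_id", "spike_time_s"), "spikes.csv")
  tr <- req(utils::read.csv(file.path(dir, "trials.csv")),
            c("trial_id", "gape_mm", "gape_index", "force_level", "fo_time_s",
              "success"), "trials.csv")
  fr <- req(utils::read.csv(file.path(dir, "force.csv")),
            c("trial_id", "time_s", "force_v"), "force.csv")
  ids <- unique(fr$trial_id)
  tgrid <- sort(unique(fr$time_s))
  m <- matrix(NA_real_, length(ids), length(tgrid))
  m[cbind(match(fr$trial_id, ids), match(fr$time_s, tgrid))] <- fr$force_v
  if (anyNA(m)) stop_gf("force.csv: traces do not share a common time grid")
  list(spikes = spike_train_set(sp, sort = sort),
       trials = trial_table(tr),
       forces = force_traces(tgrid, m, ids))
}
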