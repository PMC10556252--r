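# Synthetic task, force-trace, and spike-train generator. Everything
# downstream (GLM encoding, dPCA, decoding) is tested by parameter recovery
# against the known ground truth produced here.

#' Task specification for the synthetic biting task
#'
#' Describes the 3 gape x 3 force-level incisor biting task: three static
#' gapes (mm), three required force levels, balanced trial counts, and either
#' randomized or blocked gape presentation. Force traces rest at baseline,
#' ramp to a level proportional to the required force, and hold at target for
#' at least 100 ms; force onset (FO) is detected where the trace first
#' crosses 10% of the lowest force target.
#'
#' @param gapes_mm three gape distances in mm (default 11, 14, 17).
#' @param force_targets_v three force targets in volts, increasing.
#' @param trials_per_condition trials per (gape, force) cell (>= 1).
#' @param trial_order `"randomized"` (gape varies trial to trial) or
#'   `"blocked"` (all trials of one gape before moving to the next).
#' @param fo_jitter_s uniform jitter (+/-) of the ramp start across trials.
#' @param noise_sd_v additive white noise on the force trace.
#' @param ramp `"logistic"` (smooth sigmoidal rise, the default) or
#'   `"linear"`.
#' @param trial_dur_s trial duration; traces span `[0, trial_dur_s]` at
#'   `sample_rate_hz`.
#' @param sample_rate_hz force sampling rate.
#' @param seed RNG seed.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(gapes_mm = c(11, 14, 17),
                      force_targets_v = c(1, 2, 3),
                      trials_per_condition = 20,
                      trial_order = c("randomized", "blocked"),
                      fo_jitter_s = 0.1,
                      noise_sd_v = 0.02,
                      ramp = c("logistic", "linear"),
                      trial_dur_s = 3,
                      sample_rate_hz = 500,
                      seed = 1) {
  if (length(gapes_mm) != 3 || length(unique(gapes_mm)) != 3)
    stop_gf("exactly 3 distinct gapes are required")
  if (length(force_targets_v) != 3 || is.unsorted(force_targets_v, strictly = TRUE))
    stop_gf("exactly 3 increasing force targets are required")
  if (trials_per_condition < 1)
    stop_gf("trials_per_condition must be >= 1")
  structure(
    list(gapes_mm = sort(gapes_mm), force_targets_v = force_targets_v,
         trials_per_condition = as.integer(trials_per_condition),
         trial_order = match.arg(trial_order),
         fo_jitter_s = fo_jitter_s, noise_sd_v = noise_sd_v,
         ramp = match.arg(ramp), trial_dur_s = trial_dur_s,
         sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
    class = "task_spec"
  )
}

#' Detect force onset by sustained threshold crossing
#'
#' Returns the time at which a force trace first reaches `threshold` and
#' stays there: a crossing counts only if the mean of the following
#' `sustain_s` window remains at or above the threshold, which rejects
#' isolated sensor-noise excursions at baseline. The crossing time is
#' linearly interpolated between samples; for a noiseless linear ramp
#' starting at `t0` with slope `s` it is `t0 + threshold / s` exactly.
#'
#' @param trace force samples.
#' @param times sample times (s).
#' @param threshold crossing level.
#' @param sustain_s sustain window (s); 0 accepts any crossing.
#' @return onset time in seconds.
#' @export
detect_force_onset <- function(trace, times, threshold, sustain_s = 0.05) {
  k <- max(1L, round(sustain_s / (times[2] - times[1])))
  cand <- which(trace >= threshold)
  cand <- cand[cand <= length(trace) - k + 1L]
  i <- NA_integer_
  for (j in cand) {
    if (mean(trace[j:(j + k - 1L)]) >= threshold) { i <- j; break }
  }
  if (is.na(i)) stop_gf("force trace never reaches the threshold %g", threshold)
  if (i == 1) return(times[1])
  t0 <- times[i - 1]
  f0 <- trace[i - 1]
  t0 + (threshold - f0) / (trace[i] - f0) * (times[i] - t0)
}

#' Generate task trials and force traces
#'
#' Builds a balanced session of `9 * trials_per_condition` trials. Each
#' trial's force trace rests near 0, ramps (logistic by default, slope tied
#' to the force level) to its target, and holds through the end of the trial.
#' FO is detected on the generated (noisy) trace at 10% of the lowest force
#' target.
#'
#' @param spec a [task_spec].
#' @return list with `trials` (a [trial_table]) and `forces`
#'   (a [force_traces]).
#' @export
generate_trials <- function(spec) {
  set.seed(spec$seed)
  conds <- expand.grid(gape_index = 1:3, force_level = 1:3)
  conds <- conds[rep(seq_len(9), spec$trials_per_condition), ]
  n <- nrow(conds)
  ord <- if (spec$trial_order == "blocked") {
    # all trials of one gape (force levels randomized within) before the next
    order(conds$gape_index, stats::runif(n))
  } else {
    sample.int(n)
  }
  conds <- conds[ord, ]
  tgrid <- seq(0, spec$trial_dur_s, by = 1 / spec$sample_rate_hz)
  threshold <- 0.1 * min(spec$force_targets_v)
  ramp_dur <- 0.3  # seconds from baseline to target, all levels
  traces <- matrix(0, n, length(tgrid))
  fo <- numeric(n)
  t0 <- spec$trial_dur_s / 2 - 0.25 +
    stats::runif(n, -spec$fo_jitter_s, spec$fo_jitter_s)
  # Trial-to-trial force variability during the logistic ramp and hold:
  # ramp duration varies, the bite overshoots the target before relaxing
  # back, and slow fluctuations ride on the hold. This variability is what
  # identifies the multi-lag force covariates downstream; the linear ramp
  # variant is the idealized (closed-form FO) profile and omits it.
  # tremor correlation time ~20 ms (physiological force tremor, 8-12 Hz)
  smooth_kernel <- {
    half <- ceiling(3 * 0.02 * spec$sample_rate_hz)
    k <- exp(-0.5 * ((-half:half) / (0.02 * spec$sample_rate_hz))^2)
    k / sum(k)
  }
  for (i in seq_len(n)) {
    target <- spec$force_targets_v[conds$force_level[i]]
    if (spec$ramp == "linear") {
      f <- pmin(target, pmax(0, (tgrid - t0[i]) * target / ramp_dur))
    } else {
      rdur <- ramp_dur * exp(stats::rnorm(1, 0, 0.25))
      f <- target * stats::plogis((tgrid - t0[i] - rdur / 2) / (rdur / 10))
      over <- abs(stats::rnorm(1, 0, 0.15)) * target
      f <- f + over * exp(-0.5 * ((tgrid - t0[i] - rdur - 0.05) / 0.12)^2)
      wob <- stats::filter(stats::rnorm(length(tgrid), 0, 0.05 * target),
                           smooth_kernel, sides = 2, circular = TRUE)
      f <- f + as.numeric(wob) * sqrt(1 / sum(smooth_kernel^2)) *
        stats::plogis((tgrid - t0[i] - rdur / 2) / (rdur / 10))
    }
    if (spec$noise_sd_v > 0)
      f <- f + stats::rnorm(length(tgrid), 0, spec$noise_sd_v)
    traces[i, ] <- f
    fo[i] <- detect_force_onset(f, tgrid, threshold)
  }
  trials <- trial_table(data.frame(
    trial_id = seq_len(n),
    gape_mm = spec$gapes_mm[conds$gape_index],
    gape_index = conds$gape_index,
    force_level = conds$force_level,
    fo_time_s = fo,
    success = TRUE
  ))
  list(trials = trials, forces = force_traces(tgrid, traces, seq_len(n)))
}

#' Ground-truth encoding-model parameters for one neuron
#'
#' @param neuron_id,area identifiers.
#' @param beta0 baseline log-odds of a spike per 4-ms bin.
#' @param history 3 spike-history weights (16/44/108-ms basis).
#' @param gape gape weight (per mm).
#' @param force 8 force weights over the lag grid.
#' @param interaction 8 gape-by-force interaction weights.
#' @return object of class `glm_ground_truth`.
#' @export
glm_ground_truth <- function(neuron_id, area, beta0, history, gape, force,
                             interaction) {
  stopifnot(length(history) == 3, length(force) == length(interaction))
  b <- c(beta0, history, gape, force, interaction)
  if (!all(is.finite(b))) stop_gf("ground-truth betas must be finite")
  structure(list(neuron_id = neuron_id, area = as.character(area),
                 beta0 = beta0, history = history, gape = gape,
                 force = force, interaction = interaction),
            class = "glm_ground_truth")
}

#' Random ground-truth cohort
#'
#' Draws per-neuron encoding-model parameters with baseline rates uniform in
#' `rate_range_hz` (the baseline log-odds is solved so the rate at typical
#' covariate values lands in that range), sparse-ish force tuning, and
#' negative short-timescale history (refractoriness). Setting `gape_sd = 0`
#' and `interaction_sd = 0` yields a cohort whose spiking truly does not
#' depend on gape.
#'
#' @param n_neurons cohort size; areas cycle through MIo/SIo/CMA.
#' @param gapes_mm,force_targets_v task values used to center the baseline.
#' @param rate_range_hz range of baseline firing rates.
#' @param force_sd,gape_sd,interaction_sd sd of the corresponding weights.
#' @param history_mean,history_sd mean/sd of the 3 history weights.
#' @param bin_width spike bin width (s).
#' @param seed RNG seed.
#' @return list of [glm_ground_truth] objects.
#' @export
random_glm_truth <- function(n_neurons, gapes_mm = c(11, 14, 17),
                             force_targets_v = c(1, 2, 3),
                             rate_range_hz = c(5, 30),
                             force_sd = 0.35, gape_sd = 0.04,
                             interaction_sd = 0.01,
                             history_mean = c(-1.5, -0.6, -0.2),
                             history_sd = 0.2,
                             bin_width = 0.004, seed = 1) {
  set.seed(seed)
  areas <- rep(c("MIo", "SIo", "CMA"), length.out = n_neurons)
  mean_g <- mean(gapes_mm)
  mean_f <- mean(force_targets_v) / 2  # force is near baseline pre-FO
  lapply(seq_len(n_neurons), function(n) {
    bF <- stats::rnorm(8, 0, force_sd) * stats::rbinom(8, 1, 0.6)
    bG <- stats::rnorm(1, 0, gape_sd)
    bGF <- stats::rnorm(8, 0, interaction_sd) * stats::rbinom(8, 1, 0.4)
    bH <- history_mean + stats::rnorm(3, 0, history_sd)
    rate <- stats::runif(1, rate_range_hz[1], rate_range_hz[2])
    # interaction uses centered gape, so it does not shift the baseline
    beta0 <- stats::qlogis(rate * bin_width) - bG * mean_g - sum(bF) * mean_f
    glm_ground_truth(n, areas[n], beta0, bH, bG, bF, bGF)
  })
}

# Extrinsic covariates shared by the simulator and the design-matrix builder:
# G[trial] (gape, mm) and F[trial, bin, lag] (force at bin time + lag).
extrinsic_covariates <- function(trials, forces, window = c(-0.5, 0.5),
                                 bin_width = 0.004, lags = force_lag_grid()) {
  n_bins <- as.integer(round(diff(window) / bin_width))
  centers <- window[1] + bin_width * (seq_len(n_bins) - 0.5)
  n_tr <- nrow(trials)
  Fm <- array(0, dim = c(n_tr, n_bins, length(lags)))
  offs <- as.vector(outer(centers, lags, `+`))
  for (i in seq_len(n_tr)) {
    v <- force_at(forces, trials$trial_id[i], trials$fo_time_s[i] + offs)
    Fm[i, , ] <- v
  }
  list(G = trials$gape_mm, Fm = Fm, n_bins = n_bins, centers = centers)
}

#' Simulate spike trains from the encoding model
#'
#' Generative use of the encoding model itself: for every 4-ms bin in the
#' +/- 500 ms window around FO, a spike is drawn from a Bernoulli whose
#' log-odds is the ground-truth linear predictor — baseline, gape, the eight
#' lagged force values, gape-by-force interactions, and the neuron's own
#' just-simulated spike history filtered through the raised-cosine basis.
#' Simulation is sequential in time (history is causal) and history never
#' crosses trial boundaries. Spikes are placed at bin centers.
#'
#' @param truth list of [glm_ground_truth] (one per neuron).
#' @param trials a [trial_table].
#' @param forces a [force_traces].
#' @param window,bin_width analysis window (s around FO) and bin width (s).
#' @param basis a [make_basis] result.
#' @param lags force lag grid (s).
#' @param seed RNG seed.
#' @return a [spike_train_set]; attribute `clamp_count` reports how many
#'   bins had a numerically clamped linear predictor.
#' @export
simulate_spikes_glm <- function(truth, trials, forces, window = c(-0.5, 0.5),
                                bin_width = 0.004, basis = make_basis(),
                                lags = force_lag_grid(), seed = 1) {
  set.seed(seed)
  ex <- extrinsic_covariates(trials, forces, window, bin_width, lags)
  n_tr <- nrow(trials)
  B <- ex$n_bins
  L <- nrow(basis$B)
  Fm2 <- matrix(ex$Fm, n_tr * B, length(lags))
  clamp_count <- 0L
  out <- vector("list", length(truth))
  for (ni in seq_along(truth)) {
    tr <- truth[[ni]]
    g_c <- ex$G - mean(unique(ex$G))  # same centering as the design builder
    xstat <- matrix(Fm2 %*% tr$force, n_tr, B) +
      g_c * matrix(Fm2 %*% tr$interaction, n_tr, B) +
      (tr$beta0 + tr$gape * ex$G)
    hkern <- as.vector(basis$B %*% tr$history)
    etaH <- matrix(0, n_tr, B)
    s <- matrix(0L, n_tr, B)
    for (b in seq_len(B)) {
      eta <- xstat[, b] + etaH[, b]
      over <- abs(eta) > 30
      if (any(over)) {
        clamp_count <- clamp_count + sum(over)
        eta <- pmin(pmax(eta, -30), 30)
      }
      sp <- stats::rbinom(n_tr, 1L, stats::plogis(eta))
      s[, b] <- sp
      if (b < B && any(sp == 1L)) {
        idx <- (b + 1):min(B, b + L)
        etaH[, idx] <- etaH[, idx] + sp %o% hkern[seq_along(idx)]
      }
    }
    w <- which(s == 1L, arr.ind = TRUE)
    if (nrow(w)) {
      out[[ni]] <- data.frame(
        neuron_id = tr$neuron_id, area = tr$area,
        trial_id = trials$trial_id[w[, 1]],
        spike_time_s = trials$fo_time_s[w[, 1]] + window[1] +
          (w[, 2] - 0.5) * bin_width
      )
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(neuron_id = integer(), area = character(),
                     trial_id = integer(), spike_time_s = numeric())
  res <- spike_train_set(df, sort = TRUE)
  attr(res, "clamp_count") <- clamp_count
  res
}

#' Latent-population specification
#'
#' Describes a synthetic population whose trial-averaged rates decompose into
#' condition-independent (time), gape, force, and gape-by-force interaction
#' parts with prescribed variance fractions. Rates are built as baseline +
#' loading-weighted time-course templates per marginalization, scaled so the
#' noiseless rate tensor realizes the target fractions; spike history is
#' deliberately absent (the decomposition operates on trial-averaged rates,
#' and history would confound the variance-fraction ground truth).
#'
#' @param n_neurons population size.
#' @param fractions named vector `c(time=, gape=, force=, interaction=)`,
#'   non-negative, summing to at most 1 (renormalized internally to split the
#'   signal variance).
#' @param baseline_hz baseline firing rate.
#' @param signal_sd_hz total signal modulation (sd of the centered noiseless
#'   rate tensor).
#' @param noise_sd_hz per-trial white rate noise.
#' @param bernoulli clip per-bin Poisson counts to {0, 1}.
#' @param n_bins,bin_width time grid of the aligned window.
#' @param seed RNG seed.
#' @return object of class `population_latent_spec`.
#' @export
population_latent_spec <- function(n_neurons = 40,
                                   fractions = c(time = 0.5, gape = 0.2,
                                                 force = 0.2, interaction = 0.1),
                                   baseline_hz = 20, signal_sd_hz = 8,
                                   noise_sd_hz = 2, bernoulli = FALSE,
                                   n_bins = 250, bin_width = 0.004, seed = 1) {
  fractions <- fractions[c("time", "gape", "force", "interaction")]
  if (anyNA(fractions) || any(fractions < 0))
    stop_gf("fractions must be a named non-negative vector over time/gape/force/interaction")
  if (sum(fractions) > 1 + 1e-12)
    stop_gf("variance fractions sum to %.3f > 1", sum(fractions))
  structure(
    list(n_neurons = as.integer(n_neurons), fractions = fractions,
         baseline_hz = baseline_hz, signal_sd_hz = signal_sd_hz,
         noise_sd_hz = noise_sd_hz, bernoulli = isTRUE(bernoulli),
         n_bins = as.integer(n_bins), bin_width = bin_width,
         seed = as.integer(seed)),
    class = "population_latent_spec"
  )
}

#' Simulate a latent-structured population
#'
#' Builds per-neuron noiseless rate tensors `[gape, force, time]` as baseline
#' plus scaled templates per marginalization, then draws per-trial rates
#' (signal + Gaussian noise, rectified at 0) and per-bin Poisson spike
#' counts. The realized variance fractions — computed exactly from the
#' constructed noiseless tensor with the same marginalization operators used
#' by the analysis — are stored as ground truth.
#'
#' @param spec a [population_latent_spec].
#' @param trials a [trial_table] assigning each trial a (gape, force) cell.
#' @return list with `binned` (aligned counts, as from [align_and_bin]),
#'   `rates` (noiseless array `[neuron, gape, force, bin]`),
#'   `trial_rates` (array `[neuron, trial, bin]`, the noisy per-trial rates),
#'   `realized_fractions` (named, percent of centered variance), and
#'   `clip_fraction`.
#' @export
simulate_population_latent <- function(spec, trials) {
  set.seed(spec$seed)
  N <- spec$n_neurons
  B <- spec$n_bins
  tt <- seq(0, 1, length.out = B)
  u <- c(-1, 0, 1) / sqrt(2 / 3)  # zero-mean, unit-variance over 3 levels
  terms <- list(
    time = {
      a1 <- stats::rnorm(N); a2 <- stats::rnorm(N)
      tau1 <- sin(pi * tt); tau2 <- cos(2 * pi * tt)
      y <- array(0, c(N, 3, 3, B))
      core <- outer(a1, tau1) + outer(a2, tau2)        # N x B
      core <- core - rowMeans(core)                    # centered over time
      for (g in 1:3) for (f in 1:3) y[, g, f, ] <- core
      y
    },
    gape = {
      b <- stats::rnorm(N)
      psi <- stats::plogis((tt - 0.5) / 0.08)
      y <- array(0, c(N, 3, 3, B))
      for (g in 1:3) for (f in 1:3) y[, g, f, ] <- outer(b * u[g], psi)
      y
    },
    force = {
      cc <- stats::rnorm(N)
      phi <- exp(-((tt - 0.55) / 0.15)^2)
      y <- array(0, c(N, 3, 3, B))
      for (g in 1:3) for (f in 1:3) y[, g, f, ] <- outer(cc * u[f], phi)
      y
    },
    interaction = {
      d <- stats::rnorm(N)
      chi <- sin(2 * pi * tt + 0.5)
      y <- array(0, c(N, 3, 3, B))
      for (g in 1:3) for (f in 1:3) y[, g, f, ] <- outer(d * u[g] * u[f], chi)
      y
    }
  )
  fr <- spec$fractions
  frn <- if (sum(fr) > 0) fr / sum(fr) else fr
  R <- array(spec$baseline_hz, c(N, 3, 3, B))
  total_ss <- spec$signal_sd_hz^2 * N * 9 * B
  for (k in names(terms)) {
    ss <- sum(terms[[k]]^2)
    if (frn[[k]] > 0 && ss > 0)
      R <- R + sqrt(frn[[k]] * total_ss / ss) * terms[[k]]
  }
  clip <- mean(R < 0)
  R[R < 0] <- 0
  # realized ground truth from the final noiseless tensor
  Rc <- sweep(R, 1, apply(R, 1, mean))
  m <- marginalize_array(Rc)
  tot <- sum(Rc^2)
  realized <- 100 * vapply(m, function(x) sum(x^2), numeric(1)) / tot
  # per-trial rates and spikes
  n_tr <- nrow(trials)
  window <- c(-B * spec$bin_width / 2, B * spec$bin_width / 2)
  trial_rates <- array(0, c(N, n_tr, B))
  counts <- array(0L, c(N, n_tr, B))
  for (i in seq_len(n_tr)) {
    g <- trials$gape_index[i]; f <- trials$force_level[i]
    lam <- R[, g, f, ] + matrix(stats::rnorm(N * B, 0, spec$noise_sd_hz), N, B)
    lam[lam < 0] <- 0
    trial_rates[, i, ] <- lam
    cnt <- stats::rpois(N * B, lam * spec$bin_width)
    if (spec$bernoulli) cnt <- pmin(cnt, 1L)
    counts[, i, ] <- cnt
  }
  edges <- window[1] + spec$bin_width * (0:B)
  binned <- structure(
    list(counts = counts,
         neurons = data.frame(neuron_id = seq_len(N),
                              area = rep(c("MIo", "SIo", "CMA"),
                                         length.out = N)),
         trials = trials, bin_edges = edges,
         time = edges[-1] - spec$bin_width / 2,
         window = window, bin_width = spec$bin_width),
    class = "aligned_binned"
  )
  list(binned = binned, rates = R, trial_rates = trial_rates,
       realized_fractions = realized, clip_fraction = clip)
}
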