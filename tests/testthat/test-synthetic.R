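test_that("the task is balanced: 90 trials, 30 per gape, 30 per force level", {
  g <- generate_trials(task_spec(trials_per_condition = 10, seed = 1))
  expect_equal(nrow(g$trials), 90)
  expect_true(all(table(g$trials$gape_index) == 30))
  expect_true(all(table(g$trials$force_level) == 30))
  expect_equal(sort(unique(g$trials$gape_mm)), c(11, 14, 17))
  expect_error(task_spec(trials_per_condition = 0), ">= 1")
})

test_that("blocked ordering groups trials by gape in three blocks", {
  g <- generate_trials(task_spec(trials_per_condition = 5,
                                 trial_order = "blocked", seed = 2))
  runs <- rle(g$trials$gape_index)
  expect_equal(length(runs$lengths), 3)
  expect_true(all(runs$lengths == 15))
})

test_that("force onset on a noiseless linear ramp is t0 + threshold/slope", {
  spec <- task_spec(trials_per_condition = 2, ramp = "linear",
                    noise_sd_v = 0, fo_jitter_s = 0, seed = 3)
  g <- generate_trials(spec)
  t0 <- spec$trial_dur_s / 2 - 0.25
  threshold <- 0.1 * min(spec$force_targets_v)
  slope <- spec$force_targets_v[g$trials$force_level] / 0.3
  expect_equal(g$trials$fo_time_s, t0 + threshold / slope, tolerance = 1e-6)
  # direct closed-form check of the detector
  tt <- seq(0, 2, by = 0.01)
  expect_equal(detect_force_onset(pmax(0, (tt - 0.8) * 2), tt, 0.5),
               0.8 + 0.5 / 2, tolerance = 1e-9)
  expect_error(detect_force_onset(rep(0, 10), 1:10, 1), "threshold")
})

test_that("a null encoding model spikes at its baseline probability", {
  tk <- tiny_task()
  truth <- list(glm_ground_truth(1, "MIo", qlogis(0.1), c(0, 0, 0), 0,
                                 rep(0, 8), rep(0, 8)))
  sp <- simulate_spikes_glm(truth, tk$trials, tk$forces, seed = 6)
  n_bins <- nrow(tk$trials) * 250
  p_hat <- nrow(sp) / n_bins
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n_bins))
})

test_that("a positive force weight orders firing rates by force level", {
  tk <- tiny_task()
  truth <- list(glm_ground_truth(1, "MIo", qlogis(0.02), c(0, 0, 0), 0,
                                 c(0, 0, 0, 1.2, 0, 0, 0, 0), rep(0, 8)))
  sp <- simulate_spikes_glm(truth, tk$trials, tk$forces, seed = 7)
  b <- align_and_bin(sp, tk$trials)
  p <- compute_peth(b, factor(tk$trials$force_level))
  by_level <- rowMeans(p$rate[1, , p$time > 0])
  expect_true(by_level[3] > by_level[2] && by_level[2] > by_level[1])
})

test_that("negative short-timescale history produces a refractory ISI dip", {
  tk <- tiny_task()
  mk <- function(h) list(glm_ground_truth(1, "MIo", qlogis(0.12), h, 0,
                                          rep(0, 8), rep(0, 8)))
  short_isi <- function(sp) {
    isi <- unlist(lapply(split(sp$spike_time_s, sp$trial_id), diff))
    mean(isi <= 0.009)
  }
  with_h <- short_isi(simulate_spikes_glm(mk(c(-4, 0, 0)), tk$trials,
                                          tk$forces, seed = 8))
  no_h <- short_isi(simulate_spikes_glm(mk(c(0, 0, 0)), tk$trials,
                                        tk$forces, seed = 8))
  expect_lt(with_h, no_h / 3)
})

test_that("latent populations realize their target variance fractions", {
  tk <- pop_task()
  only_t <- simulate_population_latent(
    population_latent_spec(n_neurons = 6,
                           fractions = c(time = 1, gape = 0, force = 0,
                                         interaction = 0),
                           noise_sd_hz = 0, seed = 11), tk$trials)
  expect_equal(unname(only_t$realized_fractions[c("gape", "force",
                                                  "interaction")]),
               c(0, 0, 0), tolerance = 1e-9)
  mixed <- simulate_population_latent(
    population_latent_spec(n_neurons = 12, seed = 12), tk$trials)
  expect_lt(max(abs(mixed$realized_fractions -
                      c(50, 20, 20, 10))), 2)
  expect_error(population_latent_spec(
    fractions = c(time = 0.6, gape = 0.3, force = 0.2, interaction = 0.1)),
    "sum")
})

test_that("identical seeds reproduce simulations bit for bit", {
  tk <- tiny_task()
  truth <- random_glm_truth(2, seed = 13)
  s1 <- simulate_spikes_glm(truth, tk$trials, tk$forces, seed = 14)
  s2 <- simulate_spikes_glm(truth, tk$trials, tk$forces, seed = 14)
  expect_identical(s1$spike_time_s, s2$spike_time_s)
  g1 <- generate_trials(task_spec(trials_per_condition = 3, seed = 15))
  g2 <- generate_trials(task_spec(trials_per_condition = 3, seed = 15))
  expect_identical(g1$forces$traces, g2$forces$traces)
  p1 <- simulate_population_latent(population_latent_spec(n_neurons = 4,
                                                          seed = 16),
                                   tk$trials)
  p2 <- simulate_population_latent(population_latent_spec(n_neurons = 4,
                                                          seed = 16),
                                   tk$trials)
  expect_identical(p1$binned$counts, p2$binned$counts)
})
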