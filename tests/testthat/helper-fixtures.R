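# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Small task: 4 trials per condition, 36 trials.
tiny_task <- function() fixture("tiny_task", function()
  generate_trials(task_spec(trials_per_condition = 4, seed = 42)))

# Three moderately force-driven neurons on the small task.
tiny_spikes <- function() fixture("tiny_spikes", function() {
  tk <- tiny_task()
  truth <- random_glm_truth(3, seed = 43)
  simulate_spikes_glm(truth, tk$trials, tk$forces, seed = 44)
})

tiny_binned <- function() fixture("tiny_binned", function()
  align_and_bin(tiny_spikes(), tiny_task()$trials))

# GLM cohort at recovery-study scale (207 trials, force-driven, gape-null).
glm_task <- function() fixture("glm_task", function()
  generate_trials(task_spec(trials_per_condition = 23, seed = 21)))

glm_truth <- function() fixture("glm_truth", function()
  random_glm_truth(4, gape_sd = 0, interaction_sd = 0, seed = 22))

glm_binned <- function() fixture("glm_binned", function() {
  tk <- glm_task()
  sp <- simulate_spikes_glm(glm_truth(), tk$trials, tk$forces, seed = 23)
  align_and_bin(sp, tk$trials)
})

# All-trials fits (no cross-validation) wrapped like fit_glm results, for
# coefficient-level analyses.
fit_full_data <- function(binned, trials, forces, neuron, spec_name) {
  des <- build_design_matrix(binned, trials, forces, neuron,
                             model_spec(spec_name))
  list(neuron_id = neuron, model = spec_name,
       full = fit_logit_irls(des$X, des$y), col_groups = des$col_groups)
}

glm_full_fits <- function() fixture("glm_full_fits", function() {
  tk <- glm_task()
  lapply(glm_truth(), function(tr)
    fit_full_data(glm_binned(), tk$trials, tk$forces, tr$neuron_id, "full"))
})

glm_force_fits <- function() fixture("glm_force_fits", function() {
  tk <- glm_task()
  lapply(glm_truth(), function(tr)
    fit_full_data(glm_binned(), tk$trials, tk$forces, tr$neuron_id,
                  "force_only"))
})

# Latent population with clear structure for dPCA / decoding tests.
pop_task <- function() fixture("pop_task", function()
  generate_trials(task_spec(trials_per_condition = 8, seed = 7)))

pop_strong <- function() fixture("pop_strong", function()
  simulate_population_latent(
    population_latent_spec(
      n_neurons = 15,
      fractions = c(time = 0.3, gape = 0.6, force = 0.05, interaction = 0.05),
      signal_sd_hz = 12, noise_sd_hz = 1, seed = 8),
    pop_task()$trials))

pop_strong_ct <- function() fixture("pop_strong_ct", function()
  build_condition_tensor(pop_strong()$binned, pop_task()$trials))

# Brute-force AUROC oracle: enumerate all positive x negative pairs.
auroc_bruteforce <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}
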