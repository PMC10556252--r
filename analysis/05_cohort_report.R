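#!/usr/bin/env Rscript
# Stage 5: cohort statistics and the consolidated report.
#
# Pulls together the per-neuron encoding results (stage 2) and the
# population analyses (stages 3-4): across-area AUROC comparisons,
# force- vs gape-related proportion tests, and the figure-style CSV panels
# (plus PNG quick-looks). Run stages 1-4 first.

suppressPackageStartupMessages(library(gapeforce))
seed <- 1

cohort <- read.csv("results/glm/auroc_by_model.csv")
cls <- read.csv("results/glm/classification.csv")
lag_tab <- if (file.exists("results/glm/preferred_lags.csv"))
  read.csv("results/glm/preferred_lags.csv") else NULL

message("across-area comparison (joint extrinsic model):")
aa <- compare_across_areas(cohort, "no_history")
message(sprintf("  Kruskal-Wallis p = %.2g (n = %s)", aa$kruskal$p.value,
                paste(aa$n, collapse = "/")))

counts <- do.call(rbind, lapply(split(cls[cls$included, ], cls$area[cls$included]),
                                function(d) data.frame(
                                  area = d$area[1],
                                  n_force = sum(d$force_related),
                                  n_gape = sum(d$gape_related),
                                  n = nrow(d))))
props <- compare_proportions(counts)
write.csv(props$within, "results/glm/proportions_within.csv",
          row.names = FALSE)
write.csv(props$between, "results/glm/proportions_between.csv",
          row.names = FALSE)
message("force- vs gape-related proportions per area:")
for (i in seq_len(nrow(props$within)))
  message(sprintf("  %s: force %.0f%% +/- %.0f%%, gape %.0f%% +/- %.0f%% (chi-sq p = %.2g)",
                  props$within$area[i],
                  100 * props$within$prop_force[i],
                  100 * props$within$se_force[i],
                  100 * props$within$prop_gape[i],
                  100 * props$within$se_gape[i],
                  props$within$p.value[i]))

# rebuild the population objects for the report panels (same seeds as 03/04)
pop_task <- generate_trials(task_spec(trials_per_condition = 45,
                                      seed = seed + 3))
pop <- simulate_population_latent(population_latent_spec(seed = seed + 4),
                                  pop_task$trials)
ct <- build_condition_tensor(pop$binned, pop_task$trials)
fit <- fit_dpca(ct, n_components = 15)
dec <- decode_timecourse(ct, "gape", n_cv = 200, n_shuffle = 100,
                         seed = seed + 20)
peth <- compute_peth(pop$binned, factor(pop_task$trials$gape_index))
lags <- list(table = lag_tab, n_excluded = NA,
             median_by_area = if (!is.null(lag_tab))
               tapply(lag_tab$preferred_lag_s, lag_tab$area, median)
             else NULL)
paths <- report("results/report", cohort, lags, fit, dec, peth = peth,
                plots = TRUE)
message(sprintf("stage 5 done; %d report files under results/report/",
                length(paths)))
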