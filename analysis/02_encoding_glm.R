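#!/usr/bin/env Rscript
# Stage 2: single-neuron encoding models.
#
# Reads the simulated session from stage 1, fits the full model zoo per
# neuron with shared 10-fold trial-level cross-validation, and reproduces the
# coefficient-level analyses: paired model comparisons (force/gape removal),
# force-/gape-related classification, preferred force lags, and the
# spike-history timescale comparison. Run analysis/01_simulate_task.R first.

suppressPackageStartupMessages(library(gapeforce))
dir.create("results/glm", showWarnings = FALSE, recursive = TRUE)
seed <- 1

ds <- read_dataset("results/sim/glm")
binned <- align_and_bin(ds$spikes, ds$trials)
message(sprintf("fitting %d model specs x %d neurons (shared folds) ...",
                length(model_zoo_specs()), nrow(binned$neurons)))
zoo <- run_model_zoo(binned, ds$trials, ds$forces, folds = 10,
                     seed = seed + 10)
write.csv(zoo$table, "results/glm/auroc_by_fold.csv", row.names = FALSE)
cohort <- zoo_mean_auroc(zoo)
write.csv(cohort, "results/glm/auroc_by_model.csv", row.names = FALSE)

message("paired model comparisons across neurons:")
for (pair in list(c("no_history", "gape_only"), c("no_history", "force_only"),
                  c("full", "no_history"))) {
  cmp <- compare_models(zoo, pair[1], pair[2])
  message(sprintf("  %s > %s: mean dAUROC = %+.3f, signed-rank p = %.2g",
                  pair[1], pair[2],
                  mean(cmp$pairs$mean_auroc_a - cmp$pairs$mean_auroc_b),
                  cmp$test$p.value))
}

cls <- lapply(zoo$fits, function(f)
  classify_neuron(f$force_only, f$gape_only))
cls_tab <- data.frame(
  neuron_id = as.integer(names(zoo$fits)),
  included = vapply(cls, `[[`, logical(1), "included"),
  force_related = vapply(cls, `[[`, logical(1), "force_related"),
  gape_related = vapply(cls, `[[`, logical(1), "gape_related")
)
cls_tab <- merge(cls_tab, binned$neurons, by = "neuron_id")
write.csv(cls_tab, "results/glm/classification.csv", row.names = FALSE)
message(sprintf("force-related: %d/%d, gape-related: %d/%d (included only)",
                sum(cls_tab$force_related), sum(cls_tab$included),
                sum(cls_tab$gape_related), sum(cls_tab$included)))

force_fits <- lapply(zoo$fits, `[[`, "force_only")
lags <- preferred_force_lag(force_fits,
                            areas = binned$neurons$area[
                              match(as.integer(names(zoo$fits)),
                                    binned$neurons$neuron_id)])
if (!is.null(lags$table))
  write.csv(lags$table, "results/glm/preferred_lags.csv", row.names = FALSE)
message(sprintf("preferred lags: %d neurons with a significant lag, %d excluded",
                if (is.null(lags$table)) 0 else nrow(lags$table),
                lags$n_excluded))

hist_cmp <- compare_history_timescales(lapply(zoo$fits, `[[`, "full"))
write.csv(hist_cmp$values, "results/glm/history_betas.csv", row.names = FALSE)
message(sprintf("history |beta| Kruskal-Wallis across timescales: p = %.2g",
                hist_cmp$kruskal$p.value))
message("stage 2 done; outputs under results/glm/")
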