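# Model-zoo fitting and the single-neuron analyses built on it: paired model
# comparison, force-/gape-related classification, preferred force lags, and
# spike-history timescale comparison.

#' Exact Wilcoxon signed-rank test
#'
#' One-sample signed-rank test of `x` against `mu`. For n <= 14 non-zero
#' differences the null distribution is enumerated exactly over all sign
#' assignments (ties handled with average ranks); beyond that the normal
#' approximation of [stats::wilcox.test()] is used. Zero differences are
#' dropped; if none remain, p = 1.
#'
#' @param x sample.
#' @param mu null location.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return list with `statistic` (V), `p.value`, `n`.
#' @export
signed_rank_test <- function(x, mu = 0,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p.value = 1, n = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vnull <- as.vector(signs %*% r)
    p <- switch(alternative,
                greater = mean(vnull >= v - 1e-12),
                less = mean(vnull <= v + 1e-12),
                two.sided = min(1, 2 * min(mean(vnull >= v - 1e-12),
                                           mean(vnull <= v + 1e-12))))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, mu = mu, alternative = alternative,
                         exact = FALSE)$p.value)
  }
  list(statistic = v, p.value = p, n = n)
}

#' Fit every encoding model with shared folds
#'
#' Fits each model specification to each neuron using one fixed trial-level
#' fold partition per neuron, so AUROCs are comparable across models.
#'
#' @param binned an [align_and_bin] result.
#' @param trials the matching [trial_table].
#' @param forces a [force_traces].
#' @param neurons neuron ids (default: all in `binned`).
#' @param specs named list of [model_spec]s (default: the full zoo).
#' @param folds,seed cross-validation setup (see [make_folds()]).
#' @param basis,lags covariate construction (see [build_design_matrix()]).
#' @return object of class `model_zoo`: `fits[[neuron]][[model]]` ([fit_glm]
#'   results) and a tidy `table` (neuron_id, area, model, fold, auroc,
#'   converged).
#' @export
run_model_zoo <- function(binned, trials, forces, neurons = NULL,
                          specs = model_zoo_specs(), folds = 10, seed = 1,
                          basis = make_basis(), lags = force_lag_grid()) {
  if (is.null(neurons)) neurons <- binned$neurons$neuron_id
  fold <- make_folds(trials, k = folds, seed = seed)
  fits <- list()
  rows <- list()
  for (nid in neurons) {
    area <- binned$neurons$area[match(nid, binned$neurons$neuron_id)]
    fits_n <- list()
    for (mn in names(specs)) {
      des <- build_design_matrix(binned, trials, forces, nid, specs[[mn]],
                                 basis, lags)
      ft <- fit_glm(des, folds = fold)
      fits_n[[mn]] <- ft
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = nid, area = area, model = mn,
        fold = seq_along(ft$auroc_test),
        auroc = ft$auroc_test, converged = ft$converged
      )
    }
    fits[[as.character(nid)]] <- fits_n
  }
  structure(list(fits = fits, table = do.call(rbind, rows),
                 models = names(specs)),
            class = "model_zoo")
}

#' Mean cross-validated AUROC per neuron and model
#' @param zoo a [run_model_zoo] result.
#' @return data.frame (neuron_id, area, model, mean_auroc, n_converged).
#' @export
zoo_mean_auroc <- function(zoo) {
  tab <- zoo$table
  ok <- tab$converged & !is.na(tab$auroc)
  agg <- stats::aggregate(auroc ~ neuron_id + area + model,
                          data = tab[ok, ], FUN = mean)
  names(agg)[names(agg) == "auroc"] <- "mean_auroc"
  conv <- stats::aggregate(converged ~ neuron_id + model, data = tab, FUN = sum)
  names(conv)[names(conv) == "converged"] <- "n_converged"
  merge(agg, conv, by = c("neuron_id", "model"))
}

#' Paired model comparison across neurons
#'
#' Wilcoxon signed-rank test of per-neuron mean AUROCs between two models
#' fitted with identical folds (e.g. the joint extrinsic model vs the model
#' with force removed).
#'
#' @param zoo a [run_model_zoo] result.
#' @param model_a,model_b model names; the alternative `"greater"` tests
#'   whether `model_a` outperforms `model_b`.
#' @param alternative test direction.
#' @return list with the per-neuron AUROC pairs (`pairs`, the Fig-4-style
#'   scatter data) and the signed-rank `test`.
#' @export
compare_models <- function(zoo, model_a, model_b,
                           alternative = "greater") {
  m <- zoo_mean_auroc(zoo)
  a <- m[m$model == model_a, c("neuron_id", "mean_auroc")]
  b <- m[m$model == model_b, c("neuron_id", "mean_auroc")]
  pairs <- merge(a, b, by = "neuron_id", suffixes = c("_a", "_b"))
  test <- signed_rank_test(pairs$mean_auroc_a - pairs$mean_auroc_b, 0,
                           alternative = alternative)
  list(pairs = pairs, test = test, models = c(model_a, model_b))
}

#' Classify a neuron as force- and/or gape-related
#'
#' A neuron is included only if its model converged in at least
#' `min_converged` of the cross-validation folds. It is flagged
#' force-related (gape-related) when the fold AUROCs of the force-only
#' (gape-only) model are significantly above chance by a one-sided
#' signed-rank test.
#'
#' @param force_fit,gape_fit [fit_glm] results for the force-only and
#'   gape-only models.
#' @param alpha significance level.
#' @param min_converged minimum converged folds for inclusion.
#' @param chance chance AUROC level.
#' @return list with `included`, `force_related`, `gape_related`, and the
#'   two p-values.
#' @export
classify_neuron <- function(force_fit, gape_fit, alpha = 0.05,
                            min_converged = 6, chance = 0.5) {
  test_one <- function(fit) {
    a <- fit$auroc_test[fit$converged & !is.na(fit$auroc_test)]
    if (length(a) == 0) return(list(p.value = 1))
    signed_rank_test(a, mu = chance, alternative = "greater")
  }
  tf <- test_one(force_fit)
  tg <- test_one(gape_fit)
  included <- force_fit$n_converged >= min_converged &&
    gape_fit$n_converged >= min_converged
  list(included = included,
       force_related = included && tf$p.value < alpha,
       gape_related = included && tg$p.value < alpha,
       p_force = tf$p.value, p_gape = tg$p.value)
}

#' Preferred temporal lag of bite force per neuron
#'
#' From each neuron's force-only fit (all-trials coefficients and standard
#' errors): keep lags whose coefficient differs from zero by a Wald test
#' (p < `alpha`, two-sided, normal reference), and report the lag with the
#' largest `|beta|` among them. Ties break toward the most negative
#' (force-leading) lag. Neurons with no significant lag are excluded and
#' counted.
#'
#' @param fits list of force-only [fit_glm] results.
#' @param lags force lag grid (s).
#' @param areas optional character vector of area labels per fit (for
#'   per-area medians).
#' @param alpha Wald significance level.
#' @return list: `table` (neuron_id, area, preferred_lag_s, n_significant),
#'   `n_excluded`, `median_by_area` (s).
#' @export
preferred_force_lag <- function(fits, lags = force_lag_grid(), areas = NULL,
                                alpha = 0.05) {
  rows <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    fi <- fit$col_groups == "force"
    b <- fit$full$beta[fi]
    se <- fit$full$se[fi]
    z <- b / se
    pv <- 2 * stats::pnorm(-abs(z))
    sig <- which(is.finite(pv) & pv < alpha)
    if (length(sig) == 0) return(NULL)
    best <- sig[abs(b[sig]) == max(abs(b[sig]))]
    best <- best[which.min(lags[best])]  # tie-break: most negative lag
    data.frame(neuron_id = fit$neuron_id,
               area = if (is.null(areas)) NA_character_ else areas[i],
               preferred_lag_s = lags[best],
               n_significant = length(sig))
  })
  keep <- !vapply(rows, is.null, logical(1))
  tab <- do.call(rbind, rows[keep])
  med <- if (!is.null(tab) && !all(is.na(tab$area)))
    tapply(tab$preferred_lag_s, tab$area, stats::median) else NULL
  list(table = tab, n_excluded = sum(!keep), median_by_area = med)
}

#' Compare spike-history coefficient magnitudes across timescales
#'
#' Kruskal–Wallis test of `|beta|` for the 16/44/108-ms history filters
#' across neurons, with Bonferroni-corrected pairwise Wilcoxon follow-ups.
#'
#' @param fits list of [fit_glm] results from models that include the
#'   history group (e.g. the full model).
#' @param basis the history basis (for timescale labels).
#' @return list with `values` (long data.frame), `kruskal`, `pairwise`.
#' @export
compare_history_timescales <- function(fits, basis = make_basis()) {
  if (length(fits) < 3)
    stop_gf("at least 3 neurons are required, got %d", length(fits))
  vals <- do.call(rbind, lapply(fits, function(fit) {
    hi <- fit$col_groups == "history"
    data.frame(neuron_id = fit$neuron_id,
               timescale_ms = round(basis$timescales * 1000),
               abs_beta = abs(fit$full$beta[hi]))
  }))
  vals$timescale_ms <- factor(vals$timescale_ms)
  kw <- stats::kruskal.test(abs_beta ~ timescale_ms, data = vals)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(vals$abs_beta, vals$timescale_ms,
                                p.adjust.method = "bonferroni",
                                paired = TRUE))
  list(values = vals, kruskal = kw, pairwise = pw)
}

#' Single-lag control models
#'
#' Controls for the asymmetry in how force (8 lagged features) and gape (one
#' constant) enter the main model: at each of six spike time points after FO,
#' the spike indicator of that single 4-ms bin is modeled per trial from one
#' force value (read at `force_time` after FO), gape, and their product —
#' six mini-GLMs per neuron, each also fitted with force or gape removed.
#'
#' @param binned,trials,forces as in [build_design_matrix()].
#' @param neuron neuron id.
#' @param spike_times spike sampling time points (s after FO).
#' @param force_time time of the single force covariate (s after FO).
#' @param folds,seed trial-level cross-validation setup.
#' @return list (one element per spike time) of lists with [fit_glm] results
#'   `joint`, `force_only`, `gape_only` (elements may be `NULL` when the bin
#'   has no spikes in any trial).
#' @export
single_lag_control <- function(binned, trials, forces, neuron,
                               spike_times = c(0.06, 0.08, 0.10, 0.12,
                                               0.14, 0.16),
                               force_time = 0.1, folds = 10, seed = 1) {
  ni <- match(neuron, binned$neurons$neuron_id)
  if (is.na(ni)) stop_gf("neuron %s not present in the binned data", neuron)
  bw <- binned$bin_width
  fo <- trials$fo_time_s
  f100 <- vapply(seq_len(nrow(trials)), function(i)
    force_at(forces, trials$trial_id[i], fo[i] + force_time), numeric(1))
  G <- trials$gape_mm
  fold <- make_folds(trials, k = folds, seed = seed)
  out <- lapply(spike_times, function(ts) {
    b <- floor((ts - binned$window[1]) / bw) + 1
    if (b < 1 || b > dim(binned$counts)[3])
      stop_gf("no bin at %g s after FO", ts)
    y <- (binned$counts[ni, , b] >= 1L) + 0L
    mk <- function(cols, grp, name) {
      X <- cbind(1, cols)
      colnames(X) <- c("(Intercept)", grp)
      structure(list(X = X, y = y, col_groups = c("intercept", grp),
                     trial_index = trials$trial_id, trials = trials,
                     model = name, neuron_id = neuron),
                class = "design_matrix")
    }
    fit_or_null <- function(des) {
      if (sum(des$y) == 0L) return(NULL)
      fit_glm(des, folds = fold)
    }
    list(
      spike_time_s = ts,
      joint = fit_or_null(mk(cbind(G, f100, G * f100),
                             c("gape", "force", "interaction"), "joint")),
      force_only = fit_or_null(mk(cbind(f100), "force", "force_only")),
      gape_only = fit_or_null(mk(cbind(G), "gape", "gape_only"))
    )
  })
  names(out) <- paste0(round(spike_times * 1000), "ms")
  out
}
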