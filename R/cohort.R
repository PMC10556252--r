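# Cohort-level statistics across cortical areas and the figure-style report
# (every panel is backed by a CSV of plotted values).

#' Binomial standard error of a proportion
#' @param p proportion.
#' @param n sample size.
#' @return `sqrt(p (1 - p) / n)`.
#' @export
binomial_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Compare encoding performance across cortical areas
#'
#' Kruskal–Wallis one-way analysis of variance of per-neuron mean AUROCs
#' across the areas present, followed by Bonferroni-corrected pairwise
#' Wilcoxon rank-sum comparisons.
#'
#' @param table data.frame with columns `area`, `model`, `mean_auroc`
#'   (e.g. from [zoo_mean_auroc()]).
#' @param model model name to compare on.
#' @return list with `kruskal` (htest), `pairwise` (pairwise.htest), `n`
#'   per area.
#' @export
compare_across_areas <- function(table, model = "no_history") {
  tab <- table[table$model == model & !is.na(table$mean_auroc), ]
  tab$area <- factor(as.character(tab$area))
  if (nlevels(tab$area) < 2)
    stop_gf("need at least 2 areas, found %d", nlevels(tab$area))
  kw <- stats::kruskal.test(mean_auroc ~ area, data = tab)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(tab$mean_auroc, tab$area,
                                p.adjust.method = "bonferroni"))
  list(kruskal = kw, pairwise = pw, n = table(tab$area))
}

#' Compare force- vs gape-related proportions
#'
#' Within each area, a chi-squared test of the force-related against the
#' gape-related proportion; between areas, pairwise chi-squared tests of
#' each proportion at the Bonferroni-adjusted level alpha / 3 (0.0167 for
#' the three area pairs at alpha = 0.05).
#'
#' @param counts data.frame with columns `area`, `n_force` (force-related),
#'   `n_gape` (gape-related), `n` (included neurons).
#' @param alpha nominal level for the pairwise comparisons.
#' @param correct apply Yates continuity correction (default off).
#' @return list with `within` (per-area statistic, p, proportions and
#'   binomial SEs), `between` (per area pair and feature), and
#'   `alpha_adjusted`.
#' @export
compare_proportions <- function(counts, alpha = 0.05, correct = FALSE) {
  if (any(counts$n == 0))
    stop_gf("area %s has no included neurons",
            counts$area[which(counts$n == 0)[1]])
  chi <- function(k1, n1, k2, n2) {
    m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2)
    if (all(m == 0) || any(rowSums(m) == 0))
      return(list(statistic = NA_real_, p.value = NA_real_))
    ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
    list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  within <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    w <- chi(counts$n_force[i], counts$n[i], counts$n_gape[i], counts$n[i])
    data.frame(area = counts$area[i],
               prop_force = counts$n_force[i] / counts$n[i],
               se_force = binomial_se(counts$n_force[i] / counts$n[i],
                                      counts$n[i]),
               prop_gape = counts$n_gape[i] / counts$n[i],
               se_gape = binomial_se(counts$n_gape[i] / counts$n[i],
                                     counts$n[i]),
               statistic = w$statistic, p.value = w$p.value)
  }))
  pairs <- utils::combn(seq_len(nrow(counts)), 2)
  n_pairs <- ncol(pairs)
  between <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    do.call(rbind, lapply(c("force", "gape"), function(feat) {
      k <- counts[[paste0("n_", feat)]]
      b <- chi(k[i1], counts$n[i1], k[i2], counts$n[i2])
      data.frame(area_1 = counts$area[i1], area_2 = counts$area[i2],
                 feature = feat, statistic = b$statistic,
                 p.value = b$p.value,
                 significant = !is.na(b$p.value) &
                   b$p.value < alpha / n_pairs)
    }))
  }))
  list(within = within, between = between, alpha_adjusted = alpha / n_pairs)
}

#' Write the figure-style report
#'
#' Emits the panel families of the analysis as CSV files (PETH time courses,
#' AUROC distributions per model and area, preferred-lag histograms with
#' medians, dPCA variance bars/pie and cumulative curves, decoding accuracy
#' with null bands), deterministically for fixed inputs. Optionally renders
#' quick-look PNG panels of the same values.
#'
#' @param dir output directory (created if absent).
#' @param cohort data.frame from [zoo_mean_auroc()] (one row per
#'   neuron/model); must be non-empty.
#' @param lags a [preferred_force_lag] result.
#' @param dpca a [fit_dpca] result.
#' @param decoding a [decode_timecourse] result or named list of them.
#' @param peth optional [compute_peth] result.
#' @param plots also render PNG panels.
#' @return invisibly, the paths written.
#' @export
report <- function(dir, cohort, lags, dpca, decoding, peth = NULL,
                   plots = FALSE) {
  missing_in <- c(cohort = missing(cohort) || is.null(cohort),
                  lags = missing(lags) || is.null(lags),
                  dpca = missing(dpca) || is.null(dpca),
                  decoding = missing(decoding) || is.null(decoding))
  if (any(missing_in))
    stop_gf("missing upstream results: %s",
            paste(names(missing_in)[missing_in], collapse = ", "))
  if (nrow(cohort) == 0) stop_gf("empty cohort table")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  put(cohort, "auroc_by_model.csv")
  if (!is.null(lags$table)) put(lags$table, "preferred_lags.csv")
  med <- lags$median_by_area
  put(data.frame(area = names(med) %||% character(),
                 median_lag_s = as.numeric(med)), "lag_medians.csv")
  put(data.frame(marginalization = names(dpca$marginal_variance_pct),
                 variance_pct = as.numeric(dpca$marginal_variance_pct)),
      "variance_pie.csv")
  put(dpca$components, "variance_components.csv")
  put(dpca$cumulative, "variance_cumulative.csv")
  if (inherits(decoding, "decoding_result")) decoding <- list(decoding)
  for (dr in decoding) {
    put(data.frame(time_s = dr$time, accuracy = dr$accuracy,
                   null_max = apply(dr$null_accuracies, 2, max),
                   null_mean = colMeans(dr$null_accuracies),
                   chance = dr$chance, significant = dr$significant),
        sprintf("decoding_%s.csv", dr$target))
  }
  if (!is.null(peth)) {
    d <- dim(peth$rate)
    put(data.frame(
      neuron = rep(seq_len(d[1]), times = d[2] * d[3]),
      group = rep(rep(peth$groups, each = d[1]), times = d[3]),
      time_s = rep(peth$time, each = d[1] * d[2]),
      rate_hz = as.vector(peth$rate),
      sem_hz = as.vector(peth$sem)), "peth.csv")
  }
  if (plots) {
    png_panel <- function(name, expr) {
      p <- file.path(dir, name)
      grDevices::png(p, width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr()
      paths <<- c(paths, p)
    }
    png_panel("auroc_box.png", function()
      graphics::boxplot(mean_auroc ~ model, data = cohort,
                        ylab = "mean AUROC", las = 2))
    png_panel("variance_cumulative.png", function() {
      graphics::matplot(dpca$cumulative$n,
                        dpca$cumulative[, c("dpca", "pca")], type = "b",
                        pch = 1, xlab = "components",
                        ylab = "cumulative variance (%)")
      graphics::legend("bottomright", c("dPCA", "PCA"), col = 1:2, lty = 1:2)
    })
    for (dr in decoding) {
      png_panel(sprintf("decoding_%s.png", dr$target), function() {
        graphics::plot(dr$time, dr$accuracy, type = "l", ylim = c(0, 1),
                       xlab = "time from FO (s)", ylab = "accuracy",
                       main = dr$target)
        graphics::lines(dr$time, apply(dr$null_accuracies, 2, max),
                        col = "grey50", lty = 2)
        graphics::abline(h = dr$chance, col = "grey70")
      })
    }
  }
  invisible(paths)
}
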