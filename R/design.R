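#' Encoding-model specifications
#'
#' The model zoo: the full model uses spike history, gape, the eight lagged
#' force covariates, and the eight gape-by-force interactions; reduced models
#' drop named groups. Removing gape (or force) also removes the interaction
#' group — an interaction does not outlive its parent — unless
#' `retain_interaction = TRUE`. The `*_only` models are literal (that group
#' plus intercept). `no_history` is the joint extrinsic model (gape + force +
#' interaction) used for the force-removal / gape-removal comparison at the
#' single-neuron level.
#'
#' @param name one of `"full"`, `"no_gape"`, `"no_force"`,
#'   `"no_force_no_gape"`, `"no_history"`, `"force_only"`, `"gape_only"`,
#'   `"interaction_only"`, `"history_only"`.
#' @param retain_interaction keep the interaction group in removal-type
#'   models.
#' @return object of class `model_spec`: list with `name` and `groups`.
#' @export
model_spec <- function(name = c("full", "no_gape", "no_force",
                                "no_force_no_gape", "no_history",
                                "force_only", "gape_only",
                                "interaction_only", "history_only"),
                       retain_interaction = FALSE) {
  name <- match.arg(name)
  groups <- switch(
    name,
    full = c("history", "gape", "force", "interaction"),
    no_gape = c("history", "force", if (retain_interaction) "interaction"),
    no_force = c("history", "gape", if (retain_interaction) "interaction"),
    no_force_no_gape = c("history", if (retain_interaction) "interaction"),
    no_history = c("gape", "force", "interaction"),
    force_only = "force",
    gape_only = "gape",
    interaction_only = "interaction",
    history_only = "history"
  )
  structure(list(name = name, groups = groups), class = "model_spec")
}

#' All model specifications of the zoo
#' @return named list of [model_spec] objects.
#' @export
model_zoo_specs <- function() {
  nm <- c("full", "no_gape", "no_force", "no_force_no_gape", "no_history",
          "force_only", "gape_only", "interaction_only", "history_only")
  stats::setNames(lapply(nm, model_spec), nm)
}

#' Build the encoding-model design matrix for one neuron
#'
#' One row per (trial, 4-ms bin). Columns, by group: intercept; three
#' spike-history features (the neuron's own binarized spike train filtered
#' through the raised-cosine basis, within trial only, zero-padded at the
#' leading bins); gape (mm, constant within trial); bite force at the eight
#' lags of the lag grid (the trace evaluated at bin time + lag); and the
#' eight gape-by-force products. With all extrinsic groups present there are
#' 17 extrinsic covariates (1 + 8 + 8). The response is the binarized spike
#' indicator per bin.
#'
#' @param binned an [align_and_bin] result.
#' @param trials the matching [trial_table].
#' @param forces a [force_traces] spanning
#'   `[window[1] + min(lags), window[2] + max(lags)]` around each FO.
#' @param neuron a neuron_id present in `binned$neurons`.
#' @param spec a [model_spec].
#' @param basis a [make_basis] result.
#' @param lags force lag grid (s).
#' @return object of class `design_matrix`: list with `X` (including the
#'   intercept column), `y`, `col_groups`, `trial_index` (trial id per row),
#'   `trials`; attribute `clipped_fraction` reports the share of bins with
#'   more than one spike.
#' @export
build_design_matrix <- function(binned, trials, forces, neuron,
                                spec = model_spec("full"),
                                basis = make_basis(),
                                lags = force_lag_grid()) {
  ni <- match(neuron, binned$neurons$neuron_id)
  if (is.na(ni)) stop_gf("neuron %s not present in the binned data", neuron)
  d <- dim(binned$counts)
  cnt <- matrix(binned$counts[ni, , ], d[2], d[3])
  s <- (cnt >= 1L) + 0L
  clipped <- mean(cnt > 1L)
  y <- as.vector(t(s))  # trial-major: all bins of trial 1, then trial 2, ...
  n_tr <- d[2]; B <- d[3]
  cols <- list(intercept = matrix(1, n_tr * B, 1))
  grp <- "intercept"
  if ("history" %in% spec$groups) {
    H <- matrix(0, n_tr * B, ncol(basis$B))
    for (i in seq_len(n_tr))
      H[((i - 1) * B + 1):(i * B), ] <- history_features(s[i, ], basis)
    cols$history <- H
    grp <- c(grp, rep("history", ncol(H)))
  }
  need_force <- any(c("force", "interaction") %in% spec$groups)
  Fm2 <- NULL
  if (need_force) {
    ex <- extrinsic_covariates(trials, forces, binned$window,
                               binned$bin_width, lags)
    Fm2 <- matrix(aperm(ex$Fm, c(2, 1, 3)), n_tr * B, length(lags))
  }
  if ("gape" %in% spec$groups) {
    cols$gape <- matrix(rep(trials$gape_mm, each = B), ncol = 1)
    grp <- c(grp, "gape")
  }
  if ("force" %in% spec$groups) {
    cols$force <- Fm2
    grp <- c(grp, rep("force", ncol(Fm2)))
  }
  if ("interaction" %in% spec$groups) {
    # gape is centered on the session mean of the three gape values before
    # forming the product, so the interaction columns are not collinear with
    # the force columns (raw G*F correlates > 0.98 with F since the gape
    # spread is small relative to its mean)
    g_c <- trials$gape_mm - mean(unique(trials$gape_mm))
    cols$interaction <- Fm2 * rep(g_c, each = B)
    grp <- c(grp, rep("interaction", ncol(Fm2)))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- make_col_names(grp, lags, basis)
  structure(
    list(X = X, y = y, col_groups = grp,
         trial_index = rep(trials$trial_id, each = B),
         trials = trials, model = spec$name, neuron_id = neuron),
    class = "design_matrix", clipped_fraction = clipped
  )
}

make_col_names <- function(grp, lags, basis) {
  nm <- character(length(grp))
  nm[grp == "intercept"] <- "(Intercept)"
  nm[grp == "history"] <- paste0("H_", round(basis$timescales * 1000), "ms")[
    seq_len(sum(grp == "history"))]
  nm[grp == "gape"] <- "gape_mm"
  nm[grp == "force"] <- paste0("F_", round(lags * 1000), "ms")[
    seq_len(sum(grp == "force"))]
  nm[grp == "interaction"] <- paste0("GF_", round(lags * 1000), "ms")[
    seq_len(sum(grp == "interaction"))]
  nm
}
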