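# Demixed principal components analysis: marginalization of the
# trial-averaged population tensor into time / gape / force / interaction
# parts, and per-marginalization reduced-rank regression for the
# decoder/encoder pairs.

# Marginalization operators on a centered tensor Y [neuron, gape, force,
# time]. The grouping pools each task parameter's main effect with its
# parameter-x-time modulation:
#   time:        mean over (gape, force)               -> function of t
#   gape:        mean over force, minus time part      -> function of (g, t)
#   force:       mean over gape, minus time part       -> function of (f, t)
#   interaction: remainder                             -> function of (g, f, t)
# The four parts sum to Y exactly and are mutually orthogonal on a balanced
# grid.
marginalize_array <- function(Y) {
  d <- dim(Y)
  N <- d[1]; G <- d[2]; Fd <- d[3]; B <- d[4]
  # means via reshapes + .rowMeans (much faster than apply on large tensors)
  XT <- matrix(.rowMeans(matrix(aperm(array(Y, c(N, G * Fd, B)), c(1, 3, 2)),
                                N * B, G * Fd), N * B, G * Fd), N, B)
  XG <- matrix(.rowMeans(matrix(aperm(array(Y, c(N * G, Fd, B)), c(1, 3, 2)),
                                N * G * B, Fd), N * G * B, Fd), N * G, B)
  XF <- matrix(.rowMeans(matrix(aperm(Y, c(1, 3, 4, 2)), N * Fd * B, G),
                         N * Fd * B, G), N * Fd, B)
  bT <- array(XT[, rep(seq_len(B), each = G * Fd)], d)
  bG <- array(XG[, rep(seq_len(B), each = Fd)], d) - bT
  bF <- aperm(array(XF[, rep(seq_len(B), each = G)], c(N, Fd, G, B)),
              c(1, 3, 2, 4)) - bT
  bI <- Y - bT - bG - bF
  list(time = bT, gape = bG, force = bF, interaction = bI)
}

# mean over one collapsed middle dimension: A [N, k, B] -> [N, B]
mean_mid <- function(A) {
  d <- dim(A)
  matrix(.rowMeans(matrix(aperm(A, c(1, 3, 2)), d[1] * d[3], d[2]),
                   d[1] * d[3], d[2]), d[1], d[3])
}

#' Condition-averaged population tensor
#'
#' Converts aligned spike counts to smoothed per-trial rates (same kernel
#' policy as the PETHs), averages them within each of the nine (gape, force)
#' cells, and stores the per-neuron grand mean for centering.
#'
#' @param binned an [align_and_bin] result.
#' @param trials the matching [trial_table].
#' @param kernel_sigma Gaussian smoothing sd (s); 0 disables smoothing.
#' @param trial_rates optional precomputed array `[neuron, trial, bin]` of
#'   rates (bypasses counts->rate conversion, e.g. for ground-truth rates).
#' @return object of class `condition_tensor`: `Xbar` (`[neuron, gape,
#'   force, time]`), `trial_rates`, `gape_index`/`force_level` per trial,
#'   `grand_mean` per neuron, `time`, `bin_width`.
#' @export
build_condition_tensor <- function(binned, trials, kernel_sigma = 0.05,
                                   trial_rates = NULL) {
  d <- dim(binned$counts)
  cell_n <- table(factor(trials$gape_index, 1:3),
                  factor(trials$force_level, 1:3))
  if (any(cell_n < 2)) {
    bad <- which(cell_n < 2, arr.ind = TRUE)[1, ]
    stop_gf("condition cell (gape %d, force %d) has %d trial(s); need >= 2",
            bad[1], bad[2], cell_n[bad[1], bad[2]])
  }
  if (is.null(trial_rates)) {
    W <- smoothing_matrix(d[3], kernel_sigma, binned$bin_width)
    trial_rates <- array(0, d)
    for (n in seq_len(d[1]))
      trial_rates[n, , ] <-
        smooth_rows(matrix(binned$counts[n, , ], d[2], d[3]) /
                      binned$bin_width, W)
  }
  Xbar <- array(0, c(d[1], 3, 3, d[3]))
  for (g in 1:3) for (f in 1:3) {
    sel <- trials$gape_index == g & trials$force_level == f
    Xbar[, g, f, ] <- apply(trial_rates[, sel, , drop = FALSE], c(1, 3), mean)
  }
  structure(
    list(Xbar = Xbar, trial_rates = trial_rates,
         gape_index = trials$gape_index, force_level = trials$force_level,
         grand_mean = apply(Xbar, 1, mean),
         time = binned$time, bin_width = binned$bin_width),
    class = "condition_tensor"
  )
}

#' Marginalize a condition tensor
#'
#' Splits the centered condition-averaged tensor into its time, gape, force,
#' and interaction parts (see the additive decomposition X = X_T + X_G +
#' X_F + X_I of the centered data). The parts reconstruct the centered
#' tensor exactly and are mutually orthogonal.
#'
#' @param ct a [build_condition_tensor] result (or a centered 4-d array).
#' @return named list of arrays shaped like `Xbar`.
#' @export
marginalize <- function(ct) {
  Y <- if (inherits(ct, "condition_tensor"))
    sweep(ct$Xbar, 1, ct$grand_mean) else ct
  marginalize_array(Y)
}

flatten_tensor <- function(Y) matrix(Y, dim(Y)[1], prod(dim(Y)[-1]))

#' Fit demixed principal components
#'
#' For each marginalization phi, solves the reduced-rank ridge regression
#' \deqn{\min_{F_\phi, D_\phi} \|X_\phi - F_\phi D_\phi X\|^2 +
#'   \lambda \|F_\phi D_\phi\|^2}
#' in closed form: the full-rank ridge solution
#' \eqn{A = X_\phi X^\top (X X^\top + \lambda I)^{-1}} is rank-truncated via
#' the SVD of its action on `X`; the encoder columns are the top left
#' singular vectors `U_r` and the decoder is `D = U_r' A`. Components are
#' ordered globally by explained variance of the centered data.
#'
#' @param ct a [build_condition_tensor] result.
#' @param n_components total number of components to keep.
#' @param lambda ridge strength, relative to the mean per-neuron signal
#'   power (`lambda * trace(XX') / N` is added to the diagonal); use
#'   [select_lambda()] for a cross-validated choice.
#' @return object of class `dpca_result`: per-marginalization `encoder`
#'   (N x r) and `decoder` (r x N), a `components` table (marginalization,
#'   rank within it, explained variance % and its split across
#'   marginalizations), pie-chart `marginal_variance_pct`, and `cumulative`
#'   curves for dPCA and a matched PCA.
#' @export
fit_dpca <- function(ct, n_components = 15, lambda = 0) {
  Y <- sweep(ct$Xbar, 1, ct$grand_mean)
  marg <- marginalize_array(Y)
  X <- flatten_tensor(Y)
  N <- nrow(X)
  n_components <- min(n_components, N, ncol(X))
  C <- tcrossprod(X)
  ridge <- lambda * sum(diag(C)) / N
  Creg <- C + diag(ridge, N)
  Cinv <- tryCatch(solve(Creg), error = function(e) NULL)
  if (is.null(Cinv))
    stop_gf("X X' is rank-deficient with lambda = %g; use lambda > 0", lambda)
  totvar <- sum(X^2)
  margvar <- vapply(marg, function(m) sum(m^2), numeric(1))
  comp <- list()
  axes <- list()
  for (phi in names(marg)) {
    Xphi <- flatten_tensor(marg[[phi]])
    A <- Xphi %*% t(X) %*% Cinv          # N x N full-rank ridge solution
    sv <- svd(A %*% X, nu = n_components, nv = 0)
    r <- min(n_components, sum(sv$d > max(sv$d[1], 1e-300) * 1e-12))
    U <- sv$u[, seq_len(r), drop = FALSE]
    D <- t(U) %*% A                      # r x N decoders
    axes[[phi]] <- list(encoder = U, decoder = D)
    S <- D %*% X                         # r x CT component scores
    for (i in seq_len(r)) {
      s_i <- S[i, ]
      f_i <- U[, i]
      ev <- (2 * sum((crossprod(f_i, X)) * s_i) - sum(s_i^2)) / totvar
      split <- vapply(marg, function(m)
        sum((D[i, , drop = FALSE] %*% flatten_tensor(m))^2), numeric(1))
      comp[[length(comp) + 1L]] <- data.frame(
        marginalization = phi, rank_within = i,
        explained_pct = 100 * ev,
        t(100 * split / sum(split) * ev))
    }
  }
  comp <- do.call(rbind, comp)
  ord <- order(comp$explained_pct, decreasing = TRUE)
  comp <- comp[ord, ]
  comp$component <- seq_len(nrow(comp))
  rownames(comp) <- NULL
  # cumulative reconstruction over globally ordered components
  n_curve <- min(n_components, nrow(comp))
  cum_dpca <- numeric(n_curve)
  Xhat <- matrix(0, N, ncol(X))
  for (m in seq_len(n_curve)) {
    phi <- comp$marginalization[m]
    i <- comp$rank_within[m]
    ax <- axes[[phi]]
    Xhat <- Xhat + ax$encoder[, i, drop = FALSE] %*%
      (ax$decoder[i, , drop = FALSE] %*% X)
    cum_dpca[m] <- 100 * (1 - sum((X - Xhat)^2) / totvar)
  }
  sv_pca <- svd(X, nu = 0, nv = 0)$d
  cum_pca <- 100 * cumsum(sv_pca^2)[seq_len(n_curve)] / totvar
  structure(
    list(axes = axes, components = comp,
         marginal_variance_pct = 100 * margvar / totvar,
         cumulative = data.frame(n = seq_len(n_curve), dpca = cum_dpca,
                                 pca = cum_pca),
         lambda = lambda, totvar = totvar, n_components = n_components),
    class = "dpca_result"
  )
}

#' Cross-validated ridge selection for dPCA
#'
#' Splits trials into `folds` groups, fits the per-marginalization ridge
#' solutions on the training-trial averages, and scores the summed
#' reconstruction loss of the held-out-trial marginalizations over a
#' logarithmic grid of relative ridge strengths.
#'
#' @param ct a [build_condition_tensor] result.
#' @param grid candidate `lambda` values (relative, as in [fit_dpca()]).
#' @param folds number of trial folds.
#' @param n_components rank used during scoring.
#' @param seed RNG seed for the trial split.
#' @return the selected lambda; the full score table is attached as
#'   attribute `"scores"`.
#' @export
select_lambda <- function(ct, grid = 10^seq(-7, -1, length.out = 10),
                          folds = 2, n_components = 15, seed = 1) {
  set.seed(seed)
  n_tr <- length(ct$gape_index)
  fold <- integer(n_tr)
  for (g in 1:3) for (f in 1:3) {
    idx <- which(ct$gape_index == g & ct$force_level == f)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  avg_tensor <- function(sel) {
    Xb <- array(0, c(dim(ct$trial_rates)[1], 3, 3, dim(ct$trial_rates)[3]))
    for (g in 1:3) for (f in 1:3) {
      s <- sel & ct$gape_index == g & ct$force_level == f
      Xb[, g, f, ] <- apply(ct$trial_rates[, s, , drop = FALSE], c(1, 3), mean)
    }
    Xb
  }
  scores <- numeric(length(grid))
  for (k in seq_len(folds)) {
    Ytr <- avg_tensor(fold != k)
    Yte <- avg_tensor(fold == k)
    gm <- apply(Ytr, 1, mean)
    Ytr <- sweep(Ytr, 1, gm)
    Yte <- sweep(Yte, 1, gm)
    Xtr <- flatten_tensor(Ytr)
    Xte <- flatten_tensor(Yte)
    marg_te <- marginalize_array(Yte)
    C <- tcrossprod(Xtr)
    N <- nrow(Xtr)
    for (li in seq_along(grid)) {
      Creg <- C + diag(grid[li] * sum(diag(C)) / N, N)
      Cinv <- tryCatch(solve(Creg), error = function(e) NULL)
      if (is.null(Cinv)) { scores[li] <- scores[li] + Inf; next }
      marg_tr <- marginalize_array(Ytr)
      for (phi in names(marg_tr)) {
        A <- flatten_tensor(marg_tr[[phi]]) %*% t(Xtr) %*% Cinv
        sv <- svd(A %*% Xtr, nu = min(n_components, N), nv = 0)
        r <- min(n_components, ncol(sv$u))
        U <- sv$u[, seq_len(r), drop = FALSE]
        FD <- U %*% (t(U) %*% A)
        scores[li] <- scores[li] +
          sum((flatten_tensor(marg_te[[phi]]) - FD %*% Xte)^2)
      }
    }
  }
  best <- grid[which.min(scores)]
  attr(best, "scores") <- data.frame(lambda = grid, loss = scores)
  best
}

#' Variance accounting of a dPCA fit
#'
#' @param result a [fit_dpca] result.
#' @return list: `pie` (percent of centered variance per marginalization,
#'   exact from the decomposition), `components` (per-component explained
#'   variance and its split), `cumulative` (dPCA and matched PCA curves).
#' @export
variance_summary <- function(result) {
  list(pie = result$marginal_variance_pct,
       components = result$components,
       cumulative = result$cumulative)
}
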