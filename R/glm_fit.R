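# Bernoulli-logit fitting (IRLS with a tiny ridge for conditioning),
# trial-level stratified cross-validation, and AUROC scoring.

#' Penalized IRLS for the Bernoulli-logit model
#'
#' Newton / iteratively reweighted least squares with an L2 ridge (default
#' 1e-6) for numerical conditioning, with step halving. The fit is declared
#' converged when the max-norm of the penalized gradient falls below `tol`
#' within `max_iter` iterations.
#'
#' @param X design matrix (including intercept column).
#' @param y binary response.
#' @param ridge L2 penalty.
#' @param max_iter,tol stopping rule.
#' @return list with `beta`, `se` (from the inverse penalized Fisher
#'   information), `converged`, `n_iter`, `loglik`.
#' @export
fit_logit_irls <- function(X, y, ridge = 1e-6, max_iter = 100, tol = 1e-6) {
  p <- ncol(X)
  beta <- numeric(p)
  eps <- 1e-12
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0)) +
      0.5 * ridge * sum(b^2)
  }
  f_old <- nll(beta)
  converged <- FALSE
  it <- 0
  H <- NULL
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, mu - y)) + ridge * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), eps)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + ridge
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      bnew <- beta - alpha * step
      f_new <- nll(bnew)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { bnew <- beta; f_new <- f_old; break }
    }
    beta <- bnew
    f_old <- f_new
  }
  if (is.null(H)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), eps)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + ridge
  }
  se <- sqrt(diag(tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, p, p)
  })))
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0))
  list(beta = stats::setNames(drop(beta), colnames(X)),
       se = stats::setNames(se, colnames(X)),
       converged = converged, n_iter = it, loglik = ll)
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a randomly chosen positive
#' bin receives a higher predicted probability than a randomly chosen
#' negative bin, with ties counted half.
#'
#' @param p_hat predicted probabilities (any monotone score).
#' @param y binary outcomes containing both classes.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(p_hat, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_gf("AUROC is undefined when only one class is present")
  r <- rank(p_hat, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified trial-level folds
#'
#' Deterministically assigns whole trials to `k` folds, stratified by the
#' nine (gape, force) trial types so every fold sees every condition. The
#' partition depends only on the trial table and the seed — reusing the same
#' seed across model specifications guarantees identical folds.
#'
#' @param trials a [trial_table].
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per trial (aligned with `trials` rows).
#' @export
make_folds <- function(trials, k = 10, seed = 1) {
  set.seed(seed)
  k <- as.integer(k)
  fold <- integer(nrow(trials))
  strata <- interaction(trials$gape_index, trials$force_level, drop = TRUE)
  offset <- 0L
  for (s in levels(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold across strata so fold sizes stay balanced
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Fit a cross-validated encoding model
#'
#' Per fold: maximum-likelihood Bernoulli-logit fit on the training trials
#' (splits are at the trial level, never the bin level), AUROC of the
#' predicted per-bin spike probabilities on the held-out trials, and a
#' convergence flag. Non-converged folds are excluded from the mean AUROC.
#' A fit on all trials is kept for coefficient analyses.
#'
#' @param design a [build_design_matrix] result.
#' @param folds number of folds (default 10) or a precomputed integer fold
#'   assignment per trial.
#' @param seed fold RNG seed (ignored if `folds` is a vector).
#' @param ridge,max_iter,tol passed to [fit_logit_irls()].
#' @return object of class `glm_fit`: per-fold coefficient matrix `beta`
#'   and `se` (folds x coefficients), `converged`, `auroc_test`,
#'   `auroc_train`, `mean_auroc` (over converged folds), `full` (all-trials
#'   fit), `fold_of_trial`, plus neuron/model metadata.
#' @export
fit_glm <- function(design, folds = 10, seed = 1, ridge = 1e-6,
                    max_iter = 100, tol = 1e-6) {
  trials <- design$trials
  if (length(folds) == 1L) {
    if (nrow(trials) < folds)
      stop_gf("need at least %d trials for %d-fold cross-validation",
              folds, folds)
    fold <- make_folds(trials, k = folds, seed = seed)
  } else {
    stopifnot(length(folds) == nrow(trials))
    fold <- as.integer(folds)
  }
  if (sum(design$y) == 0L)
    stop_gf("all-zero response: neuron %s never spikes in the window",
            design$neuron_id)
  k <- max(fold)
  p <- ncol(design$X)
  row_fold <- fold[match(design$trial_index, trials$trial_id)]
  beta <- matrix(NA_real_, k, p, dimnames = list(NULL, colnames(design$X)))
  se <- matrix(NA_real_, k, p, dimnames = list(NULL, colnames(design$X)))
  converged <- logical(k)
  auroc_test <- rep(NA_real_, k)
  auroc_train <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- row_fold != f
    if (sum(design$y[tr]) == 0L || sum(design$y[tr]) == sum(tr)) next
    fit <- fit_logit_irls(design$X[tr, , drop = FALSE], design$y[tr],
                          ridge = ridge, max_iter = max_iter, tol = tol)
    beta[f, ] <- fit$beta
    se[f, ] <- fit$se
    converged[f] <- fit$converged
    p_tr <- stats::plogis(drop(design$X[tr, , drop = FALSE] %*% fit$beta))
    p_te <- stats::plogis(drop(design$X[!tr, , drop = FALSE] %*% fit$beta))
    auroc_train[f] <- auroc(p_tr, design$y[tr])
    if (length(unique(design$y[!tr])) == 2L)
      auroc_test[f] <- auroc(p_te, design$y[!tr])
  }
  full <- fit_logit_irls(design$X, design$y, ridge = ridge,
                         max_iter = max_iter, tol = tol)
  ok <- converged & !is.na(auroc_test)
  structure(
    list(neuron_id = design$neuron_id, model = design$model,
         beta = beta, se = se, converged = converged,
         auroc_test = auroc_test, auroc_train = auroc_train,
         mean_auroc = if (any(ok)) mean(auroc_test[ok]) else NA_real_,
         n_converged = sum(converged), full = full,
         fold_of_trial = fold, col_groups = design$col_groups),
    class = "glm_fit"
  )
}
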