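test_that("AUROC follows the Mann-Whitney pair-counting definition", {
  # worked 4-point example, expected value from explicit pair enumeration
  p <- c(0.9, 0.8, 0.7, 0.4)
  y <- c(1, 0, 1, 0)
  expect_equal(auroc(p, y), auroc_bruteforce(p, y))
  expect_equal(auroc(p, y), 0.75)
  expect_equal(auroc(y, y), 1)                 # perfect scores
  expect_equal(auroc(rep(0.3, 10), rep(0:1, 5)), 0.5)  # constant scores
  # ties counted half
  expect_equal(auroc(c(1, 1, 0), c(1, 0, 0)), auroc_bruteforce(c(1, 1, 0),
                                                               c(1, 0, 0)))
  expect_error(auroc(runif(5), rep(1, 5)), "one class")
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    p <- sample(round(runif(n), 2))  # rounded to force ties
    expect_equal(auroc(p, y), auroc_bruteforce(p, y))
  }
})

test_that("the IRLS fitter agrees with the reference logistic regression", {
  set.seed(32)
  n <- 3000
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  beta <- c(-1.5, 0.8, -0.5, 0.2)
  y <- rbinom(n, 1, plogis(X %*% beta))
  ours <- fit_logit_irls(X, y)
  ref <- glm.fit(X, y, family = binomial())
  expect_true(ours$converged)
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-5)
  ref_se <- sqrt(diag(chol2inv(ref$qr$qr[1:4, 1:4])))
  expect_equal(unname(ours$se), ref_se, tolerance = 1e-4)
})

test_that("cross-validated fits recover simulated coefficients within 3 SE", {
  fits <- glm_full_fits()
  truth <- glm_truth()
  z <- unlist(lapply(seq_along(fits), function(i) {
    tv <- c(truth[[i]]$history, truth[[i]]$gape, truth[[i]]$force,
            truth[[i]]$interaction)
    (fits[[i]]$full$beta[-1] - tv) / fits[[i]]$full$se[-1]
  }))
  expect_gte(mean(abs(z) <= 3), 0.95)
})

test_that("chance data scores near 0.5 and separable data near 1", {
  tk <- tiny_task()
  set.seed(33)
  n <- nrow(tk$trials) * 250
  des <- build_design_matrix(tiny_binned(), tk$trials, tk$forces, 1,
                             model_spec("no_history"))
  # response independent of the design: intercept-only truth
  des$y <- rbinom(n, 1, 0.08)
  ft <- fit_glm(des, folds = 10, seed = 1)
  expect_lt(abs(ft$mean_auroc - 0.5), 0.03)
  # near-deterministic response from one covariate
  x <- des$X[, "F_0ms"]
  des$y <- rbinom(n, 1, ifelse(x > median(x), 1, 0.001))
  ft2 <- fit_glm(des, folds = 10, seed = 1)
  expect_gt(ft2$mean_auroc, 0.95)
  des$y <- rep(0L, n)
  expect_error(fit_glm(des, folds = 10, seed = 1), "all-zero")
})

test_that("folds are deterministic, stratified, and shared across models", {
  tk <- glm_task()
  f1 <- make_folds(tk$trials, 10, seed = 4)
  f2 <- make_folds(tk$trials, 10, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(tk$trials, 10, seed = 5)))
  # every fold contains every one of the 9 trial types
  types <- interaction(tk$trials$gape_index, tk$trials$force_level)
  expect_true(all(table(f1, types) >= 1))
  # the same fold vector is reusable across model specs
  des_a <- build_design_matrix(glm_binned(), tk$trials, glm_task()$forces, 1,
                               model_spec("gape_only"))
  ft_a <- fit_glm(des_a, folds = f1)
  expect_identical(ft_a$fold_of_trial, f1)
})

test_that("neuron classification follows convergence and signed-rank rules", {
  mk <- function(aurocs, conv = rep(TRUE, length(aurocs)))
    list(auroc_test = aurocs, converged = conv, n_converged = sum(conv))
  flat <- mk(rep(0.5, 10))
  good <- mk(rep(0.8, 10))
  # all fold AUROCs at chance: no flag either way
  cls <- classify_neuron(flat, flat)
  expect_false(cls$force_related || cls$gape_related)
  # ten folds at 0.8: exact one-sided signed-rank p = 2^-10
  expect_equal(signed_rank_test(rep(0.8, 10), 0.5, "greater")$p.value,
               2^-10)
  cls2 <- classify_neuron(good, flat)
  expect_true(cls2$force_related)
  expect_false(cls2$gape_related)
  # fewer than 6 converged folds: excluded
  few <- mk(rep(0.8, 10), conv = c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_false(classify_neuron(few, good)$included)
  expect_false(classify_neuron(few, good)$force_related)
})

test_that("null cohorts are rarely flagged force-related", {
  g <- generate_trials(task_spec(trials_per_condition = 6, seed = 41))
  truth <- lapply(1:200, function(i)
    glm_ground_truth(i, "MIo", qlogis(runif(1, 0.03, 0.1)), c(0, 0, 0), 0,
                     rep(0, 8), rep(0, 8)))
  sp <- simulate_spikes_glm(truth, g$trials, g$forces, seed = 42)
  b <- align_and_bin(sp, g$trials)
  fold <- make_folds(g$trials, 10, seed = 43)
  flagged <- vapply(b$neurons$neuron_id, function(nid) {
    des <- build_design_matrix(b, g$trials, g$forces, nid,
                               model_spec("force_only"))
    ft <- fit_glm(des, folds = fold)
    classify_neuron(ft, ft)$force_related
  }, logical(1))
  expect_lte(mean(flagged), 0.10)
})

test_that("preferred lags follow significance, argmax, and tie rules", {
  mk_fit <- function(betas, ses) {
    b <- c(0, betas); se <- c(1, ses)
    names(b) <- names(se) <- c("(Intercept)", paste0("F", 1:8))
    list(neuron_id = 1, full = list(beta = b, se = se),
         col_groups = c("intercept", rep("force", 8)))
  }
  lags <- force_lag_grid()
  # insignificant 0.9 is excluded; significant 0.5 wins
  f1 <- mk_fit(c(0.9, 0.5, rep(0, 6)), c(0.7, 0.1, rep(1, 6)))
  r1 <- preferred_force_lag(list(f1), lags)
  expect_equal(r1$table$preferred_lag_s, lags[2])
  # symmetric tie at +/- 52 ms resolves to the more negative lag
  b2 <- rep(0, 8); b2[c(3, 5)] <- 0.6
  s2 <- rep(1, 8); s2[c(3, 5)] <- 0.1
  r2 <- preferred_force_lag(list(mk_fit(b2, s2)), lags)
  expect_equal(r2$table$preferred_lag_s, -0.052)
  # no significant coefficient: neuron excluded and counted
  r3 <- preferred_force_lag(list(mk_fit(rep(0.2, 8), rep(1, 8))), lags)
  expect_null(r3$table)
  expect_equal(r3$n_excluded, 1)
})

test_that("a single imposed force lag is recovered across a cohort", {
  tk <- glm_task()
  idx <- which.min(abs(force_lag_grid() - 0.052))
  bF <- rep(0, 8); bF[idx] <- 0.9
  truth <- lapply(1:3, function(i)
    glm_ground_truth(i, "MIo", qlogis(0.06), c(-1, -0.4, -0.1), 0, bF,
                     rep(0, 8)))
  sp <- simulate_spikes_glm(truth, tk$trials, tk$forces, seed = 44)
  b <- align_and_bin(sp, tk$trials)
  fits <- lapply(1:3, function(i)
    fit_full_data(b, tk$trials, tk$forces, i, "force_only"))
  r <- preferred_force_lag(fits)
  expect_gte(mean(abs(r$table$preferred_lag_s - 0.052) < 1e-9), 2 / 3)
})

test_that("history timescale comparison needs 3+ neurons and sees ordering", {
  fits <- glm_full_fits()
  cmp <- compare_history_timescales(fits)
  med <- tapply(cmp$values$abs_beta, cmp$values$timescale_ms, median)
  expect_gt(med["16"], med["108"])
  expect_error(compare_history_timescales(fits[1]), "3 neurons")
})

test_that("training AUROC of the full model dominates nested reductions", {
  tk <- glm_task()
  fold <- make_folds(tk$trials, 10, seed = 45)
  des_f <- build_design_matrix(glm_binned(), tk$trials, tk$forces, 2)
  des_h <- build_design_matrix(glm_binned(), tk$trials, tk$forces, 2,
                               model_spec("no_force_no_gape"))
  ft_f <- fit_glm(des_f, folds = fold)
  ft_h <- fit_glm(des_h, folds = fold)
  ok <- ft_f$converged & ft_h$converged
  expect_true(all(ft_f$auroc_train[ok] >= ft_h$auroc_train[ok] - 1e-6))
})

test_that("six single-lag control models are built per neuron", {
  tk <- glm_task()
  res <- single_lag_control(glm_binned(), tk$trials, tk$forces, 1,
                            folds = 5, seed = 46)
  expect_equal(length(res), 6)
  expect_equal(names(res), c("60ms", "80ms", "100ms", "120ms", "140ms",
                             "160ms"))
  has_joint <- vapply(res, function(r) !is.null(r$joint), logical(1))
  expect_true(any(has_joint))
  r1 <- res[[which(has_joint)[1]]]
  expect_equal(ncol(r1$joint$beta), 4)  # intercept + gape + force + product
})
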