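test_that("marginalization is additive, orthogonal, and idempotent", {
  set.seed(51)
  Y <- array(rnorm(6 * 3 * 3 * 25), c(6, 3, 3, 25))
  Y <- sweep(Y, 1, apply(Y, 1, mean))  # center per neuron
  m <- marginalize(Y)
  expect_equal(m$time + m$gape + m$force + m$interaction, Y,
               tolerance = 1e-12)
  # pairwise orthogonality
  parts <- lapply(m, as.vector)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(sum(parts[[i]] * parts[[j]])), 1e-8)
  # idempotence: each part maps to itself under re-marginalization
  for (phi in names(m))
    expect_equal(marginalize(m[[phi]])[[phi]], m[[phi]], tolerance = 1e-12)
  # structural zeros: gape part constant over the force axis
  expect_equal(m$gape[, , 1, ], m$gape[, , 3, ], tolerance = 1e-12)
  expect_equal(m$force[, 1, , ], m$force[, 2, , ], tolerance = 1e-12)
})

test_that("time-only activity leaves non-time marginalizations empty", {
  set.seed(52)
  core <- matrix(rnorm(5 * 30), 5, 30)
  core <- core - rowMeans(core)
  Y <- array(0, c(5, 3, 3, 30))
  for (g in 1:3) for (f in 1:3) Y[, g, f, ] <- core
  m <- marginalize(Y)
  expect_equal(m$time, Y, tolerance = 1e-12)
  expect_lt(max(abs(m$gape), abs(m$force), abs(m$interaction)), 1e-12)
})

test_that("dPCA reduces to PCA when all variance is in one marginalization", {
  set.seed(53)
  core <- matrix(rnorm(8 * 40), 8, 40)
  core <- core - rowMeans(core)
  Y <- array(0, c(8, 3, 3, 40))
  for (g in 1:3) for (f in 1:3) Y[, g, f, ] <- core
  ct <- structure(list(Xbar = Y, grand_mean = rep(0, 8)),
                  class = "condition_tensor")
  fit <- fit_dpca(ct, n_components = 8, lambda = 0)
  expect_lt(max(abs(fit$cumulative$dpca - fit$cumulative$pca)), 1e-8)
})

test_that("dPCA loss beats the PCA-axes baseline and decreases with rank", {
  set.seed(54)
  Y <- array(rnorm(7 * 3 * 3 * 20), c(7, 3, 3, 20))
  Y <- sweep(Y, 1, apply(Y, 1, mean))
  ct <- structure(list(Xbar = Y, grand_mean = rep(0, 7)),
                  class = "condition_tensor")
  X <- matrix(Y, 7, 9 * 20)
  m <- marginalize(Y)
  loss_at <- function(r) {
    fit <- fit_dpca(ct, n_components = r, lambda = 0)
    sum(vapply(names(m), function(phi) {
      ax <- fit$axes[[phi]]
      k <- min(r, ncol(ax$encoder))
      FD <- ax$encoder[, 1:k, drop = FALSE] %*% ax$decoder[1:k, , drop = FALSE]
      sum((matrix(m[[phi]], 7, 180) - FD %*% X)^2)
    }, numeric(1)))
  }
  losses <- vapply(1:5, loss_at, numeric(1))
  expect_true(all(diff(losses) < 1e-8))
  # PCA-axes baseline at rank 3
  P <- svd(X, nu = 3)$u
  base <- sum(vapply(m, function(mm)
    sum((matrix(mm, 7, 180) - P %*% crossprod(P, X))^2), numeric(1)))
  expect_lte(loss_at(3), base + 1e-8)
})

test_that("variance fractions sum to 100% and PCA dominates the curve", {
  pop <- pop_strong()
  ct0 <- build_condition_tensor(pop$binned, pop_task()$trials,
                                trial_rates = pop$trial_rates)
  fit <- fit_dpca(ct0)
  expect_equal(sum(fit$marginal_variance_pct), 100, tolerance = 1e-9)
  expect_true(all(fit$cumulative$pca >= fit$cumulative$dpca - 1e-9))
  expect_true(all(fit$components$explained_pct >= 0))
})

test_that("variance fractions of a latent population are recovered", {
  g <- generate_trials(task_spec(trials_per_condition = 20, seed = 57))
  pop <- simulate_population_latent(
    population_latent_spec(n_neurons = 20, seed = 58), g$trials)
  ct <- build_condition_tensor(pop$binned, g$trials)
  fit <- fit_dpca(ct)
  expect_lt(max(abs(fit$marginal_variance_pct - pop$realized_fractions)), 5)
  # condition tensor approximates the generator's rate tensor to within the
  # trial-averaged sampling noise (sd ~ sqrt(rate / bin / 44 / n_trials))
  gm <- apply(pop$rates, 1, mean)
  dev <- sweep(ct$Xbar, 1, ct$grand_mean) - sweep(pop$rates, 1, gm)
  expect_lt(mean(abs(dev)), 3)
})

test_that("degenerate inputs are rejected with advice", {
  set.seed(55)
  Y <- array(rnorm(4 * 3 * 3 * 10), c(4, 3, 3, 10))
  Y[4, , , ] <- Y[3, , , ]  # duplicated neuron -> rank-deficient X X'
  ct <- structure(list(Xbar = Y, grand_mean = rep(0, 4)),
                  class = "condition_tensor")
  expect_error(fit_dpca(ct, lambda = 0), "lambda")
  # empty condition cell is named
  tk <- tiny_task()
  tr <- as.data.frame(tk$trials)
  drop <- tr$gape_index == 2 & tr$force_level == 3
  tr <- trial_table(tr[!drop, ])
  b <- tiny_binned()
  b$counts <- b$counts[, !drop, , drop = FALSE]
  expect_error(build_condition_tensor(b, tr), "gape 2, force 3")
})

test_that("cross-validated ridge selection returns a grid value", {
  ct <- pop_strong_ct()
  lam <- select_lambda(ct, grid = 10^c(-6, -3, -1), n_components = 5,
                       seed = 56)
  expect_true(lam %in% 10^c(-6, -3, -1))
  expect_equal(nrow(attr(lam, "scores")), 3)
  expect_true(all(is.finite(attr(lam, "scores")$loss)))
})
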