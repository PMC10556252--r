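test_that("alignment produces 250 half-open 4-ms bins and conserves counts", {
  tk <- tiny_task()
  b <- align_and_bin(tiny_spikes(), tk$trials)
  expect_equal(dim(b$counts)[3], 250)
  # half-open bins: a spike at FO + 2 ms lands in the bin covering [0, 4) ms
  fo <- tk$trials$fo_time_s[1]
  sp1 <- spike_train_set(data.frame(neuron_id = 1, area = "MIo", trial_id = 1,
                                    spike_time_s = fo + 0.002))
  b1 <- align_and_bin(sp1, tk$trials)
  hit <- which(b1$counts[1, 1, ] == 1)
  expect_equal(length(hit), 1)
  expect_equal(b1$bin_edges[hit], 0)
  expect_equal(sum(b1$counts), 1)
  # a spike exactly at the right window edge (+500 ms) is excluded
  sp2 <- spike_train_set(data.frame(neuron_id = 1, area = "MIo", trial_id = 1,
                                    spike_time_s = fo + 0.5))
  expect_equal(sum(align_and_bin(sp2, tk$trials)$counts), 0)
})

test_that("spike-count conservation matches a brute-force scan", {
  tk <- tiny_task()
  set.seed(99)
  n <- 10000
  sp <- data.frame(neuron_id = 1, area = "MIo",
                   trial_id = sample(tk$trials$trial_id, n, replace = TRUE),
                   spike_time_s = runif(n, 0, 3))
  sp <- sp[!duplicated(sp[c("trial_id", "spike_time_s")]), ]
  sps <- spike_train_set(sp, sort = TRUE)
  b <- align_and_bin(sps, tk$trials)
  # independent oracle: direct membership count per spike
  fo <- tk$trials$fo_time_s[match(sps$trial_id, tk$trials$trial_id)]
  rel <- sps$spike_time_s - fo
  expect_equal(sum(b$counts), sum(rel >= -0.5 & rel < 0.5))
})

test_that("binning is translation-equivariant", {
  tk <- tiny_task()
  b0 <- align_and_bin(tiny_spikes(), tk$trials)
  delta <- 1.7
  sp <- as.data.frame(tiny_spikes())
  sp$spike_time_s <- sp$spike_time_s + delta
  tr <- as.data.frame(tk$trials)
  tr$fo_time_s <- tr$fo_time_s + delta
  b1 <- align_and_bin(spike_train_set(sp), trial_table(tr))
  expect_identical(b0$counts, b1$counts)
})

test_that("alignment rejects unknown trials and non-divisible windows", {
  tk <- tiny_task()
  bad <- spike_train_set(data.frame(neuron_id = 1, area = "MIo",
                                    trial_id = 999, spike_time_s = 1))
  expect_error(align_and_bin(bad, tk$trials), "999")
  expect_error(align_and_bin(tiny_spikes(), tk$trials,
                             window = c(-0.5, 0.501)), "divisible")
})

test_that("PETH recovers a constant rate and zero input exactly", {
  tk <- tiny_task()
  set.seed(5)
  lambda <- 25
  d <- c(1L, nrow(tk$trials), 250L)
  b <- tiny_binned()
  b$counts <- array(rpois(prod(d), lambda * 0.004), d)
  b$neurons <- b$neurons[1, , drop = FALSE]
  p <- compute_peth(b, factor(rep("all", d[2])))
  interior <- p$time > -0.4 & p$time < 0.4
  expect_lt(abs(mean(p$rate[1, 1, interior]) - lambda), 3)
  expect_true(all(p$rate >= 0) && all(p$sem >= 0))
  b$counts[] <- 0L
  p0 <- compute_peth(b, factor(rep("all", d[2])))
  expect_true(all(p0$rate == 0) && all(p0$sem == 0))
})

test_that("PETH of a merged group is the trial-weighted mean of subgroups", {
  tk <- tiny_task()
  b <- tiny_binned()
  by_gape <- compute_peth(b, factor(tk$trials$gape_index))
  expect_equal(length(by_gape$groups), 3)
  merged <- compute_peth(b, factor(tk$trials$gape_index %in% c(1, 2)))
  n <- by_gape$n_trials
  expect_equal(merged$rate[, 2, ],
               (n[1] * by_gape$rate[, 1, ] + n[2] * by_gape$rate[, 2, ]) /
                 (n[1] + n[2]))
  expect_error(compute_peth(b, factor(tk$trials$gape_index, levels = 1:4)),
               "empty")
})

test_that("datasets round-trip losslessly through CSV", {
  tk <- tiny_task()
  dir <- withr::local_tempdir()
  write_dataset(tiny_spikes(), tk$trials, tk$forces, dir)
  back <- read_dataset(dir)
  expect_identical(align_and_bin(back$spikes, back$trials)$counts,
                   tiny_binned()$counts)
  expect_equal(back$trials$fo_time_s, tk$trials$fo_time_s)
  expect_equal(back$forces$sample_rate_hz, tk$forces$sample_rate_hz)
  expect_equal(max(abs(back$forces$traces - tk$forces$traces)), 0,
               tolerance = 1e-12)
})

test_that("schema violations are rejected with diagnostics", {
  tk <- tiny_task()
  tr <- as.data.frame(tk$trials)
  tr$gape_mm[1] <- 20  # a fourth distinct gape value
  expect_error(trial_table(tr), "3 distinct gape")
  sp <- data.frame(neuron_id = 1, area = "MIo", trial_id = c(1, 1),
                   spike_time_s = c(0.5, 0.4))
  expect_error(spike_train_set(sp), "strictly increasing")
  sorted <- spike_train_set(sp, sort = TRUE)
  expect_equal(sorted$spike_time_s, c(0.4, 0.5))
  expect_error(spike_train_set(data.frame(neuron_id = 1, area = "M1",
                                          trial_id = 1, spike_time_s = 1)),
               "area")
})
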