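# Time-resolved single-trial classification from the first demixed
# component of a target marginalization, with Monte Carlo leave-group-out
# cross-validation and shuffle-based significance.

rebin_time <- function(time, bin_width, time_bin) {
  t0 <- time[1] - bin_width / 2
  idx <- floor((time - t0) / time_bin) + 1
  idx <- pmin(idx, max(idx))
  idx
}

# First demixed decoding axis of `target` from a training tensor M
# [N, 3, 3, B]; returns the axis d (length N), the per-neuron grand mean,
# and the per-class training centroids [n_class x B].
first_axis <- function(M, target, lambda) {
  gm <- .rowMeans(matrix(M, dim(M)[1], length(M) / dim(M)[1]),
                  dim(M)[1], length(M) / dim(M)[1])
  Y <- M - gm  # recycles down the first (neuron) dimension
  X <- flatten_tensor(Y)
  marg <- marginalize_array(Y)
  Xphi <- flatten_tensor(marg[[target]])
  N <- nrow(X)
  C <- tcrossprod(X)
  ridge <- lambda * sum(diag(C)) / N
  if (ridge == 0) ridge <- 1e-10 * sum(diag(C)) / N  # guard near-singular C
  A <- Xphi %*% t(X) %*% solve(C + diag(ridge, N))
  u <- svd(A %*% X, nu = 1, nv = 0)$u[, 1]
  d <- drop(u %*% A)
  B <- dim(M)[4]
  z <- array(drop(d %*% X), c(3, 3, B))  # training projections per condition
  list(d = d, gm = gm, centroids = class_centroids(z, target, B))
}

class_centroids <- function(z, target, B) {
  switch(target,
         gape = mean_mid(array(z, c(3, 3, B))),
         force = mean_mid(aperm(z, c(2, 1, 3))),
         interaction = matrix(z, 9, B))
}

#' Time-resolved decoding from the first demixed component
#'
#' Monte Carlo leave-group-out cross-validation: on each iteration one trial
#' per neuron per condition is held out as a pseudo-trial; the demixed
#' decoding axis of the target marginalization is fit on the training-trial
#' averages; held-out pseudo-trials are projected onto it and classified at
#' each time bin to the class with the nearest training-mean projection
#' (1-D nearest centroid, ties toward the lower class index). The null
#' distribution repeats the procedure with condition labels permuted across
#' whole trials, independently per neuron. A bin is significant when the
#' actual mean accuracy exceeds all shuffled accuracies (nominal
#' p = 1 / n_shuffle; 0.002 at the default 500 shuffles).
#'
#' @param ct a [build_condition_tensor] result.
#' @param target `"gape"` (3 classes), `"force"` (3 classes), or
#'   `"interaction"` (all 9 trial types).
#' @param n_cv cross-validation iterations for the actual accuracy.
#' @param n_shuffle number of label shuffles.
#' @param cv_per_shuffle CV iterations per shuffled accuracy curve
#'   (default `max(1, n_cv / 10)`).
#' @param time_bin classification time-bin width (s).
#' @param lambda dPCA ridge (relative, as in [fit_dpca()]).
#' @param refit_axes refit the decoding axis inside every CV iteration
#'   (default); `FALSE` fits it once on the all-trials average.
#' @param seed RNG seed.
#' @return object of class `decoding_result`: `time` (bin centers),
#'   `accuracy`, `null_accuracies` (`n_shuffle` x bins), `significant`,
#'   `chance`, and the iteration settings.
#' @export
decode_timecourse <- function(ct, target = c("gape", "force", "interaction"),
                              n_cv = 1000, n_shuffle = 500,
                              cv_per_shuffle = max(1, round(n_cv / 10)),
                              time_bin = 0.05, lambda = 0,
                              refit_axes = TRUE, seed = 1) {
  target <- match.arg(target)
  set.seed(seed)
  d <- dim(ct$trial_rates)
  N <- d[1]; n_tr <- d[2]
  cond <- ct$gape_index + 3L * (ct$force_level - 1L)
  k_c <- as.integer(table(factor(cond, 1:9)))
  if (any(k_c < 2))
    stop_gf("every condition needs >= 2 trials for leave-group-out decoding")
  idx50 <- rebin_time(ct$time, ct$bin_width, time_bin)
  B <- max(idx50)
  R50 <- array(0, c(N, n_tr, B))
  for (b in seq_len(B)) {
    sel <- which(idx50 == b)
    R50[, , b] <- .rowMeans(matrix(ct$trial_rates[, , sel], N * n_tr,
                                   length(sel)), N * n_tr, length(sel))
  }
  t0 <- ct$time[1] - ct$bin_width / 2
  times <- t0 + (seq_len(B) - 0.5) * time_bin
  true_class <- switch(target,
                       gape = rep(1:3, 3), force = rep(1:3, each = 3),
                       interaction = 1:9)
  run_cv <- function(cond_mat, n_iter) {
    # cond_mat: [N x n_tr] condition label per neuron (rows identical unless
    # shuffled). Returns mean accuracy per time bin.
    idx <- lapply(seq_len(N), function(n)
      lapply(1:9, function(c) which(cond_mat[n, ] == c)))
    S <- array(0, c(N, 9, B))
    for (n in seq_len(N)) for (c in 1:9)
      S[n, c, ] <- colSums(matrix(R50[n, idx[[n]][[c]], ],
                                  k_c[c], B))
    acc <- matrix(0, n_iter, B)
    axis0 <- NULL
    if (!refit_axes) {
      M0 <- array(0, c(N, 3, 3, B))
      for (c in 1:9) M0[, (c - 1) %% 3 + 1, (c - 1) %/% 3 + 1, ] <-
        S[, c, ] / k_c[c]
      axis0 <- first_axis(M0, target, lambda)
    }
    for (it in seq_len(n_iter)) {
      Xte <- array(0, c(N, 9, B))
      for (n in seq_len(N)) {
        held <- vapply(1:9, function(c)
          idx[[n]][[c]][sample.int(k_c[c], 1)], integer(1))
        Xte[n, , ] <- R50[n, held, ]
      }
      Mtr <- sweep(S - Xte, 2, k_c - 1L, `/`)
      M <- array(0, c(N, 3, 3, B))
      for (c in 1:9) M[, (c - 1) %% 3 + 1, (c - 1) %/% 3 + 1, ] <- Mtr[, c, ]
      ax <- if (refit_axes) first_axis(M, target, lambda) else {
        # keep the fixed axis but recompute centroids from this training set
        X <- flatten_tensor(M - axis0$gm)
        z <- array(drop(axis0$d %*% X), c(3, 3, B))
        list(d = axis0$d, gm = axis0$gm,
             centroids = class_centroids(z, target, B))
      }
      zte <- matrix(ax$d %*% matrix(Xte - ax$gm, N, 9 * B), 9, B)
      # nearest training centroid per bin; strict < keeps the lower class
      # index on ties
      best <- abs(zte - matrix(ax$centroids[1, ], 9, B, byrow = TRUE))
      pred <- matrix(1L, 9, B)
      for (k in 2:nrow(ax$centroids)) {
        dk <- abs(zte - matrix(ax$centroids[k, ], 9, B, byrow = TRUE))
        better <- dk < best
        pred[better] <- k
        best[better] <- dk[better]
      }
      acc[it, ] <- .colMeans(pred == true_class, 9, B)
    }
    colMeans(acc)
  }
  base_cond <- matrix(cond, N, n_tr, byrow = TRUE)
  accuracy <- run_cv(base_cond, n_cv)
  nulls <- matrix(0, n_shuffle, B)
  for (s in seq_len(n_shuffle)) {
    cm <- t(vapply(seq_len(N), function(n) cond[sample.int(n_tr)],
                   integer(n_tr)))
    nulls[s, ] <- run_cv(cm, cv_per_shuffle)
  }
  significant <- accuracy > apply(nulls, 2, max)
  structure(
    list(target = target, time = times, accuracy = accuracy,
         null_accuracies = nulls, significant = significant,
         chance = 1 / length(unique(true_class)),
         nominal_p = 1 / n_shuffle,
         n_cv = n_cv, n_shuffle = n_shuffle,
         cv_per_shuffle = cv_per_shuffle, time_bin = time_bin),
    class = "decoding_result"
  )
}

#' Intervals of significant decoding
#'
#' Collapses the per-bin significance mask into contiguous time intervals
#' relative to force onset.
#'
#' @param result a [decode_timecourse] result.
#' @return data.frame with `start_s`, `end_s`, `n_bins` (empty when nothing
#'   is significant).
#' @export
summarize_significance <- function(result) {
  r <- rle(as.logical(result$significant))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      n_bins = integer()))
  data.frame(
    start_s = result$time[starts[keep]] - result$time_bin / 2,
    end_s = result$time[ends[keep]] + result$time_bin / 2,
    n_bins = r$lengths[keep]
  )
}
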