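# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gf <- function(...) stop(sprintf(...), call. = FALSE)

#' Truncated Gaussian smoothing matrix
#'
#' Builds a row-stochastic smoothing operator on a regular bin grid. The
#' kernel is a Gaussian truncated at +/- 3 sigma and renormalized at the
#' window edges, so a constant signal is preserved everywhere (no rate
#' suppression at the edges).
#'
#' @param n_bins number of time bins.
#' @param sigma kernel standard deviation in seconds.
#' @param bin_width bin width in seconds.
#' @return an `n_bins x n_bins` matrix `W`; smoothing a row vector `x` is
#'   `as.vector(W %*% x)`.
#' @keywords internal
smoothing_matrix <- function(n_bins, sigma, bin_width) {
  if (sigma <= 0) return(diag(n_bins))
  half <- ceiling(3 * sigma / bin_width)
  offs <- -half:half
  k <- exp(-0.5 * (offs * bin_width / sigma)^2)
  W <- matrix(0, n_bins, n_bins)
  for (t in seq_len(n_bins)) {
    idx <- t + offs
    ok <- idx >= 1 & idx <= n_bins
    W[t, idx[ok]] <- k[ok] / sum(k[ok])
  }
  W
}

# Smooth rows of a matrix [units x bins] with a precomputed operator.
smooth_rows <- function(m, W) m %*% t(W)

# Deterministic integer sub-seed derived from a base seed and a stream tag,
# kept below 2^31.
sub_seed <- function(seed, tag) {
  (as.integer(seed) * 1009L + as.integer(tag) * 31L) %% 2147483647L
}
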