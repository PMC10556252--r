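#' Raised-cosine spike-history basis
#'
#' Builds the three raised-cosine filters used to summarize a neuron's own
#' recent spiking at short, medium, and long timescales (defaults 16, 44,
#' 108 ms). Basis `j` is
#' \deqn{b_j(\tau) = 0.5 (1 + \cos(\pi (\tau - c_j) / w_j))}
#' for \eqn{|\tau - c_j| \le w_j} and 0 elsewhere, with center and half-width
#' \eqn{c_j = w_j = \mathrm{timescale}_j / 2}, so the support of basis `j`
#' ends exactly at its timescale. The lag grid starts at one bin (4 ms by
#' default), never at 0: there is no instantaneous self-coupling.
#'
#' @param timescales increasing vector of timescales in seconds.
#' @param bin_width spike-count bin width in seconds.
#' @return object of class `raised_cosine_basis`: list with `lags_s` (lag
#'   grid, seconds), `B` (matrix, one column per basis function evaluated on
#'   the lag grid), `timescales`, `bin_width`.
#' @examples
#' b <- make_basis()
#' colSums(b$B)  # support mass grows with timescale
#' @export
make_basis <- function(timescales = c(0.016, 0.044, 0.108), bin_width = 0.004) {
  if (is.unsorted(timescales, strictly = TRUE))
    stop_gf("history timescales must be strictly increasing")
  lags <- seq(bin_width, max(timescales), by = bin_width)
  B <- vapply(timescales, function(ts) {
    c_j <- ts / 2
    w_j <- ts / 2
    v <- 0.5 * (1 + cos(pi * (lags - c_j) / w_j))
    v[abs(lags - c_j) > w_j] <- 0
    v
  }, numeric(length(lags)))
  structure(
    list(lags_s = lags, B = B, timescales = timescales, bin_width = bin_width),
    class = "raised_cosine_basis"
  )
}

#' Bite-force lag grid
#'
#' The eight temporal lags at which bite force enters the encoding model:
#' -156 ms to +208 ms in 52-ms steps. A negative lag means the force sample
#' precedes the spike bin (force leads spiking, sensory-like); a positive lag
#' means the force sample follows the spike bin (force lags spiking,
#' motor-like). The force covariate at lag \eqn{\tau_k} for a bin at time `t`
#' is the force trace evaluated at `t + tau_k`.
#'
#' @param from,to,step grid limits and step, in seconds.
#' @return numeric vector of 8 lags in seconds.
#' @export
force_lag_grid <- function(from = -0.156, to = 0.208, step = 0.052) {
  lags <- seq(from, to, by = step)
  stopifnot(length(lags) >= 2)
  lags
}

# Filter a binarized spike train (one trial) through the basis:
# H[t, j] = sum_{l >= 1} B[l, j] * s[t - l], zero-padded at the trial start.
# History never crosses trial boundaries.
history_features <- function(s, basis) {
  n <- length(s)
  B <- basis$B
  H <- matrix(0, n, ncol(B))
  L <- nrow(B)
  for (j in seq_len(ncol(B))) {
    bj <- B[, j]
    for (l in seq_len(L)) {
      if (bj[l] == 0 || l >= n) next
      H[(l + 1):n, j] <- H[(l + 1):n, j] + bj[l] * s[1:(n - l)]
    }
  }
  H
}
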