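#' Yule-Simon distribution for per-connection synapse counts
#'
#' The Yule-Simon distribution `P(k) = rho * B(k, rho + 1)`, `k >= 1`, arises
#' from preferential attachment and has a power-law tail with exponent
#' `rho + 1`.  It models the number of synapses a single thalamocortical
#' connection comprises.  Its mean is `rho / (rho - 1)` for `rho > 1`.
#'
#' @param k integer vector of counts (`k >= 1`).
#' @param rho shape parameter (`rho > 0`).
#' @return `yule_simon_pmf` returns probabilities; `yule_simon_mean` the mean.
#' @export
yule_simon_pmf <- function(k, rho) {
  stopifnot(is.numeric(rho), length(rho) == 1L)
  if (!is.finite(rho) || rho <= 0) stop("yule_simon_pmf: rho must be > 0")
  if (any(k < 1) || any(k != floor(k))) stop("yule_simon_pmf: k must be integer >= 1")
  rho * beta(k, rho + 1)
}

#' @rdname yule_simon_pmf
#' @export
yule_simon_mean <- function(rho) {
  if (rho <= 1) stop("yule_simon_mean: undefined for rho <= 1")
  rho / (rho - 1)
}

#' Sample Yule-Simon variates
#'
#' Inverse-CDF sampling on a precomputed cumulative table with an analytic
#' tail.  The table covers `k` up to the point where the CDF exceeds
#' `1 - 1e-12`; the residual tail mass collapses onto the last table entry
#' (mass `< 1e-12`, irrelevant at any realistic sample size).
#'
#' @param n number of draws.
#' @param rho shape parameter (`rho > 0`).
#' @param k_max table extent safeguard.
#' @return integer vector of length `n`, all `>= 1`.
#' @export
yule_simon_sample <- function(n, rho, k_max = 100000L) {
  if (rho <= 0) stop("yule_simon_sample: rho must be > 0")
  if (n == 0L) return(integer(0))
  ## grow the table geometrically until the tail is negligible
  kk <- 1L
  repeat {
    ks <- seq_len(kk)
    cdf <- cumsum(yule_simon_pmf(ks, rho))
    if (cdf[kk] > 1 - 1e-12 || kk >= k_max) break
    kk <- min(kk * 4L, k_max)
  }
  u <- runif(n)
  findInterval(u, cdf) + 1L
}
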