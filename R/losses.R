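#' Quantile-Huber penalty
#'
#' Asymmetric Huber penalty used for rank-matched firing-rate fitting:
#' `|tau - 1[u <= 0]| * (u^2 / (2 kappa)` if `|u| <= kappa`, else
#' `|u| - kappa/2)`.
#'
#' @param u residual(s).
#' @param tau target quantile in [0, 1].
#' @param kappa Huber transition scale (> 0).
#' @return penalty values.
#' @export
quantile_huber <- function(u, tau, kappa = 0.002) {
  if (kappa <= 0) stop("quantile_huber: kappa must be > 0")
  w <- abs(tau - as.numeric(u <= 0))
  h <- ifelse(abs(u) <= kappa, u^2 / (2 * kappa), abs(u) - kappa / 2)
  w * h
}

quantile_huber_grad <- function(u, tau, kappa = 0.002) {
  w <- abs(tau - as.numeric(u <= 0))
  w * ifelse(abs(u) <= kappa, u / kappa, sign(u))
}

#' Fixed rank-matched rate targets by inverse-CDF sampling
#'
#' Draws a sorted target vector of length `n` from an empirical rate sample
#' by linear interpolation of its quantile function at midpoint
#' probabilities.  An explicit 0 Hz entry is appended to the sample first
#' (preserving the silent-neuron fraction of short windows) unless already
#' present.
#'
#' @param samples empirical rate sample, Hz.
#' @param n number of model neurons of the type.
#' @return sorted numeric vector of length `n`.
#' @export
sample_rate_targets <- function(samples, n) {
  if (!any(samples == 0)) samples <- c(samples, 0)
  sort(as.numeric(quantile(samples, probs = (seq_len(n) - 0.5) / n,
                           type = 7, names = FALSE)))
}

#' Firing-rate distribution loss (rank-matched quantile-Huber)
#'
#' Sorts model rates within each cell type and matches them rank-to-rank
#' against a fixed sorted target vector with quantile level `q / N_c`,
#' averaging with weight `1 / N` over all neurons and scaling by
#' `lambda_rate`.
#'
#' @param rates per-neuron chunk rates, Hz.
#' @param types per-neuron type labels.
#' @param target_vectors named list: per type a sorted target vector of the
#'   type's length (see [sample_rate_targets()]).
#' @param kappa quantile-Huber scale.
#' @param lambda_rate loss coefficient.
#' @param grad also return the gradient with respect to `rates`.
#' @return list with `value` and (optionally) `grad`.
#' @export
rate_distribution_loss <- function(rates, types, target_vectors,
                                   kappa = 0.002, lambda_rate = 1e4,
                                   grad = FALSE) {
  N <- length(rates)
  value <- 0
  g <- if (grad) numeric(N) else NULL
  for (tt in unique(types)) {
    idx <- which(types == tt)
    if (!length(idx)) next
    tv <- target_vectors[[tt]]
    if (is.null(tv)) stop("rate_distribution_loss: no targets for type ", tt)
    if (length(tv) != length(idx))
      stop("rate_distribution_loss: target vector length mismatch for ", tt)
    o <- order(rates[idx])
    u <- rates[idx][o] - tv
    tau <- seq_along(idx) / length(idx)
    value <- value + sum(quantile_huber(u, tau, kappa))
    if (grad) g[idx[o]] <- quantile_huber_grad(u, tau, kappa)
  }
  list(value = lambda_rate * value / N,
       grad = if (grad) lambda_rate * g / N else NULL)
}

#' Crowd-surrogate OSI/DSI estimates
#'
#' Single-trial, cell-type-level selectivity estimator: because preferred
#' directions tile [0, 360) uniformly within each type, averaging normalized
#' responses weighted by `cos(2 * offset)` (orientation) or `cos(offset)`
#' (direction) over neurons in one trial approximates the classical
#' average over stimulus directions of the type's mean aligned tuning curve.
#' Responses are normalized by an evoked-rate EMA floored at `r_min`, and the
#' denominator is the floored population mean normalized response.
#'
#' @param rates trials x neurons matrix of single-trial rates, Hz.
#' @param tuning_angle per-neuron preferred directions, degrees.
#' @param stim_dir per-trial stimulus direction, degrees.
#' @param types per-neuron type labels.
#' @param ema per-neuron EMA of evoked rates, Hz.
#' @param r_min normalization floor (Hz, and on the normalized mean).
#' @return data.frame per (trial, type): `osi`, `dsi`, `denom`.
#' @export
crowd_osi_dsi <- function(rates, tuning_angle, stim_dir, types, ema,
                          r_min = 0.5) {
  B <- nrow(rates)
  norm <- pmax(ema, r_min)
  out <- list()
  for (b in seq_len(B)) {
    dth <- (stim_dir[b] - tuning_angle) * pi / 180
    rt <- rates[b, ] / norm
    for (tt in unique(types)) {
      idx <- which(types == tt)
      if (!length(idx)) next
      D <- max(mean(rt[idx]), r_min)
      out[[length(out) + 1L]] <- data.frame(
        trial = b, type = tt,
        osi = mean(rt[idx] * cos(2 * dth[idx])) / D,
        dsi = mean(rt[idx] * cos(dth[idx])) / D,
        denom = D)
    }
  }
  do.call(rbind, out)
}

#' OSI/DSI matching loss
#'
#' Population-weighted MSE of the batch-averaged crowd-surrogate estimates
#' against per-type targets:
#' `lambda * sum_c N_c [(OSI_c - OSI_c*)^2 + (DSI_c - DSI_c*)^2] / sum_c N_c`.
#'
#' @param est data.frame from [crowd_osi_dsi()] (all trials of the batch).
#' @param osi_target,dsi_target named per-type target vectors.
#' @param n_per_type named per-type neuron counts.
#' @param lambda loss coefficient.
#' @return list with `value` and per-type batch means `osi_hat`, `dsi_hat`.
#' @export
osi_dsi_loss <- function(est, osi_target, dsi_target, n_per_type,
                         lambda = 20) {
  tts <- unique(est$type)
  if (!all(tts %in% names(osi_target)) || !all(tts %in% names(dsi_target)))
    stop("osi_dsi_loss: missing OSI/DSI target for some type")
  osi_hat <- tapply(est$osi, est$type, mean)
  dsi_hat <- tapply(est$dsi, est$type, mean)
  nn <- n_per_type[names(osi_hat)]
  value <- sum(nn * ((osi_hat - osi_target[names(osi_hat)])^2 +
                     (dsi_hat - dsi_target[names(dsi_hat)])^2)) / sum(nn)
  list(value = lambda * value, osi_hat = osi_hat, dsi_hat = dsi_hat)
}

#' Multi-scale Fano-factor bin widths
#'
#' 20 log-spaced candidate widths spanning 1-1000 ms; widths at or above
#' half the analysis window are dropped so every width yields at least two
#' non-overlapping bins.  (A 300 ms window keeps 14 widths, the largest
#' about 113 ms.)
#'
#' @param window_ms analysis-window length, ms.
#' @return numeric vector of widths, ms.
#' @export
fano_width_set <- function(window_ms) {
  w <- exp(seq(log(1), log(1000), length.out = 20))
  w[w < window_ms / 2]
}

#' Draw random excitatory pools by shuffle-and-slice
#'
#' Pool sizes are Gaussian (mean 70, sd 30) clipped at a minimum of 15;
#' pools are successive non-overlapping slices of a random permutation so
#' each neuron is used at most once per pass, reshuffling between passes.
#'
#' @param ids candidate neuron indices.
#' @param n_pool number of pools.
#' @param size_mean,size_sd,size_min pool size distribution.
#' @return list of index vectors.
#' @export
make_fano_pools <- function(ids, n_pool = 500L, size_mean = 70,
                            size_sd = 30, size_min = 15L) {
  pools <- vector("list", n_pool)
  perm <- sample(ids)
  pos <- 1L
  for (p in seq_len(n_pool)) {
    sz <- max(size_min, round(rnorm(1, size_mean, size_sd)))
    sz <- min(sz, length(ids))
    if (pos + sz - 1L > length(ids)) {
      perm <- sample(ids)
      pos <- 1L
    }
    pools[[p]] <- perm[pos:(pos + sz - 1L)]
    pos <- pos + sz
  }
  pools
}

## bin index per 1 ms step for width w over a window of L steps; the
## effective width is rounded to whole steps (a fractional width over the
## 1 ms grid would alternate bin sizes and inflate count variance
## deterministically); steps in the trailing partial bin get 0 (dropped)
fano_bin_index <- function(L, w) {
  w <- max(1L, round(w))
  b <- floor((seq_len(L) - 1) / w) + 1L
  n_full <- floor(L / w)
  b[b > n_full] <- 0L
  b
}

#' Multi-scale Fano factors of pooled spike counts
#'
#' For each pool and bin width, the Fano factor is the variance-to-mean
#' ratio of the pool's summed spike counts over all non-overlapping bins in
#' the analysis window; the estimate at each width is the average over
#' pools (pools with zero mean count at a width are excluded there).
#'
#' @param spikes neurons x T 0/1 matrix restricted to the analysis window.
#' @param pools list of row-index vectors (see [make_fano_pools()]).
#' @param widths bin widths, ms (default [fano_width_set()] of the window).
#' @return data.frame with `width` and pool-averaged `fano`.
#' @export
fano_multi_scale <- function(spikes, pools, widths = NULL) {
  L <- ncol(spikes)
  if (is.null(widths)) widths <- fano_width_set(L)
  M <- do.call(rbind, lapply(pools, function(p)
    colSums(spikes[p, , drop = FALSE])))          # pools x T
  out <- vapply(widths, function(w) {
    b <- fano_bin_index(L, w)
    keep <- b > 0L
    counts <- t(rowsum(t(M[, keep, drop = FALSE]), b[keep]))  # pools x bins
    mu <- rowMeans(counts)
    va <- apply(counts, 1, var)
    ok <- mu > 0
    if (!any(ok)) return(NA_real_)
    mean(va[ok] / mu[ok])
  }, 0)
  data.frame(width = widths, fano = out)
}

## Synchrony loss value + gradient w.r.t. the spike matrix (window-restricted).
fano_sync_loss <- function(spikes, pools, target, lambda_sync = 1.5,
                           grad = FALSE) {
  L <- ncol(spikes)
  widths <- target$width
  Mmat <- do.call(rbind, lapply(pools, function(p)
    colSums(spikes[p, , drop = FALSE])))
  n_pool <- length(pools)
  value <- 0
  gM <- if (grad) matrix(0, n_pool, L) else NULL
  fhat <- numeric(length(widths))
  for (wi in seq_along(widths)) {
    w <- widths[wi]
    b <- fano_bin_index(L, w)
    keep <- b > 0L
    counts <- t(rowsum(t(Mmat[, keep, drop = FALSE]), b[keep]))
    B <- ncol(counts)
    mu <- rowMeans(counts)
    va <- apply(counts, 1, var)
    ok <- mu > 0
    if (!any(ok)) { fhat[wi] <- NA; next }
    Fp <- va[ok] / mu[ok]
    fhat[wi] <- mean(Fp)
    if (grad) {
      dLdF <- 2 * (fhat[wi] - target$fano[wi]) / length(widths) / sum(ok)
      ## dF/dn_b = (2 (n_b - mu) / (B - 1)) / mu - F / (B mu)
      okp <- which(ok)
      dev <- counts[okp, , drop = FALSE] - mu[okp]
      dFdn <- (2 * dev / (B - 1)) / mu[okp] - Fp / (B * mu[okp])
      gbin <- dLdF * dFdn                       # pools_ok x bins
      gM[okp, keep] <- gM[okp, keep] + gbin[, b[keep], drop = FALSE]
    }
  }
  ok_w <- !is.na(fhat)
  value <- mean((fhat[ok_w] - target$fano[ok_w])^2)
  gS <- NULL
  if (grad) {
    gS <- matrix(0, nrow(spikes), L)
    for (p in seq_len(n_pool)) {
      gS[pools[[p]], ] <- gS[pools[[p]], ] +
        matrix(gM[p, ], length(pools[[p]]), L, byrow = TRUE)
    }
    gS <- lambda_sync * gS
  }
  list(value = lambda_sync * value, fano = fhat, grad = gS)
}

#' Voltage regularizer
#'
#' Mean squared distance of the normalized voltage from threshold,
#' `lambda_volt * mean((v - 1)^2)` over batch, time and neurons, exactly as
#' specified (a mean, so doubling the simulated duration leaves the scale
#' unchanged).  The alternative one-sided (suprathreshold hinge) form is
#' available via `form = "hinge"`.
#'
#' @param v normalized voltage array/matrix (any shape).
#' @param lambda_volt coefficient.
#' @param form `"printed"` (default, `(v - 1)^2`) or `"hinge"`
#'   (`pmax(v - 1, 0)^2`).
#' @param grad also return the gradient w.r.t. `v`.
#' @return list with `value` (and `grad`).
#' @export
voltage_reg <- function(v, lambda_volt = 1, form = c("printed", "hinge"),
                        grad = FALSE) {
  form <- match.arg(form)
  d <- if (form == "printed") v - 1 else pmax(v - 1, 0)
  value <- lambda_volt * mean(d^2)
  list(value = value,
       grad = if (grad) lambda_volt * 2 * d / length(v) else NULL)
}

#' Wasserstein-1 (Earth Mover's) weight regularizer
#'
#' Penalizes per-class distributional drift of the recurrent weights from
#' their initialization: mean over classes of the mean absolute difference
#' of the sorted current and sorted initial weights, times `lambda_w`.
#' Permuting weights within a class leaves it at 0.
#'
#' @param w,w0 current and initial (normalized) weights, matched classes.
#' @param classes per-edge class labels.
#' @param lambda_w coefficient.
#' @param grad also return the gradient w.r.t. `w`.
#' @return list with `value` (and `grad`).
#' @export
emd_weight_reg <- function(w, w0, classes, lambda_w = 10, grad = FALSE) {
  if (length(w) != length(w0)) stop("emd_weight_reg: snapshot size mismatch")
  cls <- unique(classes)
  M <- length(cls)
  value <- 0
  g <- if (grad) numeric(length(w)) else NULL
  for (cc in cls) {
    idx <- which(classes == cc)
    o <- order(w[idx])
    d <- w[idx][o] - sort(w0[idx])
    value <- value + mean(abs(d))
    if (grad) g[idx[o]] <- sign(d) / length(idx) / M
  }
  list(value = lambda_w * value / M,
       grad = if (grad) lambda_w * g else NULL)
}

#' Compose the total training loss
#'
#' `L_total = L_core + lambda_peri * L_peri + L_volt + L_w`, with the core
#' block holding spontaneous/evoked rate, spontaneous/evoked synchrony and
#' evoked OSI/DSI terms, and the peripheral block the rate and OSI/DSI terms
#' only (synchrony is core-only).
#'
#' @param core named numeric vector/list of core components.
#' @param peri named numeric vector/list of peripheral components.
#' @param volt,w voltage and weight regularizer values.
#' @param lambda_peri peripheral down-weighting.
#' @return a `loss_report`: components, block sums, and `total`.
#' @export
total_loss <- function(core, peri, volt = 0, w = 0, lambda_peri = 0.1) {
  core_sum <- sum(unlist(core))
  peri_sum <- sum(unlist(peri))
  structure(list(core = as.list(core), peri = as.list(peri),
                 volt = volt, w = w, lambda_peri = lambda_peri,
                 core_sum = core_sum, peri_sum = peri_sum,
                 total = core_sum + lambda_peri * peri_sum + volt + w),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total %.4f (core %.4f + %.2f * peri %.4f + volt %.4f + w %.4f)\n",
              x$total, x$core_sum, x$lambda_peri, x$peri_sum, x$volt, x$w))
  invisible(x)
}
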