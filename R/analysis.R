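#' Vector-sum orientation and direction selectivity indices
#'
#' Classical per-neuron indices from trial-averaged responses to the eight
#' grating directions: `DSI = |sum r_k exp(i theta_k)| / sum r_k` and
#' `OSI = |sum r_k exp(2 i theta_k)| / sum r_k`.
#'
#' @param rates trial-averaged rates per direction (vector), Hz.
#' @param directions stimulus directions, degrees (default 0..315 by 45).
#' @return list with `osi` and `dsi` (both in [0, 1]); `NA` for all-zero
#'   responses.
#' @export
osi_dsi <- function(rates, directions = seq(0, 315, by = 45)) {
  stopifnot(length(rates) == length(directions), all(rates >= 0))
  if (sum(rates) == 0) return(list(osi = NA_real_, dsi = NA_real_))
  th <- directions * pi / 180
  list(osi = Mod(sum(rates * exp(2i * th))) / sum(rates),
       dsi = Mod(sum(rates * exp(1i * th))) / sum(rates))
}

#' Preferred direction from circular moments
#'
#' The preferred orientation is half the phase of the second circular moment
#' (`z2`), in (-90, 90]; it is disambiguated to a full 360-degree preferred
#' direction by the sign of the projection of the first moment (`z1`) onto
#' the orientation axis (the boundary `Re(z1 e^{-i theta}) = 0` keeps the
#' orientation branch).  Neurons whose peak-direction mean rate is below
#' `min_rate` are excluded (`NA`).
#'
#' @param rates trial-averaged rates per direction, Hz.
#' @param directions stimulus directions, degrees.
#' @param min_rate peak-rate inclusion threshold, Hz.
#' @return preferred direction in [0, 360), degrees, or `NA`.
#' @export
preferred_direction <- function(rates, directions = seq(0, 315, by = 45),
                                min_rate = 1) {
  if (max(rates) < min_rate) return(NA_real_)
  th <- directions * pi / 180
  z1 <- sum(rates * exp(1i * th))
  z2 <- sum(rates * exp(2i * th))
  ori <- Arg(z2) / 2                       # (-pi/2, pi/2]
  ## project the first moment on the orientation axis; a tiny tolerance pins
  ## the degenerate two-peak case onto the ">=" branch despite float noise
  proj <- Re(z1 * exp(-1i * ori))
  pd <- if (proj >= -1e-9 * sum(rates)) ori else ori + pi
  round(pd * 180 / pi, 9) %% 360
}

#' Response sparsity (image/stimulus selectivity)
#'
#' `S = (1 - (mean r)^2 / mean(r^2)) / (1 - 1/N)`: 0 for equal responses to
#' all stimuli, 1 for a response to a single stimulus.
#'
#' @param responses non-negative trial-averaged responses, one per stimulus.
#' @param N number of stimuli (defaults to `length(responses)`).
#' @return selectivity in [0, 1]; `NA` if all responses are zero.
#' @export
selectivity <- function(responses, N = length(responses)) {
  stopifnot(all(responses >= 0), N >= 2)
  if (all(responses == 0)) return(NA_real_)
  (1 - mean(responses)^2 / mean(responses^2)) / (1 - 1 / N)
}

#' Maximum participation ratio
#'
#' Fraction of neurons with at least one spike per non-overlapping time bin;
#' the maximum over bins (and over the given bin widths) flags brief
#' synchronized events that a mean would obscure.
#'
#' @param spikes neurons x T 0/1 matrix.
#' @param bin_widths bin widths, ms.
#' @return maximum fraction of simultaneously active neurons.
#' @export
participation_ratio <- function(spikes, bin_widths = c(10, 50, 100)) {
  if (!nrow(spikes) || sum(spikes) == 0) return(0)
  L <- ncol(spikes)
  best <- 0
  for (w in bin_widths) {
    b <- fano_bin_index(L, w)
    keep <- b > 0L
    if (!any(keep)) next
    counts <- t(rowsum(t(spikes[, keep, drop = FALSE]), b[keep]))
    best <- max(best, max(colMeans(counts > 0)))
  }
  best
}

#' Leave-one-out oracle correlation
#'
#' Response reliability across repeated stimuli: Pearson correlation between
#' single-trial responses and the leave-one-out mean over the other repeats
#' of the same stimulus, vectorized across all (stimulus, repeat) pairs.
#'
#' @param responses stimuli x repeats matrix for one neuron.
#' @return correlation coefficient, or `NA` if either vector is constant.
#' @export
oracle_correlation <- function(responses) {
  G <- nrow(responses); K <- ncol(responses)
  stopifnot(G >= 2, K >= 2)
  loo <- (rowSums(responses) - responses) / (K - 1)
  x <- as.numeric(responses); y <- as.numeric(loo)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Distribution similarity score
#'
#' `1 - D_KS` where `D_KS` is the two-sample Kolmogorov-Smirnov statistic:
#' 1 for identical samples, 0 for disjoint supports, invariant to common
#' monotone transforms.
#'
#' @param sample_a,sample_b numeric samples.
#' @return similarity in [0, 1].
#' @export
similarity_score <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  d <- suppressWarnings(ks.test(sample_a, sample_b)$statistic)
  1 - unname(d)
}

#' Like-to-like weight differences by response correlation
#'
#' Groups synaptic weights of connected pairs by the Pearson correlation of
#' the pair's responses into anti-correlated ([-1, -0.5]), uncorrelated
#' ([-0.25, 0.25]) and highly correlated ([0.5, 1.0]) bins and reports the
#' normalized differences
#' `Delta_like = (mu_like - mu_unc) / mu_unc`,
#' `Delta_anti = (mu_unc - mu_anti) / mu_unc`.  For inhibitory (negative
#' weight) sources the signed quotients make positive values indicate
#' like-to-like structure exactly as for excitatory sources.  Significance
#' via two-sided Welch's t-tests of the like/anti bins against the
#' uncorrelated bin.
#'
#' @param weights per-pair synaptic weights (signed).
#' @param correlations per-pair response correlations in [-1, 1].
#' @param mu_floor relative floor under `|mu_unc|` below which the metrics
#'   are undefined.
#' @return list with `delta_like`, `delta_anti`, `p_like`, `p_anti`, bin
#'   means and counts; deltas are `NA` when a bin is empty or the baseline
#'   is degenerate.
#' @export
response_correlation_deltas <- function(weights, correlations,
                                        mu_floor = 1e-6) {
  stopifnot(length(weights) == length(correlations))
  anti <- correlations >= -1 & correlations <= -0.5
  unc <- correlations >= -0.25 & correlations <= 0.25
  like <- correlations >= 0.5 & correlations <= 1
  mu <- c(like = mean(weights[like]), unc = mean(weights[unc]),
          anti = mean(weights[anti]))
  welch <- function(a, b) {
    if (sum(a) < 2 || sum(b) < 2) return(NA_real_)
    tryCatch(t.test(weights[a], weights[b])$p.value,
             error = function(e) NA_real_)   # zero-variance bins
  }
  degenerate <- !is.finite(mu["unc"]) ||
    abs(mu["unc"]) < mu_floor * max(abs(weights), 1e-300)
  dl <- if (degenerate || !any(like)) NA_real_ else
    unname((mu["like"] - mu["unc"]) / mu["unc"])
  da <- if (degenerate || !any(anti)) NA_real_ else
    unname((mu["unc"] - mu["anti"]) / mu["unc"])
  list(delta_like = dl, delta_anti = da,
       p_like = welch(like, unc), p_anti = welch(anti, unc),
       mu = mu, n = c(like = sum(like), unc = sum(unc), anti = sum(anti)))
}

#' Cosine-series fit of weight versus preferred-direction difference
#'
#' Fits `w(dPD) = a cos(dPD) + b cos(2 dPD) + c` by ordinary least squares,
#' where `dPD` is the circular preferred-direction difference folded to
#' [0, 180] degrees; `a` captures direction-specific and `b`
#' orientation-specific like-to-like structure, reported as normalized
#' effect sizes `a/c` and `b/c`.  Coefficient significance uses two-sided
#' t-tests with standard errors from the OLS covariance (df = n - 3).
#'
#' @param weights per-synapse weights.
#' @param delta_pd preferred-direction differences, degrees (folded
#'   internally via `min(|d|, 360 - |d|)`).
#' @return list with coefficients `a`, `b`, `c`, ratios `a_over_c`,
#'   `b_over_c`, standard errors, t statistics and p values.
#' @export
pd_difference_fit <- function(weights, delta_pd) {
  n <- length(weights)
  if (n < 4) stop("pd_difference_fit: need at least 4 observations")
  d <- abs(delta_pd) %% 360
  d <- pmin(d, 360 - d) * pi / 180
  fit <- lm(weights ~ cos(d) + cos(2 * d))
  cf <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))  # exact fits warn in summary.lm
  tstat <- cf / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 3)
  a <- unname(cf[2]); b <- unname(cf[3]); cc <- unname(cf[1])
  list(a = a, b = b, c = cc,
       a_over_c = if (abs(cc) < 1e-12) NA_real_ else a / cc,
       b_over_c = if (abs(cc) < 1e-12) NA_real_ else b / cc,
       se = unname(se[c(2, 3, 1)]), t = unname(tstat[c(2, 3, 1)]),
       p = unname(pval[c(2, 3, 1)]), df = n - 3)
}

#' Outgoing-weight cohort assignment
#'
#' Splits each cell type's core-resident neurons into low/mid/high tertiles
#' of total absolute outgoing synaptic weight (summed over all recurrent
#' targets, core and periphery), ties broken by neuron id.  Types with fewer
#' than 3 eligible neurons are skipped.  Also reports each cohort's
#' proportional distribution of outgoing weight across postsynaptic classes
#' (Exc / PV / SST / VIP).
#'
#' @param network a `column_network`.
#' @return list with `assignment` (data.frame: id, type, total_out, cohort)
#'   and `target_fractions` (data.frame per type x cohort x target class).
#' @export
cohort_split <- function(network) {
  neurons <- network$neurons
  edges <- network$edges_rec
  tot <- tapply(abs(edges$weight), factor(edges$src, levels = neurons$id), sum)
  tot[is.na(tot)] <- 0
  eligible <- which(neurons$core)
  rows <- list(); frac_rows <- list()
  tclass <- vapply(neurons$type, function(tt) {
    ct <- network$config$cell_types[[tt]]
    if (ct$class == "excitatory") "Exc" else ct$subclass
  }, "")
  for (tt in unique(neurons$type)) {
    idx <- eligible[neurons$type[eligible] == tt]
    if (length(idx) < 3) next
    o <- idx[order(tot[idx], idx)]
    n <- length(o)
    cohort <- cut(seq_len(n), breaks = quantile(seq_len(n), c(0, 1/3, 2/3, 1)),
                  labels = c("low", "mid", "high"), include.lowest = TRUE)
    rows[[tt]] <- data.frame(id = o, type = tt, total_out = unname(tot[o]),
                             cohort = as.character(cohort))
    for (ch in c("low", "mid", "high")) {
      mem <- o[cohort == ch]
      ee <- edges[edges$src %in% mem, ]
      if (!nrow(ee)) next
      w_by <- tapply(abs(ee$weight), tclass[ee$dst], sum)
      fr <- w_by / sum(w_by)
      frac_rows[[paste(tt, ch)]] <- data.frame(
        type = tt, cohort = ch, target = names(fr),
        fraction = as.numeric(fr))
    }
  }
  list(assignment = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       target_fractions = do.call(rbind, c(frac_rows,
                                           list(make.row.names = FALSE))))
}

#' Silence a cohort and compare to the matched baseline
#'
#' Injects a constant hyperpolarizing current (default -1000 pA) into the
#' targeted neurons for the full duration of every stimulus trial, repeating
#' the exact baseline protocol (shared seeds and stimuli: 8 directions x
#' `n_trials`), and reports percentage changes of firing rate and OSI on the
#' non-targeted neurons only, aggregated by cell type.
#'
#' @param network a `column_network`.
#' @param target_ids neuron ids to silence.
#' @param seed protocol seed (shared between baseline and perturbed runs).
#' @param directions stimulus directions, degrees.
#' @param n_trials trials per direction.
#' @param duration trial length, ms.
#' @param current injected current, pA (negative = hyperpolarizing).
#' @param grating evoked stimulus parameters.
#' @param core_only restrict reported metrics to core-resident neurons
#'   (the default readout convention).
#' @return list with per-type `summary` (baseline/perturbed rate and OSI,
#'   percent changes), the per-neuron tables, and the silenced ids.
#' @export
silence_and_compare <- function(network, target_ids, seed = 1L,
                                directions = seq(0, 315, by = 45),
                                n_trials = 10L, duration = 300L,
                                current = -1000,
                                grating = list(C = 0.8, f_t = 2, f_s = 0.04),
                                core_only = TRUE) {
  cs <- compile_simnet(network)
  N <- cs$N
  i_ext <- matrix(0, N, duration)
  i_ext[target_ids, ] <- current
  run_protocol <- function(perturb) {
    rates <- matrix(0, N, length(directions))
    for (di in seq_along(directions)) {
      for (tr in seq_len(n_trials)) {
        set.seed(derive_seed(seed, sprintf("sil.%d.%d", di, tr)))
        mv <- drifting_grating(grating$C, directions[di], runif(1, 0, 2 * pi),
                               grating$f_t, grating$f_s, duration,
                               field = network$config$lgn$field)
        lgn <- bernoulli_spikes(surrogate_lgn_rates(mv, network$lgn_units))
        bkg <- background_spikes(network, duration)
        out <- run_network(network, lgn, bkg, duration, compiled = cs,
                           i_ext_pA = if (perturb) i_ext else NULL)
        rates[, di] <- rates[, di] +
          rowSums(out$spikes) * 1000 / duration / n_trials
      }
    }
    rates
  }
  base <- run_protocol(FALSE)
  if (!length(target_ids)) {
    pert <- base
  } else {
    pert <- run_protocol(TRUE)
  }
  keep <- setdiff(seq_len(N), target_ids)
  if (core_only) keep <- keep[network$neurons$core[keep]]
  per_neuron <- function(rates) {
    osi <- vapply(keep, function(j) {
      if (sum(rates[j, ]) == 0) return(NA_real_)
      osi_dsi(rates[j, ], directions)$osi
    }, 0)
    data.frame(id = keep, type = network$neurons$type[keep],
               rate = rowMeans(rates)[keep], osi = osi)
  }
  b <- per_neuron(base); p <- per_neuron(pert)
  agg <- function(df, f) tapply(df[[f]], df$type, mean, na.rm = TRUE)
  tt <- sort(unique(b$type))
  pc <- function(x0, x1) ifelse(x0 > 0, 100 * (x1 - x0) / x0, NA_real_)
  summary <- data.frame(
    type = tt,
    rate_base = as.numeric(agg(b, "rate")[tt]),
    rate_pert = as.numeric(agg(p, "rate")[tt]),
    osi_base = as.numeric(agg(b, "osi")[tt]),
    osi_pert = as.numeric(agg(p, "osi")[tt]))
  summary$pct_rate <- pc(summary$rate_base, summary$rate_pert)
  summary$pct_osi <- pc(summary$osi_base, summary$osi_pert)
  list(summary = summary, baseline = b, perturbed = p,
       silenced = target_ids)
}

#' Contrast-response sweep
#'
#' Presents full-field drifting gratings over a contrast series (default
#' the standard evaluation set 0.05-0.8 at 0.04 cpd, 2 Hz), computes
#' per-neuron rates and vector-sum OSI/DSI at each contrast, and aggregates
#' by cell type.  Contrast sweeps are an out-of-distribution probe:
#' training uses only the high-contrast condition.
#'
#' @param network a `column_network`.
#' @param contrasts contrast levels.
#' @param directions stimulus directions, degrees.
#' @param n_trials trials per direction.
#' @param duration trial length, ms.
#' @param seed integer seed.
#' @param f_t,f_s temporal (Hz) and spatial (cpd) frequency.
#' @param core_only restrict to core neurons.
#' @return data.frame per (contrast, type): mean `rate`, `osi`, `dsi`.
#' @export
contrast_sweep <- function(network, contrasts = c(0.05, 0.1, 0.2, 0.4,
                                                  0.6, 0.8),
                           directions = seq(0, 315, by = 45),
                           n_trials = 10L, duration = 300L, seed = 1L,
                           f_t = 2, f_s = 0.04, core_only = TRUE) {
  cs <- compile_simnet(network)
  N <- cs$N
  keep <- if (core_only) which(network$neurons$core) else seq_len(N)
  out <- list()
  for (C in contrasts) {
    rates <- matrix(0, N, length(directions))
    for (di in seq_along(directions)) {
      for (tr in seq_len(n_trials)) {
        set.seed(derive_seed(seed, sprintf("csw.%g.%d.%d", C, di, tr)))
        mv <- drifting_grating(C, directions[di], runif(1, 0, 2 * pi),
                               f_t, f_s, duration,
                               field = network$config$lgn$field)
        lgn <- bernoulli_spikes(surrogate_lgn_rates(mv, network$lgn_units))
        sim <- run_network(network, lgn, background_spikes(network, duration),
                           duration, compiled = cs)
        rates[, di] <- rates[, di] +
          rowSums(sim$spikes) * 1000 / duration / n_trials
      }
    }
    sel <- lapply(keep, function(j)
      if (sum(rates[j, ]) > 0) osi_dsi(rates[j, ], directions)
      else list(osi = NA_real_, dsi = NA_real_))
    df <- data.frame(type = network$neurons$type[keep],
                     rate = rowMeans(rates)[keep],
                     osi = vapply(sel, `[[`, 0, "osi"),
                     dsi = vapply(sel, `[[`, 0, "dsi"))
    agg <- do.call(rbind, lapply(split(df, df$type), function(d)
      data.frame(contrast = C, type = d$type[1], rate = mean(d$rate),
                 osi = mean(d$osi, na.rm = TRUE),
                 dsi = mean(d$dsi, na.rm = TRUE))))
    out[[length(out) + 1L]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte Carlo matched-size resampling of a pairwise statistic
#'
#' Repeatedly subsamples the model's connection pairs down to an
#' experimental sample size, recomputing the statistic and its p-value each
#' time, yielding the distribution of model p-values expected under matched
#' power.
#'
#' @param data data.frame of model pairs.
#' @param n_experiment experimental sample size.
#' @param statistic_fn function(data_subset) returning
#'   `list(stat =, p =)`.
#' @param reps resampling repetitions.
#' @param seed integer seed.
#' @return data.frame with `rep`, `stat`, `p`.
#' @export
matched_resample_pvalues <- function(data, n_experiment, statistic_fn,
                                     reps = 100L, seed = 1L) {
  stopifnot(n_experiment <= nrow(data))
  set.seed(seed)
  out <- lapply(seq_len(reps), function(r) {
    idx <- sample.int(nrow(data), n_experiment)
    s <- statistic_fn(data[idx, , drop = FALSE])
    data.frame(rep = r, stat = s$stat, p = s$p)
  })
  do.call(rbind, out)
}
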