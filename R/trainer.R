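#' Triangular surrogate derivative of the spike nonlinearity
#'
#' The forward pass uses exact Heaviside spikes; the backward pass replaces
#' the threshold derivative with `gamma * max(1 - |u|, 0)` where `u` is the
#' normalized distance to threshold (support `|u| < 1`, damped slope
#' `gamma`).
#'
#' @param u normalized distance(s) to threshold, `v - 1`.
#' @param gamma damping slope.
#' @return pseudo-derivative values.
#' @export
surrogate_spike_grad <- function(u, gamma = 0.1) {
  gamma * pmax(1 - abs(u), 0)
}

#' Training configuration
#'
#' @param epochs,updates_per_epoch training schedule.
#' @param t_chunk chunk length, ms.
#' @param b_spt,b_evk spontaneous / evoked trials per update.
#' @param gamma surrogate slope.
#' @param eta,beta1,beta2,eps Exponentiated Adam hyperparameters.
#' @param rate_ceiling abort threshold on the network-mean rate, Hz.
#' @param components which loss components contribute gradients.
#' @param volt_form voltage regularizer form (see [voltage_reg()]).
#' @param a_floor positive magnitude floor preventing exp-underflow lock-in.
#' @param sync_window synchrony analysis window within the chunk, ms.
#' @param grating evoked stimulus parameters.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 75L, updates_per_epoch = 25L,
                         t_chunk = 500L, b_spt = 5L, b_evk = 5L,
                         gamma = 0.1, eta = 5e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-11,
                         rate_ceiling = 100,
                         components = c("rate", "osi_dsi", "sync",
                                        "volt", "w"),
                         volt_form = "printed",
                         a_floor = 1e-12,
                         sync_window = c(200L, 500L),
                         grating = list(C = 0.8, f_t = 2, f_s = 0.04)) {
  stopifnot(t_chunk > 0, b_spt >= 1, b_evk >= 1)
  list(epochs = epochs, updates_per_epoch = updates_per_epoch,
       t_chunk = as.integer(t_chunk), b_spt = b_spt, b_evk = b_evk,
       gamma = gamma, eta = eta, beta1 = beta1, beta2 = beta2, eps = eps,
       rate_ceiling = rate_ceiling, components = components,
       volt_form = volt_form, a_floor = a_floor,
       sync_window = as.integer(sync_window), grating = grating)
}

#' Initialize Exponentiated Adam state
#'
#' @param a initial positive magnitudes.
#' @return optimizer state list.
#' @export
exp_adam_init <- function(a) {
  if (any(a <= 0)) stop("exp_adam_init: magnitudes must be positive")
  list(a = a, m = numeric(length(a)), v = numeric(length(a)), u = 0L)
}

#' One Exponentiated Adam update
#'
#' Adam-style adaptive moments with bias correction, applied as a
#' multiplicative (log-space) update to the positive magnitudes:
#' `a <- a * exp(-eta * m_hat / (sqrt(v_hat) + eps))`.  Positivity, and
#' therefore every synaptic sign, is preserved by construction; a
#' configurable floor guards against exp-underflow to exactly zero.
#'
#' @param opt state from [exp_adam_init()].
#' @param g gradient with respect to the magnitudes.
#' @param eta,beta1,beta2,eps hyperparameters.
#' @param a_floor magnitude floor.
#' @return updated state.
#' @export
exp_adam_update <- function(opt, g, eta = 5e-3, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-11, a_floor = 1e-12) {
  u <- opt$u + 1L
  m <- beta1 * opt$m + (1 - beta1) * g
  v <- beta2 * opt$v + (1 - beta2) * g^2
  m_hat <- m / (1 - beta1^u)
  v_hat <- v / (1 - beta2^u)
  a <- opt$a * exp(-eta * m_hat / (sqrt(v_hat) + eps))
  floored <- a < a_floor
  if (any(floored)) a[floored] <- a_floor
  list(a = a, m = m, v = v, u = u, n_floored = sum(floored))
}

#' Reverse pass through a simulated chunk
#'
#' Backpropagation through time with the triangular surrogate at every
#' threshold crossing: given a forward run (with recorded voltages) and the
#' loss gradients with respect to the spike outputs and recorded voltages,
#' returns the gradient with respect to every parent (normalized, signed)
#' synaptic weight.
#'
#' @param fwd output of [run_network()] with `record_v = TRUE`.
#' @param dLdS neurons x T gradient w.r.t. spikes.
#' @param dLdv neurons x T gradient w.r.t. recorded voltages.
#' @param gamma surrogate slope.
#' @return gradient vector over parent edges (recurrent, background, LGN).
#' @export
backprop_through_time <- function(fwd, dLdS, dLdv, gamma = 0.1) {
  cs <- fwd$compiled
  if (is.null(dim(fwd$v_trace)) || nrow(fwd$v_trace) != cs$N)
    stop("backprop_through_time: forward run must record voltages")
  g <- sim_backward_cpp(cs$N, cs$pars$alpha, cs$pars$rm,
                        cs$pars$asc_b1, cs$pars$asc_b2,
                        cs$pars$asc_a1, cs$pars$asc_a2, cs$pars$tref,
                        cs$chan_decay, cs$chan_inject,
                        cs$esrc, cs$edst, cs$edelay, cs$echan,
                        cs$eparent, cs$ecoef, cs$w, cs$n_parent,
                        fwd$S_all, fwd$v_trace, fwd$init_refrac,
                        ncol(dLdS), cs$d_max, dLdS, dLdv, gamma)
  if (any(!is.finite(g))) stop("backprop_through_time: non-finite gradient")
  g
}

## Per-(type, region) structures used by the training loss
make_loss_context <- function(network, targets, config) {
  neurons <- network$neurons
  region <- ifelse(neurons$core, "core", "peri")
  key <- paste(neurons$type, region, sep = ".")
  ctx <- list(region = region, key = key,
              types = neurons$type,
              exc_core = which(neurons$core &
                vapply(neurons$type, function(tt)
                  type_class(network$config, tt) == "excitatory", TRUE)))
  ## rate targets are matched in the simulator's native unit (spikes per ms,
  ## i.e. per step), the scale on which the kappa = 0.002 Huber knee and
  ## lambda_rate = 1e4 coefficient are calibrated
  for (ch in c("spt", "evk")) {
    samples <- targets[[paste0("rate_", ch)]]
    tv <- list()
    for (kk in unique(key)) {
      tt <- sub("\\.(core|peri)$", "", kk)
      tv[[kk]] <- sample_rate_targets(samples[[tt]], sum(key == kk)) / 1000
    }
    ctx[[paste0("rate_targets_", ch)]] <- tv
  }
  ctx
}

## One chunk's worth of forward runs + loss evaluation + reverse passes.
## Returns component values and the accumulated weight gradient.
process_chunk <- function(net, cs, ctx, targets, cfg, carry, chunk,
                          ema, pools, b_tot) {
  Tch <- cfg$t_chunk
  N <- cs$N
  B <- if (chunk == "spt") cfg$b_spt else cfg$b_evk
  co <- targets$coef
  trials <- vector("list", B)
  stim_dir <- numeric(B)
  for (b in seq_len(B)) {
    if (chunk == "spt") {
      lgn <- spont_lgn_spikes(net, Tch)
    } else {
      stim_dir[b] <- runif(1, 0, 360)
      mv <- drifting_grating(cfg$grating$C, stim_dir[b], runif(1, 0, 2 * pi),
                             cfg$grating$f_t, cfg$grating$f_s, Tch,
                             field = net$config$lgn$field)
      lgn <- bernoulli_spikes(surrogate_lgn_rates(mv, net$lgn_units))
    }
    bkg <- background_spikes(net, Tch)
    trials[[b]] <- run_network(net, lgn, bkg, Tch, init = carry,
                               record_v = TRUE, compiled = cs)
  }
  rates_bt <- t(vapply(trials, function(tr) rowSums(tr$spikes) * 1000 / Tch,
                       numeric(N)))                    # B x N, Hz
  rates_chunk <- colMeans(rates_bt)
  comp <- list()
  dLdS <- lapply(seq_len(B), function(b) matrix(0, N, Tch))
  dLdv <- lapply(seq_len(B), function(b) matrix(0, N, Tch))

  if ("rate" %in% cfg$components) {
    rates_step <- rates_chunk / 1000      # spikes per ms (per-step unit)
    rl <- rate_distribution_loss(rates_step, ctx$key,
                                 ctx[[paste0("rate_targets_", chunk)]],
                                 kappa = co$kappa, lambda_rate = co$lambda_rate,
                                 grad = TRUE)
    for (rg in c("core", "peri"))
      comp[[paste0("rate_", rg)]] <- rate_region_value(
        rates_step, ctx, chunk, rg, co)
    ## peripheral terms enter the total down-weighted by lambda_peri
    g_rate <- rl$grad * ifelse(ctx$region == "peri", co$lambda_peri, 1)
    dS <- matrix(g_rate / (B * Tch), N, Tch)
    for (b in seq_len(B)) dLdS[[b]] <- dLdS[[b]] + dS
  }

  if (chunk == "evk" && "osi_dsi" %in% cfg$components) {
    ## before the first optimizer update the EMA is seeded from trial 1
    ema <- ifelse(is.na(ema), rates_bt[1, ], ema)
    osd <- osi_dsi_grad(rates_bt, net, ctx, targets, stim_dir, ema, co)
    comp$osi_dsi_core <- osd$value_core
    comp$osi_dsi_peri <- osd$value_peri
    for (b in seq_len(B))
      dLdS[[b]] <- dLdS[[b]] + matrix(osd$grad_rates[b, ] * 1000 / Tch, N, Tch)
  }

  if ("sync" %in% cfg$components && length(ctx$exc_core) >= 15) {
    win <- (cfg$sync_window[1] + 1):cfg$sync_window[2]
    tgt <- targets[[paste0("fano_", chunk)]]
    vals <- 0
    for (b in seq_len(B)) {
      fs <- fano_sync_loss(trials[[b]]$spikes[ctx$exc_core, win, drop = FALSE],
                           pools, tgt, lambda_sync = co$lambda_sync,
                           grad = TRUE)
      vals <- vals + fs$value / B
      dLdS[[b]][ctx$exc_core, win] <- dLdS[[b]][ctx$exc_core, win] + fs$grad / B
    }
    comp[[paste0("sync_", chunk)]] <- vals
  }

  if ("volt" %in% cfg$components) {
    vv <- 0
    for (b in seq_len(B)) {
      vr <- voltage_reg(trials[[b]]$v_trace, lambda_volt = co$lambda_volt,
                        form = cfg$volt_form, grad = TRUE)
      vv <- vv + vr$value / b_tot
      dLdv[[b]] <- dLdv[[b]] + vr$grad / b_tot
    }
    comp$volt <- vv
  }

  gw <- numeric(cs$n_parent)
  for (b in seq_len(B))
    gw <- gw + backprop_through_time(trials[[b]], dLdS[[b]], dLdv[[b]],
                                     gamma = cfg$gamma)
  list(comp = comp, grad_w = gw, rates = rates_chunk, rates_bt = rates_bt,
       carry = trials[[B]]$state, mean_rate = mean(rates_chunk))
}

## region-restricted rate-loss value (reported per block)
rate_region_value <- function(rates, ctx, chunk, rg, co) {
  idx <- ctx$region == rg
  if (!any(idx)) return(0)
  rate_distribution_loss(rates[idx], ctx$key[idx],
                         ctx[[paste0("rate_targets_", chunk)]],
                         kappa = co$kappa,
                         lambda_rate = co$lambda_rate)$value * sum(idx) /
    length(rates)
}

## crowd OSI/DSI loss value + gradient w.r.t. single-trial rates (Hz)
osi_dsi_grad <- function(rates_bt, net, ctx, targets, stim_dir, ema, co) {
  B <- nrow(rates_bt)
  N <- ncol(rates_bt)
  norm <- pmax(ema, co$r_min)
  grad <- matrix(0, B, N)
  vals <- c(core = 0, peri = 0)
  for (rg in c("core", "peri")) {
    ridx <- which(ctx$region == rg)
    if (!length(ridx)) next
    est <- crowd_osi_dsi(rates_bt[, ridx, drop = FALSE],
                         net$neurons$tuning_angle[ridx],
                         stim_dir, ctx$types[ridx], ema[ridx],
                         r_min = co$r_min)
    nn <- table(ctx$types[ridx])
    ol <- osi_dsi_loss(est, targets$osi, targets$dsi,
                       stats::setNames(as.numeric(nn), names(nn)),
                       lambda = co$lambda_osi_dsi)
    vals[rg] <- ol$value
    ## gradient (peripheral block is down-weighted by lambda_peri)
    blockw <- if (rg == "peri") co$lambda_peri else 1
    n_tot <- sum(nn[unique(est$type)])
    for (tt in unique(est$type)) {
      tidx <- ridx[ctx$types[ridx] == tt]
      nc <- length(tidx)
      dL_dosi <- co$lambda_osi_dsi * 2 * nc *
        (ol$osi_hat[tt] - targets$osi[tt]) / n_tot / B
      dL_ddsi <- co$lambda_osi_dsi * 2 * nc *
        (ol$dsi_hat[tt] - targets$dsi[tt]) / n_tot / B
      for (b in seq_len(B)) {
        dth <- (stim_dir[b] - net$neurons$tuning_angle[tidx]) * pi / 180
        rt <- rates_bt[b, tidx] / norm[tidx]
        D <- max(mean(rt), co$r_min)
        ee <- est[est$trial == b & est$type == tt, ]
        free <- D > co$r_min
        dosi_drt <- (cos(2 * dth) / nc) / D -
          if (free) ee$osi / D * (1 / nc) else 0
        ddsi_drt <- (cos(dth) / nc) / D -
          if (free) ee$dsi / D * (1 / nc) else 0
        grad[b, tidx] <- grad[b, tidx] +
          blockw * (dL_dosi * dosi_drt + dL_ddsi * ddsi_drt) / norm[tidx]
      }
    }
  }
  list(value_core = vals["core"], value_peri = vals["peri"], grad_rates = grad)
}

#' Train a column network
#'
#' Surrogate-gradient BPTT training of the recurrent and background weights
#' (LGN weights frozen) under the multi-objective physiological loss, with
#' the sign-preserving Exponentiated Adam optimizer acting on positive
#' weight magnitudes.  Each epoch starts from a 500 ms gray-screen warm-up
#' of the zero state; each update simulates one spontaneous and one evoked
#' chunk (batched trials) and applies one optimizer step; state carries
#' forward between updates within an epoch.
#'
#' @param network a `column_network`.
#' @param targets a target set (see [make_targets()]).
#' @param config a [train_config()].
#' @param seed master seed (fans out into stimulus/pool/optimizer streams).
#' @param verbose print per-update loss lines.
#' @param log_file optional path; every update appends one JSON line with
#'   the full component breakdown.
#' @return list with the trained `network`, the per-update `losses`
#'   data.frame, optimizer state, EMA rates, and the initial weight snapshot.
#' @export
train_network <- function(network, targets, config = train_config(),
                          seed = 1L, verbose = FALSE, log_file = NULL) {
  cs <- compile_simnet(network)
  ctx <- with_seed(derive_seed(seed, "targets"),
                   make_loss_context(network, targets, config))
  co <- targets$coef
  trainable <- c(cs$idx_rec, cs$idx_bkg)
  s_k <- sign(cs$w[trainable])
  opt <- exp_adam_init(abs(cs$w[trainable]))
  w0_rec <- cs$w[cs$idx_rec]
  emd_classes <- network$edges_rec$family
  ema <- rep(NA_real_, cs$N)
  lgn_w_hash <- sum(cs$w[cs$idx_lgn]) + length(cs$idx_lgn)
  log_rows <- list()
  b_tot <- config$b_spt + config$b_evk
  upd_global <- 0L

  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(seed, paste0("epoch", ep)))
    warm_lgn <- spont_lgn_spikes(network, 500L)
    warm_bkg <- background_spikes(network, 500L)
    carry <- run_network(network, warm_lgn, warm_bkg, 500L,
                         compiled = cs)$state
    for (up in seq_len(config$updates_per_epoch)) {
      upd_global <- upd_global + 1L
      set.seed(derive_seed(seed, paste0("update", upd_global)))
      ## pool draws on their own stream, independent of stimulus/input RNG
      pools <- with_seed(derive_seed(seed, paste0("pools", upd_global)),
                         make_fano_pools(seq_along(ctx$exc_core),
                                         n_pool = co$n_pool))
      spt <- process_chunk(network, cs, ctx, targets, config, carry,
                           "spt", ema, pools, b_tot)
      evk <- process_chunk(network, cs, ctx, targets, config, carry,
                           "evk", ema, pools, b_tot)
      ## EMA of evoked rates (normalization statistic, not differentiated);
      ## initialized at the first observed trial's rates
      ema <- ifelse(is.na(ema), evk$rates_bt[1, ],
                    co$beta_ema * ema + (1 - co$beta_ema) * colMeans(evk$rates_bt))
      gw <- spt$grad_w + evk$grad_w
      wcomp <- 0
      if ("w" %in% config$components) {
        er <- emd_weight_reg(cs$w[cs$idx_rec], w0_rec, emd_classes,
                             lambda_w = co$lambda_w, grad = TRUE)
        gw[cs$idx_rec] <- gw[cs$idx_rec] + er$grad
        wcomp <- er$value
      }
      report <- total_loss(
        core = list(rate_spt = spt$comp$rate_core %||% 0,
                    rate_evk = evk$comp$rate_core %||% 0,
                    sync_spt = spt$comp$sync_spt %||% 0,
                    sync_evk = evk$comp$sync_evk %||% 0,
                    osi_dsi = unname(evk$comp$osi_dsi_core %||% 0)),
        peri = list(rate_spt = spt$comp$rate_peri %||% 0,
                    rate_evk = evk$comp$rate_peri %||% 0,
                    osi_dsi = unname(evk$comp$osi_dsi_peri %||% 0)),
        volt = (spt$comp$volt %||% 0) + (evk$comp$volt %||% 0),
        w = wcomp, lambda_peri = co$lambda_peri)
      mean_rate <- (spt$mean_rate * config$b_spt +
                    evk$mean_rate * config$b_evk) / b_tot
      if (mean_rate > config$rate_ceiling)
        stop(sprintf("train_network: runaway mean rate %.1f Hz at epoch %d update %d",
                     mean_rate, ep, up))
      ## optimizer step on magnitudes (LGN weights excluded)
      g_a <- s_k * gw[trainable]
      opt <- exp_adam_update(opt, g_a, eta = config$eta,
                             beta1 = config$beta1, beta2 = config$beta2,
                             eps = config$eps, a_floor = config$a_floor)
      cs$w[trainable] <- s_k * opt$a
      stopifnot(sum(cs$w[cs$idx_lgn]) + length(cs$idx_lgn) == lgn_w_hash)
      carry <- spt$carry
      log_rows[[upd_global]] <- data.frame(
        epoch = ep, update = up, total = report$total,
        rate = report$core$rate_spt + report$core$rate_evk,
        osi_dsi = report$core$osi_dsi, sync = report$core$sync_spt +
          report$core$sync_evk, volt = report$volt, w = report$w,
        mean_rate = mean_rate)
      if (!is.null(log_file))
        cat(jsonlite::toJSON(c(list(epoch = ep, update = up,
                                    mean_rate = mean_rate),
                               unclass(report)),
                             auto_unbox = TRUE, digits = NA),
            "\n", sep = "", file = log_file, append = TRUE)
      if (verbose)
        message(sprintf("epoch %d update %d: total %.4f (mean rate %.2f Hz)",
                        ep, up, report$total, mean_rate))
    }
  }
  ## write trained weights back into the network tables (raw units)
  dV <- cs$pars$dV
  net2 <- network
  net2$edges_rec$weight <- denormalize_weights(cs$w[cs$idx_rec],
                                               network$edges_rec$dst, dV)
  if (length(cs$idx_bkg))
    net2$edges_bkg$weight <- denormalize_weights(cs$w[cs$idx_bkg],
                                                 network$edges_bkg$dst, dV)
  list(network = net2, losses = do.call(rbind, log_rows), opt = opt,
       ema = ema, w0_rec = w0_rec, compiled = cs)
}

#' One training epoch
#'
#' @inheritParams train_network
#' @return as [train_network()] with `epochs = 1`.
#' @export
train_epoch <- function(network, targets, config = train_config(), seed = 1L,
                        verbose = FALSE) {
  config$epochs <- 1L
  train_network(network, targets, config, seed, verbose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
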