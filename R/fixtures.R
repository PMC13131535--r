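#' Toy GLIF3 parameter pool
#'
#' Six hand-written point models with physiologically plausible parameter
#' ranges (regular-spiking excitatory, fast-spiking PV-like, adapting
#' SST/VIP-like), used by the toy build configurations.
#'
#' @return list of [glif_param_set()] objects.
#' @export
toy_glif_pool <- function() {
  list(
    glif_param_set(-70, -50, 0.20, 20, c(-20, -5), c(0.03, 0.30), 4),  # Exc RS
    glif_param_set(-72, -52, 0.25, 25, c(-15, -4), c(0.05, 0.25), 4),  # Exc RS 2
    glif_param_set(-70, -48, 0.10, 10, c(-10, -2), c(0.10, 0.50), 2),  # PV FS
    glif_param_set(-68, -47, 0.12, 12, c(-8, -2), c(0.10, 0.40), 2),   # PV FS 2
    glif_param_set(-65, -45, 0.30, 15, c(-15, -4), c(0.05, 0.30), 3),  # SST
    glif_param_set(-65, -45, 0.35, 18, c(-10, -3), c(0.06, 0.30), 3)   # VIP
  )
}

toy_kinetics <- function(src_class, dst_class) {
  if (src_class == "excitatory") {
    if (dst_class == "excitatory") list(tau_f = 1.5, tau_s = 6, lam = 0.4)
    else list(tau_f = 0.8, tau_s = 4, lam = 0.3)
  } else {
    if (dst_class == "excitatory") list(tau_f = 2.0, tau_s = 8, lam = 0.5)
    else list(tau_f = 1.2, tau_s = 6, lam = 0.3)
  }
}

#' Toy build configuration
#'
#' A four-type (L4 excitatory, PV, SST, VIP) single-layer column at the
#' package's default geometry (400 um column, 200 um core) with densities
#' chosen to give roughly `n_neurons` cells at an 80/10/5/5 class split,
#' full 16-class recurrent connectivity, and a scaled-down LGN mosaic.
#' All statistical structure of the full-scale construction rules is
#' retained (log-normal PSPs and in-degrees, like-to-like and target-size
#' modulation, Yule-Simon LGN synapse counts).
#'
#' @param n_neurons approximate total neuron count.
#' @param beta like-to-like strength for the E-to-E class.
#' @param n_lgn_units LGN unit count.
#' @param field visual field, degrees.
#' @param spont_rates named per-type spontaneous-rate targets, Hz, used by
#'   the background calibration.
#' @return a [build_config()].
#' @export
toy_build_config <- function(n_neurons = 300, beta = 0.6,
                             n_lgn_units = 80L, field = c(48, 32),
                             spont_rates = c(L4_Exc = 3, PV = 8,
                                             SST = 4, VIP = 5)) {
  depth <- c(350, 450)
  vol <- pi * 0.4^2 * diff(depth) / 1000          # mm^3 at 400 um radius
  frac <- c(L4_Exc = 0.8, PV = 0.1, SST = 0.05, VIP = 0.05)
  dens <- n_neurons * frac / vol
  ind <- list(sdlog = 0.4, scale = 250)
  cts <- list(
    cell_type_spec("L4_Exc", "excitatory", "L4", dens["L4_Exc"], depth, ind,
                   glif_pool = c(1L, 2L), lgn_fraction = 0.20, lgn_rho = 2.2),
    cell_type_spec("PV", "inhibitory", "L4", dens["PV"], depth, ind,
                   glif_pool = c(3L, 4L), subclass = "PV",
                   lgn_fraction = 0.10, lgn_rho = 2.2),
    cell_type_spec("SST", "inhibitory", "L4", dens["SST"], depth, ind,
                   glif_pool = 5L, subclass = "SST",
                   lgn_fraction = 0.04, lgn_rho = 2.2),
    cell_type_spec("VIP", "inhibitory", "L4", dens["VIP"], depth, ind,
                   glif_pool = 6L, subclass = "VIP",
                   lgn_fraction = 0.04, lgn_rho = 2.2)
  )
  for (i in seq_along(cts))
    cts[[i]]$spont_rate <- unname(spont_rates[cts[[i]]$name])
  types <- vapply(cts, `[[`, "", "name")
  classes <- vapply(cts, `[[`, "", "class")
  p_max <- matrix(c(0.15, 0.40, 0.15, 0.10,
                    0.60, 0.40, 0.20, 0.10,
                    0.40, 0.10, 0.05, 0.30,
                    0.10, 0.05, 0.40, 0.05),
                  4, 4, byrow = TRUE,
                  dimnames = list(types, types))   # row = src, col = dst
  sig <- matrix(120, 4, 4, dimnames = list(types, types))
  sig["L4_Exc", "L4_Exc"] <- 150
  delays <- matrix(c(1.6, 1.2, 1.2, 1.2,
                     1.1, 1.0, 1.0, 1.0,
                     1.1, 1.0, 1.0, 1.0,
                     1.1, 1.0, 1.0, 1.0), 4, 4, byrow = TRUE,
                   dimnames = list(types, types))
  conns <- list()
  for (s in seq_along(types)) {
    for (d in seq_along(types)) {
      psp <- if (classes[s] == "excitatory") list(meanlog = log(0.4), sdlog = 0.9)
             else list(meanlog = log(0.5), sdlog = 0.9)
      conns[[length(conns) + 1L]] <- connection_class_spec(
        types[s], types[d], p_max[s, d], sig[s, d],
        psp_lognormal = psp,
        kinetics = toy_kinetics(classes[s], classes[d]),
        delay = delays[s, d],
        beta = if (s == 1 && d == 1) beta else NULL)
    }
  }
  build_config(cts, conns, toy_glif_pool(),
               lgn = list(n_units = n_lgn_units, field = field,
                          subtype_fractions = c(sustained_on = 0.4,
                                                sustained_off = 0.4,
                                                transient_off = 0.2),
                          sigma_lgn = 5, psp_per_synapse = 0.2,
                          convergence_offset = 3, delay = 1.7,
                          deg_per_um = 1 / 70,
                          kinetics = list(tau_f = 1.5, tau_s = 6, lam = 0.3)))
}

#' Full 19-type cell composition labels
#'
#' The layer-resolved composition of the full-scale model: six excitatory
#' types and thirteen inhibitory types (PV/SST/VIP in four layers plus L1
#' interneurons).  Used to validate the effective-type aggregation and the
#' 121-family receptor enumeration; densities and depths are nominal.
#'
#' @return list of [cell_type_spec()] objects (19 entries).
#' @export
full_cell_type_table <- function() {
  ind <- list(sdlog = 0.5, scale = 3000)
  exc <- list(c("L23_Exc", "L2/3"), c("L4_Exc", "L4"), c("L5_ET", "L5"),
              c("L5_IT", "L5"), c("L5_NP", "L5"), c("L6_Exc", "L6"))
  depths <- list("L1" = c(0, 100), "L2/3" = c(100, 300), "L4" = c(300, 430),
                 "L5" = c(430, 650), "L6" = c(650, 850))
  out <- lapply(exc, function(e)
    cell_type_spec(e[1], "excitatory", e[2], 30000, depths[[e[2]]], ind, 1L))
  for (layer in c("L2/3", "L4", "L5", "L6")) {
    for (sub in c("PV", "SST", "VIP")) {
      out[[length(out) + 1L]] <- cell_type_spec(
        paste0(gsub("[/]", "", layer), "_", sub), "inhibitory", layer,
        3000, depths[[layer]], ind, 1L, subclass = sub)
    }
  }
  out[[length(out) + 1L]] <- cell_type_spec("L1_Inh", "inhibitory", "L1",
                                            2000, depths[["L1"]], ind, 1L,
                                            subclass = "L1_Inh")
  out
}

#' Build a toy network through the full construction path
#'
#' Convenience wrapper: builds a complete small network (placement, all
#' three wiring stages, background calibration) through exactly the same
#' code path as any full-scale build.
#'
#' @param n_neurons approximate size (100-2000).
#' @param seed master seed.
#' @param calibrate_background run the spontaneous-rate calibration.
#' @param ... passed to [toy_build_config()].
#' @return a `column_network`.
#' @export
make_toy_network <- function(n_neurons = 300, seed = 1L,
                             calibrate_background = TRUE, ...) {
  build_network(toy_build_config(n_neurons = n_neurons, ...), seed,
                calibrate_background = calibrate_background)
}

#' Synthetic training target set
#'
#' Generates the statistical targets a training run consumes, with the
#' structure of curated in vivo references: per-type firing-rate samples
#' (log-normal, with an explicit 0 Hz entry appended to preserve the
#' silent fraction; evoked rates above spontaneous), per-type OSI/DSI
#' scalars in [0, 1], and supra-Poisson Fano-factor curves at the analysis
#' widths with evoked fluctuations above spontaneous at every width.
#'
#' @param types cell type labels.
#' @param seed integer seed.
#' @param n_samples rate-sample size per type.
#' @param window_ms synchrony analysis-window length (sets the width grid).
#' @param rate_medians named spontaneous rate medians, Hz (defaults by
#'   class).
#' @return a `target_set` list: `rate_spt`, `rate_evk` (per-type samples),
#'   `osi`, `dsi` (named vectors), `fano_spt`, `fano_evk` (width/fano
#'   frames), and the loss `coef` block.
#' @export
make_targets <- function(types, seed = 1L, n_samples = 200L,
                         window_ms = 300L, rate_medians = NULL) {
  set.seed(seed)
  if (is.null(rate_medians))
    rate_medians <- stats::setNames(
      ifelse(grepl("PV", types), 6, ifelse(grepl("Exc", types), 2.5, 3.5)),
      types)
  rate_spt <- rate_evk <- list()
  osi <- dsi <- stats::setNames(numeric(length(types)), types)
  for (tt in types) {
    rate_spt[[tt]] <- c(rlnorm(n_samples, log(rate_medians[tt]), 1), 0)
    rate_evk[[tt]] <- c(rlnorm(n_samples, log(rate_medians[tt] * 1.8), 1), 0)
    osi[tt] <- if (grepl("PV", tt)) 0.05 else runif(1, 0.10, 0.25)
    dsi[tt] <- osi[tt] / 2
  }
  widths <- fano_width_set(window_ms)
  fano_spt <- data.frame(width = widths,
                         fano = 1 + 0.4 * sqrt(widths / 100))
  fano_evk <- data.frame(width = widths,
                         fano = 1 + 0.9 * sqrt(widths / 100))
  structure(list(
    rate_spt = rate_spt, rate_evk = rate_evk, osi = osi, dsi = dsi,
    fano_spt = fano_spt, fano_evk = fano_evk,
    coef = list(lambda_rate = 1e4, lambda_osi_dsi = 20, lambda_sync = 1.5,
                lambda_volt = 1, lambda_w = 10, lambda_peri = 0.1,
                kappa = 0.002, beta_ema = 0.95, r_min = 0.5,
                n_pool = 500L)
  ), class = "target_set")
}

#' Measure a reference network's statistics as training targets
#'
#' Simulates a network under the training protocol (spontaneous gray and
#' evoked gratings) and converts the measured per-type rate distributions
#' into a target set, so a perturbed copy of the network can be trained
#' back toward the reference statistics.
#'
#' @param network the reference `column_network`.
#' @param seed integer seed.
#' @param n_trials trials per condition.
#' @param t_chunk chunk length, ms.
#' @param grating evoked stimulus parameters.
#' @return a `target_set` (OSI/DSI and Fano blocks from the reference run).
#' @export
measure_reference_targets <- function(network, seed = 1L, n_trials = 5L,
                                      t_chunk = 500L,
                                      grating = list(C = 0.8, f_t = 2,
                                                     f_s = 0.04)) {
  force(network)   # build before seeding: argument promises must not
  set.seed(seed)   # consume the measurement RNG stream
  cs <- compile_simnet(network)
  N <- cs$N
  ## mirror the training protocol: a 500 ms gray warm-up from the zero
  ## state, then chunks simulated from the carried (stationary) state, so
  ## onset transients do not deflate the measured rates
  warm <- run_network(network, spont_lgn_spikes(network, 500L),
                      background_spikes(network, 500L), 500L,
                      compiled = cs)$state
  run_rates <- function(evoked, init) {
    r <- matrix(0, n_trials, N)
    for (b in seq_len(n_trials)) {
      if (evoked) {
        mv <- drifting_grating(grating$C, runif(1, 0, 360), runif(1, 0, 2 * pi),
                               grating$f_t, grating$f_s, t_chunk,
                               field = network$config$lgn$field)
        lgn <- bernoulli_spikes(surrogate_lgn_rates(mv, network$lgn_units))
      } else {
        lgn <- spont_lgn_spikes(network, t_chunk)
      }
      out <- run_network(network, lgn, background_spikes(network, t_chunk),
                         t_chunk, init = init, compiled = cs)
      r[b, ] <- rowSums(out$spikes) * 1000 / t_chunk
    }
    r
  }
  r_spt <- colMeans(run_rates(FALSE, warm))
  r_evk <- colMeans(run_rates(TRUE, warm))
  types <- unique(network$neurons$type)
  tg <- make_targets(types, seed = seed)
  for (tt in types) {
    tg$rate_spt[[tt]] <- c(r_spt[network$neurons$type == tt], 0)
    tg$rate_evk[[tt]] <- c(r_evk[network$neurons$type == tt], 0)
  }
  tg$reference_mean_spt <- tapply(r_spt, network$neurons$type, mean)
  tg$reference_mean_evk <- tapply(r_evk, network$neurons$type, mean)
  tg
}
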