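#' Build a complete column network from a configuration
#'
#' Runs the full construction pipeline: neuron placement, recurrent wiring
#' (spatial + like-to-like + target-size rules), thalamocortical wiring with
#' Yule-Simon synapse counts, and background wiring, all from named RNG
#' streams fanned out of one master seed.  Optionally calibrates background
#' weights so each cell model's isolated spontaneous rate matches its
#' configured target.
#'
#' @param config a [build_config()].
#' @param seed master integer seed.
#' @param calibrate_background run [calibrate_background_weights()] after
#'   wiring (requires per-type `spont_rate` fields; skipped when absent).
#' @param n_lgn_units optional LGN unit count override.
#' @return a `column_network`: neuron table, recurrent/LGN/background edge
#'   tables, LGN unit table, per-neuron GLIF parameter vectors, receptor
#'   family kinetics, and the build config.
#' @export
build_network <- function(config, seed, calibrate_background = TRUE,
                          n_lgn_units = NULL) {
  neurons <- place_neurons(config, derive_seed(seed, "place"))
  fams <- build_family_kinetics(config)
  unitary <- unitary_psp_table(config, fams)
  edges_rec <- wire_recurrent(neurons, config, derive_seed(seed, "recurrent"),
                              unitary = unitary)
  lgn_units <- make_lgn_units(config, derive_seed(seed, "lgn_units"),
                              n_units = n_lgn_units)
  edges_lgn <- wire_lgn(neurons, lgn_units, config, derive_seed(seed, "lgn"),
                        unitary = unitary)
  edges_bkg <- wire_background(neurons, config, derive_seed(seed, "background"))
  net <- structure(list(
    neurons = neurons,
    edges_rec = edges_rec,
    edges_lgn = edges_lgn[, c("src", "dst", "weight", "delay", "family")],
    edges_bkg = edges_bkg,
    lgn_units = lgn_units,
    lgn_n_syn = edges_lgn$n_syn,
    glif = glif_vectors(config$glif_pool, neurons$model_id),
    family_kinetics = fams,
    unitary = unitary,
    config = config
  ), class = "column_network")
  has_targets <- all(vapply(config$cell_types, function(ct)
    !is.null(ct$spont_rate), TRUE))
  if (calibrate_background && has_targets) {
    net <- calibrate_background_weights(net, derive_seed(seed, "bkg_calib"))
  }
  net
}

#' @export
print.column_network <- function(x, ...) {
  cat(sprintf("column network: %d neurons (%d types), %d recurrent / %d LGN / %d background edges\n",
              nrow(x$neurons), length(unique(x$neurons$type)),
              nrow(x$edges_rec), nrow(x$edges_lgn), nrow(x$edges_bkg)))
  cat(sprintf("  column radius %g um (core %g um), %d LGN units, %d background units\n",
              x$config$column_radius, x$config$core_radius,
              nrow(x$lgn_units), x$config$background$n_units))
  invisible(x)
}

#' Spontaneous (gray-screen) LGN spikes
#'
#' Under gray input the surrogate LGN sits exactly at each unit's baseline
#' rate, so spontaneous drive is Bernoulli sampling of the baselines.
#'
#' @param network a `column_network`.
#' @param T_steps duration, ms.
#' @return units x T 0/1 matrix.
#' @export
spont_lgn_spikes <- function(network, T_steps) {
  r <- matrix(network$lgn_units$baseline, nrow(network$lgn_units), T_steps)
  bernoulli_spikes(r)
}

#' Background Poisson spikes
#'
#' @param network a `column_network`.
#' @param T_steps duration, ms.
#' @return units x T 0/1 matrix.
#' @export
background_spikes <- function(network, T_steps) {
  poisson_spikes(network$config$background$n_units,
                 network$config$background$rate, T_steps)
}

#' Calibrate background weights to spontaneous-rate targets
#'
#' Iterative 1-D search (log-scale bisection, one scale factor per cell
#' model) on the background weights: the network is simulated with recurrent
#' weights removed, driven only by spontaneous LGN activity and the 250 Hz
#' background units, until each model's mean rate matches the spontaneous
#' target of its cell types within tolerance.  Targets come from the
#' `spont_rate` field of the cell types.
#'
#' @param network a `column_network`.
#' @param seed integer seed for the probe input spikes.
#' @param T_sim probe duration per iteration, ms.
#' @param iters bisection iterations.
#' @param tol relative tolerance on the rate match.
#' @return the network with calibrated `edges_bkg$weight`.
#' @export
calibrate_background_weights <- function(network, seed, T_sim = 2000L,
                                         iters = 12L, tol = 0.1) {
  force(network)
  set.seed(seed)
  cfg <- network$config
  spont <- vapply(cfg$cell_types, function(ct) {
    if (is.null(ct$spont_rate)) stop("calibrate_background_weights: missing spont_rate")
    ct$spont_rate
  }, 0)
  target_neuron <- spont[network$neurons$type]
  models <- sort(unique(network$neurons$model_id))
  target_model <- vapply(models, function(m)
    mean(target_neuron[network$neurons$model_id == m]), 0)
  if (any(cfg$background$rate <= 0) && any(target_model > 0))
    stop("calibrate_background_weights: zero background rate cannot reach a positive target")
  isolated <- network
  isolated$edges_rec <- network$edges_rec[0, ]
  base_w <- network$edges_bkg$weight
  edge_model <- network$neurons$model_id[network$edges_bkg$dst]
  lgn_in <- spont_lgn_spikes(network, T_sim)
  bkg_in <- background_spikes(network, T_sim)
  lo <- rep(-8, length(models)); hi <- rep(8, length(models))
  mid <- rep(0, length(models))
  rate_of <- function(log2s) {
    s_edge <- 2^log2s[match(edge_model, models)]
    isolated$edges_bkg$weight <- base_w * s_edge
    out <- run_network(isolated, lgn_in, bkg_in, T_sim)
    r <- rowSums(out$spikes) / (T_sim / 1000)
    vapply(models, function(m) mean(r[network$neurons$model_id == m]), 0)
  }
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    r <- rate_of(mid)
    high <- r > target_model
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  r_final <- rate_of(mid)
  rel_err <- abs(r_final - target_model) / pmax(target_model, 0.1)
  if (any(rel_err > 1))
    warning("calibrate_background_weights: target unreachable for model(s) ",
            paste(models[rel_err > 1], collapse = ", "))
  network$edges_bkg$weight <- base_w * 2^mid[match(edge_model, models)]
  attr(network$edges_bkg, "calibration") <-
    data.frame(model_id = models, target = target_model, achieved = r_final)
  network
}
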