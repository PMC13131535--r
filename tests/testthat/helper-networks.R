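## Shared fixture networks, built once per test run through the real
## construction path and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## small uncalibrated network for structural / gradient tests
net_small <- function() fixture("net_small", function()
  build_network(toy_build_config(n_neurons = 120), seed = 11,
                calibrate_background = FALSE))

## mid-size calibrated network for dynamics / training / analysis tests;
## spontaneous targets sit well above the 2 Hz quantile-Huber knee so rate
## matching during training is resolvable
net_mid <- function() fixture("net_mid", function()
  make_toy_network(300, seed = 7,
                   spont_rates = c(L4_Exc = 6, PV = 12, SST = 6, VIP = 6)))

targets_mid <- function() fixture("targets_mid", function()
  make_targets(unique(net_mid()$neurons$type), seed = 5))

## reference-measured targets of the calibrated network (training oracle)
targets_reference <- function() fixture("targets_reference", function()
  measure_reference_targets(net_mid(), seed = 21, n_trials = 5))

## mildly over-excited copy: the starting point of the recovery experiment
net_perturbed <- function() fixture("net_perturbed", function() {
  net <- net_mid()
  exc_src <- net$neurons$type[net$edges_rec$src] == "L4_Exc"
  net$edges_rec$weight[exc_src] <- net$edges_rec$weight[exc_src] * 1.08
  net$edges_bkg$weight <- net$edges_bkg$weight * 1.15
  net
})

## single-neuron network built by hand (bypasses placement randomness):
## one neuron, one LGN source, one background source, chosen kinetics.
one_neuron_net <- function(glif = glif_param_set(-70, -50, 0.2, 20,
                                                 c(0, 0), c(0.1, 0.1), 4),
                           kin = list(tau_f = 1.5, tau_s = 6, lam = 0.4),
                           w_lgn = 0, w_bkg = 0, w_rec = 0) {
  cfg <- toy_build_config(n_neurons = 300)
  cfg$glif_pool <- list(glif)
  cfg$lgn$kinetics <- kin
  fams <- build_family_kinetics(cfg)
  fam_ext <- fams$family[fams$src_eff == "ExtExc" & fams$dst_eff == "L4_Exc"]
  fam_ee <- fams$family[fams$src_eff == "L4_Exc" & fams$dst_eff == "L4_Exc"]
  neurons <- data.frame(id = 1L, type = "L4_Exc", x = 0, y = 400, z = 0,
                        tuning_angle = 0, indegree_target = 100,
                        model_id = 1L, core = TRUE)
  edge <- function(src, w, delay, fam)
    data.frame(src = src, dst = 1L, weight = w, delay = delay, family = fam)
  structure(list(
    neurons = neurons,
    edges_rec = if (w_rec != 0) edge(1L, w_rec, 1L, fam_ee) else
      edge(1L, 0, 1L, fam_ee)[0, ],
    edges_lgn = edge(1L, w_lgn, 1L, fam_ext),
    edges_bkg = edge(1L, w_bkg, 1L, fam_ext),
    lgn_units = data.frame(id = 1L, x_deg = 24, y_deg = 16,
                           subtype = "sustained_on", rf_sigma = 2,
                           gain = 50, baseline = 4),
    glif = glif_vectors(list(glif), 1L),
    family_kinetics = fams,
    config = cfg
  ), class = "column_network")
}

## deliver a deterministic input spike train through the single LGN source
run_one_neuron <- function(net, lgn_train, T_steps, w_scale = 1, ...) {
  lgn <- matrix(0L, 1, T_steps)
  lgn[1, which(lgn_train > 0)] <- 1L
  bkg <- matrix(0L, net$config$background$n_units, T_steps)
  run_network(net, lgn, bkg, T_steps, ...)
}
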