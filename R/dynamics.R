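#' Normalize a network for simulation
#'
#' Voltages and synaptic weights are expressed in threshold-distance units:
#' with `dV_j = V_th_j - E_L_j`, the normalized voltage is
#' `(V - E_L) / dV` (reset at 0, threshold at 1) and every weight and current
#' targeting neuron `j` is divided by `dV_j`.  After-spike current increments
#' are normalized the same way.
#'
#' @param network a `column_network` from [build_network()].
#' @return a list of per-neuron simulation parameter vectors (`alpha`, `rm`,
#'   ASC decays/increments, refractory steps, `dV`) and per-table normalized
#'   weight vectors `w_rec`, `w_bkg`, `w_lgn`.
#' @export
normalize_network <- function(network) {
  g <- network$glif
  dV <- g$V_th - g$E_L
  if (any(dV <= 0)) stop("normalize_network: V_th must exceed E_L for all neurons")
  norm_w <- function(edges) {
    if (!nrow(edges)) return(numeric(0))
    edges$weight / dV[edges$dst]
  }
  list(
    alpha = exp(-1 / g$tau_m),
    rm = g$R_m,
    asc_b1 = exp(-g$asc_k1), asc_b2 = exp(-g$asc_k2),
    asc_a1 = g$asc_amp1 / dV, asc_a2 = g$asc_amp2 / dV,
    tref = pmax(1L, as.integer(round(g$tau_ref))),
    dV = dV,
    w_rec = norm_w(network$edges_rec),
    w_bkg = norm_w(network$edges_bkg),
    w_lgn = norm_w(network$edges_lgn)
  )
}

#' De-normalize weights back to current units
#'
#' Algebraic inverse of the weight normalization in [normalize_network()].
#'
#' @param w_norm normalized weights.
#' @param dst postsynaptic neuron indices.
#' @param dV per-neuron threshold distances, mV.
#' @return weights in pA-scale units.
#' @export
denormalize_weights <- function(w_norm, dst, dV) {
  w_norm * dV[dst]
}

#' One forward-Euler GLIF3 step in normalized coordinates
#'
#' Reference single step of the membrane/ASC/refractory dynamics: the spike
#' indicator uses the pre-update voltage (`S = 1` iff the refractory counter
#' is 0 and `v >= 1`), the soft reset subtracts 1 within the same update, ASC
#' increments apply at the spike step while the exponential decays run every
#' step, and the refractory counter reloads to `tau_ref` steps on a spike.
#' The membrane keeps integrating during the refractory window; only spike
#' emission is disabled.
#'
#' @param state list with `v`, `a1`, `a2`, `refrac`.
#' @param i_syn normalized synaptic current per neuron (excluding ASCs).
#' @param pars normalized parameters from [normalize_network()].
#' @return list with the next `state` and the 0/1 `spikes` vector emitted at
#'   this step.
#' @export
glif3_step <- function(state, i_syn, pars) {
  if (any(!is.finite(i_syn))) stop("glif3_step: non-finite input current")
  S <- as.numeric(state$refrac == 0 & state$v >= 1)
  i_tot <- i_syn + state$a1 + state$a2
  v_new <- pars$alpha * state$v + (1 - pars$alpha) * pars$rm * i_tot - S
  list(
    state = list(
      v = v_new,
      a1 = pars$asc_b1 * state$a1 + S * pars$asc_a1,
      a2 = pars$asc_b2 * state$a2 + S * pars$asc_a2,
      refrac = ifelse(S == 1, pars$tref, pmax(state$refrac - 1L, 0L))
    ),
    spikes = S
  )
}

## Compile a network into the channel-expanded synapse arrays consumed by the
## C++ simulator.  mode "family" keeps one fast + one slow alpha channel per
## receptor family present; mode "basis" projects every family onto a shared
## alpha basis (see fit_alpha_basis), shrinking the per-neuron PSC state count
## to 2 * n_basis.
#' @export
compile_simnet <- function(network, mode = c("family", "basis"), basis = NULL) {
  mode <- match.arg(mode)
  pars <- normalize_network(network)
  N <- nrow(network$neurons)
  fam <- network$family_kinetics
  edges <- rbind(
    network$edges_rec[, c("src", "dst", "delay", "family")],
    network$edges_bkg[, c("src", "dst", "delay", "family")],
    network$edges_lgn[, c("src", "dst", "delay", "family")]
  )
  n_rec <- nrow(network$edges_rec)
  n_bkg <- nrow(network$edges_bkg)
  n_lgn <- nrow(network$edges_lgn)
  n_in_lgn <- nrow(network$lgn_units)
  n_in_bkg <- network$config$background$n_units
  ## stacked source index: recurrent neurons, then LGN units, then BKG units
  src0 <- c(network$edges_rec$src - 1L,
            if (n_bkg) N + n_in_lgn + network$edges_bkg$src - 1L else integer(0),
            if (n_lgn) N + network$edges_lgn$src - 1L else integer(0))
  w <- c(pars$w_rec, pars$w_bkg, pars$w_lgn)
  n_parent <- length(w)
  fidx <- match(edges$family, fam$family)
  if (anyNA(fidx)) stop("compile_simnet: edge with unknown receptor family")

  if (mode == "family") {
    fams_present <- sort(unique(fidx))
    kin <- fam[fams_present, ]
    chan_tau <- c(kin$tau_f, kin$tau_s)
    fast_chan <- match(fidx, fams_present)
    slow_chan <- fast_chan + length(fams_present)
    esrc <- c(src0, src0)
    edst <- c(edges$dst - 1L, edges$dst - 1L)
    edelay <- c(edges$delay, edges$delay)
    echan <- c(fast_chan, slow_chan) - 1L
    eparent <- c(seq_len(n_parent), seq_len(n_parent)) - 1L
    ecoef <- c(rep(1, n_parent), kin$lam[fast_chan])
  } else {
    ## fit the shared basis on the families that carry kinetics (rows for
    ## pairings never wired, e.g. onto the external class, stay NA)
    kin_ok <- which(!is.na(fam$tau_f))
    if (is.null(basis)) {
      kernels <- lapply(kin_ok, function(i)
        list(A = 1, tau_f = fam$tau_f[i], tau_s = fam$tau_s[i], lam = fam$lam[i]))
      basis <- fit_alpha_basis(kernels, n_basis = 4L)
    }
    nb <- length(basis$taus)
    chan_tau <- basis$taus
    esrc <- rep(src0, nb)
    edst <- rep(edges$dst - 1L, nb)
    edelay <- rep(edges$delay, nb)
    echan <- rep(seq_len(nb), each = n_parent) - 1L
    eparent <- rep(seq_len(n_parent), nb) - 1L
    frow <- match(fidx, kin_ok)
    if (anyNA(frow)) stop("compile_simnet: edge family without kinetics")
    ecoef <- as.numeric(basis$coeffs[frow, ])
  }
  keep <- ecoef != 0
  structure(list(
    N = N, pars = pars,
    chan_tau = chan_tau,
    chan_decay = exp(-1 / chan_tau),
    chan_inject = exp(1) / chan_tau,
    esrc = esrc[keep], edst = edst[keep],
    edelay = as.integer(edelay[keep]), echan = echan[keep],
    eparent = eparent[keep], ecoef = ecoef[keep],
    w = w, n_parent = n_parent,
    idx_rec = seq_len(n_rec),
    idx_bkg = if (n_bkg) n_rec + seq_len(n_bkg) else integer(0),
    idx_lgn = if (n_lgn) n_rec + n_bkg + seq_len(n_lgn) else integer(0),
    n_in_lgn = n_in_lgn, n_in_bkg = n_in_bkg,
    d_max = max(c(edges$delay, 1L)),
    mode = mode, basis = basis
  ), class = "simnet")
}

#' Zero (resting) network state
#'
#' @param compiled a compiled simulator network from [compile_simnet()].
#' @return state list with all dynamical variables at rest.
#' @export
zero_state <- function(compiled) {
  N <- compiled$N
  K <- length(compiled$chan_tau)
  list(v = numeric(N), a1 = numeric(N), a2 = numeric(N),
       I = matrix(0, N, K), C = matrix(0, N, K),
       refrac = integer(N),
       s_pre = matrix(0L, N, compiled$d_max),
       input_pre = matrix(0L, compiled$n_in_lgn + compiled$n_in_bkg,
                          compiled$d_max))
}

#' Run a network forward for T steps
#'
#' Deterministic given its inputs: all randomness lives in the provided input
#' spike matrices.  Input spikes and the recurrent spike prehistory carried in
#' `init` let consecutive chunks chain exactly.
#'
#' @param network a `column_network`.
#' @param lgn_spikes LGN input spikes, units x T 0/1 matrix.
#' @param bkg_spikes background input spikes, units x T 0/1 matrix.
#' @param T_steps chunk length in 1 ms steps.
#' @param init initial state (default [zero_state()]).
#' @param record_v record the per-step pre-update normalized voltages.
#' @param i_ext_pA optional neurons x T external current injection, pA
#'   (used by silencing perturbations).
#' @param compiled optional pre-compiled simulator network (rebuilt otherwise).
#' @return list with `spikes` (neurons x T 0/1), `v_trace` (if recorded),
#'   `state` (final state for chaining), and `S_all` (internal stacked spike
#'   buffer, used by the reverse pass).
#' @export
run_network <- function(network, lgn_spikes, bkg_spikes, T_steps,
                        init = NULL, record_v = FALSE, i_ext_pA = NULL,
                        compiled = NULL) {
  cs <- if (is.null(compiled)) compile_simnet(network) else compiled
  if (cs$N == 0L)
    return(list(spikes = matrix(0L, 0, T_steps), v_trace = NULL, state = NULL))
  if (is.null(init)) init <- zero_state(cs)
  if (ncol(lgn_spikes) != T_steps || ncol(bkg_spikes) != T_steps)
    stop("run_network: input spike matrices must have T columns")
  if (nrow(lgn_spikes) != cs$n_in_lgn || nrow(bkg_spikes) != cs$n_in_bkg)
    stop("run_network: input spike matrices have wrong unit counts")
  ## delayed arrivals from the previous chunk's inputs are carried in the
  ## state's input prehistory
  input_pre <- init$input_pre
  if (is.null(input_pre))
    input_pre <- matrix(0L, cs$n_in_lgn + cs$n_in_bkg, cs$d_max)
  s_input <- cbind(input_pre, rbind(lgn_spikes, bkg_spikes))
  storage.mode(s_input) <- "integer"
  i_ext <- if (is.null(i_ext_pA)) matrix(0, 0, 0) else i_ext_pA / cs$pars$dV
  out <- sim_forward_cpp(cs$N, cs$pars$alpha, cs$pars$rm,
                         cs$pars$asc_b1, cs$pars$asc_b2,
                         cs$pars$asc_a1, cs$pars$asc_a2, cs$pars$tref,
                         cs$chan_decay, cs$chan_inject,
                         cs$esrc, cs$edst, cs$edelay, cs$echan,
                         cs$eparent, cs$ecoef, cs$w,
                         s_input, as.integer(T_steps), cs$d_max,
                         i_ext,
                         init$v, init$a1, init$a2, init$I, init$C,
                         as.integer(init$refrac), init$s_pre,
                         record_v)
  out$state$input_pre <- s_input[, T_steps + seq_len(cs$d_max), drop = FALSE]
  out$compiled <- cs
  out$init_refrac <- as.integer(init$refrac)
  out
}

#' Convert a spike matrix to columnar (node_id, t_ms) form
#'
#' @param spikes neurons x T 0/1 matrix.
#' @return data.frame with `node_id` (1-based) and `t_ms`.
#' @export
spikes_to_df <- function(spikes) {
  idx <- which(spikes > 0, arr.ind = TRUE)
  data.frame(node_id = idx[, 1], t_ms = idx[, 2])[order(idx[, 2], idx[, 1]), ]
}

#' Poisson input spike trains via per-bin Bernoulli sampling
#'
#' @param n_units number of units.
#' @param rate rate in Hz (scalar or per-unit).
#' @param T_steps number of 1 ms bins.
#' @return units x T 0/1 integer matrix.
#' @export
poisson_spikes <- function(n_units, rate, T_steps) {
  p <- 1 - exp(-rate / 1000)
  m <- matrix(rbinom(n_units * T_steps, 1L, p), n_units, T_steps)
  m
}
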