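#' Generate the LGN unit mosaic
#'
#' Units are scattered uniformly over the visual field and assigned one of
#' three functional subtypes (sustained-ON, sustained-OFF, transient-OFF) by
#' the configured fractions.  Each unit carries a difference-of-Gaussians
#' receptive field and subtype-specific temporal kinetics used by the
#' parametric surrogate rate model ([surrogate_lgn_rates()]).
#'
#' @param config a [build_config()] (uses the `lgn` block).
#' @param seed integer seed.
#' @param n_units override for the unit count (defaults to the config value).
#' @return data.frame with `id`, `x_deg`, `y_deg`, `subtype`, `rf_sigma`,
#'   `gain`, `baseline`.
#' @export
make_lgn_units <- function(config, seed, n_units = NULL) {
  set.seed(seed)
  lg <- config$lgn
  n <- if (is.null(n_units)) lg$n_units else n_units
  fr <- lg$subtype_fractions
  subtype <- sample(names(fr), n, replace = TRUE, prob = fr)
  data.frame(
    id = seq_len(n),
    x_deg = runif(n, 0, lg$field[1]),
    y_deg = runif(n, 0, lg$field[2]),
    subtype = subtype,
    rf_sigma = runif(n, 1.5, 3),
    gain = runif(n, 40, 80),
    baseline = runif(n, 2, 6),
    stringsAsFactors = FALSE
  )
}

## Retinotopic position of each V1 neuron in visual degrees: the column's
## lateral plane maps linearly onto the field centre.
neuron_rf_positions <- function(neurons, config) {
  lg <- config$lgn
  scale <- if (is.null(lg$deg_per_um)) 1 / 70 else lg$deg_per_um
  cbind(x = lg$field[1] / 2 + neurons$x * scale,
        y = lg$field[2] / 2 + neurons$z * scale)
}

#' Wire thalamocortical (LGN) input
#'
#' For each target neuron the LGN synapse budget is the configured fraction
#' of its target in-degree.  The number of distinct connections follows from
#' the Yule-Simon synapse-count model: `N_conn = N_syn * (rho - 1) / rho`
#' (the reciprocal of the Yule-Simon mean), and per-connection synapse counts
#' are drawn from Yule-Simon(rho).  Source units are chosen (without
#' replacement per target) with receptive-field-proximity weighting of width
#' `sigma_lgn / n_syn`, so connections with more synapses come from more
#' precisely aligned sources.  Direction selectivity by convergence:
#' transient units are drawn toward a point offset from the target's
#' receptive field along its preferred direction, sustained units toward the
#' opposite offset.  Connection weight is proportional to its synapse count;
#' all LGN edges use the fixed configured delay (1.7 ms, rounded to 2 steps).
#'
#' @param neurons a `NeuronTable`.
#' @param lgn_units from [make_lgn_units()].
#' @param config a [build_config()].
#' @param seed integer seed.
#' @param unitary optional unitary-PSP table (models x families).
#' @return a `ConnectionTable` data.frame (src = LGN unit id) with an
#'   `n_syn` column recording the per-connection synapse count.
#' @export
wire_lgn <- function(neurons, lgn_units, config, seed, unitary = NULL) {
  set.seed(seed)
  lg <- config$lgn
  fams <- build_family_kinetics(config)
  if (is.null(unitary)) unitary <- unitary_psp_table(config, fams)
  rf <- neuron_rf_positions(neurons, config)
  off <- if (is.null(lg$convergence_offset)) 3 else lg$convergence_offset
  transient <- lgn_units$subtype == "transient_off"
  out <- vector("list", nrow(neurons))
  for (i in seq_len(nrow(neurons))) {
    ct <- config$cell_types[[neurons$type[i]]]
    rho <- ct$lgn_rho
    if (rho <= 1) stop("wire_lgn: lgn_rho must exceed 1 for type ", ct$name)
    n_syn_tot <- round(ct$lgn_fraction * neurons$indegree_target[i])
    n_conn <- round(n_syn_tot * (rho - 1) / rho)
    if (n_conn < 1) next
    n_conn <- min(n_conn, nrow(lgn_units))
    counts <- yule_simon_sample(n_conn, rho)
    th <- neurons$tuning_angle[i] * pi / 180
    ## subtype-dependent target point implements convergence-based DS
    cx <- rf[i, 1] + ifelse(transient, 1, -1) * off / 2 * cos(th)
    cy <- rf[i, 2] + ifelse(transient, 1, -1) * off / 2 * sin(th)
    d2 <- (lgn_units$x_deg - cx)^2 + (lgn_units$y_deg - cy)^2
    chosen <- integer(n_conn)
    avail <- rep(TRUE, nrow(lgn_units))
    for (k in order(counts, decreasing = TRUE)) {
      pw <- exp(-d2 / (2 * (lg$sigma_lgn / counts[k])^2)) * avail
      if (sum(pw) <= 0) pw <- as.numeric(avail)
      u <- sample.int(nrow(lgn_units), 1L, prob = pw)
      chosen[k] <- u
      avail[u] <- FALSE
    }
    eff <- effective_of(config, neurons$type[i])
    fam_id <- family_id(fams, "ExtExc", eff)
    w <- counts * lg$psp_per_synapse /
      unitary[neurons$model_id[i], fam_id]
    out[[i]] <- data.frame(src = chosen, dst = neurons$id[i], weight = w,
                           delay = max(1L, as.integer(round(lg$delay))),
                           family = fam_id, n_syn = counts)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(src = integer(0), dst = integer(0), weight = numeric(0),
               delay = integer(0), family = integer(0), n_syn = integer(0))
  rownames(edges) <- NULL
  edges
}
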