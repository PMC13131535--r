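#' Cell type specification
#'
#' Describes one model cell type: its class (excitatory or inhibitory, which
#' fixes the sign of all outgoing synapses under Dale's law), transcriptomic
#' subclass (used to aggregate inhibitory types across layers into effective
#' receptor-family classes), volumetric density, laminar depth range, the
#' log-normal distribution of target in-degrees (total dendritic input synapse
#' count), and the pool of GLIF3 point-model ids the type draws from.
#'
#' @param name type label, e.g. `"L4_Exc"`.
#' @param class `"excitatory"` or `"inhibitory"`.
#' @param subclass effective class label; defaults to `name` for excitatory
#'   types and must be one of `"PV"`, `"SST"`, `"VIP"`, `"L1_Inh"` for
#'   inhibitory types.
#' @param layer cortical layer label.
#' @param density neurons per mm^3 (> 0).
#' @param depth_range depth interval in micrometres, `c(lo, hi)` with lo < hi.
#' @param indegree_lognormal `list(sdlog =, scale =)`: the in-degree
#'   distribution is LogNormal with `meanlog = log(scale)` and `sdlog` shape.
#' @param glif_pool integer indices into the build's GLIF parameter pool.
#' @param lgn_fraction fraction of the target in-degree supplied by LGN
#'   synapses (e.g. 0.2 for L4 excitatory neurons).
#' @param lgn_rho Yule-Simon shape for per-connection LGN synapse counts
#'   (must exceed 1 for the connection-count formula to be defined).
#' @return an object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, class, layer, density, depth_range,
                           indegree_lognormal, glif_pool,
                           subclass = NULL, lgn_fraction = 0.1, lgn_rho = 2.2) {
  class <- match.arg(class, c("excitatory", "inhibitory"))
  if (is.null(subclass)) {
    if (class == "inhibitory")
      stop("cell_type_spec: inhibitory types need an explicit subclass (PV/SST/VIP/L1_Inh)")
    subclass <- name
  }
  if (class == "inhibitory" && !subclass %in% c("PV", "SST", "VIP", "L1_Inh"))
    stop("cell_type_spec: inhibitory subclass must be PV, SST, VIP or L1_Inh")
  if (!is.numeric(density) || density < 0)
    stop("cell_type_spec: density must be >= 0")
  if (length(depth_range) != 2L || diff(depth_range) <= 0)
    stop("cell_type_spec: depth_range must be a non-empty interval")
  if (indegree_lognormal$sdlog < 0 || indegree_lognormal$scale <= 0)
    stop("cell_type_spec: invalid in-degree log-normal parameters")
  structure(list(
    name = name, class = class, subclass = subclass, layer = layer,
    density = as.numeric(density), depth_range = as.numeric(depth_range),
    indegree_lognormal = indegree_lognormal,
    glif_pool = as.integer(glif_pool),
    lgn_fraction = lgn_fraction, lgn_rho = lgn_rho
  ), class = "cell_type_spec")
}

#' Connection class specification
#'
#' Parameters of one directed presynaptic-type to postsynaptic-type connection
#' class: peak probability and Gaussian spatial spread of the
#' distance-dependent wiring rule, optional like-to-like strength `beta`
#' (excitatory-to-excitatory only), the log-normal PSP amplitude distribution
#' (in log-mV), the double-alpha kinetic parameters of the receptor family the
#' class maps to, and the axonal delay.
#'
#' @param src_type,dst_type cell type labels.
#' @param p_max peak connection probability at zero lateral separation.
#' @param sigma Gaussian spatial spread, micrometres.
#' @param psp_lognormal `list(meanlog =, sdlog =)` of PSP amplitudes (mV).
#' @param kinetics `list(tau_f =, tau_s =, lambda =)`, ms / ms /
#'   dimensionless slow-to-fast amplitude ratio; requires `tau_f < tau_s`.
#' @param delay axonal delay in ms (rounded to integer steps at wiring time).
#' @param beta like-to-like strength in (0, 1]; `NULL` disables the rule.
#' @return an object of class `connection_class_spec`.
#' @export
connection_class_spec <- function(src_type, dst_type, p_max, sigma,
                                  psp_lognormal, kinetics, delay, beta = NULL) {
  if (p_max < 0 || p_max > 1) stop("connection_class_spec: p_max must be in [0, 1]")
  if (sigma <= 0) stop("connection_class_spec: sigma must be > 0")
  if (!is.null(beta) && (beta <= 0 || beta > 1))
    stop("connection_class_spec: beta must be in (0, 1]")
  if (kinetics$tau_f >= kinetics$tau_s)
    stop("connection_class_spec: requires tau_f < tau_s")
  if (psp_lognormal$sdlog < 0)
    stop("connection_class_spec: psp sdlog must be >= 0")
  structure(list(
    src_type = src_type, dst_type = dst_type, p_max = p_max, sigma = sigma,
    beta = beta, psp_lognormal = psp_lognormal, kinetics = kinetics,
    delay = delay
  ), class = "connection_class_spec")
}

#' Assemble a network build configuration
#'
#' @param cell_types list of [cell_type_spec()] objects.
#' @param connections list of [connection_class_spec()] objects.
#' @param glif_pool list of [glif_param_set()] objects; `glif_pool` indices in
#'   the cell types refer to positions in this list.
#' @param column_radius,core_radius cylinder radii in micrometres.  The core
#'   (default 200) is the high-fidelity readout region; the full column
#'   (default 400) adds a peripheral context shell.
#' @param displacement centroid displacement `dR` of the orientation-dependent
#'   wiring rule, micrometres.
#' @param kappa anisotropy ratio of the excitatory wiring covariance.
#' @param displacement_region_factor the displacement applies only within this
#'   multiple of the core radius from the column centre.
#' @param background background-drive settings: number of Poisson units, their
#'   rate (Hz), fan-in per neuron and delay (ms).
#' @param lgn LGN settings: number of units, visual field size (deg), subtype
#'   fractions, receptive-field scatter, proximity kernel width
#'   `sigma_lgn` (deg), per-synapse PSP (mV), convergence offset (deg) and
#'   fixed delay (ms).
#' @return an object of class `build_config`.
#' @export
build_config <- function(cell_types, connections, glif_pool,
                         column_radius = 400, core_radius = 200,
                         displacement = 50, kappa = 1.5,
                         displacement_region_factor = 1.5,
                         background = list(n_units = 100L, rate = 250,
                                           n_per_neuron = 4L, delay = 1),
                         lgn = list(n_units = 17400L,
                                    field = c(120, 80),
                                    subtype_fractions = c(sustained_on = 0.4,
                                                          sustained_off = 0.4,
                                                          transient_off = 0.2),
                                    sigma_lgn = 5,
                                    psp_per_synapse = 0.3,
                                    convergence_offset = 3,
                                    delay = 1.7)) {
  stopifnot(column_radius > 0, core_radius > 0)
  names(cell_types) <- vapply(cell_types, `[[`, "", "name")
  structure(list(
    cell_types = cell_types, connections = connections, glif_pool = glif_pool,
    column_radius = column_radius, core_radius = core_radius,
    displacement = displacement, kappa = kappa,
    displacement_region_factor = displacement_region_factor,
    background = background, lgn = lgn
  ), class = "build_config")
}

type_class <- function(config, type) config$cell_types[[type]]$class

#' Effective cell types and receptor families
#'
#' Synaptic kinetics were characterized with inhibitory types aggregated
#' across layers, so a model with the full 19-type composition (6 layer
#' specific excitatory types, PV/SST/VIP in four layers each, and L1
#' interneurons) collapses to 10 effective intracortical classes; together
#' with the generic excitatory class used for LGN and background afferents
#' this gives 11 effective types and 11 x 11 = 121 directed receptor
#' families.
#'
#' @param cell_types list of [cell_type_spec()] objects.
#' @return `effective_types()`: character vector of effective labels
#'   (external excitatory class last); `receptor_families()`: data.frame with
#'   columns `family` (integer id), `src_eff`, `dst_eff`.
#' @export
effective_types <- function(cell_types) {
  eff <- vapply(cell_types, function(ct)
    if (ct$class == "excitatory") ct$name else ct$subclass, "")
  c(unique(unname(eff)), "ExtExc")
}

#' @rdname effective_types
#' @export
receptor_families <- function(cell_types) {
  eff <- effective_types(cell_types)
  grid <- expand.grid(src_eff = eff, dst_eff = eff,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(family = seq_len(nrow(grid)), grid, stringsAsFactors = FALSE)
}

effective_of <- function(config, type) {
  ct <- config$cell_types[[type]]
  if (ct$class == "excitatory") ct$name else ct$subclass
}

family_id <- function(families, src_eff, dst_eff) {
  id <- families$family[families$src_eff == src_eff & families$dst_eff == dst_eff]
  if (length(id) != 1L) stop("family_id: unknown family ", src_eff, " -> ", dst_eff)
  id
}
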