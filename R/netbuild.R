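#' Place neurons in the cylindrical column
#'
#' Each cell type contributes `round(density * layer volume)` neurons with
#' positions uniform over the column cross-section (lateral plane is (x, z);
#' depth is y), depth uniform within the type's laminar range, tuning angles
#' uniform on [0, 360) degrees, target in-degrees drawn from the type's
#' log-normal, and point-model ids drawn uniformly from the type's GLIF pool.
#'
#' @param config a [build_config()].
#' @param seed integer seed.
#' @return a `NeuronTable` data.frame with columns `id`, `type`, `x`, `y`,
#'   `z`, `tuning_angle`, `indegree_target`, `model_id`, `core`.
#' @export
place_neurons <- function(config, seed) {
  set.seed(seed)
  R <- config$column_radius
  rows <- lapply(config$cell_types, function(ct) {
    if (ct$density < 0) stop("place_neurons: negative density for ", ct$name)
    vol_mm3 <- pi * (R / 1000)^2 * diff(ct$depth_range) / 1000
    n <- round(ct$density * vol_mm3)
    if (n == 0L) {
      warning("place_neurons: zero neurons for type ", ct$name)
      return(NULL)
    }
    rr <- R * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    data.frame(
      type = ct$name,
      x = rr * cos(th),
      y = runif(n, ct$depth_range[1], ct$depth_range[2]),
      z = rr * sin(th),
      tuning_angle = runif(n, 0, 360),
      indegree_target = pmax(1, round(rlnorm(n, log(ct$indegree_lognormal$scale),
                                             ct$indegree_lognormal$sdlog))),
      model_id = sample(ct$glif_pool, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$id <- seq_len(nrow(out))
  out$core <- sqrt(out$x^2 + out$z^2) <= config$core_radius
  out[, c("id", "type", "x", "y", "z", "tuning_angle",
          "indegree_target", "model_id", "core")]
}

#' Orientation-dependent bivariate-normal connection probability
#'
#' Baseline probability `p_max * exp(-q/2)` where `q` is the Mahalanobis
#' distance of the lateral displacement from an orientation-dependent
#' centroid.  Inhibitory presynaptic ensembles are displaced by `dR` along
#' the target's preferred orientation with isotropic spread; excitatory
#' ensembles are displaced by `dR` in the opposite direction with anisotropic
#' spread (`sigma/kappa` along the orientation, `sigma*kappa` across it).
#' Outside the displacement region the centroid is zero and the profile is a
#' centred isotropic Gaussian.
#'
#' @param delta_r n x 2 matrix of lateral displacements `r_pre - r_post` in
#'   the (x, z) plane, micrometres.
#' @param theta target tuning angle(s), degrees.
#' @param p_max,sigma peak probability and spread of the class.
#' @param src_class `"excitatory"` or `"inhibitory"`.
#' @param in_displacement_region logical vector: target within
#'   1.5 x core radius of the column centre.
#' @param dR centroid displacement, micrometres.
#' @param kappa excitatory anisotropy ratio.
#' @return probability vector.
#' @export
connection_probability <- function(delta_r, theta, p_max, sigma, src_class,
                                   in_displacement_region, dR = 50, kappa = 1.5) {
  if (sigma <= 0) stop("connection_probability: sigma must be > 0")
  src_class <- match.arg(src_class, c("excitatory", "inhibitory"))
  delta_r <- rbind(delta_r)  # tolerate a single 2-vector
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  sgn <- if (src_class == "inhibitory") 1 else -1
  mux <- ifelse(in_displacement_region, sgn * dR * ct, 0)
  muz <- ifelse(in_displacement_region, sgn * dR * st, 0)
  dx <- delta_r[, 1] - mux
  dz <- delta_r[, 2] - muz
  if (src_class == "inhibitory") {
    q <- (dx^2 + dz^2) / sigma^2
  } else {
    ## rotate into the orientation frame; anisotropy only inside the region
    u1 <- dx * ct + dz * st
    u2 <- -dx * st + dz * ct
    s1 <- ifelse(in_displacement_region, sigma / kappa, sigma)
    s2 <- ifelse(in_displacement_region, sigma * kappa, sigma)
    q <- (u1 / s1)^2 + (u2 / s2)^2
  }
  p_max * exp(-q / 2)
}

#' Like-to-like probability modulation for excitatory pairs
#'
#' Multiplies the connection probability of excitatory-to-excitatory pairs by
#' `(2 / (1 + beta)) * (1 - (1 - beta) * dphi / 90)`, where `dphi` is the
#' pre/post orientation-preference difference folded to [0, 90] degrees.  The
#' factor averages to exactly 1 over uniformly distributed differences, so
#' the class's peak probability is preserved.
#'
#' @param delta_phi orientation differences, degrees (folded internally).
#' @param beta like-to-like strength in (0, 1]; `beta = 1` disables the
#'   modulation.
#' @return multiplier vector.
#' @export
like_to_like_factor <- function(delta_phi, beta) {
  if (beta <= 0 || beta > 1) stop("like_to_like_factor: beta must be in (0, 1]")
  d <- abs(delta_phi) %% 180
  d <- pmin(d, 180 - d)
  (2 / (1 + beta)) * (1 - (1 - beta) * d / 90)
}

#' In-degree (target-size) probability modulation
#'
#' Scales connection probability by the target neuron's in-degree relative to
#' its type's population mean, so larger dendritic arbors receive
#' proportionally more connections.
#'
#' @param n_target target in-degree(s).
#' @param n_mean population mean in-degree of the target type.
#' @return multiplier vector.
#' @export
indegree_factor <- function(n_target, n_mean) {
  if (any(n_mean <= 0) || any(n_target <= 0))
    stop("indegree_factor: inputs must be positive")
  n_target / n_mean
}

#' Sample per-connection synaptic weights by the log-normal quotient rule
#'
#' In-degree heterogeneity is compensated by drawing per-connection weights
#' from `LogNormal(mu_W, sigma_W)` with
#' `sigma_W = sqrt(sigma_PSP^2 - sigma_N^2)` and
#' `mu_W = mu_PSP + mu_N - log(n_mean)`, then scaling each draw by
#' `n_mean / n_target`.  Because in-degree and weight draws are independent,
#' the population quotient is again log-normal with exactly the experimental
#' PSP parameters.  When `sigma_PSP <= sigma_N` the weight spread collapses
#' onto a small positive floor.  Weights are converted from mV to simulator
#' current units by dividing by the unitary PSP of the target cell model.
#'
#' @param psp_lognormal `list(meanlog, sdlog)` of the PSP distribution (mV).
#' @param indegree_lognormal `list(sdlog, scale)` of the target type's
#'   in-degree distribution (`meanlog = log(scale)`).
#' @param n_mean population-mean in-degree of the target type.
#' @param n_target per-edge target in-degrees (vector; one draw per entry).
#' @param unitary_psp per-edge unitary PSP amplitudes, mV per unit weight.
#' @param sigma_floor log-space floor used when `sigma_PSP <= sigma_N`.
#' @return positive weights in simulator (pA-scale) units, one per edge.
#' @export
sample_connection_weight <- function(psp_lognormal, indegree_lognormal,
                                     n_mean, n_target, unitary_psp,
                                     sigma_floor = 0.01) {
  if (any(unitary_psp <= 0)) stop("sample_connection_weight: unitary_psp must be > 0")
  s_psp <- psp_lognormal$sdlog
  s_n <- indegree_lognormal$sdlog
  if (s_psp < 0 || s_n < 0) stop("sample_connection_weight: sdlog must be >= 0")
  sigma_w <- if (s_psp > s_n) sqrt(s_psp^2 - s_n^2) else sigma_floor
  mu_n <- log(indegree_lognormal$scale)
  mu_w <- psp_lognormal$meanlog + mu_n - log(n_mean)
  n <- length(n_target)
  W <- rlnorm(n, mu_w, sigma_w)
  (W * n_mean / n_target) / unitary_psp
}

#' Unitary PSP calibration of a cell model
#'
#' Simulates the model in isolation at rest, delivers a single presynaptic
#' spike at unit weight through the given receptor-family kernel, and returns
#' the peak membrane deflection from rest in mV.  The desired PSP amplitude
#' divided by this unitary value is the simulator weight.  If the deflection
#' reaches threshold the calibration is rejected.
#'
#' @param glif a [glif_param_set()].
#' @param kinetics `list(tau_f, tau_s, lam)` of the receptor family.
#' @param T_steps simulation horizon, ms.
#' @return unitary PSP amplitude, mV (positive).
#' @export
calibrate_unitary_psp <- function(glif, kinetics, T_steps = 200L) {
  a <- exp(-1 / glif$tau_m)
  taus <- c(kinetics$tau_f, kinetics$tau_s)
  st <- list(I = c(0, 0), C = c(0, 0))
  events <- c(1, kinetics$lam)
  V <- 0   # deflection from rest, mV
  peak <- 0
  for (n in seq_len(T_steps)) {
    i_syn <- sum(st$I)
    V <- a * V + (1 - a) * glif$R_m * i_syn
    if (V + glif$E_L >= glif$V_th)
      stop("calibrate_unitary_psp: unit-weight spike reached threshold (deflection ",
           sprintf("%.2f", V), " mV)")
    peak <- max(peak, V)
    st <- psc_step(st$I, st$C, taus, if (n == 1L) events else c(0, 0))
  }
  if (peak <= 0) stop("calibrate_unitary_psp: no deflection recorded")
  peak
}

## Cache of unitary PSPs per (cell model, receptor family kinetics).
unitary_psp_table <- function(config, family_kinetics) {
  pool <- config$glif_pool
  tab <- matrix(NA_real_, length(pool), nrow(family_kinetics))
  for (m in seq_along(pool)) {
    for (f in which(!is.na(family_kinetics$tau_f))) {
      kin <- list(tau_f = family_kinetics$tau_f[f],
                  tau_s = family_kinetics$tau_s[f],
                  lam = family_kinetics$lam[f])
      tab[m, f] <- calibrate_unitary_psp(pool[[m]], kin)
    }
  }
  tab
}

## Assemble the family kinetics table for a config: one row per directed
## effective-type pair with the kinetics of the connection class that maps to
## it; LGN and background afferents use the external excitatory class row.
build_family_kinetics <- function(config) {
  fams <- receptor_families(config$cell_types)
  fams$tau_f <- NA_real_; fams$tau_s <- NA_real_; fams$lam <- NA_real_
  for (spec in config$connections) {
    se <- effective_of(config, spec$src_type)
    de <- effective_of(config, spec$dst_type)
    i <- which(fams$src_eff == se & fams$dst_eff == de)
    fams$tau_f[i] <- spec$kinetics$tau_f
    fams$tau_s[i] <- spec$kinetics$tau_s
    fams$lam[i] <- spec$kinetics$lam
  }
  ext <- config$lgn$kinetics
  if (is.null(ext)) ext <- list(tau_f = 1.5, tau_s = 6, lam = 0.3)
  i <- fams$src_eff == "ExtExc"
  fams$tau_f[i] <- ext$tau_f; fams$tau_s[i] <- ext$tau_s; fams$lam[i] <- ext$lam
  fams
}

#' Wire the recurrent connectivity
#'
#' For every connection class, every ordered (pre, post) pair is sampled
#' independently Bernoulli with probability given by the spatial rule
#' ([connection_probability()]), times the like-to-like modulation for
#' excitatory-to-excitatory classes ([like_to_like_factor()]), times the
#' target-size modulation ([indegree_factor()]).  Products exceeding 1 are
#' clipped (the clip count is recorded as an attribute).  Autapses are
#' forbidden.  Realized edges get log-normal quotient-rule weights signed by
#' the source class, and class delays rounded to the nearest integer
#' millisecond (minimum 1).
#'
#' @param neurons a `NeuronTable` from [place_neurons()].
#' @param config a [build_config()].
#' @param seed integer seed.
#' @param unitary optional precomputed unitary-PSP table (models x families).
#' @return a `ConnectionTable` data.frame (`src`, `dst`, `weight`, `delay`,
#'   `family`) with attribute `n_clipped`.
#' @export
wire_recurrent <- function(neurons, config, seed, unitary = NULL) {
  set.seed(seed)
  fams <- build_family_kinetics(config)
  if (is.null(unitary)) unitary <- unitary_psp_table(config, fams)
  disp_radius <- config$displacement_region_factor * config$core_radius
  lateral_r <- sqrt(neurons$x^2 + neurons$z^2)
  n_mean_type <- tapply(neurons$indegree_target, neurons$type, mean)
  n_clipped <- 0L
  out <- list()
  for (spec in config$connections) {
    si <- which(neurons$type == spec$src_type)
    di <- which(neurons$type == spec$dst_type)
    if (!length(si) || !length(di)) next
    src_class <- type_class(config, spec$src_type)
    dst_class <- type_class(config, spec$dst_type)
    ## pairwise displacement r_pre - r_post, one block per target
    dxm <- outer(neurons$x[si], neurons$x[di], "-")
    dzm <- outer(neurons$z[si], neurons$z[di], "-")
    in_region <- lateral_r[di] <= disp_radius
    p <- matrix(0, length(si), length(di))
    for (j in seq_along(di)) {
      p[, j] <- connection_probability(
        cbind(dxm[, j], dzm[, j]), neurons$tuning_angle[di[j]],
        spec$p_max, spec$sigma, src_class,
        rep(in_region[j], length(si)),
        dR = config$displacement, kappa = config$kappa)
    }
    if (!is.null(spec$beta) && src_class == "excitatory" &&
        dst_class == "excitatory") {
      dphi <- abs(outer(neurons$tuning_angle[si], neurons$tuning_angle[di], "-"))
      p <- p * like_to_like_factor(dphi, spec$beta)
    }
    p <- sweep(p, 2, indegree_factor(neurons$indegree_target[di],
                                     n_mean_type[[spec$dst_type]]), "*")
    n_clipped <- n_clipped + sum(p > 1)
    p <- pmin(p, 1)
    ## no autapses
    if (spec$src_type == spec$dst_type) {
      p[cbind(seq_along(si), match(si, di))] <- 0
    }
    draw <- matrix(runif(length(p)) < p, nrow(p), ncol(p))
    idx <- which(draw, arr.ind = TRUE)
    if (!nrow(idx)) next
    src <- si[idx[, 1]]; dst <- di[idx[, 2]]
    fam_id <- family_id(fams, effective_of(config, spec$src_type),
                        effective_of(config, spec$dst_type))
    w <- sample_connection_weight(
      spec$psp_lognormal,
      config$cell_types[[spec$dst_type]]$indegree_lognormal,
      n_mean_type[[spec$dst_type]],
      neurons$indegree_target[dst],
      unitary[cbind(neurons$model_id[dst], fam_id)])
    sign <- if (src_class == "excitatory") 1 else -1
    out[[length(out) + 1L]] <- data.frame(
      src = src, dst = dst, weight = sign * w,
      delay = max(1L, as.integer(round(spec$delay))),
      family = fam_id)
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(src = integer(0), dst = integer(0), weight = numeric(0),
               delay = integer(0), family = integer(0))
  rownames(edges) <- NULL
  attr(edges, "n_clipped") <- n_clipped
  edges
}

#' Wire the background drive
#'
#' Every neuron is connected to exactly 4 distinct units of the
#' 100-unit, 250 Hz virtual Poisson background population, at 1 ms delay.
#' Initial weights are a per-model placeholder; use
#' [calibrate_background_weights()] to set them so each cell model's isolated
#' spontaneous rate matches its target.
#'
#' @param neurons a `NeuronTable`.
#' @param config a [build_config()].
#' @param seed integer seed.
#' @param init_weight initial weight, simulator units.
#' @return a `ConnectionTable` data.frame (src = background unit index).
#' @export
wire_background <- function(neurons, config, seed, init_weight = 30) {
  set.seed(seed)
  bg <- config$background
  if (bg$n_units < bg$n_per_neuron)
    stop("wire_background: fewer background units than the per-neuron fan-in")
  fams <- build_family_kinetics(config)
  n <- nrow(neurons)
  src <- unlist(lapply(seq_len(n), function(i)
    sample.int(bg$n_units, bg$n_per_neuron)))
  dst <- rep(neurons$id, each = bg$n_per_neuron)
  eff <- vapply(neurons$type, function(tt)
    effective_of(config, tt), "")[match(dst, neurons$id)]
  fam_id <- vapply(eff, function(e) family_id(fams, "ExtExc", e), 0L)
  data.frame(src = src, dst = dst, weight = init_weight,
             delay = max(1L, as.integer(round(bg$delay))),
             family = as.integer(fam_id))
}
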