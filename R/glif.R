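#' GLIF3 point-neuron parameter set
#'
#' A generalized leaky integrate-and-fire parameterization with two
#' after-spike currents (ASCs): passive membrane (resting potential,
#' resistance, time constant), spike threshold, spike-triggered ASC amplitude
#' increments with exponential decay, and an absolute refractory period.
#' Simulation uses forward Euler at 1 ms with a soft reset (threshold distance
#' subtracted on spiking).
#'
#' @param E_L resting potential, mV.
#' @param V_th spike threshold, mV; must exceed `E_L`.
#' @param R_m membrane resistance, GOhm (so that R_m * pA = mV).
#' @param tau_m membrane time constant, ms.
#' @param asc_amps length-2 vector of ASC increments, pA.
#' @param asc_decays length-2 vector of ASC decay rates `k_q`, 1/ms.
#' @param tau_ref absolute refractory period, ms (typically 2-8 ms).
#' @return an object of class `glif_param_set`.
#' @export
glif_param_set <- function(E_L, V_th, R_m, tau_m, asc_amps, asc_decays, tau_ref) {
  if (tau_m <= 0) stop("glif_param_set: tau_m must be > 0")
  if (V_th <= E_L) stop("glif_param_set: V_th must exceed E_L")
  if (tau_ref < 1) stop("glif_param_set: tau_ref must be >= the 1 ms step")
  stopifnot(length(asc_amps) == 2L, length(asc_decays) == 2L, all(asc_decays > 0))
  structure(list(E_L = E_L, V_th = V_th, R_m = R_m, tau_m = tau_m,
                 asc_amps = as.numeric(asc_amps),
                 asc_decays = as.numeric(asc_decays), tau_ref = tau_ref),
            class = "glif_param_set")
}

#' @export
print.glif_param_set <- function(x, ...) {
  cat(sprintf("GLIF3: E_L=%.1f mV, V_th=%.1f mV, R_m=%.3f GOhm, tau_m=%.1f ms, tau_ref=%.0f ms\n",
              x$E_L, x$V_th, x$R_m, x$tau_m, x$tau_ref))
  cat(sprintf("  ASC amps: %.1f / %.1f pA, decays: %.3f / %.3f 1/ms\n",
              x$asc_amps[1], x$asc_amps[2], x$asc_decays[1], x$asc_decays[2]))
  invisible(x)
}

## Expand a pool of glif_param_set objects into per-neuron parameter vectors.
glif_vectors <- function(pool, model_id) {
  get1 <- function(f) vapply(pool, function(g) g[[f]], 0)[model_id]
  get2 <- function(f, q) vapply(pool, function(g) g[[f]][q], 0)[model_id]
  list(
    E_L = get1("E_L"), V_th = get1("V_th"), R_m = get1("R_m"),
    tau_m = get1("tau_m"), tau_ref = get1("tau_ref"),
    asc_amp1 = get2("asc_amps", 1), asc_amp2 = get2("asc_amps", 2),
    asc_k1 = get2("asc_decays", 1), asc_k2 = get2("asc_decays", 2)
  )
}
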