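#' Evaluate a double-alpha synaptic current kernel
#'
#' The postsynaptic current elicited by one presynaptic spike is the sum of a
#' fast and a slow alpha function,
#' `I(t) = A * [ (t/tau_f) e^(1 - t/tau_f) + lambda (t/tau_s) e^(1 - t/tau_s) ]`.
#' Each single-alpha term peaks at value 1 at `t = tau`, so `A` is the peak of
#' the fast component and `lambda` the slow-to-fast amplitude ratio.
#' Negative times return 0 (causality).
#'
#' @param t time since the spike, ms (vectorized).
#' @param A amplitude of the fast component.
#' @param tau_f,tau_s fast and slow time constants, ms, `tau_f < tau_s`.
#' @param lam slow-to-fast amplitude ratio (`>= 0`).
#' @return current values, same length as `t`.
#' @export
double_alpha_eval <- function(t, A, tau_f, tau_s, lam) {
  stopifnot(tau_f > 0, tau_s > tau_f, lam >= 0, A > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- A * ((tp / tau_f) * exp(1 - tp / tau_f) +
                   lam * (tp / tau_s) * exp(1 - tp / tau_s))
  out
}

single_alpha_eval <- function(t, tau) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (t[pos] / tau) * exp(1 - t[pos] / tau)
  out
}

#' Fit a double-alpha kernel to a current trace
#'
#' Nonlinear least squares fit of the double-alpha form to a baseline
#' subtracted, sign-corrected, onset-aligned trace.  A fit is retained only if
#' all four quality filters hold: `R^2 > 0.3`, `0.2 < tau_f < 15` ms,
#' `tau_f < tau_s < 15` ms, and both amplitude components positive.  A fit
#' failing a filter is rejected with a structured condition naming the first
#' violated rule.
#'
#' @param t sample times, ms.
#' @param y current samples.
#' @param starts optional named list of start values.
#' @return a list with `A`, `tau_f`, `tau_s`, `lam`, `r_squared`, and
#'   `accepted = TRUE`; or, on rejection, a list with `accepted = FALSE` and
#'   `reason`.
#' @export
fit_double_alpha <- function(t, y, starts = NULL) {
  stopifnot(length(t) == length(y), length(t) > 6)
  if (is.null(starts)) {
    pk <- max(y)
    tpk <- t[which.max(y)]
    tf0 <- max(min(tpk, 10), 0.05)
    starts <- list(A = max(pk, 1e-6), tau_f = tf0,
                   tau_s = max(min(tpk * 4, 14), 3 * tf0), lam = 0.3)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * ((t / tf) * exp(1 - t / tf) + lam * (t / ts) * exp(1 - t / ts)),
      data = data.frame(t = t, y = y),
      start = list(A = starts$A, tf = starts$tau_f, ts = starts$tau_s,
                   lam = starts$lam),
      lower = c(1e-9, 1e-3, 1e-3, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(accepted = FALSE, reason = "fit failed"))
  p <- as.list(coef(fit))
  yhat <- double_alpha_eval(t, p$A, min(p$tf, p$ts), max(p$tf, p$ts),
                            if (p$tf <= p$ts) p$lam else 1 / max(p$lam, 1e-12))
  ## express with tau_f < tau_s regardless of which branch nlsLM landed in
  if (p$tf > p$ts) {
    p <- list(A = p$A * p$lam, tf = p$ts, ts = p$tf, lam = 1 / p$lam)
  }
  r2 <- 1 - sum((y - yhat)^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  if (!(r2 > 0.3))
    return(list(accepted = FALSE, reason = "R^2 <= 0.3", r_squared = r2))
  if (!(p$tf > 0.2 && p$tf < 15))
    return(list(accepted = FALSE, reason = "tau_f bound", r_squared = r2))
  if (!(p$ts > p$tf && p$ts < 15))
    return(list(accepted = FALSE, reason = "tau_s bound", r_squared = r2))
  if (!(p$A > 0 && p$A * p$lam > 0))
    return(list(accepted = FALSE, reason = "amplitude sign", r_squared = r2))
  list(A = p$A, tau_f = p$tf, tau_s = p$ts, lam = p$lam,
       r_squared = r2, accepted = TRUE)
}

#' Advance alpha-kernel linear states by one 1 ms step
#'
#' Each alpha component is realized by two state variables per postsynaptic
#' neuron: the PSC amplitude state `I` and the auxiliary convolution state `C`
#' that drives it.  With decay `d = exp(-dt/tau)` the update is
#' `I <- d I + dt d C`; `C <- d C + (e/tau) * events`, where `events` are the
#' delay-resolved weighted presynaptic spike sums for this step.  A unit event
#' then produces exactly the unit-peak alpha waveform `(t/tau) e^(1 - t/tau)`
#' on the millisecond grid.
#'
#' @param I,C state matrices or vectors (neurons x components).
#' @param taus component time constants, ms (recycled across columns).
#' @param events weighted event sums, same shape as `C`.
#' @param dt step, ms.
#' @return list with updated `I` and `C`.
#' @export
psc_step <- function(I, C, taus, events, dt = 1) {
  if (any(taus <= 0)) stop("psc_step: tau must be > 0")
  d <- exp(-dt / taus)
  if (is.matrix(I)) {
    d <- matrix(d, nrow(I), ncol(I), byrow = TRUE)
    inj <- matrix(exp(1) / taus, nrow(I), ncol(I), byrow = TRUE)
  } else inj <- exp(1) / taus
  list(I = d * I + dt * d * C,
       C = d * C + inj * events)
}

#' Reference convolution of a spike train with a kernel
#'
#' Brute-force ground truth for the linear-state recursion: the current trace
#' is the explicit sum over spike history of the kernel.  Intended for short
#' traces in tests.
#'
#' @param spikes 0/1 vector over `T` 1 ms steps.  An event at step `s`
#'   contributes `kernel(n - s - 1)` at step `n`: the state recursion injects
#'   into the convolution state first, so the amplitude state starts rising
#'   one step after the event, and the reference adopts the same convention.
#' @param kernel function of time in ms, e.g. a closed-over
#'   [double_alpha_eval()].
#' @param T_steps trace length.
#' @return current trace of length `T_steps`.
#' @export
convolve_reference <- function(spikes, kernel, T_steps) {
  out <- numeric(T_steps)
  idx <- which(spikes > 0)
  for (s in idx) {
    tt <- seq_len(T_steps) - s - 1
    out <- out + spikes[s] * kernel(tt)
  }
  out
}

#' Fit a shared single-alpha basis to a set of receptor-family kernels
#'
#' Approximates every family's double-alpha kernel as a linear combination of
#' `n_basis` single-alpha kernels with shared, global time constants:
#' the time constants are fit in an outer nonlinear search (multi-start
#' Nelder-Mead over log-taus, initialized on a log-spaced ladder) and the
#' per-family coefficients in an inner linear least squares.  With shared
#' basis states a neuron carries `2 * n_basis` PSC states regardless of how
#' many receptor channels innervate it.
#'
#' @param kernels list of kernels, each `list(A=, tau_f=, tau_s=, lam=)`.
#' @param n_basis number of basis alphas.
#' @param horizon fit horizon, ms.
#' @param dt_fit sampling of the fit grid, ms.
#' @return an `alpha_basis` object: `taus`, coefficient matrix `coeffs`
#'   (families x basis), per-family `mse` over the horizon and
#'   `charge_rel_err` (relative integrated-charge error).
#' @export
fit_alpha_basis <- function(kernels, n_basis = 4L, horizon = 30, dt_fit = 0.1) {
  stopifnot(n_basis >= 1L, length(kernels) >= 1L)
  tgrid <- seq(dt_fit, horizon, by = dt_fit)
  Y <- vapply(kernels, function(k)
    double_alpha_eval(tgrid, k$A, k$tau_f, k$tau_s, k$lam), numeric(length(tgrid)))
  design <- function(taus) vapply(taus, function(tau)
    single_alpha_eval(tgrid, tau), numeric(length(tgrid)))
  sse_of <- function(log_taus) {
    X <- design(exp(log_taus))
    fit <- tryCatch(qr.solve(X, Y), error = function(e) NULL)
    if (is.null(fit)) return(1e12)
    sum((Y - X %*% fit)^2)
  }
  all_tf <- range(vapply(kernels, function(k) c(k$tau_f, k$tau_s), numeric(2)))
  ladders <- list(
    log(exp(seq(log(max(all_tf[1] / 2, 0.2)), log(all_tf[2] * 1.2),
                length.out = n_basis))),
    log(exp(seq(log(0.5), log(10), length.out = n_basis))))
  best <- NULL
  for (start in ladders) {
    opt <- if (n_basis == 1L) {
      optim(start, sse_of, method = "Brent",
            lower = log(0.02), upper = log(100))
    } else {
      optim(start, sse_of, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  taus <- sort(exp(best$par))
  X <- design(taus)
  coeffs <- t(qr.solve(X, Y))           # families x basis
  approx_Y <- X %*% t(coeffs)
  mse <- colMeans((Y - approx_Y)^2)
  ## integrated charge of an alpha (t/tau)e^{1-t/tau} over [0, Inf) is e*tau
  charge_exact <- vapply(kernels, function(k)
    exp(1) * k$A * (k$tau_f + k$lam * k$tau_s), 0)
  charge_approx <- as.numeric(coeffs %*% (exp(1) * taus))
  structure(list(taus = taus, coeffs = coeffs, mse = unname(mse),
                 charge_rel_err = abs(charge_approx - charge_exact) /
                   abs(charge_exact),
                 horizon = horizon, dt_fit = dt_fit),
            class = "alpha_basis")
}

#' @export
print.alpha_basis <- function(x, ...) {
  cat(sprintf("alpha basis: %d components, taus = %s ms\n",
              length(x$taus), paste(sprintf("%.2f", x$taus), collapse = ", ")))
  cat(sprintf("  %d families, max MSE %.2e, max charge err %.2f%%\n",
              nrow(x$coeffs), max(x$mse), 100 * max(x$charge_rel_err)))
  invisible(x)
}

#' Event-driven accumulation of weighted presynaptic spikes
#'
#' Expands only the active presynaptic neurons through a per-source lookup
#' (compressed sparse row over sources) into their outgoing synapses, writing
#' each synapse's weight into its delay lane and channel.  The result is
#' contracted to equal the dense delayed matrix-vector product; the dense path
#' is the test oracle, the sparse path is what the simulator uses.
#'
#' @param table synapse table built by [build_event_table()].
#' @param spike_history sources x steps 0/1 matrix (columns = past steps; the
#'   current step is the last column).
#' @param step current step index (column of `spike_history`).
#' @return a dense neurons x channels matrix of weighted event sums for this
#'   step.
#' @export
accumulate_events <- function(table, spike_history, step) {
  out <- matrix(0, table$n_post, table$n_chan)
  for (d in seq_len(table$d_max)) {
    lag <- step - d
    if (lag < 1) next
    active <- which(spike_history[, lag] > 0)
    if (!length(active)) next
    for (src in active) {
      ii <- table$csr_index[[src]]
      if (!length(ii)) next
      sel <- ii[table$delay[ii] == d]
      if (!length(sel)) next
      idx <- cbind(table$dst[sel], table$chan[sel])
      vals <- table$weight[sel] * spike_history[src, lag]
      for (k in seq_along(sel))
        out[idx[k, 1], idx[k, 2]] <- out[idx[k, 1], idx[k, 2]] + vals[k]
    }
  }
  out
}

#' Build the per-source synapse lookup used by event accumulation
#'
#' @param src,dst 1-based source / postsynaptic indices.
#' @param weight synapse weights (already channel-expanded).
#' @param delay integer delays in steps (>= 1).
#' @param chan 1-based channel indices.
#' @param n_src,n_post,n_chan table dimensions.
#' @return lookup table for [accumulate_events()].
#' @export
build_event_table <- function(src, dst, weight, delay, chan,
                              n_src, n_post, n_chan) {
  delay <- as.integer(delay)
  if (any(delay < 1)) stop("build_event_table: delays must be >= 1 step")
  list(src = src, dst = dst, weight = weight, delay = delay, chan = chan,
       csr_index = split(seq_along(src), factor(src, levels = seq_len(n_src))),
       n_src = n_src, n_post = n_post, n_chan = n_chan,
       d_max = max(delay, 1L))
}

#' PSC state memory footprint of a BPTT run
#'
#' Under backpropagation through time every PSC state must be retained across
#' the chunk.  The shared-basis representation stores `2 * n_basis` states per
#' neuron per step; the naive receptor-wise double-alpha representation stores
#' 4 states (fast/slow amplitude + convolution) per receptor channel.
#'
#' @param n_neurons,t_steps problem size.
#' @param n number of basis components (mode "basis") or receptor channels
#'   per neuron (mode "naive").
#' @param bytes_per_value storage width, bytes.
#' @param mode `"basis"` or `"naive"`.
#' @return total bytes.
#' @export
psc_memory_estimate <- function(n_neurons, t_steps, n, bytes_per_value = 4,
                                mode = c("basis", "naive")) {
  mode <- match.arg(mode)
  states <- if (mode == "basis") 2 * n else 4 * n
  states * as.double(n_neurons) * as.double(t_steps) * bytes_per_value
}
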