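## Independent dense reference implementation of the simulator forward pass
## and of the backward learning-signal recursion
## (delta[n] = D[n]' dL/dz[n] + J[n+1]' delta[n+1], gradients accumulated via
## the per-step parameter Jacobian).  Written against the compiled network
## arrays but with its own organization: dense per-(channel, delay) weight
## matrices and explicit R loops, no shared code with the C++ path.

ref_dense_weights <- function(cs, n_src) {
  K <- length(cs$chan_tau)
  D <- cs$d_max
  W <- lapply(seq_len(K), function(k)
    lapply(seq_len(D), function(d) matrix(0, n_src, cs$N)))
  for (e in seq_along(cs$esrc)) {
    k <- cs$echan[e] + 1L
    d <- cs$edelay[e]
    W[[k]][[d]][cs$esrc[e] + 1L, cs$edst[e] + 1L] <-
      W[[k]][[d]][cs$esrc[e] + 1L, cs$edst[e] + 1L] +
      cs$w[cs$eparent[e] + 1L] * cs$ecoef[e]
  }
  W
}

## forward: returns spike matrix, voltage trace, refractory trace and the
## full source spike history (inputs + recurrent)
ref_forward <- function(cs, s_input, T_steps) {
  N <- cs$N
  K <- length(cs$chan_tau)
  D <- cs$d_max
  n_src <- N + nrow(s_input)
  W <- ref_dense_weights(cs, n_src)
  S_hist <- matrix(0, n_src, T_steps + D)
  S_hist[(N + 1):n_src, (D + 1):(T_steps + D)] <- s_input
  p <- cs$pars
  v <- numeric(N); a1 <- numeric(N); a2 <- numeric(N)
  I <- matrix(0, N, K); C <- matrix(0, N, K)
  refrac <- integer(N)
  v_tr <- matrix(0, N, T_steps)
  ref_tr <- matrix(0L, N, T_steps)
  dk <- exp(-1 / cs$chan_tau)
  inj <- exp(1) / cs$chan_tau
  for (n in seq_len(T_steps)) {
    v_tr[, n] <- v
    ref_tr[, n] <- refrac
    S <- as.numeric(refrac == 0 & v >= 1)
    S_hist[1:N, n + D] <- S
    ev <- matrix(0, N, K)
    for (k in seq_len(K)) for (d in seq_len(D))
      ev[, k] <- ev[, k] + crossprod(W[[k]][[d]], S_hist[, n + D - d])
    isyn <- rowSums(I) + a1 + a2
    v <- p$alpha * v + (1 - p$alpha) * p$rm * isyn - S
    a1 <- p$asc_b1 * a1 + S * p$asc_a1
    a2 <- p$asc_b2 * a2 + S * p$asc_a2
    refrac <- ifelse(S == 1, p$tref, pmax(refrac - 1L, 0L))
    for (k in seq_len(K)) {
      Inew <- dk[k] * (I[, k] + C[, k])
      C[, k] <- dk[k] * C[, k] + inj[k] * ev[, k]
      I[, k] <- Inew
    }
  }
  list(S_hist = S_hist, v_tr = v_tr, ref_tr = ref_tr)
}

## backward: explicit learning-signal recursion over the dense state, with
## per-edge gradient accumulation.  Surrogate slope gamma at every crossing.
ref_backward <- function(cs, fwd, dLdS, dLdv, gamma = 0.1) {
  N <- cs$N
  K <- length(cs$chan_tau)
  D <- cs$d_max
  T_steps <- ncol(dLdS)
  p <- cs$pars
  dk <- exp(-1 / cs$chan_tau)
  inj <- exp(1) / cs$chan_tau
  gv <- numeric(N); ga1 <- numeric(N); ga2 <- numeric(N)
  gI <- matrix(0, N, K); gC <- matrix(0, N, K)
  gS_future <- matrix(0, N, T_steps + D)
  grad <- numeric(cs$n_parent)
  esrc1 <- cs$esrc + 1L; edst1 <- cs$edst + 1L
  echan1 <- cs$echan + 1L; epar1 <- cs$eparent + 1L
  for (n in T_steps:1) {
    ## synapse events at n fed C[n+1] (adjoint currently in gC)
    lag <- n + D - cs$edelay
    act <- fwd$S_hist[cbind(esrc1, lag)] > 0
    if (any(act)) {
      contrib <- inj[echan1[act]] * gC[cbind(edst1[act], echan1[act])]
      gadd <- tapply(cs$ecoef[act] * contrib, epar1[act], sum)
      grad[as.integer(names(gadd))] <- grad[as.integer(names(gadd))] + gadd
      rec <- act & esrc1 <= N & lag > D
      if (any(rec)) {
        sadd <- tapply(cs$w[epar1[rec]] * cs$ecoef[rec] *
                         inj[echan1[rec]] * gC[cbind(edst1[rec], echan1[rec])],
                       list(esrc1[rec], lag[rec]), sum)
        ii <- which(!is.na(sadd), arr.ind = TRUE)
        gS_future[cbind(as.integer(rownames(sadd))[ii[, 1]],
                        as.integer(colnames(sadd))[ii[, 2]])] <-
          gS_future[cbind(as.integer(rownames(sadd))[ii[, 1]],
                          as.integer(colnames(sadd))[ii[, 2]])] + sadd[ii]
      }
    }
    gi <- (1 - p$alpha) * p$rm * gv
    gS <- dLdS[, n] + gS_future[, n + D] - gv + p$asc_a1 * ga1 + p$asc_a2 * ga2
    u <- abs(fwd$v_tr[, n] - 1)
    surr <- ifelse(fwd$ref_tr[, n] == 0 & u < 1, gamma * (1 - u), 0)
    gv <- dLdv[, n] + p$alpha * gv + surr * gS
    ga1 <- p$asc_b1 * ga1 + gi
    ga2 <- p$asc_b2 * ga2 + gi
    for (k in seq_len(K)) {
      gInext <- gI[, k]
      gI[, k] <- dk[k] * gInext + gi
      gC[, k] <- dk[k] * (gC[, k] + gInext)
    }
  }
  grad
}
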