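#' Drifting sinusoidal grating movie
#'
#' Luminance `S(x, y, t) = C sin(2 pi f_s (x cos theta + y sin theta) +
#' 2 pi f_t t + phi)` in contrast units around gray 0, one frame per
#' millisecond at one pixel per degree, optionally padded by pre/post gray
#' periods.
#'
#' @param C contrast in [0, 1].
#' @param theta drift direction, degrees.
#' @param phi phase, radians.
#' @param f_t temporal frequency, Hz.
#' @param f_s spatial frequency, cycles per degree.
#' @param duration grating duration, ms.
#' @param pad_gray `c(pre, post)` gray padding, ms.
#' @param field visual field size `c(x, y)` in degrees (= pixels).
#' @return a `movie` object: luminance array (x, y, t) plus metadata.
#' @export
drifting_grating <- function(C, theta, phi = 0, f_t = 2, f_s = 0.04,
                             duration = 500, pad_gray = c(0, 0),
                             field = c(120, 80)) {
  stopifnot(C >= 0, C <= 1, duration > 0)
  nx <- field[1]; ny <- field[2]
  th <- theta * pi / 180
  xs <- seq_len(nx) - 1
  ys <- seq_len(ny) - 1
  sp <- outer(xs * cos(th), ys * sin(th), "+")   # x cos + y sin, deg
  tt <- (seq_len(duration) - 1) / 1000           # s
  frames <- array(0, c(nx, ny, duration))
  for (n in seq_len(duration))
    frames[, , n] <- C * sin(2 * pi * f_s * sp + 2 * pi * f_t * tt[n] + phi)
  if (any(pad_gray > 0)) {
    frames <- array(c(array(0, c(nx, ny, pad_gray[1])), frames,
                      array(0, c(nx, ny, pad_gray[2]))),
                    c(nx, ny, duration + sum(pad_gray)))
  }
  structure(list(frames = frames,
                 meta = list(C = C, theta = theta, phi = phi, f_t = f_t,
                             f_s = f_s, duration = duration,
                             pad_gray = pad_gray, field = field)),
            class = "movie")
}

#' Gray-screen movie
#'
#' @param duration length, ms.
#' @param field visual field size in degrees.
#' @return a zero-luminance `movie`.
#' @export
gray_screen <- function(duration, field = c(120, 80)) {
  structure(list(frames = array(0, c(field[1], field[2], duration)),
                 meta = list(C = 0, theta = NA, phi = NA, f_t = NA, f_s = NA,
                             duration = duration, pad_gray = c(0, 0),
                             field = field)),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie: %d x %d deg, %d ms, contrast %.2f\n",
              d[1], d[2], d[3], x$meta$C))
  invisible(x)
}

## Subtype temporal kernels (1 ms grid): sustained units low-pass the
## luminance signal and keep a maintained response; transient units apply a
## zero-DC biphasic kernel and respond only to change.  OFF subtypes flip the
## sign of the spatial filter.
lgn_temporal_kernel <- function(subtype, len = 120) {
  t <- seq_len(len) - 1
  if (grepl("^sustained", subtype)) {
    lat <- 20
    k <- exp(-(t - lat) / 30) * (t >= lat)
    k / sum(k)
  } else {
    lat <- 10
    k1 <- exp(-(t - lat) / 8) * (t >= lat)
    k2 <- exp(-(t - lat - 12) / 16) * (t >= lat + 12)
    k1 / sum(k1) - k2 / sum(k2)    # zero-DC biphasic
  }
}

#' Surrogate LGN firing-rate model
#'
#' A deliberately simple parametric stand-in for a full spatiotemporal LGN
#' filter bank: each unit applies a separable linear filter -- a
#' difference-of-Gaussians spatial profile (sign-flipped for OFF subtypes)
#' followed by a subtype-specific temporal kernel (sustained: delayed
#' low-pass; transient: biphasic, zero-DC) -- then a rectifying output
#' nonlinearity around its baseline rate.  Gray input yields exactly the
#' baseline.  Arbitrary luminance arrays are accepted; the
#' `contrast_multiplier` option scales input contrast (used to double the
#' drive for natural images).
#'
#' @param movie a `movie` object.
#' @param units LGN units from [make_lgn_units()].
#' @param contrast_multiplier luminance scale factor applied before
#'   filtering.
#' @param surround_ratio,surround_weight difference-of-Gaussians surround
#'   size ratio and weight.
#' @return units x T matrix of non-negative rates in Hz.
#' @export
surrogate_lgn_rates <- function(movie, units, contrast_multiplier = 1,
                                surround_ratio = 2, surround_weight = 0.5) {
  fr <- movie$frames * contrast_multiplier
  d <- dim(fr)
  nx <- d[1]; ny <- d[2]; T_steps <- d[3]
  flat <- matrix(fr, nx * ny, T_steps)
  xs <- seq_len(nx) - 1
  ys <- seq_len(ny) - 1
  rates <- matrix(0, nrow(units), T_steps)
  for (u in seq_len(nrow(units))) {
    if (units$x_deg[u] < 0 || units$x_deg[u] > nx ||
        units$y_deg[u] < 0 || units$y_deg[u] > ny) {
      warning("surrogate_lgn_rates: unit ", units$id[u],
              " outside the visual field; zero drive")
      rates[u, ] <- units$baseline[u]
      next
    }
    sc <- units$rf_sigma[u]
    ss <- sc * surround_ratio
    gx_c <- exp(-(xs - units$x_deg[u])^2 / (2 * sc^2))
    gy_c <- exp(-(ys - units$y_deg[u])^2 / (2 * sc^2))
    gx_s <- exp(-(xs - units$x_deg[u])^2 / (2 * ss^2))
    gy_s <- exp(-(ys - units$y_deg[u])^2 / (2 * ss^2))
    kc <- outer(gx_c, gy_c); kc <- kc / sum(kc)
    ks <- outer(gx_s, gy_s); ks <- ks / sum(ks)
    kern <- kc - surround_weight * ks
    if (units$subtype[u] != "sustained_on") kern <- -kern
    lin <- as.numeric(crossprod(matrix(kern, ncol = 1), flat))
    tk <- lgn_temporal_kernel(units$subtype[u])
    lin_t <- stats::filter(c(rep(0, length(tk) - 1), lin), tk,
                           sides = 1)[length(tk):(length(tk) - 1 + T_steps)]
    rates[u, ] <- pmax(units$baseline[u] + units$gain[u] * lin_t, 0)
  }
  rates
}

#' Bernoulli spike sampling from rates
#'
#' Independent Bernoulli spikes per unit and 1 ms bin with
#' `p = 1 - exp(-r / 1000)`.
#'
#' @param rates units x T matrix of rates, Hz (`>= 0`).
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return units x T 0/1 integer matrix.
#' @export
bernoulli_spikes <- function(rates, seed = NULL) {
  if (any(rates < 0)) stop("bernoulli_spikes: negative rate")
  if (!is.null(seed)) set.seed(seed)
  p <- 1 - exp(-rates / 1000)
  m <- matrix(rbinom(length(p), 1L, p), nrow(rates), ncol(rates))
  m
}

#' LGN drive for a stimulus: rates plus sampled spikes
#'
#' @param movie a `movie`.
#' @param units LGN units.
#' @param ... passed to [surrogate_lgn_rates()].
#' @return list with `rates` and `spikes` matrices.
#' @export
lgn_drive <- function(movie, units, ...) {
  r <- surrogate_lgn_rates(movie, units, ...)
  list(rates = r, spikes = bernoulli_spikes(r))
}
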