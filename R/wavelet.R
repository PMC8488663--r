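# Wavelet machinery: maximal-overlap discrete wavelet transform (MODWT)
# multiresolution analysis with the Daubechies least-asymmetric LA(8)
# filter, and a Morlet continuous wavelet transform. Both are implemented
# here directly (no wavelet package is declared); the MODWT follows the
# standard pyramid algorithm with circular filtering applied to a
# reflection-extended series, and the CWT is evaluated in the Fourier
# domain with the usual analytic Morlet normalization.

# LA(8) scaling filter (sums to sqrt(2)); wavelet filter by quadrature
# mirror: h[l] = (-1)^l g[L-1-l].
la8_scaling <- c(-0.0757657147893407, -0.0296355276459541,
                  0.4976186676324578,  0.8037387518052163,
                  0.2978577956055422, -0.0992195435769354,
                 -0.0126039672622612,  0.0322231006040713)

qmf <- function(g) {
  L <- length(g)
  (-1)^(0:(L - 1)) * rev(g)
}

# circular rotation: y[t] = x[t - sh] (right shift)
rot_right <- function(x, sh) {
  n <- length(x)
  sh <- sh %% n
  if (sh == 0) return(x)
  c(x[(n - sh + 1):n], x[seq_len(n - sh)])
}

# circular filtering used by the MODWT pyramid: y[t] = sum_l f[l] x[t - 2^(j-1) l]
modwt_filt_down <- function(x, f, step) {
  y <- numeric(length(x))
  for (l in seq_along(f)) y <- y + f[l] * rot_right(x, (l - 1) * step)
  y
}

# adjoint filtering used by the inverse: y[t] = sum_l f[l] x[t + 2^(j-1) l]
modwt_filt_up <- function(x, f, step) {
  y <- numeric(length(x))
  for (l in seq_along(f)) y <- y + f[l] * rot_right(x, -(l - 1) * step)
  y
}

# MODWT multiresolution analysis on a reflection-extended series.
# Returns a list with details D1..DJ and smooth SJ, each the length of x;
# sum(D_j) + S_J reconstructs x to machine precision.
modwt_mra <- function(x, J) {
  n0 <- length(x)
  if (2^J > n0) stop("series too short for ", J, " decomposition levels")
  xe <- c(x, rev(x))                     # reflection boundary
  n <- length(xe)
  g <- la8_scaling / sqrt(2)
  h <- qmf(la8_scaling) / sqrt(2)
  W <- vector("list", J)
  V <- xe
  for (j in seq_len(J)) {
    step <- 2^(j - 1)
    W[[j]] <- modwt_filt_down(V, h, step)
    V <- modwt_filt_down(V, g, step)
  }
  details <- vector("list", J)
  for (j in seq_len(J)) {
    # reconstruct from level j wavelet coefficients alone
    D <- modwt_filt_up(W[[j]], h, 2^(j - 1))
    if (j > 1) for (k in (j - 1):1) D <- modwt_filt_up(D, g, 2^(k - 1))
    details[[j]] <- D[seq_len(n0)]
  }
  S <- V
  for (k in J:1) S <- modwt_filt_up(S, g, 2^(k - 1))
  list(details = details, smooth = S[seq_len(n0)])
}

# Detail level j of a series sampled every dt hours covers periods of
# roughly [2^j, 2^(j+1)] * dt hours.
levels_for_band <- function(dt_h, lo_h, hi_h) {
  j <- 1:24
  lo_j <- 2^j * dt_h
  hi_j <- 2^(j + 1) * dt_h
  which(lo_j >= lo_h - 1e-9 & hi_j <= hi_h + 1e-9)
}

#' Morlet continuous wavelet power spectrum
#'
#' Computes the continuous wavelet transform of a uniformly sampled series
#' with an analytic Morlet wavelet (center frequency `omega0 = 6`) in the
#' Fourier domain, and averages squared modulus over time per period,
#' excluding the cone of influence.
#'
#' @param x numeric series (mean is removed).
#' @param dt_h sampling interval in hours.
#' @param periods_h period grid in hours (default 32 log-spaced values in
#'   4-32 h).
#' @param omega0 Morlet center frequency (default 6).
#' @return data frame of class `wavelet_power`: `period_h`, `power`.
#' @export
morlet_power <- function(x, dt_h, periods_h = exp(seq(log(4), log(32),
                                                      length.out = 32)),
                         omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  xh <- stats::fft(x)
  omega <- 2 * pi * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / (n * dt_h)
  if (n %% 2 == 0) omega <- omega[seq_len(n)]
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods_h / fourier_factor
  tt <- (seq_len(n) - 1) * dt_h
  pw <- vapply(scales, function(s) {
    psi <- pi^(-1 / 4) * sqrt(2 * pi * s / dt_h) * exp(-(s * omega - omega0)^2 / 2)
    psi[omega <= 0] <- 0
    w <- stats::fft(xh * psi, inverse = TRUE) / n
    coi <- sqrt(2) * s
    keep <- tt >= coi & tt <= (n - 1) * dt_h - coi
    if (!any(keep)) return(NA_real_)
    mean(Mod(w[keep])^2)
  }, numeric(1))
  structure(data.frame(period_h = periods_h, power = pw),
            class = c("wavelet_power", "data.frame"))
}
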