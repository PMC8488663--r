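# Independent brute-force oracles. These re-derive the same quantities as
# the package by literal enumeration, sharing no code with the
# implementation under test.

# literal centered moving average: direct mean over the window at each bin
bf_moving_average <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(i) {
    if (i - h < 1 || i + h > n) return(NA_real_)
    win <- x[(i - h):(i + h)]
    if (anyNA(win)) NA_real_ else mean(win)
  })
}

# literal phase-marker detection: smooth, compute delta, scan the product
# rule bin by bin, then assign first-up / last-down per ZT 6-30 day window
bf_markers <- function(counts) {
  base <- bf_moving_average(counts, 360)
  short <- bf_moving_average(base, 1080)
  long <- bf_moving_average(base, 8640)
  delta <- short - long
  ups <- c(); downs <- c()
  last <- 0
  for (i in seq_along(delta)) {
    di <- delta[i]
    if (is.na(di) || di == 0) next
    if (last != 0 && di * last < 0) {
      if (last < 0) ups <- c(ups, i) else downs <- c(downs, i)
    }
    last <- di
  }
  n_days <- floor(length(counts) / 8640)
  out <- data.frame(day = seq_len(n_days), onset_zt = NA_real_,
                    offset_zt = NA_real_)
  hr <- function(i) (i - 0.5) / 360
  for (d in seq_len(n_days)) {
    lo <- 24 * (d - 1) + 6; hi <- lo + 24
    u <- ups[hr(ups) >= lo & hr(ups) < hi]
    if (length(u)) {
      out$onset_zt[d] <- hr(u[1]) - 24 * (d - 1)
      dn <- downs[hr(downs) >= lo & hr(downs) < hi & downs > u[1]]
      if (length(dn)) out$offset_zt[d] <- hr(dn[length(dn)]) - 24 * (d - 1)
    }
  }
  out
}

# literal run-length sleep scanner: for each bin, walk left and right to
# measure the zero run it belongs to
bf_sleep <- function(counts) {
  n <- length(counts)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (counts[i] != 0) next
    len <- 1
    j <- i - 1
    while (j >= 1 && counts[j] == 0) { len <- len + 1; j <- j - 1 }
    j <- i + 1
    while (j <= n && counts[j] == 0) { len <- len + 1; j <- j + 1 }
    if (len >= 4) out[i] <- 1L
  }
  out
}

# closed-form ML deviance of a random-intercept model, profiled over the
# fixed effects and the residual variance, optimized over the variance
# ratio rho = sigma_b^2 / sigma_e^2
bf_lmm_profile_dev <- function(rho, y, X, g) {
  n <- length(y)
  XtVX <- matrix(0, ncol(X), ncol(X))
  XtVy <- numeric(ncol(X))
  logdet <- 0
  blocks <- split(seq_len(n), g)
  for (ix in blocks) {
    Vi <- diag(length(ix)) + rho * matrix(1, length(ix), length(ix))
    logdet <- logdet + as.numeric(determinant(Vi)$modulus)
    W <- solve(Vi)
    XtVX <- XtVX + t(X[ix, , drop = FALSE]) %*% W %*% X[ix, , drop = FALSE]
    XtVy <- XtVy + t(X[ix, , drop = FALSE]) %*% W %*% y[ix]
  }
  beta <- solve(XtVX, XtVy)
  rss <- 0
  for (ix in blocks) {
    Vi <- diag(length(ix)) + rho * matrix(1, length(ix), length(ix))
    r <- y[ix] - X[ix, , drop = FALSE] %*% beta
    rss <- rss + as.numeric(t(r) %*% solve(Vi) %*% r)
  }
  s2 <- rss / n
  n * log(2 * pi * s2) + logdet + n
}

bf_lmm_deviance <- function(y, X, g) {
  o <- stats::optimize(function(lr) bf_lmm_profile_dev(exp(lr), y, X, g),
                       c(-30, 10), tol = 1e-12)
  min(o$objective, bf_lmm_profile_dev(0, y, X, g))
}
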