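# Internal numeric helpers shared across modules. All are pure functions;
# lengths are in the units of their callers (the channel solver converts to SI).

# Composite trapezoid integral on an ascending (possibly non-uniform) grid.
.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

# Trapezoid quadrature weights; sum(w * y) == .trapz(x, y).
.trapz_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

# Control cells of a grid: node i owns [max(lo), mid(i-1,i)] x [mid(i,i+1)].
# Cell widths coincide with trapezoid weights, so nodal values defined as
# cell averages of an ideal profile integrate exactly under the trapezoid rule.
.cell_edges <- function(x) {
  n <- length(x)
  mid <- (x[-n] + x[-1]) / 2
  list(lo = c(x[1], mid), hi = c(mid, x[n]))
}

# Moments of the reciprocal of a linear function:
#   I0 = int_0^d dt / mu(t),  I1 = int_0^d t dt / mu(t),  I2 = int_0^d t^2 dt / mu(t)
# with mu(t) = mu1 + (mu2 - mu1) t / d. Series branch avoids cancellation for
# nearly constant intervals; zero-length intervals (d = 0, used to encode
# viscosity jumps by repeated nodes) contribute nothing.
.recip_moments <- function(mu1, mu2, d) {
  r <- (mu2 - mu1) / mu1
  L0 <- L1 <- L2 <- numeric(length(r))
  small <- abs(r) < 0.01
  if (any(small)) {
    rs <- r[small]
    s0 <- s1 <- s2 <- 0
    p <- rep(1, length(rs))
    for (k in 0:10) {
      s0 <- s0 + p / (k + 1)
      s1 <- s1 + p / (k + 2)
      s2 <- s2 + p / (k + 3)
      p <- p * (-rs)
    }
    L0[small] <- s0
    L1[small] <- s1
    L2[small] <- s2
  }
  if (any(!small)) {
    rb <- r[!small]
    l <- log1p(rb)
    L0[!small] <- l / rb
    L1[!small] <- (rb - l) / rb^2
    L2[!small] <- (rb^2 / 2 - rb + l) / rb^3
  }
  list(I0 = d / mu1 * L0, I1 = d^2 / mu1 * L1, I2 = d^3 / mu1 * L2)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate and restore RNG state around seeded generation so library calls do
# not disturb the caller's random stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
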