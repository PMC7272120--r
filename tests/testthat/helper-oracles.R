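# Independent oracles used across the suite. These never call the package
# code paths they are used to check.

# Inverse standard-normal CDF, coded independently of stats::qnorm:
# Acklam's rational approximation refined by two Halley steps on the
# forward CDF. Accurate to ~1e-15 on (0, 1).
inverse_normal_oracle <- function(p) {
  vapply(p, function(pp) {
    stopifnot(pp > 0, pp < 1)
    a <- c(-3.969683028665376e+01, 2.209460984245205e+02,
           -2.759285104469687e+02, 1.383577518672690e+02,
           -3.066479806614716e+01, 2.506628277459239e+00)
    b <- c(-5.447609879822406e+01, 1.615858368580409e+02,
           -1.556989798598866e+02, 6.680131188771972e+01,
           -1.328068155288572e+01)
    cc <- c(-7.784894002430293e-03, -3.223964580411365e-01,
            -2.400758277161838e+00, -2.549732539343734e+00,
            4.374664141464968e+00, 2.938163982698783e+00)
    d <- c(7.784695709041462e-03, 3.224671290700398e-01,
           2.445134137142996e+00, 3.754408661907416e+00)
    p_low <- 0.02425
    if (pp < p_low) {
      q <- sqrt(-2 * log(pp))
      x <- (((((cc[1] * q + cc[2]) * q + cc[3]) * q + cc[4]) * q + cc[5]) *
              q + cc[6]) /
        ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
    } else if (pp <= 1 - p_low) {
      q <- pp - 0.5
      r <- q * q
      x <- (((((a[1] * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) * r +
              a[6]) * q /
        (((((b[1] * r + b[2]) * r + b[3]) * r + b[4]) * r + b[5]) * r + 1)
    } else {
      q <- sqrt(-2 * log(1 - pp))
      x <- -(((((cc[1] * q + cc[2]) * q + cc[3]) * q + cc[4]) * q + cc[5]) *
               q + cc[6]) /
        ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
    }
    for (i in 1:2) { # Halley refinement on the forward CDF
      e <- stats::pnorm(x) - pp
      u <- e / stats::dnorm(x)
      x <- x - u / (1 + x * u / 2)
    }
    x
  }, numeric(1))
}

# Boundary-corrected d-prime built only on the oracle above.
dprime_oracle <- function(h, fa, n_stim, n_catch) {
  fix <- function(r, n) {
    if (r >= 1) 1 - 1 / (2 * n) else if (r <= 0) 1 / (2 * n) else r
  }
  inverse_normal_oracle(fix(h, n_stim)) -
    inverse_normal_oracle(fix(fa, n_catch))
}

# Closed-form temperature of a ramp-hold-ramp step, written directly from
# the piecewise-linear definition.
step_oracle <- function(t, base, target, up, hold, down) {
  vapply(t, function(tt) {
    if (tt <= 0) return(base)
    if (tt < up) return(base + (target - base) * tt / up)
    if (tt <= up + hold) return(target)
    if (tt < up + hold + down) {
      return(target + (base - target) * (tt - up - hold) / down)
    }
    base
  }, numeric(1))
}
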