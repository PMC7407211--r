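# Shared fixtures and independent oracles for the suite.

# Independent atomic-mass table (typed in from standard isotope tables, not
# taken from the package) for mass-arithmetic oracles.
ORACLE_MASS <- c(C = 12, H = 1.00782503207, D = 2.0141017778,
                 N = 14.0030740048, O = 15.9949146196,
                 P = 30.97376163, S = 31.97207100)
ORACLE_ELECTRON <- 0.00054857991

oracle_mass <- function(counts) sum(ORACLE_MASS[names(counts)] * counts)

# Closed-form weighted least squares by the normal equations.
wls_oracle <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  intercept <- (sy - slope * sx) / sw
  c(intercept = intercept, slope = slope)
}

# Brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, sum the hypergeometric probabilities <= the observed one.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- vapply(as, function(x) stats::dhyper(x, c1, n - c1, r1), 0)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Brute-force Tukey fence check.
tukey_brute <- function(v, k = 4) {
  ok <- !is.na(v)
  q1 <- stats::quantile(v[ok], 0.25, type = 7, names = FALSE)
  q3 <- stats::quantile(v[ok], 0.75, type = 7, names = FALSE)
  f <- v < q1 - k * (q3 - q1) | v > q3 + k * (q3 - q1)
  f[!ok] <- FALSE
  f
}

# Build a run directly from Gaussian channel definitions, independent of
# the package's own simulator.
channel_run <- function(channels, run_length = 4, dt = 0.5 / 60,
                        noise_sd = 0, baseline = 0, seed = 1) {
  set.seed(seed)
  t1 <- seq(0, run_length, by = dt)
  t2 <- t1 + dt / 2
  mk <- function(tt, lvl) lapply(seq_along(tt), function(i) {
    mzs <- numeric(0); ints <- numeric(0)
    for (ch in channels) if (ch$level == lvl) {
      y <- ch$height * exp(-(tt[i] - ch$rt)^2 / (2 * ch$sigma^2))
      if (noise_sd > 0) y <- max(0, y + stats::rnorm(1, baseline, noise_sd))
      if (y > 0) { mzs <- c(mzs, ch$mz); ints <- c(ints, y) }
    }
    new_spectrum(lvl, tt[i], mzs, ints)
  })
  new_run(c(mk(t1, 1L), mk(t2, 2L)))
}

chan <- function(mz, rt, height, sigma = 0.04, level = 1L)
  list(mz = mz, rt = rt, height = height, sigma = sigma, level = level)

# A short-gradient simulator configuration used throughout the suite so
# tests stay fast; peaks are placed well inside the window.
short_config <- function(seed = 1L, run_length = 7, ...)
  sim_config(run_length_min = run_length, seed = seed, ...)

# Synthetic XIC with one Gaussian peak (for detector ground-truth tests).
gauss_xic <- function(apex_rt = 2, sigma = 0.04, height = 1e6,
                      run_length = 4, dt = 0.5 / 60, noise_sd = 0,
                      baseline = 0, seed = 1) {
  set.seed(seed)
  rt <- seq(0, run_length, by = dt)
  y <- height * exp(-(rt - apex_rt)^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- pmax(0, y + stats::rnorm(length(y), baseline, noise_sd))
  structure(list(target_mz = 400, tol_ppm = 5, ms_level = 1L,
                 rt = rt, intensity = y), class = "xic")
}
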