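# Independent oracles used across the suite. These re-derive expected values
# from first principles and must stay independent of the package's own
# computational paths.

## Fixed-step RK4 integration of the coupled 2-pool (water + one shifted
## solute) Bloch-McConnell system under CW irradiation, written directly from
## the differential equations. Because the system is linear with constant
## coefficients during CW, one RK4 step is a constant matrix; applying it
## repeatedly is identical to the naive RK4 loop.
rk4_cw_zspectrum <- function(offsets_ppm, f, shift_ppm, k, T1w, T2w, T1s, T2s,
                             b1_ut, duration_s, field_t = 3,
                             gamma = 42.5775, dt = 1e-5) {
  hzppm <- gamma * field_t
  w1 <- 2 * pi * gamma * b1_ut
  kw <- f * k # water -> solute
  vapply(offsets_ppm, function(x) {
    dww <- 2 * pi * hzppm * (0 - x)
    dws <- 2 * pi * hzppm * (shift_ppm - x)
    ## state: (Mxw, Myw, Mzw, Mxs, Mys, Mzs, 1)
    A <- matrix(0, 7, 7)
    A[1, ] <- c(-1 / T2w - kw, -dww, 0, k, 0, 0, 0)
    A[2, ] <- c(dww, -1 / T2w - kw, w1, 0, k, 0, 0)
    A[3, ] <- c(0, -w1, -1 / T1w - kw, 0, 0, k, 1 / T1w)
    A[4, ] <- c(kw, 0, 0, -1 / T2s - k, -dws, 0, 0)
    A[5, ] <- c(0, kw, 0, dws, -1 / T2s - k, w1, 0)
    A[6, ] <- c(0, 0, kw, 0, -w1, -1 / T1s - k, f / T1s)
    n_steps <- round(duration_s / dt)
    I <- diag(7)
    k1 <- A
    k2 <- A %*% (I + dt / 2 * k1)
    k3 <- A %*% (I + dt / 2 * k2)
    k4 <- A %*% (I + dt * k3)
    step <- I + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    M <- c(0, 0, 1, 0, 0, f, 1)
    for (i in seq_len(n_steps)) M <- step %*% M
    M[3]
  }, numeric(1))
}

## Analytic Lorentzian Z-spectrum (broad direct-saturation-like dip).
lorentzian_z <- function(offsets, center = 0, depth = 0.85, width = 0.9) {
  1 - depth / (1 + ((offsets - center) / width)^2)
}

## Exhaustive grid search for the symmetry center of an analytic curve:
## the shift minimizing the integrated squared asymmetry of fun about it.
grid_symmetry_center <- function(fun, window = 1, step = 0.002) {
  grid <- seq(-window, window, by = step)
  del <- seq(0.05, 1, by = 0.05)
  cost <- vapply(grid, function(s) sum((fun(s + del) - fun(s - del))^2),
                 numeric(1))
  grid[which.min(cost)]
}

## Long-form Games-Howell computation with explicit per-pair quantities,
## coded independently from the definitions.
games_howell_hand <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, function(g) sum((g - mean(g))^2) / (length(g) - 1),
              numeric(1))
  out <- NULL
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      se2_i <- v[i] / n[i]
      se2_j <- v[j] / n[j]
      se <- sqrt(se2_i + se2_j)
      df <- (se2_i + se2_j)^2 /
        (se2_i^2 / (n[i] - 1) + se2_j^2 / (n[j] - 1))
      q <- sqrt(2) * abs(m[i] - m[j]) / se
      p <- 1 - stats::ptukey(q, nmeans = k, df = df)
      out <- rbind(out, data.frame(i = i, j = j, q = q, df = df, p = p))
    }
  }
  out
}

## Two-sample permutation test (difference of means), two-sided.
permutation_ttest_p <- function(a, b, n_perm = 20000) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

## Small default objects shared by tests.
test_sat <- function(...) sat_params(...)
test_pools <- function(amide = 0.003299) default_pools(amide_fraction = amide)
water_only_pools <- function() list(pool_params("water", 1, 0, 0, 1.3, 0.07))
water_mt_pools <- function() list(
  pool_params("water", 1, 0, 0, 1.3, 0.07),
  pool_params("mt", 0.06, 0, 25, 1.0, 1e-5, semisolid = TRUE))

## Small phantom spec for imaging tests.
small_spec <- function(...) phantom_spec(shape = c(24, 24, 2), ...)
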