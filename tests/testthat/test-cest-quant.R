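test_that("normalization averages repeats then divides by the reference", {
  sch <- parse_schedule("0, ±3.5 (8), ±1 (2)")
  nvol <- sum(sch$n_acq)
  set.seed(7)
  dims <- c(3, 3, 2)
  stack <- array(runif(prod(dims) * nvol, 200, 900), c(dims, nvol))
  s0 <- array(runif(prod(dims), 900, 1100), dims)
  zs <- normalize_and_average(stack, s0, sch)
  ## brute-force oracle: per-offset mean then divide, coded independently
  vo <- rep(sch$offset, sch$n_acq)
  for (k in seq_len(nrow(sch))) {
    sel <- which(vo == sch$offset[k])
    man <- apply(array(stack[, , , sel], c(dims, length(sel))), 1:3, mean) / s0
    expect_equal(zs$z[, , , k], man, tolerance = 1e-12)
  }
  expect_equal(zs$offsets, sort(sch$offset))
})

test_that("a stack equal to the reference normalizes to unity", {
  sch <- parse_schedule("0, ±1, ±3.5")
  dims <- c(2, 2, 1)
  s0 <- array(800, dims)
  stack <- array(800, c(dims, sum(sch$n_acq)))
  zs <- normalize_and_average(stack, s0, sch)
  expect_true(all(abs(zs$z - 1) < 1e-12))
})

test_that("schedule mismatches abort and bad reference voxels are flagged", {
  sch <- parse_schedule("0, ±1")
  stack <- array(1, c(2, 2, 1, 2))
  expect_error(normalize_and_average(stack, array(1, c(2, 2, 1)), sch),
               "schedule mismatch")
  stack3 <- array(1, c(2, 2, 1, 3))
  s0 <- array(c(1000, 0, -5, 1000), c(2, 2, 1))
  zs <- normalize_and_average(stack3, s0, sch)
  expect_identical(as.vector(zs$valid), c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(is.na(zs$z[2, 1, 1, ])))
})

test_that("the water center of an analytic dip is recovered", {
  offs <- default_schedule()$offset
  z0 <- zspectrum(offs, lorentzian_z(offs))
  bc0 <- b0_correct(z0)
  expect_true(bc0$valid)
  expect_lt(abs(bc0$b0_shift), 0.01 + 1e-9)
  ## shifted curve: center recovered against an exhaustive-search oracle on
  ## the analytic function
  zs <- zspectrum(offs, lorentzian_z(offs, center = 0.20))
  bc <- b0_correct(zs)
  oracle <- grid_symmetry_center(function(x) lorentzian_z(x, center = 0.20))
  expect_equal(oracle, 0.20, tolerance = 0.005)
  expect_lt(abs(bc$b0_shift - 0.20), 0.0101)
  ## spline-minimum variant agrees on this well-conditioned dip
  expect_lt(abs(b0_correct(zs, method = "spline_min")$b0_shift - 0.20), 0.0101)
})

test_that("centers on the search-window boundary invalidate the voxel", {
  offs <- seq(-3, 3, by = 0.25)
  zs <- zspectrum(offs, lorentzian_z(offs, center = 1.4))
  bc <- b0_correct(zs, search_window = 1)
  expect_false(bc$valid)
  expect_true(is.na(bc$b0_shift))
  expect_error(b0_correct(zspectrum(c(-0.5, 0, 0.5), c(0.2, 0.1, 0.2))),
               "window")
})

test_that("injected shifts on simulated protocol spectra are recovered to the documented accuracy", {
  ## the protocol samples every 0.25 ppm near water; the center estimate is
  ## interpolation-limited to ~0.02 ppm worst-case on these sharp spectra
  sat <- test_sat(); sch <- default_schedule()
  pools <- test_pools()
  dense <- sort(unique(c(seq(-7, 7, 0.05), sch$offset)))
  zd <- simulate_zspectrum(pools, sat, dense)
  sfd <- stats::splinefun(zd$offsets, zd$values, method = "fmm")
  errs <- vapply(seq(-0.4, 0.4, by = 0.05), function(s) {
    b0_correct(zspectrum(sch$offset, sfd(sch$offset - s)))$b0_shift - s
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.02)
  ## and the metric the pipeline relies on survives the round trip
  apt0 <- apt_weighted(mtr_asym_curve(zspectrum(sch$offset, sfd(sch$offset))))
  apt_err <- vapply(c(-0.1, -0.05, 0.05, 0.1), function(s) {
    bc <- b0_correct(zspectrum(sch$offset, sfd(sch$offset - s)))
    apt_weighted(mtr_asym_curve(bc$zspec)) - apt0
  }, numeric(1))
  expect_lt(max(abs(apt_err)), 0.4)
})

test_that("the two formulations of the asymmetry definition agree identically", {
  set.seed(21)
  offs <- seq(-6, 6, by = 0.5)
  for (i in 1:20) {
    vals <- runif(length(offs), 0.2, 1)
    z <- zspectrum(offs, vals)
    curve <- mtr_asym_curve(z)
    ## MTR(+x) - MTR(-x) with MTR = 1 - Z, vs [Z(-x) - Z(+x)]
    mtr <- 1 - vals
    alt <- 100 * (mtr[match(curve$offset, offs)] -
                    mtr[match(-curve$offset, offs)])
    expect_equal(curve$value, alt, tolerance = 1e-14)
  }
})

test_that("asymmetry arithmetic, symmetry and the zero offset behave as defined", {
  z <- zspectrum(c(-3.5, 0, 3.5), c(0.60, 0.05, 0.55))
  curve <- mtr_asym_curve(z)
  expect_equal(curve$value[curve$offset == 3.5], 5.0)
  expect_identical(curve$value[curve$offset == 0], 0)
  zsym <- zspectrum(seq(-4, 4), 1 - lorentzian_z(seq(-4, 4)))
  expect_lt(max(abs(mtr_asym_curve(zsym)$value)), 1e-12)
  ## one-sided offsets are omitted
  zone <- zspectrum(c(-2, -1, 0, 1, 2, 3), rep(0.5, 6))
  expect_equal(max(mtr_asym_curve(zone)$offset), 2)
})

test_that("the APT-weighted readout interpolates the curve at 3.5 ppm", {
  curve <- structure(data.frame(offset = c(0, 3.5, 4), value = c(0, 1.25, 1.4)),
                     class = c("mtr_curve", "data.frame"))
  expect_equal(apt_weighted(curve), 1.25)
  const <- structure(data.frame(offset = c(0, 4), value = c(2, 2)),
                     class = c("mtr_curve", "data.frame"))
  expect_equal(apt_weighted(const), 2)
  mid <- structure(data.frame(offset = c(3.25, 3.75), value = c(1, 2)),
                   class = c("mtr_curve", "data.frame"))
  expect_equal(apt_weighted(mid), 1.5)
  expect_error(apt_weighted(structure(data.frame(offset = c(0, 3), value = c(0, 1)),
                                      class = c("mtr_curve", "data.frame"))),
               "cover")
})

test_that("the total CEST integral matches closed forms and is linear", {
  mk <- function(o, v) structure(data.frame(offset = o, value = v),
                                 class = c("mtr_curve", "data.frame"))
  expect_equal(total_cest(mk(c(0, 4), c(1, 1))), 4)
  expect_equal(total_cest(mk(c(0, 2, 4), c(0, 2, 0))), 4)
  expect_equal(total_cest(mk(c(0, 4), c(0, 0))), 0)
  set.seed(5)
  o <- seq(0, 4.5, by = 0.25)
  f <- mk(o, runif(length(o))); g <- mk(o, runif(length(o)))
  lin <- mk(o, 2.5 * f$value + 0.7 * g$value)
  expect_equal(total_cest(lin), 2.5 * total_cest(f) + 0.7 * total_cest(g),
               tolerance = 1e-12)
  expect_error(total_cest(f, lo = 3, hi = 3), "exceed")
})

test_that("homogeneous noiseless on-resonance regions quantify to the single-spectrum value", {
  spec <- small_spec(noise_sigma = 0, b0_amplitude = 0)
  ph <- generate_phantom(spec, test_sat(), default_schedule(), seed = 1)
  qm <- quantify_volume(ph$stack, ph$unsaturated, ph$schedule,
                        mask = ph$labels > 0)
  for (i in seq_along(spec$regions)) {
    zr <- simulate_zspectrum(
      cestpd:::spec_pools(spec, spec$regions[[i]]$amide_fraction),
      test_sat(), ph$schedule)
    ref <- apt_weighted(mtr_asym_curve(zr))
    vals <- qm$apt_weighted[ph$labels %/% 10L == i]
    expect_equal(mean(vals), ref, tolerance = 1e-6)
  }
})

test_that("a dead reference image yields an all-invalid map with a warning", {
  sch <- parse_schedule("0, ±0.25, ±0.5, ±0.75, ±1, ±2, ±3, ±3.5, ±4")
  stack <- array(1, c(2, 2, 1, sum(sch$n_acq)))
  expect_warning(qm <- quantify_volume(stack, array(0, c(2, 2, 1)), sch),
                 "no valid voxels")
  expect_true(all(!qm$valid))
  expect_true(all(is.na(qm$apt_weighted)))
})

test_that("a precomputed field map bypasses the center search", {
  spec <- small_spec(noise_sigma = 0)
  ph <- generate_phantom(spec, test_sat(), default_schedule(), seed = 2)
  qm <- quantify_volume(ph$stack, ph$unsaturated, ph$schedule,
                        mask = ph$labels > 0, b0_map = ph$b0)
  expect_equal(qm$b0_shift[qm$valid], ph$b0[qm$valid])
  ## with the exact field the regional means sit at the calibrated values
  sn <- mean(qm$apt_weighted[ph$labels %/% 10L == 1], na.rm = TRUE)
  expect_equal(sn, 1.25, tolerance = 0.15)
})
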