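#' Z-spectrum container
#'
#' Per-voxel (or per-region) normalized saturation signal Ssat/S0 as a
#' function of saturation offset.
#'
#' @param offsets ppm, strictly increasing.
#' @param values Ssat/S0, same length as `offsets`, finite.
#' @return list of class `zspectrum` with elements `offsets`, `values`.
#' @export
zspectrum <- function(offsets, values) {
  stop_if_not(length(offsets) == length(values), "offsets/values length mismatch")
  stop_if_not(all(diff(offsets) > 0), "offsets must be strictly increasing")
  stop_if_not(all(is.finite(values)), "Z-spectrum values must be finite")
  structure(list(offsets = as.numeric(offsets), values = as.numeric(values)),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets in [%g, %g] ppm\n",
              length(x$offsets), min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Normalize and average a saturation image stack
#'
#' Averages repeated acquisitions at each offset, then divides by the
#' unsaturated reference, producing a per-voxel Z-spectrum stack on ascending
#' offsets. Voxels with non-positive unsaturated signal are marked invalid
#' (NA), never silently zeroed.
#'
#' @param stack 4-D array, one volume per acquisition.
#' @param unsaturated 3-D array (or 2-D, promoted), the S0 reference.
#' @param schedule `cest_schedule` describing the acquisitions.
#' @param volume_offsets optional ppm offset of each volume in `stack`;
#'   defaults to the schedule expansion order (ascending offsets, repeats
#'   adjacent).
#' @return list of class `zspec_stack`: `z` (4-D array, last dim = offsets),
#'   `offsets`, `valid` (3-D logical), `s0`.
#' @export
normalize_and_average <- function(stack, unsaturated, schedule,
                                  volume_offsets = NULL) {
  stop_if_not(inherits(schedule, "cest_schedule"), "schedule must be a cest_schedule")
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack)[1], 1, 1, dim(stack)[2])
  stop_if_not(length(dim(stack)) == 4, "stack must be a 4-D array")
  if (is.null(dim(unsaturated))) dim(unsaturated) <- dim(stack)[1:3]
  if (length(dim(unsaturated)) == 2) dim(unsaturated) <- c(dim(unsaturated), 1)
  stop_if_not(all(dim(unsaturated) == dim(stack)[1:3]),
              "unsaturated image does not match stack grid")
  if (is.null(volume_offsets)) volume_offsets <- schedule_expand(schedule)$offset
  if (length(volume_offsets) != dim(stack)[4])
    stop("schedule mismatch: stack has ", dim(stack)[4], " volumes but the ",
         "schedule expands to ", length(volume_offsets), call. = FALSE)
  for (i in seq_len(nrow(schedule))) {
    hits <- sum(abs(volume_offsets - schedule$offset[i]) < 1e-9)
    if (hits != schedule$n_acq[i])
      stop("schedule mismatch at offset ", schedule$offset[i], " ppm: expected ",
           schedule$n_acq[i], " acquisitions, found ", hits, call. = FALSE)
  }
  dims <- dim(stack)[1:3]
  noff <- nrow(schedule)
  z <- array(NA_real_, c(dims, noff))
  valid <- unsaturated > 0
  s0v <- as.vector(unsaturated)
  flat <- matrix(stack, ncol = dim(stack)[4])
  for (i in seq_len(noff)) {
    sel <- which(abs(volume_offsets - schedule$offset[i]) < 1e-9)
    m <- if (length(sel) == 1) flat[, sel] else rowMeans(flat[, sel, drop = FALSE])
    zi <- ifelse(as.vector(valid), m / s0v, NA_real_)
    z[, , , i] <- array(zi, dims)
  }
  structure(list(z = z, offsets = schedule$offset, valid = valid,
                 s0 = unsaturated),
            class = "zspec_stack")
}

#' Pixel-wise B0 correction by water-center referencing
#'
#' Locates the water resonance within a search window around 0 ppm and
#' resamples the spectrum (linear interpolation) at nominal offset + shift so
#' the water center sits at 0. Two estimators are provided:
#'
#' * `"symmetry"` (default): the maximum-symmetry center - the shift
#'   minimizing the summed squared difference between the interpolated
#'   spectrum at center + delta and center - delta (shape-preserving
#'   monotone-segment interpolant, delta up to `sym_delta_max`), evaluated on
#'   a dense grid. The direct-saturation dip at saturation powers around
#'   2 uT has a flat bottom, so its raw argmin is ill-conditioned while its
#'   symmetry center is sharply determined.
#' * `"spline_min"`: the argmin of a cubic-spline interpolation of the
#'   Z-spectrum on the dense grid.
#'
#' A center found on the window boundary is not trusted: the voxel is
#' flagged invalid.
#'
#' @param zspec a [zspectrum()].
#' @param search_window half-width of the search window, ppm.
#' @param grid_step dense-grid step for the center search, ppm.
#' @param method center estimator, see above.
#' @param sym_delta_max largest mirror offset used by the symmetry cost, ppm.
#' @return list: `zspec` (corrected spectrum on the nominal offsets),
#'   `b0_shift` (ppm), `valid`.
#' @export
b0_correct <- function(zspec, search_window = 1, grid_step = 0.01,
                       method = c("symmetry", "spline_min"),
                       sym_delta_max = 0.5) {
  method <- match.arg(method)
  stop_if_not(inherits(zspec, "zspectrum"), "zspec must be a zspectrum")
  offs <- zspec$offsets
  stop_if_not(min(offs) <= -search_window && max(offs) >= search_window,
              "spectrum does not cover the B0 search window")
  stop_if_not(sum(offs >= -search_window & offs <= search_window) >= 5,
              "need >= 5 points inside the B0 search window")
  grid <- seq(-search_window, search_window, by = grid_step)
  if (method == "spline_min") {
    sf <- stats::splinefun(offs, zspec$values, method = "fmm")
    gi <- which.min(sf(grid))
  } else {
    sf <- stats::splinefun(offs, zspec$values, method = "monoH.FC")
    del <- seq(grid_step * 5, sym_delta_max, by = grid_step * 5)
    cost <- vapply(grid, function(s) sum((sf(s + del) - sf(s - del))^2),
                   numeric(1))
    gi <- which.min(cost)
  }
  if (gi == 1L || gi == length(grid)) {
    return(list(zspec = zspec, b0_shift = NA_real_, valid = FALSE))
  }
  shift <- grid[gi]
  corr <- stats::approx(offs, zspec$values, xout = offs + shift, rule = 2)$y
  list(zspec = zspectrum(offs, corr), b0_shift = shift, valid = TRUE)
}

## 3 x 3 in-plane median filter (NA-aware) applied slice-wise; used to
## regularize the per-voxel B0 shift map before resampling, since the
## underlying field is spatially smooth while the per-voxel center estimate
## is noise-limited at the sparsely averaged near-water offsets.
median_filter_slicewise <- function(x) {
  out <- x
  nx <- dim(x)[1]; ny <- dim(x)[2]
  for (s in seq_len(dim(x)[3])) {
    sl <- x[, , s]
    res <- sl
    for (i in seq_len(nx)) {
      for (j in seq_len(ny)) {
        if (is.na(sl[i, j])) next
        block <- sl[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
        res[i, j] <- stats::median(block, na.rm = TRUE)
      }
    }
    out[, , s] <- res
  }
  out
}

#' MTR asymmetry curve
#'
#' MTRasym(offset) = MTR(+offset) - MTR(-offset)
#'                 = \[Ssat(-offset) - Ssat(+offset)\]/S0, reported in percent.
#' Computed at every non-negative nominal offset whose mirror is covered by
#' the spectrum (linear interpolation onto the symmetric grid); one-sided
#' offsets are omitted.
#'
#' @param zspec a B0-corrected [zspectrum()].
#' @return data frame of class `mtr_curve` with columns `offset` (ppm >= 0)
#'   and `value` (percent).
#' @export
mtr_asym_curve <- function(zspec) {
  stop_if_not(inherits(zspec, "zspectrum"), "zspec must be a zspectrum")
  offs <- zspec$offsets
  pos <- sort(unique(abs(offs)))
  pos <- pos[pos <= min(max(offs), -min(offs))]
  zp <- stats::approx(offs, zspec$values, xout = pos)$y
  zm <- stats::approx(offs, zspec$values, xout = -pos)$y
  out <- data.frame(offset = pos, value = 100 * (zm - zp))
  class(out) <- c("mtr_curve", "data.frame")
  out
}

#' APT-weighted signal: MTRasym at 3.5 ppm
#'
#' The value of the MTR asymmetry curve at the amide offset of 3.5 ppm
#' (linear interpolation between bracketing samples when 3.5 ppm was not
#' acquired exactly), in percent.
#'
#' @param curve an `mtr_curve`.
#' @param at offset to read, ppm.
#' @return percent value.
#' @export
apt_weighted <- function(curve, at = 3.5) {
  stop_if_not(inherits(curve, "mtr_curve"), "curve must be an mtr_curve")
  if (at < min(curve$offset) || at > max(curve$offset))
    stop("curve does not cover ", at, " ppm", call. = FALSE)
  stats::approx(curve$offset, curve$value, xout = at)$y
}

#' Total CEST signal: integral of the MTR asymmetry curve
#'
#' Trapezoidal integral of the percent-valued asymmetry curve over
#' \[`lo`, `hi`\] ppm after linear interpolation onto a uniform grid
#' (default step 0.125 ppm). Units: percent x ppm.
#'
#' @param curve an `mtr_curve`.
#' @param lo,hi integration bounds, ppm.
#' @param grid_step uniform resampling step, ppm.
#' @return percent-ppm value.
#' @export
total_cest <- function(curve, lo = 0, hi = 4, grid_step = 0.125) {
  stop_if_not(inherits(curve, "mtr_curve"), "curve must be an mtr_curve")
  if (hi <= lo) stop("hi must exceed lo", call. = FALSE)
  if (lo < min(curve$offset) || hi > max(curve$offset))
    stop("curve does not cover [", lo, ", ", hi, "] ppm", call. = FALSE)
  x <- seq(lo, hi, by = grid_step)
  if (x[length(x)] < hi) x <- c(x, hi)
  y <- stats::approx(curve$offset, curve$value, xout = x)$y
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Quantify a saturation stack into CEST metric maps
#'
#' Per-voxel orchestration: normalize and average, B0-correct (spline
#' minimum, or a supplied field map), then evaluate the APT-weighted signal
#' and the 0-4 ppm total CEST integral. Invalid voxels (non-positive S0,
#' untrusted B0 fit) carry NA, never silent zeros.
#'
#' @param stack,unsaturated,schedule as in [normalize_and_average()].
#' @param mask optional logical/integer 3-D array restricting analysis.
#' @param b0_window,b0_grid,b0_method B0 search parameters, see
#'   [b0_correct()].
#' @param b0_map optional precomputed B0 shift map (ppm, 3-D); when given the
#'   per-voxel center search is skipped and the map is applied directly.
#' @param b0_smooth apply a 3 x 3 in-plane median filter to the fitted shift
#'   map before resampling (the field is spatially smooth; the per-voxel
#'   estimate is noise-limited).
#' @param volume_offsets see [normalize_and_average()].
#' @return list of class `quant_maps`: `apt_weighted`, `total_cest`,
#'   `b0_shift` (3-D arrays), `valid` (3-D logical).
#' @export
quantify_volume <- function(stack, unsaturated, schedule, mask = NULL,
                            b0_window = 1, b0_grid = 0.01,
                            b0_method = "symmetry", b0_map = NULL,
                            b0_smooth = is.null(b0_map),
                            volume_offsets = NULL) {
  zs <- normalize_and_average(stack, unsaturated, schedule, volume_offsets)
  dims <- dim(zs$z)[1:3]
  apt <- tot <- b0 <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  analyze <- zs$valid
  if (!is.null(mask)) analyze <- analyze & (array(mask, dims) > 0)
  idx <- which(analyze)
  if (length(idx) == 0) {
    warning("no valid voxels to quantify (all-invalid unsaturated image or empty mask)")
    return(structure(list(apt_weighted = apt, total_cest = tot, b0_shift = b0,
                          valid = valid), class = "quant_maps"))
  }
  zmat <- matrix(zs$z, ncol = length(zs$offsets))
  ## pass 1: per-voxel B0 shift
  if (is.null(b0_map)) {
    for (v in idx) {
      bc <- b0_correct(zspectrum(zs$offsets, zmat[v, ]),
                       search_window = b0_window, grid_step = b0_grid,
                       method = b0_method)
      b0[v] <- bc$b0_shift   # NA when the fit hit the window boundary
    }
    if (b0_smooth) b0 <- median_filter_slicewise(b0)
  } else {
    b0[idx] <- array(b0_map, dims)[idx]
  }
  ## pass 2: resample at the final shifts and evaluate the metrics
  for (v in idx) {
    if (is.na(b0[v])) next
    corr <- stats::approx(zs$offsets, zmat[v, ], xout = zs$offsets + b0[v],
                          rule = 2)$y
    curve <- mtr_asym_curve(zspectrum(zs$offsets, corr))
    apt[v] <- apt_weighted(curve)
    tot[v] <- total_cest(curve)
    valid[v] <- TRUE
  }
  structure(list(apt_weighted = apt, total_cest = tot, b0_shift = b0,
                 valid = valid), class = "quant_maps")
}
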