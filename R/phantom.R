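#' Two-slice brain phantom specification
#'
#' Geometry and tissue model for the synthetic acquisition: bilateral
#' elliptical regions (substantia nigra on the midbrain slice; globus
#' pallidus, putamen and caudate on the basal-ganglia slice) inside an
#' elliptical head, a smooth B0 offset field, and per-region pool and
#' diffusion ground truth. Region geometry is stored in fractional image
#' coordinates so the same spec scales to any grid size.
#'
#' @param shape `c(nx, ny, n_slices)` voxel grid.
#' @param regions named list; each element has `slice`, `center` (fractional
#'   x, y of the right-hemisphere instance; the left one is mirrored),
#'   `semiaxes` (fractional), `amide_fraction`, and `dwi` (list with `md` in
#'   1e-3 mm2/s, `fa`, `axis`). Defaults come from the packaged cohort
#'   configuration.
#' @param background list with `amide_fraction` and `dwi` for head tissue
#'   outside the labeled regions.
#' @param b0_amplitude peak amplitude of the smooth B0 field, ppm (must stay
#'   within the correction search window).
#' @param noise_sigma Gaussian channel noise s.d. relative to S0.
#' @param s0 unsaturated signal level inside the head.
#' @param noe_fraction,mt_fraction,water_T1,water_T2 shared pool parameters
#'   passed to [default_pools()].
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 2), regions = NULL,
                         background = NULL, b0_amplitude = 0.1,
                         noise_sigma = 0.005, s0 = 1000,
                         noe_fraction = 0.003, mt_fraction = 0.06,
                         water_T1 = 1.3, water_T2 = 0.07) {
  defaults <- cohort_defaults()
  if (is.null(regions)) {
    regions <- lapply(defaults$regions, function(r) {
      list(slice = r$slice, center = as.numeric(r$center),
           semiaxes = as.numeric(r$semiaxes),
           amide_fraction = r$amide_fraction,
           dwi = list(md = r$md_targets$control, fa = r$fa_targets$control,
                      axis = c(0, 0, 1)))
    })
  }
  if (is.null(background)) {
    background <- list(amide_fraction = defaults$background$amide_fraction,
                       dwi = list(md = defaults$background$md,
                                  fa = defaults$background$fa,
                                  axis = c(0, 0, 1)))
  }
  stop_if_not(length(shape) == 3 && all(shape[1:2] >= 8) && shape[3] >= 1,
              "shape must be c(nx, ny, n_slices) with nx, ny >= 8")
  stop_if_not(abs(b0_amplitude) <= 1,
              "b0 amplitude must stay within the +/-1 ppm correction window")
  for (nm in names(regions)) {
    r <- regions[[nm]]
    lo <- r$center - r$semiaxes
    hi <- r$center + r$semiaxes
    if (any(lo <= 0) || any(hi >= 1) || any(1 - r$center - r$semiaxes <= 0))
      stop("region '", nm, "' extends outside the image bounds", call. = FALSE)
    if (r$slice < 1 || r$slice > shape[3])
      stop("region '", nm, "' assigned to a slice outside the image", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), regions = regions,
                 background = background, b0_amplitude = b0_amplitude,
                 noise_sigma = noise_sigma, s0 = s0,
                 noe_fraction = noe_fraction, mt_fraction = mt_fraction,
                 water_T1 = water_T1, water_T2 = water_T2),
            class = "phantom_spec")
}

## Pool set for one region (or the background) of a phantom spec.
spec_pools <- function(spec, amide_fraction) {
  default_pools(amide_fraction = amide_fraction,
                noe_fraction = spec$noe_fraction,
                mt_fraction = spec$mt_fraction,
                water_T1 = spec$water_T1, water_T2 = spec$water_T2)
}

## Integer label volume: code = 10 * region_index + hemisphere (1 = left,
## 2 = right), 0 elsewhere. Also returns the head mask and the code table.
phantom_labels <- function(spec) {
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  fx <- (matrix(seq_len(nx), nx, ny) - 0.5) / nx
  fy <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - 0.5) / ny
  head2d <- ((fx - 0.5) / 0.45)^2 + ((fy - 0.5) / 0.45)^2 <= 1
  labels <- array(0L, spec$shape)
  head <- array(FALSE, spec$shape)
  for (s in seq_len(nz)) head[, , s] <- head2d
  rows <- list()
  for (i in seq_along(spec$regions)) {
    nm <- names(spec$regions)[i]
    r <- spec$regions[[i]]
    if (any(r$center - r$semiaxes <= 0) || any(r$center + r$semiaxes >= 1))
      stop("region '", nm, "' extends outside the image bounds", call. = FALSE)
    for (h in 1:2) { # 1 = left (mirrored in x), 2 = right
      cx <- if (h == 2) r$center[1] else 1 - r$center[1]
      inside <- ((fx - cx) / r$semiaxes[1])^2 +
        ((fy - r$center[2]) / r$semiaxes[2])^2 <= 1
      sl <- labels[, , r$slice]
      if (any(sl[inside] != 0))
        stop("regions overlap at '", nm, "'", call. = FALSE)
      sl[inside] <- 10L * i + h
      labels[, , r$slice] <- sl
      rows[[length(rows) + 1]] <- data.frame(
        code = 10L * i + h, region = nm,
        hemisphere = c("left", "right")[h])
    }
  }
  list(labels = labels, head = head, table = do.call(rbind, rows))
}

## Smooth B0 offset field in ppm, |field| <= amplitude.
phantom_b0_field <- function(spec) {
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  fx <- (matrix(seq_len(nx), nx, ny) - 0.5) / nx
  fy <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - 0.5) / ny
  plane <- 0.4 * (2 * fx - 1) + 0.6 * sin(pi * (fy - 0.5))
  b0 <- array(0, spec$shape)
  for (s in seq_len(nz)) b0[, , s] <- spec$b0_amplitude * plane * (1 - 0.15 * (s - 1))
  b0
}

#' Generate a synthetic saturation acquisition
#'
#' Simulates the full two-slice CEST acquisition of a phantom: per-voxel
#' Z-spectra are Bloch-McConnell spectra of that voxel's tissue class,
#' shifted by the local B0 offset, scaled by S0, with independent Gaussian
#' channel noise on every acquisition (repeats included) and on the
#' unsaturated reference. Identical seeds give identical output.
#'
#' @param spec a [phantom_spec()].
#' @param sat a [sat_params()].
#' @param schedule a `cest_schedule`.
#' @param seed integer RNG seed.
#' @return list of class `cest_phantom`: `stack` (4-D), `unsaturated`,
#'   `labels`, `label_table`, `b0` (true field, ppm), `volume_offsets`,
#'   `schedule`, `spec`.
#' @export
generate_phantom <- function(spec, sat = sat_params(),
                             schedule = default_schedule(), seed = 1L) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  lab <- phantom_labels(spec)
  b0 <- phantom_b0_field(spec)
  exp_sched <- schedule_expand(schedule)
  nvol <- nrow(exp_sched)
  dims <- spec$shape

  ## class id per voxel: 0 outside head, 1 background tissue, 1 + i region i
  class_id <- array(0L, dims)
  class_id[lab$head] <- 1L
  for (i in seq_along(spec$regions))
    class_id[lab$labels %/% 10L == i] <- 1L + i
  fractions <- c(spec$background$amide_fraction,
                 vapply(spec$regions, function(r) r$amide_fraction, numeric(1)))

  need_dense <- any(b0[class_id > 0] != 0)
  zideal <- array(0, c(dims, nrow(schedule)))
  for (ci in seq_along(fractions)) {
    vox <- which(class_id == ci)
    if (length(vox) == 0) next
    pools <- spec_pools(spec, fractions[ci])
    if (need_dense) {
      grid <- sort(unique(c(seq(-7, 7, by = 0.05), schedule$offset)))
      zs <- simulate_zspectrum(pools, sat, grid)
      sf <- stats::splinefun(zs$offsets, zs$values, method = "fmm")
      ## water resonates at +b0, so the spectrum seen at nominal offset x is
      ## the on-resonance spectrum evaluated at x - b0
      for (k in seq_len(nrow(schedule))) {
        zk <- zideal[, , , k]
        zk[vox] <- sf(schedule$offset[k] - b0[vox])
        zideal[, , , k] <- zk
      }
    } else {
      zs <- simulate_zspectrum(pools, sat, schedule)
      for (k in seq_len(nrow(schedule))) {
        zk <- zideal[, , , k]
        zk[vox] <- zs$values[k]
        zideal[, , , k] <- zk
      }
    }
  }

  off_index <- match(exp_sched$offset, schedule$offset)
  with_seed(seed, {
    stack <- array(0, c(dims, nvol))
    for (v in seq_len(nvol)) {
      sig <- zideal[, , , off_index[v]] * spec$s0
      sig[class_id == 0L] <- 0
      stack[, , , v] <- sig +
        if (spec$noise_sigma > 0)
          array(stats::rnorm(prod(dims), 0, spec$noise_sigma * spec$s0), dims)
        else 0
    }
    unsat <- array(0, dims)
    unsat[class_id > 0L] <- spec$s0
    if (spec$noise_sigma > 0)
      unsat <- unsat + array(stats::rnorm(prod(dims), 0, spec$noise_sigma * spec$s0), dims)
    structure(list(stack = stack, unsaturated = unsat, labels = lab$labels,
                   label_table = lab$table, b0 = b0,
                   volume_offsets = exp_sched$offset, schedule = schedule,
                   spec = spec),
              class = "cest_phantom")
  })
}

#' Axially symmetric diffusion tensor with given MD and FA
#'
#' Builds the tensor with eigenvalues (md(1+2a), md(1-a), md(1-a)) whose
#' fractional anisotropy equals `fa`, principal axis along `axis`.
#'
#' @param md mean diffusivity (any units; carried through).
#' @param fa fractional anisotropy in \[0, 1).
#' @param axis principal direction (normalized internally).
#' @return 3 x 3 tensor matrix.
#' @export
axially_symmetric_tensor <- function(md, fa, axis = c(0, 0, 1)) {
  stop_if_not(md > 0, "md must be positive")
  stop_if_not(fa >= 0 && fa < 1,
              "fa must be in [0, 1) for a positive-definite tensor")
  a <- fa * sqrt(3 / (9 - 6 * fa^2))
  ev <- md * c(1 + 2 * a, 1 - a, 1 - a)
  u <- axis / sqrt(sum(axis^2))
  ## orthonormal completion
  t1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- t1 - sum(t1 * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  R <- cbind(u, v, w)
  R %*% diag(ev) %*% t(R)
}

#' Generate a synthetic diffusion-weighted acquisition
#'
#' Per voxel, the signal for gradient g at b-value b is
#' S0 exp(-b g' D g) for that voxel's ground-truth tensor D, plus seeded
#' Gaussian noise at the stated SNR (sd = S0 / snr).
#'
#' @param spec a [phantom_spec()] (supplies the per-region ground truth).
#' @param scheme a [dwi_scheme()]; default [default_dwi_scheme()].
#' @param snr signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed integer RNG seed.
#' @return list of class `dwi_phantom`: `dwi` (4-D), `scheme`, `labels`,
#'   `label_table`, `truth` (per-class tensor list).
#' @export
generate_dwi <- function(spec, scheme = default_dwi_scheme(), snr = 40,
                         seed = 1L) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  stop_if_not(inherits(scheme, "dwi_scheme"), "scheme must be a dwi_scheme")
  lab <- phantom_labels(spec)
  dims <- spec$shape
  class_id <- array(0L, dims)
  class_id[lab$head] <- 1L
  for (i in seq_along(spec$regions))
    class_id[lab$labels %/% 10L == i] <- 1L + i
  truths <- c(list(spec$background$dwi),
              lapply(spec$regions, function(r) r$dwi))
  tensors <- lapply(truths, function(d)
    axially_symmetric_tensor(d$md * 1e-3, d$fa, d$axis)) # mm2/s
  nvol <- length(scheme$bvals)
  ## per-class signal profile across volumes
  prof <- vapply(tensors, function(D) {
    vapply(seq_len(nvol), function(v) {
      g <- scheme$bvecs[, v]
      exp(-scheme$bvals[v] * drop(t(g) %*% D %*% g))
    }, numeric(1))
  }, numeric(nvol))
  with_seed(seed, {
    dwi <- array(0, c(dims, nvol))
    for (v in seq_len(nvol)) {
      sig <- array(0, dims)
      for (ci in seq_along(tensors))
        sig[class_id == ci] <- spec$s0 * prof[v, ci]
      dwi[, , , v] <- sig +
        if (is.finite(snr))
          array(stats::rnorm(prod(dims), 0, spec$s0 / snr), dims)
        else 0
    }
    structure(list(dwi = dwi, scheme = scheme, labels = lab$labels,
                   label_table = lab$table,
                   truth = stats::setNames(tensors, c("background",
                                                      names(spec$regions)))),
              class = "dwi_phantom")
  })
}
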