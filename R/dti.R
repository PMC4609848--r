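#' Diffusion acquisition scheme
#'
#' @param bvals b-values, s/mm2, one per volume.
#' @param bvecs 3 x n (or n x 3) matrix of gradient directions; unit norm
#'   required for b > 0.
#' @return list of class `dwi_scheme` with `bvals` and `bvecs` (3 x n).
#' @export
dwi_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  stop_if_not(nrow(bvecs) == 3, "bvecs must be 3 x n")
  stop_if_not(length(bvals) == ncol(bvecs), "bvals/bvecs length mismatch")
  stop_if_not(sum(bvals == 0) >= 1, "scheme needs at least one b = 0 volume")
  nz <- bvals > 0
  if (any(nz)) {
    nrms <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
    stop_if_not(all(abs(nrms - 1) < 1e-6), "gradient directions must be unit norm")
  }
  stop_if_not(length(bvals) >= 7, "need at least 7 measurements (1 b=0 + 6 directions)")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs), class = "dwi_scheme")
}

#' Default 31-direction single-shell scheme
#'
#' One b = 0 volume plus 31 directions at b = 1000 s/mm2, spread over the
#' sphere with a spherical Fibonacci layout.
#'
#' @param n_dirs number of diffusion directions.
#' @param b shell b-value, s/mm2.
#' @return a [dwi_scheme()].
#' @export
default_dwi_scheme <- function(n_dirs = 31, b = 1000) {
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  g <- rbind(r * cos(phi), r * sin(phi), z)
  dwi_scheme(c(0, rep(b, n_dirs)), cbind(c(0, 0, 0), g))
}

## 6-column b-matrix design for the log-linear tensor fit; column order
## (xx, yy, zz, xy, xz, yz) with the off-diagonal factor 2.
bmatrix_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Fit diffusion tensors by ordinary least squares
#'
#' Per-voxel OLS of log(signal) against the 6-element b-matrix design
#' (log-linear fit; exact on noiseless single-tensor data). Negative
#' eigenvalues are clamped to zero before metric computation and the voxel
#' flagged. Tensor units follow the b-value units: with b in s/mm2 the
#' returned maps are scaled to 1e-3 mm2/s, the convention in which healthy
#' gray-matter MD is about 0.7.
#'
#' @param dwi 4-D array of diffusion-weighted volumes (or 2-D, voxels x
#'   volumes).
#' @param scheme a [dwi_scheme()].
#' @param mask optional 3-D mask.
#' @return list of class `tensor_maps`: `tensor` (voxels x 6 of the unique
#'   components, 1e-3 mm2/s), `fa`, `md`, `valid`, `clamped`, `dims`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL) {
  stop_if_not(inherits(scheme, "dwi_scheme"), "scheme must be a dwi_scheme")
  if (length(dim(dwi)) == 2) dim(dwi) <- c(dim(dwi)[1], 1, 1, dim(dwi)[2])
  stop_if_not(length(dim(dwi)) == 4, "dwi must be a 4-D array")
  nvol <- dim(dwi)[4]
  stop_if_not(nvol == length(scheme$bvals), "dwi volumes do not match scheme")
  X <- bmatrix_design(scheme)
  qx <- qr(X)
  if (qx$rank < 7)
    stop("rank-deficient diffusion scheme (directions coplanar or repeated)",
         call. = FALSE)
  dims <- dim(dwi)[1:3]
  flat <- matrix(dwi, ncol = nvol)
  analyze <- rep(TRUE, nrow(flat))
  if (!is.null(mask)) analyze <- as.vector(array(mask, dims) > 0)
  usable <- analyze & apply(flat > 0, 1, all)
  fa <- md <- rep(NA_real_, nrow(flat))
  tensor <- matrix(NA_real_, nrow(flat), 6)
  clamped <- rep(FALSE, nrow(flat))
  if (any(usable)) {
    beta <- qr.coef(qx, t(log(flat[usable, , drop = FALSE])))
    D6 <- t(beta[2:7, , drop = FALSE]) * 1e3  # mm2/s -> 1e-3 mm2/s
    res <- t(apply(D6, 1, function(d) {
      ev <- eigen(matrix(d[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3),
                  symmetric = TRUE, only.values = TRUE)$values
      cl <- any(ev < 0)
      ev <- pmax(ev, 0)
      c(fa_md_from_eigenvalues(ev), cl)
    }))
    fa[usable] <- res[, 1]
    md[usable] <- res[, 2]
    clamped[usable] <- res[, 3] > 0
    tensor[usable, ] <- D6
  }
  structure(list(tensor = tensor, fa = array(fa, dims), md = array(md, dims),
                 valid = array(usable, dims), clamped = array(clamped, dims),
                 dims = dims),
            class = "tensor_maps")
}

## FA and MD from a sorted-or-not eigenvalue triple (non-negative).
fa_md_from_eigenvalues <- function(ev) {
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else sqrt(3 / 2) * sqrt(sum((ev - md)^2)) / sqrt(ss)
  c(fa = min(max(fa, 0), 1), md = md)
}

#' FA and MD of a single diffusion tensor
#'
#' MD = (l1 + l2 + l3)/3; FA = sqrt(3/2) sqrt(sum((li - MD)^2)) /
#' sqrt(sum(li^2)), defined as 0 for the zero tensor. Negative eigenvalues
#' are clamped to zero first.
#'
#' @param tensor 3 x 3 symmetric matrix, or length-6 vector
#'   (xx, yy, zz, xy, xz, yz).
#' @return named vector `c(fa =, md =)` in the units of the tensor.
#' @export
fa_md <- function(tensor) {
  D <- if (is.matrix(tensor)) tensor else
    matrix(tensor[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
  stop_if_not(all(abs(D - t(D)) < 1e-8 * (1 + max(abs(D)))),
              "tensor must be symmetric")
  ev <- pmax(eigen(D, symmetric = TRUE, only.values = TRUE)$values, 0)
  fa_md_from_eigenvalues(ev)
}
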