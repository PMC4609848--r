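# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Gyromagnetic ratio of 1H, Hz per microtesla (42.5775 MHz/T).
GAMMA_HZ_PER_UT <- 42.5775

#' Matrix exponential by scaling and squaring
#'
#' Padé(6) approximant with norm-based scaling. The Bloch-McConnell
#' propagators this package builds are small (<= 12 x 12) dissipative
#' matrices, for which this is accurate to near machine precision; it is used
#' instead of a general-purpose routine because the simulator calls it
#' thousands of times per phantom.
#' @noRd
expm_pade <- function(A) {
  nrm <- max(rowSums(abs(A)))
  j <- if (nrm > 0.5) as.integer(ceiling(log2(nrm))) + 1L else 0L
  if (j > 0L) A <- A / 2^j
  n <- nrow(A)
  I <- diag(n)
  cf <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A4 %*% A2
  U <- A %*% (cf[2] * I + cf[4] * A2 + cf[6] * A4)
  V <- cf[1] * I + cf[3] * A2 + cf[5] * A4 + cf[7] * A6
  X <- solve(V - U, V + U)
  for (k in seq_len(j)) X <- X %*% X
  X
}

## Evaluate an expression with a temporary RNG seed, restoring the caller's
## RNG state afterwards so seeded generators do not perturb the session.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Lognormal multiplicative deviates with unit mean and given coefficient of
## variation. CV = 0 returns exactly 1.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
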