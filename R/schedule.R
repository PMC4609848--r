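#' Saturation offset schedules
#'
#' An offset schedule lists the saturation frequency offsets (ppm relative to
#' water) at which Z-spectrum volumes are acquired, with a per-offset
#' acquisition count, plus a flag for the unsaturated normalization volume.
#'
#' @param offsets numeric vector of unique offsets in ppm.
#' @param n_acq integer vector of acquisition counts (recycled if length 1).
#' @param includes_unsaturated logical; whether an unsaturated reference
#'   volume accompanies the schedule.
#' @return a data frame of class `cest_schedule` with columns `offset` and
#'   `n_acq`, ordered by ascending offset.
#' @seealso [parse_schedule()], [default_schedule()]
#' @export
offset_schedule <- function(offsets, n_acq = 1L, includes_unsaturated = TRUE) {
  stop_if_not(length(offsets) > 0, "schedule must contain at least one offset")
  stop_if_not(!anyDuplicated(offsets), "duplicate offsets in schedule")
  n_acq <- rep_len(as.integer(n_acq), length(offsets))
  stop_if_not(all(n_acq >= 1L), "every offset needs n_acq >= 1")
  ord <- order(offsets)
  out <- data.frame(offset = as.numeric(offsets[ord]), n_acq = n_acq[ord])
  attr(out, "includes_unsaturated") <- isTRUE(includes_unsaturated)
  class(out) <- c("cest_schedule", "data.frame")
  out
}

#' Parse a printed offset-schedule specification
#'
#' Parses the compact textual convention used in multi-offset CEST protocols:
#' comma-separated entries of the form `"x"`, `"±x"`, `"x (k)"` or
#' `"±x (k)"`, where `±x` expands to the pair `+x` and `-x` and `(k)` gives
#' the number of acquisitions at that offset (1 when omitted).
#'
#' @param text the schedule specification, e.g. `"0, ±0.25, ±3.5 (8)"`.
#'   Either the Unicode `±` or the ASCII `+-` prefix is accepted.
#' @param includes_unsaturated passed through to [offset_schedule()].
#' @return a `cest_schedule` (see [offset_schedule()]).
#' @examples
#' parse_schedule("0, ±3.5 (8)")
#' @export
parse_schedule <- function(text, includes_unsaturated = TRUE) {
  stop_if_not(is.character(text) && length(text) == 1 && nzchar(trimws(text)),
              "schedule spec must be a single non-empty string")
  entries <- trimws(strsplit(text, ",")[[1]])
  entries <- entries[nzchar(entries)]
  ## strip a trailing units tag on the final entry ("... ppm")
  entries <- sub("\\s*ppm\\s*$", "", entries)
  offsets <- numeric(0)
  counts <- integer(0)
  pat <- "^(±|\\+-|\\+/-)?\\s*(-?[0-9.]+)\\s*(?:\\(([0-9]+)\\))?$"
  for (e in entries) {
    m <- regmatches(e, regexec(pat, e))[[1]]
    if (length(m) == 0) stop("cannot parse schedule entry: '", e, "'", call. = FALSE)
    both <- nzchar(m[2])
    x <- as.numeric(m[3])
    k <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    if (both) {
      offsets <- c(offsets, x, -x)
      counts <- c(counts, k, k)
    } else {
      offsets <- c(offsets, x)
      counts <- c(counts, k)
    }
  }
  if (anyDuplicated(offsets)) stop("duplicate offset entries in schedule spec", call. = FALSE)
  offset_schedule(offsets, counts, includes_unsaturated = includes_unsaturated)
}

#' Default 31-offset APT protocol schedule
#'
#' The multi-offset, multi-acquisition protocol this pipeline targets:
#' 31 unique offsets between -6 and +6 ppm, densely sampled near water for
#' B0 fitting, with 8 acquisitions at the amide offsets of +/- 3.5 ppm
#' (61 saturated acquisitions in total) plus an unsaturated reference.
#'
#' @return a `cest_schedule`.
#' @export
default_schedule <- function() {
  parse_schedule(paste(
    "0, ±0.25, ±0.5, ±0.75, ±1 (2), ±1.5 (2),",
    "±2 (2), ±2.5 (2), ±3 (2), ±3.25 (2), ±3.5 (8),",
    "±3.75 (2), ±4 (2), ±4.5, ±5, ±6 ppm"))
}

#' @export
print.cest_schedule <- function(x, ...) {
  cat(sprintf("<cest_schedule> %d offsets, %d saturated acquisitions, unsaturated: %s\n",
              nrow(x), sum(x$n_acq),
              attr(x, "includes_unsaturated")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

## Total number of saturated volumes a schedule expands to.
schedule_n_volumes <- function(schedule) sum(schedule$n_acq)

## Long form: one row per acquired volume (offset repeated n_acq times),
## fixing the volume order used in generated 4-D stacks.
schedule_expand <- function(schedule) {
  data.frame(volume = seq_len(sum(schedule$n_acq)),
             offset = rep(schedule$offset, schedule$n_acq))
}
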