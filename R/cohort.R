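## Packaged default cohort configuration (region geometry, pool calibration,
## group effect targets). Read once per call; values live in YAML, not code.
cohort_defaults <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_defaults.yaml", package = "cestpd",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Cohort configuration
#'
#' Describes a two-group study: control subjects plus a Parkinson group split
#' into early (Hoehn-Yahr 1-2) and advanced (>= 2.5) stages, with per-region,
#' per-stage effect multipliers on the amide pool fraction and on the
#' diffusion ground truth, and lognormal between-subject/between-hemisphere
#' variability. Defaults reproduce the packaged study design (23/12/11
#' subjects) with stage effects derived from the configured per-stage metric
#' targets.
#'
#' @param n_control,n_early_pd,n_advanced_pd group sizes (subjects).
#' @param between_subject_cv,hemisphere_cv lognormal coefficients of
#'   variation for the CEST (amide) effect.
#' @param fa_cv,fa_hemisphere_cv,md_cv,md_hemisphere_cv variability of the
#'   diffusion metrics.
#' @param effects `NULL` to derive stage multipliers from the configured
#'   targets, `"null"` for all multipliers = 1 (no group effect), or a data
#'   frame with columns `region`, `stage`, `amide`, `fa_alpha`, `fa_lin`,
#'   `md`.
#' @param defaults parsed defaults list (advanced use).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = NULL, n_early_pd = NULL,
                          n_advanced_pd = NULL,
                          between_subject_cv = NULL, hemisphere_cv = NULL,
                          fa_cv = NULL, fa_hemisphere_cv = NULL,
                          md_cv = NULL, md_hemisphere_cv = NULL,
                          effects = NULL, defaults = cohort_defaults()) {
  g <- defaults$groups
  v <- defaults$variability
  n_control <- if (is.null(n_control)) g$n_control else n_control
  n_early_pd <- if (is.null(n_early_pd)) g$n_early_pd else n_early_pd
  n_advanced_pd <- if (is.null(n_advanced_pd)) g$n_advanced_pd else n_advanced_pd
  stop_if_not(n_control >= 1 && n_early_pd >= 1 && n_advanced_pd >= 1,
              "every group needs at least one subject")
  pick <- function(x, d) if (is.null(x)) d else x
  between_subject_cv <- pick(between_subject_cv, v$between_subject_cv)
  hemisphere_cv <- pick(hemisphere_cv, v$hemisphere_cv)
  fa_cv <- pick(fa_cv, v$fa_between_subject_cv)
  fa_hemisphere_cv <- pick(fa_hemisphere_cv, v$fa_hemisphere_cv)
  md_cv <- pick(md_cv, v$md_between_subject_cv)
  md_hemisphere_cv <- pick(md_hemisphere_cv, v$md_hemisphere_cv)

  regions <- names(defaults$regions)
  baselines <- do.call(rbind, lapply(regions, function(nm) {
    r <- defaults$regions[[nm]]
    data.frame(region = nm,
               apt_control = r$apt_targets$control,
               apt_floor = defaults$calibration$apt_floor,
               tc_control = r$total_cest_targets$control,
               tc_floor = defaults$calibration$tc_floor,
               fa_control = r$fa_targets$control,
               md_control = r$md_targets$control,
               amide_fraction = r$amide_fraction)
  }))

  alpha_of <- function(fa) fa * sqrt(3 / (9 - 6 * fa^2))
  if (is.null(effects)) {
    effects <- do.call(rbind, lapply(regions, function(nm) {
      r <- defaults$regions[[nm]]
      fl <- defaults$calibration$apt_floor
      do.call(rbind, lapply(c("control", "early", "advanced"), function(s) {
        data.frame(
          region = nm, stage = s,
          amide = (r$apt_targets[[s]] - fl) / (r$apt_targets$control - fl),
          fa_alpha = alpha_of(r$fa_targets[[s]]) / alpha_of(r$fa_targets$control),
          fa_lin = r$fa_targets[[s]] / r$fa_targets$control,
          md = r$md_targets[[s]] / r$md_targets$control)
      }))
    }))
  } else if (identical(effects, "null")) {
    effects <- expand.grid(region = regions,
                           stage = c("control", "early", "advanced"),
                           stringsAsFactors = FALSE)
    effects$amide <- effects$fa_alpha <- effects$fa_lin <- effects$md <- 1
  }
  stop_if_not(all(c("region", "stage", "amide", "fa_alpha", "fa_lin", "md")
                  %in% names(effects)), "malformed effects table")
  stop_if_not(all(effects$amide > 0 & effects$fa_alpha > 0 & effects$md > 0),
              "effect multipliers must be positive")
  structure(list(n_control = n_control, n_early_pd = n_early_pd,
                 n_advanced_pd = n_advanced_pd,
                 between_subject_cv = between_subject_cv,
                 hemisphere_cv = hemisphere_cv,
                 fa_cv = fa_cv, fa_hemisphere_cv = fa_hemisphere_cv,
                 md_cv = md_cv, md_hemisphere_cv = md_hemisphere_cv,
                 effects = effects, baselines = baselines),
            class = "cohort_config")
}

## Subject roster: id, group, stage.
cohort_roster <- function(config) {
  data.frame(
    subject_id = c(sprintf("C%02d", seq_len(config$n_control)),
                   sprintf("E%02d", seq_len(config$n_early_pd)),
                   sprintf("A%02d", seq_len(config$n_advanced_pd))),
    group = c(rep("control", config$n_control),
              rep("pd", config$n_early_pd + config$n_advanced_pd)),
    stage = c(rep("control", config$n_control),
              rep("early", config$n_early_pd),
              rep("advanced", config$n_advanced_pd)))
}

effect_row <- function(config, region, stage) {
  e <- config$effects
  e[e$region == region & e$stage == stage, ]
}

#' Generate an imaging cohort of phantom datasets
#'
#' One phantom (saturation stack + DWI) per subject. Each subject's regional
#' amide fraction is the spec baseline times the stage effect multiplier
#' times a per-subject lognormal deviate; the diffusion ground truth is
#' modulated the same way (FA through its anisotropy component, MD
#' linearly).
#'
#' @param config a [cohort_config()].
#' @param spec a [phantom_spec()]; per-subject copies are derived from it.
#' @param sat,schedule saturation protocol.
#' @param dwi_scheme_obj,dwi_snr diffusion protocol.
#' @param seed integer; the whole cohort is reproducible from it.
#' @return list of class `cest_cohort`: per-subject lists with `subject_id`,
#'   `group`, `stage`, `cest` ([generate_phantom()] output) and `dwi`
#'   ([generate_dwi()] output).
#' @export
generate_cohort <- function(config, spec = phantom_spec(),
                            sat = sat_params(), schedule = default_schedule(),
                            dwi_scheme_obj = default_dwi_scheme(),
                            dwi_snr = 40, seed = 1L) {
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config")
  roster <- cohort_roster(config)
  n <- nrow(roster)
  draws <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, 2L * n),
         dev = lapply(seq_len(n), function(i)
           list(amide = rlnorm_cv(length(spec$regions), config$between_subject_cv),
                fa = rlnorm_cv(length(spec$regions), config$fa_cv),
                md = rlnorm_cv(length(spec$regions), config$md_cv))))
  })
  subjects <- vector("list", n)
  alpha_of <- function(fa) fa * sqrt(3 / (9 - 6 * fa^2))
  fa_of <- function(a) 3 * a / sqrt(3 + 6 * a^2)
  for (i in seq_len(n)) {
    sspec <- spec
    for (j in seq_along(spec$regions)) {
      nm <- names(spec$regions)[j]
      e <- effect_row(config, nm, roster$stage[i])
      r <- sspec$regions[[j]]
      r$amide_fraction <- r$amide_fraction * e$amide * draws$dev[[i]]$amide[j]
      r$dwi$fa <- fa_of(alpha_of(r$dwi$fa) * e$fa_alpha * draws$dev[[i]]$fa[j])
      r$dwi$md <- r$dwi$md * e$md * draws$dev[[i]]$md[j]
      sspec$regions[[j]] <- r
    }
    subjects[[i]] <- list(
      subject_id = roster$subject_id[i], group = roster$group[i],
      stage = roster$stage[i],
      cest = generate_phantom(sspec, sat, schedule, seed = draws$seeds[2 * i - 1]),
      dwi = generate_dwi(sspec, dwi_scheme_obj, snr = dwi_snr,
                         seed = draws$seeds[2 * i]))
  }
  structure(list(subjects = subjects, roster = roster, config = config),
            class = "cest_cohort")
}

#' Sample a cohort ROI table directly from the group-effect model
#'
#' Draws the long-format ROI sample table (subject, group, stage, region,
#' hemisphere, metric, value) from the same statistical model the imaging
#' cohort realizes - regional metric baselines, stage effect multipliers,
#' lognormal between-subject and between-hemisphere variability - without
#' simulating images. This is the scale at which large-replicate properties
#' of the statistics chain (type-I error, sign-pattern reproducibility) are
#' checked.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @return a `roi_table` data frame (see [extract_roi_table()]).
#' @export
sample_roi_cohort <- function(config, seed = 1L) {
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config")
  roster <- cohort_roster(config)
  b <- config$baselines
  with_seed(seed, {
    rows <- vector("list", nrow(roster) * nrow(b))
    k <- 0
    for (i in seq_len(nrow(roster))) {
      for (j in seq_len(nrow(b))) {
        e <- effect_row(config, b$region[j], roster$stage[i])
        dev_a <- rlnorm_cv(1, config$between_subject_cv)
        dev_f <- rlnorm_cv(1, config$fa_cv)
        dev_m <- rlnorm_cv(1, config$md_cv)
        ha <- rlnorm_cv(2, config$hemisphere_cv)
        ht <- rlnorm_cv(2, config$hemisphere_cv)
        hf <- rlnorm_cv(2, config$fa_hemisphere_cv)
        hm <- rlnorm_cv(2, config$md_hemisphere_cv)
        apt <- b$apt_floor[j] + (b$apt_control[j] - b$apt_floor[j]) *
          e$amide * dev_a * ha
        tc <- b$tc_floor[j] + (b$tc_control[j] - b$tc_floor[j]) *
          e$amide * dev_a * ht
        fa <- b$fa_control[j] * e$fa_lin * dev_f * hf
        md <- b$md_control[j] * e$md * dev_m * hm
        k <- k + 1
        rows[[k]] <- data.frame(
          subject_id = roster$subject_id[i], group = roster$group[i],
          stage = roster$stage[i], region = b$region[j],
          hemisphere = rep(c("left", "right"), 4),
          metric = rep(c("apt_weighted", "total_cest", "fa", "md"), each = 2),
          value = c(apt, tc, fa, md))
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("roi_table", "data.frame")
    out
  })
}
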