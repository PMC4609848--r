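#' Write a CEST phantom acquisition as NIfTI-1 + JSON sidecar
#'
#' Writes the 4-D saturation stack, the unsaturated volume, the integer
#' label mask and the true B0 map, plus a JSON sidecar recording the
#' per-volume offsets, the schedule and the label code table.
#'
#' @param phantom a `cest_phantom` from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stop_if_not(inherits(phantom, "cest_phantom"), "phantom must be a cest_phantom")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    stack = file.path(dir, "cest_stack.nii.gz"),
    s0 = file.path(dir, "cest_s0.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    b0 = file.path(dir, "b0_true.nii.gz"),
    sidecar = file.path(dir, "cest_stack.json"))
  RNifti::writeNifti(phantom$stack, paths$stack)
  RNifti::writeNifti(phantom$unsaturated, paths$s0)
  RNifti::writeNifti(phantom$labels, paths$labels)
  RNifti::writeNifti(phantom$b0, paths$b0)
  jsonlite::write_json(
    list(volume_offsets_ppm = phantom$volume_offsets,
         schedule = data.frame(offset = phantom$schedule$offset,
                               n_acq = phantom$schedule$n_acq),
         includes_unsaturated = attr(phantom$schedule, "includes_unsaturated"),
         label_table = phantom$label_table),
    paths$sidecar, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a DWI phantom as NIfTI-1 with FSL-style bval/bvec files
#'
#' @param dwi a `dwi_phantom` from [generate_dwi()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_dwi_nifti <- function(dwi, dir) {
  stop_if_not(inherits(dwi, "dwi_phantom"), "dwi must be a dwi_phantom")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(dwi = file.path(dir, "dwi.nii.gz"),
                bval = file.path(dir, "dwi.bval"),
                bvec = file.path(dir, "dwi.bvec"))
  RNifti::writeNifti(dwi$dwi, paths$dwi)
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE), collapse = " "),
             paths$bval)
  writeLines(apply(dwi$scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), paths$bvec)
  invisible(paths)
}

#' Read an FSL-style bval/bvec pair into a scheme
#'
#' @param bval_path,bvec_path text files: one line of b-values; three lines
#'   of gradient components.
#' @return a [dwi_scheme()].
#' @export
read_dwi_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(bvec_path), function(l)
    scan(text = l, quiet = TRUE)))
  dwi_scheme(bvals, bv)
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: cohort design, phantom
#' geometry, saturation protocol, offset schedule, diffusion scheme and SNR,
#' and the statistics design. Fully serializable: [run_all()] writes the
#' resolved configuration next to its outputs.
#'
#' @param cohort a [cohort_config()].
#' @param phantom a [phantom_spec()].
#' @param sat a [sat_params()].
#' @param schedule a `cest_schedule` (or a schedule spec string, parsed with
#'   [parse_schedule()]).
#' @param dwi_n_dirs,dwi_b,dwi_snr diffusion protocol.
#' @param sample_unit,variant statistics design, see [analyze_roi_table()].
#' @param seed integer master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), phantom = phantom_spec(),
                       sat = sat_params(), schedule = default_schedule(),
                       dwi_n_dirs = 31, dwi_b = 1000, dwi_snr = 40,
                       sample_unit = "hemisphere", variant = "student",
                       seed = 1L) {
  if (is.character(schedule)) schedule <- parse_schedule(schedule)
  cfg <- structure(list(cohort = cohort, phantom = phantom, sat = sat,
                        schedule = schedule, dwi_n_dirs = dwi_n_dirs,
                        dwi_b = dwi_b, dwi_snr = dwi_snr,
                        sample_unit = sample_unit, variant = variant,
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stop_if_not(inherits(cfg, "run_config"), "not a run_config")
  stop_if_not(inherits(cfg$schedule, "cest_schedule"),
              "run config is missing a valid offset schedule")
  stop_if_not(inherits(cfg$cohort, "cohort_config"), "missing cohort config")
  stop_if_not(inherits(cfg$phantom, "phantom_spec"), "missing phantom spec")
  stop_if_not(inherits(cfg$sat, "cest_saturation"), "missing saturation params")
  stop_if_not(cfg$dwi_n_dirs >= 6, "need >= 6 diffusion directions")
  invisible(cfg)
}

## Plain-list view of a run config, for the resolved-config YAML.
config_as_list <- function(cfg) {
  list(
    seed = cfg$seed,
    cohort = list(n_control = cfg$cohort$n_control,
                  n_early_pd = cfg$cohort$n_early_pd,
                  n_advanced_pd = cfg$cohort$n_advanced_pd,
                  between_subject_cv = cfg$cohort$between_subject_cv,
                  hemisphere_cv = cfg$cohort$hemisphere_cv),
    phantom = list(shape = as.integer(cfg$phantom$shape),
                   b0_amplitude = cfg$phantom$b0_amplitude,
                   noise_sigma = cfg$phantom$noise_sigma,
                   s0 = cfg$phantom$s0),
    saturation = unclass(cfg$sat),
    schedule = list(offsets_ppm = cfg$schedule$offset,
                    n_acq = cfg$schedule$n_acq),
    dwi = list(n_dirs = cfg$dwi_n_dirs, b = cfg$dwi_b, snr = cfg$dwi_snr),
    stats = list(sample_unit = cfg$sample_unit, variant = cfg$variant))
}

#' Run the full pipeline: simulate, quantify, fit, analyze
#'
#' End-to-end orchestration: generates the phantom cohort, writes per-subject
#' NIfTI data, computes CEST metric maps and diffusion tensor maps, samples
#' the labeled ROIs into a long-format CSV, and runs the group statistics
#' chain. Every output is traceable to the resolved configuration and seed
#' written alongside; the same config and seed give a byte-identical ROI
#' table.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (one subdirectory per subject plus
#'   `stats/`).
#' @param keep_nifti write per-subject NIfTI volumes (disable for speed in
#'   throwaway runs).
#' @param verbose log stage progress to the console as well as to the log
#'   file.
#' @return invisibly, a list with the ROI table, the analysis and the output
#'   paths.
#' @export
run_all <- function(config, out_dir, keep_nifti = TRUE, verbose = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stats_dir <- file.path(out_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  log_line("cestpd ", as.character(utils::packageVersion("cestpd")),
           " | R ", getRversion(), " | seed ", config$seed)
  yaml::write_yaml(config_as_list(config), file.path(out_dir, "resolved_config.yaml"))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line("stage ", name, " done in ",
             sprintf("%.1f s", proc.time()[["elapsed"]] - t0))
    res
  }

  roster <- cohort_roster(config$cohort)
  scheme <- default_dwi_scheme(config$dwi_n_dirs, config$dwi_b)
  n <- nrow(roster)
  draws <- with_seed(config$seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, 2L * n),
         dev = lapply(seq_len(n), function(i)
           list(amide = rlnorm_cv(length(config$phantom$regions),
                                  config$cohort$between_subject_cv),
                fa = rlnorm_cv(length(config$phantom$regions), config$cohort$fa_cv),
                md = rlnorm_cv(length(config$phantom$regions), config$cohort$md_cv))))
  })
  alpha_of <- function(fa) fa * sqrt(3 / (9 - 6 * fa^2))
  fa_of <- function(a) 3 * a / sqrt(3 + 6 * a^2)

  roi <- stage("simulate+quantify", {
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      sspec <- config$phantom
      for (j in seq_along(sspec$regions)) {
        nm <- names(sspec$regions)[j]
        e <- effect_row(config$cohort, nm, roster$stage[i])
        r <- sspec$regions[[j]]
        r$amide_fraction <- r$amide_fraction * e$amide * draws$dev[[i]]$amide[j]
        r$dwi$fa <- fa_of(alpha_of(r$dwi$fa) * e$fa_alpha * draws$dev[[i]]$fa[j])
        r$dwi$md <- r$dwi$md * e$md * draws$dev[[i]]$md[j]
        sspec$regions[[j]] <- r
      }
      ph <- generate_phantom(sspec, config$sat, config$schedule,
                             seed = draws$seeds[2 * i - 1])
      dw <- generate_dwi(sspec, scheme, snr = config$dwi_snr,
                         seed = draws$seeds[2 * i])
      if (keep_nifti) {
        sd <- file.path(out_dir, roster$subject_id[i])
        write_phantom_nifti(ph, sd)
        write_dwi_nifti(dw, sd)
      }
      qm <- quantify_volume(ph$stack, ph$unsaturated, ph$schedule,
                            mask = ph$labels > 0)
      tm <- fit_tensor(dw$dwi, scheme, mask = dw$labels > 0)
      parts[[i]] <- extract_roi_table(ph$labels, ph$label_table, quant = qm,
                                      tensor = tm,
                                      subject_id = roster$subject_id[i],
                                      group = roster$group[i],
                                      stage = roster$stage[i])
      log_line("subject ", roster$subject_id[i], " (", roster$stage[i], ") quantified")
    }
    out <- do.call(rbind, parts)
    class(out) <- c("roi_table", "data.frame")
    out
  })
  utils::write.csv(roi, file.path(stats_dir, "roi_samples.csv"), row.names = FALSE)

  analysis <- stage("group-statistics", {
    analyze_roi_table(roi, sample_unit = config$sample_unit,
                      variant = config$variant)
  })
  for (nm in c("summaries", "two_group", "three_group", "posthoc")) {
    if (!is.null(analysis[[nm]]))
      utils::write.csv(analysis[[nm]],
                       file.path(stats_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  rep_path <- file.path(stats_dir, "report.txt")
  sink(rep_path); print(analysis); sink()
  log_line("run complete")
  invisible(list(roi = roi, analysis = analysis, out_dir = out_dir,
                 report = rep_path))
}
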