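# Pipeline orchestration: config handling, seed fan-out, the simulate / fit
# / roi / stats stages, and a manifest-checked full run. The exported
# functions are the programmatic surface; inst/cli/renaldki.R wraps them as
# shell subcommands.

#' Default run configuration
#'
#' Built-in defaults mirror the study acquisition (b = 0/400/800 s/mm^2,
#' 25 directions) and the reference cohort design (4 groups x 6 timepoints x
#' 6 subjects). Values loaded from a YAML config override these; CLI flags
#' override both.
#'
#' @param seed global seed; every stage derives its own seed from it.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    scheme = list(n_directions = 25, shells = c(0, 400, 800), seed = 7),
    phantom = list(shape = c(20, 20, 10), s0 = 1000, snr = 25),
    cohort = list(n_subjects = 6, rater_sd_fraction = 0.2,
                  fibrosis_r = 0.687),
    estimator = "WLS",
    quadrature = "sphere250",
    stats = list(icc_group = "HUA",
                 correlation_timepoints = c("1d", "5d", "9d"))
  ), class = "run_config")
}

#' Read and write run configurations
#'
#' YAML round trip of a `run_config`; unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_cfg(cfg, user), class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config` to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic decorrelated child seed for a named stage (kept < 2^31)
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483647)
}

config_quadrature <- function(config, scheme) {
  if (identical(config$quadrature, "acquisition")) acquisition_quadrature(scheme)
  else default_quadrature()
}

#' Simulate stage: write all synthetic inputs
#'
#' Generates the phantom acquisition (4D NIfTI, labels, bval/bvec), the
#' longitudinal cohort table, the two-rater remeasurement table, and the
#' fibrosis scores, all under seeds derived from the global seed.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(config = default_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  scheme <- build_scheme(config$scheme$n_directions, config$scheme$shells,
                         seed = config$scheme$seed)
  quad <- config_quadrature(config, scheme)
  spec <- phantom_spec(shape = config$phantom$shape, s0 = config$phantom$s0,
                       snr = config$phantom$snr,
                       seed = stage_seed(config$seed, "phantom"))
  ph <- simulate_phantom(spec, scheme, quad)
  write_dwi(ph$dwi, file.path(out_dir, "phantom"))
  write_label_map(ph$labels, file.path(out_dir, "labels.nii.gz"))

  cohort <- simulate_cohort(n_subjects = config$cohort$n_subjects,
                            seed = stage_seed(config$seed, "cohort"))
  write_roi_table(cohort, file.path(out_dir, "cohort.csv"))
  raters <- simulate_rater_pair(cohort, config$cohort$rater_sd_fraction,
                                seed = stage_seed(config$seed, "raters"))
  write_roi_table(raters, file.path(out_dir, "raters.csv"))

  # fibrosis tracks each region's own MK (per-region conditional draws keep
  # the within-region correlation at the configured value)
  fib_tab <- do.call(rbind, lapply(c("OS", "IS"), function(r) {
    mk_rows <- cohort[cohort$metric == "MK" & cohort$region == r &
                        cohort$timepoint %in% config$stats$correlation_timepoints, ]
    fib <- simulate_fibrosis_scores(mk_rows$value, config$cohort$fibrosis_r,
                                    seed = stage_seed(config$seed,
                                                      paste0("fibrosis-", r)))
    data.frame(subject = mk_rows$subject, group = mk_rows$group,
               timepoint = mk_rows$timepoint, region = mk_rows$region,
               mod = fib$mod)
  }))
  utils::write.csv(fib_tab, file.path(out_dir, "fibrosis.csv"), row.names = FALSE)

  paths <- c(dwi = file.path(out_dir, "phantom.nii.gz"),
             bval = file.path(out_dir, "phantom.bval"),
             bvec = file.path(out_dir, "phantom.bvec"),
             labels = file.path(out_dir, "labels.nii.gz"),
             cohort = file.path(out_dir, "cohort.csv"),
             raters = file.path(out_dir, "raters.csv"),
             fibrosis = file.path(out_dir, "fibrosis.csv"))
  invisible(paths)
}

#' Fit stage: tensor fit and metric maps
#'
#' @param nifti_path,bval_path,bvec_path the acquisition files.
#' @param mask_path optional label NIfTI restricting the fit.
#' @param estimator `"WLS"` or `"OLS"`.
#' @param out_dir directory for mk/fa/md/s0 maps and the fit log.
#' @param quadrature MK quadrature.
#' @return List with `maps`, `fit`, and written `paths`, invisibly.
#' @export
pipeline_fit <- function(nifti_path, bval_path, bvec_path, mask_path = NULL,
                         estimator = "WLS", out_dir,
                         quadrature = default_quadrature()) {
  dwi <- read_dwi(nifti_path, bval_path, bvec_path)
  mask <- if (!is.null(mask_path)) read_label_map(mask_path) else NULL
  fit <- fit_volume(dwi, mask, estimator = estimator)
  maps <- maps_from_fit(fit, quadrature)
  paths <- write_maps(maps, out_dir)
  flag_counts <- c(
    negative_eigenvalue = sum(bitwAnd(fit$flag_mask, 1L) > 0),
    clipped_signal = sum(bitwAnd(fit$flag_mask, 2L) > 0),
    rank_deficient = sum(bitwAnd(fit$flag_mask, 4L) > 0))
  log_path <- file.path(out_dir, "fit_log.json")
  jsonlite::write_json(list(estimator = estimator,
                            n_fitted = sum(fit$fitted),
                            flags = as.list(flag_counts)),
                       log_path, auto_unbox = TRUE)
  invisible(list(maps = maps, fit = fit,
                 paths = c(paths, log = log_path)))
}

#' Stats stage: assemble and write the report
#'
#' @param roi_path cohort ROI table CSV.
#' @param raters_path optional two-rater table CSV (ICC skipped when absent).
#' @param fibrosis_path optional fibrosis score CSV (correlations skipped
#'   when absent).
#' @param out_dir report directory.
#' @param config a `run_config` (stats options).
#' @return The `stats_report`, invisibly.
#' @export
pipeline_stats <- function(roi_path, raters_path = NULL, fibrosis_path = NULL,
                           out_dir, config = default_config()) {
  table <- read_roi_table(roi_path)
  raters <- if (!is.null(raters_path) && file.exists(raters_path))
    read_roi_table(raters_path) else NULL
  fibrosis <- if (!is.null(fibrosis_path) && file.exists(fibrosis_path))
    utils::read.csv(fibrosis_path, stringsAsFactors = FALSE) else NULL
  report <- summary_report(table, raters, fibrosis,
                           icc_group = config$stats$icc_group,
                           correlation_timepoints = config$stats$correlation_timepoints)
  write_stats_report(report, out_dir)
  invisible(report)
}

#' Full pipeline run
#'
#' simulate -> fit -> roi -> stats, with a manifest recording every artifact,
#' its MD5 checksum, and the stage seeds. Rerunning with the same config
#' yields identical checksums.
#'
#' @param config a `run_config`.
#' @param out_dir run directory.
#' @return List with `manifest` (data frame), `report`, `roi` — invisibly.
#' @export
pipeline_full_run <- function(config = default_config(), out_dir) {
  t0 <- Sys.time()
  sim <- pipeline_simulate(config, file.path(out_dir, "inputs"))
  scheme <- build_scheme(config$scheme$n_directions, config$scheme$shells,
                         seed = config$scheme$seed)
  quad <- config_quadrature(config, scheme)
  fitres <- pipeline_fit(sim[["dwi"]], sim[["bval"]], sim[["bvec"]],
                         mask_path = sim[["labels"]],
                         estimator = config$estimator,
                         out_dir = file.path(out_dir, "maps"),
                         quadrature = quad)
  labels <- read_label_map(sim[["labels"]])
  roi <- roi_means(fitres$maps, labels)
  roi_path <- file.path(out_dir, "phantom_roi_means.csv")
  utils::write.csv(roi, roi_path, row.names = FALSE)
  report <- pipeline_stats(sim[["cohort"]], sim[["raters"]], sim[["fibrosis"]],
                           out_dir = file.path(out_dir, "stats"),
                           config = config)
  write_config(config, file.path(out_dir, "config.yaml"))

  artifacts <- c(sim, unlist(fitres$paths), roi = roi_path,
                 config = file.path(out_dir, "config.yaml"),
                 list.files(file.path(out_dir, "stats"), full.names = TRUE))
  manifest <- data.frame(
    artifact = vapply(artifacts, function(p)
      sub("^/", "", sub(normalizePath(out_dir), "", normalizePath(p), fixed = TRUE)),
      character(1)),
    md5 = unname(tools::md5sum(vapply(artifacts, identity, character(1)))),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$artifact), ]
  rownames(manifest) <- NULL
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(cbind(manifest,
                         seed = config$seed,
                         elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                                               units = "secs")), 1)),
                   manifest_path, row.names = FALSE)
  invisible(list(manifest = manifest, report = report, roi = roi))
}
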