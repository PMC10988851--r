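# Synthetic-data generators: tensors calibrated to target metric triples,
# layered kidney phantoms with Rician noise, longitudinal cohorts, two-rater
# remeasurement, and fibrosis scores correlated with mean kurtosis.

#' Tissue parameter targets
#'
#' A target (MD, FA, MK) triple for one kidney layer, as used by tensor
#' calibration. MD is given on the x 10^-3 mm^2/s reporting scale.
#'
#' @param md_target mean diffusivity (x 10^-3 mm^2/s), > 0.
#' @param fa_target fractional anisotropy in [0, 0.95) (prolate closed form).
#' @param mk_target mean kurtosis >= 0.
#' @param region one of "CO", "OS", "IS".
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(md_target, fa_target, mk_target, region = "CO") {
  if (md_target <= 0) stop("md_target must be > 0")
  if (fa_target < 0 || fa_target >= 0.95)
    stop("out-of-range: fa_target must lie in [0, 0.95)")
  if (mk_target < 0) stop("mk_target must be >= 0")
  region <- match.arg(region, COHORT_REGIONS)
  structure(list(md_target = md_target, fa_target = fa_target,
                 mk_target = mk_target, region = region),
            class = "tissue_params")
}

#' Calibrate tensors to a target metric triple
#'
#' Builds an axially symmetric prolate diffusion tensor (principal axis +z)
#' whose eigenvalues are solved in closed form from (MD, FA): with
#' delta = lambda1 - lambda23,  FA = delta / sqrt(3 MD^2 + (2/3) delta^2),
#' so  delta = FA * MD * sqrt(3 / (1 - (2/3) FA^2)).  The kurtosis tensor is
#' w0 times the unit isotropic tensor, with w0 chosen so the quadrature mean
#' kurtosis equals `mk_target`; MK is exactly linear in W, so w0 is obtained
#' by a single linear solve (w0 = mk_target / MK at w0 = 1).
#'
#' @param target a `tissue_params`.
#' @param quadrature quadrature used to define MK; default
#'   [default_quadrature()]. Calibration and downstream metric computation
#'   must share this choice for round trips to close.
#' @return List with elements `D` (`diffusion_tensor`), `W`
#'   (`kurtosis_tensor`), and `w0`.
#' @export
calibrate_tensors <- function(target, quadrature = default_quadrature()) {
  stopifnot(inherits(target, "tissue_params"))
  mdv <- target$md_target * 1e-3          # back to mm^2/s
  fa <- target$fa_target
  delta <- fa * mdv * sqrt(3 / (1 - (2 / 3) * fa^2))
  lam1 <- mdv + (2 / 3) * delta
  lam23 <- mdv - delta / 3
  if (lam23 <= 0) stop("calibration error: nonpositive radial eigenvalue")
  D <- diffusion_tensor(lam23, lam23, lam1)
  mk_unit <- mean_kurtosis(D, kt_isotropic(), quadrature)
  if (!is.finite(mk_unit) || mk_unit <= 0)
    stop("calibration error: unit-kurtosis MK not positive")
  w0 <- target$mk_target / mk_unit
  list(D = D, W = kurtosis_tensor(w0 * as.numeric(kt_isotropic())), w0 = w0)
}

#' Rician noise
#'
#' Magnitude-MRI noise: returns sqrt((S + g1 sigma)^2 + (g2 sigma)^2) with
#' independent standard normal g1, g2 per sample. `sigma = 0` is the
#' identity.
#'
#' @param signals numeric vector or array of noiseless magnitudes.
#' @param sigma noise standard deviation of each Gaussian channel (>= 0).
#' @param seed integer seed.
#' @return Noisy signals with the shape of the input.
#' @export
add_rician_noise <- function(signals, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signals)
  n <- length(signals)
  noisy <- local_seed(seed, {
    g1 <- stats::rnorm(n)
    g2 <- stats::rnorm(n)
    sqrt((as.numeric(signals) + g1 * sigma)^2 + (g2 * sigma)^2)
  })
  if (!is.null(dim(signals))) dim(noisy) <- dim(signals)
  noisy
}

#' Layered kidney phantom specification
#'
#' Three nested coaxial slabs along the x axis mapped to CO (outermost), OS,
#' and IS (innermost) plus background, emulating the layered organization of
#' the kidney in a coronal acquisition (the 2nd array axis is the coronal
#' slice axis). Default tissue parameters are the baseline control regional
#' triples of [reference_cohort_params()].
#'
#' @param shape grid dimensions (x, y, z).
#' @param tissue named list of `tissue_params` for CO, OS, IS.
#' @param s0 non-weighted signal amplitude.
#' @param snr signal-to-noise ratio s0/sigma of the Rician noise; `Inf` for
#'   noiseless. Default 25, a typical small-animal 3T regime.
#' @param seed integer noise seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(20, 20, 10), tissue = NULL, s0 = 1000,
                         snr = 25, seed = 1) {
  if (is.null(tissue)) {
    tissue <- lapply(stats::setNames(COHORT_REGIONS, COHORT_REGIONS),
      function(r) {
        tr <- reference_triple(r, "CON", "base")
        tissue_params(tr$md, tr$fa, tr$mk, r)
      })
  }
  stopifnot(all(COHORT_REGIONS %in% names(tissue)), length(shape) == 3,
            all(shape >= 6), s0 > 0, snr > 0)
  structure(list(shape = as.integer(shape), tissue = tissue, s0 = s0,
                 snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

# nested-slab label geometry: outer third CO, middle third OS, core IS,
# one-voxel background rim
phantom_labels <- function(shape) {
  lab <- array(0L, shape)
  cx <- (shape[1] + 1) / 2
  # distance from the x midline, scaled to [0, 1] at the rim
  half <- (shape[1] - 2) / 2
  for (i in seq_len(shape[1])) {
    d <- abs(i - cx) / half
    code <- if (d > 1) 0L else if (d > 2 / 3) 1L else if (d > 1 / 3) 2L else 3L
    lab[i, , ] <- code
  }
  lab
}

#' Simulate a layered kidney phantom
#'
#' Each region's voxels receive the noiseless forward-model signal of its
#' calibrated tensors; Rician noise with sigma = s0/snr is then applied with
#' the spec seed (noiseless when `snr = Inf`).
#'
#' @param spec a `phantom_spec`.
#' @param scheme a `gradient_scheme`.
#' @param quadrature quadrature shared with calibration.
#' @return List with `dwi` (a `dwi_volume`), `labels` (a `label_map`), and
#'   `truth` (per-region calibrated tensors and target triples).
#' @export
simulate_phantom <- function(spec, scheme, quadrature = default_quadrature()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "gradient_scheme"))
  lab <- phantom_labels(spec$shape)
  counts <- table(lab[lab > 0])
  if (length(counts) < 3 || any(counts < 30))
    stop("spec error: every region needs >= 30 voxels")
  data <- array(0, c(spec$shape, scheme$n_volumes))
  n_vox <- prod(spec$shape)
  flat <- matrix(0, n_vox, scheme$n_volumes)
  truth <- list()
  for (code in 1:3) {
    region <- ROI_LEGEND[[as.character(code)]]
    cal <- calibrate_tensors(spec$tissue[[region]], quadrature)
    sig <- forward_signal(cal$D, cal$W, spec$s0, scheme)
    vox <- which(lab == code)
    flat[vox, ] <- matrix(sig, length(vox), scheme$n_volumes, byrow = TRUE)
    truth[[region]] <- c(cal, target = list(spec$tissue[[region]]))
  }
  if (is.finite(spec$snr))
    flat <- add_rician_noise(flat, spec$s0 / spec$snr, spec$seed)
  data[] <- flat
  list(dwi = dwi_volume(data, scheme),
       labels = label_map(lab),
       truth = truth)
}

#' Simulate a longitudinal cohort of regional measurements
#'
#' Draws one value per subject x region x timepoint x metric from
#' Normal(cell mean, cell SD). Default cell parameters are the reference
#' cohort table ([reference_cohort_params()]); default design is 4 groups x
#' 6 timepoints x 6 subjects per cell.
#'
#' @param n_subjects subjects per group.
#' @param seed integer seed.
#' @param params cell parameter table with columns metric, region, timepoint,
#'   group, mean, sd.
#' @param groups,timepoints,regions,metrics design legends (defaults: the
#'   full reference design).
#' @return A tidy ROI table data frame (subject, group, timepoint, region,
#'   metric, value).
#' @export
simulate_cohort <- function(n_subjects = 6, seed = 1,
                            params = reference_cohort_params(),
                            groups = COHORT_GROUPS,
                            timepoints = COHORT_TIMEPOINTS,
                            regions = COHORT_REGIONS,
                            metrics = COHORT_METRICS) {
  stopifnot(n_subjects >= 2, all(params$sd > 0))
  cells <- params[params$group %in% groups & params$timepoint %in% timepoints &
                    params$region %in% regions & params$metric %in% metrics, ]
  rows <- cells[rep(seq_len(nrow(cells)), each = n_subjects), ]
  rows$subject <- paste0(rows$group, "-", rep(seq_len(n_subjects), nrow(cells)))
  rows$value <- local_seed(seed, stats::rnorm(nrow(rows), rows$mean, rows$sd))
  out <- rows[, c("subject", "group", "timepoint", "region", "metric", "value")]
  rownames(out) <- NULL
  validate_roi_table(out)
}

#' Duplicate a cohort for two raters
#'
#' Emulates independent remeasurement by two radiologists: each measurement
#' is duplicated for raters 1 and 2 with independent Normal noise of SD equal
#' to `rater_sd_fraction` times the between-subject SD of that cell
#' (estimated from the table itself within subject cells, or supplied).
#'
#' @param table an ROI table.
#' @param rater_sd_fraction in [0, 1).
#' @param seed integer seed.
#' @param cell_sd optional fixed SD (same units as value) overriding the
#'   per-cell empirical SD.
#' @return ROI table with a `rater` column (two rows per input row).
#' @export
simulate_rater_pair <- function(table, rater_sd_fraction, seed, cell_sd = NULL) {
  stopifnot(rater_sd_fraction >= 0, rater_sd_fraction < 1)
  validate_roi_table(table)
  cell <- interaction(table$group, table$timepoint, table$region, table$metric,
                      drop = TRUE)
  if (is.null(cell_sd)) {
    sds <- tapply(table$value, cell, stats::sd)
    sds[is.na(sds)] <- 0
    base_sd <- as.numeric(sds[cell])
  } else {
    base_sd <- rep(cell_sd, nrow(table))
  }
  out <- rbind(cbind(table, rater = 1L), cbind(table, rater = 2L))
  noise_sd <- rater_sd_fraction * rep(base_sd, 2)
  out$value <- out$value +
    local_seed(seed, stats::rnorm(nrow(out))) * noise_sd
  rownames(out) <- NULL
  validate_roi_table(out)
}

#' Simulate histological fibrosis scores correlated with an imaging metric
#'
#' For each input measurement (typically regional MK), draws a mean-optical-
#' density (MOD) fibrosis score from the bivariate-normal conditional with
#' correlation `true_r`; the MOD marginal is Normal(0.13, 0.01), matching the
#' reported Masson-staining score range (about 0.11-0.16), truncated at 0.
#'
#' @param values numeric vector of imaging metric values.
#' @param true_r target correlation in (-1, 1).
#' @param seed integer seed.
#' @param mod_mean,mod_sd marginal location and scale of the MOD score.
#' @return Data frame with columns value (the input) and mod.
#' @export
simulate_fibrosis_scores <- function(values, true_r, seed,
                                     mod_mean = 0.13, mod_sd = 0.01) {
  stopifnot(true_r > -1, true_r < 1, length(values) >= 2)
  sv <- stats::sd(values)
  if (sv == 0) stop("values have zero variance; correlation undefined")
  z <- (values - mean(values)) / sv
  eps <- local_seed(seed, stats::rnorm(length(values)))
  mod <- mod_mean + mod_sd * (true_r * z + sqrt(1 - true_r^2) * eps)
  mod <- pmax(mod, 0)
  data.frame(value = values, mod = mod)
}

#' One reproducibility-study replicate
#'
#' Simulates the two-rater remeasurement experiment on one metric/region
#' column: subjects are assigned round-robin to the column's timepoint cells,
#' one true value per subject is drawn from Normal(cell mean, cell SD), both
#' raters remeasure it with independent Normal noise of SD equal to
#' `rater_sd_fraction` times the between-subject SD of the drawn values, and
#' the absolute-agreement single-measure ICC is returned.
#'
#' @param cells data frame with columns mean and sd (one row per timepoint
#'   cell of the column under study).
#' @param n_subjects number of subjects spread over the cells.
#' @param rater_sd_fraction rater noise as a fraction of the between-subject
#'   SD.
#' @param seed integer seed.
#' @return Scalar ICC(2,1).
#' @export
simulate_icc_replicate <- function(cells, n_subjects, rater_sd_fraction, seed) {
  stopifnot(nrow(cells) >= 1, n_subjects >= 3)
  cell_of <- ((seq_len(n_subjects) - 1) %% nrow(cells)) + 1
  local_seed(seed, {
    truth <- stats::rnorm(n_subjects, cells$mean[cell_of], cells$sd[cell_of])
    noise_sd <- rater_sd_fraction * stats::sd(truth)
    m <- cbind(truth + stats::rnorm(n_subjects, 0, noise_sd),
               truth + stats::rnorm(n_subjects, 0, noise_sd))
    icc_absolute_agreement(m)$icc
  })
}
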