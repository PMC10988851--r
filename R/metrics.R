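# Scalar metric derivation: mean diffusivity, fractional anisotropy and
# mean kurtosis from fitted tensor pairs, voxelwise.

#' Eigendecomposition of a diffusion tensor
#'
#' @param D a `diffusion_tensor`.
#' @return List with `values` (descending) and `vectors` (orthonormal columns).
#' @export
tensor_eigen <- function(D) {
  e <- eigen(dt_to_matrix(as.numeric(D)), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Mean diffusivity
#'
#' trace(D)/3, in the native mm^2/s units of the tensor.
#'
#' @param D a `diffusion_tensor`.
#' @return Scalar MD.
#' @export
mean_diffusivity <- function(D) {
  mean(as.numeric(D)[1:3])
}

#' Fractional anisotropy
#'
#' sqrt(3/2) * sqrt(sum (lambda_i - MD)^2) / sqrt(sum lambda_i^2), clipped to
#' [0, 1] only against sub-1e-9 floating-point excursions. The all-zero
#' tensor has undefined FA and returns NA.
#'
#' @param D a `diffusion_tensor`.
#' @return Scalar FA in [0, 1], or NA.
#' @export
fractional_anisotropy <- function(D) {
  lam <- tensor_eigen(D)$values
  ss <- sum(lam^2)
  if (ss == 0) return(NA_real_)
  mdv <- mean(lam)
  fa <- sqrt(1.5 * sum((lam - mdv)^2) / ss)
  if (fa > 1 && fa < 1 + 1e-9) fa <- 1
  if (fa < 0 && fa > -1e-9) fa <- 0
  fa
}

#' Directional apparent kurtosis
#'
#' K_app(n) = (MD^2 / D(n)^2) * W(n), the directional kurtosis consistent
#' with the MD^2-scaled kurtosis term of the signal model. Directions with
#' D(n) <= 0 are undefined and return NA.
#'
#' @param D a `diffusion_tensor`.
#' @param W a `kurtosis_tensor`.
#' @param n unit direction (length-3 vector) or matrix of directions (rows).
#' @return Numeric K_app per direction (NA where undefined).
#' @export
apparent_kurtosis <- function(D, W, n) {
  dirs <- rbind(n, deparse.level = 0)
  dn <- dt_project(dirs, D)
  wn <- kt_project(dirs, W)
  mdv <- mean_diffusivity(D)
  out <- (mdv^2 / dn^2) * wn
  out[dn <= 0] <- NA_real_
  out
}

#' Mean kurtosis
#'
#' Weighted average of the directional apparent kurtosis over a spherical
#' quadrature (default: the shared 250-direction repulsion set). Undefined
#' directions are excluded with weight renormalization; the result is NA if
#' every direction is undefined.
#'
#' @param D a `diffusion_tensor`.
#' @param W a `kurtosis_tensor`.
#' @param quadrature a `sphere_quadrature`; default [default_quadrature()].
#' @return Scalar MK (dimensionless).
#' @export
mean_kurtosis <- function(D, W, quadrature = default_quadrature()) {
  stopifnot(inherits(quadrature, "sphere_quadrature"))
  k <- apparent_kurtosis(D, W, quadrature$directions)
  ok <- !is.na(k)
  if (!any(ok)) return(NA_real_)
  w <- quadrature$weights[ok]
  sum(w * k[ok]) / sum(w)
}

#' Derive MK/FA/MD/S0 maps from a fitted volume
#'
#' Applies the three scalar metrics voxelwise to a [fit_volume()] result.
#' MD is reported on the x 10^-3 mm^2/s scale. Voxels flagged rank-deficient
#' or negative-eigenvalue by the fit become NA sentinels in all maps.
#'
#' @param fit a `dki_fit_volume`.
#' @param quadrature quadrature for MK; default [default_quadrature()].
#' @return A list of class `parameter_maps`: 3D arrays `mk`, `fa`, `md`
#'   (x 10^-3 mm^2/s), `s0`, plus grid metadata.
#' @export
maps_from_fit <- function(fit, quadrature = default_quadrature()) {
  stopifnot(inherits(fit, "dki_fit_volume"))
  dims <- dim(fit$s0)
  n_vox <- prod(dims)
  d_flat <- matrix(fit$d, n_vox, 6)
  w_flat <- matrix(fit$w, n_vox, 15)
  # sentinel where unfitted or flagged rank-deficient (4) / negative-eigenvalue (1)
  bad <- !fit$fitted | bitwAnd(fit$flag_mask, 5L) > 0L
  ok <- which(fit$fitted & !bad)

  mk <- fa <- md <- rep(NA_real_, n_vox)
  if (length(ok)) {
    q2 <- quadform2_basis(quadrature$directions)
    q4 <- quadform4_basis(quadrature$directions)
    dn <- q2 %*% t(d_flat[ok, , drop = FALSE])        # ndir x nvox
    wn <- q4 %*% t(w_flat[ok, , drop = FALSE])
    mdv <- rowMeans(d_flat[ok, 1:3, drop = FALSE])    # per-voxel trace/3
    kapp <- sweep(wn / dn^2, 2, mdv^2, `*`)
    kapp[dn <= 0] <- NA
    wts <- quadrature$weights
    num <- colSums(ifelse(is.na(kapp), 0, kapp) * wts)
    den <- colSums((!is.na(kapp)) * wts)
    mk[ok] <- ifelse(den > 0, num / den, NA_real_)
    md[ok] <- mdv * 1e3
    fa[ok] <- vapply(ok, function(v)
      fractional_anisotropy(diffusion_tensor(d_flat[v, 1], d_flat[v, 2],
        d_flat[v, 3], d_flat[v, 4], d_flat[v, 5], d_flat[v, 6])), numeric(1))
  }
  shape3 <- function(x) array(x, dims)
  structure(list(mk = shape3(mk), fa = shape3(fa), md = shape3(md),
                 s0 = fit$s0, voxel_size = fit$voxel_size,
                 affine = fit$affine),
            class = "parameter_maps")
}
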