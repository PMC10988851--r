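test_that("design matrix encodes the log-linear kurtosis model", {
  sch <- study_scheme()
  X <- design_matrix(sch)
  expect_equal(dim(X), c(51L, 22L))
  # b = 0 row: intercept only
  b0 <- which(sch$bvals == 0)
  expect_equal(X[b0, ], c(1, rep(0, 21)), ignore_attr = TRUE)
  # direct substitution for n = (1, 0, 0), b = 800
  row <- gradient_scheme(c(0, 400, 800), rbind(0, c(1, 0, 0), c(1, 0, 0)))
  Xr <- design_matrix(row)[3, ]
  expected <- numeric(22); expected[1] <- 1
  expected[2] <- -800            # D_xx
  expected[8] <- 800^2 / 6       # V_xxxx
  expect_equal(Xr, expected, ignore_attr = TRUE)
  # the 51-volume scheme determines all 22 parameters
  expect_equal(qr(X)$rank, 22L)
})

test_that("forward model reduces to its closed-form limits", {
  sch <- study_scheme()
  D <- diffusion_tensor(1e-3, 1e-3, 1e-3)
  W0 <- kurtosis_tensor(numeric(15))
  s <- forward_signal(D, W0, 100, sch)
  expect_equal(s[sch$bvals == 0], 100)
  # Gaussian limit: mono-exponential decay
  expect_equal(s[sch$bvals == 800], rep(100 * exp(-0.8), 25), tolerance = 1e-12)
  # isotropic kurtosis at b = 800: exp(-0.8 + 0.64/6)
  sk <- forward_signal(D, kt_isotropic(), 1, sch)
  expect_equal(sk[sch$bvals == 800], rep(exp(-0.8 + 0.64 / 6), 25),
               tolerance = 1e-12)
  expect_equal(sk[sch$bvals == 800][1], 0.4999, tolerance = 1e-4)
  # unphysical parameters overflow the exponent
  expect_error(forward_signal(diffusion_tensor(1, 1, 1), W0, 1, sch),
               "unphysical")
})

test_that("noiseless fits invert the forward model to near machine precision", {
  sch <- study_scheme()
  set.seed(101)
  for (rep in 1:100) {
    tp <- random_tensor_pair()
    s0 <- stats::runif(1, 100, 2000)
    sig <- forward_signal(tp$D, tp$W, s0, sch)
    fit <- fit_voxel(sig, sch, "WLS")
    scale_d <- mean_diffusivity(tp$D)
    expect_lt(max(abs(as.numeric(fit$D) - as.numeric(tp$D))) / scale_d, 1e-6)
    expect_lt(max(abs(as.numeric(fit$W) - as.numeric(tp$W))) /
                max(1, max(abs(as.numeric(tp$W)))), 1e-6)
    expect_equal(fit$s0, s0, tolerance = 1e-6)
  }
})

test_that("Gaussian signals fit to zero kurtosis; OLS and WLS agree noiselessly", {
  sch <- study_scheme()
  D <- diffusion_tensor(2e-3, 1.2e-3, 0.9e-3, 1e-4, 0, 0)
  sig <- forward_signal(D, kurtosis_tensor(numeric(15)), 500, sch)
  fit <- fit_voxel(sig, sch, "WLS")
  expect_true(all(abs(as.numeric(fit$W)) < 1e-9))
  ols <- fit_voxel(sig, sch, "OLS")
  expect_equal(as.numeric(fit$D), as.numeric(ols$D), tolerance = 1e-9)
  expect_equal(as.numeric(fit$W), as.numeric(ols$W), tolerance = 1e-9)
})

test_that("fits are equivariant under rotation of tensors and scheme", {
  sch <- study_scheme()
  set.seed(77)
  cal <- calibrate_tensors(tissue_params(2.735, 0.444, 0.760, "OS"))
  for (rep in 1:5) {
    R <- random_rotation()
    Dr <- rotate_dt(cal$D, R)
    Wr <- rotate_kt(cal$W, R)
    sig <- forward_signal(Dr, Wr, 1000, sch)
    fit <- fit_voxel(sig, sch)
    expect_equal(as.numeric(fit$D), as.numeric(Dr), tolerance = 1e-6)
    expect_equal(as.numeric(fit$W), as.numeric(Wr), tolerance = 1e-6)
  }
})

test_that("rescaling s0 changes only the fitted s0", {
  sch <- study_scheme()
  cal <- calibrate_tensors(tissue_params(2.628, 0.748, 0.640, "IS"))
  f1 <- fit_voxel(forward_signal(cal$D, cal$W, 100, sch), sch)
  f2 <- fit_voxel(forward_signal(cal$D, cal$W, 1700, sch), sch)
  expect_equal(as.numeric(f1$D), as.numeric(f2$D), tolerance = 1e-9)
  expect_equal(as.numeric(f1$W), as.numeric(f2$W), tolerance = 1e-9)
  expect_equal(f2$s0 / f1$s0, 17, tolerance = 1e-9)
})

test_that("WLS is consistent at SNR 50: mean D components within 2% of truth", {
  sch <- study_scheme()
  cal <- calibrate_tensors(tissue_params(2.735, 0.444, 0.760, "OS"))
  sig <- forward_signal(cal$D, cal$W, 1000, sch)
  est <- matrix(0, 500, 6)
  for (k in 1:500)
    est[k, ] <- as.numeric(fit_voxel(add_rician_noise(sig, 20, seed = k), sch)$D)
  rel <- abs(colMeans(est) - as.numeric(cal$D)) / mean_diffusivity(cal$D)
  expect_true(all(rel < 0.02))
})

test_that("nonlinear oracle agrees noiselessly and wins in signal space", {
  sch <- study_scheme()
  cal <- calibrate_tensors(tissue_params(2.735, 0.444, 0.760, "OS"))
  sig <- forward_signal(cal$D, cal$W, 1000, sch)
  lin <- fit_voxel(sig, sch)
  nls <- nls_oracle_fit(sig, sch, lin)
  expect_equal(as.numeric(nls$D), as.numeric(lin$D),
               tolerance = 1e-6 * mean_diffusivity(cal$D) / 1e-3)
  expect_equal(as.numeric(nls$W), as.numeric(lin$W), tolerance = 1e-5)
  # Rician noise at SNR 20: NLS signal-space residual never exceeds the
  # log-space fit's signal-space residual
  sig_resid <- function(fit, s) {
    pred <- forward_signal(fit$D, fit$W, fit$s0, sch)
    sum((pred - s)^2)
  }
  for (k in 1:5) {
    noisy <- add_rician_noise(sig, 50, seed = 100 + k)
    lf <- fit_voxel(noisy, sch)
    nf <- nls_oracle_fit(noisy, sch, lf)
    expect_lte(sig_resid(nf, noisy), sig_resid(lf, noisy) * (1 + 1e-10))
  }
})

test_that("degenerate inputs are flagged, not hidden", {
  sch <- study_scheme()
  cal <- calibrate_tensors(tissue_params(2.735, 0.444, 0.760, "OS"))
  sig <- forward_signal(cal$D, cal$W, 1000, sch)
  expect_error(fit_voxel(c(sig[-1], NA), sch), "non-finite")
  sig2 <- sig; sig2[30] <- 0
  fit <- fit_voxel(sig2, sch)
  expect_true("clipped-signal" %in% fit$flags)
})

test_that("volume fits honor the mask and reproduce uniform phantoms", {
  sch <- study_scheme()
  ph <- simulate_phantom(phantom_spec(shape = c(8, 8, 6), snr = Inf, seed = 1), sch)
  fit <- fit_volume(ph$dwi, ph$labels)
  expect_identical(fit$fitted, ph$labels$labels > 0)
  expect_true(all(is.na(fit$s0[ph$labels$labels == 0])))
  # every voxel of one region fits to identical parameters
  is_vox <- which(ph$labels$labels == 3)
  d_flat <- matrix(fit$d, prod(dim(ph$labels$labels)), 6)
  spread <- apply(d_flat[is_vox, ], 2, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9 * mean_diffusivity(ph$truth$IS$D) + 1e-15))
  # shape mismatch
  bad_mask <- label_map(array(1L, c(4, 4, 4)))
  expect_error(fit_volume(ph$dwi, bad_mask), "does not match")
})
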