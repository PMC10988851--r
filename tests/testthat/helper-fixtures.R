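# Shared fixtures: the study acquisition scheme (b = 0/400/800, 25
# directions -> 51 volumes) and a few calibrated tensor pairs. Built once per
# test run; all generation is seeded.

study_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- build_scheme(25, c(0, 400, 800), seed = 7)
    sch
  }
})

# baseline control triples of the three kidney layers
baseline_targets <- function() {
  list(
    CO = tissue_params(3.163, 0.263, 0.857, "CO"),
    OS = tissue_params(2.735, 0.444, 0.760, "OS"),
    IS = tissue_params(2.628, 0.748, 0.640, "IS"))
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random plausible tensor pair: eigenvalues in [0.5, 3]e-3 mm^2/s, fully
# symmetric kurtosis tensor scaled to directional kurtosis in [0, 2]
random_tensor_pair <- function() {
  R <- random_rotation()
  lam <- sort(stats::runif(3, 0.5e-3, 3e-3), decreasing = TRUE)
  D <- rotate_dt(diffusion_tensor(lam[1], lam[2], lam[3]), R)
  # symmetric rank-4 perturbation from rank-one quartics
  w <- numeric(15)
  for (i in 1:3) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    w <- w + stats::runif(1, 0, 0.5) * quadform4_basis_for_tests(v)
  }
  W <- kurtosis_tensor(as.numeric(kt_isotropic()) * stats::runif(1, 0.3, 1) + w)
  # rescale so apparent kurtosis stays in [0, 2] over a probe direction set
  k <- apparent_kurtosis(D, W, probe_directions())
  hi <- max(abs(k))
  if (hi > 2) W <- kurtosis_tensor(as.numeric(W) * 2 / hi)
  list(D = D, W = W)
}

probe_directions <- local({
  dirs <- NULL
  function() {
    if (is.null(dirs)) dirs <<- repulsion_directions(60, seed = 11)
    dirs
  }
})

# per-component quartic monomials with multiplicities for a single direction
# (mirrors the package's internal kurtosis basis; kept here so test tensors
# are built without touching internals)
quadform4_basis_for_tests <- function(v) {
  kt <- kt_names()
  out <- numeric(15)
  comp <- c(x = v[1], y = v[2], z = v[3])
  for (r in seq_along(kt)) {
    letters4 <- strsplit(kt[r], "")[[1]]
    out[r] <- prod(comp[letters4])
  }
  out
}

# deterministic quasi-uniform sphere cover (Fibonacci lattice): the
# brute-force dense direction set used as the sphere-average oracle
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
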