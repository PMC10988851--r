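# Acquisition schemes: per-volume b-values and unit encoding directions.

#' Construct a gradient scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs n x 3 matrix of encoding directions; rows for b > 0 volumes
#'   must be unit vectors (tolerance 1e-6), b = 0 rows may be zero.
#' @param require_kurtosis if TRUE (default), validate that the scheme can
#'   determine a kurtosis fit: at least one b = 0 volume and at least two
#'   distinct nonzero shells.
#' @return An object of class `gradient_scheme` with elements `bvals`,
#'   `bvecs`, `n_volumes`.
#' @export
gradient_scheme <- function(bvals, bvecs, require_kurtosis = TRUE) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns (one unit vector per row)")
  if (length(bvals) != nrow(bvecs))
    stop("scheme length mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  if (any(bvals < 0)) stop("b-values must be nonnegative")
  nb <- bvals > 0
  norms <- sqrt(rowSums(bvecs^2))
  if (any(abs(norms[nb] - 1) > 1e-6))
    stop("nonzero-b directions must be unit vectors (|norm - 1| <= 1e-6)")
  if (require_kurtosis) {
    if (!any(bvals == 0))
      stop("scheme-underdetermined: at least one b = 0 volume is required")
    if (length(unique(bvals[nb])) < 2L)
      stop("scheme-underdetermined: >= 2 distinct nonzero shells are ",
           "required to separate diffusion from kurtosis")
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs),
                 n_volumes = length(bvals)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- sort(unique(x$bvals))
  cat("gradient_scheme:", x$n_volumes, "volumes; shells b =",
      paste(shells, collapse = "/"), "s/mm^2;",
      sum(x$bvals == 0), "b0 volume(s)\n")
  invisible(x)
}

#' Generate evenly spread half-sphere directions by electrostatic repulsion
#'
#' Places `n` points on the unit sphere with antipodal symmetry (each point
#' interacts with every other point and its antipode through an inverse-square
#' repulsion) and relaxes them iteratively from a seeded random start. This is
#' the standard construction for diffusion-encoding direction sets.
#'
#' @param n number of directions.
#' @param seed integer seed; the returned set is a deterministic function of
#'   (n, seed).
#' @param n_iter relaxation iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
repulsion_directions <- function(n, seed, n_iter = 200) {
  stopifnot(n >= 1)
  v <- local_seed(seed, {
    m <- matrix(stats::rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  })
  step <- 0.1
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      diff1 <- sweep(v[-i, , drop = FALSE], 2, v[i, ], FUN = function(a, b) b - a)
      diff2 <- sweep(-v[-i, , drop = FALSE], 2, v[i, ], FUN = function(a, b) b - a)
      d1 <- pmax(sqrt(rowSums(diff1^2)), 1e-6)
      d2 <- pmax(sqrt(rowSums(diff2^2)), 1e-6)
      force[i, ] <- colSums(diff1 / d1^3) + colSums(diff2 / d2^3)
    }
    # project force onto the tangent plane and take a damped step
    radial <- rowSums(force * v)
    tang <- force - radial * v
    v <- v + step * tang / max(1, max(sqrt(rowSums(tang^2))))
    v <- v / sqrt(rowSums(v^2))
    step <- step * 0.985
  }
  # canonical hemisphere (z >= 0; ties broken on y then x) for reproducibility
  flip <- v[, 3] < 0 | (v[, 3] == 0 & v[, 2] < 0) |
    (v[, 3] == 0 & v[, 2] == 0 & v[, 1] < 0)
  v[flip, ] <- -v[flip, , drop = FALSE]
  unname(v)
}

#' Build a multi-shell acquisition scheme
#'
#' One b = 0 volume followed by `n_directions` electrostatically spread
#' directions repeated on every nonzero shell (the same direction set on each
#' shell, as in a standard multi-shell kurtosis acquisition).
#'
#' @param n_directions number of encoding directions (>= 15; 15 unique
#'   kurtosis components must be determined).
#' @param shells b-values in s/mm^2; must contain 0 and at least two distinct
#'   positive values.
#' @param seed integer seed for the direction generator.
#' @return A `gradient_scheme` with `1 + n_directions * n_nonzero_shells`
#'   volumes.
#' @examples
#' sch <- build_scheme(25, c(0, 400, 800), seed = 7)
#' sch$n_volumes  # 51
#' @export
build_scheme <- function(n_directions, shells = c(0, 400, 800), seed = 1) {
  if (n_directions < 15)
    stop("insufficient-directions: need >= 15 directions to determine the ",
         "15 unique kurtosis components")
  shells <- as.numeric(shells)
  if (any(shells < 0)) stop("shells must be nonnegative")
  pos <- sort(unique(shells[shells > 0]))
  if (!any(shells == 0) || length(pos) < 2L)
    stop("scheme-underdetermined: shells must contain 0 and >= 2 distinct ",
         "positive b-values")
  dirs <- repulsion_directions(n_directions, seed)
  bvals <- c(0, rep(pos, each = n_directions))
  bvecs <- rbind(c(0, 0, 0), dirs[rep(seq_len(n_directions), length(pos)), ])
  gradient_scheme(bvals, bvecs)
}

#' Spherical quadrature for direction averages
#'
#' An equal-weight direction set used to average directional kurtosis over
#' orientations. The default mean-kurtosis quadrature is the 250-direction
#' seeded repulsion set returned by `default_quadrature()`.
#'
#' @param directions m x 3 matrix of unit vectors.
#' @param weights nonnegative weights summing to 1; equal by default.
#' @return An object of class `sphere_quadrature`.
#' @export
sphere_quadrature <- function(directions, weights = NULL) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L)
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-6)) stop("quadrature directions must be unit vectors")
  m <- nrow(directions)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights < 0))
    stop("weights must be nonnegative, one per direction")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  structure(list(directions = unname(directions), weights = as.numeric(weights)),
            class = "sphere_quadrature")
}

quadrature_cache <- new.env(parent = emptyenv())

#' @rdname sphere_quadrature
#' @param n number of directions in the default repulsion quadrature.
#' @param seed seed of the default quadrature (fixed so that every caller
#'   shares one direction set).
#' @export
default_quadrature <- function(n = 250, seed = 42) {
  key <- paste0("q", n, "_", seed)
  if (is.null(quadrature_cache[[key]])) {
    quadrature_cache[[key]] <- sphere_quadrature(repulsion_directions(n, seed))
  }
  quadrature_cache[[key]]
}

#' @rdname sphere_quadrature
#' @param scheme a `gradient_scheme`; builds the quadrature from its unique
#'   nonzero-b directions (the "average over acquired directions" convention).
#' @export
acquisition_quadrature <- function(scheme) {
  dirs <- unique(scheme$bvecs[scheme$bvals > 0, , drop = FALSE])
  sphere_quadrature(dirs)
}

# minimum pairwise angular separation (degrees, antipodally symmetric)
min_angular_separation <- function(dirs) {
  g <- abs(tcrossprod(dirs))
  diag(g) <- 0
  acos(pmin(1, max(g[upper.tri(g)]))) * 180 / pi
}
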