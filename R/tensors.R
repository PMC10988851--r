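# Tensor storage conventions used throughout the package.
#
# Diffusion tensor D (rank 2, symmetric): 6 unique components in the fixed
# order (xx, yy, zz, xy, xz, yz), units mm^2/s.
#
# Kurtosis tensor W (rank 4, fully symmetric, dimensionless under the
# mean-diffusivity-squared scaling): 15 unique components in lexicographic
# index order
#   xxxx, xxxy, xxxz, xxyy, xxyz, xxzz, xyyy, xyyz, xyzz, xzzz,
#   yyyy, yyyz, yyzz, yzzz, zzzz
# with permutation multiplicities 1,4,4,6,12,6,4,12,12,4,1,4,6,4,1.
# These orders are defined once here and used by every module.

DT_NAMES <- c("xx", "yy", "zz", "xy", "xz", "yz")

KT_INDEX <- matrix(c(
  1, 1, 1, 1,
  1, 1, 1, 2,
  1, 1, 1, 3,
  1, 1, 2, 2,
  1, 1, 2, 3,
  1, 1, 3, 3,
  1, 2, 2, 2,
  1, 2, 2, 3,
  1, 2, 3, 3,
  1, 3, 3, 3,
  2, 2, 2, 2,
  2, 2, 2, 3,
  2, 2, 3, 3,
  2, 3, 3, 3,
  3, 3, 3, 3), ncol = 4, byrow = TRUE)

KT_MULT <- c(1, 4, 4, 6, 12, 6, 4, 12, 12, 4, 1, 4, 6, 4, 1)

KT_NAMES <- apply(KT_INDEX, 1, function(i) paste(c("x", "y", "z")[i], collapse = ""))

#' Construct a diffusion tensor
#'
#' Stores the six unique components of a symmetric rank-2 diffusion tensor
#' in the package-wide order (xx, yy, zz, xy, xz, yz).
#'
#' @param xx,yy,zz,xy,xz,yz tensor components in mm^2/s.
#' @return A named numeric vector of class `diffusion_tensor`.
#' @examples
#' diffusion_tensor(1e-3, 1e-3, 1e-3)   # isotropic, MD = 1e-3 mm^2/s
#' @export
diffusion_tensor <- function(xx, yy, zz, xy = 0, xz = 0, yz = 0) {
  d <- c(xx, yy, zz, xy, xz, yz)
  stopifnot(is.numeric(d), length(d) == 6L, all(is.finite(d)))
  names(d) <- DT_NAMES
  structure(d, class = "diffusion_tensor")
}

#' Construct a kurtosis tensor
#'
#' Stores the fifteen unique components of a fully symmetric rank-4 kurtosis
#' tensor in lexicographic index order (see `kt_names()`).
#'
#' @param w numeric vector of length 15.
#' @return A named numeric vector of class `kurtosis_tensor`.
#' @export
kurtosis_tensor <- function(w) {
  stopifnot(is.numeric(w), length(w) == 15L, all(is.finite(w)))
  names(w) <- KT_NAMES
  structure(as.numeric(w), names = KT_NAMES, class = "kurtosis_tensor")
}

#' @rdname kurtosis_tensor
#' @export
kt_names <- function() KT_NAMES

#' Isotropic kurtosis tensor with unit directional kurtosis
#'
#' Returns the fully symmetric rank-4 tensor whose directional projection
#' W(n) equals 1 for every unit direction n:
#' W_ijkl = (d_ij d_kl + d_ik d_jl + d_il d_jk) / 3.
#'
#' @return A `kurtosis_tensor`.
#' @export
kt_isotropic <- function() {
  w <- numeric(15)
  w[c(1, 11, 15)] <- 1          # xxxx, yyyy, zzzz
  w[c(4, 6, 13)] <- 1 / 3      # xxyy, xxzz, yyzz
  kurtosis_tensor(w)
}

# 3x3 symmetric matrix <-> 6-vector
dt_to_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

dt_from_matrix <- function(m) {
  diffusion_tensor(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# full 3x3x3x3 array <-> 15-vector (used by rotation utilities and tests)
kt_to_array <- function(w15) {
  arr <- array(0, c(3, 3, 3, 3))
  for (r in seq_len(15)) {
    idx <- KT_INDEX[r, ]
    perms <- unique(perms4(idx))
    for (p in seq_len(nrow(perms))) {
      arr[perms[p, 1], perms[p, 2], perms[p, 3], perms[p, 4]] <- w15[r]
    }
  }
  arr
}

kt_from_array <- function(arr) {
  kurtosis_tensor(arr[KT_INDEX])
}

# all 24 permutations of a length-4 index (rows; duplicates retained)
perms4 <- function(x) {
  p <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  matrix(x[p], ncol = 4)
}

#' Rotate diffusion and kurtosis tensors
#'
#' Applies a rotation matrix R to the stored unique components:
#' D' = R D R^T for the rank-2 tensor and
#' W'_ijkl = sum R_ia R_jb R_kc R_ld W_abcd for the rank-4 tensor.
#'
#' @param d6 a `diffusion_tensor`.
#' @param w15 a `kurtosis_tensor`.
#' @param R a 3x3 rotation matrix.
#' @return The rotated tensor in the same storage convention.
#' @export
rotate_dt <- function(d6, R) {
  dt_from_matrix(R %*% dt_to_matrix(d6) %*% t(R))
}

#' @rdname rotate_dt
#' @export
rotate_kt <- function(w15, R) {
  arr <- kt_to_array(w15)
  # contract one index at a time
  for (ax in 1:4) {
    arr <- apply(arr, setdiff(1:4, ax), function(v) as.numeric(R %*% v))
    arr <- aperm(arr, append(2:4, 1, after = ax - 1))
  }
  kt_from_array(arr)
}

# directional quadratic/quartic forms ------------------------------------

# rows of `dirs` are unit vectors; returns the design blocks so that
# D(n) = q2 %*% d6 and W(n) = q4 %*% w15
quadform2_basis <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(x * x, y * y, z * z, 2 * x * y, 2 * x * z, 2 * y * z)
}

quadform4_basis <- function(dirs) {
  out <- matrix(0, nrow(dirs), 15)
  for (r in seq_len(15)) {
    idx <- KT_INDEX[r, ]
    out[, r] <- KT_MULT[r] *
      dirs[, idx[1]] * dirs[, idx[2]] * dirs[, idx[3]] * dirs[, idx[4]]
  }
  out
}

#' Directional tensor projections
#'
#' `dt_project()` evaluates D(n) = sum n_i n_j D_ij and `kt_project()`
#' evaluates W(n) = sum n_i n_j n_k n_l W_ijkl for unit directions n.
#'
#' @param dirs matrix with one unit direction per row (n x 3).
#' @param d6 a `diffusion_tensor`.
#' @param w15 a `kurtosis_tensor`.
#' @return Numeric vector, one projection per direction.
#' @export
dt_project <- function(dirs, d6) {
  drop(quadform2_basis(rbind(dirs, deparse.level = 0)) %*% as.numeric(d6))
}

#' @rdname dt_project
#' @export
kt_project <- function(dirs, w15) {
  drop(quadform4_basis(rbind(dirs, deparse.level = 0)) %*% as.numeric(w15))
}

# run expr with a temporary RNG state seeded at `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
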