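#' Sample random rotation triples
#'
#' Draws `n` rotation triples, each three independent angles uniform on
#' `[0, range_max]` degrees, applied about the y-, x- and z-axis (in that
#' order, about fixed world axes). `range_max = 90` emulates the randomly
#' oriented structures of woven bone; `range_max = 22.5` the nearly
#' longitudinal lacunae of parallel-fibred bone.
#'
#' Draws come from the current R random number generator, so results are
#' reproducible under [set.seed()].
#'
#' @param n Number of triples to draw.
#' @param range_max Upper bound of the sampling range in degrees (> 0).
#' @return A tibble with columns `ry`, `rx`, `rz` (degrees).
#' @examples
#' set.seed(1)
#' sample_rotations(3)
#' @export
sample_rotations <- function(n = 1, range_max = 90) {
  if (!is.numeric(range_max) || length(range_max) != 1 || !is.finite(range_max) ||
      range_max <= 0) {
    abort("`range_max` must be a single positive number.")
  }
  if (n < 1) abort("`n` must be at least 1.")
  tibble(
    ry = stats::runif(n, 0, range_max),
    rx = stats::runif(n, 0, range_max),
    rz = stats::runif(n, 0, range_max)
  )
}

#' Rotation matrix for a y-x-z rotation triple
#'
#' Composes the three elemental right-handed rotations about the fixed world
#' y-, x- and z-axes, applied in that order, i.e. `R = Rz(rz) Rx(rx) Ry(ry)`.
#'
#' @param ry,rx,rz Angles in degrees about the y-, x- and z-axis.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotation_matrix(90, 0, 0) %*% c(0, 0, 1) # maps z to x
#' @export
rotation_matrix <- function(ry, rx, rz) {
  stopifnot(is.finite(ry), is.finite(rx), is.finite(rz))
  d <- pi / 180
  cy <- cos(ry * d); sy <- sin(ry * d)
  cx <- cos(rx * d); sx <- sin(rx * d)
  cz <- cos(rz * d); sz <- sin(rz * d)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Rx %*% Ry
}

# fold a line direction angle (degrees) into the acute range [0, 90]
fold_acute <- function(angle) {
  a <- angle %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Ground-truth orientation angles for rotated phantoms
#'
#' Applies each rotation triple to the initial shape axis (the canal axis of
#' a cylinder or the major axis of a lacunar ellipsoid, along z by default)
#' and derives the two orientation angles used throughout the package:
#'
#' * `omega_true`, the longitudinal angle: the elevation of the axis relative
#'   to the transverse plane, `asin(|v_z|)` in degrees, so that 90 deg means
#'   parallel to the bone's long axis and 0 deg transverse;
#' * `theta_true`, the radial angle: the acute angle between the axis
#'   projected into the transverse plane and the x-axis (the phantom's bone
#'   surface tangent), in `[0, 90]`. It is undefined (`NA`) when the
#'   transverse projection vanishes (a perfectly longitudinal axis).
#'
#' @param rotations A data frame with columns `ry`, `rx`, `rz` (degrees).
#' @param initial_axis Unit 3-vector: the unrotated shape axis.
#' @return `rotations` with columns `axis_x`, `axis_y`, `axis_z`,
#'   `omega_true`, `theta_true` added.
#' @examples
#' ground_truth_angles(tibble::tibble(ry = 0, rx = 0, rz = 0))
#' @export
ground_truth_angles <- function(rotations, initial_axis = c(0, 0, 1)) {
  nrm <- sqrt(sum(initial_axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) abort("`initial_axis` must be non-zero.")
  u <- initial_axis / nrm
  vs <- purrr::pmap(
    list(rotations$ry, rotations$rx, rotations$rz),
    function(ry, rx, rz) drop(rotation_matrix(ry, rx, rz) %*% u)
  )
  vx <- purrr::map_dbl(vs, 1)
  vy <- purrr::map_dbl(vs, 2)
  vz <- purrr::map_dbl(vs, 3)
  omega <- asin(pmin(1, abs(vz))) * 180 / pi
  tnorm <- sqrt(vx^2 + vy^2)
  theta <- ifelse(tnorm < 1e-9, NA_real_, fold_acute(atan2(vy, vx) * 180 / pi))
  dplyr::mutate(
    as_tibble(rotations),
    axis_x = vx, axis_y = vy, axis_z = vz,
    omega_true = omega, theta_true = theta
  )
}
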