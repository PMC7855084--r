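#' Vascular-canal phantom: an elliptic cylinder
#'
#' Defines a canal phantom as an elliptic cylinder of fixed minor diameter
#' with its midpoint at the centre of a cubic voxel domain. The unrotated
#' cylinder lies along the y-axis (a circumferential canal in the image
#' frame), with the major cross-sectional axis along x and the minor along
#' z; `aspect_ratio` scales the major axis
#' (`major diameter = diameter * aspect_ratio`), so `aspect_ratio = 1` is a
#' circular canal.
#'
#' With this starting orientation the three rotations map the set angles
#' directly onto the two orientation angles (`omega_true = rx`,
#' `theta_true = 90 - rz`), so a cohort rotated uniformly covers both set
#' angles uniformly over `[0, 90]` - the natural design for validating an
#' orientation estimator over its whole range.
#'
#' All lengths are in voxel units (one model unit per voxel edge).
#'
#' @param aspect_ratio Cross-sectional aspect ratio (>= 1).
#' @param rotation A one-row data frame (or named list) with `ry`, `rx`, `rz`
#'   in degrees, e.g. one row of [sample_rotations()].
#' @param length Cylinder length in voxels.
#' @param diameter Minor cross-sectional diameter in voxels.
#' @param domain_edge Edge length of the cubic voxel domain.
#' @return A `phantom_spec` object.
#' @examples
#' cylinder_spec(1.5, list(ry = 30, rx = 10, rz = 45))
#' @export
cylinder_spec <- function(aspect_ratio = 1, rotation = list(ry = 0, rx = 0, rz = 0),
                          length = 400, diameter = 10, domain_edge = 500) {
  if (aspect_ratio < 1) abort("`aspect_ratio` must be >= 1.")
  rot <- as.list(rotation)[c("ry", "rx", "rz")]
  gt <- ground_truth_angles(tibble(ry = rot$ry, rx = rot$rx, rz = rot$rz),
                            initial_axis = c(0, 1, 0))
  structure(
    list(
      kind = "cylinder",
      rotation = rot,
      # body-frame semi-extents: (major cross semi-axis, minor, half-length)
      semi = c(diameter / 2 * aspect_ratio, diameter / 2, length / 2),
      # body basis: major cross axis along x, minor along z, cylinder axis y
      body_basis = cbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
      aspect_ratio = aspect_ratio,
      length = length,
      diameter = diameter,
      domain_edge = domain_edge,
      voxel_size = 1,
      axis = c(gt$axis_x, gt$axis_y, gt$axis_z),
      omega_true = gt$omega_true,
      theta_true = gt$theta_true,
      volume_true = NA_real_
    ),
    class = "phantom_spec"
  )
}

# voxel axis lengths used for the three nominal lacunar imaging resolutions;
# the effective voxel size is (full major axis) / (major axis in voxels)
lacuna_voxel_table <- function() {
  tibble(
    nominal = c(1.6, 0.8, 0.33),
    major_vox = c(9.375, 18.75, 45),
    minor_vox = c(3.125, 6.25, 15)
  )
}

#' Osteocyte-lacuna phantom: a 3:1:1 prolate spheroid
#'
#' Defines a lacunar phantom as a prolate spheroid with full axes
#' 15 x 5 x 5 um (analytic volume `(4/3) pi 7.5 * 2.5^2` ~ 196.35 um^3),
#' centred in a cubic voxel domain and rendered at one of three nominal
#' voxel sizes. The unrotated major axis lies along z. For the three nominal
#' sizes the axis lengths in voxels are 9.375 x 3.125 x 3.125 (1.6 um),
#' 18.75 x 6.25 x 6.25 (0.8 um) and 45 x 15 x 15 (0.33 um); volumes are
#' converted back to um^3 with the effective voxel size implied by those axis
#' lengths (15 um / major axis in voxels; exactly 1/3 um for the nominal
#' 0.33 um case). Other voxel sizes are converted exactly.
#'
#' @param voxel_size Nominal voxel size in um.
#' @param rotation A one-row data frame (or named list) with `ry`, `rx`, `rz`.
#' @param domain_edge Edge length of the cubic voxel domain, in voxels.
#' @param full_axes Full axis lengths in um (major, minor, minor).
#' @return A `phantom_spec` object.
#' @examples
#' ellipsoid_spec(0.8, list(ry = 10, rx = 5, rz = 0))
#' @export
ellipsoid_spec <- function(voxel_size = 1.6, rotation = list(ry = 0, rx = 0, rz = 0),
                           domain_edge = 50, full_axes = c(15, 5, 5)) {
  if (voxel_size <= 0) abort("`voxel_size` must be positive.")
  tab <- lacuna_voxel_table()
  hit <- which(abs(tab$nominal - voxel_size) < 1e-9)
  if (length(hit) == 1) {
    semi <- c(tab$minor_vox[hit], tab$minor_vox[hit], tab$major_vox[hit]) / 2
    vs_eff <- full_axes[1] / tab$major_vox[hit]
  } else {
    semi <- c(full_axes[2], full_axes[3], full_axes[1]) / (2 * voxel_size)
    vs_eff <- voxel_size
  }
  rot <- as.list(rotation)[c("ry", "rx", "rz")]
  gt <- ground_truth_angles(tibble(ry = rot$ry, rx = rot$rx, rz = rot$rz))
  structure(
    list(
      kind = "ellipsoid",
      rotation = rot,
      semi = semi, # body-frame semi-axes in voxels, major along e3 (z)
      body_basis = diag(3),
      domain_edge = domain_edge,
      voxel_size = vs_eff,
      nominal_voxel_size = voxel_size,
      axis = c(gt$axis_x, gt$axis_y, gt$axis_z),
      omega_true = gt$omega_true,
      theta_true = gt$theta_true,
      volume_true = 4 / 3 * pi * prod(full_axes / 2)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s, domain %d^3, rotation (ry, rx, rz) = (%.2f, %.2f, %.2f) deg\n",
    x$kind, x$domain_edge, x$rotation$ry, x$rotation$rx, x$rotation$rz
  ))
  cat(sprintf(
    "  omega_true = %.2f deg, theta_true = %s\n", x$omega_true,
    if (is.na(x$theta_true)) "undefined" else sprintf("%.2f deg", x$theta_true)
  ))
  invisible(x)
}

#' Voxelise a phantom with partial-volume occupancy
#'
#' Renders the implicit surface of a phantom into a grey-level voxel volume
#' whose values are occupancy fractions in `[0, 1]`: the fraction of
#' `supersampling^3` regularly spaced sub-voxel points falling inside the
#' rotated solid. Voxels far from the surface are classified whole, so only a
#' one-voxel boundary shell is supersampled. Evaluation is restricted to the
#' axis-aligned bounding box of the rotated shape plus a two-voxel margin;
#' the result records its offset within the full domain.
#'
#' @param spec A [cylinder_spec()] or [ellipsoid_spec()].
#' @param supersampling Sub-voxel subdivisions per voxel edge (>= 1).
#' @return A `voxel_volume` object (grey).
#' @examples
#' v <- voxelise(ellipsoid_spec(1.6, list(ry = 20, rx = 40, rz = 10)))
#' range(v$values)
#' @export
voxelise <- function(spec, supersampling = 5) {
  stopifnot(inherits(spec, "phantom_spec"), supersampling >= 1)
  R <- rotation_matrix(spec$rotation$ry, spec$rotation$rx, spec$rotation$rz)
  frame <- R %*% spec$body_basis # world directions of the body axes
  edge <- spec$domain_edge
  centre <- rep(edge / 2, 3)

  # support extents of the rotated body along each world axis
  e1 <- frame[, 1]; e2 <- frame[, 2]; e3 <- frame[, 3]
  s <- spec$semi
  ext <- if (spec$kind == "cylinder") {
    abs(e3) * s[3] + sqrt((s[1] * e1)^2 + (s[2] * e2)^2)
  } else {
    sqrt((s[1] * e1)^2 + (s[2] * e2)^2 + (s[3] * e3)^2)
  }
  lo <- floor(centre - ext) - 2
  hi <- ceiling(centre + ext) + 2
  if (any(lo < 0) || any(hi > edge)) {
    warn("Phantom exceeds the voxel domain; clipping to the domain.")
    lo <- pmax(lo, 0)
    hi <- pmin(hi, edge)
  }
  vals <- voxelise_cpp(
    if (spec$kind == "cylinder") 0L else 1L,
    frame, centre, s, as.integer(lo), as.integer(hi), as.integer(supersampling)
  )
  new_voxel_volume(vals, dim_full = rep(edge, 3), offset = as.integer(lo),
                   voxel_size = spec$voxel_size)
}

new_voxel_volume <- function(values, dim_full, offset, voxel_size,
                             binary = FALSE, threshold = NULL) {
  structure(
    list(values = values, dim_full = as.integer(dim_full),
         offset = as.integer(offset), voxel_size = voxel_size,
         binary = binary, threshold = threshold),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_volume> %s, crop %d x %d x %d of domain %d x %d x %d, voxel %.4g um\n",
    if (x$binary) "binary" else "grey", d[1], d[2], d[3],
    x$dim_full[1], x$dim_full[2], x$dim_full[3], x$voxel_size
  ))
  invisible(x)
}

#' Foreground voxel count of a binary volume
#' @param vol A binary `voxel_volume`.
#' @return Number of foreground voxels.
#' @export
foreground_count <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  sum(vol$values > 0)
}

#' Coordinates of foreground voxel centres
#'
#' @param vol A binary `voxel_volume`.
#' @return A matrix with columns x, y, z: voxel-centre coordinates in the
#'   full domain (voxel units, centres at integer + 0.5).
#' @export
foreground_coords <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  idx <- which(vol$values > 0, arr.ind = TRUE)
  sweep(unname(idx) - 0.5, 2, vol$offset, "+")
}
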