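#' Generate a phantom cohort with known ground truth
#'
#' Draws `n` independent random rotations and builds the corresponding
#' phantom specifications, returning a manifest of the whole cohort. One
#' master seed controls the cohort; each phantom gets its own derived seed
#' (`seed + index - 1`), so any single phantom can be regenerated from its
#' manifest row alone and a cohort regenerates identically under the same
#' seed.
#'
#' The defaults are the study conditions of the validation experiment:
#' cylinders of length 400 and minor diameter 10 voxels in a 500^3 domain,
#' rotated uniformly on (0, 90) degrees; ellipsoids of 15 x 5 x 5 um in a
#' 50^3 domain, rotated on (0, 90) ("woven") or (0, 22.5)
#' ("parallel_fibred") degrees; 100 phantoms per condition.
#'
#' @param kind `"cylinder"` or `"ellipsoid"`.
#' @param n Number of phantoms.
#' @param seed Master seed (integer).
#' @param aspect_ratio Cylinder cross-sectional aspect ratio.
#' @param voxel_size Ellipsoid nominal voxel size in um.
#' @param alignment Ellipsoid rotation range: `"woven"` (0-90 deg) or
#'   `"parallel_fibred"` (0-22.5 deg).
#' @param length,diameter,domain_edge Cylinder geometry in voxels (the
#'   ellipsoid domain is fixed by `ellipsoid_domain`).
#' @param ellipsoid_domain Ellipsoid domain edge in voxels.
#' @param supersampling Sub-voxel sampling used when the cohort is rendered.
#' @param dir If non-`NULL`, render every phantom and write it as a
#'   multi-page 8-bit TIFF stack under `dir` (pattern
#'   `<kind>_<condition>_<index>.tif`), plus a `manifest.csv`.
#' @return The manifest: a tibble with one row per phantom (index, seed,
#'   rotation triple, ground truth, condition columns, and file path when
#'   written).
#' @examples
#' generate_cohort("ellipsoid", n = 3, seed = 1, voxel_size = 1.6)
#' @export
generate_cohort <- function(kind = c("cylinder", "ellipsoid"), n = 100, seed = 1,
                            aspect_ratio = 1, voxel_size = 1.6,
                            alignment = c("woven", "parallel_fibred"),
                            length = 400, diameter = 10, domain_edge = 500,
                            ellipsoid_domain = 50, supersampling = 5,
                            dir = NULL) {
  kind <- match.arg(kind)
  alignment <- match.arg(alignment)
  stopifnot(n >= 1)
  range_max <- if (kind == "ellipsoid" && alignment == "parallel_fibred") 22.5 else 90
  init_axis <- if (kind == "cylinder") c(0, 1, 0) else c(0, 0, 1)
  rows <- purrr::map(seq_len(n), function(i) {
    phantom_seed <- as.integer(seed + i - 1)
    rot <- withr::with_seed(phantom_seed, sample_rotations(1, range_max))
    gt <- ground_truth_angles(rot, initial_axis = init_axis)
    tibble(
      index = i, seed = phantom_seed,
      ry = rot$ry, rx = rot$rx, rz = rot$rz,
      omega_true = gt$omega_true, theta_true = gt$theta_true
    )
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$kind <- kind
  manifest$supersampling <- supersampling
  if (kind == "cylinder") {
    manifest$aspect_ratio <- aspect_ratio
    manifest$length <- length
    manifest$diameter <- diameter
    manifest$domain_edge <- domain_edge
    manifest$volume_true <- NA_real_
    condition <- sprintf("ar%s", gsub("[.]", "p", format(aspect_ratio)))
  } else {
    manifest$voxel_size <- voxel_size
    manifest$alignment <- alignment
    manifest$domain_edge <- ellipsoid_domain
    manifest$volume_true <- ellipsoid_spec(voxel_size)$volume_true
    condition <- sprintf("%s_vs%s", alignment, gsub("[.]", "p", format(voxel_size)))
  }
  manifest$path <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      spec <- phantom_from_manifest(manifest[i, ])
      vol <- binarise_volume(voxelise(spec, supersampling))
      p <- file.path(dir, sprintf("%s_%s_%03d.tif", kind, condition, i))
      write_stack(vol, p)
      manifest$path[i] <- p
    }
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  manifest
}

#' Rebuild a phantom specification from a manifest row
#'
#' @param row One row of a [generate_cohort()] manifest.
#' @return A `phantom_spec`.
#' @export
phantom_from_manifest <- function(row) {
  rot <- list(ry = row$ry, rx = row$rx, rz = row$rz)
  if (row$kind == "cylinder") {
    cylinder_spec(row$aspect_ratio, rot, length = row$length,
                  diameter = row$diameter, domain_edge = row$domain_edge)
  } else {
    ellipsoid_spec(row$voxel_size, rot, domain_edge = row$domain_edge)
  }
}

#' Analyse a phantom cohort with the 2D and 3D estimators
#'
#' The cohort-level driver. Each phantom is regenerated from its manifest
#' row, voxelised, binarised, and analysed:
#'
#' * cylinders: the transverse mid-slice moment ellipse gives the 2D angle
#'   estimates (`omega_2d = asin(b/a)`, `theta_2d` vs the x-axis tangent);
#'   3D skeletonisation and the longest straight branch between nodes give
#'   `omega_3d` and `theta_3d`;
#' * ellipsoids: the xy and xz mid-slice ellipses give the single-slice
#'   (prolate spheroid) and two-slice (triaxial) volume estimates, and the
#'   moment ellipsoid fit of the full region gives the 3D estimate, plus
#'   the post-threshold foreground voxel count.
#'
#' Phantoms are processed one at a time, so memory stays bounded for large
#' domains.
#'
#' @param manifest A [generate_cohort()] manifest.
#' @param methods Character subset of `c("2d", "3d")`.
#' @param binarise Binarisation rule, see [binarise_volume()].
#' @param progress Print a dot per phantom.
#' @return The manifest joined with per-phantom estimate columns.
#' @export
analyse_cohort <- function(manifest, methods = c("2d", "3d"),
                           binarise = "midpoint", progress = FALSE) {
  methods <- match.arg(methods, c("2d", "3d"), several.ok = TRUE)
  res <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    spec <- phantom_from_manifest(row)
    vol <- binarise_volume(voxelise(spec, row$supersampling), method = binarise)
    out <- if (row$kind == "cylinder") {
      # spurs from thinning are at most about one local radius long
      analyse_cylinder_phantom(vol, methods,
                               prune_len = row$diameter * row$aspect_ratio / 2 + 2)
    } else {
      analyse_ellipsoid_phantom(vol, methods)
    }
    if (progress) cat(".")
    out
  })
  if (progress) cat("\n")
  dplyr::bind_cols(manifest, dplyr::bind_rows(res))
}

analyse_cylinder_phantom <- function(vol, methods, prune_len = 16) {
  out <- tibble(.rows = 1)
  if ("2d" %in% methods) {
    slc <- extract_slices(vol)
    obj <- analyse_slice_2d(slc$xy, pixel_size = vol$voxel_size)
    obj <- obj[obj$ok, , drop = FALSE]
    if (nrow(obj) == 0) {
      out$omega_2d <- NA_real_
      out$theta_2d <- NA_real_
      out$a_2d <- NA_real_
      out$b_2d <- NA_real_
    } else {
      main <- obj[which.max(obj$n_pixels), ]
      out$omega_2d <- main$omega_2d
      out$theta_2d <- main$theta_2d
      out$a_2d <- main$a
      out$b_2d <- main$b
    }
  }
  if ("3d" %in% methods) {
    sk <- prune_spurs(skeletonise_3d(vol), min_length = prune_len)
    graph <- analyse_skeleton(sk)
    br <- graph$branches
    br <- br[br$euclidean_length > 0, , drop = FALSE]
    if (nrow(br) == 0) {
      out$omega_3d <- NA_real_
      out$theta_3d <- NA_real_
      out$n_branches <- 0L
    } else {
      main <- branch_angles(br[which.max(br$euclidean_length), ])
      out$omega_3d <- main$omega_3d
      out$theta_3d <- main$theta_3d
      out$n_branches <- nrow(br)
    }
  }
  out
}

analyse_ellipsoid_phantom <- function(vol, methods) {
  out <- tibble(.rows = 1)
  out$n_foreground <- foreground_count(vol)
  if ("2d" %in% methods) {
    slc <- extract_slices(vol)
    fit_main <- function(img) {
      obj <- analyse_slice_2d(img, pixel_size = vol$voxel_size)
      obj <- obj[obj$ok, , drop = FALSE]
      if (nrow(obj) == 0) return(tibble(a = NA_real_, b = NA_real_, ok = FALSE))
      obj[which.max(obj$n_pixels), c("a", "b")] |> dplyr::mutate(ok = TRUE)
    }
    xy <- fit_main(slc$xy)
    xz <- fit_main(slc$xz)
    out$a_xy <- xy$a; out$b_xy <- xy$b
    out$a_xz <- xz$a; out$b_xz <- xz$b
    out$vol_xy <- if (xy$ok) 4 / 3 * pi * (xy$a / 2) * (xy$b / 2)^2 else NA_real_
    out$vol_xy_xz <- if (xy$ok && xz$ok) {
      4 / 3 * pi * (xz$a / 2) * (xy$a / 2) * (xy$b / 2)
    } else {
      NA_real_
    }
  }
  if ("3d" %in% methods) {
    regions <- label_regions_3d(vol)
    if (nrow(regions) == 0) {
      fit <- fit_ellipsoid_3d(matrix(numeric(), 0, 3), vol$voxel_size)
    } else {
      main <- regions$voxels[[which.max(regions$n_voxels)]]
      fit <- fit_ellipsoid_3d(main, vol$voxel_size)
    }
    out$r1 <- fit$r1; out$r2 <- fit$r2; out$r3 <- fit$r3
    out$vol_3d <- fit$volume
    out$fit_ok <- fit$fit_ok
  }
  out
}
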