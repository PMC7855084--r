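#' Label connected regions in a binary slice
#'
#' Connected-component labelling of a 2D binary image (8-connectivity by
#' default, the common particle-analysis convention). The background (zero
#' pixels) is excluded. Objects touching the image border are retained.
#'
#' @param img Binary matrix (logical or 0/1 numeric).
#' @param connectivity 8 or 4.
#' @return A tibble with one row per region: `region_id`, `n_pixels`, and a
#'   list-column `pixels` holding a two-column matrix of pixel-centre
#'   coordinates (x, y), with centres at integer + 0.5. The label matrix is
#'   attached as attribute `labels`.
#' @examples
#' img <- matrix(0, 8, 8); img[2:3, 2:3] <- 1; img[6:7, 6:7] <- 1
#' label_regions_2d(img)
#' @export
label_regions_2d <- function(img, connectivity = 8) {
  stopifnot(is.matrix(img), connectivity %in% c(4, 8))
  lab <- label_components_cpp(
    as.logical(img != 0), dim(img),
    if (connectivity == 8) 26L else 6L
  )
  ids <- sort(unique(lab[lab > 0]))
  res <- purrr::map(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    unname(idx) - 0.5
  })
  out <- tibble(
    region_id = as.integer(ids),
    n_pixels = purrr::map_int(res, nrow),
    pixels = res
  )
  attr(out, "labels") <- lab
  out
}

#' Fit the area-preserving moment ellipse of a pixel region
#'
#' Fits the standard particle-analysis ellipse: the ellipse with the same
#' centroid, the same normalised second central moments and the same area as
#' the pixel region. Pixels are treated as unit squares, so the moment of a
#' single pixel about its own centre (1/12 per axis) is included. The axis
#' ratio comes from the eigenvalues of the central moment matrix and the
#' absolute scale from area preservation
#' (`pi * (a/2) * (b/2) = n_pixels * pixel_size^2`).
#'
#' @param pixels Two-column matrix of pixel-centre coordinates (x, y), e.g.
#'   from [label_regions_2d()].
#' @param pixel_size Pixel edge length in um (1 for voxel units).
#' @return A one-row tibble: `a`, `b` (full major/minor axis lengths, in the
#'   units of `pixel_size`), `phi` (major-axis orientation in degrees,
#'   `[0, 180)`), `cx`, `cy` (centroid), `area`, `n_pixels`, `ok`. Degenerate
#'   regions (fewer than 3 pixels or collapsed moments) return `ok = FALSE`.
#' @examples
#' reg <- label_regions_2d(outer(1:40, 1:40, function(i, j) {
#'   (i - 20.5)^2 + (j - 20.5)^2 < 15^2
#' }) * 1)
#' fit_ellipse_moments(reg$pixels[[1]])
#' @export
fit_ellipse_moments <- function(pixels, pixel_size = 1) {
  n <- nrow(pixels)
  fail <- tibble(a = NA_real_, b = NA_real_, phi = NA_real_,
                 cx = NA_real_, cy = NA_real_,
                 area = n * pixel_size^2, n_pixels = n, ok = FALSE)
  if (is.null(n) || n < 3) return(fail)
  cx <- mean(pixels[, 1])
  cy <- mean(pixels[, 2])
  dx <- pixels[, 1] - cx
  dy <- pixels[, 2] - cy
  # central second moments of the union of unit pixel squares
  uxx <- mean(dx^2) + 1 / 12
  uyy <- mean(dy^2) + 1 / 12
  uxy <- mean(dx * dy)
  M <- matrix(c(uxx, uxy, uxy, uyy), 2, 2)
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  if (lam[2] <= 1e-12) return(fail)
  ratio <- sqrt(lam[1] / lam[2]) # a / b
  area <- n * pixel_size^2
  b <- 2 * sqrt(area / (pi * ratio))
  a <- ratio * b
  v <- e$vectors[, 1]
  phi <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  tibble(a = a, b = b, phi = phi,
         cx = cx * pixel_size, cy = cy * pixel_size,
         area = area, n_pixels = n, ok = TRUE)
}

#' Longitudinal angle from a section ellipse
#'
#' The section-based estimate of the longitudinal angle: a cylinder crossing
#' a transverse section at elevation omega leaves an elliptical cross
#' section whose minor/major axis ratio is `sin(omega)` (exactly, for a
#' circular cylinder), so `omega = asin(b / a)` in degrees. 90 deg means a
#' circular cross section (longitudinal canal), 0 deg an infinitely
#' elongated one (transverse canal).
#'
#' @param a,b Full major and minor axis lengths of the section ellipse
#'   (`a >= b > 0`). Vectorised.
#' @return Angle(s) in degrees in `[0, 90]`.
#' @examples
#' omega_from_ellipse(2, 1) # 30 degrees
#' @export
omega_from_ellipse <- function(a, b) {
  if (any(b > a + 1e-12, na.rm = TRUE)) abort("`b` must not exceed `a`.")
  if (any(c(a, b) <= 0, na.rm = TRUE)) abort("Axis lengths must be positive.")
  asin(pmin(1, b / a)) * 180 / pi
}

#' Radial angle from a section ellipse
#'
#' The acute angle between the major axis of the section ellipse and the
#' local tangent to the bone surface, folded into `[0, 90]`. For phantom
#' domains the tangent is the x-axis (`tangent_direction = 0`).
#'
#' @param phi Major-axis orientation in degrees (any real value).
#' @param tangent_direction Tangent direction in degrees.
#' @return Angle(s) in degrees in `[0, 90]`.
#' @examples
#' theta_from_ellipse(135, 0) # 45 degrees
#' @export
theta_from_ellipse <- function(phi, tangent_direction = 0) {
  fold_acute(phi - tangent_direction)
}

#' Separate lacunae from canals by section area
#'
#' Applies the 2D size rule separating osteocyte lacunae from vascular
#' canals: regions with physical area strictly greater than `cutoff`
#' (38 um^2 by default) are canals, the rest lacunae.
#'
#' @param regions A data frame with an `area` column in um^2 (e.g. ellipse
#'   fits from [fit_ellipse_moments()] with `pixel_size` in um).
#' @param cutoff Area cutoff in um^2 (exclusive).
#' @return `regions` with a `class_2d` column (`"canal"` or `"lacuna"`).
#' @export
separate_by_area_2d <- function(regions, cutoff = 38) {
  stopifnot(cutoff > 0)
  dplyr::mutate(
    regions,
    class_2d = ifelse(.data$area > cutoff, "canal", "lacuna")
  )
}

#' Mean lacunar volume from single transverse sections (prolate-spheroid rule)
#'
#' Estimates mean lacunar volume from one transverse section per lacuna,
#' modelling each lacuna as a prolate spheroid with the section's major
#' radius as polar radius: per-object volume
#' `(4/3) pi r1 r2^2` with `r1 = a / 2`, `r2 = b / 2`.
#'
#' @param ellipses Data frame of per-lacuna section ellipses with columns
#'   `a`, `b` in um (rows with `ok = FALSE`, if present, are skipped and
#'   counted).
#' @return A one-row tibble: `method`, `mean_volume`, `sd`, `n`, `n_skipped`.
#' @examples
#' mean_volume_xy(tibble::tibble(a = 15, b = 5, ok = TRUE))
#' @export
mean_volume_xy <- function(ellipses) {
  e <- drop_failed_fits(ellipses)
  if (nrow(e) == 0) abort("No successfully fitted ellipses to average.")
  v <- 4 / 3 * pi * (e$a / 2) * (e$b / 2)^2
  tibble(method = "xy_plane", mean_volume = mean(v), sd = sd(v),
         n = length(v), n_skipped = nrow(ellipses) - nrow(e))
}

#' Mean lacunar volume from two perpendicular sections (triaxial rule)
#'
#' Estimates mean lacunar volume from paired transverse (xy) and
#' perpendicular (xz) sections: per-object volume `(4/3) pi r1 r2 r3` with
#' `r1` the half major axis of the xz ellipse and `r2 >= r3` the half axes
#' of the xy ellipse. For phantoms the pairing is the same object's two
#' mid-slices; for ensembles where slices cannot be paired object-by-object
#' use `pairing = "cohort_mean"`, which combines the cohort-mean radii of
#' the two slice populations into a single volume estimate.
#'
#' @param xy_ellipses,xz_ellipses Data frames with columns `a`, `b` in um;
#'   paired row-by-row when `pairing = "object"`.
#' @param pairing `"object"` or `"cohort_mean"`.
#' @return A one-row tibble as in [mean_volume_xy()] (`sd` is `NA` for
#'   cohort-mean pairing).
#' @export
mean_volume_xy_xz <- function(xy_ellipses, xz_ellipses,
                              pairing = c("object", "cohort_mean")) {
  pairing <- match.arg(pairing)
  if (pairing == "cohort_mean") {
    xy <- drop_failed_fits(xy_ellipses)
    xz <- drop_failed_fits(xz_ellipses)
    if (nrow(xy) == 0 || nrow(xz) == 0) abort("No fitted ellipses to average.")
    v <- 4 / 3 * pi * mean(xz$a / 2) * mean(xy$a / 2) * mean(xy$b / 2)
    return(tibble(method = "xy_xz_plane", mean_volume = v, sd = NA_real_,
                  n = nrow(xy), n_skipped = 0L))
  }
  if (nrow(xy_ellipses) != nrow(xz_ellipses)) {
    abort("Object pairing requires equally many xy and xz ellipses.")
  }
  ok <- fit_ok_flag(xy_ellipses) & fit_ok_flag(xz_ellipses)
  if (!any(ok)) abort("No complete xy/xz pairs to average.")
  r1 <- xz_ellipses$a[ok] / 2
  r2 <- xy_ellipses$a[ok] / 2
  r3 <- xy_ellipses$b[ok] / 2
  v <- 4 / 3 * pi * r1 * r2 * r3
  tibble(method = "xy_xz_plane", mean_volume = mean(v), sd = sd(v),
         n = length(v), n_skipped = sum(!ok))
}

fit_ok_flag <- function(df) {
  if ("ok" %in% names(df)) df$ok & is.finite(df$a) & is.finite(df$b)
  else is.finite(df$a) & is.finite(df$b)
}

drop_failed_fits <- function(df) df[fit_ok_flag(df), , drop = FALSE]

#' Analyse all objects in a binary section
#'
#' The section-level driver: labels the connected regions of a binary slice,
#' fits the moment ellipse of each, derives the section-based orientation
#' angles and classifies each object as canal or lacuna by area.
#'
#' @param img Binary matrix.
#' @param pixel_size Pixel edge length in um.
#' @param tangent_direction Bone-surface tangent direction in degrees
#'   (0, the x-axis, for phantom domains).
#' @param connectivity Passed to [label_regions_2d()].
#' @param area_cutoff Canal/lacuna area cutoff in um^2.
#' @return A tibble with one row per object: ellipse parameters, `omega_2d`,
#'   `theta_2d`, and `class_2d`.
#' @export
analyse_slice_2d <- function(img, pixel_size = 1, tangent_direction = 0,
                             connectivity = 8, area_cutoff = 38) {
  regions <- label_regions_2d(img, connectivity)
  if (nrow(regions) == 0) {
    return(tibble(region_id = integer(), a = numeric(), b = numeric(),
                  phi = numeric(), cx = numeric(), cy = numeric(),
                  area = numeric(), n_pixels = integer(), ok = logical(),
                  omega_2d = numeric(), theta_2d = numeric(),
                  class_2d = character()))
  }
  fits <- purrr::map(regions$pixels, fit_ellipse_moments, pixel_size = pixel_size)
  out <- dplyr::bind_cols(regions[, "region_id"], dplyr::bind_rows(fits))
  out <- dplyr::mutate(
    out,
    omega_2d = ifelse(.data$ok, asin(pmin(1, .data$b / .data$a)) * 180 / pi,
                      NA_real_),
    theta_2d = ifelse(.data$ok, theta_from_ellipse(.data$phi, tangent_direction),
                      NA_real_)
  )
  separate_by_area_2d(out, cutoff = area_cutoff)
}
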