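#' Sensitivity of 2D and 3D orientation estimates to aspect ratio
#'
#' Summarises analysed cylinder cohorts into the orientation-agreement
#' table: for each angle (omega, theta) and aspect ratio, the r-squared of
#' estimated vs set angle and the mean difference (estimated minus set, so
#' systematic 2D underestimation of omega is negative), for the 2D mid-slice
#' method and the 3D skeleton method. Canals whose ground-truth radial angle
#' is undefined (no transverse projection) are excluded from the theta rows.
#'
#' @param cylinders Analysed cylinder cohorts from [analyse_cohort()],
#'   stacked over aspect ratios (must contain `aspect_ratio`, the ground
#'   truth columns and the 2D/3D estimate columns).
#' @return A tibble with one row per angle x aspect ratio: `r2_2d`,
#'   `diff_2d`, `r2_3d`, `diff_3d`, `n`.
#' @export
orientation_agreement_table <- function(cylinders) {
  if (nrow(cylinders) == 0) abort("No analysed cylinders supplied.")
  one <- function(df, truth, est) {
    keep <- is.finite(df[[truth]]) & is.finite(df[[est]])
    d <- df[keep, ]
    tibble(
      r2 = tryCatch(r_squared(d[[est]], d[[truth]]), error = function(e) NA_real_),
      diff = if (nrow(d)) mean(d[[est]] - d[[truth]]) else NA_real_,
      n = nrow(d)
    )
  }
  dplyr::bind_rows(lapply(split(cylinders, cylinders$aspect_ratio), function(df) {
    ar <- df$aspect_ratio[1]
    dplyr::bind_rows(
      dplyr::bind_cols(tibble(angle = "omega", aspect_ratio = ar, method = "2d"),
                       one(df, "omega_true", "omega_2d")),
      dplyr::bind_cols(tibble(angle = "omega", aspect_ratio = ar, method = "3d"),
                       one(df, "omega_true", "omega_3d")),
      dplyr::bind_cols(tibble(angle = "theta", aspect_ratio = ar, method = "2d"),
                       one(df, "theta_true", "theta_2d")),
      dplyr::bind_cols(tibble(angle = "theta", aspect_ratio = ar, method = "3d"),
                       one(df, "theta_true", "theta_3d"))
    )
  })) |>
    tidyr::pivot_wider(names_from = "method", values_from = c("r2", "diff", "n"),
                       names_glue = "{.value}_{method}") |>
    dplyr::rename(n = "n_2d") |>
    dplyr::select(-"n_3d")
}

#' Classification accuracy of 2D vs 3D orientation estimates
#'
#' Classifies every canal from its ground-truth angles and from its 2D and
#' 3D estimates, and tabulates per-category accuracy for each aspect ratio.
#' Only the three named categories (longitudinal, radial, laminar) are
#' reported; obliques have no accuracy row in the reference table.
#'
#' @inheritParams orientation_agreement_table
#' @return A tibble: `aspect_ratio`, `category`, `n_true`, `n_correct_3d`,
#'   `pct_correct_3d`, `n_correct_2d`, `pct_correct_2d`.
#' @export
classification_accuracy_table <- function(cylinders) {
  dplyr::bind_rows(lapply(split(cylinders, cylinders$aspect_ratio), function(df) {
    truth <- categorise(df$omega_true, df$theta_true)
    est2 <- categorise_estimates(df$omega_2d, df$theta_2d)
    est3 <- categorise_estimates(df$omega_3d, df$theta_3d)
    acc3 <- classification_accuracy(est3, truth)
    acc2 <- classification_accuracy(est2, truth)
    tibble(
      aspect_ratio = df$aspect_ratio[1],
      category = acc3$category,
      n_true = acc3$n_true,
      n_correct_3d = acc3$n_correct, pct_correct_3d = acc3$pct_correct,
      n_correct_2d = acc2$n_correct, pct_correct_2d = acc2$pct_correct
    )
  })) |>
    dplyr::filter(.data$category != "oblique")
}

#' Categorise estimated angles, tolerating undefined estimates
#'
#' Unlike [categorise()], which requires a defined radial angle for every
#' sub-longitudinal canal, an estimator may return `NA` angles (for example
#' the radial angle of a branch with a negligible transverse projection,
#' even when its estimated longitudinal angle falls below the longitudinal
#' threshold). Such canals cannot be placed in a theta-dependent category
#' and are returned as `NA`.
#'
#' @param omega,theta Estimated angles in degrees (may contain `NA`).
#' @return A factor with the [categorise()] levels, `NA` where the estimate
#'   cannot be categorised.
#' @export
categorise_estimates <- function(omega, theta) {
  ok <- is.finite(omega) & (is.finite(theta) | omega > 67.5)
  out <- rep(NA_character_, length(omega))
  out[ok] <- as.character(categorise(omega[ok], theta[ok]))
  factor(out, levels = c("longitudinal", "radial", "laminar", "oblique"))
}

#' Lacunar volume estimates by method, voxel size and alignment
#'
#' Summarises analysed ellipsoid cohorts into the lacunar-volume table: the
#' cohort mean and standard deviation of the single-slice (xy-plane),
#' two-slice (xy/xz-plane) and 3D ellipsoid-fit volume estimates, for each
#' voxel size and alignment mode, with fit-failure counts.
#'
#' @param ellipsoids Analysed ellipsoid cohorts from [analyse_cohort()],
#'   stacked over conditions (must contain `alignment` and `voxel_size`).
#' @return A tibble with one row per alignment x voxel size x method:
#'   `mean_volume`, `sd`, `n`, `n_failed`, `set_value`.
#' @export
lacunar_volume_table <- function(ellipsoids) {
  if (nrow(ellipsoids) == 0) abort("No analysed ellipsoids supplied.")
  dplyr::bind_rows(lapply(
    split(ellipsoids, list(ellipsoids$alignment, ellipsoids$voxel_size),
          drop = TRUE),
    function(df) {
      base <- tibble(alignment = df$alignment[1], voxel_size = df$voxel_size[1],
                     set_value = df$volume_true[1])
      row <- function(method, v, failed) {
        ok <- is.finite(v)
        dplyr::bind_cols(base, tibble(
          method = method, mean_volume = mean(v[ok]), sd = sd(v[ok]),
          n = sum(ok), n_failed = failed
        ))
      }
      dplyr::bind_rows(
        row("xy_plane", df$vol_xy, sum(!is.finite(df$vol_xy))),
        row("xy_xz_plane", df$vol_xy_xz, sum(!is.finite(df$vol_xy_xz))),
        row("ellipsoid_3d", df$vol_3d, sum(!df$fit_ok))
      )
    }
  )) |>
    dplyr::arrange(.data$alignment, dplyr::desc(.data$voxel_size), .data$method)
}

#' Assemble the full validation report
#'
#' Bundles the orientation-agreement, classification-accuracy and
#' lacunar-volume tables from analysed cohorts into one report object;
#' missing inputs yield explicitly absent (`NULL`) tables rather than being
#' skipped silently.
#'
#' @param cylinders Analysed cylinder cohorts (or `NULL`).
#' @param ellipsoids Analysed ellipsoid cohorts (or `NULL`).
#' @return A list of tibbles: `orientation`, `classification`, `volumes`.
#' @export
build_report <- function(cylinders = NULL, ellipsoids = NULL) {
  if (is.null(cylinders) && is.null(ellipsoids)) {
    abort("At least one analysed cohort is required.")
  }
  list(
    orientation = if (!is.null(cylinders)) orientation_agreement_table(cylinders),
    classification = if (!is.null(cylinders)) classification_accuracy_table(cylinders),
    volumes = if (!is.null(ellipsoids)) lacunar_volume_table(ellipsoids)
  )
}
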