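#' Orientation category of a canal
#'
#' Maps a (longitudinal angle omega, radial angle theta) pair to the four
#' canal orientation categories:
#'
#' * longitudinal: `omega > 67.5` (theta irrelevant, may be undefined);
#' * radial: `omega <= 67.5` and `theta > 67.5`;
#' * laminar: `omega <= 67.5` and `theta <= 22.5`;
#' * oblique: `omega <= 67.5` and `22.5 < theta <= 67.5` (excluded from the
#'   three named indices but kept in their denominator).
#'
#' Boundary values fall into the lower band (`omega = 67.5` is not
#' longitudinal; `theta = 22.5` is laminar), and a measured 0 is admitted
#' into its band (a perfectly transverse canal is valid). `theta = NA` is
#' only permitted for longitudinal canals.
#'
#' @param omega,theta Angles in degrees, `[0, 90]`; vectorised. `theta` may
#'   be `NA` where `omega > 67.5`.
#' @param omega_threshold,theta_lo,theta_hi Category thresholds in degrees.
#' @return A factor with levels longitudinal, radial, laminar, oblique.
#' @examples
#' categorise(c(80, 30, 30, 30), c(NA, 80, 10, 45))
#' @export
categorise <- function(omega, theta, omega_threshold = 67.5,
                       theta_lo = 22.5, theta_hi = 67.5) {
  stopifnot(length(omega) == length(theta))
  bad <- !is.na(omega) & (omega < 0 | omega > 90)
  if (any(bad)) abort("`omega` must lie in [0, 90].")
  if (any(!is.na(theta) & (theta < 0 | theta > 90))) {
    abort("`theta` must lie in [0, 90].")
  }
  if (any(is.na(theta) & omega <= omega_threshold)) {
    abort("Undefined `theta` is only permitted when omega exceeds the longitudinal threshold.")
  }
  out <- ifelse(
    omega > omega_threshold, "longitudinal",
    ifelse(theta > theta_hi, "radial",
           ifelse(theta <= theta_lo, "laminar", "oblique"))
  )
  factor(out, levels = c("longitudinal", "radial", "laminar", "oblique"))
}

#' Orientation indices of a canal population
#'
#' The longitudinal, radial and laminar indices are the proportions of the
#' canal network in each named category. Oblique canals are excluded from
#' the numerators but kept in the denominator, so the three indices need not
#' sum to 1. `indices_count()` weights each canal equally (the only option
#' for single-section data); `indices_length()` weights each skeleton branch
#' by its length, reducing the influence of short branches.
#'
#' @param categories Factor or character vector of categories from
#'   [categorise()].
#' @return A one-row tibble: `longitudinal_index`, `radial_index`,
#'   `laminar_index`, `oblique_fraction`, `weighting`, and `n` (count) or
#'   `total_length`.
#' @examples
#' indices_count(categorise(c(80, 30, 30, 30), c(NA, 80, 10, 45)))
#' @export
indices_count <- function(categories) {
  n <- length(categories)
  if (n == 0) abort("At least one canal is required.")
  tab <- table(factor(categories,
                      levels = c("longitudinal", "radial", "laminar", "oblique")))
  tibble(
    longitudinal_index = unname(tab["longitudinal"]) / n,
    radial_index = unname(tab["radial"]) / n,
    laminar_index = unname(tab["laminar"]) / n,
    oblique_fraction = unname(tab["oblique"]) / n,
    weighting = "count",
    n = n
  )
}

#' @rdname indices_count
#' @param branches Data frame of skeleton branches with a length column and
#'   a `category` column (or supply `categories`).
#' @param lengths Branch lengths (same order as `categories`); defaults to
#'   `branches$euclidean_length`.
#' @param categories Branch categories; defaults to `branches$category`.
#' @export
indices_length <- function(branches = NULL, lengths = branches$euclidean_length,
                           categories = branches$category) {
  if (length(lengths) == 0) abort("At least one branch is required.")
  stopifnot(length(lengths) == length(categories))
  tot <- sum(lengths)
  if (tot <= 0) abort("Total branch length must be positive.")
  f <- factor(categories,
              levels = c("longitudinal", "radial", "laminar", "oblique"))
  by_cat <- tapply(lengths, f, sum, default = 0)
  tibble(
    longitudinal_index = unname(by_cat["longitudinal"]) / tot,
    radial_index = unname(by_cat["radial"]) / tot,
    laminar_index = unname(by_cat["laminar"]) / tot,
    oblique_fraction = unname(by_cat["oblique"]) / tot,
    weighting = "length",
    total_length = tot
  )
}

#' Classification accuracy against ground truth
#'
#' For each ground-truth category, counts how many canals the estimator
#' placed in that same category.
#'
#' @param estimated,truth Paired category vectors of equal length (levels as
#'   in [categorise()]).
#' @return A tibble with one row per ground-truth category: `category`,
#'   `n_true`, `n_correct`, `pct_correct`.
#' @export
classification_accuracy <- function(estimated, truth) {
  if (length(estimated) != length(truth)) {
    abort("`estimated` and `truth` must have equal length.")
  }
  lv <- c("longitudinal", "radial", "laminar", "oblique")
  truth <- factor(truth, levels = lv)
  estimated <- factor(estimated, levels = lv)
  dplyr::bind_rows(lapply(lv, function(cat) {
    in_cat <- !is.na(truth) & truth == cat
    tibble(
      category = cat,
      n_true = sum(in_cat),
      n_correct = sum(in_cat & !is.na(estimated) & estimated == cat),
      pct_correct = if (sum(in_cat) > 0) {
        100 * sum(in_cat & !is.na(estimated) & estimated == cat) / sum(in_cat)
      } else {
        NA_real_
      }
    )
  }))
}
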