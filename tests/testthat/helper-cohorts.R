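# Shared full-scale phantom cohorts for the acceptance checks. Built once per
# test run (several minutes of compute) and reused across test blocks.
#
# Study conditions: cylinders of length 400 and minor diameter 10 voxels in a
# 500^3 domain, 100 per aspect ratio; ellipsoids of 15 x 5 x 5 um in a 50^3
# domain, 100 per condition; supersampled occupancy (5^3) with midpoint
# binarisation.

.cohort_cache <- new.env(parent = emptyenv())

study_cylinders <- function() {
  if (is.null(.cohort_cache$cyl)) {
    .cohort_cache$cyl <- dplyr::bind_rows(lapply(c(1, 1.25, 1.5, 3), function(ar) {
      man <- generate_cohort("cylinder", n = 100, seed = 42L + as.integer(100 * ar),
                             aspect_ratio = ar)
      analyse_cohort(man)
    }))
  }
  .cohort_cache$cyl
}

study_ellipsoids <- function() {
  if (is.null(.cohort_cache$ell)) {
    conds <- list(
      list(alignment = "woven", voxel_size = 0.33),
      list(alignment = "parallel_fibred", voxel_size = 0.33),
      list(alignment = "woven", voxel_size = 0.8),
      list(alignment = "parallel_fibred", voxel_size = 0.8),
      list(alignment = "parallel_fibred", voxel_size = 1.6)
    )
    .cohort_cache$ell <- dplyr::bind_rows(lapply(seq_along(conds), function(k) {
      man <- generate_cohort("ellipsoid", n = 100, seed = 7L + 100L * k,
                             voxel_size = conds[[k]]$voxel_size,
                             alignment = conds[[k]]$alignment)
      analyse_cohort(man)
    }))
  }
  .cohort_cache$ell
}

ell_condition <- function(df, alignment, voxel_size) {
  df[df$alignment == alignment & abs(df$voxel_size - voxel_size) < 0.05, ]
}
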