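#' Minimum cross-entropy (Li) threshold
#'
#' Computes the binarisation threshold that minimises the Li-Tam cross
#' entropy between a grey image and its binarised version, over a histogram
#' of `n_bins` uniform bins spanning the grey range (256 bins by default,
#' matching the 8-bit convention of microscopy toolchains). Zero-valued
#' grey levels carry no weight in the criterion, so large empty backgrounds
#' do not destabilise it.
#'
#' Two implementations are provided: an exhaustive search over all bin-edge
#' cut points (the default, guaranteed global minimiser) and the classical
#' fixed-point iteration started at the image mean. On histograms with a
#' single well-defined minimum they agree; when the minimum is attained on a
#' flat plateau (an empty grey-level gap), any cut in the gap yields the same
#' binarisation.
#'
#' @param grey Numeric vector or array of grey values (at least two distinct
#'   values).
#' @param n_bins Number of histogram bins.
#' @param method `"exhaustive"` or `"iterative"`.
#' @return The threshold, a single number on the grey scale. Values
#'   `>= threshold` are foreground.
#' @examples
#' li_threshold(c(rep(0.05, 50), rep(0.95, 50)))
#' @export
li_threshold <- function(grey, n_bins = 256, method = c("exhaustive", "iterative")) {
  method <- match.arg(method)
  v <- as.numeric(grey)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) {
    abort("Cannot threshold a constant image: no threshold exists.")
  }
  if (method == "iterative") {
    return(li_threshold_iterative(v))
  }
  # scale to [0, 1] for binning, report on the original scale
  u <- (v - rng[1]) / diff(rng)
  h <- tabulate(pmin(n_bins, floor(u * n_bins) + 1L), n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  gh <- h * mids
  cum_gh <- cumsum(gh)
  cum_h <- cumsum(h)
  tot_gh <- cum_gh[n_bins]
  tot_h <- cum_h[n_bins]
  best_eta <- Inf
  best_cut <- NA_real_
  for (t in 2:n_bins) {
    m0 <- cum_gh[t - 1]; n0 <- cum_h[t - 1]
    m1 <- tot_gh - m0; n1 <- tot_h - n0
    if (n1 == 0) next
    mu0 <- if (n0 > 0) m0 / n0 else 0
    mu1 <- m1 / n1
    if (mu1 <= 0) next
    eta <- -(if (mu0 > 0) m0 * log(mu0) else 0) - m1 * log(mu1)
    if (eta < best_eta - 1e-12) {
      best_eta <- eta
      best_cut <- (t - 1) / n_bins
    }
  }
  rng[1] + best_cut * diff(rng)
}

# classical fixed-point iteration: t <- (mu0 - mu1) / (log mu0 - log mu1),
# started at the image mean; operates on positive shifted values
li_threshold_iterative <- function(v, tol = 1e-7, max_iter = 200) {
  rng <- range(v)
  u <- (v - rng[1]) / diff(rng)
  t <- mean(u)
  for (i in seq_len(max_iter)) {
    lo <- u[u < t]
    hi <- u[u >= t]
    if (length(lo) == 0 || length(hi) == 0) break
    mu0 <- mean(lo)
    mu1 <- mean(hi)
    t_new <- if (mu0 <= 0) mu1 / 2 else (mu0 - mu1) / (log(mu0) - log(mu1))
    if (abs(t_new - t) < tol) {
      t <- t_new
      break
    }
    t <- t_new
  }
  rng[1] + t * diff(rng)
}

#' Binarise a grey voxel volume
#'
#' Converts an occupancy (grey) volume into a binary one. The default
#' `"midpoint"` rule marks voxels with occupancy at or above 0.5 as
#' foreground, i.e. voxels whose centres lie (in expectation) inside the
#' surface; it is unbiased for supersampled occupancy renderings and
#' reproduces the per-object voxel counts expected from the analytic shape
#' volume. The `"li"` rule applies the minimum cross-entropy threshold of
#' [li_threshold()], appropriate for genuinely grey-valued images such as
#' reconstructed CT data.
#'
#' @param vol A grey `voxel_volume`.
#' @param method `"midpoint"` or `"li"`.
#' @param ... Passed to [li_threshold()].
#' @return A binary `voxel_volume`; the threshold used is stored in the
#'   `threshold` field.
#' @export
binarise_volume <- function(vol, method = c("midpoint", "li"), ...) {
  stopifnot(inherits(vol, "voxel_volume"))
  method <- match.arg(method)
  thr <- switch(method,
    midpoint = 0.5,
    li = li_threshold(vol$values, ...)
  )
  vals <- (vol$values >= thr) * 1
  dim(vals) <- dim(vol$values)
  new_voxel_volume(vals, vol$dim_full, vol$offset, vol$voxel_size,
                   binary = TRUE, threshold = thr)
}

#' Extract the two orthogonal mid-slices of a volume
#'
#' Returns the transverse mid-slice (xy-plane at the mid z index,
#' `floor(Nz / 2)` in 0-based indexing) and the perpendicular xz-plane
#' mid-slice (at the mid y index). For centred phantoms both pass through
#' the shape midpoint. Slices are returned embedded at full domain size so
#' that pixel coordinates match world coordinates regardless of cropping.
#'
#' @param vol A `voxel_volume`.
#' @return A list with matrices `xy` (dimensions Nx x Ny) and `xz`
#'   (Nx x Nz), plus the 0-based slice indices `z_index` and `y_index`.
#' @export
extract_slices <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- vol$dim_full
  off <- vol$offset
  dc <- dim(vol$values)
  zi <- d[3] %/% 2 # 0-based index of the transverse mid-slice
  yi <- d[2] %/% 2

  xy <- matrix(0, d[1], d[2])
  kz <- zi - off[3] + 1 # 1-based index into the crop
  if (kz >= 1 && kz <= dc[3]) {
    xy[off[1] + seq_len(dc[1]), off[2] + seq_len(dc[2])] <- vol$values[, , kz]
  }
  xz <- matrix(0, d[1], d[3])
  ky <- yi - off[2] + 1
  if (ky >= 1 && ky <= dc[2]) {
    xz[off[1] + seq_len(dc[1]), off[3] + seq_len(dc[3])] <- vol$values[, ky, ]
  }
  list(xy = xy, xz = xz, z_index = zi, y_index = yi)
}
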