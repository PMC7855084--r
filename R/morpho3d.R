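#' Label connected regions in a binary volume
#'
#' 26-connected component labelling of a binary `voxel_volume` (or plain 3D
#' array). Physical volumes are voxel counts times the cubed voxel size.
#'
#' @param vol Binary `voxel_volume` or 3D array.
#' @param connectivity 26, 18 or 6.
#' @param voxel_size Voxel edge length in um (taken from `vol` when it is a
#'   `voxel_volume`).
#' @return A tibble with one row per region: `region_id`, `n_voxels`,
#'   `volume` (um^3) and a list-column `voxels` of voxel-centre coordinates
#'   (full-domain voxel units).
#' @export
label_regions_3d <- function(vol, connectivity = 26, voxel_size = NULL) {
  if (inherits(vol, "voxel_volume")) {
    arr <- vol$values
    off <- vol$offset
    if (is.null(voxel_size)) voxel_size <- vol$voxel_size
  } else {
    arr <- vol
    off <- c(0L, 0L, 0L)
    if (is.null(voxel_size)) voxel_size <- 1
  }
  stopifnot(length(dim(arr)) == 3, connectivity %in% c(6, 18, 26))
  lab <- label_components_cpp(as.logical(arr != 0), dim(arr), as.integer(connectivity))
  ids <- sort(unique(lab[lab > 0]))
  coords <- purrr::map(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    sweep(unname(idx) - 0.5, 2, off, "+")
  })
  tibble(
    region_id = as.integer(ids),
    n_voxels = purrr::map_int(coords, nrow),
    volume = purrr::map_int(coords, nrow) * voxel_size^3,
    voxels = coords
  )
}

#' Separate lacunae, excluded objects and canals by volume
#'
#' Applies the volumetric size rules: objects of 50-500 um^3 are osteocyte
#' lacunae, objects above 1000 um^3 are vascular canals, objects between
#' 500 and 1000 um^3 are excluded (typically unresolvable lacunar clusters),
#' and objects below 50 um^3 are discarded as noise (counted).
#'
#' @param regions Data frame with a `volume` column in um^3.
#' @param lacuna_range Lacunar volume range, um^3.
#' @param canal_min Minimum canal volume, um^3.
#' @return `regions` with a `class_3d` column
#'   (`"lacuna"`, `"excluded"`, `"canal"` or `"noise"`).
#' @export
separate_by_volume <- function(regions, lacuna_range = c(50, 500), canal_min = 1000) {
  dplyr::mutate(
    regions,
    class_3d = dplyr::case_when(
      .data$volume > canal_min ~ "canal",
      .data$volume > lacuna_range[2] ~ "excluded",
      .data$volume >= lacuna_range[1] ~ "lacuna",
      TRUE ~ "noise"
    )
  )
}

#' Skeletonise a binary volume
#'
#' Topology-preserving medial-axis thinning of a binary volume to unit-width
#' curves: border voxels are removed in six directional sub-iterations when
#' their removal preserves local foreground 26-connectivity and background
#' 6-connectivity, and curve endpoints are retained. The skeleton is a
#' subset of the original object.
#'
#' @param vol Binary `voxel_volume` or 3D array.
#' @return Same type as the input, containing the skeleton.
#' @export
skeletonise_3d <- function(vol) {
  if (inherits(vol, "voxel_volume")) {
    arr <- vol$values
    if (sum(arr != 0) < 1) abort("Cannot skeletonise an empty volume.")
    sk <- thin_3d_cpp(as.logical(arr != 0), dim(arr))
    out <- new_voxel_volume(sk * 1, vol$dim_full, vol$offset, vol$voxel_size,
                            binary = TRUE, threshold = vol$threshold)
    dim(out$values) <- dim(arr)
    return(out)
  }
  stopifnot(length(dim(vol)) == 3)
  if (sum(vol != 0) < 1) abort("Cannot skeletonise an empty volume.")
  sk <- thin_3d_cpp(as.logical(vol != 0), dim(vol)) * 1
  dim(sk) <- dim(vol)
  sk
}

#' Analyse a curve skeleton into nodes and branches
#'
#' Classifies skeleton voxels by their number of 26-connected skeleton
#' neighbours (1 = endpoint, 2 = slab, >= 3 = junction), and traces each
#' branch between two nodes through the intervening slab voxels. Following
#' the straight-branch simplification, each branch is summarised by the
#' straight line between its two end nodes; the voxel path length along the
#' skeleton is recorded as well (always at least the Euclidean node
#' distance).
#'
#' @param skel Skeleton as a binary `voxel_volume` or 3D array (e.g. from
#'   [skeletonise_3d()]), or a 3-column matrix of skeleton voxel-centre
#'   coordinates.
#' @param voxel_size Voxel edge in um (taken from a `voxel_volume` input).
#' @return An object of class `skeleton_graph`: a list with
#'   * `nodes`: tibble of node voxels (`x`, `y`, `z`, `degree`, `type`);
#'   * `branches`: tibble with endpoints (`x1 ... z2`), `euclidean_length`
#'     and `path_length` (um), and voxel step count `n_steps`;
#'   * `total_length`: summed path length (um).
#' @export
analyse_skeleton <- function(skel, voxel_size = NULL) {
  if (inherits(skel, "voxel_volume")) {
    if (is.null(voxel_size)) voxel_size <- skel$voxel_size
    coords <- foreground_coords(skel)
  } else if (is.matrix(skel) && ncol(skel) == 3) {
    coords <- skel
  } else {
    stopifnot(length(dim(skel)) == 3)
    idx <- which(skel != 0, arr.ind = TRUE)
    coords <- unname(idx) - 0.5
  }
  if (is.null(voxel_size)) voxel_size <- 1
  n <- nrow(coords)
  if (n == 0) abort("Empty skeleton.")

  adj <- skeleton_adjacency(coords)
  nbr <- adj$nbr
  deg <- adj$deg

  node_type <- dplyr::case_when(
    deg == 0 ~ "isolated",
    deg == 1 ~ "endpoint",
    deg == 2 ~ "slab",
    TRUE ~ "junction"
  )
  is_node <- deg != 2
  nodes <- tibble(
    x = coords[is_node, 1], y = coords[is_node, 2], z = coords[is_node, 3],
    degree = deg[is_node], type = node_type[is_node]
  )

  paths <- skeleton_paths(coords, nbr, deg)
  step_len <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  branches <- purrr::map(paths, function(path) {
    a <- path[1]
    b <- path[length(path)]
    plen <- if (length(path) > 1) {
      sum(vapply(seq_len(length(path) - 1),
                 function(t) step_len(path[t], path[t + 1]), 0))
    } else {
      0
    }
    tibble(
      x1 = coords[a, 1], y1 = coords[a, 2], z1 = coords[a, 3],
      x2 = coords[b, 1], y2 = coords[b, 2], z2 = coords[b, 3],
      euclidean_length = step_len(a, b) * voxel_size,
      path_length = plen * voxel_size,
      n_steps = length(path) - 1L
    )
  })
  branches <- if (length(branches)) dplyr::bind_rows(branches) else
    tibble(x1 = numeric(), y1 = numeric(), z1 = numeric(),
           x2 = numeric(), y2 = numeric(), z2 = numeric(),
           euclidean_length = numeric(), path_length = numeric(),
           n_steps = integer())
  structure(
    list(nodes = nodes, branches = branches,
         total_length = sum(branches$path_length), voxel_size = voxel_size),
    class = "skeleton_graph"
  )
}

# run the thinning pass over a sparse coordinate set
rethin_coords <- function(coords) {
  if (nrow(coords) == 0) return(coords)
  ic <- round(coords - 0.5)
  lo <- apply(ic, 2, min) - 1
  d <- apply(ic, 2, max) - lo + 2
  arr <- array(FALSE, d)
  arr[cbind(ic[, 1] - lo[1] + 1, ic[, 2] - lo[2] + 1, ic[, 3] - lo[3] + 1)] <- TRUE
  sk <- thin_3d_cpp(as.vector(arr), d)
  dim(sk) <- d
  idx <- which(sk, arr.ind = TRUE)
  cbind(idx[, 1] + lo[1] - 0.5, idx[, 2] + lo[2] - 0.5, idx[, 3] + lo[3] - 0.5)
}

# 26-adjacency between skeleton voxels, via hashed integer coordinates
skeleton_adjacency <- function(coords) {
  n <- nrow(coords)
  ic <- round(coords - 0.5)
  ic <- sweep(ic, 2, pmin(apply(ic, 2, min), 0)) # keep keys non-negative
  span <- apply(ic, 2, max) + 2
  key <- ic[, 1] + span[1] * (ic[, 2] + span[2] * ic[, 3])
  ord <- order(key)
  key_sorted <- key[ord]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbr <- vector("list", n)
  for (r in seq_len(nrow(offs))) {
    dk <- offs[r, 1] + span[1] * (offs[r, 2] + span[2] * offs[r, 3])
    pos <- findInterval(key + dk, key_sorted)
    hit <- pos > 0 & key_sorted[pmax(pos, 1)] == key + dk
    if (any(hit)) {
      j <- ord[pos[hit]]
      i <- which(hit)
      # guard against hash wrap-around at the grid edge
      good <- abs(ic[i, 1] - ic[j, 1]) <= 1 & abs(ic[i, 2] - ic[j, 2]) <= 1 &
        abs(ic[i, 3] - ic[j, 3]) <= 1
      i <- i[good]; j <- j[good]
      for (t in seq_along(i)) nbr[[i[t]]] <- c(nbr[[i[t]]], j[t])
    }
  }
  list(nbr = nbr, deg = lengths(nbr))
}

# trace maximal paths between nodes (degree != 2 voxels) through slab voxels;
# isolated voxels become single-element paths
skeleton_paths <- function(coords, nbr, deg) {
  visited_edge <- new.env(hash = TRUE)
  edge_id <- function(i, j) paste0(min(i, j), "_", max(i, j))
  paths <- list()
  for (v in which(deg != 2 & deg > 0)) {
    for (w in nbr[[v]]) {
      if (!is.null(visited_edge[[edge_id(v, w)]])) next
      path <- c(v, w)
      visited_edge[[edge_id(v, w)]] <- TRUE
      prev <- v
      cur <- w
      while (deg[cur] == 2) {
        nxt <- setdiff(nbr[[cur]], prev)[1]
        if (is.na(nxt)) break
        visited_edge[[edge_id(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
      paths[[length(paths) + 1]] <- path
    }
  }
  for (v in which(deg == 0)) paths[[length(paths) + 1]] <- v
  paths
}

#' Prune short terminal branches from a skeleton
#'
#' Medial-axis thinning of a thick structure leaves short terminal spurs of
#' roughly one local radius in length wherever the eroding boundary pinched
#' off early. This removes, iteratively, every terminal branch (one end a
#' free endpoint) whose voxel path length is below `min_length`, except the
#' longest branch of the skeleton, until the skeleton is stable. Junction
#' voxels whose spurs were removed melt back into the through-going branch.
#'
#' `min_length` should be chosen above the maximum local radius of the
#' structure and well below the length of real branches.
#'
#' @param skel Skeleton as a binary `voxel_volume`, 3D array or coordinate
#'   matrix (as in [analyse_skeleton()]).
#' @param min_length Minimum terminal branch length to keep, in voxel units.
#' @return The pruned skeleton, same type as the input.
#' @export
prune_spurs <- function(skel, min_length = 16) {
  vol_in <- inherits(skel, "voxel_volume")
  arr_in <- !vol_in && !is.null(dim(skel)) && length(dim(skel)) == 3
  coords <- if (vol_in) {
    foreground_coords(skel)
  } else if (arr_in) {
    unname(which(skel != 0, arr.ind = TRUE)) - 0.5
  } else {
    skel
  }
  repeat {
    adj <- skeleton_adjacency(coords)
    paths <- skeleton_paths(coords, adj$nbr, adj$deg)
    if (length(paths) <= 1) break
    plens <- vapply(paths, function(p) {
      if (length(p) < 2) return(0)
      sum(sqrt(rowSums((coords[p[-1], , drop = FALSE] -
                          coords[p[-length(p)], , drop = FALSE])^2)))
    }, 0)
    keep_main <- which.max(plens)
    drop <- vapply(seq_along(paths), function(k) {
      if (k == keep_main) return(FALSE)
      p <- paths[[k]]
      terminal <- adj$deg[p[1]] <= 1 || adj$deg[p[length(p)]] <= 1
      terminal && plens[k] < min_length
    }, TRUE)
    if (!any(drop)) break
    remove <- unique(unlist(lapply(paths[drop], function(p) {
      # keep the attachment node (the non-terminal end), drop the rest
      if (adj$deg[p[1]] <= 1) p[-length(p)] else p[-1]
    })))
    remove <- setdiff(remove, unlist(paths[!drop]))
    if (length(remove) == 0) break
    coords <- coords[-remove, , drop = FALSE]
    # re-thin: removing a spur can leave its attachment voxel as a redundant
    # bump beside the through-going line
    coords <- rethin_coords(coords)
  }
  if (vol_in) {
    out <- skel
    out$values[] <- 0
    idx <- cbind(round(coords[, 1] + 0.5) - skel$offset[1],
                 round(coords[, 2] + 0.5) - skel$offset[2],
                 round(coords[, 3] + 0.5) - skel$offset[3])
    out$values[idx] <- 1
    return(out)
  }
  if (arr_in) {
    out <- array(0, dim(skel))
    out[cbind(round(coords[, 1] + 0.5), round(coords[, 2] + 0.5),
              round(coords[, 3] + 0.5))] <- 1
    return(out)
  }
  coords
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d branches, total length %.1f\n",
              nrow(x$nodes), nrow(x$branches), x$total_length))
  invisible(x)
}

#' Estimate the longitudinal bone axis
#'
#' For phantom domains the bone axis is the z-axis. For real stacks the axis
#' is reconstructed from manually selected bone-surface points on the first
#' and last slice: a circle is fitted (least squares) to the first-slice
#' points, a circle of that same radius is fitted (centre only) to the
#' last-slice points, and the axis is the unit vector between the two
#' centres.
#'
#' @param first_points,last_points Two-column matrices of (x, y) surface
#'   points on the first and last slice (>= 3 points each). Ignored in
#'   phantom mode.
#' @param n_slices Number of slices separating the two point sets.
#' @param mode `"phantom"` or `"points"`.
#' @return A list with unit `direction` (3-vector) and `origin`.
#' @export
estimate_bone_axis <- function(first_points = NULL, last_points = NULL,
                               n_slices = NULL, mode = c("phantom", "points")) {
  mode <- match.arg(mode)
  if (mode == "phantom") {
    return(list(direction = c(0, 0, 1), origin = c(0, 0, 0)))
  }
  if (is.null(first_points) || nrow(first_points) < 3 ||
      is.null(last_points) || nrow(last_points) < 3) {
    abort("Circle fitting needs at least 3 points per slice.")
  }
  stopifnot(is.numeric(n_slices), n_slices >= 2)
  c1 <- fit_circle_kasa(first_points)
  c2 <- fit_circle_fixed_radius(last_points, c1$r)
  d <- c(c2$cx - c1$cx, c2$cy - c1$cy, n_slices - 1)
  list(direction = d / sqrt(sum(d^2)),
       origin = c(c1$cx, c1$cy, 0), radius = c1$r)
}

# algebraic (Kasa) circle fit
fit_circle_kasa <- function(p) {
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- p[, 1]^2 + p[, 2]^2
  sol <- qr.solve(A, b)
  list(cx = sol[1], cy = sol[2], r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

# geometric fit of the centre with the radius held fixed
fit_circle_fixed_radius <- function(p, r) {
  start <- fit_circle_kasa(p)
  obj <- function(c0) sum((sqrt((p[, 1] - c0[1])^2 + (p[, 2] - c0[2])^2) - r)^2)
  fit <- stats::optim(c(start$cx, start$cy), obj, method = "Nelder-Mead")
  list(cx = fit$par[1], cy = fit$par[2], r = r)
}

#' Orientation angles of skeleton branches
#'
#' Computes the longitudinal angle omega and radial angle theta of each
#' branch relative to the bone axis and surface tangent: omega is 90 deg
#' minus the angle between the branch vector and the axis direction (so a
#' branch parallel to the axis has omega = 90), and theta is the acute angle
#' between the branch's transverse-plane projection and the tangent
#' direction. Theta is `NA` when the transverse projection is negligible
#' (below `1e-9` of the branch length).
#'
#' @param branches Data frame with endpoint columns `x1, y1, z1, x2, y2, z2`
#'   (e.g. from [analyse_skeleton()]).
#' @param axis Bone axis from [estimate_bone_axis()].
#' @param tangent_direction Tangent direction in degrees (phantoms: 0).
#' @return `branches` with `omega_3d` and `theta_3d` columns added.
#' @export
branch_angles <- function(branches, axis = estimate_bone_axis(),
                          tangent_direction = 0) {
  vx <- branches$x2 - branches$x1
  vy <- branches$y2 - branches$y1
  vz <- branches$z2 - branches$z1
  len <- sqrt(vx^2 + vy^2 + vz^2)
  if (any(len < 1e-12)) abort("Branch vectors must be non-zero.")
  u <- axis$direction / sqrt(sum(axis$direction^2))
  dotu <- (vx * u[1] + vy * u[2] + vz * u[3]) / len
  omega <- asin(pmin(1, abs(dotu))) * 180 / pi
  # transverse-plane projection (plane orthogonal to the bone axis; for the
  # phantom axis z this is the xy-plane)
  px <- vx - (vx * u[1] + vy * u[2] + vz * u[3]) * u[1]
  py <- vy - (vx * u[1] + vy * u[2] + vz * u[3]) * u[2]
  pz <- vz - (vx * u[1] + vy * u[2] + vz * u[3]) * u[3]
  pn <- sqrt(px^2 + py^2 + pz^2)
  # express the projection in the transverse frame; with axis = z this is
  # simply (px, py)
  if (all(abs(u - c(0, 0, 1)) < 1e-12)) {
    ang <- atan2(py, px) * 180 / pi
  } else {
    ex <- c(1, 0, 0) - u[1] * u
    ex <- ex / sqrt(sum(ex^2))
    ey <- c(u[2] * ex[3] - u[3] * ex[2],
            u[3] * ex[1] - u[1] * ex[3],
            u[1] * ex[2] - u[2] * ex[1])
    ang <- atan2(px * ey[1] + py * ey[2] + pz * ey[3],
                 px * ex[1] + py * ex[2] + pz * ex[3]) * 180 / pi
  }
  theta <- ifelse(pn / len < 1e-9, NA_real_,
                  fold_acute(ang - tangent_direction))
  dplyr::mutate(as_tibble(branches), omega_3d = omega, theta_3d = theta)
}

#' Moment-based ellipsoid fit of a voxel region
#'
#' Fits the equivalent uniform solid ellipsoid of a 3D voxel region: the
#' centroid and central second-moment matrix of the voxel centres are
#' computed (voxels treated as unit cubes, adding 1/12 per axis), the
#' principal directions are the moment eigenvectors, and the semi-axes
#' follow from the uniform-ellipsoid relation `r_k = sqrt(5 lambda_k)`.
#' Regions with fewer than `min_voxels` voxels or degenerate moments are
#' flagged as failed fits.
#'
#' @param voxels Three-column matrix of voxel-centre coordinates (voxel
#'   units).
#' @param voxel_size Voxel edge in um.
#' @param min_voxels Minimum region size for a fit.
#' @return A one-row tibble: semi-axes `r1 >= r2 >= r3` (um), `volume`
#'   (um^3), centroid, `n_voxels`, `fit_ok`.
#' @export
fit_ellipsoid_3d <- function(voxels, voxel_size = 1, min_voxels = 6) {
  n <- nrow(voxels)
  fail <- tibble(r1 = NA_real_, r2 = NA_real_, r3 = NA_real_,
                 volume = NA_real_, cx = NA_real_, cy = NA_real_, cz = NA_real_,
                 n_voxels = if (is.null(n)) 0L else n, fit_ok = FALSE)
  if (is.null(n) || n < min_voxels) return(fail)
  ctr <- colMeans(voxels)
  d <- sweep(voxels, 2, ctr)
  M <- crossprod(d) / n + diag(1 / 12, 3)
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values <= 1e-12)) return(fail)
  r <- sqrt(5 * e$values) * voxel_size # descending
  tibble(r1 = r[1], r2 = r[2], r3 = r[3],
         volume = 4 / 3 * pi * prod(r),
         cx = ctr[1] * voxel_size, cy = ctr[2] * voxel_size,
         cz = ctr[3] * voxel_size,
         n_voxels = n, fit_ok = TRUE)
}

#' Mean lacunar volume from 3D ellipsoid fits
#'
#' Averages the triaxial volumes of successfully fitted ellipsoids and
#' reports the number of fit failures.
#'
#' @param fits Data frame of per-lacuna ellipsoid fits (rows from
#'   [fit_ellipsoid_3d()]).
#' @return A one-row tibble: `method`, `mean_volume`, `sd`, `n`, `n_failed`.
#' @export
mean_volume_3d <- function(fits) {
  ok <- fits$fit_ok & is.finite(fits$volume)
  if (!any(ok)) abort("No successful ellipsoid fits to average.")
  v <- fits$volume[ok]
  tibble(method = "ellipsoid_3d", mean_volume = mean(v), sd = sd(v),
         n = sum(ok), n_failed = sum(!ok))
}
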