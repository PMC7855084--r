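ball_array <- function(n, ctr, r) {
  arr <- array(0, c(n, n, n))
  idx <- which(arr == 0, arr.ind = TRUE)
  d2 <- (idx[, 1] - 0.5 - ctr[1])^2 + (idx[, 2] - 0.5 - ctr[2])^2 +
    (idx[, 3] - 0.5 - ctr[3])^2
  arr[idx[d2 <= r^2, , drop = FALSE]] <- 1
  arr
}

tube_array <- function(n, r, axis_len) {
  # straight circular tube along z, centred
  arr <- array(0, c(n, n, n))
  z0 <- (n - axis_len) / 2
  idx <- which(arr == 0, arr.ind = TRUE)
  keep <- (idx[, 1] - 0.5 - n / 2)^2 + (idx[, 2] - 0.5 - n / 2)^2 <= r^2 &
    idx[, 3] - 0.5 >= z0 & idx[, 3] - 0.5 <= z0 + axis_len
  arr[idx[keep, , drop = FALSE]] <- 1
  arr
}

test_that("3D labelling separates and merges components per 26-connectivity", {
  arr <- array(0, c(24, 24, 24))
  arr[3:6, 3:6, 3:6] <- 1
  arr[15:18, 15:18, 15:18] <- 1
  regs <- label_regions_3d(arr)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$n_voxels, c(64, 64))
  # corner-touching voxels merge under 26-connectivity
  arr2 <- array(0, c(5, 5, 5))
  arr2[2, 2, 2] <- 1
  arr2[3, 3, 3] <- 1
  expect_equal(nrow(label_regions_3d(arr2)), 1)
  expect_equal(nrow(label_regions_3d(arr2, connectivity = 6)), 2)
  expect_equal(nrow(label_regions_3d(array(0, c(4, 4, 4)))), 0)
  # a single lacunar phantom at 0.8 um is one region of ~383 voxels
  v <- binarise_volume(voxelise(ellipsoid_spec(0.8, list(ry = 15, rx = 75, rz = 40))))
  r1 <- label_regions_3d(v)
  expect_equal(nrow(r1), 1)
  expect_lt(abs(r1$n_voxels - 383) / 383, 0.1)
})

test_that("volume rules split lacunae, exclusions, canals and noise", {
  d <- separate_by_volume(tibble::tibble(volume = c(100, 750, 1200, 30, 500, 1000)))
  expect_equal(d$class_3d,
               c("lacuna", "excluded", "canal", "noise", "lacuna", "excluded"))
})

test_that("thinning reduces tubes to chains and balls to near-points", {
  # an obliquely oriented circular canal, as in the study conditions
  spec <- cylinder_spec(1, list(ry = 20, rx = 65, rz = 30),
                        length = 60, domain_edge = 80)
  v <- binarise_volume(voxelise(spec))
  sk <- skeletonise_3d(v)
  expect_true(all(v$values[sk$values == 1] == 1)) # skeleton subset of object
  g <- analyse_skeleton(sk)
  expect_equal(sum(g$nodes$type == "endpoint"), 2)
  expect_equal(sum(g$nodes$type == "junction"), 0)
  expect_equal(nrow(g$branches), 1)
  # the chain runs along the canal axis
  br <- branch_angles(g$branches)
  expect_lt(abs(br$omega_3d - spec$omega_true), 2)
  expect_lt(abs(br$theta_3d - spec$theta_true), 4)

  ball <- ball_array(24, c(12, 12, 12), 8)
  skb <- skeletonise_3d(ball)
  expect_lte(sum(skb), 5)
  expect_error(skeletonise_3d(array(0, c(4, 4, 4))), "empty")
})

test_that("skeleton analysis resolves a Y-junction and honours path lengths", {
  # three straight arms meeting at one voxel
  arr <- array(0, c(30, 30, 30))
  for (t in 0:10) {
    arr[15, 15, 15 - t] <- 1        # stem down
    arr[15 - t, 15, 15 + t] <- 1    # diagonal arm
    arr[15 + t, 15, 15 + t] <- 1    # diagonal arm
  }
  g <- analyse_skeleton(arr)
  expect_equal(sum(g$nodes$type == "endpoint"), 3)
  expect_equal(sum(g$nodes$type == "junction"), 1)
  expect_equal(nrow(g$branches), 3)
  expect_true(all(g$branches$path_length >= g$branches$euclidean_length - 1e-9))

  # a 50-voxel straight chain is one branch with two endpoints
  chain <- array(0, c(54, 5, 5))
  chain[3:52, 3, 3] <- 1
  gc <- analyse_skeleton(chain)
  expect_equal(nrow(gc$branches), 1)
  expect_equal(gc$branches$n_steps, 49)
  expect_equal(gc$branches$euclidean_length, 49)
  # an isolated voxel yields a degenerate zero-length branch
  lone <- array(0, c(3, 3, 3)); lone[2, 2, 2] <- 1
  gl <- analyse_skeleton(lone)
  expect_equal(gl$branches$n_steps, 0L)
  expect_equal(gl$branches$euclidean_length, 0)
})

test_that("spur pruning removes short terminal branches only", {
  arr <- array(0, c(40, 9, 9))
  arr[3:37, 5, 5] <- 1       # main line
  arr[20, 6:8, 5] <- 1       # 3-voxel spur
  pruned <- prune_spurs(arr, min_length = 6)
  g <- analyse_skeleton(pruned)
  expect_equal(nrow(g$branches), 1)
  expect_equal(sum(pruned), 35)
  # long branches survive
  same <- prune_spurs(arr, min_length = 2)
  expect_equal(sum(same), sum(arr))
})

test_that("the bone axis comes out of phantom mode and circle fits", {
  expect_equal(estimate_bone_axis()$direction, c(0, 0, 1))
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- function(cx, cy, r) cbind(cx + r * cos(ang), cy + r * sin(ang))
  conc <- estimate_bone_axis(circ(50, 50, 40), circ(50, 50, 40),
                             n_slices = 1001, mode = "points")
  expect_equal(conc$direction, c(0, 0, 1), tolerance = 1e-6)
  off <- estimate_bone_axis(circ(50, 50, 40), circ(60, 50, 40),
                            n_slices = 1001, mode = "points")
  expect_equal(acos(off$direction[3]) * 180 / pi, atan(10 / 1000) * 180 / pi,
               tolerance = 0.01)
  expect_error(estimate_bone_axis(circ(0, 0, 1)[1:2, ], circ(0, 0, 1),
                                  n_slices = 10, mode = "points"), "3 points")
})

test_that("branch angles follow the elevation and tangent conventions", {
  br <- tibble::tibble(x1 = 0, y1 = 0, z1 = 0, x2 = 0, y2 = 0, z2 = 1)
  expect_equal(branch_angles(br)$omega_3d, 90)
  expect_true(is.na(branch_angles(br)$theta_3d))
  br2 <- tibble::tibble(x1 = 0, y1 = 0, z1 = 0, x2 = 1, y2 = 0, z2 = 0)
  a2 <- branch_angles(br2)
  expect_equal(a2$omega_3d, 0)
  expect_equal(a2$theta_3d, 0)
  br3 <- tibble::tibble(x1 = 0, y1 = 0, z1 = 0, x2 = 1, y2 = 0, z2 = 1)
  expect_equal(branch_angles(br3)$omega_3d, 45)
  expect_error(branch_angles(tibble::tibble(x1 = 0, y1 = 0, z1 = 0,
                                            x2 = 0, y2 = 0, z2 = 0)), "non-zero")
  # a tilted bone axis shifts omega accordingly
  ax <- list(direction = c(sin(0.1), 0, cos(0.1)))
  expect_equal(branch_angles(br, axis = ax)$omega_3d, 90 - 0.1 * 180 / pi,
               tolerance = 1e-6)
})

test_that("moment ellipsoid fits recover spheres and lacunar phantoms", {
  ball <- ball_array(26, c(13, 13, 13), 10)
  coords <- which(ball == 1, arr.ind = TRUE) - 0.5
  fit <- fit_ellipsoid_3d(unname(coords))
  expect_true(fit$fit_ok)
  expect_true(all(abs(c(fit$r1, fit$r2, fit$r3) - 10) / 10 < 0.03))

  v <- binarise_volume(voxelise(ellipsoid_spec(0.33, list(ry = 70, rx = 20, rz = 55))))
  regs <- label_regions_3d(v)
  f <- fit_ellipsoid_3d(regs$voxels[[1]], v$voxel_size)
  expect_equal(f$r1, 7.5, tolerance = 0.05)
  expect_equal(f$r2, 2.5, tolerance = 0.05)
  expect_equal(f$r3, 2.5, tolerance = 0.05)
  expect_equal(f$volume, 196.35, tolerance = 0.05)

  expect_false(fit_ellipsoid_3d(rbind(c(1, 1, 1), c(2, 1, 1)))$fit_ok)
})

test_that("cohort averaging reports failures without distorting volumes", {
  fits <- dplyr::bind_rows(
    tibble::tibble(volume = c(100, 100, 100), fit_ok = TRUE),
    tibble::tibble(volume = NA_real_, fit_ok = FALSE)
  )
  m <- mean_volume_3d(fits)
  expect_equal(m$mean_volume, 100)
  expect_equal(m$sd, 0)
  expect_equal(m$n, 3)
  expect_equal(m$n_failed, 1)
  expect_error(mean_volume_3d(tibble::tibble(volume = NA_real_, fit_ok = FALSE)))
})

test_that("ellipsoid fits fail at very coarse voxel sizes but not at fine ones", {
  set.seed(17)
  rots <- sample_rotations(20)
  fails <- function(vs) {
    sum(vapply(seq_len(20), function(i) {
      v <- binarise_volume(voxelise(ellipsoid_spec(vs, rots[i, ])))
      regs <- label_regions_3d(v)
      if (nrow(regs) == 0) return(TRUE)
      !fit_ellipsoid_3d(regs$voxels[[which.max(regs$n_voxels)]], v$voxel_size)$fit_ok
    }, TRUE))
  }
  expect_gt(fails(3.2), 0)
  expect_equal(fails(0.33), 0)
})
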