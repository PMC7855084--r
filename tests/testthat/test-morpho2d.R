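disc_image <- function(n, cx, cy, r) {
  outer(seq_len(n) - 0.5, seq_len(n) - 0.5,
        function(x, y) as.numeric((x - cx)^2 + (y - cy)^2 <= r^2))
}

ellipse_image <- function(n, cx, cy, a, b, phi_deg = 0) {
  d <- phi_deg * pi / 180
  outer(seq_len(n) - 0.5, seq_len(n) - 0.5, function(x, y) {
    u <- (x - cx) * cos(d) + (y - cy) * sin(d)
    v <- -(x - cx) * sin(d) + (y - cy) * cos(d)
    as.numeric((u / a)^2 + (v / b)^2 <= 1)
  })
}

test_that("2D labelling finds 8-connected components", {
  img <- matrix(0, 20, 20)
  img[3:6, 3:6] <- 1
  img[12:15, 12:15] <- 1
  expect_equal(nrow(label_regions_2d(img)), 2)
  expect_equal(nrow(label_regions_2d(matrix(0, 5, 5))), 0)
  # diagonal checkerboard: one region under 8-connectivity, per a flood fill
  chk <- outer(1:8, 1:8, function(i, j) as.numeric((i + j) %% 2 == 0))
  expect_equal(nrow(label_regions_2d(chk, connectivity = 8)), 1)
  expect_gt(nrow(label_regions_2d(chk, connectivity = 4)), 1)
})

test_that("moment ellipses recover analytic discs and ellipses", {
  d <- label_regions_2d(disc_image(64, 32, 32, 20))
  f <- fit_ellipse_moments(d$pixels[[1]])
  expect_equal(f$a, 40, tolerance = 0.02)
  expect_equal(f$b, 40, tolerance = 0.02)

  e <- label_regions_2d(ellipse_image(64, 32, 32, 20, 10))
  fe <- fit_ellipse_moments(e$pixels[[1]])
  expect_equal(fe$a, 40, tolerance = 0.02)
  expect_equal(fe$b, 20, tolerance = 0.02)
  expect_lt(min(fe$phi, 180 - fe$phi), 2)

  r <- label_regions_2d(ellipse_image(64, 32, 32, 20, 10, phi_deg = 30))
  fr <- fit_ellipse_moments(r$pixels[[1]])
  expect_lt(abs(fr$phi - 30), 2)

  # area preservation is exact by construction
  expect_equal(pi * fr$a / 2 * fr$b / 2, fr$n_pixels, tolerance = 1e-9)
  # degenerate regions are flagged, not fitted
  expect_false(fit_ellipse_moments(cbind(1.5, 1.5))$ok)
})

test_that("the longitudinal-angle map is exact and monotone", {
  expect_equal(omega_from_ellipse(10, 10), 90)
  expect_equal(omega_from_ellipse(2, 1), 30)
  expect_equal(omega_from_ellipse(1e6, 1), 0, tolerance = 1e-3)
  expect_error(omega_from_ellipse(1, 2), "exceed")
  ratios <- seq(0.01, 1, length.out = 50)
  om <- omega_from_ellipse(rep(1, 50), ratios)
  expect_true(all(diff(om) > 0))
})

test_that("the radial angle folds into the acute range against the tangent", {
  expect_equal(theta_from_ellipse(0, 0), 0)
  expect_equal(theta_from_ellipse(90, 0), 90)
  expect_equal(theta_from_ellipse(135, 0), 45)
  expect_equal(theta_from_ellipse(10, 40), 30)
})

test_that("the 38 um^2 rule separates canals from lacunae exclusively", {
  d <- separate_by_area_2d(tibble::tibble(area = c(30, 40, 38)))
  expect_equal(d$class_2d, c("lacuna", "canal", "lacuna"))
})

test_that("single-slice and two-slice volume rules match their closed forms", {
  one <- mean_volume_xy(tibble::tibble(a = 15, b = 5))
  expect_equal(one$mean_volume, 4 / 3 * pi * 7.5 * 2.5^2, tolerance = 1e-12)
  expect_equal(round(one$mean_volume), 196)
  sphere <- mean_volume_xy(tibble::tibble(a = 6, b = 6))
  expect_equal(sphere$mean_volume, 4 / 3 * pi * 27)
  two <- mean_volume_xy(tibble::tibble(a = c(15, 15), b = c(5, 5 * sqrt(3))))
  expect_equal(two$mean_volume, 2 * 4 / 3 * pi * 7.5 * 2.5^2)

  tri <- mean_volume_xy_xz(tibble::tibble(a = 5, b = 5),
                           tibble::tibble(a = 15, b = 5))
  expect_equal(tri$mean_volume, 4 / 3 * pi * 7.5 * 2.5^2, tolerance = 1e-12)
  # Eq.-collapse: equal minor radii reduce the triaxial rule to the prolate one
  set.seed(4)
  for (i in 1:10) {
    ab <- sort(stats::runif(2, 2, 12), decreasing = TRUE)
    xy <- tibble::tibble(a = ab[1], b = ab[1])
    xz <- tibble::tibble(a = ab[2] * 3, b = 1)
    expect_equal(
      mean_volume_xy_xz(xy, xz)$mean_volume,
      4 / 3 * pi * (xz$a / 2) * (xy$a / 2) * (xy$b / 2)
    )
  }
  # missing pairs are skipped and counted
  sk <- mean_volume_xy_xz(tibble::tibble(a = c(5, NA), b = c(5, NA)),
                          tibble::tibble(a = c(15, 15), b = c(5, 5)))
  expect_equal(sk$n, 1)
  expect_equal(sk$n_skipped, 1)
  expect_error(mean_volume_xy(tibble::tibble(a = numeric(), b = numeric())))
})

test_that("mid-slice aspect ratio of a circular cylinder equals sin(omega)", {
  for (om in c(12, 25, 45, 70, 85)) {
    spec <- cylinder_spec(1, list(ry = 0, rx = om, rz = 30),
                          length = 120, domain_edge = 160)
    v <- binarise_volume(voxelise(spec))
    obj <- analyse_slice_2d(extract_slices(v)$xy)
    main <- obj[which.max(obj$n_pixels), ]
    expect_lt(abs(main$b / main$a - sin(om * pi / 180)), 0.05)
  }
})
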