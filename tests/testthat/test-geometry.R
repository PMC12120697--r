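test_that("calibration divides length by pixel span", {
  expect_equal(round(calibrate(10, 1028)$mm_per_px, 6), 0.009728)
  expect_equal(calibrate(10, 1000)$mm_per_px, 0.01)
  # ratio invariant under equal scaling
  expect_equal(calibrate(5, 514)$mm_per_px, calibrate(10, 1028)$mm_per_px)
  expect_error(calibrate(0, 100), class = "dropsizer_error_calibration")
  expect_error(calibrate(10, -5), class = "dropsizer_error_calibration")
})

test_that("circle-baseline intersection yields chord, contact points and angle", {
  # diameter chord of a hemisphere
  g <- circle_baseline_geometry(0, 0, 1, 0)
  expect_equal(c(g$ax, g$bx), c(-1, 1))
  expect_equal(g$chord, 2)
  expect_equal(g$theta_deg, 90)

  # center above baseline -> hydrophobic branch (theta > 90)
  g2 <- circle_baseline_geometry(0, 0.5, 1, 0)
  expect_equal(g2$chord, 2 * sqrt(0.75), tolerance = 1e-9)
  expect_equal(g2$theta_deg, 120, tolerance = 1e-9)

  # mirrored center -> theta < 90
  g3 <- circle_baseline_geometry(0, -0.5, 1, 0)
  expect_equal(g3$chord, g2$chord, tolerance = 1e-12)
  expect_equal(g3$theta_deg, 60, tolerance = 1e-9)

  expect_error(circle_baseline_geometry(0, 2, 1, 0),
               class = "dropsizer_error_no_intersection")
  expect_error(circle_baseline_geometry(0, 1, 1, 0),
               class = "dropsizer_error_no_intersection")
})

test_that("cap volume matches hemisphere and classical-cap closed forms", {
  expect_equal(cap_volume(2, 90), pi * 2^3 / 12, tolerance = 1e-12)
  expect_equal(cap_volume(2, 60), cap_volume_classical(2, 60), tolerance = 1e-9)
  expect_equal(round(cap_volume(2, 60), 4), 1.0077)
  expect_equal(cap_volume(0, 45), 0)
  expect_error(cap_volume(2, 0), class = "dropsizer_error_geometry")
  expect_error(cap_volume(2, 180), class = "dropsizer_error_geometry")
  expect_error(cap_volume(-1, 90), class = "dropsizer_error_geometry")
})

test_that("cap volume equals the classical formula over a diameter-angle grid", {
  D <- seq(0.5, 5, by = 0.5)
  th <- seq(10, 170, by = 10)
  grid <- expand.grid(D = D, th = th)
  v1 <- cap_volume(grid$D, grid$th)
  v2 <- cap_volume_classical(grid$D, grid$th)
  expect_true(all(abs(v1 - v2) / v2 <= 1e-9))
})

test_that("cap volume is strictly increasing in angle and cubic in diameter", {
  th <- seq(5, 175, by = 5)
  v <- cap_volume(2, th)
  expect_true(all(diff(v) > 0))
  expect_equal(cap_volume(4, 70), 8 * cap_volume(2, 70), tolerance = 1e-12)
  expect_equal(cap_volume(1, 130), cap_volume(2, 130) / 8, tolerance = 1e-12)
})

test_that("constructing a circle from (D, theta) and intersecting recovers them", {
  for (D in c(0.8, 2, 3.5)) {
    for (th in c(30, 60, 90, 120, 150)) {
      g0 <- cap_geometry(D, th)
      r <- g0$sphere_radius_mm
      a <- 1.3 # arbitrary baseline height
      cy <- a - r * cos(th * pi / 180)
      g <- circle_baseline_geometry(0.7, cy, r, a)
      expect_equal(g$chord, D, tolerance = 1e-9)
      expect_equal(g$theta_deg, th, tolerance = 1e-9)
      expect_equal(cap_volume(g$chord, g$theta_deg), g0$volume_uL,
                   tolerance = 1e-9)
    }
  }
})

test_that("calibration is invariant to image resolution", {
  # the same 2.5 mm object seen at 1x and 2x resolution
  c1 <- calibrate(10, 1028)
  c2 <- calibrate(10, 2056)
  span1 <- 2.5 / c1$mm_per_px
  span2 <- 2.5 / c2$mm_per_px
  expect_equal(span1 * c1$mm_per_px, span2 * c2$mm_per_px)
})

test_that("cap_geometry exposes height and sphere radius consistently", {
  g <- cap_geometry(2, 60)
  th <- pi / 3
  expect_equal(g$height_mm, 1 * (1 - cos(th)) / sin(th), tolerance = 1e-12)
  expect_equal(g$sphere_radius_mm, 1 / sin(th), tolerance = 1e-12)
  # hemisphere: height equals base radius, sphere radius equals base radius
  g90 <- cap_geometry(2, 90)
  expect_equal(g90$height_mm, 1)
  expect_equal(g90$sphere_radius_mm, 1)
})
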