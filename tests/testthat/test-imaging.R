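test_that("preprocessing yields four single-channel views of matching size", {
  r <- render_droplet(render_spec(2, 100, seed = 4))
  rgb <- array(rep(r$image, 3), dim = c(dim(r$image), 3))
  v <- preprocess_droplet(rgb)
  for (view in list(v$gray, v$edges, v$binary, v$merged)) {
    expect_true(is.matrix(view))
    expect_equal(dim(view), dim(r$image))
  }
  expect_true(all(v$edges %in% c(0, 1)))
  expect_true(all(v$binary %in% c(0, 1)))
  # droplet foreground is dark in the binary view
  expect_equal(v$binary[r$circle_px$cy - 5, round(r$circle_px$cx)], 0)
})

test_that("a uniform image has no edges and an empty image errors", {
  v <- preprocess_droplet(matrix(0.5, 60, 60))
  expect_equal(sum(v$edges), 0)
  expect_error(preprocess_droplet(matrix(numeric(0), 0, 0)),
               class = "dropsizer_error_input")
})

test_that("edge pixels trace the true droplet boundary", {
  s <- render_spec(2, 100, seed = 8)
  r <- render_droplet(s)
  v <- preprocess_droplet(r$image)
  circ <- r$circle_px
  H <- nrow(r$image)
  idx <- which(v$edges == 1, arr.ind = TRUE)
  er <- idx[, 1] - 1; ec <- idx[, 2] - 1

  # sample points along the visible cap arc and require a detected edge
  # within 2 px of nearly all of them
  th <- r$truth$theta_deg * pi / 180
  phi <- seq(-0.95, 0.95, length.out = 80) * th
  cy_phys <- (H - 1) - circ$cy
  bx <- circ$cx + circ$radius * sin(phi)
  by_down <- (H - 1) - (cy_phys + circ$radius * cos(phi))
  covered <- vapply(seq_along(phi), function(i) {
    min((er - by_down[i])^2 + (ec - bx[i])^2) <= 4
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("the circle detector recovers a rendered circle to 2 px", {
  set.seed(2)
  img <- matrix(1, 320, 400)
  img <- draw_disk(img, cx = 200, cy = 150, radius = 100)
  img <- pmin(pmax(img + matrix(rnorm(320 * 400, 0, 3 / 255), 320, 400), 0), 1)
  v <- preprocess_droplet(img)
  dc <- detect_circle(v)
  expect_lt(abs(dc$circle$cx - 200), 2)
  expect_lt(abs(dc$circle$cy - 150), 2)
  expect_lt(abs(dc$circle$radius - 100), 2)
  expect_gt(dc$score, 0.4)
})

test_that("with two circles in range the larger high-scoring one wins", {
  img <- matrix(1, 400, 500)
  img <- draw_disk(img, cx = 160, cy = 200, radius = 100)
  img <- draw_disk(img, cx = 380, cy = 120, radius = 40)
  v <- preprocess_droplet(img)
  dc <- detect_circle(v)
  expect_lt(abs(dc$circle$radius - 100), 2)
  expect_lt(abs(dc$circle$cx - 160), 2)
})

test_that("blank images raise NoCircleFound", {
  v <- preprocess_droplet(matrix(1, 200, 200))
  expect_error(detect_circle(v), class = "dropsizer_error_no_circle")
})

test_that("the baseline detector finds the substrate row", {
  s <- render_spec(2, 100, seed = 5)
  r <- render_droplet(s)
  v <- preprocess_droplet(r$image)
  dc <- detect_circle(v)
  bl <- detect_baseline(v, dc)
  expect_lt(abs(bl - r$baseline_px), 1)

  # override short-circuits detection entirely
  expect_equal(detect_baseline(v, dc, override = 250), 250)

  # an edge-free image has no baseline
  v0 <- preprocess_droplet(matrix(0.5, 100, 100))
  expect_error(detect_baseline(v0), class = "dropsizer_error_no_baseline")
})

test_that("measured volumes match ground truth on clean renders", {
  r90 <- render_droplet(render_spec(2, 90, seed = 1))
  m90 <- measure_droplet(r90$image, default_cal)
  expect_lt(abs(m90$volume_uL - 2.0944) / 2.0944, 0.05)

  r60 <- render_droplet(render_spec(2, 60, seed = 1))
  m60 <- measure_droplet(r60$image, default_cal)
  expect_lt(abs(m60$volume_uL - 1.0077) / 1.0077, 0.05)
  expect_lt(abs(m60$theta_deg - 60), 2)
})

test_that("a baseline entirely below the circle gives NoIntersection", {
  r <- render_droplet(render_spec(2, 90, seed = 1))
  cfg <- pipeline_config(baseline_override = nrow(r$image) + 400)
  err <- tryCatch(measure_droplet(r$image, default_cal, cfg),
                  error = function(e) e)
  expect_s3_class(err, "dropsizer_error_no_intersection")
  expect_match(conditionMessage(err), "circle_baseline_geometry")
})

test_that("batch measurement isolates per-image failures and is deterministic", {
  dir <- withr::local_tempdir()
  mf <- render_batch(list(render_spec(1.8, 85, seed = 1),
                          render_spec(2.4, 105, seed = 2)), dir)
  paths <- c(mf$path, file.path(dir, "missing.png"))
  res <- measure_batch(paths, default_cal)
  expect_equal(nrow(res), 3)
  expect_equal(res$status[1:2], c("ok", "ok"))
  expect_match(res$status[3], "error")
  expect_true(is.na(res$volume_uL[3]))
  expect_equal(res$image, paths)

  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  write_measurements(measure_batch(paths, default_cal), f1)
  write_measurements(measure_batch(paths, default_cal), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(measure_batch(character(0), default_cal),
               class = "dropsizer_error_input")
})
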