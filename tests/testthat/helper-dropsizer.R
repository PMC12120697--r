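# shared fixtures and independent oracles for the test suite

default_cal <- calibrate(10, 1028)

# classical spherical-cap volume V = (pi h / 6) (3 a^2 + h^2); independent of
# the closed form used by cap_volume()
cap_volume_classical <- function(diameter_mm, theta_deg) {
  th <- theta_deg * pi / 180
  a <- diameter_mm / 2
  h <- a * (1 - cos(th)) / sin(th)
  pi * h / 6 * (3 * a^2 + h^2)
}

# Kasa algebraic least-squares circle fit through >= 3 points
lsq_circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  list(cx = sol[1], cy = sol[2], radius = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

# five-point-style manual oracle: least-squares circle through points sampled
# on the true rendered boundary, then chord/angle/volume via the geometry
# module's closed forms
manual_volume_oracle <- function(render, mm_per_px, n_points = 7) {
  circ <- render$circle_px
  H <- nrow(render$image)
  th_true <- render$truth$theta_deg * pi / 180
  # angles on the cap arc, measured in the y-up frame from the upward vertical
  phi <- seq(-0.9, 0.9, length.out = n_points) * th_true
  cy_phys <- (H - 1) - circ$cy
  px <- circ$cx + circ$radius * sin(phi)
  py <- cy_phys + circ$radius * cos(phi)
  fit <- lsq_circle_fit(px * mm_per_px, py * mm_per_px)
  a_mm <- ((H - 1) - render$baseline_px) * mm_per_px
  g <- circle_baseline_geometry(fit$cx, fit$cy, fit$radius, a_mm)
  cap_volume(g$chord, g$theta_deg)
}

# small grid-sampled records with a known linear response, for exact-fit tests
linear_records <- function(n = 40, seed = 5) {
  cfg <- generator_config(noise_cv = 0, seed = seed)
  rec <- generate_records(n, cfg, seed = seed)
  rec$volume_uL <- 2 + 3 * rec$printing_time_s * 10 + 0.5 * rec$pressure_psi
  rec
}

# draw a filled dark disk onto a light canvas (for detector tests)
draw_disk <- function(img, cx, cy, radius) {
  H <- nrow(img); W <- ncol(img)
  y <- seq_len(H) - 1; x <- seq_len(W) - 1
  d <- sqrt(outer((y - cy)^2, (x - cx)^2, `+`))
  img[d <= radius] <- 0
  img
}
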