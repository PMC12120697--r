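#' Specification for a rendered side-view droplet image
#'
#' Describes one synthetic sessile droplet: its physical geometry (base
#' diameter and contact angle), the imaging scale, frame size, substrate
#' position, and the noise/blur model. When `image_size_px` or
#' `baseline_row_px` are `NULL` they are sized automatically so the droplet
#' fits with a comfortable margin.
#'
#' In the rendered frame the continuum contact line sits exactly on the pixel
#' boundary below `baseline_row_px`: pixel rows `<= baseline_row_px` can carry
#' droplet, and the dark substrate band starts at `baseline_row_px + 1`.
#'
#' @param diameter_mm Base diameter, mm.
#' @param theta_deg Contact angle, degrees, in (0, 180).
#' @param mm_per_px Imaging scale; default is a typical calibrated value for
#'   a 10 mm ruler spanning 1028 px.
#' @param image_size_px `c(height, width)` in pixels, or `NULL` to autosize.
#' @param baseline_row_px Row (0-based) of the last droplet-bearing pixel row,
#'   or `NULL` to place the substrate near the bottom of the frame.
#' @param noise Standard deviation of additive Gaussian pixel noise on the
#'   0-1 intensity scale (0 disables).
#' @param blur_sigma_px Gaussian blur applied before noise (0 disables).
#' @param seed Integer seed fixing the noise.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(diameter_mm, theta_deg, mm_per_px = 10 / 1028,
                        image_size_px = NULL, baseline_row_px = NULL,
                        noise = 0, blur_sigma_px = 1, seed = 1L) {
  check_cap_args(diameter_mm, theta_deg)
  stopifnot(mm_per_px > 0, noise >= 0, blur_sigma_px >= 0)
  geom <- cap_geometry(diameter_mm, theta_deg)
  r_px <- geom$sphere_radius_mm / mm_per_px
  extent_px <- if (theta_deg > 90) 2 * r_px else diameter_mm / mm_per_px
  height_px <- geom$height_mm / mm_per_px
  margin <- 48
  if (is.null(image_size_px)) {
    # frame tall/wide enough that the sphere radius sits inside the default
    # detector search range (<= 60% of the smaller dimension)
    min_dim <- ceiling(r_px / 0.55)
    image_size_px <- c(max(ceiling(height_px + margin + 24), min_dim),
                       max(ceiling(extent_px + 2 * margin), min_dim))
  }
  if (is.null(baseline_row_px)) {
    baseline_row_px <- image_size_px[1] - 21
  }
  spec <- structure(
    list(diameter_mm = diameter_mm, theta_deg = theta_deg,
         mm_per_px = mm_per_px,
         image_size_px = as.integer(image_size_px),
         baseline_row_px = as.integer(baseline_row_px),
         noise = noise, blur_sigma_px = blur_sigma_px,
         seed = as.integer(seed)),
    class = "render_spec"
  )
  # the droplet must fit fully inside the frame
  apex_row <- baseline_row_px - height_px
  if (apex_row < 1 || extent_px + 2 >= image_size_px[2] ||
      baseline_row_px + 3 > image_size_px[1]) {
    stop_dropsizer("Droplet does not fit inside the requested frame.",
                   class = "dropsizer_error_render")
  }
  spec
}

#' Render a synthetic sessile droplet with analytic ground truth
#'
#' Draws the spherical-cap silhouette (dark droplet and substrate band on a
#' light background), applies the spec's Gaussian blur, then seeded additive
#' Gaussian noise. The returned ground truth is computed analytically by the
#' geometry module, so rendered images carry an exact reference measurement
#' for testing the imaging pipeline.
#'
#' @param spec A [render_spec()].
#' @return A list with:
#'   * `image`: numeric height x width matrix, intensities in 0-1;
#'   * `truth`: one-row tibble from [cap_geometry()];
#'   * `circle_px`: true circle in the y-down pixel frame
#'     (`cx`, `cy`, `radius`, 0-based);
#'   * `baseline_px`: true continuum baseline row (0-based, half-integer).
#' @export
render_droplet <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  truth <- cap_geometry(spec$diameter_mm, spec$theta_deg)
  r <- truth$sphere_radius_mm / spec$mm_per_px
  th <- spec$theta_deg * pi / 180

  # y-up physical pixel coordinates; continuum baseline on pixel boundary
  a_phys <- (H - 1) - spec$baseline_row_px - 0.5
  cy_phys <- a_phys - r * cos(th)
  cx <- (W - 1) / 2

  y_phys <- (H - 1) - (seq_len(H) - 1)
  x <- seq_len(W) - 1
  dy2 <- (y_phys - cy_phys)^2
  dist <- sqrt(outer(dy2, (x - cx)^2, `+`))
  alpha <- pmin(pmax(r - dist + 0.5, 0), 1)
  alpha[(seq_len(H) - 1) > spec$baseline_row_px, ] <- 0
  img <- 1 - alpha
  # solid dark substrate filling everything below the wetting plane
  img[(seq_len(H) - 1) > spec$baseline_row_px, ] <- 0

  if (spec$blur_sigma_px > 0) {
    img <- ebi_blur(img, spec$blur_sigma_px)
  }
  if (spec$noise > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise), H, W)
  }
  img <- pmin(pmax(img, 0), 1)

  list(
    image = img,
    truth = truth,
    circle_px = list(cx = cx, cy = (H - 1) - cy_phys, radius = r),
    baseline_px = spec$baseline_row_px + 0.5
  )
}

# Gaussian blur via EBImage (isotropic, so the x/y transposition of EBImage's
# frame convention is irrelevant). gblur convolves circularly, so the image is
# padded with replicated borders first and cropped afterwards.
ebi_blur <- function(m, sigma) {
  p <- ceiling(4 * sigma) + 1
  H <- nrow(m); W <- ncol(m)
  ri <- c(rep(1, p), seq_len(H), rep(H, p))
  ci <- c(rep(1, p), seq_len(W), rep(W, p))
  padded <- m[ri, ci]
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(padded), sigma = sigma))
  out[p + seq_len(H), p + seq_len(W)]
}

#' Base diameter that yields a target cap volume at a given contact angle
#'
#' Inverts the spherical-cap volume formula at fixed contact angle; used to
#' construct droplet renders with prescribed volumes.
#'
#' @param volume_uL Target volume, uL. Vectorised.
#' @param theta_deg Contact angle, degrees.
#' @return Base diameter in mm.
#' @export
cap_diameter_for_volume <- function(volume_uL, theta_deg) {
  stopifnot(all(volume_uL > 0))
  th <- theta_deg * pi / 180
  (24 * volume_uL * sin(th)^3 / (pi * (2 - 3 * cos(th) + cos(th)^3)))^(1 / 3)
}

#' Render a batch of droplets to PNG files with a manifest
#'
#' @param specs A list of [render_spec()] objects.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return A tibble manifest: `path`, true `diameter_mm`, `theta_deg`,
#'   `volume_uL` and `seed`, one row per image, in input order.
#' @export
render_batch <- function(specs, dir, prefix = "droplet") {
  stopifnot(length(specs) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::imap(specs, function(spec, i) {
    r <- render_droplet(spec)
    path <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
    png::writePNG(r$image, path)
    tibble::tibble(
      path = path,
      diameter_mm = r$truth$diameter_mm,
      theta_deg = r$truth$theta_deg,
      volume_uL = r$truth$volume_uL,
      seed = spec$seed
    )
  })
  dplyr::bind_rows(rows)
}
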