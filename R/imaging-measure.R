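#' Pipeline configuration for droplet measurement
#'
#' @param preprocess A [preprocess_config()].
#' @param detector A [detector_config()].
#' @param baseline_override Optional known baseline row (0-based, y-down
#'   pixels); skips baseline detection.
#' @param baseline_min_run Optional minimum horizontal edge-run length for
#'   baseline detection (pixels).
#' @param save_merged If `TRUE`, [measure_batch()] writes each merged
#'   analysis view next to its input with suffix `_merged.png`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            detector = detector_config(),
                            baseline_override = NULL,
                            baseline_min_run = NULL,
                            save_merged = FALSE) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(detector, "detector_config"))
  structure(list(preprocess = preprocess, detector = detector,
                 baseline_override = baseline_override,
                 baseline_min_run = baseline_min_run,
                 save_merged = save_merged),
            class = "pipeline_config")
}

#' Measure one sessile droplet from a side-view image
#'
#' Runs the full measurement pipeline: preprocessing into grayscale, edge and
#' binary views; gradient-voting Hough circle detection on the merged view;
#' substrate baseline detection; conversion from the y-down pixel frame into
#' a y-up physical frame in millimetres; circle-baseline intersection for
#' base diameter and contact angle; and the spherical-cap volume.
#'
#' @param image An image matrix/array, or a path to a PNG/TIFF file.
#' @param calibration A [calibrate()] result.
#' @param config A [pipeline_config()].
#' @return A one-row tibble: `diameter_mm`, `theta_deg`, `height_mm`,
#'   `volume_uL`, contact points `ax_mm`/`bx_mm`, the detected circle in
#'   pixels (`circle_cx_px`, `circle_cy_px`, `circle_r_px`, `circle_score`),
#'   `baseline_row_px` and `status` (`"ok"`).
#' @examples
#' spec <- render_spec(2, 90, seed = 3)
#' r <- render_droplet(spec)
#' measure_droplet(r$image, calibrate(10, 1028))
#' @export
measure_droplet <- function(image, calibration, config = pipeline_config()) {
  stopifnot(inherits(calibration, "calibration"),
            inherits(config, "pipeline_config"))
  if (is.character(image)) image <- read_droplet_image(image)

  views <- with_stage("preprocess", preprocess_droplet(image, config$preprocess))
  dc <- with_stage("detect_circle", detect_circle(views, config$detector))
  bl <- with_stage("detect_baseline",
                   detect_baseline(views, circle = dc,
                                   override = config$baseline_override,
                                   min_run = config$baseline_min_run))

  H <- nrow(views$gray)
  s <- calibration$mm_per_px
  # y-down pixel rows -> y-up physical frame, then to mm
  cx_mm <- dc$circle$cx * s
  cy_mm <- ((H - 1) - dc$circle$cy) * s
  r_mm <- dc$circle$radius * s
  a_mm <- ((H - 1) - bl) * s

  geom <- with_stage("circle_baseline_geometry",
                     circle_baseline_geometry(cx_mm, cy_mm, r_mm, a_mm))
  cap <- cap_geometry(geom$chord, geom$theta_deg)

  tibble::tibble(
    diameter_mm = geom$chord,
    theta_deg = geom$theta_deg,
    height_mm = cap$height_mm,
    volume_uL = cap$volume_uL,
    ax_mm = geom$ax, bx_mm = geom$bx,
    circle_cx_px = dc$circle$cx,
    circle_cy_px = dc$circle$cy,
    circle_r_px = dc$circle$radius,
    circle_score = dc$score,
    baseline_row_px = bl,
    status = "ok"
  )
}

# re-raise any pipeline error with the failing stage named, preserving class
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    dropsizer_error = function(e) {
      e$message <- paste0(stage, ": ", conditionMessage(e))
      stop(e)
    }
  )
}

#' Measure a batch of droplet images
#'
#' Applies [measure_droplet()] to each path. Per-image failures are recorded
#' in the `status` column (stage-named message) with `NA` measurements and
#' never abort the batch. Row order equals input order.
#'
#' @param image_paths Character vector of image paths (length >= 1).
#' @inheritParams measure_droplet
#' @return A tibble with one row per image: `image` (path) plus the
#'   [measure_droplet()] columns.
#' @export
measure_batch <- function(image_paths, calibration, config = pipeline_config()) {
  if (length(image_paths) < 1) {
    stop_dropsizer("`image_paths` must contain at least one path.",
                   class = "dropsizer_error_input")
  }
  na_row <- tibble::tibble(
    diameter_mm = NA_real_, theta_deg = NA_real_, height_mm = NA_real_,
    volume_uL = NA_real_, ax_mm = NA_real_, bx_mm = NA_real_,
    circle_cx_px = NA_real_, circle_cy_px = NA_real_, circle_r_px = NA_real_,
    circle_score = NA_real_, baseline_row_px = NA_real_, status = NA_character_
  )
  rows <- purrr::map(image_paths, function(p) {
    out <- tryCatch(
      {
        m <- measure_droplet(p, calibration, config)
        if (isTRUE(config$save_merged)) {
          v <- preprocess_droplet(read_droplet_image(p), config$preprocess)
          png::writePNG(v$merged, sub("\\.(png|tif|tiff)$", "_merged.png",
                                      p, ignore.case = TRUE))
        }
        m
      },
      error = function(e) {
        r <- na_row
        r$status <- paste0("error: ", conditionMessage(e))
        r
      }
    )
    dplyr::bind_cols(tibble::tibble(image = p), out)
  })
  dplyr::bind_rows(rows)
}

#' Write a batch measurement table to CSV
#'
#' Columns follow the batch-report schema (`image`, `diameter_mm`,
#' `contact_angle_deg`, `volume_uL`, `status`); diameters and volumes are
#' written to 4 significant figures and angles to 2 decimal places, the
#' package's reporting convention.
#'
#' @param measurements A [measure_batch()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- tibble::tibble(
    image = measurements$image,
    diameter_mm = signif(measurements$diameter_mm, 4),
    contact_angle_deg = round(measurements$theta_deg, 2),
    volume_uL = signif(measurements$volume_uL, 4),
    status = measurements$status
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Plot a measured droplet with its detected circle and baseline
#'
#' @param image Image matrix or path.
#' @param measurement One-row tibble from [measure_droplet()].
#' @return A ggplot object: the image raster with the fitted circle, the
#'   baseline and the contact points overlaid.
#' @export
plot_measurement <- function(image, measurement) {
  if (is.character(image)) image <- read_droplet_image(image)
  g <- to_gray(image)
  H <- nrow(g); W <- ncol(g)
  df <- tidyr::expand_grid(row = seq_len(H) - 1, col = seq_len(W) - 1)
  df$value <- as.vector(t(g))
  tt <- seq(0, 2 * pi, length.out = 361)
  circ <- tibble::tibble(
    col = measurement$circle_cx_px + measurement$circle_r_px * cos(tt),
    row = measurement$circle_cy_px + measurement$circle_r_px * sin(tt)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = circ, colour = "#D55E00", linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = measurement$baseline_row_px,
                        colour = "#0072B2", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("D = %.4g mm, theta = %.2f deg, V = %.4g uL",
                      measurement$diameter_mm, measurement$theta_deg,
                      measurement$volume_uL)
    )
}
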