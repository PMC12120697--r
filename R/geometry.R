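#' Pixel-to-millimetre calibration
#'
#' Converts a known physical length and its measured span in image pixels into
#' a scale factor. A ruler (or any object of known length) photographed in the
#' droplet plane gives the span; the resulting factor translates every pixel
#' measurement into millimetres.
#'
#' @param known_length_mm Physical length of the reference object, in mm.
#' @param span_px Length of the same object measured in the image, in pixels.
#'
#' @return An object of class `calibration`: a list with `known_length_mm`,
#'   `span_px` and the derived `mm_per_px`.
#' @examples
#' calibrate(10, 1028) # 0.009728 mm per pixel
#' @export
calibrate <- function(known_length_mm, span_px) {
  if (!is.numeric(known_length_mm) || length(known_length_mm) != 1 ||
      !is.finite(known_length_mm) || known_length_mm <= 0) {
    stop_dropsizer("`known_length_mm` must be a single positive number.",
                   class = "dropsizer_error_calibration")
  }
  if (!is.numeric(span_px) || length(span_px) != 1 ||
      !is.finite(span_px) || span_px <= 0) {
    stop_dropsizer("`span_px` must be a single positive number.",
                   class = "dropsizer_error_calibration")
  }
  structure(
    list(
      known_length_mm = known_length_mm,
      span_px = span_px,
      mm_per_px = known_length_mm / span_px
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g mm over %g px = %.6f mm/px\n",
              x$known_length_mm, x$span_px, x$mm_per_px))
  invisible(x)
}

#' Intersection of a circle with a horizontal baseline
#'
#' The side profile of a sessile droplet is modelled as a circle cut by the
#' horizontal substrate line `y = a`. This computes the two contact points A
#' and B, the base chord between them, and the contact angle of the circular
#' cap lying *above* the baseline. All coordinates are in a y-up physical
#' frame (image pixel rows must be flipped before calling; see
#' [measure_droplet()]).
#'
#' The contact angle follows `theta = acos((a - cy) / r)`: a center above the
#' baseline gives theta > 90 deg (hydrophobic substrate), a center below gives
#' theta < 90 deg.
#'
#' @param cx,cy Circle center coordinates (any consistent unit).
#' @param radius Circle radius (> 0), same unit.
#' @param a Baseline height `y = a`, same unit and frame.
#'
#' @return A one-row tibble: `ax`, `ay`, `bx`, `by` (contact points),
#'   `chord` (base diameter `|AB|`) and `theta_deg`.
#' @examples
#' circle_baseline_geometry(0, 0.5, 1, 0) # theta 120 deg
#' @export
circle_baseline_geometry <- function(cx, cy, radius, a) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(radius), is.numeric(a))
  if (!is.finite(radius) || radius <= 0) {
    stop_dropsizer("`radius` must be positive.", class = "dropsizer_error_geometry")
  }
  if (abs(a - cy) >= radius) {
    stop_dropsizer(
      sprintf(
        "Baseline y = %g does not intersect the circle (center y = %g, radius = %g).",
        a, cy, radius
      ),
      class = "dropsizer_error_no_intersection"
    )
  }
  half <- sqrt(radius^2 - (a - cy)^2)
  theta <- acos((a - cy) / radius) * 180 / pi
  tibble::tibble(
    ax = cx - half, ay = a,
    bx = cx + half, by = a,
    chord = 2 * half,
    theta_deg = theta
  )
}

#' Spherical-cap droplet volume from base diameter and contact angle
#'
#' The volume of an axisymmetric sessile droplet modelled as a spherical cap:
#'
#' \deqn{V = \frac{\pi D^3}{24} \cdot
#'       \frac{2 - 3\cos\theta + \cos^3\theta}{\sin^3\theta}}
#'
#' with `D` the base diameter in mm and `theta` the contact angle in degrees.
#' With `D` in mm the volume comes out in cubic millimetres, i.e. microlitres.
#' At `theta = 90` this reduces exactly to the hemisphere `pi D^3 / 12`.
#'
#' @param diameter_mm Base chord diameter, mm. Vectorised.
#' @param theta_deg Contact angle in degrees, strictly inside (0, 180).
#'   Vectorised.
#'
#' @return Numeric vector of volumes in microlitres.
#' @seealso [cap_geometry()] for the cap height and sphere radius as well.
#' @examples
#' cap_volume(2, 90)              # hemisphere: pi * 8 / 12
#' cap_volume(c(1, 2, 3), 60)
#' @export
cap_volume <- function(diameter_mm, theta_deg) {
  check_cap_args(diameter_mm, theta_deg)
  th <- theta_deg * pi / 180
  (pi * diameter_mm^3 / 24) * (2 - 3 * cos(th) + cos(th)^3) / sin(th)^3
}

#' Full spherical-cap geometry
#'
#' Expands a (base diameter, contact angle) pair into the derived cap
#' quantities: apex height `h = (D/2)(1 - cos(theta))/sin(theta)`, the radius
#' `r_s = (D/2)/sin(theta)` of the sphere the cap is cut from, and the volume.
#'
#' @inheritParams cap_volume
#' @return A tibble with columns `diameter_mm`, `theta_deg`, `height_mm`,
#'   `sphere_radius_mm`, `volume_uL`; one row per input element.
#' @export
cap_geometry <- function(diameter_mm, theta_deg) {
  check_cap_args(diameter_mm, theta_deg)
  th <- theta_deg * pi / 180
  tibble::tibble(
    diameter_mm = diameter_mm + 0 * theta_deg,
    theta_deg = theta_deg + 0 * diameter_mm,
    height_mm = (diameter_mm / 2) * (1 - cos(th)) / sin(th),
    sphere_radius_mm = (diameter_mm / 2) / sin(th),
    volume_uL = cap_volume(diameter_mm, theta_deg)
  )
}

check_cap_args <- function(diameter_mm, theta_deg) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm < 0)) {
    stop_dropsizer("`diameter_mm` must be non-negative and finite.",
                   class = "dropsizer_error_geometry")
  }
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0) || any(theta_deg >= 180)) {
    stop_dropsizer("`theta_deg` must lie strictly between 0 and 180 degrees.",
                   class = "dropsizer_error_geometry")
  }
  invisible(NULL)
}

# classed condition helper used across the package
stop_dropsizer <- function(message, class, call = NULL) {
  cond <- structure(
    class = c(class, "dropsizer_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}
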