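#' Circle detector configuration
#'
#' The detector searches radii between `rmin_frac` and `rmax_frac` of the
#' smaller image dimension (the plausible droplet size range for a framed
#' side-view photograph), and rejects candidates whose edge support covers
#' less than `min_score` of the circle circumference.
#'
#' @param rmin_frac,rmax_frac Radius search range as fractions of
#'   `min(height, width)`.
#' @param max_candidates Number of accumulator peaks examined.
#' @param min_score Minimum fraction of circumference supported by edge
#'   pixels.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(rmin_frac = 0.05, rmax_frac = 0.6,
                            max_candidates = 5, min_score = 0.2) {
  stopifnot(rmin_frac > 0, rmax_frac > rmin_frac, rmax_frac <= 1,
            max_candidates >= 1, min_score >= 0)
  structure(list(rmin_frac = rmin_frac, rmax_frac = rmax_frac,
                 max_candidates = max_candidates, min_score = min_score),
            class = "detector_config")
}

#' Detect the droplet circle with a gradient-voting Hough transform
#'
#' Two-stage circle Hough transform in the spirit of the OpenCV gradient
#' method: every edge pixel votes for candidate centers along its local
#' gradient direction at all radii in the search range; accumulator peaks are
#' then scored by the fraction of circumference supported by edge pixels at
#' the best-fitting radius. Center and radius are reported at 0.5-pixel
#' resolution (no further sub-pixel refinement). Selection is by score, ties
#' broken toward the larger radius, then the topmost center.
#'
#' @param views A [preprocess_droplet()] result.
#' @param config A [detector_config()].
#' @return An object of class `detected_circle`: list with `circle`
#'   (`cx`, `cy`, `radius`; 0-based y-down pixel coordinates) and `score`.
#' @export
detect_circle <- function(views, config = detector_config()) {
  stopifnot(inherits(views, "processed_views"))
  H <- nrow(views$edges); W <- ncol(views$edges)
  rmin <- max(5, floor(config$rmin_frac * min(H, W)))
  rmax <- floor(config$rmax_frac * min(H, W))
  idx <- which(views$edges == 1)
  if (length(idx) < 10) {
    stop_dropsizer("No circle found: too few edge pixels.",
                   class = "dropsizer_error_no_circle")
  }
  er <- (idx - 1) %% H          # 0-based row
  ec <- (idx - 1) %/% H         # 0-based col
  m <- views$gmag[idx]
  m[m == 0] <- 1
  uy <- views$gy[idx] / m
  ux <- views$gx[idx] / m

  # stage 1: center accumulator (integer grid), voting both ways along the
  # gradient so in/out orientation does not matter
  # the center may sit outside the frame (flat caps have their sphere center
  # below the substrate), so the accumulator rows extend by rmax both ways
  pad <- rmax
  HA <- H + 2 * pad
  votes <- vector("list", 2 * (rmax - rmin + 1))
  v <- 0L
  for (t in seq(rmin, rmax)) {
    for (s in c(-1, 1)) {
      rr <- round(er + s * t * uy) + pad
      cc <- round(ec + s * t * ux)
      ok <- rr >= 0 & rr < HA & cc >= 0 & cc < W
      v <- v + 1L
      votes[[v]] <- rr[ok] + 1 + cc[ok] * HA
    }
  }
  acc <- tabulate(unlist(votes), nbins = HA * W)
  accm <- matrix(acc, HA, W)
  accs <- shift_mat(accm, 0, 0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr != 0 || dc != 0) accs <- accs + shift_mat(accm, dr, dc)
  }

  # stage 2: examine top accumulator peaks (non-max suppressed)
  ord <- order(accs, decreasing = TRUE)
  centers <- matrix(numeric(0), 0, 2)
  for (k in ord) {
    if (nrow(centers) >= config$max_candidates) break
    r0 <- (k - 1) %% HA - pad
    c0 <- (k - 1) %/% HA
    if (accs[k] < 3) break
    if (nrow(centers) == 0 ||
        min((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) > (rmin / 2)^2) {
      centers <- rbind(centers, c(r0, c0))
    }
  }

  best <- NULL
  for (ci in seq_len(nrow(centers))) {
    cand <- score_circle_candidate(centers[ci, 1], centers[ci, 2],
                                   er, ec, rmin, rmax)
    if (is.null(cand)) next
    # scores within 0.05 of each other count as a tie, resolved toward the
    # larger radius, then the topmost center
    if (is.null(best) ||
        cand$score > best$score + 0.05 ||
        (abs(cand$score - best$score) <= 0.05 &&
           (cand$radius > best$radius + 1e-9 ||
              (abs(cand$radius - best$radius) <= 1e-9 && cand$cy < best$cy)))) {
      best <- cand
    }
  }
  if (is.null(best) || best$score < config$min_score) {
    stop_dropsizer("No circle found above the score threshold.",
                   class = "dropsizer_error_no_circle")
  }
  structure(
    list(circle = list(cx = best$cx, cy = best$cy, radius = best$radius),
         score = best$score),
    class = "detected_circle"
  )
}

# Refine one accumulator peak on a 0.5 px grid and pick the radius with the
# strongest circumference support. Returns NULL when support is degenerate.
score_circle_candidate <- function(r0, c0, er, ec, rmin, rmax) {
  best <- NULL
  # the accumulator peak can sit a couple of pixels off the true center for
  # large radii (gradient-direction quantisation); search a +/- 2 px window
  # on the 0.5 px grid
  offs <- seq(-2, 2, by = 0.5)
  for (dy in offs) for (dx in offs) {
    cy <- r0 + dy; cx <- c0 + dx
    d <- sqrt((er - cy)^2 + (ec - cx)^2)
    inr <- d >= rmin - 1 & d <= rmax + 1
    if (sum(inr) < 10) next
    bins <- round(d[inr] * 2)          # 0.5 px radius bins
    tab <- tabulate(bins, nbins = 2 * (rmax + 2))
    rng <- seq(2 * rmin, 2 * (rmax + 1))
    tabr <- tab[rng]
    peak <- rng[which(tabr == max(tabr))]
    radius <- max(peak) / 2            # tie toward larger radius
    support <- sum(abs(d - radius) <= 0.75)
    score <- support / (2 * pi * radius)
    if (is.null(best) || score > best$score ||
        (score == best$score && radius > best$radius)) {
      best <- list(cx = cx, cy = cy, radius = radius, score = score)
    }
  }
  best
}

#' @export
print.detected_circle <- function(x, ...) {
  cat(sprintf("<detected_circle> center (%.1f, %.1f) px, radius %.1f px, score %.2f\n",
              x$circle$cx, x$circle$cy, x$circle$radius, x$score))
  invisible(x)
}

#' Detect the substrate baseline row
#'
#' Finds the horizontal substrate line the droplet rests on. Unless an
#' explicit `override` row is given, the detector scans image rows below the
#' top of the detected circle (the substrate always lies below the droplet
#' apex, whatever the contact angle) for long horizontal edge runs, computed
#' with one row of vertical tolerance because edge thinning may split a
#' perfectly horizontal edge between adjacent rows. Among qualifying rows the
#' bottommost is taken: the substrate edge is the lowest long horizontal edge
#' in a sessile-droplet image, which separates it from the near-horizontal
#' arc at the droplet apex. The returned row is
#' refined to sub-pixel precision by the vertical-gradient centroid across
#' the edge, so it denotes the continuum boundary in 0-based y-down pixel
#' units (typically half-integer).
#'
#' @param views A [preprocess_droplet()] result.
#' @param circle Optional [detect_circle()] result used to restrict the
#'   search region.
#' @param override Optional known baseline row; returned unchanged.
#' @param min_run Minimum edge run length (pixels) for a row to qualify;
#'   default `max(15, 5%` of image width`)`.
#' @return Baseline row as a single numeric (0-based, y-down).
#' @export
detect_baseline <- function(views, circle = NULL, override = NULL,
                            min_run = NULL) {
  stopifnot(inherits(views, "processed_views"))
  if (!is.null(override)) return(as.numeric(override))
  H <- nrow(views$edges); W <- ncol(views$edges)
  if (is.null(min_run)) min_run <- max(15, floor(0.05 * W))

  first_row <- 1L
  if (!is.null(circle)) {
    top <- circle$circle$cy - circle$circle$radius
    first_row <- max(1L, as.integer(floor(top)) + 1L)
  }
  banded <- pmax(views$edges, shift_mat(views$edges, 1, 0),
                 shift_mat(views$edges, -1, 0))
  runs <- apply(banded, 1, max_run_length)
  runs[seq_len(first_row - 1L)] <- 0
  best <- max(runs)
  if (best < min_run) {
    stop_dropsizer("No substrate baseline found (no sufficiently long horizontal edge run).",
                   class = "dropsizer_error_no_baseline")
  }
  row1 <- max(which(runs >= pmax(min_run, 0.4 * best))) # bottommost qualifying

  # sub-pixel: vertical-gradient-magnitude centroid across the edge, averaged
  # over the columns of the run; second pass recenters the window so it is
  # symmetric about the half-integer edge position
  cols <- which(banded[row1, ] == 1)
  est <- baseline_centroid(views$gy, row1, cols, H)
  baseline_centroid(views$gy, floor(est) + 1L, cols, H)
}

baseline_centroid <- function(gy, row1, cols, H) {
  rows_w <- pmin(pmax(row1 + (-3:4), 1), H)
  g <- abs(gy[rows_w, cols, drop = FALSE])
  wsum <- colSums(g)
  wsum[wsum == 0] <- 1
  centroid <- colSums(g * (rows_w - 1)) / wsum  # 0-based rows
  mean(centroid)
}

max_run_length <- function(v) {
  r <- rle(v == 1)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}
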