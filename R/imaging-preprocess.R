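#' Preprocessing configuration for droplet images
#'
#' @param canny_sigma Gaussian smoothing (pixels) applied before gradient
#'   computation in the edge detector.
#' @param canny_low,canny_high Hysteresis thresholds on the Sobel gradient
#'   magnitude, expressed on the 0-255 intensity scale.
#' @param merge_gray_weight Weight of the grayscale view in the merged
#'   composite (see [preprocess_droplet()]).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(canny_sigma = 1.4, canny_low = 50,
                              canny_high = 150, merge_gray_weight = 0.5) {
  stopifnot(canny_sigma > 0, canny_low > 0, canny_high >= canny_low,
            merge_gray_weight >= 0, merge_gray_weight <= 1)
  structure(list(canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high,
                 merge_gray_weight = merge_gray_weight),
            class = "preprocess_config")
}

#' Read a droplet image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric matrix (grayscale) or height x width x 3 array (RGB)
#'   with intensities in 0-1.
#' @export
read_droplet_image <- function(path) {
  if (!file.exists(path)) {
    stop_dropsizer(paste0("Image not found: ", path),
                   class = "dropsizer_error_input")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_dropsizer(paste0("Unsupported image format: .", ext),
                   class = "dropsizer_error_input")
  )
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3]
  } else if (length(dim(img)) == 3) {
    img <- img[, , 1] # gray + alpha
  }
  img
}

#' Three-stage preprocessing of a side-view droplet image
#'
#' Produces the four working views used by the measurement pipeline:
#'
#' * `gray`: luminance reduction of the input channels;
#' * `edges`: thinned binary edge map from a Gaussian-smoothed Sobel gradient
#'   with double-threshold hysteresis;
#' * `binary`: Otsu-thresholded two-level image with the droplet foreground
#'   dark (0);
#' * `merged`: the composite analysed downstream, the pixel-wise maximum of
#'   the inverted binary view and the edge map overlaid on an attenuated
#'   grayscale view, which reinforces the silhouette boundary while keeping
#'   interior contrast.
#'
#' The gradient fields (`gx`, `gy`, `gmag`) of the smoothed grayscale view
#' are carried along for the circle and baseline detectors.
#'
#' @param image Matrix (grayscale) or height x width x 3 array (RGB),
#'   intensities in 0-1 or 0-255.
#' @param config A [preprocess_config()].
#' @return An object of class `processed_views`.
#' @export
preprocess_droplet <- function(image, config = preprocess_config()) {
  if (is.null(dim(image)) || any(dim(image)[1:2] == 0)) {
    stop_dropsizer("Empty image.", class = "dropsizer_error_input")
  }
  gray <- to_gray(image)
  ed <- canny_edges(gray, sigma = config$canny_sigma,
                    low = config$canny_low, high = config$canny_high)
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  binary <- (gray > thr) * 1 # droplet (dark) -> 0, background -> 1
  merged <- pmax(config$merge_gray_weight * gray, 1 - binary, ed$edges)
  structure(
    list(gray = gray, edges = ed$edges, binary = binary, merged = merged,
         gx = ed$gx, gy = ed$gy, gmag = ed$gmag),
    class = "processed_views"
  )
}

#' @export
print.processed_views <- function(x, ...) {
  cat(sprintf("<processed_views> %d x %d px, %d edge pixels\n",
              nrow(x$gray), ncol(x$gray), sum(x$edges)))
  invisible(x)
}

to_gray <- function(image) {
  if (max(image, na.rm = TRUE) > 1) image <- image / 255
  if (length(dim(image)) == 3) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    image
  }
}

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dr, 1), H)
  ci <- pmin(pmax(seq_len(W) - dc, 1), W)
  m[ri, ci, drop = FALSE]
}

# Canny-style edge detection: Gaussian smoothing, Sobel gradient, non-maximum
# suppression quantised to four directions, double-threshold hysteresis with
# connected-component linking.
canny_edges <- function(gray, sigma = 1.4, low = 50, high = 150) {
  g <- ebi_blur(gray * 255, sigma)
  # Sobel kernels; gy positive toward increasing row index (downward)
  gx <- (shift_mat(g, -1, -1) + 2 * shift_mat(g, 0, -1) + shift_mat(g, 1, -1)) -
        (shift_mat(g, -1,  1) + 2 * shift_mat(g, 0,  1) + shift_mat(g, 1,  1))
  gy <- (shift_mat(g, -1, -1) + 2 * shift_mat(g, -1, 0) + shift_mat(g, -1, 1)) -
        (shift_mat(g,  1, -1) + 2 * shift_mat(g,  1, 0) + shift_mat(g,  1, 1))
  mag <- sqrt(gx^2 + gy^2)

  # non-maximum suppression along the quantised gradient direction
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  d0 <- (ang < 22.5) | (ang >= 157.5)          # horizontal gradient
  d45 <- ang >= 22.5 & ang < 67.5
  d90 <- ang >= 67.5 & ang < 112.5             # vertical gradient
  d135 <- ang >= 112.5 & ang < 157.5
  n1 <- matrix(0, nrow(g), ncol(g)); n2 <- n1
  n1[d0] <- shift_mat(mag, 0, 1)[d0];   n2[d0] <- shift_mat(mag, 0, -1)[d0]
  n1[d45] <- shift_mat(mag, 1, 1)[d45]; n2[d45] <- shift_mat(mag, -1, -1)[d45]
  n1[d90] <- shift_mat(mag, 1, 0)[d90]; n2[d90] <- shift_mat(mag, -1, 0)[d90]
  n1[d135] <- shift_mat(mag, -1, 1)[d135]; n2[d135] <- shift_mat(mag, 1, -1)[d135]
  keep <- mag >= n1 & mag >= n2

  weak <- keep & mag >= low
  strong <- keep & mag >= high
  edges <- hysteresis_link(weak, strong)
  # image border rows/cols carry replication artefacts; drop them
  edges[c(1, nrow(edges)), ] <- 0
  edges[, c(1, ncol(edges))] <- 0
  list(edges = edges * 1, gx = gx, gy = gy, gmag = mag)
}

hysteresis_link <- function(weak, strong) {
  if (!any(strong)) return(weak & FALSE)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keep_labels <- unique(lab[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  (lab %in% keep_labels) & weak
}
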