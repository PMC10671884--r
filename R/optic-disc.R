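# Optic disc localization: grayscale -> monochrome (quantile threshold +
# opening) -> largest bright blob. The disc radius is the ROD unit that
# scales every ring ROI downstream.

#' Localize the optic disc
#'
#' Converts the fundus image to grayscale (standard luminance weighting
#' 0.299 R + 0.587 G + 0.114 B), thresholds at an intensity quantile to get
#' a monochrome mask, applies morphological opening with a small disc
#' structuring element to drop speckle, and returns the centroid and
#' equivalent radius (`sqrt(area / pi)`) of the largest surviving connected
#' component.
#'
#' @param image a [fundus_image()].
#' @param brightness_quantile intensity quantile used as the threshold;
#'   the brightest `1 - brightness_quantile` fraction of pixels is kept.
#' @param min_area smallest component area (pixels) accepted as a disc.
#' @param opening_radius radius (pixels) of the opening structuring element.
#' @return an `optic_disc` object: `center` `(row, col)`, `radius` in
#'   pixels, `method = "auto"`.
#' @seealso [manual_od()] for the manual override.
#' @export
localize_od <- function(image, brightness_quantile = 0.995, min_area = 100,
                        opening_radius = 5) {
  stopifnot(inherits(image, "fundus_image"))
  if (brightness_quantile <= 0 || brightness_quantile >= 1)
    stop("brightness_quantile must lie in (0, 1)")
  px <- image$pixels
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  thr <- quantile(gray, brightness_quantile)
  if (thr <= min(gray))
    stop("disc not found: image intensity is (nearly) uniform; ",
         "supply the disc with manual_od()")
  mask <- (gray >= thr) * 1
  brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
  mask <- EBImage::opening(mask, brush)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0)
    stop("disc not found: no bright component survives opening; ",
         "supply the disc with manual_od()")
  areas <- tabulate(lab[lab > 0], nbins = n)
  if (max(areas) < min_area)
    stop("disc not found: largest bright component (", max(areas),
         " px) is below min_area = ", min_area,
         "; supply the disc with manual_od()")
  best <- which.max(areas)
  idx <- which(lab == best, arr.ind = TRUE)
  structure(list(center = c(mean(idx[, 1]), mean(idx[, 2])),
                 radius = sqrt(areas[best] / pi), method = "auto"),
            class = "optic_disc")
}

#' Manually specify the optic disc
#'
#' Pass-through constructor for a user-supplied disc center and radius,
#' used when automatic localization fails (e.g. pathology obscuring the
#' disc).
#'
#' @param center numeric `(row, col)` in pixels.
#' @param radius disc radius in pixels; must be positive.
#' @return an `optic_disc` with `method = "manual"`.
#' @export
manual_od <- function(center, radius) {
  if (length(center) != 2 || !is.numeric(center))
    stop("center must be a numeric (row, col) pair")
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a single positive number")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 method = "manual"),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("<optic_disc center=(%.1f, %.1f) radius=%.1f px [%s]>\n",
              x$center[1], x$center[2], x$radius, x$method))
  invisible(x)
}
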