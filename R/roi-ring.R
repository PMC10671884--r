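# Annular regions of interest around the optic disc, expressed in ROD
# (radius-of-optic-disc) multiples. The two standard rings are 2-3 ROD and
# 2-5 ROD.

#' Define a ring ROI
#'
#' @param disc an `optic_disc` (see [localize_od()], [manual_od()]).
#' @param inner_factor inner ring radius as a multiple of the disc radius.
#' @param outer_factor outer ring radius as a multiple of the disc radius;
#'   must exceed `inner_factor`.
#' @param name label used in feature tables; defaults to e.g. `"2-3ROD"`.
#' @return a `ring_roi` object.
#' @export
ring_roi <- function(disc, inner_factor = 2, outer_factor = 3,
                     name = sprintf("%g-%gROD", inner_factor, outer_factor)) {
  stopifnot(inherits(disc, "optic_disc"))
  if (inner_factor < 0 || inner_factor >= outer_factor)
    stop("need 0 <= inner_factor < outer_factor")
  structure(list(disc = disc, inner_factor = inner_factor,
                 outer_factor = outer_factor, name = name),
            class = "ring_roi")
}

#' Binary mask of a ring ROI
#'
#' Pixel `(r, c)` is inside iff
#' `inner_factor * R <= dist((r,c), center) < outer_factor * R` with
#' Euclidean distance on pixel centers (half-open interval, so adjacent
#' rings sharing a radius partition without double counting).
#'
#' @param roi a [ring_roi()].
#' @param shape integer `(height, width)`.
#' @return logical `height x width` matrix.
#' @export
ring_mask <- function(roi, shape) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  ctr <- roi$disc$center; R <- roi$disc$radius
  dr2 <- (seq_len(shape[1]) - ctr[1])^2
  dc2 <- (seq_len(shape[2]) - ctr[2])^2
  d <- sqrt(outer(dr2, dc2, `+`))
  d >= roi$inner_factor * R & d < roi$outer_factor * R
}

#' Clip a label map to a ring ROI
#'
#' Pixels outside the ring become background; inside pixels are unchanged.
#' Vessels crossing the ring boundary are truncated at the last inside
#' pixel. Idempotent, and never introduces non-background classes.
#'
#' @param labels a [label_map()].
#' @param roi a [ring_roi()].
#' @return a clipped [label_map()].
#' @export
clip_labels <- function(labels, roi) {
  stopifnot(inherits(labels, "vessel_label_map"))
  cls <- labels$classes
  cls[!ring_mask(roi, dim(cls))] <- AV_CLASSES[["background"]]
  label_map(cls, provenance = labels$provenance)
}
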