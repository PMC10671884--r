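# Synthetic phantom scenes: a bright disc plus artery/vein trees drawn
# from parametric curves with analytic/numeric ground truth. The truth is
# computed from the parametric form only - it never touches the raster or
# the pipeline - so it serves as an independent oracle for every stage.

#' Specify a parametric vessel curve
#'
#' Supported kinds and their parameters (all coordinates `(row, col)`,
#' pixels):
#' \itemize{
#'   \item `line`: `from`, `to`.
#'   \item `circular_arc`: `center`, `radius`, `theta` (length-2 angular
#'     range, radians; the point at angle t is
#'     `center + radius * (sin t, cos t)`).
#'   \item `sine`: `start`, `length` (along the axis), `amplitude`,
#'     `periods`, `orientation` (radians; 0 runs along columns).
#'   \item `cubic_bezier`: `p0`, `p1`, `p2`, `p3` control points.
#' }
#'
#' @param kind curve family.
#' @param ... kind-specific parameters (above).
#' @param width stroke width in pixels (>= 1).
#' @param vessel_class `"artery"` or `"vein"`.
#' @return a `curve_spec`.
#' @export
curve_spec <- function(kind = c("line", "circular_arc", "sine",
                                "cubic_bezier"),
                       ..., width = 3, vessel_class = c("artery", "vein")) {
  kind <- match.arg(kind)
  vessel_class <- match.arg(vessel_class)
  if (width < 1) stop("width must be >= 1")
  pars <- list(...)
  needed <- switch(kind,
    line = c("from", "to"),
    circular_arc = c("center", "radius", "theta"),
    sine = c("start", "length", "amplitude", "periods"),
    cubic_bezier = c("p0", "p1", "p2", "p3"))
  if (!all(needed %in% names(pars)))
    stop(kind, " needs parameters: ", paste(needed, collapse = ", "))
  if (kind == "sine" && is.null(pars$orientation)) pars$orientation <- 0
  structure(c(list(kind = kind, width = width,
                   vessel_class = vessel_class), pars),
            class = "curve_spec")
}

# Evaluate the parametric curve at t in [0, 1]; returns an n x 2 matrix.
.curve_xy <- function(spec, t) {
  switch(spec$kind,
    line = {
      cbind(spec$from[1] + t * (spec$to[1] - spec$from[1]),
            spec$from[2] + t * (spec$to[2] - spec$from[2]))
    },
    circular_arc = {
      th <- spec$theta[1] + t * (spec$theta[2] - spec$theta[1])
      cbind(spec$center[1] + spec$radius * sin(th),
            spec$center[2] + spec$radius * cos(th))
    },
    sine = {
      u <- t * spec$length
      v <- spec$amplitude * sin(2 * pi * spec$periods * t)
      a <- spec$orientation
      cbind(spec$start[1] + u * sin(a) + v * cos(a),
            spec$start[2] + u * cos(a) - v * sin(a))
    },
    cubic_bezier = {
      b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
      ctrl <- rbind(spec$p0, spec$p1, spec$p2, spec$p3)
      b %*% ctrl
    })
}

#' Analytic/numeric ground truth for a curve
#'
#' Chord from the parametric endpoints; arc length by dense polyline
#' integration (`nsamp` samples); interior inflection count from the sign
#' changes of the parametric curvature (analytically zero for lines and
#' arcs, `2k - 1` for a k-period sine); total absolute turning and mean
#' absolute curvature from the dense tangent field. Never calls any
#' pipeline code.
#'
#' @param spec a [curve_spec()].
#' @param nsamp number of dense samples for the numeric integrals.
#' @return one-row data frame: `chord`, `arc`, `inflections`,
#'   `total_turning`, `mean_abs_curvature`.
#' @export
curve_truth <- function(spec, nsamp = 10000) {
  t <- seq(0, 1, length.out = nsamp)
  P <- .curve_xy(spec, t)
  chord <- sqrt(sum((P[nsamp, ] - P[1, ])^2))
  steps <- sqrt(rowSums(diff(P)^2))
  arc <- sum(steps)
  d <- diff(P)
  phi <- atan2(d[, 1], d[, 2])
  dphi <- atan2(sin(diff(phi)), cos(diff(phi)))
  total_turning <- sum(abs(dphi))
  inflections <- switch(spec$kind,
    line = 0L,
    circular_arc = 0L,
    {
      kap <- dphi / steps[-1]
      s <- sign(kap)
      s[abs(kap) < max(abs(kap)) * 1e-3] <- 0
      s <- s[s != 0]
      if (length(s) < 2) 0L else sum(diff(s) != 0)
    })
  data.frame(chord = chord, arc = arc, inflections = inflections,
             total_turning = total_turning,
             mean_abs_curvature = total_turning / arc)
}

# Stamp a curve onto logical canvas `mask` at its stroke width.
.rasterize_curve <- function(spec, shape) {
  tr <- curve_truth(spec, nsamp = 512)
  nsamp <- max(512, ceiling(4 * tr$arc))
  P <- round(.curve_xy(spec, seq(0, 1, length.out = nsamp)))
  rad <- (spec$width - 1) / 2
  g <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                   dc = -ceiling(rad):ceiling(rad))
  g <- g[g$dr^2 + g$dc^2 <= rad^2 + 0.25, , drop = FALSE]
  mask <- matrix(FALSE, shape[1], shape[2])
  for (j in seq_len(nrow(g))) {
    r <- P[, 1] + g$dr[j]; c <- P[, 2] + g$dc[j]
    if (any(r < 1 | r > shape[1] | c < 1 | c > shape[2]))
      stop("curve extends outside the canvas")
    mask[cbind(r, c)] <- TRUE
  }
  mask
}

#' Render a phantom fundus scene
#'
#' Rasterizes a bright circular disc on a dark background plus the given
#' curves in their class colors (default palette: artery red, vein blue),
#' and returns the matching label map and the independent ground-truth
#' table. Rendering is deterministic: no anti-aliasing, no jitter, so the
#' same spec always yields bit-identical rasters.
#'
#' @param curves list of [curve_spec()]s; later curves overwrite earlier
#'   ones where they overlap (avoid overlaps unless testing junctions).
#' @param canvas integer `(height, width)`.
#' @param disc `NULL` or a list with `center` `(row, col)` and `radius`;
#'   drawn as a bright uniform circle.
#' @param background,disc_intensity gray levels in `[0, 255]`.
#' @param image_id,eye passed to the [fundus_image()].
#' @return list: `image` ([fundus_image()]), `labels` ([label_map()],
#'   provenance `"synthetic"`), `truth` (data frame, one row per curve:
#'   `curve`, `vessel_class`, `width` and the [curve_truth()] columns),
#'   `disc` (an `optic_disc` or `NULL`).
#' @export
render_phantom <- function(curves, canvas = c(400, 400), disc = NULL,
                           background = 26, disc_intensity = 242,
                           image_id = "phantom", eye = "unknown") {
  h <- canvas[1]; w <- canvas[2]
  px <- array(background, c(h, w, 3))
  cls <- matrix(AV_CLASSES[["background"]], h, w)
  disc_obj <- NULL
  if (!is.null(disc)) {
    if (disc$center[1] - disc$radius < 1 || disc$center[1] + disc$radius > h ||
        disc$center[2] - disc$radius < 1 || disc$center[2] + disc$radius > w)
      stop("disc extends outside the canvas")
    d2 <- outer((seq_len(h) - disc$center[1])^2,
                (seq_len(w) - disc$center[2])^2, `+`)
    inside <- d2 <= disc$radius^2
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[inside] <- disc_intensity
      px[, , ch] <- plane
    }
    disc_obj <- manual_od(disc$center, disc$radius)
  }
  truth <- NULL
  for (i in seq_along(curves)) {
    spec <- curves[[i]]
    m <- .rasterize_curve(spec, c(h, w))
    code <- AV_CLASSES[[spec$vessel_class]]
    cls[m] <- code
    col <- if (spec$vessel_class == "artery") c(255, 0, 0) else c(0, 0, 255)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- col[ch]
      px[, , ch] <- plane
    }
    truth <- rbind(truth, cbind(data.frame(curve = i,
                                           vessel_class = spec$vessel_class,
                                           width = spec$width),
                                curve_truth(spec)))
  }
  list(image = fundus_image(px, image_id = image_id, eye = eye),
       labels = label_map(cls, provenance = "synthetic"),
       truth = truth, disc = disc_obj)
}

#' Sample a cohort of phantom scenes
#'
#' Each scene draws 5-15 artery and 5-15 vein curves laid out as
#' horizontal sine strokes in disjoint bands (no crossings, so per-stage
#' behavior stays isolated), with lengths drawn LogNormal
#' (`meanlog = log(120)`, `sdlog = 0.3`), artery lengths multiplied by
#' `artery_scale`, and sine amplitudes proportional to curve length
#' (3.3-8.3% of it, times `tortuosity_level`), so each class's arc
#' lengths scale exactly with its length factor. A bright disc occupies
#' a reserved top band. Reproducible per `seed`.
#'
#' @param n_images number of scenes.
#' @param artery_scale multiplicative factor on artery lengths.
#' @param tortuosity_level multiplicative factor on sine amplitudes.
#' @param seed integer seed fixing the cohort.
#' @param eye eye tag applied to every scene.
#' @return list of scenes as returned by [render_phantom()].
#' @export
sample_population <- function(n_images, artery_scale = 1,
                              tortuosity_level = 1, seed = 1,
                              eye = "unknown") {
  stopifnot(n_images >= 1)
  set.seed(seed)
  lapply(seq_len(n_images), function(i) {
    n_a <- sample(5:15, 1)
    n_v <- sample(5:15, 1)
    cls <- sample(c(rep("artery", n_a), rep("vein", n_v)))
    lens <- rlnorm(n_a + n_v, meanlog = log(120), sdlog = 0.3)
    lens[cls == "artery"] <- lens[cls == "artery"] * artery_scale
    # amplitude proportional to length (geometric similarity), so scaling
    # a class's lengths by k scales its arc lengths by exactly k
    amps <- runif(n_a + n_v, 4, 10) / 120 * lens * tortuosity_level
    periods <- sample(1:2, n_a + n_v, replace = TRUE)
    band <- ceiling(2 * max(amps) + 8)
    disc_band <- 96
    h <- disc_band + band * (n_a + n_v) + 10
    w <- max(110, ceiling(max(lens)) + 40)
    curves <- lapply(seq_along(cls), function(j) {
      curve_spec("sine",
                 start = c(disc_band + band * (j - 1) + band / 2, 20),
                 length = lens[j], amplitude = amps[j],
                 periods = periods[j], width = 3, vessel_class = cls[j])
    })
    render_phantom(curves, canvas = c(h, w),
                   disc = list(center = c(46, 60), radius = 38),
                   image_id = sprintf("phantom_%03d", i), eye = eye)
  })
}
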