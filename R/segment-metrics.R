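# The nine per-segment length/tortuosity metrics. All angles are radians;
# curvature is 1/pixels. The normative discrete formulas are the ones in
# metrics_for_segment(); they are the standard tortuosity-literature
# definitions the metric names refer to.

.CHORD_EPS <- 1e-6
METRIC_NAMES <- c("chord", "arc", "dm", "icm", "icmb", "soam", "nc",
                  "sdac", "cl")

.seg_path <- function(seg) {
  if (inherits(seg, "vessel_segment")) seg$path else as.matrix(seg)
}

#' Chord length of a segment
#'
#' Euclidean distance between the first and last path pixels. For a
#' degenerate closed path (coincident ends) the chord is clamped to a small
#' epsilon so downstream ratios never divide by zero; such segments carry a
#' `degenerate` flag in [metrics_for_segment()].
#'
#' @param seg a `vessel_segment` or an n x 2 path matrix.
#' @return chord length in pixels.
#' @export
chord_length <- function(seg) {
  p <- .seg_path(seg)
  stopifnot(nrow(p) >= 2)
  max(sqrt(sum((p[nrow(p), ] - p[1, ])^2)), .CHORD_EPS)
}

#' Arc (geodesic) length of a segment
#'
#' Chain-code sum of Euclidean steps between consecutive path pixels
#' (1 for orthogonal, sqrt(2) for diagonal moves). On rasterized curves
#' this overestimates the true length by the classic chain-code bias:
#' zero for axis-aligned and 45-degree paths, up to 8.2% near 22.5
#' degrees, about 3% averaged over orientations of a smooth curve. The
#' smoothed centerline length `cl` is the low-bias counterpart.
#'
#' @inheritParams chord_length
#' @return arc length in pixels.
#' @export
arc_length <- function(seg) {
  p <- .seg_path(seg)
  stopifnot(nrow(p) >= 2)
  .path_arc(p)
}

#' Smooth a segment path and estimate tangents and curvature
#'
#' Coordinates are smoothed with a symmetric moving average of odd width
#' `window` (shrinking symmetrically near the ends, so the endpoints are
#' retained exactly). Tangents are per-interval unit direction vectors.
#' Signed curvature is the discrete turning of consecutive tangents
#' divided by the local step length; to suppress rasterization noise, the
#' turning is computed from the unwrapped tangent-angle series smoothed
#' with a moving average of width `2 * window - 1`. A straight path has
#' exactly zero curvature everywhere; `window = 1` leaves the coordinates
#' untouched.
#'
#' @inheritParams chord_length
#' @param window odd moving-average width in path samples (default 5).
#' @return a `smooth_path`: `points` (m x 2), `step_lengths` (m-1),
#'   `tangents` (m-1 x 2 unit vectors), `turning` (m-2 signed angles,
#'   radians), `curvatures` (m-2 signed, 1/pixels).
#' @export
smooth_path <- function(seg, window = 5) {
  p <- .seg_path(seg)
  if (nrow(p) < 5) stop("path too short to smooth (need >= 5 pixels)")
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  S <- .moving_average(p, window)
  ds <- sqrt(rowSums(diff(S)^2))
  S <- S[c(TRUE, ds > 1e-12), , drop = FALSE]
  d <- diff(S)
  sl <- sqrt(rowSums(d^2))
  tangents <- d / sl
  phi <- atan2(d[, 1], d[, 2])
  # unwrap, then smooth the angle series itself
  phi <- phi[1] + c(0, cumsum(atan2(sin(diff(phi)), cos(diff(phi)))))
  phs <- .moving_average(cbind(phi, 0), 2 * window - 1)[, 1]
  m <- nrow(S)
  turning <- diff(phs)
  sbar <- (sl[-(m - 1)] + sl[-1]) / 2
  structure(list(points = S, step_lengths = sl, tangents = tangents,
                 turning = turning, curvatures = turning / sbar,
                 window = window),
            class = "smooth_path")
}

.moving_average <- function(P, window) {
  n <- nrow(P)
  half <- (window - 1) / 2
  if (half == 0) return(P)
  out <- P
  for (i in seq_len(n)) {
    k <- min(i - 1, n - i, half)
    if (k > 0) out[i, ] <- colMeans(P[(i - k):(i + k), , drop = FALSE])
  }
  out
}

#' Count inflection points along a smoothed path
#'
#' `sign_change`: the number of sign changes of the smoothed signed
#' curvature; curvature with magnitude below `zero_tol` counts as zero and
#' sign runs shorter than `min_run` samples are discarded before counting,
#' which collapses zero-runs and rasterization chatter. `normal_flip`: the
#' classical large-flip criterion; unit normals (tangent rotated toward
#' the center of curvature) are evaluated along resolvable curvature sign
#' runs (same `zero_tol`/`min_run` debouncing), and positions where the
#' squared difference of consecutive normals exceeds 1 are counted.
#'
#' @param sp a [smooth_path()].
#' @param method `"sign_change"` or `"normal_flip"`.
#' @param zero_tol curvature magnitudes below this (1/pixels) are treated
#'   as zero (default 5e-3, i.e. radius of curvature beyond 200 px is
#'   considered straight).
#' @param min_run minimum length (samples) of a curvature sign run.
#' @return integer inflection count.
#' @export
inflection_count <- function(sp, method = c("sign_change", "normal_flip"),
                             zero_tol = 5e-3, min_run = 5) {
  stopifnot(inherits(sp, "smooth_path"))
  method <- match.arg(method)
  kap <- sp$curvatures
  if (method == "sign_change") {
    s <- sign(kap)
    s[abs(kap) < zero_tol] <- 0
    runs <- rle(s)
    v <- runs$values[runs$values != 0 & runs$lengths >= min_run]
    if (length(v) < 2) return(0L)
    return(sum(diff(v) != 0))
  }
  # normal_flip: normals defined where curvature is resolvable, i.e. on
  # sign runs of at least min_run samples with |curvature| >= zero_tol
  # (the same debouncing as sign_change, so rasterization chatter between
  # runs is ignored)
  s <- sign(kap)
  s[abs(kap) < zero_tol] <- 0
  runs <- rle(s)
  run_id <- rep(seq_along(runs$values), runs$lengths)
  keep_run <- runs$values != 0 & runs$lengths >= min_run
  idx <- which(keep_run[run_id])
  if (length(idx) < 2) return(0L)
  tmid <- (sp$tangents[idx, , drop = FALSE] +
             sp$tangents[idx + 1, , drop = FALSE]) / 2
  tmid <- tmid / sqrt(rowSums(tmid^2))
  normals <- cbind(-tmid[, 2], tmid[, 1]) * sign(kap[idx])
  dn2 <- rowSums(diff(normals)^2)
  sum(dn2 > 1)
}

#' Compute the nine metrics for one segment
#'
#' The normative discrete formulas:
#' \itemize{
#'   \item `chord`: Euclidean endpoint distance (pixels).
#'   \item `arc`: chain-code path length (pixels).
#'   \item `dm`: distance metric, `arc / chord` (>= 1, 1 iff collinear).
#'   \item `icm`: `(inflections_sign_change + 1) * dm`, so a curve with no
#'     inflection reduces to `dm`.
#'   \item `icmb`: `(inflections_normal_flip + 1) * dm`.
#'   \item `soam`: sum of absolute turning angles / `arc` (radians/pixel).
#'   \item `nc`: sum of |curvature| * local step / `arc` (1/pixels). Under
#'     this discretization `nc` coincides with `soam` because the turning
#'     angle is curvature times the local step.
#'   \item `sdac`: standard deviation of pointwise |curvature| (1/pixels).
#'   \item `cl`: centerline length, the polyline length of the smoothed
#'     subpixel path (pixels); the low-bias counterpart of `arc`.
#' }
#' Paths shorter than 5 pixels are flagged `too_short`: `chord`, `arc`,
#' `dm` are still computed but the curvature-based metrics are `NA`.
#'
#' @inheritParams chord_length
#' @inheritParams smooth_path
#' @inheritParams inflection_count
#' @return a one-row data frame: `chord`, `arc`, `dm`, `icm`, `icmb`,
#'   `soam`, `nc`, `sdac`, `cl`, `n_inflections`, `too_short`,
#'   `degenerate`.
#' @export
metrics_for_segment <- function(seg, window = 5, zero_tol = 5e-3,
                                min_run = 5) {
  p <- .seg_path(seg)
  chord_raw <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  chord <- max(chord_raw, .CHORD_EPS)
  arc <- arc_length(p)
  degenerate <- chord_raw < .CHORD_EPS
  if (nrow(p) < 5) {
    return(data.frame(chord = chord, arc = arc, dm = arc / chord,
                      icm = NA_real_, icmb = NA_real_, soam = NA_real_,
                      nc = NA_real_, sdac = NA_real_, cl = NA_real_,
                      n_inflections = NA_integer_, too_short = TRUE,
                      degenerate = degenerate))
  }
  sp <- smooth_path(p, window)
  dm <- arc / chord
  n_inf <- inflection_count(sp, "sign_change", zero_tol, min_run)
  n_inf_b <- inflection_count(sp, "normal_flip", zero_tol, min_run)
  sbar <- (sp$step_lengths[-length(sp$step_lengths)] +
             sp$step_lengths[-1]) / 2
  data.frame(chord = chord, arc = arc, dm = dm,
             icm = (n_inf + 1) * dm, icmb = (n_inf_b + 1) * dm,
             soam = sum(abs(sp$turning)) / arc,
             nc = sum(abs(sp$curvatures) * sbar) / arc,
             sdac = if (length(sp$curvatures) > 1) sd(abs(sp$curvatures)) else 0,
             cl = sum(sp$step_lengths),
             n_inflections = n_inf, too_short = FALSE,
             degenerate = degenerate)
}

#' Metrics table for a list of segments
#'
#' Applies [metrics_for_segment()] to each segment and binds identifier
#' columns (`segment_id`, `vessel_class`, `roi_name`, end types, pixel
#' count).
#'
#' @param segments list of `vessel_segment`s.
#' @inheritParams metrics_for_segment
#' @return data frame, one row per segment.
#' @export
metrics_table <- function(segments, window = 5, zero_tol = 5e-3,
                          min_run = 5) {
  if (!length(segments)) {
    return(data.frame(segment_id = character(), vessel_class = character(),
                      roi_name = character(), end_type_1 = character(),
                      end_type_2 = character(), n_pixels = integer(),
                      chord = double(), arc = double(), dm = double(),
                      icm = double(), icmb = double(), soam = double(),
                      nc = double(), sdac = double(), cl = double(),
                      n_inflections = integer(), too_short = logical(),
                      degenerate = logical()))
  }
  rows <- lapply(segments, function(s) {
    cbind(data.frame(segment_id = s$segment_id,
                     vessel_class = s$vessel_class, roi_name = s$roi_name,
                     end_type_1 = s$end_types[1], end_type_2 = s$end_types[2],
                     n_pixels = nrow(s$path)),
          metrics_for_segment(s, window, zero_tol, min_run))
  })
  do.call(rbind, rows)
}
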