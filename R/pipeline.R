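# End-to-end workflow: optic disc -> ring ROIs -> skeleton -> segments ->
# metrics -> AVLR feature tables, with per-image failure isolation.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the workflow with its default.
#' All thresholds are in pixels unless noted.
#'
#' @param palette an [av_palette()] for label rasters.
#' @param brightness_quantile,od_min_area,od_opening_radius see
#'   [localize_od()].
#' @param od_manual `NULL`, or `c(row, col, radius)` to override automatic
#'   disc localization everywhere downstream.
#' @param ring_factors list of `(inner, outer)` ROD-multiple pairs;
#'   the defaults are the two standard rings.
#' @param min_spur spur-removal threshold, see [remove_spurs()].
#' @param max_junction_len junction-artifact threshold, see
#'   [prune_junction_artifacts()].
#' @param smooth_window path smoothing window, see [smooth_path()].
#' @param curvature_zero_tol,inflection_min_run see [inflection_count()].
#' @param seed integer seed recorded in provenance (the pipeline itself is
#'   deterministic; the seed matters for synthetic inputs).
#' @return an `avlr_config` list.
#' @export
avlr_config <- function(palette = default_av_palette(),
                        brightness_quantile = 0.995, od_min_area = 100,
                        od_opening_radius = 5, od_manual = NULL,
                        ring_factors = list(c(2, 3), c(2, 5)),
                        min_spur = 10, max_junction_len = 5,
                        smooth_window = 5, curvature_zero_tol = 5e-3,
                        inflection_min_run = 5, seed = NULL) {
  stopifnot(min_spur >= 0, max_junction_len >= 0, smooth_window >= 1)
  for (rf in ring_factors)
    if (length(rf) != 2 || rf[1] < 0 || rf[1] >= rf[2])
      stop("each ring factor pair must satisfy 0 <= inner < outer")
  structure(list(palette = palette,
                 brightness_quantile = brightness_quantile,
                 od_min_area = od_min_area,
                 od_opening_radius = od_opening_radius,
                 od_manual = od_manual, ring_factors = ring_factors,
                 min_spur = min_spur, max_junction_len = max_junction_len,
                 smooth_window = smooth_window,
                 curvature_zero_tol = curvature_zero_tol,
                 inflection_min_run = inflection_min_run, seed = seed),
            class = "avlr_config")
}

#' Read a pipeline configuration from a key-value text file
#'
#' Lines of the form `key = value`; `#` starts a comment. Palette entries
#' use `palette.<class> = r,g,b`; `ring_factors = 2,3;2,5`;
#' `od_manual = row,col,radius`. Unknown keys are an error.
#'
#' @param path text file path.
#' @return an [avlr_config()].
#' @export
read_avlr_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  args <- list()
  pal_map <- list()
  pal_tol <- 30
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "palette.")) {
      if (k == "palette.tolerance") pal_tol <- as.numeric(v)
      else pal_map[[sub("^palette\\.", "", k)]] <-
          as.numeric(strsplit(v, ",")[[1]])
    } else if (k == "ring_factors") {
      args$ring_factors <- lapply(strsplit(v, ";")[[1]], function(p)
        as.numeric(strsplit(p, ",")[[1]]))
    } else if (k == "od_manual") {
      args$od_manual <- as.numeric(strsplit(v, ",")[[1]])
    } else if (k %in% c("brightness_quantile", "od_min_area",
                        "od_opening_radius", "min_spur", "max_junction_len",
                        "smooth_window", "curvature_zero_tol",
                        "inflection_min_run", "seed")) {
      args[[k]] <- as.numeric(v)
    } else {
      stop("unknown config key: ", k)
    }
  }
  if (length(pal_map)) args$palette <- av_palette(pal_map, tolerance = pal_tol)
  do.call(avlr_config, args)
}

#' Compute segment and image features for one label map
#'
#' Runs skeletonization, spur removal, branch detection, segment
#' extraction, junction-artifact pruning, per-segment metrics,
#' segment-wise ratios and image-level AVLR aggregation on an
#' (already clipped) label map.
#'
#' @param labels a [label_map()].
#' @param image_id,eye,roi_name identifiers for the output rows.
#' @param config an [avlr_config()].
#' @return list: `segment_rows` (data frame, one row per segment with
#'   identifiers, the nine metrics and segment-wise ratios), `record`
#'   (the [image_ratios()] record), `accounting` (pixel bookkeeping from
#'   [extract_segments()]).
#' @export
image_features <- function(labels, image_id = "image", eye = "unknown",
                           roi_name = "full", config = avlr_config()) {
  skel <- skeletonize(labels)
  skel <- remove_spurs(skel, config$min_spur)
  branches <- detect_branch_points(skel)
  segs <- extract_segments(skel, branches, roi_name = roi_name)
  segs <- prune_junction_artifacts(segs, config$max_junction_len)
  mt <- metrics_table(segs, window = config$smooth_window,
                      zero_tol = config$curvature_zero_tol,
                      min_run = config$inflection_min_run)
  mt <- segmentwise_ratios(mt)
  rec <- image_ratios(mt, image_id = image_id, eye = eye,
                      roi_name = roi_name)
  seg_rows <- if (nrow(mt)) {
    cbind(data.frame(image_id = image_id, eye = eye), mt)
  } else {
    cbind(data.frame(image_id = character(), eye = character()), mt)
  }
  list(segment_rows = seg_rows, record = rec,
       accounting = attr(segs, "accounting"))
}

#' Run the full AVLR pipeline over a batch of images
#'
#' For each image: locate the optic disc (or use the manual override), cut
#' each configured ring ROI, clip the label map, and compute segment and
#' image features. Failures are isolated per image: remaining images are
#' still processed and partial results are always written.
#'
#' Writes `segments.csv`, `images.csv`, `run_log.txt` and
#' `provenance.json` (the configuration and package version) into
#' `out_dir`. Reruns with identical inputs and configuration produce
#' byte-identical CSVs.
#'
#' @param images list of [fundus_image()]s or raster paths.
#' @param labels list of [label_map()]s or raster paths (same length).
#' @param out_dir output directory.
#' @param config an [avlr_config()].
#' @param eyes optional character vector of eye tags (overrides the
#'   images' own).
#' @return (invisibly) list: `tables` (a [feature_tables()]), `status`
#'   (data frame with one row per image: `image_id`, `ok`, `message`),
#'   `n_failed`.
#' @export
run_pipeline <- function(images, labels, out_dir, config = avlr_config(),
                         eyes = NULL) {
  if (length(images) != length(labels))
    stop("images and labels must have the same length")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  seg_rows <- list(); img_rows <- list(); status <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.character(img)) img <- read_fundus_image(img)
    if (!is.null(eyes)) img$eye <- eyes[i]
    lab <- labels[[i]]
    if (is.character(lab)) lab <- read_label_map(lab, config$palette)
    res <- tryCatch({
      od <- if (!is.null(config$od_manual)) {
        manual_od(config$od_manual[1:2], config$od_manual[3])
      } else {
        localize_od(img, config$brightness_quantile, config$od_min_area,
                    config$od_opening_radius)
      }
      log_lines <- c(log_lines, sprintf(
        "%s: optic disc at (%.1f, %.1f), radius %.1f [%s]", img$image_id,
        od$center[1], od$center[2], od$radius, od$method))
      any_incomplete <- FALSE
      for (rf in config$ring_factors) {
        roi <- ring_roi(od, rf[1], rf[2])
        clipped <- clip_labels(lab, roi)
        feats <- image_features(clipped, image_id = img$image_id,
                                eye = img$eye, roi_name = roi$name,
                                config = config)
        seg_rows[[length(seg_rows) + 1]] <- feats$segment_rows
        img_rows[[length(img_rows) + 1]] <-
          as.data.frame(feats$record)
        any_incomplete <- any_incomplete || feats$record$incomplete
        log_lines <- c(log_lines, sprintf(
          "%s [%s]: %d artery + %d vein segments%s", img$image_id,
          roi$name, feats$record$n_artery_segments,
          feats$record$n_vein_segments,
          if (feats$record$incomplete) " (incomplete)" else ""))
      }
      list(ok = !any_incomplete,
           message = if (any_incomplete) "incomplete record" else "ok")
    }, error = function(e) list(ok = FALSE, message = conditionMessage(e)))
    status[[i]] <- data.frame(image_id = img$image_id, ok = res$ok,
                              message = res$message)
    if (!res$ok)
      log_lines <- c(log_lines,
                     sprintf("%s: FAILED (%s)", img$image_id, res$message))
  }
  tables <- feature_tables(
    do.call(rbind, c(seg_rows, list(.empty_segment_rows()))),
    do.call(rbind, c(img_rows, list(NULL))))
  if (is.null(tables$image_rows))
    tables$image_rows <- data.frame()
  write_feature_tables(tables, out_dir)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  prov <- config
  prov$palette <- list(colors = unclass(config$palette$colors),
                       classes = config$palette$classes,
                       tolerance = config$palette$tolerance,
                       fallback = config$palette$fallback)
  jsonlite::write_json(
    list(package = "avlr",
         version = as.character(packageVersion("avlr")),
         config = unclass(prov)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  status <- do.call(rbind, status)
  invisible(list(tables = tables, status = status,
                 n_failed = sum(!status$ok)))
}

.empty_segment_rows <- function() {
  segmentwise_ratios(
    cbind(data.frame(image_id = character(), eye = character()),
          metrics_table(list())))[0, ]
}
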