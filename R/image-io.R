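# Raster and table I/O: fundus images, artery/vein label maps, feature CSVs.

AV_CLASSES <- c(background = 0L, artery = 1L, vein = 2L, unknown = 3L)
AV_CLASS_NAMES <- names(AV_CLASSES)

#' Construct a fundus image object
#'
#' Wraps an 8-bit RGB raster as a `fundus_image`. Pixel values are stored as
#' a `height x width x 3` array of integers in `[0, 255]`.
#'
#' @param pixels numeric array `h x w x 3` with values in `[0, 255]`, or in
#'   `[0, 1]` (auto-rescaled when the maximum is `<= 1`).
#' @param image_id opaque identifier string.
#' @param eye one of `"left"`, `"right"`, `"unknown"`.
#' @return a `fundus_image` object with fields `pixels`, `height`, `width`,
#'   `image_id`, `eye`.
#' @export
fundus_image <- function(pixels, image_id = "image", eye = "unknown") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  eye <- match.arg(eye, c("left", "right", "unknown"))
  if (max(pixels) <= 1) pixels <- pixels * 255
  pixels <- array(as.integer(round(pixels)), dim(pixels))
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("channel values must lie in [0, 255]")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop("image must have positive height and width")
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         image_id = image_id, eye = eye),
    class = "fundus_image")
}

#' Construct a vessel label map
#'
#' @param classes integer matrix of class codes (0 background, 1 artery,
#'   2 vein, 3 unknown) or character matrix with those class names.
#' @param provenance `"file"` or `"synthetic"`.
#' @return a `vessel_label_map` with fields `classes` (integer matrix) and
#'   `provenance`.
#' @export
label_map <- function(classes, provenance = c("file", "synthetic")) {
  provenance <- match.arg(provenance)
  if (is.character(classes)) {
    codes <- AV_CLASSES[classes]
    if (anyNA(codes)) stop("unknown class name in label matrix")
    classes <- matrix(as.integer(codes), nrow(classes), ncol(classes))
  }
  storage.mode(classes) <- "integer"
  if (!all(classes %in% AV_CLASSES)) stop("class codes must be in 0:3")
  structure(list(classes = classes, provenance = provenance),
            class = "vessel_label_map")
}

#' @export
print.vessel_label_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = AV_CLASSES, labels = AV_CLASS_NAMES))
  cat(sprintf("<vessel_label_map %dx%d, %s>\n", nrow(x$classes),
              ncol(x$classes), x$provenance))
  print(tab)
  invisible(x)
}

#' Define an artery/vein color palette
#'
#' Maps RGB triplets (0-255) to vessel classes when reading color-coded
#' label rasters. Colors within `tolerance` per channel of a palette entry
#' resolve to the nearest entry (Euclidean distance); anything else resolves
#' to `fallback`.
#'
#' @param mapping named list of length-3 RGB vectors; names are class names
#'   among `background`, `artery`, `vein`, `unknown`.
#' @param tolerance per-channel integer slack for anti-aliased rasters.
#' @param fallback class assigned to unmapped colors.
#' @return an `av_palette` object.
#' @export
#' @examples
#' av_palette(list(artery = c(255, 0, 0), vein = c(0, 0, 255),
#'                 background = c(0, 0, 0)))
av_palette <- function(mapping, tolerance = 30, fallback = "unknown") {
  stopifnot(is.list(mapping), length(mapping) >= 1)
  if (!all(names(mapping) %in% AV_CLASS_NAMES))
    stop("palette classes must be among: ",
         paste(AV_CLASS_NAMES, collapse = ", "))
  cols <- do.call(rbind, mapping)
  if (ncol(cols) != 3) stop("each palette color must be an RGB triplet")
  if (anyDuplicated(cols)) stop("no two classes may claim the same color")
  fallback <- match.arg(fallback, AV_CLASS_NAMES)
  structure(list(colors = cols, classes = names(mapping),
                 tolerance = tolerance, fallback = fallback),
            class = "av_palette")
}

#' Default artery/vein palette
#'
#' Artery pure red, vein pure blue, background black, tolerance 30,
#' everything else `unknown`. Fully overridable: the labeling color
#' convention is a property of the dataset, not of the method.
#'
#' @inheritParams av_palette
#' @return an `av_palette`.
#' @export
default_av_palette <- function(tolerance = 30) {
  av_palette(list(background = c(0, 0, 0), artery = c(255, 0, 0),
                  vein = c(0, 0, 255)), tolerance = tolerance)
}

# EBImage stores rasters as [x = col, y = row(, channel)]; convert to the
# package's (row, col) convention.
.read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2) {
    t(img) * 255
  } else {
    aperm(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(2, 1, 3)) * 255
  }
}

#' Read a fundus image from PNG or TIFF
#'
#' @param path raster file path.
#' @inheritParams fundus_image
#' @return a [fundus_image()].
#' @export
read_fundus_image <- function(path, image_id = basename(path),
                              eye = "unknown") {
  px <- .read_raster(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  fundus_image(px, image_id = image_id, eye = eye)
}

#' Read an artery/vein label map from a color-coded raster
#'
#' Each pixel is assigned the class of the nearest palette color whose
#' per-channel distance is within the palette tolerance; unmatched pixels
#' get the palette's fallback class. Grayscale rasters are accepted only
#' when the palette contains an achromatic (r = g = b) non-background entry,
#' otherwise a configuration error names the missing mapping.
#'
#' @param path raster file path (PNG or TIFF).
#' @param palette an [av_palette()].
#' @return a [label_map()] with provenance `"file"`.
#' @export
read_label_map <- function(path, palette = default_av_palette()) {
  px <- .read_raster(path)
  if (length(dim(px)) == 2) {
    achromatic <- apply(palette$colors, 1, function(x) length(unique(x)) == 1)
    nonbg <- palette$classes != "background"
    if (!any(achromatic & nonbg))
      stop("grayscale raster but the palette has no achromatic entry for ",
           "any of: ", paste(palette$classes[nonbg], collapse = ", "),
           "; add e.g. a class mapped to c(255,255,255)")
    px <- array(rep(px, 3), c(dim(px), 3))
  }
  classify_colors(px, palette)
}

#' Classify an RGB array into vessel classes via a palette
#'
#' @param pixels `h x w x 3` array, values 0-255.
#' @inheritParams read_label_map
#' @return a [label_map()].
#' @export
classify_colors <- function(pixels, palette = default_av_palette()) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  flat <- matrix(as.numeric(pixels), h * w, 3)
  k <- nrow(palette$colors)
  d2 <- matrix(0, h * w, k)
  within <- matrix(TRUE, h * w, k)
  for (j in seq_len(k)) {
    diffs <- abs(sweep(flat, 2, palette$colors[j, ]))
    within[, j] <- diffs[, 1] <= palette$tolerance &
      diffs[, 2] <= palette$tolerance & diffs[, 3] <= palette$tolerance
    d2[, j] <- rowSums(diffs^2)
  }
  d2[!within] <- Inf
  best <- max.col(-d2, ties.method = "first")
  matched <- within[cbind(seq_len(h * w), best)]
  cls <- ifelse(matched, palette$classes[best], palette$fallback)
  label_map(matrix(AV_CLASSES[cls], h, w), provenance = "file")
}

#' Assemble segment- and image-level feature tables
#'
#' @param segment_rows data frame, one row per (image, ROI, segment), as
#'   produced by [image_features()].
#' @param image_rows data frame, one row per (image, ROI).
#' @return a `feature_tables` object.
#' @export
feature_tables <- function(segment_rows, image_rows) {
  tabs <- structure(list(segment_rows = segment_rows, image_rows = image_rows),
                    class = "feature_tables")
  validate_feature_tables(tabs)
  tabs
}

#' Check feature-table invariants
#'
#' Every segment row's `(image_id, roi_name)` must appear among the image
#' rows, and image-row segment counts must equal the matching number of
#' usable segment rows per class.
#'
#' @param tables a [feature_tables()] object.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_feature_tables <- function(tables) {
  seg <- tables$segment_rows; img <- tables$image_rows
  if (nrow(seg)) {
    keys_seg <- paste(seg$image_id, seg$roi_name)
    keys_img <- paste(img$image_id, img$roi_name)
    if (!all(keys_seg %in% keys_img))
      stop("segment rows reference (image, roi) pairs absent from image rows")
    for (i in seq_len(nrow(img))) {
      m <- seg[keys_seg == keys_img[i], ]
      usable <- !m$too_short
      n_a <- sum(m$vessel_class == "artery" & usable)
      n_v <- sum(m$vessel_class == "vein" & usable)
      if (n_a != img$n_artery_segments[i] || n_v != img$n_vein_segments[i])
        stop("image-row segment counts disagree with segment rows for ",
             keys_img[i])
    }
  }
  invisible(TRUE)
}

#' Write feature tables to CSV
#'
#' Writes `segments.csv` and `images.csv` into `out_dir`. Numeric columns
#' are serialized at full double precision (15 significant digits), so a
#' write-then-read round trip reproduces values bit-equal at that precision.
#' Headers are the column names documented in [image_features()].
#'
#' @param tables a [feature_tables()] object.
#' @param out_dir output directory (created if absent).
#' @return character vector of the two file paths (segments, images).
#' @export
write_feature_tables <- function(tables, out_dir) {
  validate_feature_tables(tables)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, c("segments.csv", "images.csv"))
  write.csv(tables$segment_rows, paths[1], row.names = FALSE)
  write.csv(tables$image_rows, paths[2], row.names = FALSE)
  paths
}

#' Read feature tables back from CSV
#'
#' @param out_dir directory containing `segments.csv` and `images.csv`.
#' @return a [feature_tables()] object.
#' @export
read_feature_tables <- function(out_dir) {
  seg <- read.csv(file.path(out_dir, "segments.csv"),
                  stringsAsFactors = FALSE)
  img <- read.csv(file.path(out_dir, "images.csv"), stringsAsFactors = FALSE)
  feature_tables(seg, img)
}
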