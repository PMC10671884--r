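# Test helpers: small phantom builders and independent brute-force
# oracles. The oracles deliberately share no code with the package
# internals (naive double loops instead of shifted-matrix algebra).

CLS <- c(background = 0L, artery = 1L, vein = 2L, unknown = 3L)

# Build a vessel_label_map from a list of pixel paths (n x 2 matrices)
# with classes.
lm_from_paths <- function(paths, classes, shape) {
  m <- matrix(CLS[["background"]], shape[1], shape[2])
  for (i in seq_along(paths)) m[paths[[i]]] <- CLS[[classes[i]]]
  label_map(m, provenance = "synthetic")
}

# Straight 8-connected pixel path between two points (Bresenham-ish via
# rounding along the longer axis).
px_line <- function(from, to) {
  n <- max(abs(to - from)) + 1
  cbind(round(seq(from[1], to[1], length.out = n)),
        round(seq(from[2], to[2], length.out = n)))
}

# Naive 8-connected component count over a logical matrix, by repeated
# stack-based flood fill with explicit double loops.
naive_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] > 0) next
    cur <- cur + 1L
    stack <- list(c(r, c))
    lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  list(n = cur, labels = lab)
}

# Naive neighbor count at one pixel.
naive_nb <- function(mask, r, c) {
  s <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
        mask[rr, cc]) s <- s + 1L
  }
  s
}

# Brute-force spur removal to fixpoint. Each round takes a snapshot of
# the mask, finds every endpoint whose walk reaches a (>=3)-neighbor pixel
# in arc length < min_spur, deletes the union of those twigs, and repeats
# until no round deletes anything (per-round parallel semantics, computed
# with naive double loops).
naive_remove_spurs <- function(mask, min_spur) {
  repeat {
    ends <- NULL
    for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
      if (mask[r, c] && naive_nb(mask, r, c) == 1)
        ends <- rbind(ends, c(r, c))
    doomed <- NULL
    for (i in seq_len(NROW(ends))) {
      cur <- ends[i, ]
      twig <- matrix(cur, 1)
      acc <- 0
      hit_branch <- FALSE
      prev <- c(-1, -1)
      repeat {
        nxt <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- cur[1] + dr; cc <- cur[2] + dc
          if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
          if (!mask[rr, cc]) next
          if (rr == prev[1] && cc == prev[2]) next
          if (any(twig[, 1] == rr & twig[, 2] == cc)) next
          if (naive_nb(mask, rr, cc) >= 3) { hit_branch <- TRUE }
          else if (is.null(nxt)) nxt <- c(rr, cc)
        }
        if (hit_branch || is.null(nxt)) break
        acc <- acc + sqrt(sum((nxt - cur)^2))
        if (acc >= min_spur) break
        prev <- cur; cur <- nxt
        twig <- rbind(twig, cur)
      }
      if (hit_branch && acc < min_spur) doomed <- rbind(doomed, twig)
    }
    if (is.null(doomed)) return(mask)
    mask[doomed] <- FALSE
  }
}

# Brute-force nearest-palette classification of one RGB triplet.
naive_palette_class <- function(rgb, palette) {
  best <- palette$fallback
  bestd <- Inf
  for (j in seq_len(nrow(palette$colors))) {
    d <- abs(rgb - palette$colors[j, ])
    if (all(d <= palette$tolerance)) {
      d2 <- sum(d^2)
      if (d2 < bestd) { bestd <- d2; best <- palette$classes[j] }
    }
  }
  best
}

# Write a class matrix as a colored PNG (via the default palette colors);
# returns the file path.
write_class_png <- function(cls, path = tempfile(fileext = ".png")) {
  cols <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 1, 1))
  arr <- array(cols[cls + 1, ], c(dim(cls), 3))
  EBImage::writeImage(
    EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color"), path)
  path
}

# Minimal eye_pair_report for cohort simulations (documented structure).
fake_pair_report <- function(left, right, metric = "avlr_dm") {
  structure(data.frame(metric = metric, left = left, right = right,
                       difference = right - left,
                       log_ratio = log(right / left),
                       asymmetry_index = abs(right - left) /
                         ((right + left) / 2),
                       missing_side = FALSE),
            class = c("eye_pair_report", "data.frame"))
}

# Feature record with all nine ratios set to one value (for eye tests).
fake_record <- function(value, roi_name = "2-3ROD", image_id = "img") {
  metrics <- data.frame(
    vessel_class = c("artery", "vein"), too_short = FALSE,
    chord = c(value, 1), arc = c(value, 1), dm = c(value, 1),
    icm = c(value, 1), icmb = c(value, 1), soam = c(value, 1),
    nc = c(value, 1), sdac = c(value, 1), cl = c(value, 1))
  image_ratios(metrics, image_id = image_id, roi_name = roi_name)
}
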