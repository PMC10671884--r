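# Centerline extraction: Zhang-Suen thinning with a sequential
# simple-point cleanup to strict unit width, spur removal, branch-point
# detection, and segment extraction between skeleton critical points.

# 8-neighborhood offsets, clockwise from north-west.
.RING <- cbind(dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
               dc = c(-1, 0, 1, 1, 1, 0, -1, -1))

.shift <- function(M, dr, dc) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(FALSE, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

.neighbor_count <- function(B) {
  s <- matrix(0L, nrow(B), ncol(B))
  for (k in seq_len(8))
    s <- s + .shift(B, .RING[k, 1], .RING[k, 2])
  s
}

# Zhang-Suen parallel thinning (two-subiteration).
.thin_zs <- function(B) {
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- .shift(B, -1, 0); P3 <- .shift(B, -1, 1); P4 <- .shift(B, 0, 1)
      P5 <- .shift(B, 1, 1);  P6 <- .shift(B, 1, 0);  P7 <- .shift(B, 1, -1)
      P8 <- .shift(B, 0, -1); P9 <- .shift(B, -1, -1)
      nsum <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      a <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      del <- if (sub == 1) {
        B & nsum >= 2 & nsum <= 6 & a == 1 & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        B & nsum >= 2 & nsum <= 6 & a == 1 & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(del)) { B[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) return(B)
  }
}

# A pixel is 8-simple when its foreground ring neighbors form exactly one
# 8-connected component; deleting such a pixel preserves connectivity.
.is_simple8 <- function(B, r, c) {
  fg <- which(B[cbind(r + .RING[, 1], c + .RING[, 2])])
  k <- length(fg)
  if (k == 0) return(FALSE)
  if (k == 1) return(TRUE)
  coords <- .RING[fg, , drop = FALSE]
  comp <- seq_len(k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (max(abs(coords[i, ] - coords[j, ])) <= 1 && comp[i] != comp[j])
      comp[comp == comp[j]] <- comp[i]
  }
  length(unique(comp)) == 1
}

# Sequentially delete 8-simple pixels with >= 2 neighbors. Endpoints (1
# neighbor) are protected, interior path pixels are not simple, so only
# staircase/corner redundancy is removed; the result is strictly unit-wide.
.cleanup_skeleton <- function(B) {
  repeat {
    changed <- FALSE
    idx <- which(B, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      if (!B[r, c]) next
      nbs <- sum(B[cbind(r + .RING[, 1], c + .RING[, 2])])
      if (nbs < 2 || nbs == 8) next
      if (.is_simple8(B, r, c)) { B[r, c] <- FALSE; changed <- TRUE }
    }
    if (!changed) return(B)
  }
}

#' Thin a label map to a one-pixel skeleton
#'
#' Morphological thinning (Zhang-Suen followed by a sequential simple-point
#' cleanup to strict unit width) of the union of all non-background pixels.
#' Pixels classed `unknown` count as vessel for connectivity, so crossings
#' do not sever the skeleton. Each skeleton pixel inherits the class of the
#' corresponding input pixel (the skeleton is a subset of the foreground).
#'
#' @param labels a [label_map()].
#' @return a `vessel_skeleton`: `mask` (logical matrix) and `classes`
#'   (integer matrix, 0 off-skeleton).
#' @export
skeletonize <- function(labels) {
  stopifnot(inherits(labels, "vessel_label_map"))
  cls <- labels$classes
  fg <- cls != AV_CLASSES[["background"]]
  # pad so border pixels have a full neighborhood
  pad <- matrix(FALSE, nrow(fg) + 2, ncol(fg) + 2)
  pad[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)] <- fg
  sk <- .cleanup_skeleton(.thin_zs(pad))
  sk <- sk[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)]
  kcls <- cls
  kcls[!sk] <- AV_CLASSES[["background"]]
  structure(list(mask = sk, classes = kcls), class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton %dx%d, %d pixels>\n", nrow(x$mask),
              ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# Walk from `start` along a unit-wide structure, never revisiting; used by
# spur tracing. Returns visited pixels (rows of a matrix) and the stop
# reason.
.walk_twig <- function(B, nb, start, max_len) {
  path <- matrix(start, 1, 2)
  acc <- 0
  cur <- start
  prev <- c(-1L, -1L)
  repeat {
    nxt <- NULL
    for (k in seq_len(8)) {
      r <- cur[1] + .RING[k, 1]; c <- cur[2] + .RING[k, 2]
      if (B[r, c] && !(r == prev[1] && c == prev[2]) &&
          !any(path[, 1] == r & path[, 2] == c)) {
        if (nb[r, c] >= 3) return(list(path = path, acc = acc, hit = "branch"))
        if (is.null(nxt)) nxt <- c(r, c)
      }
    }
    if (is.null(nxt)) return(list(path = path, acc = acc, hit = "end"))
    acc <- acc + sqrt(sum((nxt - cur)^2))
    if (acc >= max_len) return(list(path = path, acc = acc, hit = "long"))
    prev <- cur; cur <- nxt
    path <- rbind(path, cur)
  }
}

#' Remove short spurs from a skeleton
#'
#' Iteratively deletes endpoint-terminated twigs of arc length below
#' `min_spur` that attach to a branch point, until a fixpoint. Each round
#' identifies every qualifying twig against the current skeleton and
#' deletes them together (parallel per-round semantics). Free segments
#' (endpoint to endpoint) are never deleted, so true endpoints of long
#' vessels are preserved. `min_spur = 0` is the identity.
#'
#' @param skel a `vessel_skeleton`.
#' @param min_spur minimum arc length (pixels) for a twig to survive.
#' @return a pruned `vessel_skeleton`.
#' @export
remove_spurs <- function(skel, min_spur = 10) {
  stopifnot(inherits(skel, "vessel_skeleton"), min_spur >= 0)
  if (min_spur == 0) return(skel)
  B <- matrix(FALSE, nrow(skel$mask) + 2, ncol(skel$mask) + 2)
  B[2:(nrow(skel$mask) + 1), 2:(ncol(skel$mask) + 1)] <- skel$mask
  repeat {
    nb <- .neighbor_count(B)
    ends <- which(B & nb == 1, arr.ind = TRUE)
    doomed <- NULL
    for (i in seq_len(nrow(ends))) {
      w <- .walk_twig(B, nb, ends[i, ], min_spur)
      if (w$hit == "branch" && w$acc < min_spur) doomed <- rbind(doomed, w$path)
    }
    if (is.null(doomed)) break
    B[doomed] <- FALSE
  }
  mask <- B[2:(nrow(skel$mask) + 1), 2:(ncol(skel$mask) + 1)]
  cls <- skel$classes
  cls[!mask] <- AV_CLASSES[["background"]]
  structure(list(mask = mask, classes = cls), class = "vessel_skeleton")
}

#' Detect branch points of a skeleton
#'
#' Branch points are skeleton pixels with at least 3 skeleton neighbors in
#' the 8-neighborhood. Adjacent branch pixels (thinning emits small
#' clusters at crossings) are grouped into clusters, and each cluster is
#' collapsed to one representative (the member nearest the cluster
#' centroid), so a crossing counts as a single junction.
#'
#' @param skel a `vessel_skeleton`.
#' @return a `branch_points` object: `points` data frame
#'   (`row`, `col`, `cluster`, `representative`).
#' @export
detect_branch_points <- function(skel) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  B <- matrix(FALSE, nrow(skel$mask) + 2, ncol(skel$mask) + 2)
  B[2:(nrow(skel$mask) + 1), 2:(ncol(skel$mask) + 1)] <- skel$mask
  nb <- .neighbor_count(B)
  bp <- which(B & nb >= 3, arr.ind = TRUE) - 1L  # unpad
  if (nrow(bp) == 0) {
    pts <- data.frame(row = integer(), col = integer(), cluster = integer(),
                      representative = logical())
    return(structure(list(points = pts), class = "branch_points"))
  }
  cl <- .label_components(bp)
  rep_flag <- logical(nrow(bp))
  for (g in unique(cl)) {
    m <- which(cl == g)
    ctr <- colMeans(bp[m, , drop = FALSE])
    d2 <- (bp[m, 1] - ctr[1])^2 + (bp[m, 2] - ctr[2])^2
    rep_flag[m[which.min(d2)]] <- TRUE
  }
  pts <- data.frame(row = bp[, 1], col = bp[, 2], cluster = cl,
                    representative = rep_flag)
  structure(list(points = pts), class = "branch_points")
}

# 8-connected components over a pixel list (n x 2 matrix); returns labels.
.label_components <- function(px) {
  n <- nrow(px)
  if (n == 0) return(integer())
  key <- paste(px[, 1], px[, 2])
  index <- seq_len(n)
  names(index) <- key
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      nk <- paste(px[p, 1] + .RING[, 1], px[p, 2] + .RING[, 2])
      hit <- index[nk]
      hit <- hit[!is.na(hit)]
      hit <- hit[lab[hit] == 0L]
      if (length(hit)) {
        lab[hit] <- cur
        queue <- c(queue, hit)
      }
    }
  }
  lab
}

# Order the pixels of a unit-wide component into a path. Components are
# simple paths or cycles by construction (all branch pixels removed first).
.order_path <- function(px) {
  n <- nrow(px)
  if (n == 1) return(px)
  key <- paste(px[, 1], px[, 2])
  index <- seq_len(n)
  names(index) <- key
  deg <- integer(n)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nk <- paste(px[i, 1] + .RING[, 1], px[i, 2] + .RING[, 2])
    hit <- index[nk]
    adj[[i]] <- unname(hit[!is.na(hit)])
    deg[i] <- length(adj[[i]])
  }
  if (any(deg > 2))
    stop("internal invariant violation: path pixel with >2 neighbors ",
         "after branch removal")
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  ord <- integer(n)
  visited <- logical(n)
  cur <- start
  for (k in seq_len(n)) {
    ord[k] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  px[ord[ord > 0], , drop = FALSE]
}

#' Extract vessel segments between branch points
#'
#' Removes all branch-cluster pixels from the skeleton; the remainder
#' decomposes into simple 8-connected paths, each ordered end to end. A
#' segment's class is the pixel-majority class (ties resolve to
#' `unknown`); each end is typed `"branch"` if it touches a branch cluster
#' and `"endpoint"` otherwise. Single-pixel fragments (between two
#' adjacent junctions) cannot form a valid path and are dropped; their
#' count is kept in the accounting attribute.
#'
#' @param skel a `vessel_skeleton`.
#' @param branches a `branch_points` object from [detect_branch_points()].
#' @param roi_name ROI label stored on each segment.
#' @return list of `vessel_segment` objects (`segment_id`, `path` n x 2
#'   matrix, `vessel_class`, `end_types`, `roi_name`), with an
#'   `accounting` attribute: `n_skeleton`, `n_branch`, `n_dropped`,
#'   `n_in_segments` (pixel conservation:
#'   `n_skeleton = n_in_segments + n_branch + n_dropped`).
#' @export
extract_segments <- function(skel, branches = detect_branch_points(skel),
                             roi_name = "full") {
  stopifnot(inherits(skel, "vessel_skeleton"))
  mask <- skel$mask
  n_skel <- sum(mask)
  bp <- branches$points
  if (nrow(bp)) mask[cbind(bp$row, bp$col)] <- FALSE
  px <- which(mask, arr.ind = TRUE)
  segs <- list()
  n_dropped <- 0L
  if (nrow(px)) {
    lab <- .label_components(px)
    sid <- 0L
    for (g in sort(unique(lab))) {
      comp <- px[lab == g, , drop = FALSE]
      if (nrow(comp) < 2) {
        n_dropped <- n_dropped + nrow(comp)
        next
      }
      path <- .order_path(comp)
      ends <- rbind(path[1, ], path[nrow(path), ])
      end_types <- apply(ends, 1, function(e) {
        nk <- cbind(e[1] + .RING[, 1], e[2] + .RING[, 2])
        ok <- nk[, 1] >= 1 & nk[, 1] <= nrow(skel$mask) &
          nk[, 2] >= 1 & nk[, 2] <= ncol(skel$mask)
        if (nrow(bp) && any(paste(nk[ok, 1], nk[ok, 2]) %in%
                              paste(bp$row, bp$col))) "branch" else "endpoint"
      })
      cls_codes <- skel$classes[path]
      n_a <- sum(cls_codes == AV_CLASSES[["artery"]])
      n_v <- sum(cls_codes == AV_CLASSES[["vein"]])
      n_u <- sum(cls_codes == AV_CLASSES[["unknown"]])
      vessel_class <- if (n_a > n_v && n_a >= n_u) "artery"
        else if (n_v > n_a && n_v >= n_u) "vein"
        else "unknown"
      sid <- sid + 1L
      segs[[sid]] <- structure(
        list(segment_id = sprintf("%s_seg%03d", roi_name, sid), path = path,
             vessel_class = vessel_class, end_types = end_types,
             roi_name = roi_name),
        class = "vessel_segment")
    }
  }
  attr(segs, "accounting") <- list(
    n_skeleton = n_skel, n_branch = nrow(bp), n_dropped = n_dropped,
    n_in_segments = sum(vapply(segs, function(s) nrow(s$path), 0L)))
  segs
}

#' Prune junction artifacts
#'
#' Thinning creates short "L"-shaped branch-to-branch connectors at vessel
#' crossings that are not anatomical segments. Segments whose both ends are
#' branch-typed and whose arc length is at most `max_junction_len` are
#' discarded; everything else passes through unchanged. A threshold of 0
#' removes nothing.
#'
#' @param segments list of `vessel_segment`s from [extract_segments()].
#' @param max_junction_len arc-length threshold in pixels.
#' @return filtered segment list; the `accounting` attribute is updated so
#'   pruned pixels move to `n_dropped`.
#' @export
prune_junction_artifacts <- function(segments, max_junction_len = 5) {
  stopifnot(max_junction_len >= 0)
  acc <- attr(segments, "accounting")
  keep <- vapply(segments, function(s) {
    !(all(s$end_types == "branch") &&
        .path_arc(s$path) <= max_junction_len)
  }, logical(1))
  out <- segments[keep]
  if (!is.null(acc)) {
    pruned_px <- sum(vapply(segments[!keep], function(s) nrow(s$path), 0L))
    acc$n_dropped <- acc$n_dropped + pruned_px
    acc$n_in_segments <- acc$n_in_segments - pruned_px
    attr(out, "accounting") <- acc
  }
  out
}

.path_arc <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

#' Validate a vessel segment
#'
#' Checks the path invariants: at least 2 pixels, no repeats, consecutive
#' pixels 8-adjacent.
#'
#' @param seg a `vessel_segment`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_segment <- function(seg) {
  p <- seg$path
  if (nrow(p) < 2) stop("segment path must contain at least 2 pixels")
  if (anyDuplicated(paste(p[, 1], p[, 2]))) stop("segment path repeats a pixel")
  d <- abs(diff(p))
  if (any(pmax(d[, 1], d[, 2]) != 1))
    stop("consecutive path pixels must be 8-adjacent")
  invisible(TRUE)
}
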