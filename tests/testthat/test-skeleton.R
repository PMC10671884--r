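test_that("a wide bar thins to its one-pixel centerline", {
  cls <- matrix(0L, 25, 60)
  cls[10:14, 5:55] <- CLS[["artery"]]
  sk <- skeletonize(label_map(cls, "synthetic"))
  rows <- unique(which(sk$mask, arr.ind = TRUE)[, 1])
  expect_equal(rows, 12)
  expect_true(all(sk$classes[sk$mask] == CLS[["artery"]]))
  segs <- extract_segments(sk)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$vessel_class, "artery")
})

test_that("empty maps give empty skeletons and incomplete records", {
  lm <- label_map(matrix(0L, 30, 30), "synthetic")
  sk <- skeletonize(lm)
  expect_equal(sum(sk$mask), 0)
  segs <- extract_segments(sk)
  expect_length(segs, 0)
  f <- image_features(lm)
  expect_true(f$record$incomplete)
  expect_true(all(is.na(f$record$ratios)))
})

test_that("an annulus thins to a closed loop of degree-2 pixels", {
  d <- sqrt(outer((1:160 - 80)^2, (1:160 - 80)^2, `+`))
  cls <- matrix(0L, 160, 160)
  cls[d >= 50 & d < 57] <- CLS[["vein"]]
  sk <- skeletonize(label_map(cls, "synthetic"))
  px <- which(sk$mask, arr.ind = TRUE)
  # exhaustive neighbor-count audit
  nbs <- vapply(seq_len(nrow(px)),
                function(i) naive_nb(sk$mask, px[i, 1], px[i, 2]), 0L)
  expect_true(all(nbs == 2))
  expect_equal(naive_components(sk$mask)$n, 1)
})

test_that("thinning preserves the component count of the input", {
  set.seed(8)
  cls <- matrix(0L, 120, 120)
  for (i in 1:4) {
    r0 <- 15 + 25 * (i - 1)
    p <- px_line(c(r0, 10), c(r0 + sample(0:8, 1), 110))
    for (dr in 0:2) cls[cbind(p[, 1] + dr, p[, 2])] <- CLS[["artery"]]
  }
  before <- naive_components(cls != 0)$n
  sk <- skeletonize(label_map(cls, "synthetic"))
  expect_equal(naive_components(sk$mask)$n, before)
})

test_that("spur removal deletes short twigs and keeps true endpoints", {
  # long horizontal line with a 3-px twig attached mid-way
  main <- px_line(c(20, 5), c(20, 55))
  twig <- px_line(c(19, 30), c(17, 32))
  lm <- lm_from_paths(list(main, twig), c("artery", "artery"), c(40, 60))
  sk <- skeletonize(lm)
  pruned <- remove_spurs(sk, min_spur = 10)
  # the twig tip is gone, no branch point remains, and the surviving
  # skeleton is a single open path spanning the full main line
  expect_false(pruned$mask[17, 32])
  expect_false(pruned$mask[18, 31])
  expect_equal(nrow(detect_branch_points(pruned)$points), 0)
  segs <- extract_segments(pruned)
  expect_length(segs, 1)
  expect_equal(sort(range(segs[[1]]$path[, 2])), c(5, 55))
  expect_identical(pruned$mask, naive_remove_spurs(sk$mask, 10))
  # min_spur = 0 is the identity
  expect_identical(remove_spurs(sk, 0)$mask, sk$mask)
})

test_that("spur removal reaches the brute-force fixpoint on a random tree", {
  set.seed(14)
  trunk <- px_line(c(40, 5), c(40, 95))
  branches <- list(trunk)
  ats <- sample(seq(15, 85, by = 14), 5)  # separated junctions
  for (i in 1:5) {
    at <- ats[i]
    len <- sample(2:13, 1)
    dir <- sample(c(-1, 1), 1)
    branches[[i + 1]] <- px_line(c(40 + dir, at), c(40 + dir * len, at + len - 1))
  }
  lm <- lm_from_paths(branches, rep("vein", 6), c(80, 100))
  sk <- skeletonize(lm)
  got <- remove_spurs(sk, min_spur = 10)
  want <- naive_remove_spurs(sk$mask, min_spur = 10)
  expect_identical(got$mask, want)
})

test_that("branch points are exactly the >=3-neighbor pixels, clustered", {
  # straight line: none
  line <- skeletonize(lm_from_paths(list(px_line(c(10, 2), c(10, 38))),
                                    "artery", c(20, 40)))
  expect_equal(nrow(detect_branch_points(line)$points), 0)
  # "+" cross: one cluster, one representative at the center
  cross <- lm_from_paths(list(px_line(c(25, 5), c(25, 45)),
                              px_line(c(5, 25), c(45, 25))),
                         c("artery", "artery"), c(50, 50))
  bp <- detect_branch_points(skeletonize(cross))$points
  expect_gte(nrow(bp), 1)
  expect_equal(length(unique(bp$cluster)), 1)
  expect_equal(sum(bp$representative), 1)
  expect_lt(max(abs(bp$row[bp$representative] - 25),
                abs(bp$col[bp$representative] - 25)), 3)
  # exhaustive audit: every detected point has >= 3 neighbors
  skc <- skeletonize(cross)
  for (i in seq_len(nrow(bp)))
    expect_gte(naive_nb(skc$mask, bp$row[i], bp$col[i]), 3)
  # "Y": one representative
  y <- lm_from_paths(list(px_line(c(45, 25), c(25, 25)),
                          px_line(c(25, 25), c(5, 5)),
                          px_line(c(25, 25), c(5, 45))),
                     rep("vein", 3), c(50, 50))
  bpy <- detect_branch_points(skeletonize(y))$points
  expect_equal(length(unique(bpy$cluster)), 1)
  expect_equal(sum(bpy$representative), 1)
})

test_that("segment extraction matches brute-force component counts", {
  y <- lm_from_paths(list(px_line(c(45, 25), c(25, 25)),
                          px_line(c(25, 25), c(5, 5)),
                          px_line(c(25, 25), c(5, 45))),
                     rep("artery", 3), c(50, 50))
  sk <- skeletonize(y)
  bp <- detect_branch_points(sk)
  segs <- extract_segments(sk, bp)
  # oracle: delete branch pixels, count 8-connected components
  m <- sk$mask
  m[cbind(bp$points$row, bp$points$col)] <- FALSE
  expect_equal(length(segs), naive_components(m)$n)
  expect_length(segs, 3)

  cross <- lm_from_paths(list(px_line(c(25, 5), c(25, 45)),
                              px_line(c(5, 25), c(45, 25))),
                         c("artery", "vein"), c(50, 50))
  skc <- skeletonize(cross)
  bpc <- detect_branch_points(skc)
  segsc <- extract_segments(skc, bpc)
  mc <- skc$mask
  mc[cbind(bpc$points$row, bpc$points$col)] <- FALSE
  expect_equal(length(segsc), naive_components(mc)$n)
  expect_length(segsc, 4)
})

test_that("disjoint curves yield one segment each with correct classes", {
  paths <- list(px_line(c(10, 5), c(10, 55)),
                px_line(c(25, 5), c(35, 55)),
                px_line(c(50, 5), c(50, 55)))
  lm <- lm_from_paths(paths, c("artery", "vein", "artery"), c(60, 60))
  segs <- extract_segments(skeletonize(lm))
  expect_length(segs, 3)
  expect_setequal(vapply(segs, `[[`, "", "vessel_class"),
                  c("artery", "vein", "artery"))
  for (s in segs) {
    expect_no_error(validate_segment(s))
    expect_equal(s$end_types, c("endpoint", "endpoint"))
  }
})

test_that("pixel conservation holds through extraction and pruning", {
  cross <- lm_from_paths(list(px_line(c(25, 5), c(25, 45)),
                              px_line(c(5, 25), c(45, 25))),
                         c("artery", "vein"), c(50, 50))
  sk <- skeletonize(cross)
  segs <- prune_junction_artifacts(extract_segments(sk), 5)
  acc <- attr(segs, "accounting")
  expect_equal(acc$n_skeleton,
               acc$n_in_segments + acc$n_branch + acc$n_dropped)
  expect_equal(acc$n_in_segments,
               sum(vapply(segs, function(s) nrow(s$path), 0L)))
})

test_that("junction artifacts are pruned by length and end types", {
  # "H": two long verticals joined by a short crossbar -> crossbar is
  # branch-to-branch
  h <- lm_from_paths(list(px_line(c(5, 10), c(45, 10)),
                          px_line(c(5, 16), c(45, 16)),
                          px_line(c(25, 11), c(25, 15))),
                     rep("artery", 3), c(50, 30))
  sk <- skeletonize(h)
  segs <- extract_segments(sk)
  bridge <- Filter(function(s) all(s$end_types == "branch"), segs)
  expect_gte(length(bridge), 1)
  pruned <- prune_junction_artifacts(segs, max_junction_len = 5)
  expect_lt(length(pruned), length(segs))
  expect_false(any(vapply(pruned, function(s)
    all(s$end_types == "branch") && arc_length(s) <= 5, TRUE)))
  # a generous threshold keeps long connectors; zero threshold keeps all
  expect_length(prune_junction_artifacts(segs, 0), length(segs))
  wide <- lm_from_paths(list(px_line(c(5, 10), c(45, 10)),
                             px_line(c(5, 60), c(45, 60)),
                             px_line(c(25, 11), c(25, 59))),
                        rep("vein", 3), c(50, 70))
  segs_w <- extract_segments(skeletonize(wide))
  expect_length(prune_junction_artifacts(segs_w, 5), length(segs_w))
})

test_that("every segment from a rendered scene satisfies path invariants", {
  sc <- sample_population(1, seed = 2)[[1]]
  sk <- remove_spurs(skeletonize(sc$labels), 10)
  segs <- extract_segments(sk)
  expect_gt(length(segs), 0)
  for (s in segs) expect_no_error(validate_segment(s))
})
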