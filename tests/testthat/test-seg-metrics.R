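# Pixel paths used directly (chord/arc/smoothing are defined on paths).

hline <- function(n) cbind(rep(1, n), seq_len(n))
dline <- function(n) cbind(seq_len(n), seq_len(n))

test_that("chord length is the endpoint distance, with 3-4-5 check", {
  expect_equal(chord_length(hline(100)), 99)
  expect_equal(chord_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_error(chord_length(hline(1)))
})

test_that("arc length is the chain-code sum", {
  expect_equal(arc_length(hline(100)), 99)
  expect_equal(arc_length(dline(100)), 99 * sqrt(2))
})

test_that("straight paths have exactly zero curvature everywhere", {
  for (p in list(hline(60), dline(60))) {
    sp <- smooth_path(p, 5)
    expect_true(all(abs(sp$curvatures) < 1e-9))
    expect_equal(inflection_count(sp, "sign_change"), 0)
    expect_equal(inflection_count(sp, "normal_flip"), 0)
  }
})

test_that("window = 1 leaves coordinates untouched", {
  p <- px_line(c(3, 2), c(17, 40))
  sp <- smooth_path(p, 1)
  expect_equal(sp$points, unname(p))
})

test_that("smoothing a circular arc recovers its curvature", {
  sc <- render_phantom(list(curve_spec("circular_arc", center = c(150, 150),
                                       radius = 50, theta = c(0, pi),
                                       vessel_class = "artery")),
                       canvas = c(300, 300))
  seg <- extract_segments(skeletonize(sc$labels))[[1]]
  sp <- smooth_path(seg, 5)
  expect_lt(abs(mean(abs(sp$curvatures)) - 1 / 50) * 50, 0.10)
})

test_that("flat metrics: dm=1, icm=1, soam=0, nc=0, sdac=0, cl=chord", {
  m <- metrics_for_segment(hline(100))
  expect_identical(m$dm, 1)
  expect_identical(m$icm, 1)
  expect_identical(m$icmb, 1)
  expect_identical(m$soam, 0)
  expect_identical(m$nc, 0)
  expect_identical(m$sdac, 0)
  expect_equal(m$cl, m$chord)
  expect_equal(m$n_inflections, 0L)
  expect_false(m$too_short)
})

test_that("semicircle metrics match the analytic circle", {
  sc <- render_phantom(list(curve_spec("circular_arc", center = c(150, 150),
                                       radius = 50, theta = c(0, pi),
                                       vessel_class = "artery")),
                       canvas = c(300, 300))
  seg <- extract_segments(skeletonize(sc$labels))[[1]]
  m <- metrics_for_segment(seg)
  expect_lt(abs(m$chord - 100), 1.5)            # phantom endpoints
  expect_lt(abs(m$arc - pi * 50) / (pi * 50), 0.06)
  expect_lt(abs(m$dm - pi / 2) / (pi / 2), 0.06)
  expect_lt(abs(m$soam - 1 / 50) * 50, 0.10)    # constant-turning arc
  expect_equal(m$nc, m$soam)                    # identical discretization
})

test_that("sine phantoms count 2k-1 interior inflections", {
  for (k in 1:2) {
    sc <- render_phantom(list(curve_spec("sine", start = c(100, 20),
                                         length = k * 100, amplitude = 20,
                                         periods = k,
                                         vessel_class = "artery")),
                         canvas = c(200, k * 100 + 40))
    seg <- extract_segments(skeletonize(sc$labels))[[1]]
    sp <- smooth_path(seg, 5)
    expect_equal(inflection_count(sp, "sign_change"), 2 * k - 1)
    m <- metrics_for_segment(seg)
    expect_equal(m$icm, (2 * k - 1 + 1) * m$dm)
  }
})

test_that("short paths are flagged and skip curvature metrics", {
  m <- metrics_for_segment(hline(3))
  expect_true(m$too_short)
  expect_equal(m$dm, 1)
  expect_true(is.na(m$soam) && is.na(m$cl) && is.na(m$icm))
})

test_that("dm >= 1 with equality only for collinear paths", {
  set.seed(31)
  for (i in 1:12) {
    a <- runif(1, 0, 2 * pi)
    sc <- render_phantom(list(curve_spec("sine", start = c(150, 150),
                                         length = runif(1, 60, 110),
                                         amplitude = runif(1, 0, 12),
                                         periods = sample(1:2, 1),
                                         orientation = a,
                                         vessel_class = "vein")),
                         canvas = c(300, 300))
    segs <- extract_segments(skeletonize(sc$labels))
    for (s in segs) expect_gte(metrics_for_segment(s)$dm, 1)
  }
  expect_equal(metrics_for_segment(dline(80))$dm, 1)
})

test_that("metrics are stable under rotation of the same curve", {
  seg_at <- function(a) {
    sc <- render_phantom(list(curve_spec("sine", start = c(200, 60),
                                         length = 100, amplitude = 20,
                                         periods = 1, orientation = a,
                                         vessel_class = "artery")),
                         canvas = c(400, 400))
    metrics_for_segment(extract_segments(skeletonize(sc$labels))[[1]])
  }
  ms <- lapply(c(0, pi / 6, pi / 2), seg_at)
  spread <- function(col) {
    v <- vapply(ms, `[[`, 0, col)
    (max(v) - min(v)) / mean(v)
  }
  # geometry-dominated metrics: tight
  for (col in c("chord", "dm", "icm", "icmb", "cl"))
    expect_lt(spread(col), 0.05)
  # chain-code arc and angle sums carry orientation-dependent
  # quantization bias (documented)
  for (col in c("arc", "soam", "nc")) expect_lt(spread(col), 0.08)
  # sdac is a second moment of curvature noise: order-of-magnitude only
  expect_lt(spread("sdac"), 0.5)
  # translation invariance is exact on integer shifts
  p <- px_line(c(5, 5), c(60, 40))
  m1 <- metrics_for_segment(p)
  m2 <- metrics_for_segment(p + 17L)
  expect_equal(m1, m2)
})

test_that("doubling the scale doubles lengths and halves curvatures", {
  seg_scaled <- function(s) {
    sc <- render_phantom(list(curve_spec("sine", start = c(100 * s, 30),
                                         length = 100 * s,
                                         amplitude = 10 * s, periods = 1,
                                         vessel_class = "artery")),
                         canvas = c(200 * s, 100 * s + 60))
    metrics_for_segment(extract_segments(skeletonize(sc$labels))[[1]])
  }
  m1 <- seg_scaled(1); m2 <- seg_scaled(2)
  for (col in c("chord", "arc", "cl"))
    expect_lt(abs(m2[[col]] / m1[[col]] - 2) / 2, 0.05, label = col)
  expect_lt(abs(m2$dm / m1$dm - 1), 0.02)
  expect_lt(abs(m2$icm / m1$icm - 1), 0.02)
  for (col in c("soam", "nc"))
    expect_lt(abs(m2[[col]] / m1[[col]] - 0.5) / 0.5, 0.10, label = col)
})

test_that("pipeline lengths agree with independent dense integration", {
  specs <- list(
    curve_spec("line", from = c(30, 20), to = c(90, 160),
               vessel_class = "artery"),
    curve_spec("circular_arc", center = c(120, 100), radius = 60,
               theta = c(0.2, 2.6), vessel_class = "vein"),
    curve_spec("sine", start = c(60, 20), length = 150, amplitude = 12,
               periods = 2, vessel_class = "artery"),
    curve_spec("cubic_bezier", p0 = c(170, 20), p1 = c(120, 80),
               p2 = c(190, 140), p3 = c(150, 190),
               vessel_class = "vein"))
  for (spec in specs) {
    sc <- render_phantom(list(spec), canvas = c(220, 220))
    seg <- extract_segments(skeletonize(sc$labels))[[1]]
    m <- metrics_for_segment(seg)
    truth <- sc$truth
    # chain-code arc bias ranges from 0 (axis/diagonal) to 8.2% (near
    # 22.5 degrees); the smoothed centerline removes most of it
    expect_lt(abs(m$arc - truth$arc) / truth$arc, 0.09, label = spec$kind)
    expect_lt(abs(m$cl - truth$arc) / truth$arc, 0.05, label = spec$kind)
    expect_lt(abs(m$dm - truth$arc / truth$chord) / (truth$arc / truth$chord),
              0.09, label = spec$kind)
  }
})
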