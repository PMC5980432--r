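test_that("helix closed forms match the finite-difference Frenet oracle", {
  a <- 0.01; b <- 0.003
  fr <- fd_frenet(function(t) a * cos(t), function(t) a * sin(t),
                  function(t) b * t, seq(0.5, 6, length.out = 50))
  expect_equal(mean(fr$kappa), a / (a^2 + b^2), tolerance = 1e-4)
  expect_equal(mean(fr$tau), b / (a^2 + b^2), tolerance = 1e-4)
})

test_that("descriptors of exact analytic samples hit their closed forms", {
  a <- 0.01; b <- 0.003
  cv <- make_curve(curve_spec("helix", a = a, b = b, turns = 1), 400)
  d <- curve_descriptors(cv$points, smoothing = 0)
  expect_equal(d$arc_length, 2 * pi * sqrt(a^2 + b^2), tolerance = 1e-3)
  expect_equal(d$average_curvature, a / (a^2 + b^2), tolerance = 1e-3)
  expect_equal(d$average_torsion, b / (a^2 + b^2), tolerance = 1e-3)

  # smoothing-0 fit is interpolatory
  cur <- smooth_curve(cv$points, smoothing = 0)
  res <- eval_curve(cur, cur$s) - cv$points
  expect_lt(max(abs(res)), 1e-10)

  # line: arc = net, ratio exactly 1
  t <- seq(0, 1, length.out = 101)
  line <- cbind(t * 0.003, 0, 0)
  expect_equal(aspect_ratio(smooth_curve(line, smoothing = 0)), 1,
               tolerance = 1e-9)
  expect_equal(arc_length(smooth_curve(line, smoothing = 0)), 0.003,
               tolerance = 1e-9)

  # half circle: ratio pi/2; closed circle net length 0 -> error
  th <- seq(0, pi, length.out = 301)
  half <- cbind(0.002 * cos(th), 0.002 * sin(th), 0)
  expect_equal(aspect_ratio(smooth_curve(half, smoothing = 0)), pi / 2,
               tolerance = 1e-5)
  th2 <- seq(0, 2 * pi, length.out = 301)
  closed <- cbind(0.002 * cos(th2), 0.002 * sin(th2), 0)
  closed[301, ] <- closed[1, ]     # exactly closed
  expect_error(aspect_ratio(smooth_curve(closed, smoothing = 0)), "coincide")
})

test_that("torsion signs follow handedness and planar curves are torsion-free", {
  cv <- make_curve(curve_spec("helix", a = 0.01, b = 0.003, turns = 3), 400)
  tor <- torsion(smooth_curve(cv$points, smoothing = 0))
  expect_gt(tor$average, 0)
  mir <- cv$points; mir[, 3] <- -mir[, 3]
  tor_m <- torsion(smooth_curve(mir, smoothing = 0))
  expect_equal(tor_m$average, -tor$average, tolerance = 1e-9)

  arc <- make_curve(curve_spec("circle_arc", r = 0.002, angle = pi), 200)
  tor_p <- torsion(smooth_curve(arc$points, smoothing = 0))
  expect_lt(abs(tor_p$average), 1e-6)
})

test_that("near-straight segments are excluded without poisoning average torsion", {
  # line spliced onto a helix: torsion undefined on the straight part
  a <- 0.01; b <- 0.003
  t <- seq(0, 4 * pi, length.out = 300)
  hel <- cbind(a * cos(t), a * sin(t), b * t)
  tan_end <- c(-a * sin(0), a * cos(0), b)
  tan_end <- tan_end / sqrt(sum(tan_end^2))
  line <- outer(seq(0.05, 0.0, length.out = 120), -tan_end) +
    matrix(hel[1, ], 120, 3, byrow = TRUE)
  spliced <- rbind(line[-120, ], hel)
  tor <- torsion(smooth_curve(spliced, smoothing = 0), kappa_min = 1)
  expect_lt(tor$defined_fraction, 0.75)
  expect_equal(tor$average, b / (a^2 + b^2), tolerance = 0.1)
})

test_that("rigid motions leave every descriptor unchanged", {
  cv <- make_curve(curve_spec("helix", a = 0.01, b = 0.003, turns = 2), 300)
  th <- 0.7; ph <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  moved <- cv$points %*% t(Rx %*% Rz) +
    matrix(c(0.3, -0.2, 0.15), nrow(cv$points), 3, byrow = TRUE)
  d0 <- curve_descriptors(cv$points, smoothing = 0)
  d1 <- curve_descriptors(moved, smoothing = 0)
  for (nm in c("arc_length", "net_length", "aspect_ratio",
               "average_curvature", "total_curvature", "average_torsion"))
    expect_equal(d1[[nm]], d0[[nm]], tolerance = 1e-9, label = nm)
  expect_equal(d1$writhe, d0$writhe, tolerance = 1e-6)
})

test_that("scaling bookkeeping: lengths scale, shape measures do not", {
  cv <- make_curve(curve_spec("helix", a = 0.01, b = 0.003, turns = 2), 300)
  c_ <- 3.7
  d0 <- curve_descriptors(cv$points, smoothing = 0)
  d1 <- curve_descriptors(cv$points * c_, smoothing = 0)
  expect_equal(d1$arc_length, c_ * d0$arc_length, tolerance = 1e-9)
  expect_equal(d1$net_length, c_ * d0$net_length, tolerance = 1e-9)
  expect_equal(d1$aspect_ratio, d0$aspect_ratio, tolerance = 1e-9)
  expect_equal(d1$total_curvature, d0$total_curvature, tolerance = 1e-9)
  expect_equal(d1$average_curvature, d0$average_curvature / c_,
               tolerance = 1e-9)
  expect_equal(writhe(cv$points * c_, spacing = NULL),
               writhe(cv$points, spacing = NULL), tolerance = 1e-9)
})

test_that("average curvature equals total curvature over arc length", {
  for (seed in 1:5) {
    cv <- make_curve(curve_spec("random_spline", seed = seed), 200)
    cur <- smooth_curve(cv$points, smoothing = 0)
    k <- curvature(cur)
    expect_equal(k$average, k$total / arc_length(cur), tolerance = 1e-9)
  }
})

test_that("writhe: planar zero, mirror antisymmetry, brute-force agreement", {
  arc <- make_curve(curve_spec("circle_arc", r = 0.02, angle = 5), 300)
  expect_lt(abs(writhe(arc$points, spacing = 0.002)), 1e-6)

  cv <- make_curve(curve_spec("helix", a = 0.01, b = 0.003, turns = 3), 400)
  w <- writhe(cv$points, spacing = 0.002)
  mir <- cv$points; mir[, 3] <- -mir[, 3]
  expect_identical(writhe(mir, spacing = 0.002), -w)

  # 4x-resolution brute-force Gauss double sum
  dense <- make_curve(curve_spec("helix", a = 0.01, b = 0.003, turns = 3),
                      1600)
  w4 <- brute_writhe(resample_uniform(dense$points, 5e-4))
  expect_equal(w, w4, tolerance = 0.01)
})

test_that("writhe rejects degenerate polygons", {
  expect_error(writhe(matrix(rnorm(15), 5, 3), spacing = NULL), "at least 10")
  P <- matrix(rnorm(36), 12, 3)
  P[6, ] <- P[5, ]
  expect_error(writhe(P, spacing = NULL), "coincident")
})

test_that("aspect ratio is always at least 1 on random smooth curves", {
  for (seed in 1:20) {
    cv <- make_curve(curve_spec("random_spline", seed = seed), 150)
    expect_gte(curve_descriptors(cv$points, smoothing = 0)$aspect_ratio,
               1 - 1e-9)
  }
})

test_that("smoothing-sweep: total curvature non-increasing on a noisy curve", {
  cv <- make_curve(curve_spec("helix", a = 0.01, b = 0.003, turns = 3), 100)
  set.seed(11)
  noisy <- cv$points + matrix(rnorm(length(cv$points), 0, 5e-4), ncol = 3)
  totals <- vapply(c(0.2, 0.4, 0.6, 0.8), function(sp)
    curvature(smooth_curve(noisy, smoothing = sp))$total, numeric(1))
  expect_true(all(diff(totals) < 0.05 * totals[-length(totals)]))
  # jittered helix, adaptive smoothing: curvature recovered within 10%
  d <- curve_descriptors(noisy, smoothing = "auto")
  expect_equal(d$average_curvature, cv$descriptors$average_curvature,
               tolerance = 0.1)
})
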