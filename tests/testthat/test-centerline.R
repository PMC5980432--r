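test_that("density score matches the all-pairs oracle and basic geometry", {
  g <- voxel_grid(array(1, c(9, 9, 9)), c(0.002, 5e-4, 5e-4))

  # isolated voxel scores zero
  m1 <- mask_from_sites(rbind(c(5L, 5L, 5L), c(1L, 1L, 1L)), g)
  s1 <- density_score(m1, g)
  expect_equal(s1, c(0, 0))

  # cube centre beats cube corner
  cube <- as.matrix(expand.grid(4:6, 4:6, 4:6))
  mc <- mask_from_sites(cube, g)
  sc <- density_score(mc, g)
  centre_i <- which(cube[, 1] == 5 & cube[, 2] == 5 & cube[, 3] == 5)
  corner_i <- which(cube[, 1] == 4 & cube[, 2] == 4 & cube[, 3] == 4)
  expect_gt(sc[centre_i], sc[corner_i])

  # 50 random voxels vs O(n^2) double loop, radius 2 voxels each axis
  set.seed(6)
  sites <- unique(cbind(sample(9, 50, TRUE), sample(9, 50, TRUE),
                        sample(9, 50, TRUE)))
  m <- mask_from_sites(sites, g)
  got <- density_score(m, g, radius = 2L)
  sp <- c(0.002, 5e-4, 5e-4)
  want <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(sites))) {
    if (i == j) next
    didx <- abs(sites[i, ] - sites[j, ])
    if (max(didx) > 2) next
    d <- sqrt(sum((didx * sp)^2))
    want[i] <- want[i] + 1 / (1 + d)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("find_start lands on the tube axis of a straight segment", {
  cv <- make_curve(curve_spec("line", from = c(-0.02, 0, 0),
                              to = c(0.02, 0, 0)), 100)
  ras <- rasterize_scene(scene_spec(egg_semiaxes = c(0.03, 0.008, 0.006),
                                    noise_sd = 0, seed = 2), cv)
  st <- find_start(ras$masks$flagellum, ras$grid)
  # axis is y = 0.008, z = 0.006 in the grid frame
  expect_lt(abs(st$p0[2] - 0.008), 5e-4 / 2 + 1e-6)
  expect_lt(abs(st$p0[3] - 0.006), 0.002 / 2 + 1e-6)
  d01 <- sqrt(sum((st$p1 - st$p0)^2))
  p <- trace_params(ras$grid$spacing)
  expect_gte(d01, p$eps)
  expect_lte(d01, 2 * p$s0)
})

test_that("start-point distance stays within [eps, 2 s0] on random tubes", {
  for (seed in 1:3) {
    cv <- make_curve(curve_spec("random_spline", seed = seed, n_control = 6,
                                semiaxes = c(0.035, 0.012, 0.008)), 300)
    ras <- rasterize_scene(scene_spec(egg_semiaxes = c(0.05, 0.025, 0.015),
                                      noise_sd = 0, seed = seed), cv)
    st <- find_start(ras$masks$flagellum, ras$grid)
    p <- trace_params(ras$grid$spacing)
    d01 <- sqrt(sum((st$p1 - st$p0)^2))
    expect_gte(d01, p$eps)
    expect_lte(d01, 2 * p$s0)
  }
})

test_that("straight tube traces monotonically along the axis", {
  cv <- make_curve(curve_spec("line", from = c(-0.03, 0, 0),
                              to = c(0.03, 0, 0)), 150)
  ras <- rasterize_scene(scene_spec(egg_semiaxes = c(0.04, 0.008, 0.006),
                                    noise_sd = 0, seed = 2), cv)
  poly <- trace_centerline(ras$masks$flagellum, ras$grid)
  proj <- poly[, 1]
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
  # every point within one voxel diagonal of the axis
  off_axis <- sqrt((poly[, 2] - 0.008)^2 + (poly[, 3] - 0.006)^2)
  expect_lt(max(off_axis), sqrt(sum(ras$grid$spacing^2)))
})

test_that("tracing is deterministic and insensitive to the starting point", {
  fx <- helix_fixture()
  p1 <- trace_centerline(fx$ras$masks$flagellum, fx$ras$grid)
  p2 <- trace_centerline(fx$ras$masks$flagellum, fx$ras$grid)
  expect_identical(unclass(p1)[, ], unclass(p2)[, ])

  L1 <- sum(sqrt(rowSums(diff(p1)^2)))
  # deleting a short run of voxels far from the density peak does not exist
  # as a "seed choice" API; instead check the documented invariance: the
  # backward+forward composition covers the same curve when the start falls
  # mid-curve (the density maximum of a clean helix tube is interior)
  P <- fx$ras$ground_truth$points
  ends <- rbind(p1[1, ], p1[nrow(p1), ])
  d_ends <- apply(ends, 1, function(q)
    min(sqrt(rowSums(sweep(P, 2, q)^2))))
  expect_lt(max(d_ends), 3 * max(fx$ras$grid$spacing))
  expect_equal(L1, fx$cv$descriptors$arc_length, tolerance = 0.05)
})

test_that("traced points stay within a voxel diagonal of the true curve", {
  fx <- helix_fixture()
  poly <- trace_centerline(fx$ras$masks$flagellum, fx$ras$grid)
  P <- fx$ras$ground_truth$points
  nearest <- vapply(seq_len(nrow(poly)), function(i)
    min(sqrt(rowSums(sweep(P, 2, poly[i, ])^2))), numeric(1))
  expect_lt(mean(nearest), sqrt(sum(fx$ras$grid$spacing^2)))
})

test_that("an in-plane 90-degree rotation of the scene rotates the trace", {
  cv <- make_curve(curve_spec("circle_arc", r = 0.015, angle = 4), 300)
  sc <- scene_spec(egg_semiaxes = c(0.025, 0.025, 0.008), noise_sd = 0,
                   seed = 5)
  ras0 <- rasterize_scene(sc, cv)
  rot <- cbind(-cv$points[, 2], cv$points[, 1], cv$points[, 3])
  ras1 <- rasterize_scene(sc, rot)
  d0 <- curve_descriptors(trace_centerline(ras0$masks$flagellum, ras0$grid))
  d1 <- curve_descriptors(trace_centerline(ras1$masks$flagellum, ras1$grid))
  # rasterization breaks exact lattice symmetry at the half-voxel level
  expect_equal(d1$arc_length, d0$arc_length, tolerance = 0.03)
  expect_equal(d1$average_curvature, d0$average_curvature, tolerance = 0.1)
})

test_that("resampling is uniform, idempotent and length-preserving", {
  seg <- rbind(c(0, 0, 0), c(0.01, 0, 0))
  out <- resample_uniform(seg, 0.001)
  expect_equal(nrow(out), 11L)
  expect_equal(diff(out[, 1]), rep(0.001, 10))

  un <- cbind(seq(0, 0.01, by = 5e-4), 0, 0)
  expect_equal(resample_uniform(un, 5e-4), unname(un), tolerance = 1e-12,
               ignore_attr = TRUE)

  cv <- make_curve(curve_spec("random_spline", seed = 8), 800)
  out <- resample_uniform(cv$points, 0.002)
  sp <- sqrt(rowSums(diff(out)^2))
  body <- sp[-length(sp)]
  expect_lt(max(abs(body - 0.002)) / 0.002, 0.01)
  # dense input: chord length preserved tightly; the spline through a
  # coarser polygon may legitimately be slightly longer than its chords
  chord_in <- sum(sqrt(rowSums(diff(cv$points)^2)))
  expect_equal(sum(sp), chord_in, tolerance = 0.001)
  coarse <- make_curve(curve_spec("random_spline", seed = 8), 150)
  out2 <- resample_uniform(coarse$points, 0.002)
  expect_equal(sum(sqrt(rowSums(diff(out2)^2))),
               sum(sqrt(rowSums(diff(coarse$points)^2))), tolerance = 0.02)

  expect_warning(resample_uniform(seg, 0.1), "exceeds")
})
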