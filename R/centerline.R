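#' Tracing parameters
#'
#' Parameters of the iterative directed centerline tracer. Defaults are tied
#' to the grid spacing: the preferred step `s0` is three times the coarsest
#' axis spacing, the minimal step `eps` half of it, and points are resampled
#' at 0.002 mm (the canonical confocal z-step) so point spacing is consistent
#' between samples.
#'
#' @param spacing `(z, y, x)` voxel spacing in mm (used for defaults).
#' @param density_radius neighbourhood radius in voxels for the density
#'   score; a scalar (Chebyshev) or a `(z, y, x)` vector. The default
#'   scales inversely with the per-axis spacing so the neighbourhood is
#'   roughly isotropic in physical units, spanning the tube cross-section:
#'   the score then peaks on the tube axis instead of plateauing across the
#'   whole interior, which is what keeps the selected voxels centred.
#' @param centroid_radius neighbourhood radius in voxels for the sub-voxel
#'   neighbourhood centroids (same physically-isotropic default); during
#'   stepping only the transverse component of the centroid shift is used,
#'   so the wide window recentres across the tube without smearing points
#'   along it.
#' @param s0 preferred step distance in mm.
#' @param eps minimal step in mm; the trace stops when the next point is
#'   closer than this.
#' @param cone_deg forward-cone half-angle in degrees. Candidates at a larger
#'   angle off the current direction are "behind" and not considered. A
#'   strict half-space (90 degrees) would re-admit the perpendicular branch
#'   at a self-crossing; the default 80 is slightly tighter.
#' @param gain curvature-adaptation gain: the preferred step shrinks linearly
#'   with the candidate angle, `s(theta) = s0 * (1 - gain * theta / pi)`, so
#'   the tracer takes smaller steps into turns.
#' @param weight_scale width of the triangular distance kernel relative to
#'   the preferred step.
#' @param consume_radius radius (mm) of the tube of voxels consumed around
#'   each new segment; `NULL` (default) estimates the flagellum tube radius
#'   from mask volume and a pilot trace. Set to 0 to disable consumption
#'   (diagnostic ablation only — self-crossing curves then fail).
#' @param resample_spacing uniform point spacing (mm) of the final polyline.
#' @param max_steps hard cap on steps per direction; reaching it raises a
#'   warning (a healthy trace terminates by running out of candidates or by
#'   the minimal-step rule long before).
#' @return list of class `trace_params`.
#' @export
trace_params <- function(spacing = c(0.002, 5e-4, 5e-4),
                         density_radius = pmax(1L, round(1.5 * max(spacing) /
                                                           spacing)),
                         centroid_radius = pmax(1L, round(1.5 * max(spacing) /
                                                            spacing)),
                         s0 = 3 * max(spacing),
                         eps = 0.5 * max(spacing),
                         cone_deg = 80,
                         gain = 1,
                         weight_scale = 1,
                         consume_radius = NULL,
                         resample_spacing = 0.002,
                         max_steps = 10000L) {
  stopifnot(eps < s0, s0 > 0, eps > 0, all(density_radius >= 1),
            length(density_radius) %in% c(1L, 3L), all(centroid_radius >= 1),
            cone_deg > 0, cone_deg <= 90, resample_spacing > 0, max_steps >= 1)
  structure(list(density_radius = as.integer(density_radius),
                 centroid_radius = as.integer(centroid_radius), s0 = s0,
                 eps = eps, cone_deg = cone_deg, gain = gain,
                 weight_scale = weight_scale, consume_radius = consume_radius,
                 resample_spacing = resample_spacing,
                 max_steps = as.integer(max_steps)),
            class = "trace_params")
}

# Internal tracer state: mask sites, their physical positions and density
# scores, plus a site-index lattice (cropped to the mask bounding box) for
# fast neighbourhood lookups.
trace_state <- function(mask, grid, params) {
  sites <- mask$sites
  n <- nrow(sites)
  if (n < 2L) stop("mask too small to trace (need at least 2 voxels)")
  rs <- params$density_radius
  if (length(rs) == 1L) rs <- rep(rs, 3L)
  rc <- params$centroid_radius %||% 2L
  if (length(rc) == 1L) rc <- rep(rc, 3L)
  rm <- pmax(rs, rc)
  lo <- pmax(apply(sites, 2, min) - max(rm), 1L)
  dimc <- apply(sites, 2, max) - lo + 1L + max(rm)
  idx <- array(0L, dimc)
  cs <- cbind(sites[, 1] - lo[1] + 1L, sites[, 2] - lo[2] + 1L,
              sites[, 3] - lo[3] + 1L)
  idx[cs] <- seq_len(n)
  sp <- grid$spacing
  mk_offs <- function(r) {
    offs <- as.matrix(expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2],
                                  dx = -r[3]:r[3]))
    offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  }
  lookup <- function(offk) {
    sh <- cbind(cs[, 1] + offk[1], cs[, 2] + offk[2], cs[, 3] + offk[3])
    ok <- sh[, 1] >= 1L & sh[, 1] <= dimc[1] & sh[, 2] >= 1L &
      sh[, 2] <= dimc[2] & sh[, 3] >= 1L & sh[, 3] <= dimc[3]
    out <- rep(0L, n)
    out[ok] <- idx[sh[ok, , drop = FALSE]]
    out
  }
  # density score: sum over masked neighbours of 1 / (1 + distance_mm)
  soffs <- mk_offs(rs)
  soffd <- sqrt((soffs[, 1] * sp[["z"]])^2 + (soffs[, 2] * sp[["y"]])^2 +
                  (soffs[, 3] * sp[["x"]])^2)
  score <- numeric(n)
  for (k in seq_len(nrow(soffs)))
    score <- score + (lookup(soffs[k, ]) > 0L) / (1 + soffd[k])
  # compact neighbour table for sub-voxel centroids
  coffs <- mk_offs(rc)
  nb <- lapply(seq_len(nrow(coffs)), function(k) lookup(coffs[k, ]))
  list(sites = sites, pos = index_to_mm(sites, mask), score = score,
       nb = nb, n = n)
}

#' Density score of every masked voxel
#'
#' Each voxel in the mask is scored by the number and distance of its masked
#' neighbours: `score(v) = sum over masked u within the neighbourhood of
#' 1 / (1 + |u - v|)`, distances in mm. Voxels deep inside the labelled tube
#' score higher than surface or stray voxels, so the score acts as the
#' "intensity" that start-point selection and stepping weights use.
#'
#' @param mask a `voxel_mask`.
#' @param grid the [voxel_grid()] the mask refers to.
#' @param radius neighbourhood radius in voxels (Chebyshev).
#' @return numeric vector, one score per row of `mask$sites`.
#' @export
density_score <- function(mask, grid, radius = 2L) {
  st <- trace_state(mask, grid, trace_params(grid$spacing,
                                             density_radius = radius))
  st$score
}

# Score-weighted centroid (mm) of the masked neighbourhood of site i.
# When a travel direction is known, only the transverse component of the
# centroid shift is applied: recentring across the tube must not smear the
# point along it (which would shrink curved sections and bias step lengths).
neighborhood_centroid <- function(state, i, dir = NULL) {
  ids <- c(i, vapply(state$nb, function(v) v[i], integer(1)))
  ids <- ids[ids > 0L]
  w <- state$score[ids]
  if (sum(w) <= 0) w <- rep(1, length(ids))
  ctr <- colSums(state$pos[ids, , drop = FALSE] * w) / sum(w)
  if (is.null(dir)) return(ctr)
  shift <- ctr - state$pos[i, ]
  state$pos[i, ] + shift - sum(shift * dir) * dir
}

# argmax with deterministic tie-break: lexicographically smallest (z, y, x).
argmax_site <- function(values, sites, cand = NULL) {
  if (!is.null(cand)) {
    values <- ifelse(cand, values, -Inf)
  }
  m <- max(values)
  if (!is.finite(m)) return(NA_integer_)
  ties <- which(values >= m - 1e-300 & values == m)
  if (length(ties) == 1L) return(ties)
  o <- order(sites[ties, 1], sites[ties, 2], sites[ties, 3])
  ties[o[1]]
}

#' Find the two starting points of a trace
#'
#' Point 0 is the neighbourhood centroid of the highest-density voxel; point
#' 1 is the neighbourhood centroid of the voxel maximising
#' `score(v) * w_d(|v - point0|)`, where `w_d` is a triangular kernel peaking
#' at the preferred step distance. Ties are broken by the lexicographically
#' smallest `(z, y, x)` index so the result is deterministic.
#'
#' @inheritParams density_score
#' @param params a [trace_params()].
#' @return list with `p0`, `p1` (mm, `(x, y, z)`).
#' @export
find_start <- function(mask, grid, params = trace_params(grid$spacing)) {
  state <- trace_state(mask, grid, params)
  find_start_state(state, params)
}

find_start_state <- function(state, params) {
  i0 <- argmax_site(state$score, state$sites)
  p0 <- neighborhood_centroid(state, i0)
  d <- sqrt(rowSums(sweep(state$pos, 2, p0)^2))
  wd <- pmax(0, 1 - abs(d - params$s0) / (params$weight_scale * params$s0))
  w <- state$score * wd
  w[d <= 0] <- -Inf
  i1 <- argmax_site(w, state$sites)
  if (is.na(i1) || max(w) <= 0)
    stop("mask too small: no candidate for the second start point")
  p1 <- neighborhood_centroid(state, i1)
  if (sqrt(sum((p1 - p0)^2)) < params$eps)
    stop("mask too small: start points closer than the minimal step")
  list(p0 = p0, p1 = p1)
}

# squared distance from points P (n x 3) to segment AB
dist_to_segment <- function(P, A, B) {
  AB <- B - A
  len2 <- sum(AB^2)
  rel <- sweep(P, 2, A)
  t <- if (len2 > 0) pmin(1, pmax(0, as.vector(rel %*% AB) / len2)) else 0
  proj <- outer(t, AB)
  sqrt(rowSums((rel - proj)^2))
}

#' Trace one direction from an ordered point pair
#'
#' Iterates the directed step rule: candidate voxels are the unconsumed
#' masked voxels ahead of the current point (positive projection on the
#' current direction, within the forward cone); each is weighted by
#' `score(v) * w_d(|v - current|)` where the triangular kernel `w_d` peaks at
#' the angle-adapted preferred distance `s(theta) = s0 (1 - gain theta / pi)`
#' (smaller steps into turns); the next point is the neighbourhood centroid
#' of the best candidate. After each step the masked voxels within the
#' consumption radius of the new segment are removed from consideration,
#' which is what lets the tracer pass through a self-crossing of the curve
#' instead of switching branches. Tracing stops when no candidate remains or
#' the step falls below the minimal distance.
#'
#' @inheritParams find_start
#' @param p0,p1 the two seed points (mm); tracing proceeds beyond `p1` in the
#'   direction from `p0` to `p1`.
#' @param consume_radius consumption tube radius in mm (0 disables).
#' @param consumed optional logical vector (one per mask site) of voxels
#'   already consumed before the first step.
#' @return matrix of appended points (mm), possibly with zero rows; the seed
#'   points are not repeated.
#' @export
trace_direction <- function(mask, grid, p0, p1,
                            params = trace_params(grid$spacing),
                            consume_radius = 1.5 * max(grid$spacing),
                            consumed = NULL) {
  state <- trace_state(mask, grid, params)
  if (is.null(consumed)) {
    consumed <- logical(state$n)
    if (consume_radius > 0)
      consumed <- consumed | (dist_to_segment(state$pos, p0, p1) <= consume_radius)
  }
  trace_direction_state(state, p0, p1, params, consume_radius, consumed)$points
}

trace_direction_state <- function(state, p0, p1, params, consume_radius,
                                  consumed,
                                  max_steps = params$max_steps %||% 10000L) {
  cur <- p1
  dir <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  cone <- params$cone_deg * pi / 180
  out <- list()
  repeat {
    rel <- sweep(state$pos, 2, cur)
    dist <- sqrt(rowSums(rel^2))
    proj <- as.vector(rel %*% dir)
    cand <- !consumed & proj > 0 & dist > 0
    if (!any(cand)) break
    theta <- rep(Inf, state$n)
    theta[cand] <- acos(pmin(1, proj[cand] / dist[cand]))
    cand <- cand & theta <= cone
    if (!any(cand)) break
    s_th <- params$s0 * (1 - params$gain * theta / pi)
    wd <- pmax(0, 1 - abs(dist - s_th) / (params$weight_scale * s_th))
    w <- state$score * wd
    w[!cand | wd <= 0] <- -Inf
    i <- argmax_site(w, state$sites)
    if (is.na(i) || !is.finite(w[i]) || w[i] <= 0) break
    nxt <- neighborhood_centroid(state, i, dir)
    step <- sqrt(sum((nxt - cur)^2))
    if (step < params$eps) break
    if (consume_radius > 0)
      consumed <- consumed | (dist_to_segment(state$pos, cur, nxt) <= consume_radius)
    out[[length(out) + 1L]] <- nxt
    dir <- (nxt - cur) / step
    cur <- nxt
    if (length(out) >= max_steps) {
      warning("trace stopped at the step limit")
      break
    }
  }
  # tip completion: the minimal-step rule stops about half a step short of
  # the tube end; append the centroid of the end cap (the farthest
  # projection band of the mask voxels still ahead, within the cone)
  rel <- sweep(state$pos, 2, cur)
  dist <- sqrt(rowSums(rel^2))
  proj <- as.vector(rel %*% dir)
  ahead <- proj > 0 & dist <= params$s0 &
    proj >= dist * cos(cone)
  if (sum(ahead) >= 3L) {
    tp <- colMeans(state$pos[ahead, , drop = FALSE])
    if (sum((tp - cur) * dir) > params$eps / 2)
      out[[length(out) + 1L]] <- tp
  }
  pts <- if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, consumed = consumed)
}

#' Extract the full flagellum centerline from a mask
#'
#' Runs [find_start()], traces forward from (point 0, point 1), then repeats
#' the iteration in the opposite direction with the roles of the two seed
#' points swapped, on a fresh consumption state seeded with the forward
#' trace's first segment. The two traces are concatenated (backward half
#' reversed, seed points kept once) and resampled to uniform spacing.
#'
#' If `params$consume_radius` is `NULL`, a pilot trace first estimates the
#' tube radius as `sqrt(mask_volume / (pi * length))` and the trace is run
#' again with that radius.
#'
#' @inheritParams find_start
#' @return the centerline as a `polyline`: a numeric matrix of ordered
#'   `(x, y, z)` points in mm with attributes `raw_points` (before
#'   resampling), `params` and `consume_radius`.
#' @export
trace_centerline <- function(mask, grid, params = trace_params(grid$spacing)) {
  state <- trace_state(mask, grid, params)
  rho <- params$consume_radius
  if (is.null(rho)) {
    rho0 <- 1.5 * max(grid$spacing)
    pilot <- trace_both(state, params, rho0)
    L <- sum(sqrt(rowSums(diff(pilot)^2)))
    # tube radius estimate plus half a voxel diagonal: consumed segments must
    # cover the whole rasterized cross-section or boundary slivers survive a
    # crossing and re-attract the tracer
    rho <- if (L > 0) sqrt(mask_volume(mask) / (pi * L)) +
      0.5 * sqrt(sum(grid$spacing^2)) else rho0
  }
  raw <- trace_both(state, params, rho)
  if (nrow(raw) < 3L)
    warning("trace produced fewer than 3 points; mask may be degenerate")
  poly <- resample_uniform(raw, params$resample_spacing)
  attr(poly, "raw_points") <- raw
  attr(poly, "params") <- params
  attr(poly, "consume_radius") <- rho
  class(poly) <- c("polyline", class(poly))
  poly
}

trace_both <- function(state, params, rho) {
  st <- find_start_state(state, params)
  p0 <- st$p0; p1 <- st$p1
  base <- logical(state$n)
  if (rho > 0) base <- dist_to_segment(state$pos, p0, p1) <= rho
  fwd <- trace_direction_state(state, p0, p1, params, rho, base)
  back_consumed <- base
  if (rho > 0 && nrow(fwd$points) > 0)
    back_consumed <- back_consumed |
      (dist_to_segment(state$pos, p1, fwd$points[1, ]) <= rho)
  bwd <- trace_direction_state(state, p1, p0, params, rho, back_consumed)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(p0, 1, 3), matrix(p1, 1, 3), fwd$points)
  colnames(pts) <- c("x", "y", "z")
  keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-12)
  pts[keep, , drop = FALSE]
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Chord-length parameterisation re-sampled every `spacing` mm. With at
#' least 4 input points, cubic-spline interpolation through the points is
#' used (a traced polyline's steps are coarser than the resample spacing,
#' and linear interpolation would freeze the polygonized chords into every
#' later measurement); with fewer points, linear interpolation. Both
#' endpoints are preserved; the final segment may be shorter than `spacing`
#' when the total length is not an exact multiple.
#'
#' @param points numeric matrix of ordered `(x, y, z)` points (>= 2 rows).
#' @param spacing target spacing in mm.
#' @return resampled point matrix.
#' @export
resample_uniform <- function(points, spacing) {
  stopifnot(is.matrix(points), nrow(points) >= 2L, spacing > 0)
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) {
    points <- points[c(TRUE, seg > 0), , drop = FALSE]
    seg <- sqrt(rowSums(diff(points)^2))
  }
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (spacing > L) {
    warning("resample spacing exceeds the curve length; returning endpoints")
    out <- points[c(1L, nrow(points)), , drop = FALSE]
    colnames(out) <- c("x", "y", "z")
    return(out)
  }
  targets <- seq(0, L, by = spacing)
  if (L - targets[length(targets)] > 1e-9 * max(L, 1)) targets <- c(targets, L)
  itp <- if (nrow(points) >= 4L)
    function(y) stats::splinefun(s, y, method = "fmm")(targets)
  else
    function(y) stats::approx(s, y, xout = targets)$y
  cbind(x = itp(points[, 1]), y = itp(points[, 2]), z = itp(points[, 3]))
}
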