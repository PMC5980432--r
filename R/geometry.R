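#' Fit a differentiable curve through traced points
#'
#' Curvature needs a second derivative and torsion a third; raw finite
#' differences of traced points amplify voxel-scale jitter at every
#' differentiation. The curve is therefore represented by per-coordinate
#' smoothing splines against the chord-length parameter; an interpolating
#' cubic spline ([stats::splinefun()]) through the smoothed values then
#' supplies analytic derivatives up to third order. At `smoothing = 0` the
#' interpolating spline passes through the raw points exactly.
#'
#' The default is a fixed moderate smoothing (`spar = 0.4`): strong enough
#' to suppress the sub-voxel jitter of traced points, weak enough to keep
#' features at and above the flagellum tube-radius scale (validated on the
#' synthetic line/arc/helix recovery suite). `smoothing = "auto"` instead
#' selects the flexibility by the discrepancy principle — the jitter scale
#' is estimated per coordinate from second differences
#' (`sigma^2 = mean |d2|^2 / 6`, exact for independent jitter) and the
#' equivalent degrees of freedom bisected until the residual RMS matches it.
#' Generalized cross-validation is deliberately not offered as a default:
#' tracer noise is serially correlated along the curve, for which GCV
#' collapses to interpolation. Both ends are padded by odd reflection before
#' fitting so the spline's natural boundary conditions do not flatten the
#' curvature near the ends.
#'
#' @param points numeric matrix of ordered `(x, y, z)` points in mm
#'   (>= 4 rows; consecutive duplicates are dropped), roughly uniformly
#'   spaced, as traced polylines are.
#' @param smoothing a number in (0, 1.5] passed as `spar` to
#'   [stats::smooth.spline()] (default 0.4); `0` interpolates the points
#'   exactly; `"auto"` uses the discrepancy principle.
#' @return an object of class `isei_curve`: component spline functions, the
#'   parameter range, and the smoothing actually used.
#' @export
smooth_curve <- function(points, smoothing = 0.4) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  seg <- sqrt(rowSums(diff(points)^2))
  points <- points[c(TRUE, seg > 0), , drop = FALSE]
  n <- nrow(points)
  if (n < 4L) stop("need at least 4 distinct points to fit a curve")
  s <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  interp <- function(y) stats::splinefun(s, y, method = "fmm")
  fit_coord <- interp
  if (identical(smoothing, "auto") && n >= 8L) {
    # per-coordinate noise scale: anisotropic voxels jitter the axes very
    # differently, so each coordinate gets its own discrepancy target.
    # Each end is padded by odd reflection before fitting: the natural
    # boundary conditions of a smoothing spline force zero second
    # derivative at the ends, which would otherwise flatten the curvature
    # over the outer portion of the curve.
    m <- min(n - 1L, 10L)
    pad <- function(y) {
      c(2 * y[1] - y[(m + 1L):2L], y, 2 * y[n] - y[(n - 1L):(n - m)])
    }
    sp_ <- c(2 * s[1] - s[(m + 1L):2L], s, 2 * s[n] - s[(n - 1L):(n - m)])
    fit_coord <- function(y) {
      sig <- sqrt(mean(diff(y, differences = 2)^2) / 6)
      if (sig < 1e-12) return(interp(y))
      yp <- pad(y)
      lo <- 4; hi <- length(yp) - 1
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        f <- stats::smooth.spline(sp_, yp, df = mid, all.knots = TRUE)
        rms <- sqrt(mean((stats::predict(f, s)$y - y)^2))
        if (rms > sig) lo <- mid else hi <- mid
      }
      f <- stats::smooth.spline(sp_, yp, df = (lo + hi) / 2, all.knots = TRUE)
      stats::splinefun(s, stats::predict(f, s)$y, method = "fmm")
    }
  } else if (is.numeric(smoothing) && smoothing > 0) {
    m <- min(n - 1L, 10L)
    sp_ <- c(2 * s[1] - s[(m + 1L):2L], s, 2 * s[n] - s[(n - 1L):(n - m)])
    fit_coord <- function(y) {
      yp <- c(2 * y[1] - y[(m + 1L):2L], y, 2 * y[n] - y[(n - 1L):(n - m)])
      f <- stats::smooth.spline(sp_, yp, spar = smoothing, all.knots = TRUE)
      stats::splinefun(s, stats::predict(f, s)$y, method = "fmm")
    }
  }
  structure(list(fx = fit_coord(points[, 1]), fy = fit_coord(points[, 2]),
                 fz = fit_coord(points[, 3]), s = s,
                 range = c(0, s[length(s)]), n_points = n,
                 smoothing = smoothing),
            class = "isei_curve")
}

#' Evaluate a fitted curve (or a derivative) at parameter values
#'
#' @param curve an `isei_curve` from [smooth_curve()].
#' @param t parameter values within the curve's range.
#' @param deriv derivative order 0..3.
#' @return numeric matrix, one `(x, y, z)` row per element of `t`.
#' @export
eval_curve <- function(curve, t, deriv = 0L) {
  cbind(x = curve$fx(t, deriv = deriv), y = curve$fy(t, deriv = deriv),
        z = curve$fz(t, deriv = deriv))
}

as_isei_curve <- function(x, smoothing = 0.4) {
  if (inherits(x, "isei_curve")) x else smooth_curve(x, smoothing = smoothing)
}

# uniform parameter grid + trapezoid weights; a fixed grid keeps every
# integral exactly equivariant under rigid motion and scaling of the input
curve_grid <- function(curve, ngrid = 4001L) {
  tg <- seq(curve$range[1], curve$range[2], length.out = ngrid)
  list(t = tg, h = tg[2] - tg[1])
}

trapz <- function(y, h) sum((y[-1] + y[-length(y)]) / 2) * h

#' Arc length of a curve
#'
#' Total length along the curve between its two ends, `integral |r'(t)| dt`,
#' by composite trapezoid quadrature on a fixed uniform parameter grid.
#'
#' @inheritParams eval_curve
#' @param ngrid quadrature grid size.
#' @return length in mm.
#' @export
arc_length <- function(curve, ngrid = 4001L) {
  curve <- as_isei_curve(curve)
  g <- curve_grid(curve, ngrid)
  trapz(sqrt(rowSums(eval_curve(curve, g$t, 1L)^2)), g$h)
}

#' Net length: straight-line distance between the curve's two ends
#'
#' @inheritParams eval_curve
#' @return distance in mm.
#' @export
net_length <- function(curve) {
  curve <- as_isei_curve(curve)
  ends <- eval_curve(curve, curve$range)
  sqrt(sum((ends[2, ] - ends[1, ])^2))
}

#' Aspect ratio: arc length divided by net length
#'
#' 1 for a straight curve; larger for wavy or folded curves. Undefined (an
#' error) when the two ends coincide.
#'
#' @inheritParams arc_length
#' @return dimensionless ratio >= 1.
#' @export
aspect_ratio <- function(curve, ngrid = 4001L) {
  curve <- as_isei_curve(curve)
  nl <- net_length(curve)
  if (nl <= 0) stop("aspect ratio undefined: curve ends coincide")
  arc_length(curve, ngrid) / nl
}

#' Curvature profile, total curvature and average curvature
#'
#' Local curvature is the reciprocal radius of the best-fit circle,
#' `kappa = |r' x r''| / |r'|^3`. Total curvature is curvature integrated
#' along arc length (radians of net turning); average curvature is total
#' curvature divided by arc length.
#'
#' @inheritParams arc_length
#' @return list with `s` (arc-length positions), `profile` (kappa in 1/mm),
#'   `total` (radians) and `average` (1/mm).
#' @export
curvature <- function(curve, ngrid = 4001L) {
  curve <- as_isei_curve(curve)
  g <- curve_grid(curve, ngrid)
  d1 <- eval_curve(curve, g$t, 1L)
  d2 <- eval_curve(curve, g$t, 2L)
  cr <- cross3(d1, d2)
  sp <- sqrt(rowSums(d1^2))
  kappa <- sqrt(rowSums(cr^2)) / sp^3
  total <- trapz(kappa * sp, g$h)
  L <- trapz(sp, g$h)
  list(s = cumsum(c(0, (sp[-1] + sp[-length(sp)]) / 2 * g$h))[-1],
       profile = kappa, total = total, average = total / L)
}

#' Torsion profile and average torsion
#'
#' Torsion measures how much the curve locally resembles a helix — how
#' tightly it winds and whether it is right-handed (positive) or left-handed
#' (negative): `tau = ((r' x r'') . r''') / |r' x r''|^2`. Torsion is
#' undefined where the curve is locally straight; such points (curvature
#' below `kappa_min`) are masked out and excluded from the arc-length-
#' weighted average.
#'
#' Because torsion rests on a third derivative, the spline's one-sided
#' boundary derivatives make it unreliable near the curve ends; the outer
#' `end_trim` fraction of arc length at each end is therefore excluded from
#' the average (the profile is still reported there).
#'
#' @inheritParams arc_length
#' @param kappa_min curvature floor (1/mm) below which torsion is undefined.
#' @param end_trim fraction of the parameter range excluded from the average
#'   at each end.
#' @return list with `profile` (tau in 1/mm, `NA` where undefined),
#'   `average` (1/mm, `NA` if undefined everywhere) and `defined_fraction`
#'   (fraction of arc length where torsion is defined).
#' @export
torsion <- function(curve, ngrid = 4001L, kappa_min = 1e-6, end_trim = 0.05) {
  curve <- as_isei_curve(curve)
  g <- curve_grid(curve, ngrid)
  d1 <- eval_curve(curve, g$t, 1L)
  d2 <- eval_curve(curve, g$t, 2L)
  d3 <- eval_curve(curve, g$t, 3L)
  cr <- cross3(d1, d2)
  cr2 <- rowSums(cr^2)
  sp <- sqrt(rowSums(d1^2))
  kappa <- sqrt(cr2) / sp^3
  tau <- rowSums(cr * d3) / cr2
  defined <- kappa > kappa_min
  tau[!defined] <- NA_real_
  span <- curve$range[2] - curve$range[1]
  interior <- g$t >= curve$range[1] + end_trim * span &
    g$t <= curve$range[2] - end_trim * span
  w <- sp * as.numeric(defined & interior)
  denom <- trapz(w, g$h)
  avg <- if (denom > 0) trapz(ifelse(w > 0, tau * sp, 0), g$h) / denom
  else NA_real_
  list(profile = tau, average = avg,
       defined_fraction = denom / trapz(sp, g$h))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Writhe of an open curve (Gauss double integral)
#'
#' A global measure of helical and figure-of-eight structure:
#' `Wr = (1/4pi) double-integral (t(s) x t(s')) . (r(s) - r(s')) /
#' |r(s) - r(s')|^3 ds ds'` over `s != s'`, evaluated by pairwise summation
#' over the segments of a uniformly resampled polygon. The diagonal and
#' adjacent segment pairs (singular or near-singular) are excluded; planar
#' curves give exactly 0 and a mirror image flips the sign exactly.
#'
#' @param x an `isei_curve` or an ordered point matrix.
#' @param spacing segment length (mm) of the polygon the sum runs over; when
#'   `x` is already a point matrix and `spacing` is `NULL` the points are
#'   used as-is.
#' @return dimensionless writhe.
#' @export
writhe <- function(x, spacing = 0.002) {
  if (inherits(x, "isei_curve")) {
    g <- curve_grid(x, 4001L)
    P <- resample_uniform(eval_curve(x, g$t), spacing)
  } else {
    P <- as.matrix(x)
    if (!is.null(spacing)) P <- resample_uniform(P, spacing)
  }
  n <- nrow(P) - 1L
  if (n < 9L) stop("writhe needs at least 10 sample points")
  e <- diff(P)
  len <- sqrt(rowSums(e^2))
  if (any(len == 0)) stop("coincident sample points")
  tt <- e / len
  mid <- (P[-1, , drop = FALSE] + P[-(n + 1L), , drop = FALSE]) / 2
  total <- 0
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    r <- sweep(mid[j, , drop = FALSE], 2, mid[i, ])
    d3 <- (rowSums(r^2))^1.5
    if (any(d3 == 0)) stop("coincident segment midpoints")
    cx <- cross3(matrix(tt[i, ], length(j), 3, byrow = TRUE),
                 tt[j, , drop = FALSE])
    # integrand (t_i x t_j) . (m_i - m_j); r above is m_j - m_i, hence the -
    total <- total - sum(rowSums(cx * r) / d3 * len[i] * len[j])
  }
  2 * total / (4 * pi)
}

#' Compute the full descriptor set of a traced centerline
#'
#' Fits the differentiable curve representation and evaluates every shape
#' descriptor: arc length, net length, aspect ratio, curvature
#' (average and total), average torsion, and writhe.
#'
#' @param points ordered `(x, y, z)` point matrix (e.g. a traced polyline).
#' @param smoothing passed to [smooth_curve()].
#' @param ngrid quadrature grid size.
#' @param writhe_spacing polygon spacing for the writhe sum (mm).
#' @return named list of descriptor values (plus `torsion_defined_fraction`
#'   and the `smoothing` used).
#' @export
curve_descriptors <- function(points, smoothing = 0.4, ngrid = 4001L,
                              writhe_spacing = 0.002) {
  curve <- as_isei_curve(points, smoothing = smoothing)
  L <- arc_length(curve, ngrid)
  nl <- net_length(curve)
  kap <- curvature(curve, ngrid)
  tau <- torsion(curve, ngrid)
  # writhe is summed over the sampled polygon itself (tangents only, no
  # spline derivatives), at the standard resample spacing
  wr <- if (inherits(points, "isei_curve"))
    writhe(points, spacing = min(writhe_spacing, L / 20))
  else writhe(as.matrix(points), spacing = min(writhe_spacing, L / 20))
  list(arc_length = L, net_length = nl,
       aspect_ratio = if (nl > 0) L / nl else NA_real_,
       average_curvature = kap$average, total_curvature = kap$total,
       average_torsion = tau$average,
       torsion_defined_fraction = tau$defined_fraction,
       writhe = wr, smoothing = smoothing)
}
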