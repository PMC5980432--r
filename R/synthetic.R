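#' Specify a generating flagellum curve
#'
#' Curve families used to build synthetic eggs with known geometry:
#'
#' * `line`: endpoints `from`, `to`.
#' * `circle_arc`: radius `r` (mm), arc `angle` (radians). Constant
#'   curvature `1/r` — the defining property of curvature.
#' * `helix`: radius `a`, pitch parameter `b` (mm per radian; negative for a
#'   left-handed helix), `turns`. The canonical object torsion is defined
#'   against: `kappa = a/(a^2+b^2)`, `tau = b/(a^2+b^2)`.
#' * `figure8`: `lobe` radius (mm) and out-of-plane `offset` (mm). A Gerono
#'   lemniscate lifted out of plane so the true curve never self-intersects
#'   in 3D while its voxel tube does — the case the tracer's voxel
#'   consumption rule exists for.
#' * `random_spline`: `n_control` control points from a smooth random walk
#'   inside a bounding ellipsoid `semiaxes`; C2-continuous by construction.
#'
#' A rigid placement (`rotation` as a 3x3 matrix, `translation` length-3 mm)
#' is applied after generation.
#'
#' @param family one of `"line"`, `"circle_arc"`, `"helix"`, `"figure8"`,
#'   `"random_spline"`.
#' @param ... family parameters (see above).
#' @param rotation 3x3 rotation matrix.
#' @param translation `(x, y, z)` offset in mm.
#' @return list of class `curve_spec`.
#' @export
curve_spec <- function(family, ..., rotation = diag(3),
                       translation = c(0, 0, 0)) {
  p <- list(...)
  fam <- match.arg(family,
                   c("line", "circle_arc", "helix", "figure8", "random_spline"))
  chk <- function(val, name) {
    if (is.null(val) || !is.finite(val) || val <= 0)
      stop(sprintf("curve_spec('%s'): parameter `%s` must be > 0", fam, name))
    val
  }
  switch(fam,
    line = {
      if (is.null(p$from) || is.null(p$to)) stop("line needs `from` and `to`")
      if (sqrt(sum((p$to - p$from)^2)) <= 0) stop("line endpoints coincide")
    },
    circle_arc = {
      chk(p$r, "r"); chk(p$angle, "angle")
    },
    helix = {
      chk(p$a, "a"); chk(abs(p$b %||% 0), "b"); chk(p$turns, "turns")
    },
    figure8 = {
      chk(p$lobe, "lobe")
      if (is.null(p$offset)) p$offset <- 0.0015
      # trim per end (radians): keeps the curve open, with its two ends
      # separated by more than the tracer's step-kernel reach
      if (is.null(p$gap)) p$gap <- 0.7
      # y-compression: sets the self-crossing angle to 2*atan(squeeze), i.e.
      # shallower than the tracer's forward cone, so the crossing genuinely
      # exercises the voxel-consumption rule
      if (is.null(p$squeeze)) p$squeeze <- 0.6
    },
    random_spline = {
      p$n_control <- p$n_control %||% 8L
      if (p$n_control < 4L) stop("random_spline needs >= 4 control points")
      p$semiaxes <- p$semiaxes %||% c(0.15, 0.05, 0.05)
      p$seed <- p$seed %||% 1L
      # resolvability constraints: a labelled tube of radius ~0.0025 mm is
      # only traceable if the curve bends no tighter than a few tube radii
      # and never approaches itself closer than a tube diameter; candidate
      # curves violating these are rejected and redrawn
      p$min_radius <- p$min_radius %||% 0.0075
      p$min_separation <- p$min_separation %||% 0.0065
    })
  structure(list(family = fam, params = p, rotation = rotation,
                 translation = translation),
            class = "curve_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate curve sample points and ground-truth descriptors
#'
#' Samples the specified curve uniformly in arc length and returns its
#' descriptors: closed forms where the family admits them (line, circle arc,
#' helix lengths/curvature/torsion), otherwise high-resolution numerical
#' values flagged as such.
#'
#' @param spec a [curve_spec()].
#' @param n_samples number of points (>= 50).
#' @return list with `points` (n x 3 mm, uniform in arc length),
#'   `descriptors` (named list), `analytic` (named logical flags), `spec`.
#' @export
make_curve <- function(spec, n_samples = 400L) {
  stopifnot(inherits(spec, "curve_spec"))
  if (n_samples < 50L) stop("n_samples must be >= 50")
  dense_n <- max(20L * n_samples, 4000L)
  p <- spec$params
  pts <- switch(spec$family,
    line = {
      t <- seq(0, 1, length.out = dense_n)
      outer(rep(1, dense_n), p$from) + outer(t, p$to - p$from)
    },
    circle_arc = {
      t <- seq(0, p$angle, length.out = dense_n)
      cbind(p$r * cos(t), p$r * sin(t), 0)
    },
    helix = {
      t <- seq(0, 2 * pi * p$turns, length.out = dense_n)
      cbind(p$a * cos(t), p$a * sin(t), p$b * t)
    },
    figure8 = {
      t <- seq(p$gap, 2 * pi - p$gap, length.out = dense_n)
      cbind(p$lobe * cos(t), p$squeeze * p$lobe * sin(t) * cos(t),
            p$offset * sin(t))
    },
    random_spline = draw_random_spline(p, dense_n))
  pts <- pts %*% t(spec$rotation)
  pts <- sweep(pts, 2, spec$translation, `+`)
  colnames(pts) <- c("x", "y", "z")
  points <- resample_count(pts, n_samples)

  nm <- c("arc_length", "net_length", "aspect_ratio", "average_curvature",
          "total_curvature", "average_torsion", "writhe")
  if (spec$family == "line") {
    L <- sqrt(sum((p$to - p$from)^2))
    desc <- list(arc_length = L, net_length = L, aspect_ratio = 1,
                 average_curvature = 0, total_curvature = 0,
                 average_torsion = NA_real_, writhe = 0)
    analytic <- setNames(rep(TRUE, 7L), nm)
  } else if (spec$family == "circle_arc") {
    L <- p$r * p$angle
    desc <- list(arc_length = L,
                 net_length = 2 * p$r * abs(sin(p$angle / 2)),
                 aspect_ratio = NA, average_curvature = 1 / p$r,
                 total_curvature = p$angle, average_torsion = 0, writhe = 0)
    desc$aspect_ratio <- desc$arc_length / desc$net_length
    analytic <- setNames(rep(TRUE, 7L), nm)
  } else if (spec$family == "helix") {
    den <- p$a^2 + p$b^2
    T <- 2 * pi * p$turns
    desc <- list(arc_length = T * sqrt(den),
                 net_length = sqrt((p$a * cos(T) - p$a)^2 +
                                     (p$a * sin(T))^2 + (p$b * T)^2),
                 aspect_ratio = NA, average_curvature = p$a / den,
                 total_curvature = NA, average_torsion = p$b / den,
                 writhe = writhe(points, spacing =
                                   min(0.002, T * sqrt(den) / 20)))
    desc$aspect_ratio <- desc$arc_length / desc$net_length
    desc$total_curvature <- desc$average_curvature * desc$arc_length
    analytic <- setNames(rep(TRUE, 7L), nm)
    analytic["writhe"] <- FALSE     # no closed form for the open Gauss sum
  } else {
    num <- curve_descriptors(pts[seq(1, nrow(pts), length.out = 4000L), ],
                             smoothing = 0)
    desc <- num[nm]
    analytic <- setNames(rep(FALSE, 7L), nm)
  }
  list(points = points, descriptors = desc, analytic = analytic, spec = spec)
}

# draw a C2 random open curve inside the bounding ellipsoid, redrawing until
# the resolvability constraints (bend radius, self-separation) are met
draw_random_spline <- function(p, dense_n) {
  k <- p$n_control
  for (try_i in 0:199) {
    set.seed(p$seed + 10000L * try_i)
    # momentum walk: persistent direction gives flagellum-like smoothness
    step <- matrix(0, k - 1, 3)
    v <- stats::rnorm(3)
    for (j in seq_len(k - 1)) {
      v <- 0.7 * v + 0.5 * stats::rnorm(3)
      step[j, ] <- v
    }
    ctrl <- apply(rbind(0, step), 2, cumsum)
    ctrl <- scale(ctrl, center = TRUE, scale = FALSE)
    ctrl <- sweep(ctrl, 2, apply(abs(ctrl), 2, max) + 1e-9, `/`)
    ctrl <- sweep(ctrl, 2, 0.8 * p$semiaxes, `*`)
    u <- seq_len(k)
    ud <- seq(1, k, length.out = dense_n)
    pts <- cbind(stats::splinefun(u, ctrl[, 1], "fmm")(ud),
                 stats::splinefun(u, ctrl[, 2], "fmm")(ud),
                 stats::splinefun(u, ctrl[, 3], "fmm")(ud))
    if (spline_resolvable(pts, p$min_radius, p$min_separation)) return(pts)
  }
  stop("random_spline: no curve satisfying the resolvability constraints ",
       "after 200 draws; relax min_radius/min_separation or enlarge the ",
       "bounding ellipsoid")
}

spline_resolvable <- function(pts, min_radius, min_sep) {
  m <- pts[seq(1, nrow(pts), length.out = 400L), ]
  seg <- sqrt(rowSums(diff(m)^2))
  s <- c(0, cumsum(seg))
  # discrete curvature via turning angles
  t1 <- diff(m) / seg
  ang <- acos(pmin(1, pmax(-1, rowSums(t1[-1, ] * t1[-nrow(t1), ]))))
  kap <- ang / ((seg[-1] + seg[-length(seg)]) / 2)
  if (max(kap) > 1 / min_radius) return(FALSE)
  # self-separation: non-neighbouring samples (arc distance > 4*min_sep)
  d2 <- as.matrix(stats::dist(m))
  arcd <- abs(outer(s, s, `-`))
  off <- arcd > 4 * min_sep
  all(d2[off] >= min_sep)
}

# resample a dense point set to exactly n points uniform in chord length
resample_count <- function(pts, n) {
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tg <- seq(0, s[length(s)], length.out = n)
  cbind(x = stats::approx(s, pts[, 1], xout = tg)$y,
        y = stats::approx(s, pts[, 2], xout = tg)$y,
        z = stats::approx(s, pts[, 3], xout = tg)$y)
}

#' Specify a synthetic egg scene
#'
#' Defaults emulate an *obscura*-group egg imaged confocally: ellipsoid egg
#' with semi-axes `(0.20, 0.075, 0.075)` mm, anisotropic voxel spacing
#' `(0.002, 0.0005, 0.0005)` mm in `(z, y, x)` (the canonical 0.002 mm
#' z-step, finer in-plane), a labelled flagellum tube whose intensity falls
#' off as a Gaussian of distance to the curve (half peak exactly at the tube
#' radius), Gaussian landmark blobs, and additive Gaussian noise at 10% of
#' the tube peak.
#'
#' @param egg_semiaxes `(x, y, z)` semi-axes in mm.
#' @param spacing `(z, y, x)` voxel spacing in mm.
#' @param tube_radius flagellum tube radius in mm; must be at least the
#'   coarsest voxel spacing to be resolvable.
#' @param blobs list of landmark blobs, each
#'   `list(kind = , center = c(x,y,z), radius = )` with kind one of
#'   `male_pronucleus`, `female_pronucleus`, `polar_bodies`, `nucleus`.
#' @param peak tube peak intensity above background (arbitrary units).
#' @param background background intensity.
#' @param noise_sd additive Gaussian noise sd as a fraction of `peak`.
#' @param poisson add Poisson resampling of the noise-free signal (off by
#'   default).
#' @param seed RNG seed; together with the spec it fully determines the
#'   output stack.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(egg_semiaxes = c(0.20, 0.075, 0.075),
                       spacing = c(0.002, 5e-4, 5e-4),
                       tube_radius = 0.0025,
                       blobs = list(),
                       peak = 10000, background = 500,
                       noise_sd = 0.1, poisson = FALSE, seed = 1L) {
  stopifnot(all(spacing > 0), all(egg_semiaxes > 0), peak > 0,
            noise_sd >= 0, background >= 0)
  if (tube_radius < max(spacing))
    stop("tube_radius must be >= the coarsest voxel spacing (unresolvable)")
  for (b in blobs) {
    if (any(abs(b$center) > egg_semiaxes))
      stop("blob centre outside the egg ellipsoid: ",
           paste(signif(b$center, 3), collapse = ", "))
  }
  structure(list(egg_semiaxes = egg_semiaxes, spacing = spacing,
                 tube_radius = tube_radius, blobs = blobs, peak = peak,
                 background = background, noise_sd = noise_sd,
                 poisson = poisson, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Rasterize a curve and landmarks into a synthetic voxel stack
#'
#' Builds the intensity grid `background + peak * exp(-d^2 / (2 sigma^2))`
#' where `d` is distance to the flagellum curve (with `sigma` chosen so the
#' intensity at the tube radius is exactly half peak), adds Gaussian blobs at
#' the landmark centres, then noise per the scene's noise model. The
#' noise-free binary masks (tube and blobs) and the ground truth are emitted
#' alongside. The egg is centred in the grid; scene coordinates are relative
#' to the egg centre.
#'
#' @param scene a [scene_spec()].
#' @param curve a [make_curve()] result (or a bare point matrix, mm).
#' @return list with `grid` (a [voxel_grid()]), `masks` (named list of
#'   `voxel_mask`), `ground_truth` (curve points in grid coordinates, the
#'   analytic descriptors, true landmark centres, and the scene).
#' @export
rasterize_scene <- function(scene, curve) {
  stopifnot(inherits(scene, "scene_spec"))
  if (is.list(curve) && !is.null(curve$points)) {
    pts <- curve$points; gt_desc <- curve$descriptors
    gt_analytic <- curve$analytic
  } else {
    pts <- as.matrix(curve); gt_desc <- NULL; gt_analytic <- NULL
  }
  sp <- setNames(scene$spacing, c("z", "y", "x"))
  dims <- c(z = ceiling(2 * scene$egg_semiaxes[3] / sp[["z"]]),
            y = ceiling(2 * scene$egg_semiaxes[2] / sp[["y"]]),
            x = ceiling(2 * scene$egg_semiaxes[1] / sp[["x"]]))
  centre <- c(dims[["x"]] * sp[["x"]], dims[["y"]] * sp[["y"]],
              dims[["z"]] * sp[["z"]]) / 2
  P <- sweep(pts, 2, centre, `+`)      # grid-frame mm
  extent <- c(dims[["x"]] * sp[["x"]], dims[["y"]] * sp[["y"]],
              dims[["z"]] * sp[["z"]])
  margin <- scene$tube_radius
  for (ax in 1:3) {
    bad <- which(P[, ax] < margin | P[, ax] > extent[ax] - margin)
    if (length(bad) > 0)
      stop(sprintf(
        "curve exits the grid: point (%.4f, %.4f, %.4f) mm on axis %s",
        P[bad[1], 1], P[bad[1], 2], P[bad[1], 3], c("x", "y", "z")[ax]))
  }
  sigma <- scene$tube_radius / sqrt(2 * log(2))
  dense <- resample_uniform(P, min(sp) / 2)
  gain <- array(0, dims)           # running max of exp(-d^2/2sigma^2)
  for (k in seq_len(nrow(dense))) {
    st <- stamp_ball(dense[k, ], sigma, 2.5 * sigma, sp, dims)
    if (is.null(st)) next
    gain[st$iz, st$iy, st$ix] <- pmax(gain[st$iz, st$iy, st$ix], st$val)
  }
  # truncate the tube at the endpoint planes: without this the spherical
  # stamp caps extend the mask ~tube_radius beyond the generating curve and
  # any traced centerline would rightly be longer than the ground truth
  nd <- nrow(dense)
  for (end in list(list(p = dense[1, ], t = dense[1, ] - dense[2, ]),
                   list(p = dense[nd, ], t = dense[nd, ] - dense[nd - 1L, ]))) {
    tv <- end$t / sqrt(sum(end$t^2))
    st <- stamp_ball(end$p, sigma, 2.5 * sigma, sp, dims)
    if (is.null(st)) next
    px <- (st$ix - 0.5) * sp[["x"]] - end$p[1]
    py <- (st$iy - 0.5) * sp[["y"]] - end$p[2]
    pz <- (st$iz - 0.5) * sp[["z"]] - end$p[3]
    beyond <- outer(pz * tv[3], outer(py * tv[2], px * tv[1], `+`), `+`) > 0
    sub <- gain[st$iz, st$iy, st$ix]
    sub[beyond] <- 0
    gain[st$iz, st$iy, st$ix] <- sub
  }
  tube_mask_arr <- gain >= exp(-scene$tube_radius^2 / (2 * sigma^2)) - 1e-12
  intensity <- scene$background + scene$peak * gain

  masks <- list()
  blob_centres <- list()
  for (b in scene$blobs) {
    bc <- b$center + centre
    bsig <- b$radius / sqrt(2 * log(2))
    st <- stamp_ball(bc, bsig, 2.5 * bsig, sp, dims)
    if (is.null(st)) next
    sub <- intensity[st$iz, st$iy, st$ix]
    intensity[st$iz, st$iy, st$ix] <-
      pmax(sub, scene$background + scene$peak * st$val)
    bm <- which(st$val >= exp(-b$radius^2 / (2 * bsig^2)) - 1e-12,
                arr.ind = TRUE)
    sites <- cbind(st$iz[bm[, 1]], st$iy[bm[, 2]], st$ix[bm[, 3]])
    masks[[b$kind]] <- rbind(masks[[b$kind]], sites)
    blob_centres[[b$kind]] <- rbind(blob_centres[[b$kind]], bc)
  }

  set.seed(scene$seed)
  if (scene$poisson)
    intensity <- array(stats::rpois(length(intensity), pmax(intensity, 0)),
                       dims)
  if (scene$noise_sd > 0)
    intensity <- intensity +
      stats::rnorm(length(intensity), 0, scene$noise_sd * scene$peak)
  intensity[intensity < 0] <- 0
  grid <- voxel_grid(intensity, sp)

  mask_list <- list(flagellum = mask_from_sites(
    unname(which(tube_mask_arr, arr.ind = TRUE)), grid, "flagellum"))
  for (kind in names(masks)) {
    m <- unique(masks[[kind]])
    colnames(m) <- NULL
    mask_list[[kind]] <- mask_from_sites(m, grid, kind)
  }
  centres <- lapply(blob_centres, function(m) colMeans(m))
  list(grid = grid, masks = mask_list,
       ground_truth = list(points = P, descriptors = gt_desc,
                           analytic = gt_analytic,
                           landmarks = centres, scene = scene))
}

# Gaussian ball exp(-d^2/(2 sigma^2)) around a point (x,y,z) mm: returns the
# index ranges and the [z, y, x] value box (NULL if outside the grid)
stamp_ball <- function(pt, sigma, reach, sp, dims) {
  ix <- floor((pt[1] - reach) / sp[["x"]] + 0.5):ceiling((pt[1] + reach) / sp[["x"]] + 0.5)
  iy <- floor((pt[2] - reach) / sp[["y"]] + 0.5):ceiling((pt[2] + reach) / sp[["y"]] + 0.5)
  iz <- floor((pt[3] - reach) / sp[["z"]] + 0.5):ceiling((pt[3] + reach) / sp[["z"]] + 0.5)
  ix <- ix[ix >= 1 & ix <= dims[["x"]]]
  iy <- iy[iy >= 1 & iy <= dims[["y"]]]
  iz <- iz[iz >= 1 & iz <= dims[["z"]]]
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
  dx2 <- ((ix - 0.5) * sp[["x"]] - pt[1])^2
  dy2 <- ((iy - 0.5) * sp[["y"]] - pt[2])^2
  dz2 <- ((iz - 0.5) * sp[["z"]] - pt[3])^2
  d2 <- outer(dz2, outer(dy2, dx2, `+`), `+`)       # [z, y, x] box
  list(iz = iz, iy = iy, ix = ix, val = exp(-d2 / (2 * sigma^2)))
}

#' Specify a group-effect model for simulated experiments
#'
#' The generating flagellum is a helix; group effects act multiplicatively on
#' its radius `a` and pitch `b`, and between-egg variation is lognormal on
#' both. A zero effect model (the default `shift_fn`) makes every group
#' exchangeable, which is the null configuration used for type-I-error
#' calibration of the statistics stage.
#'
#' The default base helix is rotated so its axis lies along the egg's long
#' (x) axis, where the sperm is found in a real egg.
#'
#' @param base a [curve_spec()] for the population-typical flagellum.
#' @param shift_fn `function(female, male, stage)` returning a named list
#'   with multipliers `a` and `b` (defaults to all 1: no group effect).
#' @param egg_cv between-egg coefficient of variation (lognormal sd of the
#'   log multiplier) applied independently to `a` and `b`.
#' @param landmark_sd sd (mm) of the landmark centre jitter between eggs.
#' @return list of class `effect_model`.
#' @export
effect_model <- function(base = curve_spec("helix", a = 0.01, b = 0.003,
                                           turns = 3,
                                           rotation = rbind(c(0, 0, 1),
                                                            c(0, 1, 0),
                                                            c(-1, 0, 0))),
                         shift_fn = NULL, egg_cv = 0.08,
                         landmark_sd = 0.005) {
  if (is.null(shift_fn)) shift_fn <- function(female, male, stage)
    list(a = 1, b = 1)
  structure(list(base = base, shift_fn = shift_fn, egg_cv = egg_cv,
                 landmark_sd = landmark_sd),
            class = "effect_model")
}

#' Simulate a full crossing experiment
#'
#' Generates one egg per design row count: a per-egg flagellum curve (group
#' effect times lognormal egg-to-egg variation on the helix parameters),
#' its exact descriptors, and the landmark positions. With
#' `rasterize = TRUE` each egg is also rendered to a multi-page TIFF stack
#' (plus ground-truth JSON) under `out_dir`; with `rasterize = FALSE`
#' ("tables-only" mode) only the annotation and record tables are produced,
#' which is what large statistical calibrations use.
#'
#' @param design data frame with columns `female`, `male`, `stage`
#'   (PN/2N/4N/8N) and `n` (eggs per cell, >= 1).
#' @param scene a [scene_spec()] shared by all eggs.
#' @param model an [effect_model()].
#' @param seed integer seed; fully determines the experiment.
#' @param out_dir output directory for stacks/tables (required if
#'   `rasterize`).
#' @param rasterize render voxel stacks to disk.
#' @return list with `annotations` (egg_id, female_species, male_species,
#'   stage, path), `records` (analytic descriptor rows, same schema as
#'   [measure_egg()]), and `ground_truths` (per egg).
#' @export
generate_experiment <- function(design, scene = scene_spec(),
                                model = effect_model(), seed = 1L,
                                out_dir = NULL, rasterize = FALSE) {
  stopifnot(all(c("female", "male", "stage", "n") %in% names(design)))
  if (any(design$n < 1)) stop("every design cell needs n >= 1 egg")
  if (rasterize && is.null(out_dir))
    stop("rasterize = TRUE needs an `out_dir`")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  set.seed(seed)
  base <- model$base$params
  ann <- list(); recs <- list(); gts <- list()
  for (r in seq_len(nrow(design))) {
    sh <- model$shift_fn(design$female[r], design$male[r], design$stage[r])
    for (i in seq_len(design$n[r])) {
      egg_id <- sprintf("%s_%s_%s_%02d", design$female[r], design$male[r],
                        design$stage[r], i)
      a <- base$a * (sh$a %||% 1) * exp(stats::rnorm(1, 0, model$egg_cv))
      b <- base$b * (sh$b %||% 1) * exp(stats::rnorm(1, 0, model$egg_cv))
      rot <- model$base$rotation
      spec <- curve_spec("helix", a = a, b = b, turns = base$turns,
                         rotation = rot,
                         translation =
                           as.numeric(rot %*% c(0, 0, -pi * base$turns * b)))
      cv <- make_curve(spec, n_samples = 200L)
      stage <- design$stage[r]
      pb <- c(0.04, 0, 0.01) + stats::rnorm(3, 0, model$landmark_sd)
      mpn <- c(0.01, 0.005, 0) + stats::rnorm(3, 0, model$landmark_sd)
      fpn <- c(-0.01, -0.005, 0) + stats::rnorm(3, 0, model$landmark_sd)
      d <- cv$descriptors
      rec <- data.frame(
        egg_id = egg_id, female_species = design$female[r],
        male_species = design$male[r], stage = stage,
        sperm_positioning = if (stage == "PN")
          mean(sqrt(rowSums(sweep(cv$points, 2, pb)^2))) else NA_real_,
        pronuclei_distance = if (stage == "PN")
          sqrt(sum((mpn - fpn)^2)) else NA_real_,
        arc_length = d$arc_length, net_length = d$net_length,
        aspect_ratio = d$aspect_ratio,
        average_curvature = d$average_curvature,
        total_curvature = d$total_curvature,
        average_torsion = if (stage == "PN") d$average_torsion else NA_real_,
        writhe = NA_real_, stringsAsFactors = FALSE)
      path <- NA_character_
      if (rasterize) {
        sc <- scene
        if (stage == "PN")
          sc$blobs <- list(list(kind = "polar_bodies", center = pb,
                                radius = 0.005),
                           list(kind = "male_pronucleus", center = mpn,
                                radius = 0.004),
                           list(kind = "female_pronucleus", center = fpn,
                                radius = 0.004))
        ras <- rasterize_scene(sc, cv)
        path <- file.path(out_dir, paste0(egg_id, ".tif"))
        write_stack(ras$grid, path)
        jsonlite::write_json(
          list(egg_id = egg_id, descriptors = cv$descriptors,
               landmarks = ras$ground_truth$landmarks,
               curve_points = unname(split(ras$ground_truth$points,
                                           row(ras$ground_truth$points)))),
          file.path(out_dir, paste0(egg_id, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
      ann[[egg_id]] <- data.frame(egg_id = egg_id,
                                  female_species = design$female[r],
                                  male_species = design$male[r],
                                  stage = stage, path = path,
                                  stringsAsFactors = FALSE)
      recs[[egg_id]] <- rec
      gts[[egg_id]] <- list(spec = spec, descriptors = cv$descriptors,
                            landmarks = list(polar_bodies = pb,
                                             male_pronucleus = mpn,
                                             female_pronucleus = fpn))
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(annotations, file.path(out_dir, "annotations.csv"),
                     row.names = FALSE, na = "")
  list(annotations = annotations, records = records, ground_truths = gts)
}
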