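# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force double loops, finite differences,
# and projection-matrix ANOVA.

# Frenet curvature/torsion of a parametric curve by central finite
# differences at high resolution.
fd_frenet <- function(fx, fy, fz, t, h = 1e-3) {
  ev <- function(tt) cbind(fx(tt), fy(tt), fz(tt))
  d1 <- (ev(t + h) - ev(t - h)) / (2 * h)
  d2 <- (ev(t + h) - 2 * ev(t) + ev(t - h)) / h^2
  d3 <- (ev(t + 2 * h) - 2 * ev(t + h) + 2 * ev(t - h) - ev(t - 2 * h)) /
    (2 * h^3)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  sp <- sqrt(rowSums(d1^2))
  list(kappa = sqrt(rowSums(cr^2)) / sp^3,
       tau = rowSums(cr * d3) / rowSums(cr^2))
}

# Writhe by a plain O(n^2) double loop over polygon segments.
brute_writhe <- function(P) {
  n <- nrow(P) - 1L
  e <- diff(P)
  len <- sqrt(rowSums(e^2))
  tt <- e / len
  mid <- (P[-1, , drop = FALSE] + P[-(n + 1L), , drop = FALSE]) / 2
  tot <- 0
  for (i in 1:(n - 2L)) for (j in (i + 2L):n) {
    r <- mid[i, ] - mid[j, ]
    d3 <- sum(r^2)^1.5
    cx <- c(tt[i, 2] * tt[j, 3] - tt[i, 3] * tt[j, 2],
            tt[i, 3] * tt[j, 1] - tt[i, 1] * tt[j, 3],
            tt[i, 1] * tt[j, 2] - tt[i, 2] * tt[j, 1])
    tot <- tot + sum(cx * r) / d3 * len[i] * len[j]
  }
  2 * tot / (4 * pi)
}

# One-way ANOVA F by projection: SSB/SSW from hat matrices.
proj_anova_oneway <- function(y, g) {
  g <- factor(g)
  X1 <- stats::model.matrix(~g)
  X0 <- matrix(1, length(y), 1)
  P <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  f1 <- P(X1) %*% y
  f0 <- P(X0) %*% y
  ssb <- sum(f1^2) - sum(f0^2)
  ssw <- sum(y^2) - sum(f1^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Sequential (Type I) two-way ANOVA by nested projections, order
# female -> male -> interaction.
proj_anova_seq <- function(y, female, male) {
  female <- factor(female); male <- factor(male)
  Xs <- list(matrix(1, length(y), 1),
             stats::model.matrix(~female),
             stats::model.matrix(~female + male),
             stats::model.matrix(~female * male))
  P <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  fits <- lapply(Xs, function(X) sum((P(X) %*% y)^2))
  ranks <- vapply(Xs, function(X) qr(X)$rank, integer(1))
  sse <- sum(y^2) - fits[[4]]
  dfe <- length(y) - ranks[4]
  ss <- diff(unlist(fits))
  df <- diff(ranks)
  F <- (ss / df) / (sse / dfe)
  data.frame(effect = c("female", "male", "female:male"), F = F,
             df1 = df, df2 = dfe,
             p = stats::pf(F, df, dfe, lower.tail = FALSE))
}

# rotation taking the helix axis (z) onto the egg's long axis (x)
axis_to_x <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))

# shared rasterized fixtures, built once per test run
fixture_env <- new.env()
get_fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

helix_fixture <- function(b = 0.003, seed = 1) {
  get_fixture(paste0("helix_", b, "_", seed), function() {
    spec <- curve_spec("helix", a = 0.01, b = b, turns = 3,
                       rotation = axis_to_x,
                       translation = c(-pi * 3 * b, 0, 0))
    cv <- make_curve(spec, 400)
    ras <- rasterize_scene(scene_spec(egg_semiaxes = c(0.04, 0.02, 0.02),
                                      noise_sd = 0, seed = seed), cv)
    list(cv = cv, ras = ras)
  })
}

fig8_fixture <- function() {
  get_fixture("fig8", function() {
    cv <- make_curve(curve_spec("figure8", lobe = 0.02), 400)
    ras <- rasterize_scene(scene_spec(egg_semiaxes = c(0.03, 0.02, 0.01),
                                      noise_sd = 0, seed = 3), cv)
    list(cv = cv, ras = ras)
  })
}

circle_fixture <- function() {
  get_fixture("circle", function() {
    cv <- make_curve(curve_spec("circle_arc", r = 0.02,
                                angle = 300 * pi / 180), 400)
    ras <- rasterize_scene(scene_spec(egg_semiaxes = c(0.03, 0.03, 0.01),
                                      noise_sd = 0, seed = 1), cv)
    list(cv = cv, ras = ras)
  })
}

max_tangent_turn_deg <- function(poly) {
  tg <- diff(poly)
  tg <- tg / sqrt(rowSums(tg^2))
  max(acos(pmin(1, pmax(-1, rowSums(tg[-1, ] * tg[-nrow(tg), ])))) * 180 / pi)
}
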