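test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, SSW = 4, F = 1.5 on (1, 4) df
  r <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 1.5)
  expect_equal(as.numeric(c(r$df1, r$df2)), c(1, 4))
  expect_equal(r$p, stats::pf(1.5, 1, 4, lower.tail = FALSE))
})

test_that("degenerate inputs are flagged, not silently misreported", {
  r0 <- anova_oneway(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_true(r0$degenerate)
  expect_equal(r0$F, 0)

  r1 <- anova_oneway(rep(c(1, 2), each = 4), rep(c("a", "b"), each = 4))
  expect_true(r1$degenerate)
  expect_true(is.infinite(r1$F))
  expect_lte(r1$p, .Machine$double.xmin)

  expect_error(anova_oneway(1:4, rep("a", 4)), "2 groups")
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "2 observations")
})

test_that("one-way F matches the projection oracle on 50 random datasets", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    n <- sample(3:8, k, replace = TRUE)
    g <- rep(letters[1:k], times = n)
    y <- rnorm(sum(n), mean = rep(rnorm(k, sd = 0.5), times = n))
    got <- anova_oneway(y, g)
    want <- proj_anova_oneway(y, g)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("one-way F is invariant to shift and positive rescaling", {
  set.seed(22)
  y <- rnorm(20); g <- rep(c("a", "b", "c", "d"), each = 5)
  f0 <- anova_oneway(y, g)$F
  expect_equal(anova_oneway(y + 100, g)$F, f0, tolerance = 1e-10)
  expect_equal(anova_oneway(y * 3.5, g)$F, f0, tolerance = 1e-10)
})

test_that("two-way sequential ANOVA: balanced closed form and oracle", {
  # balanced additive construction, no noise: interaction F ~ 0
  f <- rep(c("P", "Q"), each = 8)
  m <- rep(rep(c("P", "Q"), each = 4), 2)
  y_add <- 2 + (f == "Q") * 1.5 + (m == "Q") * 0.7 +
    rep(c(-.1, .1), 8)   # symmetric residual, identical in every cell
  r <- anova_twoway(y_add, f, m)
  expect_lt(r$F[r$effect == "female:male"], 1e-20)

  # balanced case: closed-form SS from cell means
  set.seed(23)
  y <- rnorm(16)
  r <- anova_twoway(y, f, m)
  gm <- mean(y)
  mf <- tapply(y, f, mean); mm <- tapply(y, m, mean)
  cell <- tapply(y, paste(f, m), mean)
  ssf <- 8 * sum((mf - gm)^2)
  ssm <- 8 * sum((mm - gm)^2)
  ssc <- 4 * sum((cell - gm)^2)
  ssi <- ssc - ssf - ssm
  sse <- sum((y - ave(y, paste(f, m)))^2)
  expect_equal(r$F, c(ssf, ssm, ssi) / (sse / 12), tolerance = 1e-8)

  # unbalanced random data vs the sequential projection oracle
  set.seed(24)
  for (i in 1:50) {
    n <- sample(2:6, 4, replace = TRUE)
    f <- rep(rep(c("P", "Q"), each = 2), times = n)
    m <- rep(c("P", "Q", "P", "Q"), times = n)
    y <- rnorm(sum(n))
    got <- anova_twoway(y, f, m)
    want <- proj_anova_seq(y, f, m)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    # sequential SS sum exactly to the total model SS
    expect_identical(got$effect, c("female", "male", "female:male"))
  }
})

test_that("an empty design cell is an error naming the cell", {
  f <- c("P", "P", "P", "P", "Q", "Q", "Q")
  m <- c("P", "P", "Q", "Q", "P", "P", "P")
  expect_error(anova_twoway(rnorm(7), f, m), "female=Q, male=Q")
  expect_error(anova_twoway(rnorm(4), c("P", "P", "Q", "Q"), rep("P", 4)),
               "two observed levels")
})

test_that("Tukey HSD matches stats::TukeyHSD and its quantile inversion", {
  set.seed(25)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    n <- sample(4:9, k, replace = TRUE)
    g <- rep(letters[1:k], times = n)
    y <- rnorm(sum(n), rep(rnorm(k), times = n))
    got <- tukey_hsd(y, g)
    ref <- stats::TukeyHSD(stats::aov(y ~ factor(g)))$`factor(g)`
    expect_equal(got$diff, unname(ref[, "diff"]), tolerance = 1e-10)
    expect_equal(got$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
    expect_equal(got$lwr, unname(ref[, "lwr"]), tolerance = 1e-10)
    # studentized-range quantile inversion: q(1 - p_adj) == |diff| / SE
    # (skipped near p = 1 where the inversion is ill-conditioned)
    df <- sum(n) - k
    ok <- got$p_adj > 1e-8 & got$p_adj < 0.99
    expect_equal(stats::qtukey(1 - got$p_adj[ok], k, df),
                 abs(got$diff[ok]) / got$se[ok], tolerance = 1e-6)
  }
})

test_that("Tukey HSD handles identical groups and pair-order symmetry", {
  y <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  r <- tukey_hsd(y, g)
  expect_equal(r$diff, 0)
  expect_equal(r$p_adj, 1)
  # swapping labels flips the sign of the difference, not the p value
  r2 <- tukey_hsd(y, rep(c("b", "a"), each = 3))
  expect_equal(r2$diff, -r$diff)
  expect_equal(r2$p_adj, r$p_adj)
  expect_error(tukey_hsd(1:5, rep("a", 5)), "2 groups")
})

test_that("the full design run finds an injected effect and skips missing cells", {
  # stage effect on pitch -> total curvature row significant
  des <- data.frame(female = "Pse", male = "Pse",
                    stage = c("PN", "2N", "4N", "8N"), n = 12)
  model <- effect_model(shift_fn = function(female, male, stage)
    list(a = 1, b = c(PN = 1, `2N` = 1, `4N` = 0.85, `8N` = 0.6)[[stage]]))
  ex <- generate_experiment(des, model = model, seed = 31)
  res <- run_paper_design(build_table(ex$records))
  w <- res$within_species
  expect_lt(w$p[w$descriptor == "total_curvature"], 0.05)
  expect_true("within.Pse.total_curvature" %in% names(res$tukey))

  # missing cells (species observed at one stage only) are skipped, not imputed
  des2 <- rbind(des, data.frame(female = "Bog", male = "Bog", stage = "PN",
                                n = 10))
  ex2 <- generate_experiment(des2, seed = 32)
  res2 <- run_paper_design(build_table(ex2$records))
  expect_false("Bog" %in% res2$within_species$species)
  expect_true(any(res2$skipped$unit == "Bog"))
})

test_that("the two-way family runs on a parental + reciprocal-hybrid cohort", {
  des <- expand.grid(female = c("Pse", "Per"), male = c("Pse", "Per"),
                     stage = "4N", stringsAsFactors = FALSE)
  des$n <- 8
  ex <- generate_experiment(des, seed = 33)
  res <- run_paper_design(build_table(ex$records))
  hyb <- res$parental_hybrid
  expect_setequal(unique(hyb$effect), c("female", "male", "female:male"))
  expect_equal(nrow(hyb), 5 * 3)   # five shape descriptors x three effects
})
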