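#' One-way ANOVA
#'
#' Classical between/within decomposition via [stats::aov()]:
#' `F = MS_between / MS_within`, p from the F distribution. When every group
#' mean is identical the statistic is 0; when the within-group variance is
#' zero but means differ, F is infinite and the result carries a
#' `degenerate` flag with p reported below machine minimum.
#'
#' @param values numeric response.
#' @param group grouping factor (>= 2 levels, each with >= 2 observations).
#' @return data frame with `effect`, `F`, `df1`, `df2`, `p`, `degenerate`.
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 observations")
  df1 <- nlevels(group) - 1L
  df2 <- length(values) - nlevels(group)
  tot_ss <- sum((values - mean(values))^2)
  within_ss <- sum(unlist(tapply(values, group,
                                 function(v) (v - mean(v))^2)))
  if (tot_ss <= 1e-300) {                      # all values identical
    return(data.frame(effect = "group", F = 0, df1 = df1, df2 = df2, p = 1,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  if (within_ss <= 1e-12 * tot_ss) {           # zero within-group variance
    return(data.frame(effect = "group", F = Inf, df1 = df1, df2 = df2,
                      p = .Machine$double.xmin, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  s <- summary(stats::aov(values ~ group))[[1]]
  data.frame(effect = "group", F = s[1, "F value"], df1 = s[1, "Df"],
             df2 = s[2, "Df"], p = s[1, "Pr(>F)"], degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA with sequential sums of squares
#'
#' Fixed-effect 2x2 (or larger) factorial ANOVA with sequential (Type I)
#' sums of squares in the fixed order female origin, male origin, their
#' interaction — the order in which the hybrid-cross comparisons are
#' reported. Each effect is tested against the residual mean square. On
#' unbalanced data the sequential decomposition depends on this order, which
#' is why it is fixed rather than configurable by accident; pass
#' `order = c("male", "female")` to reverse it deliberately.
#'
#' @param values numeric response.
#' @param female,male factor labels (species of origin of egg and sperm).
#' @param order which main effect enters the model first.
#' @return data frame with one row per effect (`female`, `male`,
#'   `female:male`): `F`, `df1`, `df2`, `p`.
#' @export
anova_twoway <- function(values, female, male,
                         order = c("female", "male")) {
  female <- factor(female); male <- factor(male)
  keep <- is.finite(values)
  values <- values[keep]
  female <- droplevels(female[keep]); male <- droplevels(male[keep])
  if (nlevels(female) < 2L || nlevels(male) < 2L)
    stop("two-way ANOVA needs at least two observed levels of each factor")
  cells <- table(female, male)
  if (any(cells == 0L)) {
    i <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: female=%s, male=%s",
                 rownames(cells)[i[1]], colnames(cells)[i[2]]))
  }
  if (any(cells < 2L)) stop("every design cell needs >= 2 observations")
  order <- match.arg(order)
  df <- data.frame(values = values, female = female, male = male)
  form <- if (order == "female") values ~ female + male + female:male
  else values ~ male + female + male:female
  a <- stats::anova(stats::lm(form, data = df))
  eff <- rownames(a)
  res <- a["Residuals", ]
  out <- data.frame(effect = sub("male:female", "female:male",
                                 gsub("^\\s+|\\s+$", "", eff[eff != "Residuals"])),
                    F = a$`F value`[eff != "Residuals"],
                    df1 = a$Df[eff != "Residuals"],
                    df2 = res$Df,
                    p = a$`Pr(>F)`[eff != "Residuals"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey's Honest Significant Difference test
#'
#' All pairwise group comparisons after an ANOVA, controlling the
#' family-wise error rate via the studentized range distribution. For
#' unequal group sizes the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))` is used.
#'
#' @param values numeric response.
#' @param group grouping factor.
#' @param conf_level confidence level of the interval bounds.
#' @return data frame with one row per unordered pair: `pair`, `diff`
#'   (first minus second level), `se`, `p_adj`, `lwr`, `upr`.
#' @export
tukey_hsd <- function(values, group, conf_level = 0.95) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups")
  n <- tapply(values, group, length)
  m <- tapply(values, group, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(levels(group), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    g2 <- pairs[1, j]; g1 <- pairs[2, j]   # "later-earlier", as TukeyHSD
    d <- m[[g1]] - m[[g2]]
    se <- sqrt(mse / 2 * (1 / n[[g1]] + 1 / n[[g2]]))
    q <- if (se > 0) abs(d) / se else Inf
    p <- if (is.finite(q)) stats::ptukey(q, k, df, lower.tail = FALSE)
    else if (d == 0) 1 else 0
    hw <- stats::qtukey(conf_level, k, df) * se
    data.frame(pair = paste(g1, g2, sep = "-"), diff = d, se = se,
               p_adj = min(1, p), lwr = d - hw, upr = d + hw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full comparative analysis over a cohort table
#'
#' The three analysis families applied to whichever cells of the cohort
#' table support them:
#'
#' 1. *Within species across development*: for each conspecific cross
#'    observed at >= 2 stages, a one-way ANOVA per descriptor across stages.
#' 2. *Between species per stage*: for each stage with >= 2 conspecific
#'    crosses, a one-way ANOVA per descriptor across species.
#' 3. *Parental vs reciprocal hybrids*: for each unordered species pair with
#'    all four crosses present at a stage, a sequential two-way ANOVA
#'    (female origin, male origin, interaction) per descriptor.
#'
#' Positional descriptors (sperm positioning, pronuclei distance) are
#' analysed only at the PN stage; the five shape descriptors at every stage.
#' Cells that cannot be analysed (missing data, single group, empty design
#' cell) are skipped and listed in `skipped`, never imputed. Tukey HSD post
#' hoc tables are produced for one-way rows significant at `alpha`.
#'
#' @param table a cohort table from [build_table()].
#' @param alpha significance level gating the post hoc tests.
#' @return list with data frames `within_species`, `between_species`,
#'   `parental_hybrid`, a list `tukey`, and a data frame `skipped`.
#' @export
run_paper_design <- function(table, alpha = 0.05) {
  shape_desc <- c("arc_length", "net_length", "aspect_ratio",
                  "average_curvature", "total_curvature")
  pn_desc <- c("pronuclei_distance", "sperm_positioning")
  skipped <- list(); tukey <- list()
  note_skip <- function(family, unit, desc, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      family = family, unit = unit, descriptor = desc, reason = reason,
      stringsAsFactors = FALSE)
  }

  consp <- table[table$female_species == table$male_species, , drop = FALSE]

  within <- list()
  for (spp in unique(consp$female_species)) {
    sub <- consp[consp$female_species == spp, ]
    ok_stage <- names(which(table(sub$stage) >= 2))
    sub <- sub[sub$stage %in% ok_stage, ]
    if (length(unique(sub$stage)) < 2) {
      note_skip("within_species", spp, "*", "fewer than 2 stages")
      next
    }
    for (d in shape_desc) {
      res <- try(anova_oneway(sub[[d]], sub$stage), silent = TRUE)
      if (inherits(res, "try-error")) {
        note_skip("within_species", spp, d, conditionMessage(attr(res, "condition")))
        next
      }
      within[[paste(spp, d)]] <- cbind(species = spp, descriptor = d, res)
      if (is.finite(res$p) && res$p < alpha)
        tukey[[paste("within", spp, d, sep = ".")]] <-
          tukey_hsd(sub[[d]], sub$stage)
    }
  }

  between <- list()
  for (stg in unique(consp$stage)) {
    sub <- consp[consp$stage == stg, ]
    ok_sp <- names(which(table(sub$female_species) >= 2))
    sub <- sub[sub$female_species %in% ok_sp, ]
    if (length(unique(sub$female_species)) < 2) {
      note_skip("between_species", stg, "*", "fewer than 2 species")
      next
    }
    descs <- if (stg == "PN") c(pn_desc, shape_desc) else shape_desc
    for (d in descs) {
      v <- sub[[d]]
      if (all(is.na(v))) { note_skip("between_species", stg, d, "no data"); next }
      res <- try(anova_oneway(v, sub$female_species), silent = TRUE)
      if (inherits(res, "try-error")) {
        note_skip("between_species", stg, d, conditionMessage(attr(res, "condition")))
        next
      }
      between[[paste(stg, d)]] <- cbind(stage = stg, descriptor = d, res)
      if (is.finite(res$p) && res$p < alpha)
        tukey[[paste("between", stg, d, sep = ".")]] <-
          tukey_hsd(v, sub$female_species)
    }
  }

  species <- unique(c(table$female_species, table$male_species))
  hyb <- list()
  if (length(species) >= 2) {
    prs <- utils::combn(sort(species), 2)
    for (j in seq_len(ncol(prs))) {
      s1 <- prs[1, j]; s2 <- prs[2, j]
      sub <- table[table$female_species %in% c(s1, s2) &
                     table$male_species %in% c(s1, s2), ]
      for (stg in unique(sub$stage)) {
        ss <- sub[sub$stage == stg, ]
        descs <- if (stg == "PN") c(pn_desc, shape_desc) else shape_desc
        for (d in descs) {
          v <- ss[[d]]
          ok <- is.finite(v)
          if (sum(ok) == 0) { next }
          res <- try(anova_twoway(v[ok], ss$female_species[ok],
                                  ss$male_species[ok]), silent = TRUE)
          if (inherits(res, "try-error")) {
            note_skip("parental_hybrid", paste(s1, s2, stg), d,
                      conditionMessage(attr(res, "condition")))
            next
          }
          hyb[[paste(s1, s2, stg, d)]] <-
            cbind(pair = paste(s1, s2, sep = "-"), stage = stg,
                  descriptor = d, res)
        }
      }
    }
  }

  bindrows <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else data.frame()
  list(within_species = bindrows(within), between_species = bindrows(between),
       parental_hybrid = bindrows(hyb), tukey = tukey,
       skipped = bindrows(skipped))
}
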