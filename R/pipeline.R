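#' Sperm positioning within the egg
#'
#' Mean Euclidean distance from the polar-body centre to the points along
#' the flagellum. With the polyline resampled uniformly in arc length the
#' plain mean is an arc-length-weighted average over the whole sperm, so the
#' value reads as "how far from the polar bodies the sperm lies" in mm.
#' Measurable only at the pronuclear stage, before the polar bodies
#' disintegrate.
#'
#' @param polyline uniformly resampled `(x, y, z)` point matrix (mm).
#' @param polar_body_center `(x, y, z)` centre in mm.
#' @return mean distance in mm.
#' @export
sperm_positioning <- function(polyline, polar_body_center) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 3L, length(polar_body_center) == 3L)
  mean(sqrt(rowSums(sweep(polyline, 2, as.numeric(polar_body_center))^2)))
}

#' Distance between the male and female pronuclei
#'
#' Three-dimensional Euclidean distance between the two pronuclear centres.
#' Measurable only at the pronuclear stage, before karyogamy fuses them.
#'
#' @param male_center,female_center `(x, y, z)` centres in mm.
#' @return distance in mm.
#' @export
pronuclei_distance <- function(male_center, female_center) {
  sqrt(sum((as.numeric(male_center) - as.numeric(female_center))^2))
}

#' Measure one egg: masks to descriptor record
#'
#' Runs the per-egg measurement chain: trace the flagellum centerline,
#' compute the curve descriptors, locate the landmark centres, and add the
#' positional descriptors where the developmental stage allows. At the
#' pronuclear (PN) stage all seven parameters are measured (sperm
#' positioning, pronuclei distance, arc length, net length, aspect ratio,
#' average curvature, total curvature); after karyogamy (2N-8N) the
#' pronuclei have fused and the polar bodies disintegrated, so only the five
#' shape descriptors are recorded and the positional fields stay empty.
#'
#' @param grid a [voxel_grid()].
#' @param masks named list of `voxel_mask` objects; must contain
#'   `flagellum`, and at PN stage may contain `male_pronucleus`,
#'   `female_pronucleus`, `polar_bodies`.
#' @param annotation list or one-row data frame with `egg_id`,
#'   `female_species`, `male_species` (female listed first by convention)
#'   and `stage` (`PN`, `2N`, `4N` or `8N`).
#' @param params a [trace_params()].
#' @param smoothing passed to [curve_descriptors()].
#' @return one-row data frame with the full record schema (see
#'   [write_records()]); `NULL` with a warning if the flagellum mask is
#'   missing.
#' @export
measure_egg <- function(grid, masks, annotation,
                        params = trace_params(grid$spacing),
                        smoothing = 0.4) {
  stage <- match.arg(as.character(annotation$stage),
                     c("PN", "2N", "4N", "8N"))
  if (is.null(masks$flagellum)) {
    warning("egg ", annotation$egg_id, " skipped: no flagellum mask")
    return(NULL)
  }
  poly <- trace_centerline(masks$flagellum, grid, params)
  desc <- curve_descriptors(poly, smoothing = smoothing)
  flags <- character(0)

  sp_pos <- NA_real_; pn_dist <- NA_real_; avg_tau <- NA_real_; wr <- NA_real_
  if (stage == "PN") {
    avg_tau <- desc$average_torsion
    wr <- desc$writhe
    if (!is.null(masks$polar_bodies)) {
      pb <- compute_center(masks$polar_bodies)$mm
      sp_pos <- sperm_positioning(poly, pb)
    } else flags <- c(flags, "no_polar_bodies_mask")
    if (!is.null(masks$male_pronucleus) && !is.null(masks$female_pronucleus)) {
      pn_dist <- pronuclei_distance(compute_center(masks$male_pronucleus)$mm,
                                    compute_center(masks$female_pronucleus)$mm)
    } else flags <- c(flags, "missing_pronucleus_mask")
  }
  data.frame(
    egg_id = as.character(annotation$egg_id),
    female_species = as.character(annotation$female_species),
    male_species = as.character(annotation$male_species),
    stage = stage,
    sperm_positioning = sp_pos, pronuclei_distance = pn_dist,
    arc_length = desc$arc_length, net_length = desc$net_length,
    aspect_ratio = desc$aspect_ratio,
    average_curvature = desc$average_curvature,
    total_curvature = desc$total_curvature,
    average_torsion = avg_tau, writhe = wr,
    qc_trace_points = nrow(poly),
    qc_flagellum_voxels = nrow(masks$flagellum$sites),
    qc_flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Assemble the cohort analysis table
#'
#' Long-format table keyed by cross (female species listed first) and stage,
#' with one row per egg. Positional descriptors never appear outside the PN
#' stage (they are forced to `NA` if present), and duplicate egg ids are an
#' error.
#'
#' @param records list of per-egg records (from [measure_egg()] or the
#'   generator) or a single data frame.
#' @return data frame with a `cross` column prepended, plus an attribute
#'   `group_sizes`: the egg count per (cross, stage) cell, the shape of the
#'   experimental design.
#' @export
build_table <- function(records) {
  if (is.data.frame(records)) tab <- records
  else tab <- do.call(rbind, records)
  if (is.null(tab) || nrow(tab) == 0L) {
    out <- data.frame(cross = character(0))
    attr(out, "group_sizes") <- data.frame()
    return(out)
  }
  if (anyDuplicated(tab$egg_id))
    stop("duplicated egg_id: ", tab$egg_id[duplicated(tab$egg_id)][1])
  not_pn <- tab$stage != "PN"
  tab$sperm_positioning[not_pn] <- NA_real_
  tab$pronuclei_distance[not_pn] <- NA_real_
  tab <- cbind(cross = paste(tab$female_species, tab$male_species, sep = ":"),
               tab)
  sizes <- as.data.frame(table(cross = tab$cross, stage = tab$stage),
                         stringsAsFactors = FALSE)
  sizes <- sizes[sizes$Freq > 0, ]
  names(sizes)[3] <- "n"
  rownames(sizes) <- NULL
  attr(tab, "group_sizes") <- sizes
  tab
}
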