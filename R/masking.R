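#' Seeded threshold masking ("paint with threshold")
#'
#' Selects the voxels of a single structure: all voxels whose intensity lies
#' in `[lo, hi]` and that are connected (26-connectivity by default) to at
#' least one seed voxel. Disconnected in-range voxels — other structures or
#' background speckle that happen to share the intensity range — are ignored,
#' mirroring how an operator paints only the target structure.
#'
#' @param grid a [voxel_grid()].
#' @param seeds integer matrix of seed sites, one row per seed, columns
#'   `(z, y, x)` (1-based). Every seed must be in bounds and in range.
#' @param range numeric `c(lo, hi)` intensity window, `lo <= hi`.
#' @param label structure label, one of `"flagellum"`, `"male_pronucleus"`,
#'   `"female_pronucleus"`, `"polar_bodies"`, `"nucleus"`.
#' @param connectivity 6, 18 or 26 (neighbours sharing a face, an edge, or
#'   any vertex). Default 26, the permissive choice matching interactive
#'   painting behaviour.
#' @return a `voxel_mask`: list with `sites` (n x 3 integer matrix, `(z,y,x)`),
#'   `dim`, `spacing`, `label`.
#' @export
paint_threshold <- function(grid, seeds, range, label = "flagellum",
                            connectivity = 26L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(seeds))) seeds <- matrix(as.integer(seeds), nrow = 1L)
  storage.mode(seeds) <- "integer"
  d <- dim(grid$data)
  if (length(range) != 2L || range[1] > range[2])
    stop("`range` must be c(lo, hi) with lo <= hi")
  if (any(seeds < 1L) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seed out of grid bounds")
  sval <- grid$data[seeds]
  bad <- which(sval < range[1] | sval > range[2])
  if (length(bad) > 0)
    stop(sprintf("seed (%d,%d,%d) has intensity %g outside [%g, %g]",
                 seeds[bad[1], 1], seeds[bad[1], 2], seeds[bad[1], 3],
                 sval[bad[1]], range[1], range[2]))

  inrange <- grid$data >= range[1] & grid$data <= range[2]
  # pad with one FALSE layer so linear-index neighbour offsets never wrap
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- inrange
  offs <- connectivity_offsets(connectivity)
  lin_offs <- offs[, 1] + dp[1] * (offs[, 2] + dp[2] * offs[, 3])

  seed_lin <- (seeds[, 1] + 1L) +
    dp[1] * ((seeds[, 2] + 1L) - 1L + dp[2] * ((seeds[, 3] + 1L) - 1L))
  visited <- array(FALSE, dp)
  visited[seed_lin] <- TRUE
  frontier <- unique(seed_lin)
  while (length(frontier) > 0) {
    cand <- unique(as.vector(outer(frontier, lin_offs, `+`)))
    cand <- cand[padded[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  sel <- which(visited & padded)
  iz <- ((sel - 1L) %% dp[1]) + 1L
  iy <- (((sel - 1L) %/% dp[1]) %% dp[2]) + 1L
  ix <- ((sel - 1L) %/% (dp[1] * dp[2])) + 1L
  sites <- cbind(z = iz - 1L, y = iy - 1L, x = ix - 1L)
  structure(list(sites = sites, dim = d, spacing = grid$spacing, label = label),
            class = "voxel_mask")
}

#' @keywords internal
connectivity_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  nn <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nn == 1, "18" = nn <= 2, "26" = nn <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask '%s': %d sites in a %d x %d x %d grid\n",
              x$label, nrow(x$sites), x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

#' Physical volume of a mask
#'
#' @param mask a `voxel_mask`.
#' @return volume in mm^3: site count times the voxel volume.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (nrow(mask$sites) == 0L) stop("mask is empty")
  nrow(mask$sites) * prod(mask$spacing)
}

#' Build a mask directly from sites (no painting)
#'
#' Used by the synthetic generator to emit ground-truth masks, and handy in
#' tests.
#' @param sites integer `(z, y, x)` site matrix.
#' @param grid the [voxel_grid()] the sites index into.
#' @param label structure label.
#' @return a `voxel_mask`.
#' @export
mask_from_sites <- function(sites, grid, label = "flagellum") {
  if (is.null(dim(sites))) sites <- matrix(as.integer(sites), nrow = 1L)
  storage.mode(sites) <- "integer"
  d <- dim(grid$data)
  if (any(sites < 1L) || any(sites[, 1] > d[1]) || any(sites[, 2] > d[2]) ||
      any(sites[, 3] > d[3]))
    stop("site out of grid bounds")
  structure(list(sites = sites, dim = d, spacing = grid$spacing, label = label),
            class = "voxel_mask")
}

#' Write a mask as an 8-bit label TIFF for visual inspection
#'
#' Background 0, structure 255.
#' @param mask a `voxel_mask`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  arr <- array(0, mask$dim)
  arr[mask$sites] <- 255
  pages <- lapply(seq_len(mask$dim[1]), function(i) {
    p <- arr[i, , , drop = TRUE] / 255
    if (is.null(dim(p))) dim(p) <- mask$dim[2:3]
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
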