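#' Construct a voxel grid
#'
#' A `voxel_grid` is a 3D scalar intensity lattice together with its physical
#' per-axis spacing. The array is stored in `(slice, row, column)` order, i.e.
#' `(z, y, x)`; all physical coordinates produced by the package are `(x, y, z)`
#' in millimetres. Voxel centres sit at `(index - 0.5) * spacing` on each axis
#' (half-voxel convention), so the first slice is centred half a z-step into
#' the volume.
#'
#' @param data numeric 3D array, indexed `[z, y, x]`. All values must be
#'   finite.
#' @param spacing numeric length-3 vector, physical voxel spacing in mm for
#'   the `(z, y, x)` axes. Strictly positive. The canonical confocal z-step
#'   used throughout is 0.002 mm.
#' @param origin numeric length-3 `(x, y, z)` offset in mm added to all
#'   physical coordinates. Default zero.
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(3, 4, 4)), spacing = c(0.002, 5e-4, 5e-4))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [z, y, x]")
  if (length(data) == 0L) stop("`data` must be non-empty")
  if (!all(is.finite(data))) stop("grid intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (z, y, x) in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (x, y, z) in mm")
  structure(
    list(data = data, spacing = setNames(spacing, c("z", "y", "x")),
         origin = setNames(origin, c("x", "y", "z"))),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_grid: %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (z,y,x) mm: %g %g %g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Convert lattice indices to physical coordinates
#'
#' Maps 1-based `(z, y, x)` voxel indices to `(x, y, z)` positions in mm using
#' the half-voxel convention: the centre of voxel `i` lies at
#' `(i - 0.5) * spacing` plus the grid origin.
#'
#' @param sites integer matrix with one row per site and columns `(z, y, x)`,
#'   or a single length-3 index vector.
#' @param grid a [voxel_grid()] (or any list with `spacing`/`origin` fields).
#' @return numeric matrix, one row per site, columns `(x, y, z)` in mm.
#' @export
index_to_mm <- function(sites, grid) {
  if (is.null(dim(sites))) sites <- matrix(sites, nrow = 1L)
  sp <- grid$spacing
  or <- if (is.null(grid$origin)) c(0, 0, 0) else grid$origin
  cbind(x = (sites[, 3L] - 0.5) * sp[["x"]] + or[[1L]],
        y = (sites[, 2L] - 0.5) * sp[["y"]] + or[[2L]],
        z = (sites[, 1L] - 0.5) * sp[["z"]] + or[[3L]])
}

#' Convert physical coordinates to nearest lattice indices
#'
#' Inverse of [index_to_mm()]; rounds to the nearest voxel centre. Points are
#' not clamped to the grid bounds.
#'
#' @param points numeric matrix `(x, y, z)` in mm (or a length-3 vector).
#' @param grid a [voxel_grid()].
#' @return integer matrix with columns `(z, y, x)`.
#' @export
mm_to_index <- function(points, grid) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  sp <- grid$spacing
  or <- if (is.null(grid$origin)) c(0, 0, 0) else grid$origin
  cbind(z = as.integer(round((points[, 3L] - or[[3L]]) / sp[["z"]] + 0.5)),
        y = as.integer(round((points[, 2L] - or[[2L]]) / sp[["y"]] + 0.5)),
        x = as.integer(round((points[, 1L] - or[[1L]]) / sp[["x"]] + 0.5)))
}
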