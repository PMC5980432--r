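#' Centre of a masked structure
#'
#' The single central position of a pronucleus or polar-body mask is the
#' simple arithmetic mean of the masked sites' coordinates, taken
#' component-wise. Two centres are returned:
#'
#' * `index`: the mean of the raw integer `(z, y, x)` indices, matching the
#'   convention in which two voxels at \[3,9,7\] and \[5,3,7\] have their
#'   centre at \[4,6,7\]. No half-voxel shift is applied here.
#' * `mm`: the mean of the voxel-centre physical positions `(x, y, z)` in mm
#'   (half-voxel convention via [index_to_mm()]). This is what all downstream
#'   distance computations use.
#'
#' @param mask a non-empty `voxel_mask`.
#' @return list with `index` (named `(z, y, x)`), `mm` (named `(x, y, z)`),
#'   `n_sites`, and `label`.
#' @export
compute_center <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (nrow(mask$sites) == 0L) stop("cannot take the centre of an empty mask")
  idx <- colMeans(mask$sites)
  mm <- colMeans(index_to_mm(mask$sites, mask))
  list(index = setNames(idx, c("z", "y", "x")),
       mm = setNames(mm, c("x", "y", "z")),
       n_sites = nrow(mask$sites), label = mask$label)
}

#' Locate all landmark centres of an egg
#'
#' @param masks named list of `voxel_mask` objects (names are the structure
#'   labels, e.g. `male_pronucleus`, `female_pronucleus`, `polar_bodies`).
#' @return named list of [compute_center()] results.
#' @export
locate_landmarks <- function(masks) {
  lapply(masks, compute_center)
}
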