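#' Read an image stack from disk
#'
#' Reads either a multi-page grayscale TIFF (one page per z slice) or a
#' directory of equally shaped single-page 2D TIFFs taken in lexicographic
#' slice order. Pixel values are preserved exactly (integer TIFFs are read
#' as stored integers, not rescaled).
#'
#' Physical spacing is mandatory: it is taken from the `spacing` argument or,
#' if that is `NULL`, from a JSON sidecar `<path>.json` (for a multi-page
#' file) or `<dir>/spacing.json` (for a directory), which must contain
#' `{"spacing_mm": [z, y, x]}`. There is no silent default of 1.
#'
#' @param path multi-page TIFF file or directory of 2D TIFF slices.
#' @param spacing optional `(z, y, x)` spacing in mm; overrides any sidecar.
#' @return a [voxel_grid()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, spacing = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in directory: ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    sidecar <- file.path(path, "spacing.json")
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar <- paste0(path, ".json")
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("ragged slice shapes: all slices must share the same 2D dimensions")
  if (is.null(spacing)) {
    if (!file.exists(sidecar))
      stop("spacing not given and no sidecar found at ", sidecar,
           "; physical spacing is required (never defaulted)")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$spacing_mm))
      stop("sidecar ", sidecar, " lacks a `spacing_mm` field")
    spacing <- as.numeric(meta$spacing_mm)
  }
  arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  voxel_grid(arr, spacing)
}

#' Write an image stack to disk
#'
#' Writes a [voxel_grid()] as a 16-bit multi-page grayscale TIFF plus a JSON
#' sidecar `<path>.json` holding `{"spacing_mm": [z, y, x]}`. Intensities
#' outside `[0, 65535]` are clamped with a warning; fractional values are
#' rounded so that integer grids round-trip losslessly.
#'
#' @param grid a [voxel_grid()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- round(grid$data)
  if (any(arr < 0) || any(arr > 65535)) {
    warning("intensities clamped to the 16-bit range [0, 65535]")
    arr[arr < 0] <- 0
    arr[arr > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(i) arr[i, , , drop = TRUE] / 65535)
  pages <- lapply(pages, function(p) {
    if (is.null(dim(p))) dim(p) <- dim(arr)[2:3]
    p
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(spacing_mm = unname(grid$spacing)),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Columns of the per-egg record table, in stable output order
#' @keywords internal
record_columns <- function() {
  c("egg_id", "female_species", "male_species", "stage",
    "sperm_positioning", "pronuclei_distance",
    "arc_length", "net_length", "aspect_ratio",
    "average_curvature", "total_curvature",
    "average_torsion", "writhe",
    "qc_trace_points", "qc_flagellum_voxels", "qc_flags")
}

#' Write egg records to CSV
#'
#' One row per egg, fixed column order. Descriptors that are not measurable
#' at a record's developmental stage (the positional descriptors exist only
#' at the pronuclear stage, before karyogamy) are written as empty cells.
#'
#' @param records a data frame of egg records (see [measure_egg()]), possibly
#'   with zero rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- record_columns()
  if (nrow(records) > 0) {
    missing_cols <- setdiff(cols, names(records))
    for (mc in missing_cols) records[[mc]] <- NA
    records <- records[, cols, drop = FALSE]
  } else {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
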