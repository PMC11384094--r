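#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (axis order CZYX). Intensities are stored
#' as 16-bit samples scaled by `intensity_scale`; the scale, voxel calibration
#' and channel names go to a JSON sidecar (`<path>.json`) so that
#' [read_stack_tiff()] restores a calibrated stack. Ground-truth tables, when
#' present, are written next to the TIFF as CSV.
#'
#' @param stack A `fish_stack` (see [render_scene()]).
#' @param path Output TIFF path.
#' @param intensity_scale Photons represented by the full 16-bit range;
#'   defaults to the next power of two above the stack maximum.
#' @param write_truth Also write `<path>_spots.csv` / `<path>_nuclei.csv`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, intensity_scale = NULL,
                             write_truth = TRUE) {
  stopifnot(inherits(stack, "fish_stack"))
  mx <- max(vapply(stack$channels, max, numeric(1)), 1)
  if (is.null(intensity_scale)) intensity_scale <- 2^ceiling(log2(mx * 1.01))
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (iz in seq_len(dim(a)[1])) {
      pages[[length(pages) + 1L]] <-
        pmin(pmax(a[iz, , ] / intensity_scale, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(axes = "CZYX",
                  shape = c(length(stack$channels), stack$grid$shape),
                  channels = names(stack$channels),
                  dxy_nm = stack$grid$dxy, dz_nm = stack$grid$dz,
                  intensity_scale = intensity_scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (write_truth && !is.null(stack$truth)) {
    base <- sub("\\.tiff?$", "", path)
    if (nrow(stack$truth$spots)) {
      utils::write.csv(stack$truth$spots, paste0(base, "_spots.csv"),
                       row.names = FALSE)
    }
    if (nrow(stack$truth$nuclei)) {
      utils::write.csv(stack$truth$nuclei, paste0(base, "_nuclei.csv"),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path with an adjacent `<path>.json` sidecar.
#' @return A `fish_stack` with calibrated intensities (photon scale) and no
#'   truth tables.
#' @export
read_stack_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- as.integer(sidecar$shape)  # (C, Z, Y, X)
  stopifnot(length(pages) == shape[1] * shape[2])
  grid <- voxel_grid(shape[2:4], dxy = sidecar$dxy_nm, dz = sidecar$dz_nm)
  chans <- vector("list", shape[1])
  names(chans) <- sidecar$channels
  k <- 1L
  for (ci in seq_len(shape[1])) {
    a <- array(0, dim = shape[2:4])
    for (iz in seq_len(shape[2])) {
      a[iz, , ] <- pages[[k]] * sidecar$intensity_scale
      k <- k + 1L
    }
    chans[[ci]] <- a
  }
  structure(list(channels = chans, grid = grid, truth = NULL),
            class = "fish_stack")
}
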