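#' Quantify one labeling-density condition image
#'
#' Implements the satellite-blob measurement for one condition: cells are
#' segmented by automatic (Otsu) thresholding of the counterstain z-maximum
#' projection, then a second Otsu threshold on the reference ("binding")
#' channel projection within the cell mask segments the satellite regions.
#' Median intensities of the reference and brightness channels over the
#' satellite pixels are taken per cell, after subtracting the background
#' measured in a user-chosen ROI outside the cells.
#'
#' @param stack A `fish_stack` with channels counterstain, reference,
#'   brightness (in that order).
#' @param bg_roi Background rectangle outside all cells:
#'   `list(y = c(y0, y1), x = c(x0, x1))` in pixels.
#' @param min_area_um2 Minimum nucleus area for segmentation.
#' @return data.frame with one row per retained cell: `cell`, `median_ref`,
#'   `median_bright` (background-subtracted), `n_sat_px`. Cells with an
#'   empty satellite mask are dropped with a message.
#' @export
quantify_density_image <- function(stack, bg_roi, min_area_um2 = 0.5) {
  stopifnot(inherits(stack, "fish_stack"), length(stack$channels) >= 3L)
  grid <- stack$grid
  proj_dapi <- max_project(stack$channels[[1]])
  proj_ref <- max_project(stack$channels[[2]])
  proj_bri <- max_project(stack$channels[[3]])
  lm <- segment_nuclei(proj_dapi, grid, min_area_um2 = min_area_um2)
  yr <- bg_roi$y[1]:bg_roi$y[2]; xr <- bg_roi$x[1]:bg_roi$x[2]
  if (any(lm$labels[yr, xr] > 0L)) {
    stop("background ROI overlaps a segmented cell", call. = FALSE)
  }
  bg_ref <- stats::median(proj_ref[yr, xr])
  bg_bri <- stats::median(proj_bri[yr, xr])
  # second threshold: satellites within the cell mask, from the reference
  # channel
  inmask <- lm$labels > 0L
  if (!any(inmask)) return(data.frame(cell = integer(0),
                                      median_ref = numeric(0),
                                      median_bright = numeric(0),
                                      n_sat_px = integer(0)))
  vals <- proj_ref[inmask]
  vn <- (vals - min(vals)) / max(diff(range(vals)), .Machine$double.eps)
  thr <- EBImage::otsu(matrix(vn, nrow = 1), range = c(0, 1))
  sat <- inmask & (proj_ref - min(vals)) / diff(range(vals)) > thr
  out <- list()
  for (id in lm$table$id) {
    sel <- sat & lm$labels == id
    if (!any(sel)) {
      message("cell ", id, " has no satellite pixels; dropped")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      cell = id, median_ref = stats::median(proj_ref[sel]) - bg_ref,
      median_bright = stats::median(proj_bri[sel]) - bg_bri,
      n_sat_px = sum(sel))
  }
  if (!length(out)) return(data.frame(cell = integer(0),
                                      median_ref = numeric(0),
                                      median_bright = numeric(0),
                                      n_sat_px = integer(0)))
  do.call(rbind, out)
}

#' Quantify a labeling-density series and normalize across conditions
#'
#' Applies [quantify_density_image()] to each condition and normalizes the
#' condition means by convention: the reference (binding) channel to its
#' value at the 100 percent condition, the brightness channel to its value
#' at the 25 percent condition.
#'
#' @param stacks List of `fish_stack`s, one per condition.
#' @param ratios Labeling ratios matching `stacks`.
#' @param bg_roi Background rectangle passed to each image quantification.
#' @param min_area_um2 Minimum nucleus area.
#' @return list with `cells` (per-cell table with a `ratio` column) and
#'   `conditions` (`ratio`, `mean_ref`, `mean_bright`, `ref_norm`,
#'   `bright_norm`, `n_cells`).
#' @export
quantify_density_series <- function(stacks, ratios, bg_roi,
                                    min_area_um2 = 0.5) {
  stopifnot(length(stacks) == length(ratios))
  cells <- list()
  for (i in seq_along(stacks)) {
    tb <- quantify_density_image(stacks[[i]], bg_roi,
                                 min_area_um2 = min_area_um2)
    if (nrow(tb)) tb$ratio <- ratios[i]
    cells[[i]] <- tb
  }
  cells <- do.call(rbind, cells)
  conds <- do.call(rbind, lapply(ratios, function(r) {
    tb <- cells[cells$ratio == r, , drop = FALSE]
    data.frame(ratio = r, mean_ref = mean(tb$median_ref),
               mean_bright = mean(tb$median_bright), n_cells = nrow(tb))
  }))
  if (!any(conds$ratio == 1)) {
    stop("the 100% condition is required to anchor the reference channel",
         call. = FALSE)
  }
  if (!any(conds$ratio == 0.25)) {
    stop("the 25% condition is required to anchor the brightness channel",
         call. = FALSE)
  }
  conds$ref_norm <- conds$mean_ref / conds$mean_ref[conds$ratio == 1]
  conds$bright_norm <-
    conds$mean_bright / conds$mean_bright[conds$ratio == 0.25]
  list(cells = cells, conditions = conds)
}
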