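#' Maximum-intensity z-projection
#'
#' @param x A 3D `(z, y, x)` array, or a `fish_stack` together with a
#'   `channel` name.
#' @param channel Channel name when `x` is a `fish_stack` (default: first,
#'   the counterstain).
#' @return A 2D `(y, x)` matrix of per-pixel maxima over z.
#' @export
max_project <- function(x, channel = NULL) {
  if (inherits(x, "fish_stack")) {
    if (is.null(channel)) channel <- names(x$channels)[1]
    x <- x$channels[[channel]]
    if (is.null(x)) stop("unknown channel '", channel, "'", call. = FALSE)
  }
  if (length(dim(x)) != 3L || any(dim(x) == 0L)) {
    stop("max_project expects a non-empty 3D (z, y, x) array", call. = FALSE)
  }
  if (dim(x)[1] == 1L) return(x[1, , ])
  apply(x, c(2, 3), max)
}

#' Segment nuclei by Otsu thresholding
#'
#' Global Otsu threshold on the counterstain projection, followed by hole
#' filling, connected-component labeling and removal of components below a
#' minimum area. Nuclei touching the image border can be excluded (cells
#' that were not entirely imaged).
#'
#' @param img 2D counterstain image (typically [max_project()] of the DAPI
#'   channel).
#' @param grid A [voxel_grid()] for pixel calibration.
#' @param min_area_um2 Minimum nucleus area in square micrometers.
#' @param exclude_border Drop nuclei whose pixels touch the image border.
#' @return A `nucleus_label_map`: `labels` (integer matrix, 0 = background,
#'   nuclei numbered 1..n), `table` (data.frame `id`, `area_px`, `area_um2`,
#'   `cy`, `cx` centroids in pixels), `source = "projection"`.
#' @export
segment_nuclei <- function(img, grid, min_area_um2 = 0.5,
                           exclude_border = FALSE) {
  stopifnot(is.matrix(img), inherits(grid, "voxel_grid"))
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("constant image: Otsu threshold undefined, no nuclei found",
            call. = FALSE)
    return(empty_label_map(dim(img)))
  }
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  mask <- EBImage::fillHull(norm > thr)
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(round(labels)), nrow = nrow(img))
  min_area_px <- min_area_um2 * 1e6 / grid$dxy^2
  keep <- integer(0)
  for (id in seq_len(max(labels))) {
    px <- which(labels == id, arr.ind = TRUE)
    if (nrow(px) < min_area_px) {
      labels[labels == id] <- 0L
      next
    }
    if (exclude_border &&
        (any(px[, 1] %in% c(1L, nrow(img))) ||
         any(px[, 2] %in% c(1L, ncol(img))))) {
      labels[labels == id] <- 0L
      next
    }
    keep <- c(keep, id)
  }
  if (!length(keep)) return(empty_label_map(dim(img)))
  # relabel to contiguous 1..n
  out <- matrix(0L, nrow(img), ncol(img))
  tab <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    px <- which(labels == keep[i], arr.ind = TRUE)
    out[px] <- i
    tab[[i]] <- data.frame(id = i, area_px = nrow(px),
                           area_um2 = nrow(px) * grid$dxy^2 / 1e6,
                           cy = mean(px[, 1]), cx = mean(px[, 2]))
  }
  structure(list(labels = out, table = do.call(rbind, tab),
                 source = "projection"),
            class = "nucleus_label_map")
}

empty_label_map <- function(dims) {
  structure(list(labels = matrix(0L, dims[1], dims[2]),
                 table = data.frame(id = integer(0), area_px = integer(0),
                                    area_um2 = numeric(0), cy = numeric(0),
                                    cx = numeric(0)),
                 source = "projection"),
            class = "nucleus_label_map")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  cat(sprintf("<nucleus_label_map> %d nuclei (%s)\n", nrow(x$table),
              x$source))
  invisible(x)
}
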