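# voxel-mean of a unit-peak Gaussian along one axis, in voxel units:
# voxel i covers [i-1, i], center mu (fractional index - 0.5 convention
# handled by caller passing mu in edge coordinates)
integ_gauss_1d <- function(n_lo, n_hi, mu, sigma) {
  edges <- (n_lo - 1L):n_hi
  diff(stats::pnorm(edges, mean = mu, sd = sigma)) * sqrt(2 * pi) * sigma
}

#' Fit a 3D Gaussian plus constant background to a spot candidate
#'
#' Least-squares (Levenberg-Marquardt) fit of a voxel-integrated anisotropic
#' Gaussian plus a constant offset in a window around the candidate voxel,
#' initialized from the candidate. The fitted peak height (`amplitude`) is
#' the spot intensity; the subpixel center is reported both in voxel and in
#' physical (nm) coordinates. Fits that do not converge, leave the window, or
#' end with non-positive amplitude are marked `status = "failed"` rather than
#' raising. Windows clipped at the stack border are shrunk with a warning and
#' fail if fewer than 5 voxels per axis remain (for axes whose full extent
#' allows 5). Single-slice stacks are fitted in 2D.
#'
#' @param stack 3D `(z, y, x)` array.
#' @param candidate One-row data.frame or vector with integer `z`, `y`, `x`
#'   (e.g. a [detect_spots_log()] row).
#' @param grid A [voxel_grid()].
#' @param window Odd window sizes `c(z = 5, y = 7, x = 7)` in voxels.
#' @param sigma_start_nm Starting values `c(xy = ..., z = ...)`.
#' @param max_iter,ftol Levenberg-Marquardt iteration cap and relative cost
#'   tolerance.
#' @return One-row data.frame (`spot_fit` row): `z_vox`, `y_vox`, `x_vox`
#'   (subpixel), `z_nm`, `y_nm`, `x_nm`, `amplitude`, `background`,
#'   `sigma_xy_nm`, `sigma_z_nm`, `rss`, `status` ("converged"/"failed"),
#'   `nucleus_id`, `response`.
#' @export
fit_spot_gaussian <- function(stack, candidate, grid,
                              window = c(z = 5L, y = 7L, x = 7L),
                              sigma_start_nm = c(xy = 60, z = 200),
                              max_iter = 200L, ftol = 1e-8) {
  stopifnot(length(dim(stack)) == 3L, inherits(grid, "voxel_grid"))
  cz <- as.integer(candidate[["z"]]); cy <- as.integer(candidate[["y"]])
  cx <- as.integer(candidate[["x"]])
  nid <- if (!is.null(candidate[["nucleus_id"]])) {
    as.integer(candidate[["nucleus_id"]])
  } else NA_integer_
  resp <- if (!is.null(candidate[["response"]])) {
    as.numeric(candidate[["response"]])
  } else NA_real_
  dm <- dim(stack)
  is3d <- dm[1] > 1L
  hw <- as.integer(c(window[["z"]], window[["y"]], window[["x"]])) %/% 2L
  lo <- pmax(c(cz, cy, cx) - hw, 1L)
  hi <- pmin(c(cz, cy, cx) + hw, dm)
  len <- hi - lo + 1L
  full <- pmin(c(window[["z"]], window[["y"]], window[["x"]]), dm)
  if (any(len < full)) {
    warning("fit window clipped at the stack border; shrunk to ",
            paste(len, collapse = "x"), call. = FALSE)
  }
  # an axis that could hold 5 voxels but has fewer after clipping fails
  if (any(len < pmin(5L, dm))) {
    return(failed_fit_row(nid, resp))
  }
  d <- stack[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (diff(range(d)) == 0) return(failed_fit_row(nid, resp))  # flat window

  sxy0 <- sigma_start_nm[["xy"]] / grid$dxy
  sz0 <- if (is3d) sigma_start_nm[["z"]] / grid$dz else 1
  b0 <- min(d)
  a0 <- max(d) - b0
  # centers in edge coordinates relative to the window: voxel i center i-0.5
  p0 <- c(A = a0, z0 = cz - lo[1] + 0.5, y0 = cy - lo[2] + 0.5,
          x0 = cx - lo[3] + 0.5, sxy = sxy0, sz = sz0, b = b0)
  lower <- c(0, 0, 0, 0, 0.3, 0.3, -Inf)
  upper <- c(Inf, len[1], len[2], len[3], max(len[2:3]), max(len[1], 2),
             Inf)
  model <- function(p) {
    uy <- integ_gauss_1d(1L, len[2], p[["y0"]], p[["sxy"]])
    ux <- integ_gauss_1d(1L, len[3], p[["x0"]], p[["sxy"]])
    uz <- if (is3d) integ_gauss_1d(1L, len[1], p[["z0"]], p[["sz"]]) else 1
    p[["b"]] + p[["A"]] * outer(outer(uz, uy), ux)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = function(p) as.vector(model(p) - d),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(failed_fit_row(nid, resp))
  p <- fit$par
  center_ok <- p[["y0"]] > 0 && p[["y0"]] < len[2] &&
    p[["x0"]] > 0 && p[["x0"]] < len[3] &&
    (!is3d || (p[["z0"]] > 0 && p[["z0"]] < len[1]))
  if (p[["A"]] <= 0 || !center_ok) return(failed_fit_row(nid, resp))
  # back to global fractional voxel indices (voxel center convention)
  zv <- if (is3d) lo[1] - 1 + p[["z0"]] + 0.5 else 1
  yv <- lo[2] - 1 + p[["y0"]] + 0.5
  xv <- lo[3] - 1 + p[["x0"]] + 0.5
  nm <- voxel_to_nm(c(zv, yv, xv), grid)
  data.frame(z_vox = zv, y_vox = yv, x_vox = xv,
             z_nm = nm[1], y_nm = nm[2], x_nm = nm[3],
             amplitude = p[["A"]], background = p[["b"]],
             sigma_xy_nm = p[["sxy"]] * grid$dxy,
             sigma_z_nm = if (is3d) p[["sz"]] * grid$dz else NA_real_,
             rss = fit$deviance, status = "converged", nucleus_id = nid,
             response = resp)
}

failed_fit_row <- function(nucleus_id = NA_integer_, response = NA_real_) {
  data.frame(z_vox = NA_real_, y_vox = NA_real_, x_vox = NA_real_,
             z_nm = NA_real_, y_nm = NA_real_, x_nm = NA_real_,
             amplitude = NA_real_, background = NA_real_,
             sigma_xy_nm = NA_real_, sigma_z_nm = NA_real_, rss = NA_real_,
             status = "failed", nucleus_id = nucleus_id, response = response)
}

#' Fit all candidates of a channel
#'
#' @param stack 3D array.
#' @param candidates data.frame from [detect_spots_log()].
#' @param grid A [voxel_grid()].
#' @param ... Passed to [fit_spot_gaussian()].
#' @return data.frame of spot-fit rows, one per candidate, with an `id`
#'   column.
#' @export
fit_spots <- function(stack, candidates, grid, ...) {
  if (!nrow(candidates)) {
    out <- failed_fit_row()[0, ]
    out$id <- integer(0)
    return(out)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    fit_spot_gaussian(stack, candidates[i, ], grid, ...)
  })
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out
}

#' Per-nucleus background statistics excluding spot regions
#'
#' Mean and standard deviation of the stack intensity over the voxels of each
#' nucleus (2D labels extended through z), excluding a dilated box around
#' every detected spot so that spot photons do not inflate the background.
#'
#' @param stack 3D array of the FISH channel.
#' @param label_map A [segment_nuclei()] result.
#' @param spots data.frame with integer `z`, `y`, `x` voxel positions of
#'   detected spots (all spots of the channel, converged or not).
#' @param grid A [voxel_grid()].
#' @param sigma_nm Spot size used to scale the exclusion box.
#' @param dilate_vox Extra margin in voxels beyond `2 * sigma` (default 2).
#' @return data.frame `nucleus_id`, `bg_mean`, `bg_sd`, `n_vox`.
#' @export
nucleus_background_stats <- function(stack, label_map, spots, grid,
                                     sigma_nm = c(xy = 60, z = 200),
                                     dilate_vox = 2L) {
  dm <- dim(stack)
  excl <- array(FALSE, dim = dm)
  hxy <- ceiling(2 * sigma_nm[["xy"]] / grid$dxy) + dilate_vox
  hz <- if (dm[1] > 1L) ceiling(2 * sigma_nm[["z"]] / grid$dz) + dilate_vox
        else 0L
  for (i in seq_len(nrow(spots))) {
    z <- spots$z[i]; y <- spots$y[i]; x <- spots$x[i]
    excl[max(1, z - hz):min(dm[1], z + hz),
         max(1, y - hxy):min(dm[2], y + hxy),
         max(1, x - hxy):min(dm[3], x + hxy)] <- TRUE
  }
  ids <- label_map$table$id
  out <- lapply(ids, function(id) {
    inmask2d <- label_map$labels == id
    m3 <- aperm(array(inmask2d, dim = c(dm[2], dm[3], dm[1])), c(3, 1, 2))
    v <- stack[m3 & !excl]
    data.frame(nucleus_id = id, bg_mean = mean(v), bg_sd = stats::sd(v),
               n_vox = length(v))
  })
  do.call(rbind, out)
}

#' Attach intensity metrics to spot fits
#'
#' Signal-over-background is the fitted peak height divided by the mean
#' nuclear background of the spot's nucleus; the signal-to-noise ratio
#' divides by the background standard deviation instead. Both definitions are
#' exported so alternatives can be recomputed from the same columns. A zero
#' background SD yields `snr = NA` with a warning.
#'
#' @param fits data.frame from [fit_spots()].
#' @param bg_stats data.frame from [nucleus_background_stats()].
#' @return `fits` with `bg_mean`, `bg_sd`, `signal_over_bg`, `snr` columns
#'   (NA for failed fits).
#' @export
spot_metrics <- function(fits, bg_stats) {
  m <- match(fits$nucleus_id, bg_stats$nucleus_id)
  fits$bg_mean <- bg_stats$bg_mean[m]
  fits$bg_sd <- bg_stats$bg_sd[m]
  conv <- fits$status == "converged"
  fits$signal_over_bg <- ifelse(conv, fits$amplitude / fits$bg_mean,
                                NA_real_)
  zero_sd <- conv & !is.na(fits$bg_sd) & fits$bg_sd == 0
  if (any(zero_sd)) {
    warning("zero background SD in ", sum(zero_sd),
            " nucleus/nuclei: snr undefined", call. = FALSE)
  }
  fits$snr <- ifelse(conv & !zero_sd, fits$amplitude / fits$bg_sd, NA_real_)
  fits
}
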