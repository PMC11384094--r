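#' Synthetic microscopy scene
#'
#' Ground-truth specification of a multi-channel z-stack: nuclei rendered as
#' bright ellipsoids in a counterstain channel, diffraction-limited FISH spots
#' as voxel-integrated 3D Gaussians, a constant background inside nuclei, an
#' optional constant base level everywhere (camera offset), and optional
#' extra ellipsoidal intensity regions (e.g. satellite blobs). Rendering is
#' deterministic for a fixed scene and seed.
#'
#' @param grid A [voxel_grid()].
#' @param channels Character vector of channel names; the first is the
#'   counterstain by convention.
#' @param nuclei data.frame with one ellipsoid per row: `id`, centers
#'   `cz,cy,cx` (nm), radii `rz,ry,rx` (nm), `intensity` (counterstain
#'   photons).
#' @param spots data.frame of ground-truth spots: `channel` (index into
#'   `channels`), position `z,y,x` (nm), `amplitude` (peak photons above
#'   background), `sigma_xy`, `sigma_z` (nm), `nucleus_id`, logical
#'   `extranuclear`. May have zero rows.
#' @param background Per-channel constant added inside nuclei (photons);
#'   recycled to the number of channels.
#' @param base_level Per-channel constant added everywhere (camera offset).
#' @param regions Optional data.frame of extra ellipsoidal regions: `channel`,
#'   `cz,cy,cx`, `rz,ry,rx`, `intensity`; or `NULL`.
#' @param poisson_noise Apply Poisson shot noise.
#' @param read_noise_sd Gaussian read noise standard deviation (0 = none).
#' @param blur_sigma_nm PSF blur `c(xy, z)` in nm applied to the structural
#'   content (nuclei, background, regions) at render time, since the
#'   microscope convolves everything with its PSF; spots are already
#'   rendered as PSF-shaped Gaussians. `c(0, 0)` disables.
#' @param seed RNG seed used by [render_scene()] for the noise draws.
#' @return A `synthetic_scene` object.
#' @export
synthetic_scene <- function(grid, channels, nuclei, spots,
                            background = 0, base_level = 0, regions = NULL,
                            poisson_noise = TRUE, read_noise_sd = 0,
                            blur_sigma_nm = c(xy = 60, z = 200),
                            seed = 0L) {
  stopifnot(inherits(grid, "voxel_grid"), is.character(channels),
            length(channels) >= 1L)
  nuclei <- as.data.frame(nuclei)
  spots <- as.data.frame(spots)
  nc <- length(channels)
  background <- rep_len(as.numeric(background), nc)
  base_level <- rep_len(as.numeric(base_level), nc)
  scene <- structure(
    list(grid = grid, channels = channels, nuclei = nuclei, spots = spots,
         background = background, base_level = base_level, regions = regions,
         poisson_noise = isTRUE(poisson_noise),
         read_noise_sd = as.numeric(read_noise_sd),
         blur_sigma_nm = rep_len(as.numeric(blur_sigma_nm), 2L),
         seed = as.integer(seed)),
    class = "synthetic_scene"
  )
  validate_scene(scene)
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d channel(s), %d nuclei, %d spots, seed %d\n",
    length(x$channels), nrow(x$nuclei), nrow(x$spots), x$seed))
  print(x$grid)
  invisible(x)
}

validate_scene <- function(scene) {
  ext <- scene$grid$extent_nm
  if (nrow(scene$spots)) {
    sp <- scene$spots
    stopifnot(all(sp$amplitude >= 0), all(sp$sigma_xy > 0),
              all(sp$sigma_z > 0))
    inside <- sp$z >= 0 & sp$z <= ext[1] & sp$y >= 0 & sp$y <= ext[2] &
      sp$x >= 0 & sp$x <= ext[3]
    if (!all(inside)) {
      stop("spot(s) outside the grid extent: rows ",
           paste(which(!inside), collapse = ", "), call. = FALSE)
    }
    if (is.null(sp$extranuclear)) sp$extranuclear <- FALSE
    intra <- !sp$extranuclear
    if (any(intra) && nrow(scene$nuclei)) {
      ok <- vapply(which(intra), function(i) {
        any(point_in_ellipsoids(c(sp$z[i], sp$y[i], sp$x[i]), scene$nuclei))
      }, logical(1))
      if (!all(ok)) {
        stop("spot(s) not inside any nucleus (and not flagged extranuclear):",
             " rows ", paste(which(intra)[!ok], collapse = ", "),
             call. = FALSE)
      }
    }
  }
  invisible(scene)
}

point_in_ellipsoids <- function(p, nuclei) {
  ((p[1] - nuclei$cz) / nuclei$rz)^2 +
    ((p[2] - nuclei$cy) / nuclei$ry)^2 +
    ((p[3] - nuclei$cx) / nuclei$rx)^2 <= 1
}

# fill an ellipsoid into a (z,y,x) array, adding `value` inside
add_ellipsoid <- function(arr, grid, cz, cy, cx, rz, ry, rx, value) {
  zc <- axis_centers_nm(grid$shape[1], grid$dz)
  yc <- axis_centers_nm(grid$shape[2], grid$dxy)
  xc <- axis_centers_nm(grid$shape[3], grid$dxy)
  zi <- which(abs(zc - cz) <= rz)
  yi <- which(abs(yc - cy) <= ry)
  xi <- which(abs(xc - cx) <= rx)
  if (!length(zi) || !length(yi) || !length(xi)) return(arr)
  qz <- ((zc[zi] - cz) / rz)^2
  qy <- ((yc[yi] - cy) / ry)^2
  qx <- ((xc[xi] - cx) / rx)^2
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  sub <- arr[zi, yi, xi, drop = FALSE]
  sub[q <= 1] <- sub[q <= 1] + value
  arr[zi, yi, xi] <- sub
  arr
}

# voxel-averaged Gaussian weights along one axis: mean over each voxel of a
# unit-peak Gaussian centered at mu_nm. Returns list(idx, w).
gauss_axis_weights <- function(n, spacing, mu_nm, sigma_nm, halfwidth = 4.5) {
  lo <- max(1L, floor((mu_nm - halfwidth * sigma_nm) / spacing))
  hi <- min(n, ceiling((mu_nm + halfwidth * sigma_nm) / spacing) + 1L)
  if (lo > hi) return(list(idx = integer(0), w = numeric(0)))
  idx <- lo:hi
  edges <- (c(idx, hi + 1L) - 1) * spacing
  cdf <- stats::pnorm(edges, mean = mu_nm, sd = sigma_nm)
  # voxel mean of the unit-peak Gaussian = integral * sqrt(2*pi)*sigma / dx
  w <- diff(cdf) * sqrt(2 * pi) * sigma_nm / spacing
  list(idx = idx, w = w)
}

add_gaussian_spot <- function(arr, grid, z, y, x, amplitude, sigma_xy,
                              sigma_z) {
  wz <- gauss_axis_weights(grid$shape[1], grid$dz, z, sigma_z)
  wy <- gauss_axis_weights(grid$shape[2], grid$dxy, y, sigma_xy)
  wx <- gauss_axis_weights(grid$shape[3], grid$dxy, x, sigma_xy)
  if (!length(wz$idx) || !length(wy$idx) || !length(wx$idx)) return(arr)
  blk <- amplitude * outer(outer(wz$w, wy$w), wx$w)
  arr[wz$idx, wy$idx, wx$idx] <- arr[wz$idx, wy$idx, wx$idx] + blk
  arr
}

#' Render a synthetic scene to an image stack
#'
#' Deterministically renders nuclei, background and spots into per-channel
#' `(z, y, x)` arrays, then applies Poisson shot noise followed by additive
#' Gaussian read noise under the scene seed. Spot profiles are integrated
#' over each voxel (not point-sampled), so the noiseless voxel sum of a spot
#' equals `amplitude * (2*pi)^1.5 * sigma_xy^2 * sigma_z / (dxy^2 * dz)`.
#'
#' @param scene A [synthetic_scene()].
#' @return A `fish_stack`: `channels` (named list of 3D arrays), `grid`, and
#'   `truth` (list with the scene's `spots` and `nuclei` tables).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  g <- scene$grid
  nc <- length(scene$channels)
  arrs <- vector("list", nc)
  names(arrs) <- scene$channels
  for (ci in seq_len(nc)) {
    a <- array(scene$base_level[ci], dim = g$shape)
    if (nrow(scene$nuclei)) {
      for (i in seq_len(nrow(scene$nuclei))) {
        nu <- scene$nuclei[i, ]
        val <- if (ci == 1L) nu$intensity + scene$background[ci]
               else scene$background[ci]
        if (val != 0) {
          a <- add_ellipsoid(a, g, nu$cz, nu$cy, nu$cx, nu$rz, nu$ry, nu$rx,
                             val)
        }
      }
    }
    if (!is.null(scene$regions)) {
      rg <- scene$regions[scene$regions$channel == ci, , drop = FALSE]
      for (i in seq_len(nrow(rg))) {
        r <- rg[i, ]
        a <- add_ellipsoid(a, g, r$cz, r$cy, r$cx, r$rz, r$ry, r$rx,
                           r$intensity)
      }
    }
    bs <- scene$blur_sigma_nm
    if (bs[1] > 0) {
      sz_vox <- if (g$shape[1] > 1L && bs[2] > 0) bs[2] / g$dz else 0
      a <- gaussian_smooth_stack(a, sz_vox, bs[1] / g$dxy)
    }
    if (nrow(scene$spots)) {
      sp <- scene$spots[scene$spots$channel == ci, , drop = FALSE]
      for (i in seq_len(nrow(sp))) {
        s <- sp[i, ]
        a <- add_gaussian_spot(a, g, s$z, s$y, s$x, s$amplitude, s$sigma_xy,
                               s$sigma_z)
      }
    }
    arrs[[ci]] <- a
  }
  if (scene$poisson_noise || scene$read_noise_sd > 0) {
    arrs <- with_seed(scene$seed, {
      for (ci in seq_len(nc)) {
        v <- arrs[[ci]]
        if (scene$poisson_noise) {
          v <- array(stats::rpois(length(v), pmax(v, 0)), dim = dim(v))
        }
        if (scene$read_noise_sd > 0) {
          v <- v + array(stats::rnorm(length(v), 0, scene$read_noise_sd),
                         dim = dim(v))
        }
        arrs[[ci]] <- v
      }
      arrs
    })
  }
  structure(list(channels = arrs, grid = g,
                 truth = list(spots = scene$spots, nuclei = scene$nuclei)),
            class = "fish_stack")
}

#' @export
print.fish_stack <- function(x, ...) {
  cat(sprintf("<fish_stack> channels: %s\n",
              paste(names(x$channels), collapse = ", ")))
  print(x$grid)
  invisible(x)
}
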