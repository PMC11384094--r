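# Separable Gaussian smoothing of a (z, y, x) stack. The lateral part runs
# per slice through EBImage::filter2 (FFT, replicate boundary); the axial
# part is a small dense convolution matrix with truncated-renormalized rows,
# cheap because nz is small.
gaussian_smooth_stack <- function(a, sigma_z_vox, sigma_xy_vox) {
  dm <- dim(a)
  kr <- max(1L, ceiling(4 * sigma_xy_vox))
  g <- stats::dnorm(-kr:kr, sd = sigma_xy_vox)
  g <- g / sum(g)
  k2 <- outer(g, g)
  out <- a
  for (iz in seq_len(dm[1])) {
    out[iz, , ] <- EBImage::filter2(a[iz, , ], k2, boundary = "replicate")
  }
  if (dm[1] > 1L && sigma_z_vox > 0) {
    nz <- dm[1]
    K <- outer(seq_len(nz), seq_len(nz),
               function(i, j) stats::dnorm(i - j, sd = sigma_z_vox))
    K <- K / rowSums(K)
    dim(out) <- c(nz, dm[2] * dm[3])
    out <- K %*% out
    out <- array(out, dim = dm)
  }
  out
}

# second difference along one axis with replicated edges
second_diff <- function(a, axis) {
  dm <- dim(a)
  n <- dm[axis]
  if (n < 3L) return(array(0, dim = dm))
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  idx_p <- pmin(seq_len(n) + 1L, n)
  pick <- function(i) {
    switch(axis,
           a[i, , , drop = FALSE],
           a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  pick(idx_m) + pick(idx_p) - 2 * a
}

#' Detect spots with a scale-normalized Laplacian-of-Gaussian filter
#'
#' The stack is smoothed with an anisotropic Gaussian matched to the expected
#' spot size, the negative Laplacian is scale-normalized per axis
#' (`sigma^2` times the second difference, in voxel units), and local maxima
#' of the response above a threshold and inside the nuclear mask become
#' candidate spots. The default threshold is `k_mad` times the MAD of the
#' response over in-mask voxels; an absolute threshold can be given instead.
#'
#' @param stack A 3D `(z, y, x)` array (single channel), or a `fish_stack`
#'   with `channel`.
#' @param label_map A [segment_nuclei()] result restricting detection to
#'   nuclei; `NULL` to search everywhere.
#' @param grid A [voxel_grid()].
#' @param sigma_nm Expected spot size, named `c(xy = ..., z = ...)` in nm;
#'   each must be at least one voxel.
#' @param threshold `"mad"` (default) or `"absolute"`.
#' @param k_mad Multiplier for the MAD policy (default 6).
#' @param threshold_abs Absolute response threshold when
#'   `threshold = "absolute"`.
#' @param channel Channel name when `stack` is a `fish_stack`.
#' @return data.frame of candidates: integer voxel position `z`, `y`, `x`,
#'   `response`, `nucleus_id`.
#' @export
detect_spots_log <- function(stack, label_map, grid,
                             sigma_nm = c(xy = 60, z = 200),
                             threshold = c("mad", "absolute"), k_mad = 6,
                             threshold_abs = NULL, channel = NULL) {
  threshold <- match.arg(threshold)
  if (inherits(stack, "fish_stack")) {
    g <- stack$grid
    stack <- stack$channels[[channel %||% names(stack$channels)[2]]]
    if (missing(grid) || is.null(grid)) grid <- g
  }
  stopifnot(length(dim(stack)) == 3L, inherits(grid, "voxel_grid"))
  is3d <- dim(stack)[1] > 1L
  sxy <- sigma_nm[["xy"]] / grid$dxy
  if (sxy < 1) stop("lateral sigma smaller than one pixel", call. = FALSE)
  sz <- if (is3d) sigma_nm[["z"]] / grid$dz else 0
  if (is3d && sz < 1) stop("axial sigma smaller than one z-step",
                           call. = FALSE)
  S <- gaussian_smooth_stack(stack, sz, sxy)
  resp <- -(sxy^2 * (second_diff(S, 2L) + second_diff(S, 3L)))
  if (is3d) resp <- resp - sz^2 * second_diff(S, 1L)
  mask3d <- if (is.null(label_map)) {
    array(TRUE, dim = dim(stack))
  } else {
    aperm(array(label_map$labels > 0L,
                dim = c(dim(stack)[2:3], dim(stack)[1])), c(3, 1, 2))
  }
  thr <- if (threshold == "mad") {
    vals <- resp[mask3d]
    if (!length(vals)) return(empty_candidates())
    stats::median(vals) + k_mad * stats::mad(vals)
  } else {
    if (is.null(threshold_abs)) stop("threshold_abs required", call. = FALSE)
    threshold_abs
  }
  cand <- which(resp > thr & mask3d, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_candidates())
  dm <- dim(resp)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    z <- cand[i, 1]; y <- cand[i, 2]; x <- cand[i, 3]
    nb <- resp[max(1, z - 1):min(dm[1], z + 1),
               max(1, y - 1):min(dm[2], y + 1),
               max(1, x - 1):min(dm[3], x + 1)]
    v <- resp[z, y, x]
    mx <- max(nb)
    if (v < mx) next
    # plateau tie-break: keep only the lexicographically first voxel
    if (sum(nb == mx) > 1L) {
      w <- which(resp[max(1, z - 1):min(dm[1], z + 1),
                      max(1, y - 1):min(dm[2], y + 1),
                      max(1, x - 1):min(dm[3], x + 1)] == mx,
                 arr.ind = TRUE)
      w[, 1] <- w[, 1] + max(1, z - 1) - 1L
      w[, 2] <- w[, 2] + max(1, y - 1) - 1L
      w[, 3] <- w[, 3] + max(1, x - 1) - 1L
      first <- w[order(w[, 1], w[, 2], w[, 3])[1], ]
      if (!all(first == c(z, y, x))) next
    }
    keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_candidates())
  nucleus_id <- if (is.null(label_map)) {
    rep(NA_integer_, nrow(cand))
  } else {
    label_map$labels[cand[, 2:3, drop = FALSE]]
  }
  data.frame(z = as.integer(cand[, 1]), y = as.integer(cand[, 2]),
             x = as.integer(cand[, 3]),
             response = resp[cand], nucleus_id = as.integer(nucleus_id))
}

empty_candidates <- function() {
  data.frame(z = integer(0), y = integer(0), x = integer(0),
             response = numeric(0), nucleus_id = integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
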