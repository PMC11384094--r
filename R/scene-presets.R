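#' Configuration for a two-color paired-locus scene
#'
#' Describes the ground truth of a two-color experiment in which each cell
#' carries one locus detected by probe set A and one by probe set B: the true
#' 3D separation distribution of colocalizing pairs, the fraction of pairs
#' that truly colocalize, per-channel amplitudes and optional detection
#' dropout.
#'
#' @param n_cells Number of cells (one nucleus each).
#' @param distance_dist True A-B separation of colocalizing pairs:
#'   `list(kind = "point", value = nm)`,
#'   `list(kind = "uniform", min = , max = )`, or
#'   `list(kind = "lognormal", meanlog = , sdlog = )`.
#' @param coloc_fraction Fraction of cells whose pair truly colocalizes; the
#'   rest have the B partner displaced beyond the colocalization radius.
#' @param coloc_radius_nm Radius defining colocalization (default 500 nm).
#' @param amplitude Peak photons above background, per channel `c(A, B)`.
#' @param dropout Per-channel probability that a spot is absent `c(A, B)`.
#' @param sigma_xy,sigma_z Spot Gaussian widths in nm.
#' @param nucleus_radius_nm Ellipsoid radii `c(z, xy)` in nm.
#' @param nucleus_intensity Counterstain photons inside nuclei.
#' @param background FISH-channel photons inside nuclei.
#' @param base_level Camera offset everywhere.
#' @param read_noise_sd Gaussian read noise SD.
#' @return A `pair_scene_config` list.
#' @export
pair_scene_config <- function(n_cells = 50L,
                              distance_dist = list(kind = "point",
                                                   value = 300),
                              coloc_fraction = 0.5, coloc_radius_nm = 500,
                              amplitude = c(60, 60), dropout = c(0, 0),
                              sigma_xy = 60, sigma_z = 200,
                              nucleus_radius_nm = c(z = 400, xy = 850),
                              nucleus_intensity = 400, background = 50,
                              base_level = 5, read_noise_sd = 3) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1, n_cells >= 1,
            all(dropout >= 0 & dropout <= 1))
  structure(list(n_cells = as.integer(n_cells),
                 distance_dist = distance_dist,
                 coloc_fraction = coloc_fraction,
                 coloc_radius_nm = coloc_radius_nm,
                 amplitude = rep_len(amplitude, 2L),
                 dropout = rep_len(dropout, 2L),
                 sigma_xy = sigma_xy, sigma_z = sigma_z,
                 nucleus_radius_nm = nucleus_radius_nm,
                 nucleus_intensity = nucleus_intensity,
                 background = background, base_level = base_level,
                 read_noise_sd = read_noise_sd),
            class = "pair_scene_config")
}

draw_distances <- function(spec, n) {
  switch(spec$kind,
         point = rep(spec$value, n),
         uniform = stats::runif(n, spec$min, spec$max),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         stop("unknown distance distribution kind '", spec$kind, "'",
              call. = FALSE))
}

#' Build a two-color paired-locus scene
#'
#' Cells are laid out on a tile grid, one ellipsoidal nucleus per tile. Each
#' cell receives an A spot near the nucleus center; with probability
#' `coloc_fraction` the B partner is placed at a separation drawn from
#' `distance_dist`, otherwise it is displaced to a separation beyond the
#' colocalization radius (or dropped, per the dropout probabilities).
#' Directions are drawn uniformly on the sphere, rejection-sampled so both
#' spots stay inside the nucleus; an error is raised when the nuclei are too
#' small for the requested separations.
#'
#' @param config A [pair_scene_config()].
#' @param grid A [voxel_grid()], or `NULL` to auto-size from `n_cells`.
#' @param seed RNG seed for the scene layout (rendering noise uses the same
#'   seed via the scene).
#' @return A [synthetic_scene()] with channels `dapi`, `A`, `B` and an extra
#'   `pair_truth` element: per-cell truth (`cell`, true positions,
#'   `true_distance_nm`, `colocalized_truth`, `a_present`, `b_present`).
#' @export
make_pair_scene <- function(config = pair_scene_config(), grid = NULL,
                            seed = 0L) {
  stopifnot(inherits(config, "pair_scene_config"))
  rz <- config$nucleus_radius_nm[["z"]]
  rxy <- config$nucleus_radius_nm[["xy"]]
  dxy <- 30; dz <- 80
  tile_px <- ceiling(2 * (rxy + 150) / dxy)
  ncol_t <- ceiling(sqrt(config$n_cells))
  nrow_t <- ceiling(config$n_cells / ncol_t)
  if (is.null(grid)) {
    nz <- ceiling(2 * (rz + 80) / dz)
    grid <- voxel_grid(c(nz, nrow_t * tile_px, ncol_t * tile_px),
                       dxy = dxy, dz = dz)
  } else {
    dxy <- grid$dxy; dz <- grid$dz
    tile_px <- ceiling(2 * (rxy + 150) / dxy)
    if (nrow_t * tile_px > grid$shape[2] || ncol_t * tile_px > grid$shape[3]) {
      stop("grid too small for ", config$n_cells, " cells", call. = FALSE)
    }
  }
  margin <- 60  # nm clearance of spots from the nuclear envelope
  if (rxy - margin <= 0 || rz - margin <= 0) {
    stop("nuclei too small for spot placement", call. = FALSE)
  }
  built <- with_seed(seed, {
    nuclei <- list(); spots <- list(); truth <- list()
    sid <- 0L
    for (cell in seq_len(config$n_cells)) {
      ti <- (cell - 1L) %/% ncol_t
      tj <- (cell - 1L) %% ncol_t
      cz <- grid$extent_nm[1] / 2
      cy <- (ti + 0.5) * tile_px * dxy
      cx <- (tj + 0.5) * tile_px * dxy
      nuclei[[cell]] <- data.frame(id = cell, cz = cz, cy = cy, cx = cx,
                                   rz = rz, ry = rxy, rx = rxy,
                                   intensity = config$nucleus_intensity)
      a_pos <- c(cz, cy, cx) +
        c(stats::runif(1, -40, 40), stats::runif(1, -100, 100),
          stats::runif(1, -100, 100))
      coloc <- stats::runif(1) < config$coloc_fraction
      b_pos <- NULL
      if (coloc) {
        # place B at the drawn separation in a direction that stays nuclear
        d <- draw_distances(config$distance_dist, 1L)
        for (try in seq_len(500L)) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- a_pos + d * u
          q <- ((cand[1] - cz) / (rz - margin))^2 +
            ((cand[2] - cy) / (rxy - margin))^2 +
            ((cand[3] - cx) / (rxy - margin))^2
          if (q <= 1) { b_pos <- cand; break }
        }
        if (is.null(b_pos)) {
          stop("nuclei too small for requested separation ", round(d),
               " nm", call. = FALSE)
        }
      } else {
        # B anywhere in the nucleus beyond the colocalization radius
        min_d <- config$coloc_radius_nm + 100
        for (try in seq_len(1000L)) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
          cand <- c(cz, cy, cx) +
            u * c(rz - margin, rxy - margin, rxy - margin)
          if (sqrt(sum((cand - a_pos)^2)) > min_d) { b_pos <- cand; break }
        }
        if (is.null(b_pos)) {
          stop("nuclei too small to place a non-colocalizing partner beyond ",
               min_d, " nm", call. = FALSE)
        }
      }
      a_present <- stats::runif(1) >= config$dropout[1]
      b_present <- stats::runif(1) >= config$dropout[2]
      if (a_present) {
        sid <- sid + 1L
        spots[[sid]] <- data.frame(
          channel = 2L, z = a_pos[1], y = a_pos[2], x = a_pos[3],
          amplitude = config$amplitude[1], sigma_xy = config$sigma_xy,
          sigma_z = config$sigma_z, nucleus_id = cell, extranuclear = FALSE)
      }
      if (b_present) {
        sid <- sid + 1L
        spots[[sid]] <- data.frame(
          channel = 3L, z = b_pos[1], y = b_pos[2], x = b_pos[3],
          amplitude = config$amplitude[2], sigma_xy = config$sigma_xy,
          sigma_z = config$sigma_z, nucleus_id = cell, extranuclear = FALSE)
      }
      truth[[cell]] <- data.frame(
        cell = cell, az = a_pos[1], ay = a_pos[2], ax = a_pos[3],
        bz = b_pos[1], by = b_pos[2], bx = b_pos[3],
        true_distance_nm = sqrt(sum((a_pos - b_pos)^2)),
        colocalized_truth = coloc, a_present = a_present,
        b_present = b_present)
    }
    list(nuclei = do.call(rbind, nuclei), spots = do.call(rbind, spots),
         truth = do.call(rbind, truth))
  })
  scene <- synthetic_scene(
    grid, channels = c("dapi", "A", "B"), nuclei = built$nuclei,
    spots = built$spots,
    background = c(0, config$background, config$background),
    base_level = config$base_level, poisson_noise = TRUE,
    read_noise_sd = config$read_noise_sd, seed = seed)
  scene$pair_truth <- built$truth
  scene
}

#' Build a labeling-density dilution series of scenes
#'
#' One scene per labeling ratio, emulating the two-channel satellite-blob
#' experiment: large blob regions inside each nucleus carry a reference
#' ("binding") channel whose intensity is independent of the labeling ratio,
#' and a "brightness" channel whose intensity follows the labeling model's
#' mean predicted brightness at that ratio (per probe, times a gain). The
#' per-condition expected intensities are recorded as truth.
#'
#' @param ratios Labeled dCTP fractions (default the 0-100 percent series).
#' @param seed RNG seed (each condition derives its own sub-seed).
#' @param n_cells Cells per condition.
#' @param probe Probe whose labelable sites set the dye pattern; default the
#'   40-nt polymerase-screen probe with a 20-nt primer (8 sites).
#' @param primer_len Primer length for the labelable region.
#' @param curve A [quench_curve()] applied to dye patterns.
#' @param ref_intensity Reference-channel photons in blobs.
#' @param gain_per_brightness Brightness-channel photons per unit predicted
#'   relative brightness.
#' @param blobs_per_cell Satellite blobs per nucleus.
#' @param base_level,read_noise_sd Noise settings (Poisson always on).
#' @return list with `scenes` (one [synthetic_scene()] per ratio, channels
#'   `dapi`, `ref`, `bright`), `truth` (data.frame `ratio`, `expected_ref`,
#'   `expected_bright`), and `bg_roi` (a nucleus-free rectangle usable as
#'   background ROI).
#' @export
make_density_series_scene <- function(ratios = c(0, 0.25, 0.5, 0.75, 1),
                                      seed = 0L, n_cells = 6L,
                                      probe = polymerase_screen_probe(),
                                      primer_len = 20L,
                                      curve = quench_curve(),
                                      ref_intensity = 200,
                                      gain_per_brightness = 40,
                                      blobs_per_cell = 3L,
                                      base_level = 5, read_noise_sd = 3) {
  stopifnot(all(ratios >= 0 & ratios <= 1))
  pred <- brightness_vs_density_curve(probe, primer_len, curve,
                                      ratios = ratios, seed = seed,
                                      n_draws = 4000L)
  dxy <- 30; dz <- 80
  rz <- 350; rxy <- 750
  tile_px <- ceiling(2 * (rxy + 120) / dxy)
  margin_px <- 20L  # nucleus-free strip on the left, usable as bg ROI
  ncol_t <- ceiling(sqrt(n_cells))
  nrow_t <- ceiling(n_cells / ncol_t)
  nz <- ceiling(2 * (rz + 80) / dz)
  grid <- voxel_grid(c(nz, nrow_t * tile_px, margin_px + ncol_t * tile_px),
                     dxy = dxy, dz = dz)
  scenes <- vector("list", length(ratios))
  for (ri in seq_along(ratios)) {
    sub_seed <- seed + 1000L * ri
    built <- with_seed(sub_seed, {
      nuclei <- list(); regions <- list()
      for (cell in seq_len(n_cells)) {
        ti <- (cell - 1L) %/% ncol_t
        tj <- (cell - 1L) %% ncol_t
        cz <- grid$extent_nm[1] / 2
        cy <- (ti + 0.5) * tile_px * dxy
        cx <- margin_px * dxy + (tj + 0.5) * tile_px * dxy
        nuclei[[cell]] <- data.frame(id = cell, cz = cz, cy = cy, cx = cx,
                                     rz = rz, ry = rxy, rx = rxy,
                                     intensity = 150)
        for (b in seq_len(blobs_per_cell)) {
          # evenly spread angles with jitter keep blobs from overlapping,
          # so the reference intensity is the same in every blob
          ang <- 2 * pi * (b - 1) / blobs_per_cell +
            stats::runif(1, -0.15, 0.15)
          rad <- stats::runif(1, 0.42, 0.55) * rxy
          bz <- cz + stats::runif(1, -0.25, 0.25) * rz
          by <- cy + rad * sin(ang)
          bx <- cx + rad * cos(ang)
          for (chan in 2:3) {
            inten <- if (chan == 2L) ref_intensity else
              gain_per_brightness * pred$mean_brightness[ri]
            regions[[length(regions) + 1L]] <- data.frame(
              channel = chan, cz = bz, cy = by, cx = bx,
              rz = 170, ry = 230, rx = 230, intensity = inten)
          }
        }
      }
      list(nuclei = do.call(rbind, nuclei),
           regions = do.call(rbind, regions))
    })
    scenes[[ri]] <- synthetic_scene(
      grid, channels = c("dapi", "ref", "bright"), nuclei = built$nuclei,
      spots = data.frame(), background = c(0, 20, 10),
      base_level = base_level, regions = built$regions,
      poisson_noise = TRUE, read_noise_sd = read_noise_sd, seed = sub_seed)
  }
  names(scenes) <- paste0("ratio_", ratios * 100)
  list(scenes = scenes,
       truth = data.frame(
         ratio = ratios, expected_ref = ref_intensity,
         expected_bright = gain_per_brightness * pred$mean_brightness),
       bg_roi = list(y = c(1L, grid$shape[2]), x = c(1L, margin_px - 4L)))
}

#' The 40-nt polymerase-screen probe sequence
#'
#' The printed oligonucleotide used to screen polymerases for dye-dCTP
#' incorporation; with its 20-nt primer it has 8 labelable cytosines in the
#' extension region, the maximum dye count of that probe.
#'
#' @return A 40-character DNA string.
#' @export
polymerase_screen_probe <- function() {
  "CATCCTGAAGGAATGGTCCATGCTTACCTGGGCCCATCCT"
}
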