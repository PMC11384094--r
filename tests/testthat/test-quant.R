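grid8 <- voxel_grid(c(8, 64, 64), dxy = 30, dz = 80)

nm_to_vox <- function(pos_nm, grid) {
  pos_nm / c(grid$dz, grid$dxy, grid$dxy) + 0.5
}

test_that("max projection is the per-pixel maximum over z", {
  a <- array(0, dim = c(1, 4, 4)); a[1, 2, 3] <- 5
  expect_equal(max_project(a), a[1, , ])
  b <- array(0, dim = c(2, 4, 4)); b[1, 1, 1] <- 3; b[2, 4, 4] <- 7
  pr <- max_project(b)
  expect_equal(pr[1, 1], 3); expect_equal(pr[4, 4], 7)
  expect_error(max_project(array(0, dim = c(0, 4, 4))), "non-empty")
  # projection area of a thresholded nucleus >= any single slice
  st <- render_scene(make_pair_scene(pair_scene_config(n_cells = 1),
                                     seed = 2))
  d <- st$channels$dapi
  pr <- max_project(d)
  thr <- 100
  expect_gte(sum(pr > thr), max(apply(d, 1, function(s) sum(s > thr))))
})

test_that("Otsu segmentation finds nuclei, honors min area and border exclusion", {
  expect_warning(lm0 <- segment_nuclei(matrix(5, 40, 40), grid8),
                 "constant image")
  expect_equal(nrow(lm0$table), 0)
  # two disjoint nuclei, noiseless: centroids within 1 px of truth
  nuc <- data.frame(id = 1:2, cz = c(320, 320), cy = c(600, 1350),
                    cx = c(700, 1300), rz = 250, ry = 450, rx = 450,
                    intensity = 200)
  sc <- synthetic_scene(grid8, channels = "dapi", nuclei = nuc,
                        spots = data.frame(), poisson_noise = FALSE)
  lm <- segment_nuclei(max_project(render_scene(sc)$channels$dapi), grid8)
  expect_equal(nrow(lm$table), 2)
  got <- lm$table[order(lm$table$cy), ]
  expect_lt(abs(got$cy[1] - 600 / 30), 1)
  expect_lt(abs(got$cx[1] - 700 / 30), 1)
  expect_lt(abs(got$cy[2] - 1350 / 30), 1)
  # min-area filter removes small components
  lm_big <- segment_nuclei(max_project(render_scene(sc)$channels$dapi),
                           grid8, min_area_um2 = 10)
  expect_equal(nrow(lm_big$table), 0)
  # border exclusion drops a nucleus that touches the edge
  nuc_edge <- data.frame(id = 1, cz = 320, cy = 430, cx = 960, rz = 250,
                         ry = 500, rx = 500, intensity = 200)
  sce <- synthetic_scene(grid8, channels = "dapi", nuclei = nuc_edge,
                         spots = data.frame(), poisson_noise = FALSE)
  pr <- max_project(render_scene(sce)$channels$dapi)
  expect_equal(nrow(segment_nuclei(pr, grid8)$table), 1)
  expect_equal(nrow(segment_nuclei(pr, grid8,
                                   exclude_border = TRUE)$table), 0)
})

test_that("LoG detection recovers planted spots inside nuclei and only there", {
  cfg <- pair_scene_config(n_cells = 10, coloc_fraction = 1,
                           amplitude = c(80, 80))
  sc <- make_pair_scene(cfg, seed = 13)
  st <- render_scene(sc)
  lm <- segment_nuclei(max_project(st$channels$dapi), st$grid)
  cand <- detect_spots_log(st$channels$A, lm, st$grid)
  truth <- sc$spots[sc$spots$channel == 2, ]
  expect_equal(nrow(cand), 10)
  for (i in seq_len(nrow(truth))) {
    tv <- nm_to_vox(c(truth$z[i], truth$y[i], truth$x[i]), st$grid)
    d <- abs(sweep(as.matrix(cand[, c("z", "y", "x")]), 2, tv))
    expect_lte(min(apply(d, 1, max)), 1)  # within 1 voxel of truth
  }
  # a spot planted outside all nuclei is excluded by the mask contract
  sc2 <- make_pair_scene(pair_scene_config(n_cells = 4,
                                           amplitude = c(80, 80)),
                         seed = 14)
  extra <- data.frame(channel = 2, z = 300, y = 50, x = 50, amplitude = 200,
                      sigma_xy = 60, sigma_z = 200, nucleus_id = NA,
                      extranuclear = TRUE)
  sc2$spots <- rbind(sc2$spots, extra)
  st2 <- render_scene(sc2)
  lm2 <- segment_nuclei(max_project(st2$channels$dapi), st2$grid)
  cand2 <- detect_spots_log(st2$channels$A, lm2, st2$grid)
  vy <- ceiling(50 / 30)
  expect_false(any(abs(cand2$y - vy) <= 2 & abs(cand2$x - vy) <= 2))
  expect_error(detect_spots_log(st2$channels$A, lm2, st2$grid,
                                sigma_nm = c(xy = 10, z = 200)),
               "smaller than one pixel")
})

nm_to_vox <- function(pos_nm, grid) {
  pos_nm / c(grid$dz, grid$dxy, grid$dxy) + 0.5
}

test_that("Gaussian fitting recovers noiseless spots to high precision", {
  # spot off voxel centers by 0.3 px laterally
  pos <- c((4 - 0.5) * 80, (32 - 0.5 + 0.3) * 30, (32 - 0.5 - 0.3) * 30)
  nuc <- data.frame(id = 1, cz = 320, cy = 960, cx = 960, rz = 280,
                    ry = 700, rx = 700, intensity = 300)
  sc <- synthetic_scene(
    grid8, channels = c("dapi", "fish"), nuclei = nuc,
    spots = data.frame(channel = 2, z = pos[1], y = pos[2], x = pos[3],
                       amplitude = 100, sigma_xy = 60, sigma_z = 200,
                       nucleus_id = 1, extranuclear = FALSE),
    background = c(0, 10), poisson_noise = FALSE, blur_sigma_nm = c(0, 0))
  a <- render_scene(sc)$channels$fish
  cand <- data.frame(z = 4, y = 32, x = 32)
  fit <- fit_spot_gaussian(a, cand, grid8)
  expect_equal(fit$status, "converged")
  expect_equal(fit$amplitude, 100, tolerance = 1e-4)
  expect_equal(fit$background, 10, tolerance = 1e-3)
  expect_lt(abs(fit$y_nm - pos[2]), 0.3)   # nm-scale accuracy
  expect_lt(abs(fit$x_nm - pos[3]), 0.3)
  # independent coarse grid-search oracle over candidate centers
  win <- a[2:6, 29:35, 29:35]
  offs <- seq(-1, 1, by = 0.05)
  rss <- outer(offs, offs, Vectorize(function(oy, ox) {
    uy <- diff(pnorm(0:7, 3.5 + oy, 2)) * sqrt(2 * pi) * 2
    ux <- diff(pnorm(0:7, 3.5 + ox, 2)) * sqrt(2 * pi) * 2
    uz <- diff(pnorm(0:5, 2.5, 2.5)) * sqrt(2 * pi) * 2.5
    m <- outer(outer(uz, uy), ux)
    f <- lm.fit(cbind(1, as.vector(m)), as.vector(win))
    sum(f$residuals^2)
  }))
  best <- which(rss == min(rss), arr.ind = TRUE)
  expect_equal(offs[best[1]], 0.3, tolerance = 0.051)
  expect_equal(offs[best[2]], -0.3, tolerance = 0.051)
  # determinism: two fits on the same data are identical
  fit2 <- fit_spot_gaussian(a, cand, grid8)
  expect_identical(fit, fit2)
  # flat window fails without raising
  flat <- array(7, dim = c(8, 64, 64))
  expect_equal(fit_spot_gaussian(flat, cand, grid8)$status, "failed")
})

test_that("spot metrics divide amplitude by nucleus background mean and sd", {
  fits <- data.frame(amplitude = c(100, 100), nucleus_id = c(1, 1),
                     status = c("converged", "failed"))
  bg <- data.frame(nucleus_id = 1, bg_mean = 10, bg_sd = 5, n_vox = 1000)
  out <- spot_metrics(fits, bg)
  expect_equal(out$signal_over_bg[1], 10)
  expect_equal(out$snr[1], 20)
  expect_true(is.na(out$snr[2]))
  bg0 <- data.frame(nucleus_id = 1, bg_mean = 10, bg_sd = 0, n_vox = 10)
  expect_warning(out0 <- spot_metrics(fits[1, ], bg0), "zero background")
  expect_true(is.na(out0$snr))
})

test_that("per-condition SNR ranking follows true amplitudes", {
  snrs <- vapply(c(40, 80, 160), function(amp) {
    cfg <- pair_scene_config(n_cells = 6, amplitude = c(amp, amp))
    st <- render_scene(make_pair_scene(cfg, seed = 17))
    res <- run_pair_pipeline(st)
    mean(res$spots$snr, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("physical distances use anisotropic calibration", {
  g <- voxel_grid(c(16, 256, 256), dxy = 30, dz = 80)
  expect_equal(physical_distance(c(0, 0, 0), c(0, 0, 10), g), 300)
  expect_equal(physical_distance(c(0, 0, 0), c(5, 0, 0), g), 400)
  expect_equal(physical_distance(c(0, 0, 0), c(0, 3, 4), g), 150)
})

test_that("pairing is greedy, symmetric, and optimal on small configurations", {
  mk <- function(ids, zyx) {
    data.frame(id = ids, z_nm = zyx[, 1], y_nm = zyx[, 2], x_nm = zyx[, 3])
  }
  a1 <- mk(1, cbind(0, 0, 0)); b1 <- mk(1, cbind(0, 0, 300))
  p <- pair_and_colocalize(a1, b1)
  expect_equal(nrow(p), 1); expect_true(p$colocalized)
  expect_equal(p$distance_nm, 300)
  b2 <- mk(1, cbind(0, 0, 600))
  expect_false(pair_and_colocalize(a1, b2)$colocalized)
  expect_equal(nrow(pair_and_colocalize(a1[0, ], b1)), 0)
  # symmetry: swapping channels gives the same pair set
  set.seed(23)
  for (rep in 1:20) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    A <- mk(seq_len(na), cbind(runif(na, 0, 500), runif(na, 0, 2000),
                               runif(na, 0, 2000)))
    B <- mk(seq_len(nb), cbind(runif(nb, 0, 500), runif(nb, 0, 2000),
                               runif(nb, 0, 2000)))
    pab <- pair_and_colocalize(A, B)
    pba <- pair_and_colocalize(B, A)
    expect_equal(pab[order(pab$id_a), c("id_a", "id_b", "distance_nm")],
                 setNames(pba[order(pba$id_b),
                              c("id_b", "id_a", "distance_nm")],
                          c("id_a", "id_b", "distance_nm")),
                 ignore_attr = TRUE)
    # colocalized count never exceeds the smaller channel count
    expect_lte(sum(pab$colocalized), min(na, nb))
  }
  # near-tie geometry: greedy agrees with brute-force optimal matching
  A3 <- mk(1:3, cbind(0, c(0, 400, 800), 0))
  B3 <- mk(1:2, cbind(0, c(190, 590), 10))
  g <- pair_and_colocalize(A3, B3)
  o <- pair_spots_optimal(A3, B3)
  expect_equal(g[order(g$id_a), c("id_a", "id_b")],
               o[order(o$id_a), c("id_a", "id_b")], ignore_attr = TRUE)
})

test_that("cell summaries count spots, pairs, singles and keep empty cells", {
  lm <- list(labels = matrix(0L, 2, 2),
             table = data.frame(id = 1:2, area_px = 10, area_um2 = 1,
                                cy = 1, cx = 1))
  class(lm) <- "nucleus_label_map"
  fits <- data.frame(channel = c("A", "A", "B", "B"),
                     nucleus_id = c(1, 1, 1, 1))
  pairs <- data.frame(id_a = 1:2, id_b = 1:2, distance_nm = c(100, 200),
                      colocalized = c(TRUE, TRUE), nucleus_id = 1)
  s <- summarize_cells(lm, fits, pairs)
  expect_equal(s$cells$n_A, c(2, 0))
  expect_equal(s$cells$single_A, c(0, 0))
  expect_equal(s$cells$n_coloc, c(2, 0))
  expect_equal(s$cells$coloc_ratio_A[1], 1)
  expect_equal(nrow(s$cells), 2)  # the spotless cell is retained
  expect_true(is.na(s$cells$coloc_ratio_A[2]))
  bad <- data.frame(channel = "A", nucleus_id = 9)
  expect_error(summarize_cells(lm, bad, pairs[0, ]), "unknown nucleus")
})

test_that("density-series quantification anchors the stated normalizations", {
  ds <- make_density_series_scene(ratios = c(0, 0.25, 0.5, 1), seed = 19,
                                  n_cells = 4)
  stacks <- lapply(ds$scenes, render_scene)
  q <- quantify_density_series(stacks, c(0, 0.25, 0.5, 1), ds$bg_roi)
  expect_equal(q$conditions$ref_norm[q$conditions$ratio == 1], 1)
  expect_equal(q$conditions$bright_norm[q$conditions$ratio == 0.25], 1)
  # reference (binding) channel is ratio-independent within noise
  expect_true(all(abs(q$conditions$ref_norm - 1) < 0.15))
  # brightness rises with the labeling ratio
  expect_true(all(diff(q$conditions$mean_bright) > 0))
  expect_error(quantify_density_series(stacks[1:3], c(0, 0.25, 0.5),
                                       ds$bg_roi), "100%")
})
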