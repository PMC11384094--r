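#' Pair two-channel spots and flag colocalization
#'
#' Greedy mutual-nearest-neighbor matching: the globally closest unpaired
#' (A, B) spot pair is matched repeatedly until one channel is exhausted.
#' Each spot enters at most one pair; distance ties are broken by the lower A
#' id, then the lower B id, so the result is deterministic and symmetric in
#' the two channels. Pairs closer than `threshold_nm` are flagged
#' colocalized (two detections of the same locus).
#'
#' @param spots_a,spots_b data.frames with columns `id`, `z_nm`, `y_nm`,
#'   `x_nm` (e.g. converged [fit_spots()] rows of one cell).
#' @param threshold_nm Colocalization radius in nm (default 500).
#' @return data.frame `id_a`, `id_b`, `distance_nm`, `colocalized`; empty
#'   inputs give an empty table.
#' @export
pair_and_colocalize <- function(spots_a, spots_b, threshold_nm = 500) {
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      distance_nm = numeric(0), colocalized = logical(0))
  na <- nrow(spots_a); nb <- nrow(spots_b)
  if (!na || !nb) return(empty)
  pa <- as.matrix(spots_a[, c("z_nm", "y_nm", "x_nm")])
  pb <- as.matrix(spots_b[, c("z_nm", "y_nm", "x_nm")])
  D <- sqrt(outer(pa[, 1], pb[, 1], `-`)^2 +
            outer(pa[, 2], pb[, 2], `-`)^2 +
            outer(pa[, 3], pb[, 3], `-`)^2)
  ord_a <- order(spots_a$id); ord_b <- order(spots_b$id)
  D <- D[ord_a, ord_b, drop = FALSE]
  ids_a <- spots_a$id[ord_a]; ids_b <- spots_b$id[ord_b]
  pairs <- list()
  free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
  for (k in seq_len(min(na, nb))) {
    sub <- D
    sub[!free_a, ] <- Inf
    sub[, !free_b] <- Inf
    # which.min on the id-ordered matrix is column-major, so among equal
    # distances the lowest B id wins within the lowest A id's column order;
    # resolve ties explicitly: lowest A id first, then lowest B id
    mn <- min(sub)
    if (!is.finite(mn)) break
    w <- which(sub == mn, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    i <- w[1, 1]; j <- w[1, 2]
    free_a[i] <- FALSE; free_b[j] <- FALSE
    pairs[[k]] <- data.frame(id_a = ids_a[i], id_b = ids_b[j],
                             distance_nm = mn,
                             colocalized = mn < threshold_nm)
  }
  if (!length(pairs)) return(empty)
  do.call(rbind, pairs)
}

#' Optimal minimum-total-distance pairing (validation mode)
#'
#' Exhaustive search over all assignments of the smaller channel's spots to
#' the larger channel's, minimizing the total pair distance. Intended as a
#' cross-check of [pair_and_colocalize()] on small cells; refuses more than 8
#' spots per channel.
#'
#' @inheritParams pair_and_colocalize
#' @return data.frame like [pair_and_colocalize()].
#' @export
pair_spots_optimal <- function(spots_a, spots_b, threshold_nm = 500) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  if (!na || !nb) return(pair_and_colocalize(spots_a, spots_b, threshold_nm))
  if (na > 8 || nb > 8) {
    stop("optimal matching is exhaustive; limited to <= 8 spots per channel",
         call. = FALSE)
  }
  swap <- na > nb
  s1 <- if (swap) spots_b else spots_a
  s2 <- if (swap) spots_a else spots_b
  n1 <- nrow(s1); n2 <- nrow(s2)
  p1 <- as.matrix(s1[, c("z_nm", "y_nm", "x_nm")])
  p2 <- as.matrix(s2[, c("z_nm", "y_nm", "x_nm")])
  D <- sqrt(outer(p1[, 1], p2[, 1], `-`)^2 +
            outer(p1[, 2], p2[, 2], `-`)^2 +
            outer(p1[, 3], p2[, 3], `-`)^2)
  perms <- all_injections(n1, n2)
  costs <- vapply(perms, function(j) sum(D[cbind(seq_len(n1), j)]),
                  numeric(1))
  best <- perms[[which.min(costs)]]
  d <- D[cbind(seq_len(n1), best)]
  out <- data.frame(
    id_a = if (swap) s2$id[best] else s1$id,
    id_b = if (swap) s1$id else s2$id[best],
    distance_nm = d, colocalized = d < threshold_nm)
  out[order(out$id_a), , drop = FALSE]
}

# all injective maps 1..n1 -> 1..n2 (n1 <= n2)
all_injections <- function(n1, n2) {
  subsets <- utils::combn(n2, n1, simplify = FALSE)
  out <- list()
  perm_all <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perm_all(v[-i]), function(r) c(v[i], r))
    }), recursive = FALSE)
  }
  for (s in subsets) out <- c(out, perm_all(s))
  out
}

#' Per-cell summaries and detectability histograms
#'
#' For each nucleus: spot counts per channel, number of pairs, colocalized
#' pairs, single (unpaired-or-distant) spots per channel and the
#' colocalization ratio per channel (colocalized / total). Cells without any
#' spot are retained as zero rows. Also returns the relative per-cell
#' spot-count histogram per channel.
#'
#' @param label_map A [segment_nuclei()] result.
#' @param fits Converged spot fits with `channel` and `nucleus_id` columns.
#' @param pairs Pair table with `nucleus_id` column (e.g. from
#'   [run_pair_pipeline()] internals).
#' @return list with `cells` (one row per nucleus) and `detectability`
#'   (`channel`, `n_spots`, `n_cells`, `fraction`).
#' @export
summarize_cells <- function(label_map, fits, pairs) {
  ids <- label_map$table$id
  if (nrow(fits)) {
    unknown <- setdiff(unique(fits$nucleus_id), ids)
    if (length(unknown)) {
      stop("spot fit(s) assigned to unknown nucleus id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  channels <- sort(unique(fits$channel))
  if (!length(channels)) channels <- c("A", "B")
  cells <- lapply(ids, function(id) {
    f <- fits[fits$nucleus_id == id, , drop = FALSE]
    p <- pairs[pairs$nucleus_id == id, , drop = FALSE]
    counts <- vapply(channels, function(ch) sum(f$channel == ch), integer(1))
    n_coloc <- sum(p$colocalized)
    row <- data.frame(nucleus_id = id, n_pairs = nrow(p),
                      n_coloc = n_coloc)
    for (i in seq_along(channels)) {
      row[[paste0("n_", channels[i])]] <- counts[i]
      row[[paste0("single_", channels[i])]] <- counts[i] - n_coloc
      row[[paste0("coloc_ratio_", channels[i])]] <-
        if (counts[i] > 0) n_coloc / counts[i] else NA_real_
    }
    row
  })
  cells <- do.call(rbind, cells)
  detect <- do.call(rbind, lapply(channels, function(ch) {
    cnt <- cells[[paste0("n_", ch)]]
    tab <- table(cnt)
    data.frame(channel = ch, n_spots = as.integer(names(tab)),
               n_cells = as.integer(tab),
               fraction = as.integer(tab) / length(cnt))
  }))
  list(cells = cells, detectability = detect)
}

#' Full two-color FISH quantification pipeline
#'
#' Runs the complete analysis on a rendered or loaded stack whose first
#' channel is the counterstain and next two channels are FISH signals:
#' z-maximum projection, Otsu nuclear segmentation (optionally excluding
#' border-touching nuclei), LoG detection per channel within nuclei, subpixel
#' Gaussian fitting, background metrics, per-cell greedy mutual-NN pairing
#' with the colocalization threshold, and per-cell summaries.
#'
#' @param stack A `fish_stack` with at least 3 channels.
#' @param sigma_nm Expected spot size for detection and fitting.
#' @param threshold_nm Colocalization radius (default 500 nm).
#' @param min_area_um2 Minimum nucleus area.
#' @param exclude_border Exclude nuclei touching the image border
#'   (default TRUE: only entirely imaged nuclei are analyzed).
#' @param k_mad LoG threshold multiplier.
#' @return list: `label_map`, `spots` (converged fits, both channels, with
#'   metrics), `pairs` (with `nucleus_id`), `cells`, `detectability`.
#' @export
run_pair_pipeline <- function(stack, sigma_nm = c(xy = 60, z = 200),
                              threshold_nm = 500, min_area_um2 = 0.5,
                              exclude_border = TRUE, k_mad = 6) {
  stopifnot(inherits(stack, "fish_stack"), length(stack$channels) >= 3L)
  grid <- stack$grid
  proj <- max_project(stack$channels[[1]])
  lm <- segment_nuclei(proj, grid, min_area_um2 = min_area_um2,
                       exclude_border = exclude_border)
  fish_names <- names(stack$channels)[2:3]
  all_fits <- list()
  for (ch in fish_names) {
    a <- stack$channels[[ch]]
    cand <- detect_spots_log(a, lm, grid, sigma_nm = sigma_nm, k_mad = k_mad)
    fits <- fit_spots(a, cand, grid, sigma_start_nm = sigma_nm)
    bg <- nucleus_background_stats(a, lm, cand, grid, sigma_nm = sigma_nm)
    fits <- spot_metrics(fits, bg)
    fits$channel <- rep(ch, nrow(fits))
    all_fits[[ch]] <- fits[fits$status == "converged", , drop = FALSE]
  }
  spots <- do.call(rbind, all_fits)
  rownames(spots) <- NULL
  spots$id <- seq_len(nrow(spots))
  pairs <- list()
  for (id in lm$table$id) {
    sa <- spots[spots$channel == fish_names[1] & spots$nucleus_id == id, ]
    sb <- spots[spots$channel == fish_names[2] & spots$nucleus_id == id, ]
    p <- pair_and_colocalize(sa, sb, threshold_nm = threshold_nm)
    if (nrow(p)) {
      p$nucleus_id <- id
      pairs[[length(pairs) + 1L]] <- p
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_a = integer(0), id_b = integer(0),
               distance_nm = numeric(0), colocalized = logical(0),
               nucleus_id = integer(0))
  summ <- summarize_cells(lm, spots, pairs)
  list(label_map = lm, spots = spots, pairs = pairs, cells = summ$cells,
       detectability = summ$detectability)
}
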