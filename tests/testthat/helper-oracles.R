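# Independent oracles and shared fixtures for the test suite.

# character-by-character reverse complement, independent of the package path
rc_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

# brute-force cytosine-spacing check by position scan
c_spacing_oracle <- function(seq, period = 10L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(b)) {
    at_period <- (i %% period) == 0L
    if (at_period && b[i] != "C") return(FALSE)
    if (!at_period && b[i] == "C") return(FALSE)
  }
  TRUE
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive dye-count pmf over all 2^n labeling patterns
dye_pmf_oracle <- function(n, p) {
  pmf <- numeric(n + 1)
  for (m in 0:(2^n - 1)) {
    k <- sum(bitwAnd(m, 2^(0:(n - 1))) > 0)
    pmf[k + 1] <- pmf[k + 1] + p^k * (1 - p)^(n - k)
  }
  pmf
}

# exhaustive mean predicted brightness over all 2^n labeling patterns
brightness_oracle <- function(sites, p, curve) {
  n <- length(sites)
  total <- 0
  for (m in 0:(2^n - 1)) {
    on <- bitwAnd(m, 2^(0:(n - 1))) > 0
    w <- p^sum(on) * (1 - p)^(n - sum(on))
    total <- total + w * predicted_relative_brightness(sites[on], curve)
  }
  total
}

# shared 200-cell pair scene result, computed once per test run
.pair_cache <- new.env(parent = emptyenv())
get_pair_scene_result <- function() {
  if (is.null(.pair_cache$res)) {
    cfg <- pair_scene_config(n_cells = 200, coloc_fraction = 0.5,
                             distance_dist = list(kind = "point",
                                                  value = 300),
                             amplitude = c(70, 70))
    scene <- make_pair_scene(cfg, seed = 7L)
    stack <- render_scene(scene)
    .pair_cache$scene <- scene
    .pair_cache$res <- run_pair_pipeline(stack)
  }
  list(scene = .pair_cache$scene, res = .pair_cache$res)
}
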