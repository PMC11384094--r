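#' Count labelable cytosines in the extension region of a probe
#'
#' During primer extension only bases synthesized beyond the primer can be
#' drawn from the labeled dCTP pool, so the labelable sites of a probe are the
#' cytosines of `full_seq` strictly after the primer region. For the 40-nt
#' polymerase-screen probe with a 20-nt primer this count is 8, the maximum
#' number of dyes that probe can carry.
#'
#' @param probe A [probe_oligo()] or DNA string.
#' @param primer_len Primer length in nt.
#' @return Integer count of labelable C positions.
#' @export
count_labelable_sites <- function(probe, primer_len) {
  length(labelable_positions(probe, primer_len))
}

#' Labelable cytosine positions of a probe
#' @inheritParams count_labelable_sites
#' @return Integer vector of 1-based positions in `full_seq`.
#' @export
labelable_positions <- function(probe, primer_len) {
  full_seq <- probe_full_seq(probe)
  primer_len <- as.integer(primer_len)
  if (primer_len > nchar(full_seq)) {
    stop("primer_len exceeds probe length", call. = FALSE)
  }
  pos <- base_positions(full_seq, "C")
  pos[pos > primer_len]
}

#' Labeling reaction parameters
#'
#' Describes a probe-synthesis reaction for absorbance-based quantification:
#' the labeled:unlabeled dCTP ratio and the spectral constants of the dye and
#' oligo needed for degree-of-labeling estimation.
#'
#' @param ratio_labeled Fraction of dCTP that is dye-labeled, in `[0, 1]`
#'   (the 0/25/50/75/100 percent series).
#' @param dye Dye name; when it matches a row of [atto_dye_registry()] the
#'   registry values fill any missing constants.
#' @param cf260 Dye correction factor at 260 nm (fraction of the dye-max
#'   absorbance that the dye contributes at 260 nm).
#' @param eps_dye Molar extinction of the dye at its absorption maximum
#'   (1/(M cm)).
#' @param eps_oligo Molar extinction of the oligo at 260 nm (1/(M cm)).
#' @return A `labeling_reaction` list.
#' @export
labeling_reaction <- function(ratio_labeled, dye = NA_character_,
                              cf260 = NULL, eps_dye = NULL,
                              eps_oligo = 4e5) {
  if (ratio_labeled < 0 || ratio_labeled > 1) {
    stop("ratio_labeled must be in [0, 1]", call. = FALSE)
  }
  reg <- atto_dye_registry()
  if (!is.na(dye) && dye %in% reg$dye) {
    row <- reg[reg$dye == dye, ]
    if (is.null(cf260)) cf260 <- row$cf260
    if (is.null(eps_dye)) eps_dye <- row$eps_dye
  }
  if (is.null(cf260) || is.null(eps_dye)) {
    stop("cf260 and eps_dye must be given for dye '", dye, "'", call. = FALSE)
  }
  stopifnot(cf260 >= 0, eps_dye > 0, eps_oligo > 0)
  structure(list(ratio_labeled = ratio_labeled, dye = dye, cf260 = cf260,
                 eps_dye = eps_dye, eps_oligo = eps_oligo),
            class = "labeling_reaction")
}

#' Registry of ATTO dye spectral constants
#'
#' The 260 nm correction factors are the ones used for absorbance
#' quantification of synthesized probes (ATTO488 0.22, ATTO594 0.22,
#' ATTO647N 0.04). The extinction coefficients at the dye absorption maxima
#' are vendor-published typical values, not measured here.
#'
#' @return A data.frame with columns `dye`, `cf260`, `eps_dye`.
#' @export
atto_dye_registry <- function() {
  data.frame(
    dye = c("ATTO488", "ATTO594", "ATTO647N"),
    cf260 = c(0.22, 0.22, 0.04),
    eps_dye = c(9.0e4, 1.2e5, 1.5e5)
  )
}

#' Molar extinction of an oligo at 260 nm from its sequence
#'
#' Simple base-composition sum using standard monomer extinction
#' coefficients (A 15400, C 7400, G 11500, T 8700 1/(M cm)); ignores
#' nearest-neighbor effects.
#'
#' @param seq DNA string.
#' @return Extinction coefficient in 1/(M cm).
#' @export
eps_oligo_from_seq <- function(seq) {
  seq <- normalize_dna(seq)
  eps <- c(A = 15400, C = 7400, G = 11500, T = 8700)
  sum(eps[strsplit(seq, "", fixed = TRUE)[[1L]]])
}

#' Distribution of incorporated dye counts per probe
#'
#' Under site-independent incorporation, each labelable cytosine carries a dye
#' with probability equal to the labeled fraction `p` of the dCTP pool, so the
#' number of dyes per probe is Binomial(`n_sites`, `p`). This reproduces the
#' multi-species product (distinct dye counts per molecule) seen when probes
#' are synthesized at intermediate labeling ratios.
#'
#' @param n_sites Number of labelable cytosines.
#' @param p Labeled fraction in `[0, 1]`.
#' @return A `dye_count_distribution`: `n_sites`, `p`, `pmf` (probabilities
#'   over k = 0..n_sites), `mean`.
#' @examples
#' d <- dye_count_distribution(8, 0.25)
#' d$mean        # 2
#' d$pmf[3]      # P(k = 2) ~ 0.3115
#' @export
dye_count_distribution <- function(n_sites, p) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 0L) stop("n_sites must be >= 0", call. = FALSE)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  pmf <- stats::dbinom(0:n_sites, n_sites, p)
  structure(list(n_sites = n_sites, p = p,
                 pmf = pmf / sum(pmf), mean = n_sites * p),
            class = "dye_count_distribution")
}

#' Expected number of incorporated dyes
#' @inheritParams dye_count_distribution
#' @return `n_sites * p`.
#' @export
expected_dye_count <- function(n_sites, p) {
  dye_count_distribution(n_sites, p)$mean
}

#' Distance-dependent quenching curve
#'
#' Relative emission efficiency of a dye as a function of its separation (in
#' bases) from the nearest neighboring dye. Efficiency must be nondecreasing
#' in separation and is clamped to `[0, 1]`; evaluation interpolates linearly
#' between the supplied points and extrapolates as constant. The default
#' (no points) is the identity curve, efficiency 1 at all separations, i.e.
#' no quenching.
#'
#' @param separations Numeric vector of dye-dye separations in bases
#'   (e.g. the measured 1, 3, 5, 7, 10 series), or `NULL` for no quenching.
#' @param efficiencies Matching relative efficiencies in `[0, 1]`,
#'   nondecreasing.
#' @param dye Optional dye name.
#' @return A `quench_curve` object, callable through [quench_efficiency()].
#' @export
quench_curve <- function(separations = NULL, efficiencies = NULL,
                         dye = NA_character_) {
  if (is.null(separations)) {
    return(structure(list(separations = numeric(0),
                          efficiencies = numeric(0), dye = dye),
                     class = "quench_curve"))
  }
  ord <- order(separations)
  separations <- as.numeric(separations)[ord]
  efficiencies <- pmin(1, pmax(0, as.numeric(efficiencies)[ord]))
  stopifnot(length(separations) == length(efficiencies),
            !anyDuplicated(separations))
  if (is.unsorted(efficiencies)) {
    stop("quench efficiencies must be nondecreasing in separation",
         call. = FALSE)
  }
  structure(list(separations = separations, efficiencies = efficiencies,
                 dye = dye),
            class = "quench_curve")
}

#' Evaluate a quenching curve
#' @param curve A [quench_curve()].
#' @param separation Dye-dye separations in bases.
#' @return Relative efficiencies in `[0, 1]`.
#' @export
quench_efficiency <- function(curve, separation) {
  stopifnot(inherits(curve, "quench_curve"))
  if (length(curve$separations) == 0L) return(rep(1, length(separation)))
  if (length(curve$separations) == 1L) {
    return(rep(curve$efficiencies, length(separation)))
  }
  stats::approx(curve$separations, curve$efficiencies, xout = separation,
                rule = 2)$y
}

#' Predicted relative brightness of a labeling pattern
#'
#' Each dye emits at the efficiency given by the quenching curve evaluated at
#' its distance (in bases) to the nearest other dye; the probe brightness is
#' the sum over dyes. A single dye has no neighbor and emits at efficiency 1;
#' with no quenching the brightness equals the dye count. Multi-body effects
#' beyond the nearest neighbor are ignored.
#'
#' @param labeled_positions Sorted distinct 1-based dye positions.
#' @param curve A [quench_curve()].
#' @return Relative brightness (>= 0); 0 for an empty pattern.
#' @export
predicted_relative_brightness <- function(labeled_positions,
                                          curve = quench_curve()) {
  pos <- as.numeric(labeled_positions)
  n <- length(pos)
  if (n == 0L) return(0)
  if (anyDuplicated(pos) || is.unsorted(pos)) {
    stop("labeled_positions must be sorted and distinct", call. = FALSE)
  }
  if (n == 1L) return(1)
  gaps <- diff(pos)
  nn <- pmin(c(gaps[1], pmin(gaps[-length(gaps)], gaps[-1]), gaps[n - 1L]),
             Inf)
  sum(quench_efficiency(curve, nn))
}

#' Degree of labeling from absorbance
#'
#' Average number of dyes per oligo estimated from the absorbance at the dye
#' maximum and at 260 nm. The dye's own contribution at 260 nm is removed
#' with the dye correction factor before converting to molar ratios:
#' `DOL = (a_dye / eps_dye) / ((a260 - cf260 * a_dye) / eps_oligo)`.
#'
#' @param a260 Absorbance at 260 nm.
#' @param a_dye Absorbance at the dye absorption maximum.
#' @param reaction A [labeling_reaction()] supplying `cf260`, `eps_dye`,
#'   `eps_oligo`.
#' @return Dyes per oligo (0 when `a_dye` is 0). The estimate is invariant
#'   under joint rescaling of both absorbances.
#' @export
degree_of_labeling <- function(a260, a_dye, reaction) {
  stopifnot(inherits(reaction, "labeling_reaction"), a260 >= 0, a_dye >= 0)
  if (a_dye == 0) return(0)
  corrected_a260 <- a260 - reaction$cf260 * a_dye
  if (corrected_a260 <= 0) {
    stop("dye absorbance exceeds DNA signal: corrected A260 = ",
         signif(corrected_a260, 4), call. = FALSE)
  }
  (a_dye / reaction$eps_dye) / (corrected_a260 / reaction$eps_oligo)
}

#' Raw dye:DNA absorbance ratio
#'
#' The uncorrected-units companion to [degree_of_labeling()]: the dye
#' absorbance over the dye-corrected 260 nm absorbance, without conversion to
#' molar ratios. Useful when extinction coefficients are not trusted.
#'
#' @inheritParams degree_of_labeling
#' @return `a_dye / (a260 - cf260 * a_dye)`.
#' @export
dye_dna_absorbance_ratio <- function(a260, a_dye, reaction) {
  stopifnot(inherits(reaction, "labeling_reaction"))
  if (a_dye == 0) return(0)
  corrected_a260 <- a260 - reaction$cf260 * a_dye
  if (corrected_a260 <= 0) {
    stop("dye absorbance exceeds DNA signal", call. = FALSE)
  }
  a_dye / corrected_a260
}

#' Mean predicted brightness versus labeling density
#'
#' Monte-Carlo expectation of [predicted_relative_brightness()] when each
#' labelable site of a probe independently carries a dye with probability
#' equal to the labeling ratio. With no quenching the mean reduces to
#' `n_sites * ratio`; with quenching, densely labeled probes fall below that
#' line because neighboring dyes partially quench each other.
#'
#' @param probe A [probe_oligo()] or DNA string.
#' @param primer_len Primer length delimiting the labelable region.
#' @param curve A [quench_curve()].
#' @param ratios Labeling ratios to evaluate (default the 0-100 percent
#'   series).
#' @param seed RNG seed.
#' @param n_draws Monte-Carlo draws per ratio (>= 1).
#' @return A data.frame with columns `ratio`, `mean_brightness`,
#'   `expected_dyes` (= n_sites * ratio) and `n_draws`.
#' @export
brightness_vs_density_curve <- function(probe, primer_len,
                                        curve = quench_curve(),
                                        ratios = c(0, 0.25, 0.5, 0.75, 1),
                                        seed = 0L, n_draws = 2000L) {
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  if (any(ratios < 0 | ratios > 1)) {
    stop("ratios must be in [0, 1]", call. = FALSE)
  }
  sites <- labelable_positions(probe, primer_len)
  n <- length(sites)
  means <- with_seed(seed, vapply(ratios, function(r) {
    if (n == 0L || r == 0) return(0)
    draws <- matrix(stats::runif(n_draws * n) < r, nrow = n_draws)
    mean(apply(draws, 1L, function(on) {
      predicted_relative_brightness(sites[on], curve)
    }))
  }, numeric(1)))
  data.frame(ratio = ratios, mean_brightness = means,
             expected_dyes = n * ratios, n_draws = as.integer(n_draws))
}
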