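#' Probe oligonucleotide
#'
#' A FISH probe consisting of a genome-binding sequence plus zero or more
#' 10-base extension units appended at the 3' end. Each unit ends in a single
#' cytosine and contains no other C, so that during enzymatic synthesis with
#' dye-labeled dCTP every unit contributes exactly one labelable position at a
#' fixed 10-base spacing.
#'
#' @param id Probe identifier.
#' @param binding_seq Genome-binding DNA sequence.
#' @param extension_units Number of appended 10-mer units (0-3 typical).
#' @param unit_seq The 10-base unit sequence (ignored when
#'   `extension_units = 0`).
#' @param dye Dye name carried at the labelable cytosines, or `NA`.
#' @return A `probe_oligo` object with fields `id`, `binding_seq`,
#'   `extension_units`, `unit_seq`, `full_seq`, `dye`, `labeled_positions`
#'   (1-based positions in `full_seq` of the unit cytosines).
#' @seealso [assemble_xnova()] for unit generation, [build_template_primer()]
#'   for the synthesis template.
#' @export
probe_oligo <- function(id, binding_seq, extension_units = 0L,
                        unit_seq = NA_character_, dye = NA_character_) {
  binding_seq <- normalize_dna(binding_seq, "binding_seq")
  extension_units <- as.integer(extension_units)
  stopifnot(extension_units >= 0L)
  if (extension_units > 0L) {
    unit_seq <- validate_extension_unit(unit_seq)
    full_seq <- paste0(binding_seq, strrep(unit_seq, extension_units))
    labeled <- nchar(binding_seq) + 10L * seq_len(extension_units)
  } else {
    full_seq <- binding_seq
    labeled <- integer(0)
  }
  structure(
    list(id = as.character(id), binding_seq = binding_seq,
         extension_units = extension_units, unit_seq = unit_seq,
         full_seq = full_seq, dye = dye, labeled_positions = labeled),
    class = "probe_oligo"
  )
}

#' @export
print.probe_oligo <- function(x, ...) {
  cat(sprintf("<probe_oligo> %s: %d nt (%d nt binding + %d x 10-mer unit)\n",
              x$id, nchar(x$full_seq), nchar(x$binding_seq),
              x$extension_units))
  cat(" full_seq:", x$full_seq, "\n")
  if (length(x$labeled_positions)) {
    cat(" labelable C at:", paste(x$labeled_positions, collapse = ", "), "\n")
  }
  invisible(x)
}

# unit must be a 10-mer whose only C is the final base
validate_extension_unit <- function(unit_seq) {
  unit_seq <- normalize_dna(unit_seq, "unit_seq")
  if (nchar(unit_seq) != 10L) {
    stop("extension unit must be 10 bases, got ", nchar(unit_seq),
         call. = FALSE)
  }
  if (substr(unit_seq, 10L, 10L) != "C") {
    stop("extension unit must end in C", call. = FALSE)
  }
  if (grepl("C", substr(unit_seq, 1L, 9L), fixed = TRUE)) {
    stop("extension unit must not contain interior C ",
         "(one labelable position per unit)", call. = FALSE)
  }
  unit_seq
}

#' Assemble an extended probe with labeled 10-mer units
#'
#' Builds a probe whose 3' end carries `n_units` copies of a 10-base unit of
#' the form `NNNNNNNNNC`: nine non-cytosine bases followed by one cytosine.
#' With `unit_seq = "auto"` the nine N positions are drawn uniformly from
#' A/G/T under `seed`, guaranteeing exactly one labelable C per unit spaced
#' 10 bases apart. A 40-nt binding sequence with 1-3 units yields 50-70 nt
#' probes.
#'
#' @param binding_seq Genome-binding sequence (30-45 nt recommended).
#' @param n_units Number of extension units, 0-3 (values above 3 are allowed
#'   with a warning).
#' @param unit_seq A 10-mer ending in its only C, or `"auto"`.
#' @param seed RNG seed used when `unit_seq = "auto"`.
#' @param id,dye Passed to [probe_oligo()].
#' @return A [probe_oligo()].
#' @examples
#' p <- assemble_xnova(strrep("AT", 20), n_units = 3)
#' nchar(p$full_seq)  # 70
#' @export
assemble_xnova <- function(binding_seq, n_units, unit_seq = "auto", seed = 0L,
                           id = "xnova", dye = NA_character_) {
  binding_seq <- normalize_dna(binding_seq, "binding_seq")
  n_units <- as.integer(n_units)
  if (n_units < 0L) stop("n_units must be >= 0", call. = FALSE)
  if (n_units > 3L) {
    warning("n_units > 3 is outside the characterized range", call. = FALSE)
  }
  bl <- nchar(binding_seq)
  if (bl < 30L || bl > 45L) {
    warning("binding_seq length ", bl, " outside the typical 30-45 nt range",
            call. = FALSE)
  }
  if (n_units > 0L && identical(unit_seq, "auto")) {
    unit_seq <- with_seed(seed, paste0(
      paste(sample(c("A", "G", "T"), 9L, replace = TRUE), collapse = ""), "C"))
  }
  probe_oligo(id, binding_seq, extension_units = n_units, unit_seq = unit_seq,
              dye = dye)
}

#' Template/primer pair for enzymatic probe synthesis
#'
#' A probe is synthesized by annealing a short primer to a 5'-phosphorylated
#' template (the reverse complement of the desired probe) and extending with a
#' polymerase in the presence of dye-labeled dCTP; the phosphorylated template
#' is afterwards removed by lambda exonuclease. This function derives the pair
#' from a probe: 20-nt primers pair with 40-nt templates for plain probes, and
#' 40-nt primers with 50-70 nt templates for extended probes.
#'
#' @param probe A [probe_oligo()] or a plain DNA string (the probe full
#'   sequence).
#' @param primer_len Primer length in nt; must be shorter than the probe.
#' @return A `template_primer_pair`: `template_seq` (reverse complement of the
#'   probe), `is_phosphorylated = TRUE`, `primer_seq` (first `primer_len`
#'   bases of the probe), `primer_len`.
#' @export
build_template_primer <- function(probe, primer_len = 20L) {
  full_seq <- probe_full_seq(probe)
  primer_len <- as.integer(primer_len)
  if (primer_len < 1L) stop("primer_len must be positive", call. = FALSE)
  if (primer_len >= nchar(full_seq)) {
    stop("primer_len (", primer_len, ") >= probe length (", nchar(full_seq),
         "): nothing to extend", call. = FALSE)
  }
  structure(
    list(template_seq = reverse_complement(full_seq),
         is_phosphorylated = TRUE,
         primer_seq = substr(full_seq, 1L, primer_len),
         primer_len = primer_len),
    class = "template_primer_pair"
  )
}

#' @export
print.template_primer_pair <- function(x, ...) {
  cat(sprintf("<template_primer_pair> %d nt template (5'-phos), %d nt primer\n",
              nchar(x$template_seq), x$primer_len))
  cat(" template:", x$template_seq, "\n primer:  ", x$primer_seq, "\n")
  invisible(x)
}

probe_full_seq <- function(probe) {
  if (inherits(probe, "probe_oligo")) probe$full_seq
  else normalize_dna(probe, "probe sequence")
}

#' Simulate the primer-extension reaction
#'
#' Checks that the primer anneals perfectly to the 3' end of the template,
#' then extends it to the full product (the original probe sequence) and
#' reports which product positions can carry a dye: positions of
#' `labeled_base` strictly after the primer region, since the primer itself is
#' unlabeled.
#'
#' @param pair A [build_template_primer()] result.
#' @param labeled_base The nucleotide supplied in labeled form (default `"C"`,
#'   for dCTP-dye).
#' @return A list with `product` (DNA string), `labelable_positions` (1-based
#'   in the product) and `n_labelable`.
#' @export
simulate_extension <- function(pair, labeled_base = "C") {
  stopifnot(inherits(pair, "template_primer_pair"))
  labeled_base <- normalize_dna(labeled_base, "labeled_base")
  stopifnot(nchar(labeled_base) == 1L)
  product <- reverse_complement(pair$template_seq)
  anneal_site <- substr(product, 1L, pair$primer_len)
  if (!identical(anneal_site, pair$primer_seq)) {
    stop("primer does not anneal: primer ", pair$primer_seq,
         " is not complementary to the template 3' end (expected ",
         anneal_site, ")", call. = FALSE)
  }
  pos <- base_positions(product, labeled_base)
  pos <- pos[pos > pair$primer_len]
  list(product = product, labelable_positions = pos, n_labelable = length(pos))
}
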