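#' Normalize a DNA sequence string
#'
#' Uppercases the input and maps U to T (with a warning), then validates the
#' alphabet. All sequence-handling functions in the package call this on
#' ingest, so lowercase or RNA-style input is accepted everywhere.
#'
#' @param seq A single character string.
#' @param what Label used in error messages.
#' @return The normalized sequence (uppercase, alphabet ACGT).
#' @export
normalize_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!nzchar(seq)) stop(what, " must be non-empty", call. = FALSE)
  out <- toupper(seq)
  if (grepl("U", out, fixed = TRUE)) {
    warning(what, " contains U; mapped to T", call. = FALSE)
    out <- gsub("U", "T", out, fixed = TRUE)
  }
  bad <- regexpr("[^ACGT]", out)
  if (bad > 0L) {
    stop("invalid alphabet in ", what, ": character '",
         substr(out, bad, bad), "' at position ", bad, call. = FALSE)
  }
  out
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement, used to derive synthesis templates from
#' probe sequences. Applying the function twice returns the input.
#'
#' @param seq DNA string (case-insensitive; U accepted as T with a warning).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC content of a sequence
#' @param seq DNA string.
#' @return Fraction of G or C bases in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- normalize_dna(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(b %in% c("G", "C"))
}

#' Longest homopolymer run
#' @param seq DNA string.
#' @return Length of the longest run of a single base.
#' @export
max_homopolymer_run <- function(seq) {
  seq <- normalize_dna(seq)
  max(rle(strsplit(seq, "", fixed = TRUE)[[1L]])$lengths)
}

# 1-based positions of a base within a sequence
base_positions <- function(seq, base = "C") {
  which(strsplit(seq, "", fixed = TRUE)[[1L]] == base)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}
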