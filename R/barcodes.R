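#' Cytosine-spacing filter for barcode sequences
#'
#' Barcodes read out through dye-labeled cytosines need a C exactly every
#' `period` bases and nowhere else, so that incorporated dyes sit at a fixed
#' spacing. The predicate is TRUE iff every position that is a multiple of
#' `period` (1-based) carries a C and no other position does.
#'
#' @param seq DNA string.
#' @param period Spacing in bases (default 10).
#' @return TRUE or FALSE.
#' @examples
#' check_c_spacing("AAAAAAAAAC")            # TRUE
#' check_c_spacing("CAAAAAAAAA")            # FALSE
#' @export
check_c_spacing <- function(seq, period = 10L) {
  seq <- normalize_dna(seq)
  period <- as.integer(period)
  stopifnot(period >= 1L)
  cpos <- base_positions(seq, "C")
  expected <- seq_len(nchar(seq) %/% period) * period
  identical(as.integer(cpos), as.integer(expected))
}

#' Merge two orthogonal sequences into a barcode
#'
#' Candidate barcodes are formed by concatenating a pair of orthogonal parent
#' sequences, trimming to the required length, and keeping only candidates
#' that pass the cytosine-spacing filter ([check_c_spacing()]). Rejected
#' candidates are still returned, flagged, so a caller screening many pairs
#' can count acceptances.
#'
#' @param parent_a,parent_b Parent DNA strings.
#' @param out_len Barcode length after trimming; the concatenation must be at
#'   least this long. A length that is not a multiple of `period` triggers a
#'   warning (the trailing partial period carries no labelable C).
#' @param period Cytosine spacing (default 10).
#' @return A `barcode_spec`: `parent_a`, `parent_b`, `merged`, `period`,
#'   `accepted`.
#' @export
merge_orthogonal_barcodes <- function(parent_a, parent_b, out_len,
                                      period = 10L) {
  parent_a <- normalize_dna(parent_a, "parent_a")
  parent_b <- normalize_dna(parent_b, "parent_b")
  out_len <- as.integer(out_len)
  if (out_len < 1L) stop("out_len must be positive", call. = FALSE)
  if (out_len %% period != 0L) {
    warning("out_len ", out_len, " is not a multiple of the period ", period,
            call. = FALSE)
  }
  concat <- paste0(parent_a, parent_b)
  if (nchar(concat) < out_len) {
    stop("parents too short: concatenated length ", nchar(concat),
         " < out_len ", out_len, call. = FALSE)
  }
  merged <- substr(concat, 1L, out_len)
  structure(
    list(parent_a = parent_a, parent_b = parent_b, merged = merged,
         period = as.integer(period),
         accepted = check_c_spacing(merged, period)),
    class = "barcode_spec"
  )
}

#' @export
print.barcode_spec <- function(x, ...) {
  cat(sprintf("<barcode_spec> %d nt, period %d, %s\n", nchar(x$merged),
              x$period, if (x$accepted) "accepted" else "rejected"))
  cat(" ", x$merged, "\n")
  invisible(x)
}
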