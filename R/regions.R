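#' Genomic target region
#'
#' A region on a chromosome, stored internally in 0-based half-open (BED)
#' convention. Coordinates printed in publications are conventionally 1-based
#' inclusive; pass `basis = "1-based"` for those and the constructor converts
#' on ingest, so that round trips between the two conventions are lossless.
#'
#' @param chrom Chromosome name, e.g. `"chr11"`.
#' @param start,end Integer base positions in the convention given by `basis`.
#' @param basis `"1-based"` (inclusive, as printed) or `"bed"`
#'   (0-based half-open).
#' @param assembly Free-text genome assembly tag (e.g. `"hg38"`), or `NA`.
#' @return A `genomic_region` object with 0-based half-open `start`/`end`.
#' @examples
#' r <- genomic_region("chr11", 55810891, 55816978, basis = "1-based",
#'                     assembly = "hg38")
#' region_span_kb(r)  # 6.1
#' @export
genomic_region <- function(chrom, start, end, basis = c("1-based", "bed"),
                           assembly = NA_character_) {
  basis <- match.arg(basis)
  start <- as.numeric(start); end <- as.numeric(end)
  if (basis == "1-based") {
    start <- start - 1  # half-open: width = end - start = printed inclusive span
  }
  if (end <= start) stop("region has non-positive span", call. = FALSE)
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         assembly = assembly),
    class = "genomic_region"
  )
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%d-%d (1-based %s), %s bp%s\n",
              x$chrom, x$start + 1, x$end,
              if (is.na(x$assembly)) "coords" else x$assembly,
              format(region_width(x), big.mark = ","),
              ""))
  invisible(x)
}

#' Region width in bases
#' @param region A [genomic_region()].
#' @return Integer span in bases (half-open `end - start`).
#' @export
region_width <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  region$end - region$start
}

#' Printed 1-based inclusive coordinates of a region
#' @param region A [genomic_region()].
#' @return Named numeric vector `c(start, end)` in 1-based inclusive form.
#' @export
as_printed_coords <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  c(start = region$start + 1, end = region$end)
}

# round half away from zero at `digits` decimals (contract for printed spans;
# base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Region span in kilobases
#'
#' The span printed for a probe-set target: `(end - start + 1)/1000` of the
#' 1-based inclusive coordinates, rounded to one decimal (half up). This is
#' identical to the half-open width divided by 1000.
#'
#' @param region A [genomic_region()].
#' @return Span in kb, one decimal.
#' @examples
#' region_span_kb(genomic_region("chr1", 1, 1000, basis = "1-based"))  # 1.0
#' @export
region_span_kb <- function(region) {
  w <- region_width(region)
  if (w <= 0) stop("non-positive span", call. = FALSE)
  round_half_up(w / 1000, 1)
}

#' Read target regions from a BED file
#'
#' Thin wrapper around `rtracklayer::import` returning a list of
#' [genomic_region()] objects (BED is already 0-based half-open, so no
#' coordinate shift is applied).
#'
#' @param path Path to a BED file.
#' @param assembly Optional assembly tag attached to every region.
#' @return A list of `genomic_region` objects, named by BED name column when
#'   present.
#' @export
read_regions_bed <- function(path, assembly = NA_character_) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_regions_bed requires the rtracklayer package", call. = FALSE)
  }
  df <- as.data.frame(rtracklayer::import(path, format = "BED"))
  regions <- lapply(seq_len(nrow(df)), function(i) {
    # GRanges holds 1-based inclusive coordinates internally
    genomic_region(as.character(df$seqnames[i]), df$start[i] - 1, df$end[i],
                   basis = "bed", assembly = assembly)
  })
  if (!is.null(df$name)) names(regions) <- df$name
  regions
}
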