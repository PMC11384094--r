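#' Probe selection filters
#'
#' Filter configuration for [select_probes_for_region()]. Defaults follow
#' standard oligo-FISH practice: GC content between 35 and 65 percent, no
#' homopolymer run longer than 5, and (optionally) no binding k-mer present in
#' a user-supplied background set.
#'
#' @param gc_min,gc_max Allowed GC fraction range.
#' @param max_homopolymer Longest allowed single-base run.
#' @param background_kmers Character vector of k-mers that must not occur in a
#'   probe (e.g. repetitive genome k-mers), or `NULL` to skip the check.
#' @param k K-mer length for the background check (default 16).
#' @return A `probe_filters` list.
#' @export
probe_filters <- function(gc_min = 0.35, gc_max = 0.65, max_homopolymer = 5L,
                          background_kmers = NULL, k = 16L) {
  stopifnot(gc_min >= 0, gc_max <= 1, gc_min <= gc_max, max_homopolymer >= 1)
  if (!is.null(background_kmers)) {
    background_kmers <- toupper(background_kmers)
    stopifnot(all(nchar(background_kmers) == k))
  }
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 background_kmers = background_kmers, k = as.integer(k)),
            class = "probe_filters")
}

# TRUE iff a candidate window passes every configured filter
window_passes_filters <- function(seq, filters) {
  if (is.null(filters)) return(TRUE)
  gc <- gc_content(seq)
  if (gc < filters$gc_min || gc > filters$gc_max) return(FALSE)
  if (max_homopolymer_run(seq) > filters$max_homopolymer) return(FALSE)
  if (!is.null(filters$background_kmers)) {
    n <- nchar(seq)
    if (n >= filters$k) {
      for (i in seq_len(n - filters$k + 1L)) {
        if (substr(seq, i, i + filters$k - 1L) %in% filters$background_kmers) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Probe pool with a primer index
#'
#' A collection of probes together with the primer that selectively amplifies
#' each one from a common template pool. Subsets of a synthesized template
#' pool can then be turned into probe sets simply by choosing the matching
#' primers, which [subset_pool()] models.
#'
#' @param probes List of [probe_oligo()] objects with unique ids.
#' @param primer_len Primer length used to build the primer index.
#' @return A `probe_pool` with `probes` (named list) and `primer_index`
#'   (named character vector id -> primer sequence).
#' @export
probe_pool <- function(probes, primer_len = 20L) {
  stopifnot(is.list(probes),
            all(vapply(probes, inherits, logical(1), "probe_oligo")))
  ids <- vapply(probes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("probe ids must be unique", call. = FALSE)
  names(probes) <- ids
  primer_index <- vapply(
    probes, function(p) substr(p$full_seq, 1L, primer_len), character(1))
  structure(list(probes = probes, primer_index = primer_index,
                 primer_len = as.integer(primer_len)),
            class = "probe_pool")
}

#' @export
print.probe_pool <- function(x, ...) {
  cat(sprintf("<probe_pool> %d probes, %d nt primers\n",
              length(x$probes), x$primer_len))
  invisible(x)
}

#' @export
length.probe_pool <- function(x) length(x$probes)

#' Select tiling probes for a target region
#'
#' Greedy leftmost-first tiling: the target is scanned 5' to 3' and each
#' filter-passing window of `probe_len` bases that does not overlap an
#' already-selected probe is taken, until `n_probes` are found or the target
#' is exhausted. The result is deterministic for fixed inputs.
#'
#' @param target_seq Target DNA sequence.
#' @param n_probes Number of probes requested (typically 60 per region).
#' @param probe_len Probe (binding) length in nt, default 40.
#' @param filters A [probe_filters()] object, or `NULL` for none.
#' @param id_prefix Prefix for generated probe ids (`<prefix>001`, ...).
#' @param primer_len Primer length for the pool's primer index.
#' @return A [probe_pool()]; probes carry a `target_start` attribute with the
#'   1-based start offset of each probe in the target. If fewer than
#'   `n_probes` candidates pass, the available ones are returned with a
#'   warning.
#' @export
select_probes_for_region <- function(target_seq, n_probes, probe_len = 40L,
                                     filters = probe_filters(),
                                     id_prefix = "P", primer_len = 20L) {
  target_seq <- normalize_dna(target_seq, "target_seq")
  n_probes <- as.integer(n_probes); probe_len <- as.integer(probe_len)
  stopifnot(n_probes >= 1L, probe_len >= 1L)
  L <- nchar(target_seq)
  starts <- integer(0)
  pos <- 1L
  while (pos + probe_len - 1L <= L && length(starts) < n_probes) {
    win <- substr(target_seq, pos, pos + probe_len - 1L)
    if (window_passes_filters(win, filters)) {
      starts <- c(starts, pos)
      pos <- pos + probe_len
    } else {
      pos <- pos + 1L
    }
  }
  if (length(starts) < n_probes) {
    warning("only ", length(starts), " of ", n_probes,
            " requested probes pass the filters", call. = FALSE)
  }
  probes <- lapply(seq_along(starts), function(i) {
    p <- probe_oligo(sprintf("%s%03d", id_prefix, i),
                     substr(target_seq, starts[i], starts[i] + probe_len - 1L))
    attr(p, "target_start") <- starts[i]
    p
  })
  probe_pool(probes, primer_len = primer_len)
}

#' Subset a probe pool by id
#'
#' Models selective synthesis from a common template pool: adding only the
#' primers for `ids` yields exactly that probe subset (e.g. reducing a
#' 60-probe set to its first 10 probes).
#'
#' @param pool A [probe_pool()].
#' @param ids Character vector of probe ids; may be empty.
#' @return A `probe_pool` containing only the requested probes, in the
#'   requested order.
#' @export
subset_pool <- function(pool, ids) {
  stopifnot(inherits(pool, "probe_pool"))
  ids <- as.character(ids)
  missing <- setdiff(ids, names(pool$probes))
  if (length(missing)) {
    stop("unknown probe ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probe_pool(pool$probes[ids], primer_len = pool$primer_len)
}

#' Write a probe pool as a TSV table
#'
#' One row per probe with columns `id`, `binding_seq`, `unit_seq`, `n_units`,
#' `full_seq`, `template_seq`, `template_phosphorylated`, `primer_seq`,
#' `dye`. The template column is the 5'-phosphorylated synthesis template
#' (reverse complement of `full_seq`).
#'
#' @param pool A [probe_pool()].
#' @param path Output file path; use `""` for stdout.
#' @return The table, invisibly.
#' @export
write_probe_table <- function(pool, path) {
  stopifnot(inherits(pool, "probe_pool"))
  tab <- do.call(rbind, lapply(names(pool$probes), function(id) {
    p <- pool$probes[[id]]
    data.frame(id = id, binding_seq = p$binding_seq,
               unit_seq = ifelse(is.na(p$unit_seq), "", p$unit_seq),
               n_units = p$extension_units, full_seq = p$full_seq,
               template_seq = reverse_complement(p$full_seq),
               template_phosphorylated = TRUE,
               primer_seq = pool$primer_index[[id]],
               dye = ifelse(is.na(p$dye), "", p$dye))
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read a target sequence from FASTA
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_target_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write probe full sequences to FASTA
#' @param pool A [probe_pool()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "probe_pool"))
  seqs <- vapply(pool$probes, `[[`, character(1), "full_seq")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
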