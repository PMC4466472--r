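# Small RNA library I/O: read collapsing, length filtering, exact mapping
# against a reference sequence set, and RPM normalization.
#
# Coordinates are 0-based half-open throughout ([start, end)); GFF3 export
# converts to 1-based closed. A minus-strand hit means the read sequence
# equals the reverse complement of contig[start:end].

#' Collapse raw reads into unique sequences with per-library counts
#'
#' Each unique sequence becomes one record carrying its count in every
#' library. Reads containing characters other than A/C/G/T (after U -> T
#' normalization) are rejected with a warning.
#'
#' @param raw_reads named list, one character vector of reads per library.
#'   Names are the library ids (unnamed lists get `lib1..libk`).
#' @return a `data.frame` of class `srna_reads`, ordered lexicographically
#'   by sequence, with columns `sequence`, `length`, matrix column `counts`
#'   (one column per library), `total_count`, and (until
#'   [rpm_normalize()] is called) an all-`NA` matrix column `rpm` plus
#'   `total_rpm`.
#' @export
collapse_reads <- function(raw_reads) {
  stopifnot(is.list(raw_reads))
  lib_ids <- names(raw_reads)
  if (is.null(lib_ids) || any(!nzchar(lib_ids))) {
    lib_ids <- paste0("lib", seq_along(raw_reads))
  }
  cleaned <- vector("list", length(raw_reads))
  n_rejected <- 0L
  for (i in seq_along(raw_reads)) {
    x <- normalize_seq(as.character(raw_reads[[i]]))
    ok <- !is.na(x) & grepl("^[ACGT]+$", x)
    n_rejected <- n_rejected + sum(!ok)
    cleaned[[i]] <- x[ok]
  }
  if (n_rejected > 0) {
    warning(sprintf("rejected %d read(s) with non-nucleotide characters", n_rejected))
  }
  all_seqs <- sort(unique(unlist(cleaned, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seqs), ncol = length(lib_ids),
                   dimnames = list(NULL, lib_ids))
  for (i in seq_along(cleaned)) {
    if (length(cleaned[[i]]) == 0) next
    tab <- table(cleaned[[i]])
    counts[match(names(tab), all_seqs), i] <- as.integer(tab)
  }
  new_srna_reads(all_seqs, counts)
}

new_srna_reads <- function(sequence, counts, rpm = NULL) {
  stopifnot(length(sequence) == nrow(counts))
  if (is.null(rpm)) {
    rpm <- matrix(NA_real_, nrow = nrow(counts), ncol = ncol(counts),
                  dimnames = dimnames(counts))
  }
  df <- data.frame(sequence = sequence,
                   length = nchar(sequence),
                   total_count = as.integer(rowSums(counts)),
                   stringsAsFactors = FALSE)
  df$counts <- counts
  df$rpm <- rpm
  df$total_rpm <- rowSums(rpm)
  class(df) <- c("srna_reads", "data.frame")
  df
}

#' Filter collapsed reads by sequence length
#'
#' @param reads an `srna_reads` collection.
#' @param min,max inclusive length bounds (default 18-26 nt, the size range
#'   of Dicer products retained for small RNA analysis).
#' @return the filtered `srna_reads` collection; counts are untouched.
#' @export
length_filter <- function(reads, min = 18L, max = 26L) {
  if (min > max) stop("length_filter: min > max")
  keep <- reads$length >= min & reads$length <= max
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an exact-match index over a reference sequence set
#'
#' The reference stands in for a genome-plus-EST sequence library. Matching
#' is exact (perfect matches only) on both strands; `N` in the reference
#' never matches any read base.
#'
#' @param contigs named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @return an object of class `ref_index`.
#' @export
build_index <- function(contigs) {
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(normalize_seq(contigs))
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("build_index: contigs must have unique names")
  }
  structure(list(ref = contigs,
                 lengths = stats::setNames(Biostrings::width(contigs), names(contigs))),
            class = "ref_index")
}

#' Map collapsed reads to a reference by exact matching
#'
#' All perfect-match loci on both strands are enumerated (via
#' Aho-Corasick dictionary matching, one dictionary per read length).
#' Reads hitting more than `max_loci` positions are flagged
#' hyper-repetitive and report zero hits, excluding them from downstream
#' discovery.
#'
#' @param reads an `srna_reads` collection.
#' @param index a `ref_index` from [build_index()].
#' @param max_loci maximum number of loci per read (default 500).
#' @return list with elements
#'   \describe{
#'     \item{hits}{data.frame `sequence`, `contig_id`, `start`, `end`
#'       (0-based half-open), `strand`, sorted by (sequence, contig_id,
#'       start, strand).}
#'     \item{n_loci}{named integer vector, total loci per read sequence
#'       (including hyper-repetitive ones).}
#'     \item{hyper_repetitive}{character vector of flagged sequences.}
#'   }
#' @export
map_exact <- function(reads, index, max_loci = 500L) {
  stopifnot(inherits(index, "ref_index"))
  seqs <- reads$sequence
  if (length(seqs) == 0) {
    return(list(hits = empty_hits(), n_loci = integer(0),
                hyper_repetitive = character(0)))
  }
  pieces <- list()
  for (len in sort(unique(nchar(seqs)))) {
    sub <- seqs[nchar(seqs) == len]
    pieces[[length(pieces) + 1L]] <- match_fixed_width(sub, index, "+")
    pieces[[length(pieces) + 1L]] <- match_fixed_width(sub, index, "-")
  }
  hits <- do.call(rbind, pieces)
  if (is.null(hits) || nrow(hits) == 0) hits <- empty_hits()
  n_loci <- table(factor(hits$sequence, levels = seqs))
  n_loci <- stats::setNames(as.integer(n_loci), seqs)
  hyper <- names(n_loci)[n_loci > max_loci]
  hits <- hits[!(hits$sequence %in% hyper), , drop = FALSE]
  hits <- hits[order(hits$sequence, hits$contig_id, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, n_loci = n_loci, hyper_repetitive = hyper)
}

empty_hits <- function() {
  data.frame(sequence = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

match_fixed_width <- function(seqs, index, strand) {
  patt <- if (strand == "+") seqs else revcomp(seqs)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(patt))
  pieces <- list()
  for (ci in seq_along(index$ref)) {
    m <- Biostrings::matchPDict(pd, index$ref[[ci]])
    cnt <- S4Vectors::elementNROWS(m)
    if (sum(cnt) == 0) next
    ir <- unlist(m)
    pieces[[length(pieces) + 1L]] <- data.frame(
      sequence = rep(seqs, cnt),
      contig_id = names(index$ref)[ci],
      start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir),
      strand = strand,
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(NULL)
  do.call(rbind, pieces)
}

#' Populate RPM (reads per million) normalization
#'
#' @param reads an `srna_reads` collection.
#' @param library_totals named numeric vector of per-library total read
#'   counts used as the denominator (by default, callers use the total of
#'   18-26 nt reference-matching reads in each library).
#' @return `reads` with the `rpm` matrix column and `total_rpm` populated.
#' @export
rpm_normalize <- function(reads, library_totals) {
  lib_ids <- colnames(reads$counts)
  if (!all(lib_ids %in% names(library_totals))) {
    stop("rpm_normalize: library_totals missing for some libraries")
  }
  totals <- library_totals[lib_ids]
  if (any(totals <= 0)) stop("rpm_normalize: zero or negative library total")
  rpm <- sweep(reads$counts, 2, totals, "/") * 1e6
  reads$rpm <- rpm
  reads$total_rpm <- rowSums(rpm)
  reads
}

#' Write collapsed reads as FASTA plus sidecar count table
#'
#' FASTA headers follow the collapsed-read dialect `seq<serial>_x<count>`;
#' the sidecar TSV carries the per-library counts.
#'
#' @param reads an `srna_reads` collection.
#' @param fasta_path,tsv_path output paths.
#' @return invisibly, `fasta_path`.
#' @export
write_collapsed <- function(reads, fasta_path, tsv_path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(reads)), reads$total_count)
  write_fasta(stats::setNames(reads$sequence, ids), fasta_path)
  tab <- data.frame(sequence = reads$sequence, stringsAsFactors = FALSE)
  for (lib in colnames(reads$counts)) tab[[lib]] <- reads$counts[, lib]
  write_tsv_stable(tab, tsv_path)
  invisible(fasta_path)
}

#' Read collapsed reads back from a sidecar count table
#'
#' @param tsv_path path written by [write_collapsed()].
#' @return an `srna_reads` collection.
#' @export
read_collapsed <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  ord <- order(tab$sequence)
  new_srna_reads(tab$sequence[ord], counts[ord, , drop = FALSE])
}
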