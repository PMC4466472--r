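#' @useDynLib phasiforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Nucleotide alphabet used throughout. U is normalized to T on input; all
# internal sequence handling is DNA-alphabet.
VALID_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] for
#' plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalize sequences to uppercase DNA alphabet
#'
#' Uppercases and converts U to T.
#'
#' @param x character vector.
#' @return character vector.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' GC content in percent
#'
#' @param x character vector of sequences.
#' @return numeric vector, percent of G+C bases.
#' @export
gc_percent <- function(x) {
  if (length(x) == 0) return(numeric(0))
  xs <- Biostrings::DNAStringSet(x)
  freq <- Biostrings::alphabetFrequency(xs, baseOnly = TRUE)
  100 * (freq[, "C"] + freq[, "G"]) / Biostrings::width(xs)
}

# Deterministic per-stream seed derivation. Keeps derived seeds positive and
# below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009L + as.numeric(stream) * 9176L) %% 2147483629)
}

#' Read a FASTA file into a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of sequences (U normalized to T).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- normalize_seq(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Write a data.frame as a TSV with stable formatting (no row names, no
# quoting surprises) so that repeated runs are byte-identical.
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Export loci as GFF3
#'
#' Converts internal 0-based half-open coordinates to the 1-based closed
#' convention of GFF3.
#'
#' @param df data.frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `type`, `id`, and optionally `attributes` (extra `key=value` pairs).
#' @param path output path.
#' @param source source field for column 2.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(df, path, source = "phasiforge") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0) {
    attr_col <- paste0("ID=", df$id)
    if (!is.null(df$attributes)) {
      has_extra <- !is.na(df$attributes) & nzchar(df$attributes)
      attr_col[has_extra] <- paste0(attr_col[has_extra], ";", df$attributes[has_extra])
    }
    lines <- paste(df$contig_id, source, df$type,
                   df$start + 1L, df$end, ".", df$strand, ".", attr_col,
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
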