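# Shared fixtures. The small planted dataset and its pipeline run are
# computed once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function() {
  sim_config(n_hairpins = 6L, n_pgts_mirna = 3L, n_pgts_cis = 1L,
             n_pgts_trans = 1L, depth = 2e4, n_decoys = 80L)
}

small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_all(run_config(sim = small_sim_config()),
                                  seed = 17L)
  }
  .fixture_cache$run
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Build an srna_reads collection with prescribed per-library counts by
# expanding raw reads and collapsing them, then normalizing against given
# totals (defaults to 1e6 so RPM == count).
reads_with_counts <- function(seqs, counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  }
  raw <- lapply(seq_len(ncol(counts)), function(j)
    rep(seqs, counts[, j]))
  names(raw) <- colnames(counts)
  r <- collapse_reads(raw)
  if (is.null(totals)) {
    totals <- stats::setNames(rep(1e6, ncol(counts)), colnames(counts))
  }
  rpm_normalize(r, totals)
}

# A transcript with planted in-register (sense + antisense) and
# out-of-register reads, for phasing-detector tests.
make_phase_fixture <- function(sense_counts, nonphased_counts = integer(0),
                               antisense = TRUE, register = 90L) {
  set.seed(55)
  tx <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  pos <- register + 21L * (seq_along(sense_counts) - 1L)
  seqs <- substring(tx, pos + 1L, pos + 21L)
  strands <- rep("+", length(pos))
  counts <- sense_counts
  if (antisense) {
    apos <- register + 21L * seq_len(length(sense_counts) - 1L) + 2L
    aseq <- revcomp(substring(tx, apos - 19L, apos + 1L))
    seqs <- c(seqs, aseq); counts <- c(counts, rep(4L, length(aseq)))
    strands <- c(strands, rep("-", length(aseq)))
  }
  if (length(nonphased_counts) > 0) {
    npos <- register + 5L + 21L * (seq_along(nonphased_counts) - 1L)
    seqs <- c(seqs, substring(tx, npos + 1L, npos + 21L))
    counts <- c(counts, nonphased_counts)
    strands <- c(strands, rep("+", length(npos)))
  }
  reads <- reads_with_counts(seqs, cbind(lib1 = as.integer(counts)))
  idx <- build_index(c(tx = tx))
  hits <- map_exact(reads, idx)$hits
  list(reads = reads, hits = hits, idx = idx, register = register)
}

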