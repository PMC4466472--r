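# Phased siRNA locus detection. Candidate windows are scored with a
# hypergeometric tail probability on occupied 5'-end positions: with M
# candidate positions in a window (both strands), m of them in a given
# 21-nt register (antisense positions participate with a +2 nt offset,
# the DCL 2-nt 3'-overhang geometry), n distinct occupied positions and k
# of those in register, the p-value is P(X >= k) for X hypergeometric.
# Occupancy is binary: abundance enters only through the locus filters.

#' Hypergeometric phasing tail probability
#'
#' @param M total candidate 5' positions in the window (both strands).
#' @param m in-register positions among the M.
#' @param n distinct occupied positions.
#' @param k occupied in-register positions.
#' @return P(X >= k) where X ~ Hypergeometric(M, m, n); 1 when `n = 0` or
#'   `k = 0`.
#' @export
phasing_pvalue <- function(M, m, n, k) {
  stopifnot(all(k <= n), all(n <= M), all(m <= M))
  ifelse(k <= 0, 1, stats::phyper(k - 1, m, M - m, n, lower.tail = FALSE))
}

# 5'-end phase position of a hit: sense reads use their leftmost (start)
# coordinate; antisense reads use the contig coordinate facing their 5'
# nucleotide (end - 1).
phase_position <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

in_register <- function(position, strand, register, cycle = 21L) {
  off <- (position - register) %% cycle
  (strand == "+" & off == 0L) | (strand == "-" & off == 2L)
}

#' Scan mapped reads for phased siRNA windows
#'
#' Slides windows of `window_len` (default 189 nt = 9 cycles) in steps of
#' one cycle across every contig carrying eligible reads, scores each
#' window with [phasing_pvalue()] over all `cycle` possible registers, and
#' reports the register maximizing the in-register occupancy k (ties by
#' smaller p, then smaller register).
#'
#' Callers supply reads already restricted to the phasing input (total
#' abundance >= 2, not derived from miRNA loci).
#'
#' @param reads an `srna_reads` collection (the phasing input set).
#' @param hits mapping table for those reads.
#' @param index the `ref_index`.
#' @param window_len window length, a multiple of `cycle` (default 189).
#' @param cycle phasing cycle length (default 21; 24 supported).
#' @param best_register when `TRUE` (default), each window reports the
#'   register maximizing the in-register occupancy k; its tail
#'   probability is then a best-of-`cycle` statistic and is
#'   anti-conservative under the null (downstream abundance filters
#'   control false locus calls). With `FALSE` the register is fixed at the
#'   window start, giving a calibrated per-window p-value.
#' @return data.frame of scanned windows: `contig_id`, `win_start`,
#'   `win_end`, `register` (absolute 0-based contig coordinate class
#'   representative), `M`, `m`, `n`, `k`, `p_value`.
#' @export
phasing_scan <- function(reads, hits, index, window_len = 189L, cycle = 21L,
                         best_register = TRUE) {
  if (window_len < 3L * cycle) stop("phasing_scan: window shorter than 3 cycles")
  if (window_len %% cycle != 0) stop("phasing_scan: window_len must be a multiple of cycle")
  out <- list()
  hits <- hits[hits$sequence %in% reads$sequence, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_phase_windows())
  hits$phase_pos <- phase_position(hits$start, hits$end, hits$strand)
  M <- 2L * window_len
  m <- 2L * (window_len %/% cycle)
  for (contig in unique(hits$contig_id)) {
    sub <- hits[hits$contig_id == contig, , drop = FALSE]
    occ <- unique(sub[, c("phase_pos", "strand")])
    clen <- index$lengths[[contig]]
    first <- max(0L, min(occ$phase_pos) - (window_len - cycle))
    last <- min(max(occ$phase_pos), clen - window_len)
    if (last < first) last <- first
    starts <- seq.int(first, last, by = cycle)
    for (ws in starts) {
      we <- ws + window_len
      inw <- occ$phase_pos >= ws & occ$phase_pos < we
      n <- sum(inw)
      if (n < 3L) next
      pos <- occ$phase_pos[inw]; strd <- occ$strand[inw]
      if (best_register) {
        ks <- vapply(0:(cycle - 1L), function(r)
          sum(in_register(pos, strd, ws + r, cycle)), integer(1))
        kbest <- max(ks)
        regs <- which(ks == kbest) - 1L
      } else {
        kbest <- sum(in_register(pos, strd, ws, cycle))
        regs <- 0L
      }
      p <- phasing_pvalue(M, m, n, kbest)
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig, win_start = ws, win_end = we,
        register = ws + regs[1], M = M, m = m, n = n, k = kbest,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_phase_windows())
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$win_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_phase_windows <- function() {
  data.frame(contig_id = character(0), win_start = integer(0),
             win_end = integer(0), register = integer(0),
             M = integer(0), m = integer(0), n = integer(0), k = integer(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

#' Call phased siRNA loci (PGT loci) from scanned windows
#'
#' Significant windows (p below the cutoff) that overlap and share a
#' register class are merged into maximal loci (locus p-value = minimum
#' window p-value). A merged locus is retained iff:
#' at least one phased read has total count >= `min_pha_reads`; the
#' RPM-weighted phased fraction is >= `min_pha_frac`; and the locus
#' strand bias is < `max_strand_bias` (strict, unlike the miRNA filter).
#'
#' @param windows data.frame from [phasing_scan()].
#' @param reads,hits the phasing input reads and their hits.
#' @param p_cut p-value cutoff (default 0.01, strict `<`).
#' @param min_pha_reads minimum total count of the most abundant phased
#'   read (default 10).
#' @param min_pha_frac minimum phased fraction of locus RPM (default 0.5).
#' @param max_strand_bias maximum strand bias (default 0.9, strict `<`).
#' @param cycle cycle length.
#' @return data.frame of loci: `pgt_id`, `contig_id`, `locus_start`,
#'   `locus_end`, `register`, `p_value`, `n_windows`, `n_phased`,
#'   `n_nonphased`, `phased_rpm`, `nonphased_rpm`, `phased_fraction`,
#'   `strand_bias`, `max_phased_count`.
#' @export
call_pgts <- function(windows, reads, hits, p_cut = 0.01,
                      min_pha_reads = 10, min_pha_frac = 0.5,
                      max_strand_bias = 0.9, cycle = 21L) {
  sig <- windows[windows$p_value < p_cut, , drop = FALSE]
  if (nrow(sig) == 0) return(empty_pgts())
  sig$reg_class <- sig$register %% cycle
  sig <- sig[order(sig$contig_id, sig$reg_class, sig$win_start), , drop = FALSE]
  grp <- integer(nrow(sig)); cur <- 0L
  last_key <- ""; last_end <- -1L
  for (i in seq_len(nrow(sig))) {
    key <- paste(sig$contig_id[i], sig$reg_class[i])
    if (key != last_key || sig$win_start[i] > last_end) {
      cur <- cur + 1L; last_key <- key; last_end <- sig$win_end[i]
    } else {
      last_end <- max(last_end, sig$win_end[i])
    }
    grp[i] <- cur
  }
  sig$grp <- grp
  loci <- list()
  for (g in unique(grp)) {
    sub <- sig[sig$grp == g, , drop = FALSE]
    locus <- list(contig_id = sub$contig_id[1],
                  locus_start = min(sub$win_start),
                  locus_end = max(sub$win_end),
                  register = sub$register[which.min(sub$p_value)],
                  p_value = min(sub$p_value),
                  n_windows = nrow(sub))
    part <- partition_reads(locus, reads, hits, cycle = cycle)
    phased_rpm <- sum(part$phased$total_rpm)
    nonphased_rpm <- sum(part$nonphased$total_rpm)
    tot_rpm <- phased_rpm + nonphased_rpm
    counts <- c(part$phased$total_count, part$nonphased$total_count)
    strands <- c(part$phased$strand, part$nonphased$strand)
    sense <- sum(counts[strands == "+"])
    loci[[length(loci) + 1L]] <- data.frame(
      contig_id = locus$contig_id, locus_start = locus$locus_start,
      locus_end = locus$locus_end, register = locus$register,
      p_value = locus$p_value, n_windows = locus$n_windows,
      n_phased = nrow(part$phased), n_nonphased = nrow(part$nonphased),
      phased_rpm = phased_rpm, nonphased_rpm = nonphased_rpm,
      phased_fraction = if (tot_rpm > 0) phased_rpm / tot_rpm else 0,
      strand_bias = if (sum(counts) > 0) sense / sum(counts) else NA_real_,
      max_phased_count = if (nrow(part$phased) > 0)
        max(part$phased$total_count) else 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, loci)
  keep <- res$max_phased_count >= min_pha_reads &
    res$phased_fraction >= min_pha_frac &
    !is.na(res$strand_bias) & res$strand_bias < max_strand_bias
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0) return(empty_pgts())
  res <- res[order(res$contig_id, res$locus_start), , drop = FALSE]
  res$pgt_id <- sprintf("PGT_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("pgt_id", setdiff(names(res), "pgt_id"))]
}

empty_pgts <- function() {
  data.frame(pgt_id = character(0), contig_id = character(0),
             locus_start = integer(0), locus_end = integer(0),
             register = integer(0), p_value = numeric(0),
             n_windows = integer(0), n_phased = integer(0),
             n_nonphased = integer(0), phased_rpm = numeric(0),
             nonphased_rpm = numeric(0), phased_fraction = numeric(0),
             strand_bias = numeric(0), max_phased_count = numeric(0),
             stringsAsFactors = FALSE)
}

#' Partition locus reads into phased and non-phased sets
#'
#' Reads whose 5' phase position is in register (sense offset 0, antisense
#' offset +2 modulo the cycle) are phased; every other locus read is
#' non-phased. The sets are disjoint by construction.
#'
#' @param locus list/row with `contig_id`, `locus_start`, `locus_end`,
#'   `register`.
#' @param reads,hits the phasing input reads and their hits.
#' @param cycle cycle length.
#' @return list of two data.frames (`phased`, `nonphased`) with columns
#'   `sequence`, `position` (5' phase position), `strand`, `total_count`,
#'   `total_rpm`.
#' @export
partition_reads <- function(locus, reads, hits, cycle = 21L) {
  sub <- hits[hits$contig_id == locus$contig_id &
                hits$start < locus$locus_end &
                hits$end > locus$locus_start, , drop = FALSE]
  sub$position <- phase_position(sub$start, sub$end, sub$strand)
  sub <- sub[!duplicated(paste(sub$sequence, sub$position, sub$strand)), ,
             drop = FALSE]
  idx <- match(sub$sequence, reads$sequence)
  sub$total_count <- reads$total_count[idx]
  sub$total_rpm <- reads$total_rpm[idx]
  phased <- in_register(sub$position, sub$strand, locus$register, cycle)
  cols <- c("sequence", "position", "strand", "total_count", "total_rpm")
  list(phased = sub[phased, cols, drop = FALSE],
       nonphased = sub[!phased, cols, drop = FALSE])
}
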