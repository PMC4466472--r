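# miRNA hairpin discovery: candidate precursor extraction around abundant
# read loci, secondary-structure scoring (MFE / AMFE / MFEI / duplex
# mismatches), read-bias filters, and conserved vs lineage-specific
# classification against a known-miRNA library.

#' Default miRNA discovery thresholds
#'
#' The canonical plant-miRNA annotation criteria applied by
#' [apply_structure_filters()] and the pipeline. All comparisons are
#' inclusive on the stated bound.
#'
#' @return named list of thresholds.
#' @export
mirna_thresholds <- function() {
  list(min_abundance = 10,      # total read count to seed a candidate
       shift = 3L,              # allowed shift of mature placement (nt)
       max_span = 450L,         # max miRNA / miRNA* distance (nt)
       max_loci = 500L,         # hyper-repetitive read cutoff
       max_mismatches = 4,      # miRNA/miRNA* duplex mismatches
       mfe_max = -30,           # kcal/mol, precursor fold energy
       mfei_min = 0.30, mfei_max = 1.80,
       amfe_min = 22,           # kcal/mol/100nt
       gc_min = 25,             # percent
       strand_bias_min = 0.9,
       abundance_bias_min = 0.6,
       conservation_mm = 3L)    # max mismatches to a known plant miRNA
}

#' Extract hairpin precursor candidate windows
#'
#' Reads with total abundance at or above the threshold seed candidate
#' loci. Overlapping seed loci within `max_span` are clustered; the most
#' abundant read of a cluster anchors the putative mature, and precursor
#' windows of several sizes are emitted in both flank orders (mature on
#' the 5' or the 3' arm), each window keeping a short flank beyond the
#' mature end.
#'
#' @param reads an `srna_reads` collection.
#' @param hits mapping table from [map_exact()].
#' @param index the `ref_index`.
#' @param min_abundance seed abundance threshold (total count, default 10).
#' @param max_span maximum mature/star distance (default 450 nt).
#' @param window_sizes candidate precursor lengths to try.
#' @param flank flank retained 5' of the mature (nt).
#' @return data.frame of candidate windows with the precursor sequence in
#'   5'->3' orientation and the 0-based mature offset within it.
#' @export
extract_precursor_candidates <- function(reads, hits, index,
                                         min_abundance = 10,
                                         max_span = 450L,
                                         window_sizes = c(100L, 120L, 150L,
                                                          210L, 300L, 420L),
                                         flank = 10L) {
  qseq <- reads$sequence[reads$total_count >= min_abundance]
  qh <- hits[hits$sequence %in% qseq, , drop = FALSE]
  if (nrow(qh) == 0) return(empty_candidates())
  qh$total_count <- reads$total_count[match(qh$sequence, reads$sequence)]
  qh <- qh[order(qh$contig_id, qh$start), , drop = FALSE]
  # cluster seed loci per contig with gap <= max_span
  cl <- integer(nrow(qh))
  cur <- 0L; last_end <- -Inf; last_contig <- ""
  for (i in seq_len(nrow(qh))) {
    if (qh$contig_id[i] != last_contig || qh$start[i] - last_end > max_span) {
      cur <- cur + 1L
      last_contig <- qh$contig_id[i]
      last_end <- qh$end[i]
    } else {
      last_end <- max(last_end, qh$end[i])
    }
    cl[i] <- cur
  }
  qh$cluster <- cl
  out <- vector("list", max(cl))
  for (k in seq_len(max(cl))) {
    sub <- qh[qh$cluster == k, , drop = FALSE]
    a <- order(-sub$total_count, sub$start, sub$sequence)[1]
    anchor <- sub[a, ]
    clen <- index$lengths[[anchor$contig_id]]
    rows <- list()
    for (W in window_sizes) {
      for (ori in c("mature5p", "mature3p")) {
        if (ori == "mature5p") {
          if (anchor$strand == "+") {
            ws <- anchor$start - flank; we <- ws + W
          } else {
            we <- anchor$end + flank; ws <- we - W
          }
        } else {
          if (anchor$strand == "+") {
            we <- anchor$end + flank; ws <- we - W
          } else {
            ws <- anchor$start - flank; we <- ws + W
          }
        }
        ws <- max(0L, ws); we <- min(clen, we)
        if (we - ws < nchar(anchor$sequence) + 2L * flank) next
        if (anchor$start < ws || anchor$end > we) next
        contig_seq <- as.character(index$ref[[anchor$contig_id]])
        win_seq <- substr(contig_seq, ws + 1L, we)
        if (anchor$strand == "+") {
          prec <- win_seq
          moff <- anchor$start - ws
        } else {
          prec <- revcomp(win_seq)
          moff <- we - anchor$end
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, contig_id = anchor$contig_id,
          win_start = ws, win_end = we, strand = anchor$strand,
          orientation = ori, window = W,
          anchor_seq = anchor$sequence, anchor_start = anchor$start,
          anchor_end = anchor$end, anchor_total = anchor$total_count,
          precursor_seq = prec, mature_offset = moff,
          mature_len = nchar(anchor$sequence),
          stringsAsFactors = FALSE)
      }
    }
    out[[k]] <- do.call(rbind, rows)
  }
  cand <- do.call(rbind, out)
  if (is.null(cand)) return(empty_candidates())
  cand <- unique(cand)
  cand$candidate_id <- sprintf("cand_%05d", seq_len(nrow(cand)))
  rownames(cand) <- NULL
  cand
}

empty_candidates <- function() {
  data.frame(cluster = integer(0), contig_id = character(0),
             win_start = integer(0), win_end = integer(0),
             strand = character(0), orientation = character(0),
             window = integer(0), anchor_seq = character(0),
             anchor_start = integer(0), anchor_end = integer(0),
             anchor_total = numeric(0), precursor_seq = character(0),
             mature_offset = integer(0), mature_len = integer(0),
             candidate_id = character(0), stringsAsFactors = FALSE)
}

#' Single-strand bias of a locus
#'
#' Total read counts from the sense strand of the putative precursor
#' divided by total counts from both strands.
#'
#' @param locus list/row with `contig_id`, `win_start`, `win_end`, `strand`
#'   (the precursor's sense strand).
#' @param reads an `srna_reads` collection.
#' @param hits mapping table.
#' @return numeric in `[0,1]`, or `NA` if no reads map to the locus.
#' @export
compute_strand_bias <- function(locus, reads, hits) {
  sub <- locus_reads(locus, reads, hits)
  if (nrow(sub) == 0) return(NA_real_)
  sense <- sum(sub$total_count[sub$strand == locus$strand])
  sense / sum(sub$total_count)
}

#' Abundance bias of a locus
#'
#' Summed counts of the three most abundant distinct reads of the locus
#' divided by the summed counts of all its reads (fewer than three
#' distinct reads use what is available).
#'
#' @inheritParams compute_strand_bias
#' @return numeric in `[0,1]`, or `NA` if no reads map to the locus.
#' @export
compute_abundance_bias <- function(locus, reads, hits) {
  sub <- locus_reads(locus, reads, hits)
  if (nrow(sub) == 0) return(NA_real_)
  per_read <- tapply(sub$total_count, sub$sequence, max)
  top <- sort(per_read, decreasing = TRUE)
  sum(top[seq_len(min(3L, length(top)))]) / sum(per_read)
}

# Distinct reads with a hit overlapping [win_start, win_end) on contig_id.
locus_reads <- function(locus, reads, hits) {
  sub <- hits[hits$contig_id == locus$contig_id &
                hits$start < locus$win_end &
                hits$end > locus$win_start, , drop = FALSE]
  sub <- sub[!duplicated(paste(sub$sequence, sub$strand)), , drop = FALSE]
  sub$total_count <- reads$total_count[match(sub$sequence, reads$sequence)]
  sub
}

#' Fold candidate precursors and compute hairpin quality metrics
#'
#' Folds each candidate window, locates the star arm as the region paired
#' with the mature, and computes MFE, GC%, AMFE (`-mfe/len*100`), MFEI
#' (`amfe/gc_pct`) and the duplex mismatch count. G:U wobbles count as
#' paired; every unpaired mature position facing the star arm (including
#' bulged mature bases) counts one mismatch. Candidates whose mature arm
#' does not pair with a disjoint star region are marked unevaluable.
#'
#' @param candidates data.frame from [extract_precursor_candidates()].
#' @param backend folding backend (default [default_fold_backend()]).
#' @return `candidates` with columns `structure`, `mfe`, `gc_pct`, `amfe`,
#'   `mfei`, `duplex_mismatches`, `star_seq`, `star_offset`, `evaluable`.
#' @export
fold_and_score <- function(candidates, backend = default_fold_backend()) {
  n <- nrow(candidates)
  if (n == 0) {
    candidates$structure <- character(0)
    candidates$mfe <- numeric(0)
    candidates$gc_pct <- numeric(0)
    candidates$amfe <- numeric(0)
    candidates$mfei <- numeric(0)
    candidates$duplex_mismatches <- integer(0)
    candidates$star_seq <- character(0)
    candidates$star_offset <- integer(0)
    candidates$evaluable <- logical(0)
    return(candidates)
  }
  fold <- backend(candidates$precursor_seq)
  candidates$structure <- fold$structure
  candidates$mfe <- fold$mfe
  len <- nchar(candidates$precursor_seq)
  candidates$gc_pct <- gc_percent(candidates$precursor_seq)
  candidates$amfe <- -candidates$mfe / len * 100
  candidates$mfei <- candidates$amfe / candidates$gc_pct
  star_seq <- character(n); star_off <- rep(NA_integer_, n)
  mm <- rep(NA_integer_, n); ok <- logical(n)
  for (i in seq_len(n)) {
    pt <- pair_table(candidates$structure[i])
    mp <- (candidates$mature_offset[i] + 1L):(candidates$mature_offset[i] +
                                                candidates$mature_len[i])
    partners <- pt[mp]
    if (all(is.na(partners))) next
    s1 <- min(partners, na.rm = TRUE); s2 <- max(partners, na.rm = TRUE)
    # star arm must be disjoint from the mature arm (a true stem-loop)
    if (s1 <= max(mp) && s2 >= min(mp)) next
    ok[i] <- TRUE
    mm[i] <- sum(is.na(partners))
    star_off[i] <- s1 - 1L
    star_seq[i] <- substr(candidates$precursor_seq[i], s1, s2)
  }
  candidates$duplex_mismatches <- mm
  candidates$star_seq <- star_seq
  candidates$star_offset <- star_off
  candidates$evaluable <- ok
  candidates
}

#' Apply the structural and bias filters to scored candidates
#'
#' A candidate is accepted iff duplex mismatches <= 4, 0.30 <= MFEI <=
#' 1.80, AMFE >= 22 kcal/mol/100nt, GC >= 25%, MFE <= -30 kcal/mol,
#' strand bias >= 0.9 and abundance bias >= 0.6 (all bounds inclusive).
#' Rejected candidates carry the complete set of failed-rule reason codes.
#'
#' @param scored data.frame from [fold_and_score()] with `strand_bias` and
#'   `abundance_bias` columns added.
#' @param thresholds list as from [mirna_thresholds()].
#' @return `scored` with logical `accepted` and character `reasons`.
#' @export
apply_structure_filters <- function(scored, thresholds = mirna_thresholds()) {
  th <- thresholds
  n <- nrow(scored)
  reasons <- vector("list", n)
  add <- function(cond, code) {
    bad <- !is.na(cond) & !cond
    bad[is.na(cond)] <- TRUE
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  if (n > 0) {
    add(scored$evaluable, "unevaluable")
    add(scored$duplex_mismatches <= th$max_mismatches, "duplex_mismatches")
    add(scored$mfe <= th$mfe_max, "mfe")
    add(scored$mfei >= th$mfei_min & scored$mfei <= th$mfei_max, "mfei")
    add(scored$amfe >= th$amfe_min, "amfe")
    add(scored$gc_pct >= th$gc_min, "gc")
    add(scored$strand_bias >= th$strand_bias_min, "strand_bias")
    add(scored$abundance_bias >= th$abundance_bias_min, "abundance_bias")
  }
  scored$accepted <- vapply(reasons, function(r) is.null(r), logical(1))
  scored$reasons <- vapply(reasons, function(r)
    if (is.null(r)) "" else paste(r, collapse = ","), character(1))
  scored
}

#' End-anchored mismatch distance between two sequences
#'
#' Best ungapped alignment over shifts of at most `max_shift` nt; the
#' distance is the number of mismatched overlapping positions plus one per
#' unaligned overhang base. Sequences differing in length by more than
#' `max_shift` are at infinite distance. Ties prefer the smaller absolute
#' shift.
#'
#' @param a,b sequences.
#' @param max_shift maximum end shift (default 3).
#' @return numeric distance (possibly `Inf`).
#' @export
end_anchored_dist <- function(a, b, max_shift = 3L) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > max_shift) return(Inf)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- Inf
  for (o in order(abs(-max_shift:max_shift))) {
    sh <- (-max_shift:max_shift)[o]
    # b shifted by sh relative to a: a[i] aligns b[i - sh]
    i1 <- max(1L, 1L + sh); i2 <- min(la, lb + sh)
    if (i2 < i1) next
    ov <- i2 - i1 + 1L
    mism <- sum(av[i1:i2] != bv[(i1:i2) - sh])
    d <- mism + (la - ov) + (lb - ov)
    if (d < best) best <- d
  }
  best
}

#' Classify miRNAs as conserved (cs) or lineage-specific (ls)
#'
#' A mature is conserved when it, or its star sequence, is within
#' `max_mm` mismatches (end-anchored distance) of any known plant miRNA.
#'
#' @param mature character vector of mature sequences.
#' @param star optional character vector of star sequences (same length,
#'   `NA` allowed).
#' @param known named character vector of known mature miRNAs.
#' @param max_mm maximum mismatches (default 3).
#' @return character vector `"cs"`/`"ls"`.
#' @export
classify_conservation <- function(mature, star = NULL, known, max_mm = 3L) {
  if (length(known) == 0) {
    warning("empty known-miRNA set: all miRNAs classified lineage-specific")
    return(rep("ls", length(mature)))
  }
  known <- normalize_seq(known)
  one <- function(q) {
    if (is.na(q) || !nzchar(q)) return(Inf)
    min(vapply(known, end_anchored_dist, numeric(1), a = q, max_shift = max_mm))
  }
  dm <- vapply(normalize_seq(mature), one, numeric(1), USE.NAMES = FALSE)
  ds <- if (is.null(star)) rep(Inf, length(mature))
        else vapply(normalize_seq(star), one, numeric(1), USE.NAMES = FALSE)
  unname(ifelse(pmin(dm, ds) <= max_mm, "cs", "ls"))
}

#' Discover miRNAs from mapped reads
#'
#' Runs candidate extraction, bias computation, folding, filtering, and
#' per-mature aggregation. One locus (seed cluster) contributes at most
#' one accepted precursor: the smallest accepted window. Multiple
#' precursors yielding the same mature sequence aggregate into one
#' annotation.
#'
#' @param reads an `srna_reads` collection (RPM populated).
#' @param hits mapping table from [map_exact()].
#' @param index the `ref_index`.
#' @param known_mirnas named character vector of known mature miRNAs (may
#'   be `NULL`: everything is then lineage-specific).
#' @param thresholds list from [mirna_thresholds()].
#' @param backend folding backend.
#' @return list with `candidates` (all scored windows), `precursors`
#'   (accepted, one row per locus) and `annotations` (one row per unique
#'   mature: sequence, precursor ids, conservation, canonical flag).
#' @export
discover_mirnas <- function(reads, hits, index, known_mirnas = NULL,
                            thresholds = mirna_thresholds(),
                            backend = default_fold_backend()) {
  th <- thresholds
  cand <- extract_precursor_candidates(reads, hits, index,
                                       min_abundance = th$min_abundance,
                                       max_span = th$max_span)
  if (nrow(cand) > 0) {
    # bias filters are cheap; apply per candidate window before folding
    bias <- compute_candidate_bias(cand, reads, hits)
    cand$strand_bias <- bias$strand_bias
    cand$abundance_bias <- bias$abundance_bias
    prefilter <- !is.na(cand$strand_bias) &
      cand$strand_bias >= th$strand_bias_min &
      cand$abundance_bias >= th$abundance_bias_min
    tofold <- cand[prefilter, , drop = FALSE]
    rest <- cand[!prefilter, , drop = FALSE]
    tofold <- fold_and_score(tofold, backend = backend)
    tofold <- apply_structure_filters(tofold, th)
    if (nrow(rest) > 0) {
      rest[c("structure", "star_seq")] <- NA_character_
      rest[c("mfe", "gc_pct", "amfe", "mfei")] <- NA_real_
      rest$duplex_mismatches <- NA_integer_
      rest$star_offset <- NA_integer_
      rest$evaluable <- FALSE
      rest$accepted <- FALSE
      rest$reasons <- ifelse(is.na(rest$strand_bias), "no_reads",
                             trimws(paste0(
        ifelse(rest$strand_bias < th$strand_bias_min, "strand_bias,", ""),
        ifelse(rest$abundance_bias < th$abundance_bias_min, "abundance_bias", "")),
        whitespace = ","))
      cand <- rbind(tofold, rest)
    } else {
      cand <- tofold
    }
  } else {
    cand$strand_bias <- numeric(0)
    cand <- apply_structure_filters(fold_and_score(cand), th)
    cand$abundance_bias <- numeric(0)
  }
  acc <- cand[cand$accepted, , drop = FALSE]
  precursors <- NULL
  if (nrow(acc) > 0) {
    acc <- acc[order(acc$cluster, acc$window,
                     match(acc$orientation, c("mature5p", "mature3p"))), ,
               drop = FALSE]
    precursors <- acc[!duplicated(acc$cluster), , drop = FALSE]
    precursors$precursor_id <- sprintf("MIRP_%04d", seq_len(nrow(precursors)))
  } else {
    precursors <- acc
    precursors$precursor_id <- character(0)
  }
  annotations <- aggregate_annotations(precursors, known_mirnas,
                                       max_mm = th$conservation_mm)
  list(candidates = cand, precursors = precursors, annotations = annotations)
}

compute_candidate_bias <- function(cand, reads, hits) {
  n <- nrow(cand)
  sb <- ab <- rep(NA_real_, n)
  hits_by_contig <- split(hits, hits$contig_id)
  count_of <- stats::setNames(reads$total_count, reads$sequence)
  for (i in seq_len(n)) {
    h <- hits_by_contig[[cand$contig_id[i]]]
    if (is.null(h)) next
    sub <- h[h$start < cand$win_end[i] & h$end > cand$win_start[i], ,
             drop = FALSE]
    sub <- sub[!duplicated(paste(sub$sequence, sub$strand)), , drop = FALSE]
    if (nrow(sub) == 0) next
    cnt <- count_of[sub$sequence]
    sb[i] <- sum(cnt[sub$strand == cand$strand[i]]) / sum(cnt)
    per_read <- tapply(cnt, sub$sequence, max)
    top <- sort(per_read, decreasing = TRUE)
    ab[i] <- sum(top[seq_len(min(3L, length(top)))]) / sum(per_read)
  }
  list(strand_bias = sb, abundance_bias = ab)
}

aggregate_annotations <- function(precursors, known_mirnas, max_mm = 3L) {
  if (nrow(precursors) == 0) {
    return(data.frame(mature_seq = character(0), length = integer(0),
                      precursor_ids = character(0), n_precursors = integer(0),
                      conservation = character(0), canonical = logical(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(precursors)), precursors$anchor_seq)
  mature <- names(sp)
  pids <- vapply(sp, function(ix)
    paste(sort(precursors$precursor_id[ix]), collapse = ","), character(1))
  stars <- vapply(sp, function(ix) precursors$star_seq[ix][1], character(1))
  cons <- if (is.null(known_mirnas)) {
    rep("ls", length(mature))
  } else {
    classify_conservation(mature, stars, known_mirnas, max_mm = max_mm)
  }
  out <- data.frame(mature_seq = mature, length = nchar(mature),
                    precursor_ids = pids,
                    n_precursors = lengths(sp),
                    conservation = cons,
                    canonical = nchar(mature) <= 22L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mature_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}
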