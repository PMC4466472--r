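# Hairpin candidate extraction, quality metrics, structural/bias filters
# and conservation classification.

# a stub folding backend with a hand-built stem-loop structure: positions
# 1..20 pair 60..41, the rest unpaired
stub_backend <- function(mfe) {
  function(seqs) {
    stopifnot(all(nchar(seqs) == 100))
    data.frame(structure = paste0(strrep("(", 20), strrep(".", 20),
                                  strrep(")", 20), strrep(".", 40)),
               mfe = rep(mfe, length(seqs)), stringsAsFactors = FALSE)
  }
}

stub_candidate <- function(gc = 0.5) {
  # precursor with GC fraction gc: first 20 = mature arm
  n_gc <- round(100 * gc)
  prec <- paste(c(rep("G", ceiling(n_gc / 2)), rep("A", ceiling((100 - n_gc) / 2)),
                  rep("C", floor(n_gc / 2)), rep("T", floor((100 - n_gc) / 2))),
                collapse = "")
  data.frame(cluster = 1L, contig_id = "c", win_start = 0L, win_end = 100L,
             strand = "+", orientation = "mature5p", window = 100L,
             anchor_seq = substr(prec, 1, 20), anchor_start = 0L,
             anchor_end = 20L, anchor_total = 100, precursor_seq = prec,
             mature_offset = 0L, mature_len = 20L, candidate_id = "cand_1",
             stringsAsFactors = FALSE)
}

test_that("fold_and_score computes MFE-derived hairpin metrics", {
  sc <- fold_and_score(stub_candidate(gc = 0.5), backend = stub_backend(-45))
  expect_equal(sc$amfe, 45)
  expect_equal(sc$gc_pct, 50)
  expect_equal(sc$mfei, 0.90)
  expect_equal(sc$duplex_mismatches, 0L)
  expect_true(sc$evaluable)
  expect_equal(sc$star_offset, 40L)
  # MFEI identity holds to numerical precision
  expect_equal(sc$mfei, sc$amfe / sc$gc_pct, tolerance = 1e-9)
})

test_that("strand and abundance bias match their definitions", {
  seqs <- random_seq(5, 21)
  reads <- reads_with_counts(seqs, cbind(l1 = c(50L, 30L, 20L, 40L, 10L)))
  hits <- data.frame(sequence = seqs,
                     contig_id = "c", start = c(0L, 30L, 60L, 90L, 120L),
                     end = c(21L, 51L, 81L, 111L, 141L),
                     strand = c("+", "+", "+", "+", "-"),
                     stringsAsFactors = FALSE)
  locus <- list(contig_id = "c", win_start = 0L, win_end = 150L, strand = "+")
  expect_equal(compute_strand_bias(locus, reads, hits), 140 / 150)
  # top3 = 50+40+30 of 150
  expect_equal(compute_abundance_bias(locus, reads, hits), 120 / 150)
  # no antisense reads -> bias 1
  locus2 <- list(contig_id = "c", win_start = 0L, win_end = 100L, strand = "+")
  expect_equal(compute_strand_bias(locus2, reads, hits), 1.0)
  # fewer than 3 distinct reads uses what is available
  locus3 <- list(contig_id = "c", win_start = 0L, win_end = 40L, strand = "+")
  expect_equal(compute_abundance_bias(locus3, reads, hits), 1.0)
  # empty locus is undefined
  expect_true(is.na(compute_strand_bias(list(contig_id = "z", win_start = 0,
                                             win_end = 10, strand = "+"),
                                        reads, hits)))
})

test_that("abundance bias equals a sort-and-sum oracle on random count vectors", {
  set.seed(14)
  for (rep in 1:20) {
    k <- sample(1:8, 1)
    cnt <- sample(1:500, k)
    seqs <- random_seq(k, 21)
    reads <- reads_with_counts(seqs, cbind(l1 = cnt))
    hits <- data.frame(sequence = seqs, contig_id = "c",
                       start = seq(0, by = 25, length.out = k),
                       end = seq(21, by = 25, length.out = k), strand = "+",
                       stringsAsFactors = FALSE)
    locus <- list(contig_id = "c", win_start = 0L, win_end = 1000L, strand = "+")
    oracle <- sum(sort(cnt, decreasing = TRUE)[seq_len(min(3, k))]) / sum(cnt)
    expect_equal(compute_abundance_bias(locus, reads, hits), oracle)
  }
})

test_that("structure filters accept the exact boundary and reject beyond it", {
  base <- data.frame(evaluable = TRUE, duplex_mismatches = 4L, mfe = -30,
                     mfei = 0.30, amfe = 22, gc_pct = 25, strand_bias = 0.9,
                     abundance_bias = 0.6)
  at <- apply_structure_filters(base)
  expect_true(at$accepted)
  expect_identical(at$reasons, "")
  upper <- base; upper$mfei <- 1.80
  expect_true(apply_structure_filters(upper)$accepted)

  cases <- list(
    list(col = "duplex_mismatches", val = 5L, code = "duplex_mismatches"),
    list(col = "mfe", val = -29.99, code = "mfe"),
    list(col = "mfei", val = 0.2999, code = "mfei"),
    list(col = "mfei", val = 1.8001, code = "mfei"),
    list(col = "amfe", val = 21.99, code = "amfe"),
    list(col = "gc_pct", val = 24.99, code = "gc"),
    list(col = "strand_bias", val = 0.8999, code = "strand_bias"),
    list(col = "abundance_bias", val = 0.5999, code = "abundance_bias"))
  for (cs in cases) {
    row <- base
    row[[cs$col]] <- cs$val
    out <- apply_structure_filters(row)
    expect_false(out$accepted)
    expect_identical(out$reasons, cs$code)
  }
  # reason codes enumerate every failed rule
  row <- base; row$duplex_mismatches <- 9L; row$gc_pct <- 10
  expect_identical(apply_structure_filters(row)$reasons, "duplex_mismatches,gc")
})

test_that("filter monotonicity: tightening thresholds never adds acceptances", {
  run <- small_run()
  scored <- run$mirna$candidates
  scored <- scored[!is.na(scored$strand_bias), , drop = FALSE]
  base_acc <- apply_structure_filters(scored)$accepted
  for (tweak in list(c("max_mismatches", -1), c("amfe_min", +5),
                     c("gc_min", +10), c("strand_bias_min", +0.05),
                     c("abundance_bias_min", +0.2), c("mfe_max", -5),
                     c("mfei_min", +0.2), c("mfei_max", -0.4))) {
    th <- mirna_thresholds()
    th[[tweak[1]]] <- as.numeric(th[[tweak[1]]]) + as.numeric(tweak[2])
    tight_acc <- apply_structure_filters(scored, th)$accepted
    expect_true(all(base_acc | !tight_acc))
  }
})

test_that("end-anchored distance and conservation classification", {
  expect_equal(end_anchored_dist("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA"), 0)
  m <- "ACGTACGTACGTACGTACGTA"
  mutate <- function(x, k) {
    v <- strsplit(x, "")[[1]]
    swap <- c(A = "C", C = "A", G = "T", T = "G")
    pos <- c(2, 6, 10, 14)[seq_len(k)]
    v[pos] <- swap[v[pos]]
    paste(v, collapse = "")
  }
  m3 <- mutate(m, 3)
  m4 <- mutate(m, 4)
  expect_equal(end_anchored_dist(m, m3), 3)
  expect_equal(end_anchored_dist(m, m4), 4)
  # length differences count as unaligned overhangs
  expect_equal(end_anchored_dist(m, substr(m, 1, 19)), 2)
  expect_equal(end_anchored_dist(m, paste0("AA", m)), 2)  # shifted alignment
  expect_equal(end_anchored_dist(m, paste0("AAAA", m)), Inf)  # length diff > 3
  known <- c(k1 = m)
  expect_equal(classify_conservation(m, NULL, known), "cs")
  expect_equal(classify_conservation(m3, NULL, known), "cs")   # boundary 3
  expect_equal(classify_conservation(m4, NULL, known), "ls")   # beyond 3
  # star rescue: mature distance > 3 but star within 3
  expect_equal(classify_conservation(m4, m3, known), "cs")
  expect_warning(out <- classify_conservation(m, NULL, character(0)), "empty")
  expect_equal(out, "ls")
})

test_that("candidate extraction respects the abundance seed threshold", {
  set.seed(19)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""))
  idx <- build_index(ref)
  s <- substr(ref[["c1"]], 301, 321)
  for (cnt in c(9L, 10L)) {
    reads <- reads_with_counts(s, cbind(l1 = cnt))
    hits <- map_exact(reads, idx)$hits
    cand <- extract_precursor_candidates(reads, hits, idx)
    if (cnt == 9L) expect_equal(nrow(cand), 0L) else expect_gt(nrow(cand), 0L)
  }
})

test_that("discovery recovers planted hairpins with correct conservation labels", {
  run <- small_run()
  ev <- evaluate_run(run)
  expect_gte(ev$mirna$precision, 0.9)
  expect_gte(ev$mirna$recall, 0.9)
  expect_equal(ev$mirna$conservation_accuracy, 1.0)
  # accepted candidates carry all metric values
  prec <- run$mirna$precursors
  expect_true(all(!is.na(prec$mfe) & !is.na(prec$mfei) & !is.na(prec$amfe) &
                    !is.na(prec$strand_bias) & !is.na(prec$abundance_bias)))
  # a candidate window covers the planted precursor coordinates
  h1 <- run$sim$manifest$planted_hairpins[[1]]
  sub <- prec[prec$contig_id == h1$contig_id, ]
  expect_true(any(sub$win_start <= h1$mature_start & sub$win_end >= h1$star_end))
  # rejections carry reason codes
  rej <- run$mirna$candidates[!run$mirna$candidates$accepted, ]
  expect_true(all(nzchar(rej$reasons)))
})
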