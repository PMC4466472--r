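# Hypergeometric phasing statistic, window scan, locus calling and
# read partitioning.

test_that("phasing tail probability handles degenerate cases in closed form", {
  expect_equal(phasing_pvalue(378, 18, 0, 0), 1)
  expect_equal(phasing_pvalue(378, 18, 5, 0), 1)
  # all occupied positions in register with n = m
  for (M in c(20, 42)) {
    m <- 2 * (M / 2) %/% 21 + 4  # a small in-register count
    expect_equal(phasing_pvalue(M, m, m, m), 1 / choose(M, m))
  }
})

test_that("tail probability equals exhaustive subset enumeration (small cases)", {
  # oracle: enumerate every n-subset of M positions and count those with
  # at least k of the m in-register slots
  for (M in c(8, 11)) {
    for (m in c(2, 4)) {
      for (n in 2:5) {
        subsets <- utils::combn(M, n)
        for (k in 0:min(n, m)) {
          hits <- colSums(subsets <= m)  # positions 1..m are in-register
          oracle <- mean(hits >= k)
          expect_equal(phasing_pvalue(M, m, n, k), oracle, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("register membership follows the 2-nt antisense offset convention", {
  reg <- 100L
  # sense read at register + 42 is phased; +43 is not
  expect_true(phasiforge:::in_register(reg + 42L, "+", reg))
  expect_false(phasiforge:::in_register(reg + 43L, "+", reg))
  # antisense 5' end at register + 23 is phased (offset +2 mod 21)
  expect_true(phasiforge:::in_register(reg + 23L, "-", reg))
  expect_false(phasiforge:::in_register(reg + 21L, "-", reg))
})

test_that("locus filters apply at their exact boundaries", {
  # most abundant phased read at 9 vs 10 total counts
  f9 <- make_phase_fixture(rep(9L, 8))
  w9 <- phasing_scan(f9$reads, f9$hits, f9$idx)
  expect_equal(nrow(call_pgts(w9, f9$reads, f9$hits)), 0L)
  f10 <- make_phase_fixture(c(10L, rep(9L, 7)))
  w10 <- phasing_scan(f10$reads, f10$hits, f10$idx)
  expect_equal(nrow(call_pgts(w10, f10$reads, f10$hits)), 1L)

  # phased fraction just below / at 50% (RPM-weighted; equal totals)
  phased_total <- 8 * 10 + 7 * 4  # sense + antisense counts in fixture
  f_lo <- make_phase_fixture(rep(10L, 8),
                             nonphased_counts = c(phased_total + 1L))
  w_lo <- phasing_scan(f_lo$reads, f_lo$hits, f_lo$idx)
  expect_equal(nrow(call_pgts(w_lo, f_lo$reads, f_lo$hits)), 0L)
  f_eq <- make_phase_fixture(rep(10L, 8), nonphased_counts = c(phased_total))
  w_eq <- phasing_scan(f_eq$reads, f_eq$hits, f_eq$idx)
  expect_equal(nrow(call_pgts(w_eq, f_eq$reads, f_eq$hits)), 1L)

  # strand bias exactly 0.9 is rejected (strict <), just below passes
  f_sb <- make_phase_fixture(rep(9L, 9), antisense = FALSE)
  # sense counts 81; one antisense phased read with count 9 gives 81/90 = 0.9
  tx <- as.character(f_sb$idx$ref[[1]])
  apos <- f_sb$register + 23L
  aseq <- revcomp(substring(tx, apos - 19L, apos + 1L))
  for (acount in c(9L, 11L)) {
    seqs <- c(substring(tx, f_sb$register + 1L + 21L * 0:8,
                        f_sb$register + 21L + 21L * 0:8), aseq)
    reads <- reads_with_counts(seqs, cbind(lib1 = c(rep(9L, 9), acount)))
    hits <- map_exact(reads, f_sb$idx)$hits
    w <- phasing_scan(reads, hits, f_sb$idx)
    got <- call_pgts(w, reads, hits, min_pha_reads = 9)
    if (acount == 9L) {
      expect_equal(nrow(got), 0L)   # bias = 81/90 = 0.9 exactly
    } else {
      expect_equal(nrow(got), 1L)   # bias = 81/92 < 0.9
    }
  }
})

test_that("p-value cutoff is strict", {
  f <- make_phase_fixture(rep(12L, 8))
  w <- phasing_scan(f$reads, f$hits, f$idx)
  pmin_ <- min(w$p_value)
  # a cutoff equal to the best window p excludes it (strict <)
  expect_equal(nrow(call_pgts(w, f$reads, f$hits, p_cut = pmin_)), 0L)
  expect_equal(nrow(call_pgts(w, f$reads, f$hits, p_cut = pmin_ * 1.0001)), 1L)
})

test_that("partition separates phased from non-phased reads disjointly", {
  f <- make_phase_fixture(rep(12L, 6), nonphased_counts = c(5L, 7L))
  locus <- list(contig_id = "tx", locus_start = 0L, locus_end = 900L,
                register = f$register)
  part <- partition_reads(locus, f$reads, f$hits)
  expect_equal(nrow(part$phased), 6 + 5)      # sense + antisense phased
  expect_equal(nrow(part$nonphased), 2)
  expect_length(intersect(paste(part$phased$sequence, part$phased$position),
                          paste(part$nonphased$sequence,
                                part$nonphased$position)), 0)
  expect_true(all(part$phased$position[part$phased$strand == "+"] %% 21 ==
                    f$register %% 21))
})

test_that("fixed-register null p-values are calibrated; best-register inflation is bounded", {
  set.seed(77)
  glen <- 60000L
  idx <- build_index(c(bg = paste(sample(c("A", "C", "G", "T"), glen, TRUE),
                                  collapse = "")))
  nreads <- 1500L
  pos <- sample(0:(glen - 22L), nreads)
  seqs <- sprintf("read%05d", seq_len(nreads))
  hits <- data.frame(sequence = seqs, contig_id = "bg", start = pos,
                     end = pos + 21L,
                     strand = sample(c("+", "-"), nreads, TRUE),
                     stringsAsFactors = FALSE)
  reads <- data.frame(sequence = seqs, length = 21L, total_count = 2L,
                      stringsAsFactors = FALSE)
  reads$counts <- matrix(2L, nreads, 1, dimnames = list(NULL, "l1"))
  reads$rpm <- matrix(1, nreads, 1, dimnames = list(NULL, "l1"))
  reads$total_rpm <- rep(1, nreads)
  w_fix <- phasing_scan(reads, hits, idx, best_register = FALSE)
  expect_gt(nrow(w_fix), 1000)
  for (alpha in c(0.01, 0.05)) {
    mc <- 3 * sqrt(alpha / nrow(w_fix))
    expect_lte(mean(w_fix$p_value < alpha), alpha + mc + 0.01)
  }
  # best-register selection inflates by at most the number of registers
  w_best <- phasing_scan(reads, hits, idx, best_register = TRUE)
  expect_lte(mean(w_best$p_value < 0.01), 21 * 0.01)
  # and the abundance filters keep background from producing locus calls
  expect_equal(nrow(call_pgts(w_best, reads, hits)), 0L)
})

test_that("background-only simulations yield no PGT calls", {
  cfg <- small_sim_config()
  cfg$n_hairpins <- 0L; cfg$n_pgts_mirna <- 0L; cfg$n_pgts_cis <- 0L
  cfg$n_pgts_trans <- 0L; cfg$n_isomirs_per_mirna <- 0L
  cfg$n_de_mirna <- 0L; cfg$n_de_sirna <- 0L
  for (seed in c(101, 202)) {
    d <- simulate_dataset(cfg, seed = seed)
    reads <- length_filter(collapse_reads(d$libraries))
    idx <- build_index(d$reference)
    mp <- map_exact(reads, idx)
    reads <- reads[reads$sequence %in% mp$hits$sequence, , drop = FALSE]
    reads <- rpm_normalize(reads, colSums(reads$counts))
    ph <- reads[reads$total_count >= 2, , drop = FALSE]
    hh <- mp$hits[mp$hits$sequence %in% ph$sequence, , drop = FALSE]
    w <- phasing_scan(ph, hh, idx)
    expect_equal(nrow(call_pgts(w, ph, hh)), 0L)
  }
})

test_that("window shorter than 3 cycles is rejected", {
  f <- make_phase_fixture(rep(5L, 4))
  expect_error(phasing_scan(f$reads, f$hits, f$idx, window_len = 42L),
               "3 cycles")
})
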