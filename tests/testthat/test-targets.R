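# Target-site scoring, trigger prediction, cis/trans classification and
# network assembly.

# independent brute-force scorer: per-window penalty sum written from the
# scheme definition (mismatch 1, G:U 0.5, doubled at sRNA positions 2-13)
brute_score <- function(srna, transcript, cutoff = Inf) {
  s <- strsplit(srna, "")[[1]]
  t <- strsplit(transcript, "")[[1]]
  L <- length(s); out <- NULL
  pairs_ok <- list(A = "T", C = "G", G = "C", T = "A")
  for (ws in seq_len(length(t) - L + 1)) {
    pen <- 0
    for (i in seq_len(L)) {
      tb <- t[ws + L - i]
      p <- if (pairs_ok[[s[i]]] == tb) 0
      else if ((s[i] == "G" && tb == "T") || (s[i] == "T" && tb == "G")) 0.5
      else 1
      if (i >= 2 && i <= 13) p <- 2 * p
      pen <- pen + p
    }
    if (pen <= cutoff) out <- rbind(out, c(ws - 1, pen))
  }
  out
}

test_that("perfect complements score zero with the documented cleavage position", {
  set.seed(61)
  srna <- random_seq(1, 21)
  tx <- paste0(random_seq(1, 50), revcomp(srna), random_seq(1, 50))
  sites <- score_target(srna, tx, cutoff = 0)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$site_start, 50)
  expect_equal(sites$expectation, 0)
  # cleavage position opposite sRNA positions 10/11
  expect_equal(sites$cleavage_pos, 50 + 21 - 10)
})

test_that("G:U wobbles cost 0.5, doubled inside the 5' seed region", {
  set.seed(62)
  # build an sRNA with G at positions 5 and 15; pair them to T in the site
  s <- strsplit(random_seq(1, 21), "")[[1]]
  s[5] <- "G"; s[15] <- "G"
  srna <- paste(s, collapse = "")
  site <- strsplit(revcomp(srna), "")[[1]]
  # transcript index pairing sRNA position i is L - i + 1 within the site
  site15 <- site; site15[21 - 15 + 1] <- "T"  # wobble outside the seed
  tx <- paste0(strrep("A", 30), paste(site15, collapse = ""), strrep("A", 30))
  got <- score_target(srna, tx, cutoff = 3)
  expect_equal(min(got$expectation), 0.5)
  site5 <- site; site5[21 - 5 + 1] <- "T"     # wobble at seed position 5
  tx5 <- paste0(strrep("A", 30), paste(site5, collapse = ""), strrep("A", 30))
  got5 <- score_target(srna, tx5, cutoff = 3)
  expect_equal(min(got5$expectation), 1.0)
})

test_that("score_target equals the brute-force window oracle", {
  set.seed(63)
  for (i in 1:15) {
    srna <- random_seq(1, sample(19:24, 1))
    tx <- random_seq(1, 120)
    oracle <- brute_score(srna, tx, cutoff = Inf)
    got <- score_target(srna, tx, cutoff = Inf)
    expect_equal(got$site_start, oracle[, 1])
    expect_equal(got$expectation, oracle[, 2])
  }
})

trigger_fixture <- function(shift = 0L) {
  set.seed(64)
  trig <- random_seq(1, 21)
  pg <- simulate_pgt(900, register_start = 90 + shift, n_cycles = 6,
                     trigger = trig)
  pgts <- data.frame(pgt_id = "PGT_X", contig_id = "tx",
                     locus_start = 60L, locus_end = 300L, register = 90L,
                     p_value = 1e-6, stringsAsFactors = FALSE)
  cand <- data.frame(sequence = trig, class = "miRNA", origin = NA_character_,
                     total_count = 50, stringsAsFactors = FALSE)
  idx <- build_index(c(tx = pg$transcript))
  list(trig = trig, pgts = pgts, cand = cand, idx = idx)
}

test_that("triggers must cleave in phase with the locus register", {
  f <- trigger_fixture(shift = 0L)
  tr <- predict_triggers(f$pgts, f$cand, f$idx)
  expect_equal(nrow(tr), 1L)
  expect_true(tr$in_phase)
  expect_equal(tr$hit_model, "one_hit")
  expect_equal(tr$cleavage_pos %% 21, 90 %% 21)
  # site cleaving 1 nt off register with tolerance 0 is excluded
  f1 <- trigger_fixture(shift = 1L)
  expect_equal(nrow(predict_triggers(f1$pgts, f1$cand, f1$idx)), 0L)
  # but admitted with tolerance 1
  expect_equal(nrow(predict_triggers(f1$pgts, f1$cand, f1$idx,
                                     tolerance = 1L)), 1L)
  # unexpressed candidates are never triggers
  f$cand$total_count <- 1
  expect_equal(nrow(predict_triggers(f$pgts, f$cand, f$idx)), 0L)
  # no candidate under the cutoff leaves the PGT untriggered
  other <- data.frame(sequence = random_seq(1, 21), class = "miRNA",
                      origin = NA_character_, total_count = 50,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(predict_triggers(f$pgts, other, f$idx)), 0L)
})

test_that("cleavage modes separate initiator, cis and trans", {
  pgts <- data.frame(pgt_id = c("PGT_A", "PGT_B"),
                     contig_id = c("tx1", "tx2"),
                     locus_start = c(0L, 0L), locus_end = c(400L, 400L),
                     register = c(90L, 111L), p_value = c(1e-8, 1e-6),
                     stringsAsFactors = FALSE)
  asg <- data.frame(
    pgt_id = c("PGT_A", "PGT_A", "PGT_B"),
    trigger = c("M1", "S1", "S2"),
    trigger_class = c("miRNA", "pha-siRNA", "pha-siRNA"),
    trigger_origin = c(NA, "PGT_A", "PGT_A"),
    site_start = 0L, site_end = 21L, expectation = 0,
    cleavage_pos = c(90L, 90L, 111L), in_phase = TRUE,
    hit_model = "one_hit", stringsAsFactors = FALSE)
  out <- classify_cleavage(asg, pgts)
  expect_equal(out$cleavage_mode, c("initiator", "cis", "trans"))
  # every assignment gets exactly one mode
  expect_true(all(nzchar(out$cleavage_mode)))
  # a second register on the same transcript: miRNA there is trans,
  # same-transcript siRNA is cis
  pgts2 <- rbind(pgts, data.frame(pgt_id = "PGT_A2", contig_id = "tx1",
                                  locus_start = 300L, locus_end = 700L,
                                  register = 510L, p_value = 1e-4,
                                  stringsAsFactors = FALSE))
  asg2 <- data.frame(pgt_id = c("PGT_A2", "PGT_A2"),
                     trigger = c("M2", "S3"),
                     trigger_class = c("miRNA", "nonpha-siRNA"),
                     trigger_origin = c(NA, "PGT_A"),
                     site_start = 0L, site_end = 21L, expectation = 1,
                     cleavage_pos = 510L, in_phase = TRUE,
                     hit_model = "one_hit", stringsAsFactors = FALSE)
  asg2 <- rbind(asg[1, ], asg2)
  out2 <- classify_cleavage(asg2, pgts2)
  expect_equal(out2$cleavage_mode, c("initiator", "trans", "cis"))
  # unknown siRNA origin is an error
  bad <- asg; bad$trigger_origin[2] <- NA
  expect_error(classify_cleavage(bad, pgts), "origin")
})

test_that("the regulatory network carries typed edges and survives cycles", {
  g0 <- build_network(data.frame(pgt_id = character(0), trigger = character(0),
                                 trigger_class = character(0),
                                 trigger_origin = character(0),
                                 site_start = integer(0), site_end = integer(0),
                                 expectation = numeric(0),
                                 cleavage_pos = integer(0),
                                 in_phase = logical(0),
                                 hit_model = character(0),
                                 cleavage_mode = character(0)),
                      data.frame(pgt_id = character(0),
                                 contig_id = character(0)))
  expect_equal(igraph::ecount(g0), 0)

  pgts <- data.frame(pgt_id = c("PGT_A", "PGT_B"), contig_id = c("tx1", "tx2"),
                     stringsAsFactors = FALSE)
  asg <- data.frame(pgt_id = c("PGT_A", "PGT_A", "PGT_B", "PGT_A"),
                    trigger = c("M1", "S1", "S1", "S2"),
                    trigger_class = c("miRNA", "pha-siRNA", "pha-siRNA",
                                      "pha-siRNA"),
                    trigger_origin = c(NA, "PGT_A", "PGT_A", "PGT_B"),
                    site_start = 0L, site_end = 21L, expectation = 0.5,
                    cleavage_pos = 90L, in_phase = TRUE, hit_model = "one_hit",
                    cleavage_mode = c("initiator", "cis", "trans", "trans"),
                    stringsAsFactors = FALSE)
  g <- build_network(asg, pgts)
  expect_equal(igraph::ecount(g), 4)
  expect_setequal(igraph::E(g)$type, c("initiator", "cis", "trans", "trans"))
  # tx1 -> (via S2 from PGT_B) and tx2 -> (via S1 from PGT_A): a cycle
  # at transcript level; serialization must still work
  gml <- tempfile(fileext = ".graphml")
  el <- tempfile(fileext = ".tsv")
  write_network(g, gml, el)
  expect_true(file.exists(gml) && file.exists(el))
  back <- utils::read.delim(el)
  expect_equal(nrow(back), 4)
  # deterministic serialization
  el2 <- tempfile(fileext = ".tsv")
  write_network(g, NULL, el2)
  expect_identical(readLines(el), readLines(el2))
})

test_that("a planted miRNA -> PGT -> siRNA -> PGT cascade is recovered end-to-end", {
  run <- small_run()
  ev <- evaluate_run(run)
  expect_equal(ev$triggers$label_accuracy, 1.0)
  det <- ev$triggers$detail
  # the trans-triggered PGT is reached by a phased siRNA from another PGT
  tr_row <- det[det$expected_mode == "trans", ]
  expect_true(all(tr_row$recovered & tr_row$trigger_found))
  # the two-step cascade miRNA -> donor tx, donor siRNA -> recipient tx
  # is present as typed edges in the network
  g <- run$network
  el <- igraph::as_data_frame(g, what = "edges")
  don <- run$triggers[run$triggers$cleavage_mode == "trans", ][1, ]
  donor_tx <- run$pgts$contig_id[run$pgts$pgt_id == don$trigger_origin]
  recip_tx <- run$pgts$contig_id[run$pgts$pgt_id == don$pgt_id]
  init <- run$triggers[run$triggers$pgt_id == don$trigger_origin &
                         run$triggers$cleavage_mode == "initiator", ]
  expect_gt(nrow(init), 0)
  expect_true(any(el$from == init$trigger[1] & el$to == donor_tx &
                    el$type == "initiator"))
  expect_true(any(el$from == don$trigger & el$to == recip_tx &
                    el$type == "trans"))
  # the trans trigger really is one of the donor locus reads
  expect_true(don$trigger %in%
                run$phased$sequence[run$phased$pgt_id == don$trigger_origin])
})
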