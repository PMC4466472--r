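# Synthetic small RNA dataset generator with planted ground truth.
#
# The generator emulates the structure of a plant small RNA sequencing
# study: a reference sequence set (hairpin-bearing contigs, PGT-like
# transcripts, and unstructured decoy contigs), and multiple tissue
# libraries of 18-26 nt reads dominated by the 24-nt size class, with
# planted miRNA duplexes inside foldable hairpins, end-variant isomiRs,
# 21-nt phase registers downstream of trigger target sites (with miRNA
# initiators plus cis- and trans-acting secondary triggers), tissue
# differential abundances, and uniform reference-derived background.
# Every planted feature is recorded in a manifest that downstream tests
# use as the oracle.

#' Default configuration of the synthetic dataset
#'
#' The defaults define the standard study conditions used throughout the
#' test-suite: 30 hairpins, 10 miRNA-initiated PGTs plus 3 PGTs carrying a
#' planted cis-trigger register and 2 trans-triggered PGTs, 3 tissue
#' libraries of nominal depth 1e5, and 50% reference-derived background
#' with the 24-nt class dominant.
#'
#' @param n_hairpins number of planted miRNA hairpins.
#' @param n_pgts_mirna PGTs whose primary register is set by a planted
#'   miRNA initiator.
#' @param n_pgts_cis PGTs (miRNA-initiated) carrying a second register
#'   triggered in cis by one of their own phased siRNAs.
#' @param n_pgts_trans PGTs whose register is set by a phased siRNA from a
#'   different PGT (trans).
#' @param n_libraries number of tissue libraries (>= 2).
#' @param depth nominal per-library read depth; planted expected counts are
#'   `rpm * depth / 1e6` and background reads number
#'   `depth * background_frac`.
#' @param background_frac fraction of `depth` emitted as uniform
#'   reference-derived background reads.
#' @param n_decoys,decoy_len number and length of unstructured decoy
#'   contigs.
#' @param dispersion negative-binomial dispersion of planted counts
#'   (`size = 1/dispersion`).
#' @param mature_len,loop_len mature miRNA and hairpin loop lengths (nt).
#' @param hairpin_flank random flank added on each side of the planted
#'   precursor within its contig.
#' @param cycle,n_cycles phasing cycle length and number of phased duplex
#'   cycles planted per register.
#' @param transcript_len length of PGT-like transcripts.
#' @param n_isomirs_per_mirna planted end-variant isomiRs per hairpin.
#' @param n_nonphased planted out-of-register siRNAs per PGT.
#' @param n_de_mirna,n_de_sirna numbers of matures / phased siRNAs given a
#'   planted tissue effect.
#' @param de_fold planted tissue fold change (>= 2).
#' @param length_profile named numeric vector of background read-length
#'   probabilities (18..26 nt); the default peaks at 24 nt.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_hairpins = 30L,
                       n_pgts_mirna = 10L,
                       n_pgts_cis = 3L,
                       n_pgts_trans = 2L,
                       n_libraries = 3L,
                       depth = 1e5,
                       background_frac = 0.5,
                       n_decoys = 400L,
                       decoy_len = 2000L,
                       dispersion = 0.1,
                       mature_len = 21L,
                       loop_len = 48L,
                       hairpin_flank = 150L,
                       cycle = 21L,
                       n_cycles = 8L,
                       transcript_len = 900L,
                       n_isomirs_per_mirna = 2L,
                       n_nonphased = 4L,
                       n_de_mirna = 8L,
                       n_de_sirna = 6L,
                       de_fold = 4,
                       length_profile = c(`18` = 0.02, `19` = 0.03, `20` = 0.05,
                                          `21` = 0.15, `22` = 0.12, `23` = 0.09,
                                          `24` = 0.45, `25` = 0.06, `26` = 0.03)) {
  cfg <- as.list(environment())
  if (cfg$depth <= 0) stop("sim_config: depth must be positive")
  if (cfg$background_frac < 0 || cfg$background_frac > 1) {
    stop("sim_config: background_frac must be in [0,1]")
  }
  if (cfg$n_libraries < 2) stop("sim_config: need >= 2 libraries")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# A base that can face `partner` in a duplex without pairing: neither its
# Watson-Crick complement nor a G:U wobble partner. Substituting it at the
# opposing position always creates a true duplex mismatch (and never
# reproduces the complement).
noncomplement_of <- function(partner) {
  allowed <- list(A = c("A", "C", "G"),  # excludes T (A:U pair)
                  C = c("A", "C", "T"),  # excludes G (C:G pair)
                  G = c("A", "G"),       # excludes C (G:C) and T (G:U)
                  T = c("C", "T"))       # excludes A (U:A) and G (U:G)
  sample(allowed[[partner]], 1)
}

#' Simulate a miRNA hairpin precursor
#'
#' Builds `mature + loop + star`, where the star arm is the reverse
#' complement of the mature carrying the requested number of planted
#' duplex mismatches (substitutions that are neither Watson-Crick nor G:U
#' pairs, placed away from the duplex ends).
#'
#' @param mature mature miRNA sequence (20-24 nt).
#' @param loop_len loop length in nt.
#' @param mismatches number of planted miRNA/miRNA* mismatches (0-4).
#' @return list with `precursor`, `mature`, `star`, 0-based
#'   `mature_start`/`mature_end` and `star_start`/`star_end` within the
#'   precursor, and `mismatches`.
#' @export
simulate_hairpin <- function(mature, loop_len = 48L, mismatches = 0L) {
  mature <- normalize_seq(mature)
  len <- nchar(mature)
  if (len < 20 || len > 24) stop("simulate_hairpin: mature must be 20-24 nt")
  if (mismatches > 4) stop("simulate_hairpin: at most 4 duplex mismatches allowed")
  if (loop_len < 3) stop("simulate_hairpin: loop too short to fold")
  star <- strsplit(revcomp(mature), "")[[1]]
  if (mismatches > 0) {
    # spread mismatches over the duplex interior (one per band) so that
    # no long sub-window of the mature arm stays exactly complementary
    # to the star arm; real arms are never perfect complements, and an
    # exactly complementary stretch would cross-map between the arms.
    lo <- 4L; hi <- len - 3L
    cuts <- floor(seq(lo, hi + 1L, length.out = mismatches + 1L))
    pos <- vapply(seq_len(mismatches), function(b)
      sample(cuts[b]:(cuts[b + 1L] - 1L), 1L), integer(1))
    mat <- strsplit(mature, "")[[1]]
    # star position p faces mature position len + 1 - p
    for (p in pos) star[p] <- noncomplement_of(mat[len + 1L - p])
  }
  star <- paste(star, collapse = "")
  loop <- random_dna(loop_len, gc = 0.4)
  precursor <- paste0(mature, loop, star)
  list(precursor = precursor, mature = mature, star = star,
       mature_start = 0L, mature_end = len,
       star_start = len + loop_len, star_end = len + loop_len + nchar(star),
       mismatches = as.integer(mismatches))
}

# Embed `piece` into `seq` at 0-based position `at` (overwriting).
embed_at <- function(seq, piece, at) {
  paste0(substr(seq, 1, at), piece,
         substr(seq, at + nchar(piece) + 1, nchar(seq)))
}

# Complementary target site for `trigger` whose slicing position falls at
# `register` (0-based transcript coordinate of the first base of the
# downstream cleavage fragment, opposite trigger positions 10/11). One
# non-seed mismatch (trigger position 16) is introduced so the site is
# near-perfect but not an exact reverse complement.
make_target_site <- function(trigger, register) {
  len <- nchar(trigger)
  site <- strsplit(revcomp(trigger), "")[[1]]
  p <- len - 16 + 1  # transcript-side index pairing trigger position 16
  site[p] <- noncomplement_of(substr(trigger, 16, 16))
  list(seq = paste(site, collapse = ""),
       start = register - (len - 10L), end = register + 10L)
}

#' Simulate a phased-siRNA gene transcript (PGT)
#'
#' Plants a trigger target site whose cleavage position (opposite trigger
#' positions 10/11) equals `register_start`, then lays down sense phased
#' reads with 5' ends at `register_start + cycle*i` and antisense phased
#' reads whose 5' ends sit at `register_start + cycle*i + 2` (the 2-nt
#' 3'-overhang register convention used by the phasing detector).
#'
#' @param transcript_len transcript length (nt).
#' @param register_start 0-based phase register origin.
#' @param n_cycles number of phased cycles (>= 3).
#' @param trigger trigger sRNA sequence.
#' @param cycle cycle length (default 21).
#' @param transcript optional pre-built transcript sequence to embed into.
#' @return list with `transcript`, `site` (trigger site coords), phased
#'   read tables (`sense`, `antisense`: position is the 5'-end coordinate),
#'   and `register_start`.
#' @export
simulate_pgt <- function(transcript_len, register_start, n_cycles, trigger,
                         cycle = 21L, transcript = NULL) {
  if (n_cycles < 3) stop("simulate_pgt: need at least 3 phased cycles")
  need <- register_start + cycle * n_cycles
  if (need > transcript_len) stop("simulate_pgt: transcript too short for n_cycles")
  if (register_start < nchar(trigger) - 10L) {
    stop("simulate_pgt: register too close to transcript start for the target site")
  }
  if (is.null(transcript)) transcript <- random_dna(transcript_len, gc = 0.45)
  site <- make_target_site(trigger, register_start)
  transcript <- embed_at(transcript, site$seq, site$start)
  sense_pos <- register_start + cycle * (seq_len(n_cycles) - 1L)
  sense <- data.frame(position = sense_pos,
                      sequence = substring(transcript, sense_pos + 1L,
                                           sense_pos + cycle),
                      strand = "+", stringsAsFactors = FALSE)
  as_pos <- register_start + cycle * seq_len(n_cycles - 1L) + 2L
  as_pos <- as_pos[as_pos + 1L <= transcript_len & as_pos - cycle + 1L >= 0L]
  antisense <- data.frame(position = as_pos,
                          sequence = revcomp(substring(transcript,
                                                       as_pos - cycle + 2L,
                                                       as_pos + 1L)),
                          strand = "-", stringsAsFactors = FALSE)
  list(transcript = transcript, site = site,
       sense = sense, antisense = antisense,
       register_start = as.integer(register_start))
}

draw_isomir_offsets <- function(n) {
  # 3'-end variation is made twice as likely as 5'-end variation,
  # mirroring the dominance of 3' variants among plant isomiRs.
  offs <- list()
  guard <- 0L
  while (length(offs) < n && guard < 200L) {
    guard <- guard + 1L
    o5 <- sample(c(-2L, -1L, 0L, 1L, 2L), 1, prob = c(1, 2, 8, 2, 1))
    o3 <- sample(c(-2L, -1L, 0L, 1L, 2L), 1, prob = c(1.5, 3, 5, 3, 1.5))
    if (o5 == 0L && o3 == 0L) next
    key <- paste(o5, o3)
    if (!key %in% names(offs)) offs[[key]] <- c(o5, o3)
  }
  offs
}

#' Simulate a complete planted dataset
#'
#' Builds the reference (hairpin contigs + PGT transcripts + decoys), the
#' planted sRNA species with per-library expected RPM, the raw read
#' libraries, and the ground-truth manifest.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; the run is fully reproducible from it.
#'   Structure generation and each library use independent derived
#'   streams.
#' @return list with elements `reference` (named character vector),
#'   `libraries` (named list of raw read vectors), `manifest` (ground
#'   truth), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 17L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(derive_seed(seed, 0L))

  ## ---- planted matures and hairpins -----------------------------------
  matures <- character(0)
  while (length(matures) < cfg$n_hairpins) {
    m <- random_dna(cfg$mature_len, gc = 0.52)
    gc <- gc_percent(m)
    if (gc >= 40 && gc <= 62 && !(m %in% matures)) matures <- c(matures, m)
  }
  hairpins <- vector("list", cfg$n_hairpins)
  reference <- character(0)
  for (i in seq_len(cfg$n_hairpins)) {
    mm <- sample(1:3, 1, prob = c(0.35, 0.45, 0.2))
    hp <- simulate_hairpin(matures[i], loop_len = cfg$loop_len, mismatches = mm)
    contig_id <- sprintf("hp_contig_%03d", i)
    contig <- paste0(random_dna(cfg$hairpin_flank, gc = 0.4),
                     hp$precursor,
                     random_dna(cfg$hairpin_flank, gc = 0.4))
    reference[contig_id] <- contig
    off <- cfg$hairpin_flank
    hairpins[[i]] <- list(id = sprintf("hairpin_%03d", i),
                          contig_id = contig_id,
                          precursor_start = off,
                          precursor_end = off + nchar(hp$precursor),
                          mature = hp$mature,
                          mature_start = off, mature_end = off + cfg$mature_len,
                          star = hp$star,
                          star_start = off + hp$star_start,
                          star_end = off + hp$star_end,
                          mismatches = hp$mismatches)
  }

  ## ---- known-miRNA library (miRBase stand-in) -------------------------
  # The first half of the planted matures get a "known plant miRNA"
  # relative within 0-3 substitutions, so conserved/lineage-specific
  # classification has a ground truth: those hairpins are conserved, the
  # rest lineage-specific.
  n_known <- cfg$n_hairpins %/% 2L
  known_rows <- vector("list", n_known)
  for (i in seq_len(n_known)) {
    k <- sample(0:3, 1)
    sq <- strsplit(matures[i], "")[[1]]
    if (k > 0) {
      pos <- sample(length(sq), k)
      for (p in pos) sq[p] <- sample(setdiff(VALID_BASES, sq[p]), 1)
    }
    known_rows[[i]] <- data.frame(id = sprintf("known-mir-%03d", i),
                                  sequence = paste(sq, collapse = ""),
                                  parent = sprintf("hairpin_%03d", i),
                                  substitutions = k, stringsAsFactors = FALSE)
  }
  known_mirnas <- do.call(rbind, known_rows)

  ## ---- isomiRs --------------------------------------------------------
  isomirs <- list()
  for (i in seq_len(cfg$n_hairpins)) {
    offs <- draw_isomir_offsets(cfg$n_isomirs_per_mirna)
    hpc <- reference[[hairpins[[i]]$contig_id]]
    for (o in offs) {
      s <- hairpins[[i]]$mature_start + o[1]
      e <- hairpins[[i]]$mature_end + o[2]
      isomirs[[length(isomirs) + 1L]] <-
        list(parent = hairpins[[i]]$id,
             parent_mature = hairpins[[i]]$mature,
             sequence = substring(hpc, s + 1L, e),
             offset5 = o[1], offset3 = o[2])
    }
  }

  ## ---- PGTs -----------------------------------------------------------
  n_pgts <- cfg$n_pgts_mirna + cfg$n_pgts_cis + cfg$n_pgts_trans
  cis_idx <- if (cfg$n_pgts_cis > 0)
    cfg$n_pgts_mirna + seq_len(cfg$n_pgts_cis) else integer(0)
  trans_idx <- if (cfg$n_pgts_trans > 0)
    cfg$n_pgts_mirna + cfg$n_pgts_cis + seq_len(cfg$n_pgts_trans) else integer(0)
  register1 <- 90L
  pgts <- vector("list", n_pgts)

  build_pgt <- function(i, trigger, trigger_class, trigger_origin) {
    contig_id <- sprintf("transcript_%03d", i)
    pg <- simulate_pgt(cfg$transcript_len, register1, cfg$n_cycles, trigger,
                       cycle = cfg$cycle)
    res <- list(id = sprintf("pgt_%03d", i), contig_id = contig_id,
                transcript = pg$transcript,
                registers = list(list(
                  register_start = register1,
                  trigger = trigger, trigger_class = trigger_class,
                  trigger_origin = trigger_origin,
                  expected_mode = if (trigger_class == "miRNA") "initiator" else "trans",
                  site_start = pg$site$start, site_end = pg$site$end,
                  sense = pg$sense, antisense = pg$antisense)))
    res
  }

  for (i in seq_len(cfg$n_pgts_mirna + cfg$n_pgts_cis)) {
    pgts[[i]] <- build_pgt(i, matures[i], "miRNA", hairpins[[i]]$id)
  }
  # cis: a second register on the same transcript, triggered by one of the
  # transcript's own primary-register phased siRNAs.
  for (i in cis_idx) {
    p <- pgts[[i]]
    trig <- p$registers[[1]]$sense$sequence[2]
    # place the secondary register well clear of the primary read block
    # (more than one scan window), so the two phased loci stay separable
    register2 <- register1 + cfg$cycle * (cfg$n_cycles + 2L) + 189L + 10L
    n_cyc2 <- (cfg$transcript_len - register2 - cfg$cycle) %/% cfg$cycle
    n_cyc2 <- min(n_cyc2, 6L)
    pg2 <- simulate_pgt(cfg$transcript_len, register2, n_cyc2, trig,
                        cycle = cfg$cycle, transcript = p$transcript)
    p$transcript <- pg2$transcript
    # re-extract primary register reads from the final transcript (the
    # secondary site may overwrite a base of a primary-register read)
    r1 <- p$registers[[1]]
    r1$sense$sequence <- substring(p$transcript, r1$sense$position + 1L,
                                   r1$sense$position + cfg$cycle)
    r1$antisense$sequence <- revcomp(substring(p$transcript,
                                               r1$antisense$position - cfg$cycle + 2L,
                                               r1$antisense$position + 1L))
    r1$sense <- r1$sense; p$registers[[1]] <- r1
    p$registers[[2]] <- list(register_start = register2,
                             trigger = trig, trigger_class = "pha-siRNA",
                             trigger_origin = p$id,
                             expected_mode = "cis",
                             site_start = pg2$site$start, site_end = pg2$site$end,
                             sense = pg2$sense, antisense = pg2$antisense)
    pgts[[i]] <- p
  }
  # trans: register set by a phased siRNA exported from another PGT.
  for (k in seq_along(trans_idx)) {
    i <- trans_idx[k]
    donor <- pgts[[k]]
    trig <- donor$registers[[1]]$sense$sequence[3]
    pgts[[i]] <- build_pgt(i, trig, "pha-siRNA", donor$id)
  }
  for (i in seq_len(n_pgts)) {
    reference[pgts[[i]]$contig_id] <- pgts[[i]]$transcript
  }

  ## ---- non-phased siRNAs on PGTs -------------------------------------
  for (i in seq_len(n_pgts)) {
    p <- pgts[[i]]
    reg_classes <- vapply(p$registers, function(r)
      r$register_start %% cfg$cycle, numeric(1))
    bad <- unique(c(reg_classes, (reg_classes + 2) %% cfg$cycle))
    pos <- integer(0)
    guard <- 0L
    while (length(pos) < cfg$n_nonphased && guard < 500L) {
      guard <- guard + 1L
      cand <- sample(110:(cfg$transcript_len - cfg$cycle - 1L), 1)
      if ((cand %% cfg$cycle) %in% bad) next
      if (any(abs(cand - pos) < cfg$cycle)) next
      pos <- c(pos, cand)
    }
    p$nonphased <- data.frame(position = pos,
                              sequence = substring(p$transcript, pos + 1L,
                                                   pos + cfg$cycle),
                              strand = "+", stringsAsFactors = FALSE)
    pgts[[i]] <- p
  }

  ## ---- decoy contigs --------------------------------------------------
  for (i in seq_len(cfg$n_decoys)) {
    reference[sprintf("decoy_%04d", i)] <- random_dna(cfg$decoy_len, gc = 0.42)
  }

  ## ---- species table with expected RPM -------------------------------
  species <- list()
  add_species <- function(sequence, rpm, role, origin) {
    species[[length(species) + 1L]] <<-
      list(sequence = sequence, rpm = rpm, role = role, origin = origin)
  }
  for (i in seq_len(cfg$n_hairpins)) {
    m_rpm <- min(max(stats::rlnorm(1, log(3000), 0.7), 800), 20000)
    add_species(hairpins[[i]]$mature, m_rpm, "mature", hairpins[[i]]$id)
    add_species(hairpins[[i]]$star, max(m_rpm * stats::runif(1, 0.03, 0.15), 50),
                "star", hairpins[[i]]$id)
  }
  mature_rpm <- if (cfg$n_hairpins > 0) {
    vapply(species[seq(1, 2 * cfg$n_hairpins, 2)], `[[`, numeric(1), "rpm")
  } else numeric(0)
  for (iso in isomirs) {
    i <- as.integer(sub("hairpin_", "", iso$parent))
    add_species(iso$sequence, max(mature_rpm[i] * stats::runif(1, 0.05, 0.3), 50),
                "isomir", iso$parent)
  }
  for (i in seq_len(n_pgts)) {
    p <- pgts[[i]]
    for (r in p$registers) {
      base <- min(max(stats::rlnorm(1, log(400), 0.5), 150), 2000)
      for (j in seq_len(nrow(r$sense))) {
        add_species(r$sense$sequence[j], base * stats::runif(1, 0.4, 1.6),
                    "phased", p$id)
      }
      for (j in seq_len(nrow(r$antisense))) {
        add_species(r$antisense$sequence[j], base * stats::runif(1, 0.3, 1.2),
                    "phased", p$id)
      }
    }
    for (j in seq_len(nrow(p$nonphased))) {
      add_species(p$nonphased$sequence[j], stats::runif(1, 50, 150),
                  "nonphased", p$id)
    }
  }
  sp <- data.frame(sequence = vapply(species, `[[`, character(1), "sequence"),
                   base_rpm = vapply(species, `[[`, numeric(1), "rpm"),
                   role = vapply(species, `[[`, character(1), "role"),
                   origin = vapply(species, `[[`, character(1), "origin"),
                   stringsAsFactors = FALSE)
  # collapse duplicated species (e.g. a read shared by two registers)
  if (anyDuplicated(sp$sequence)) {
    agg <- tapply(sp$base_rpm, sp$sequence, sum)
    first <- !duplicated(sp$sequence)
    sp <- sp[first, , drop = FALSE]
    sp$base_rpm <- as.numeric(agg[sp$sequence])
  }

  ## ---- tissue effects -------------------------------------------------
  rpm_mat <- matrix(rep(sp$base_rpm, cfg$n_libraries), ncol = cfg$n_libraries,
                    dimnames = list(NULL, paste0("lib", seq_len(cfg$n_libraries))))
  de_pool_m <- which(sp$role == "mature")
  de_pool_s <- which(sp$role == "phased")
  de_m <- sample(de_pool_m, min(cfg$n_de_mirna, length(de_pool_m)))
  de_s <- sample(de_pool_s, min(cfg$n_de_sirna, length(de_pool_s)))
  de_rows <- c(de_m, de_s)
  de_lib <- sample(cfg$n_libraries, length(de_rows), replace = TRUE)
  for (k in seq_along(de_rows)) {
    rpm_mat[de_rows[k], de_lib[k]] <- rpm_mat[de_rows[k], de_lib[k]] * cfg$de_fold
  }

  manifest <- list(
    rng_seed = as.integer(seed),
    known_mirnas = known_mirnas,
    planted_hairpins = hairpins,
    planted_isomirs = isomirs,
    planted_pgts = lapply(pgts, function(p) p[setdiff(names(p), "transcript")]),
    species = sp,
    tissue_effects = data.frame(
      sequence = sp$sequence[de_rows],
      role = sp$role[de_rows],
      up_library = colnames(rpm_mat)[de_lib],
      fold = rep(cfg$de_fold, length(de_rows)), stringsAsFactors = FALSE),
    expected_rpm = cbind(data.frame(sequence = sp$sequence,
                                    stringsAsFactors = FALSE),
                         as.data.frame(rpm_mat))
  )

  libraries <- simulate_libraries(manifest, reference, cfg, seed)
  list(reference = reference, libraries = libraries,
       manifest = manifest, config = cfg)
}

#' Emit raw read libraries from a manifest
#'
#' Planted species counts are drawn from a negative binomial around the
#' expected per-library RPM; background reads are uniform 18-26-mers
#' sampled from the reference (so they map), with lengths following the
#' configured profile. One RNG stream per library (`seed + library index`
#' derivation) keeps libraries individually reproducible.
#'
#' @param manifest manifest from [simulate_dataset()].
#' @param reference named character vector of reference sequences.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return named list of character vectors of raw reads.
#' @export
simulate_libraries <- function(manifest, reference, config, seed) {
  cfg <- config
  if (cfg$depth <= 0) stop("simulate_libraries: depth must be positive")
  rpm_cols <- setdiff(names(manifest$expected_rpm), "sequence")
  out <- vector("list", cfg$n_libraries)
  names(out) <- rpm_cols
  ref_names <- names(reference)
  ref_len <- nchar(reference)
  lens <- as.integer(names(cfg$length_profile))
  size <- 1 / cfg$dispersion
  for (l in seq_len(cfg$n_libraries)) {
    set.seed(derive_seed(seed, l))
    mu <- manifest$expected_rpm[[rpm_cols[l]]] * cfg$depth / 1e6
    counts <- stats::rnbinom(length(mu), mu = mu, size = size)
    planted <- rep(manifest$expected_rpm$sequence, counts)
    n_bg <- round(cfg$depth * cfg$background_frac)
    bg <- character(0)
    if (n_bg > 0) {
      bg_len <- sample(lens, n_bg, replace = TRUE, prob = cfg$length_profile)
      w <- pmax(ref_len - max(lens), 0)
      bg_contig <- sample(ref_names, n_bg, replace = TRUE, prob = w)
      bg_start <- floor(stats::runif(n_bg) * (ref_len[bg_contig] - bg_len)) + 1L
      bg <- substring(reference[bg_contig], bg_start, bg_start + bg_len - 1L)
      flip <- stats::runif(n_bg) < 0.5
      if (any(flip)) bg[flip] <- revcomp(bg[flip])
    }
    out[[l]] <- c(planted, bg)
  }
  out
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest manifest list.
#' @param path file path.
#' @return `write_manifest`: invisibly, `path`; `read_manifest`: the
#'   manifest.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  cols_to_df <- function(x) {
    as.data.frame(lapply(x, function(cl)
      if (length(cl)) unlist(cl) else character(0)),
      stringsAsFactors = FALSE)
  }
  m$rng_seed <- as.integer(m$rng_seed)
  for (fld in c("known_mirnas", "species", "tissue_effects", "expected_rpm")) {
    if (!is.null(m[[fld]])) m[[fld]] <- cols_to_df(m[[fld]])
  }
  m$planted_pgts <- lapply(m$planted_pgts, function(p) {
    p$registers <- lapply(p$registers, function(r) {
      r$sense <- cols_to_df(r$sense)
      r$antisense <- cols_to_df(r$antisense)
      r
    })
    p$nonphased <- cols_to_df(p$nonphased)
    p
  })
  m
}
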