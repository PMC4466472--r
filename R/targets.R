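# Plant small-RNA target scoring and trigger prediction. The scorer is
# the classic plant-target penalty scheme: ungapped complementary windows
# scored with mismatch 1.0, G:U wobble 0.5, penalties doubled at sRNA
# positions 2-13 from the 5' end; sites at or below the expectation
# cutoff are reported with the cleavage position opposite sRNA positions
# 10/11. Gapped alignments are not searched (cleavage-competent plant
# sites are overwhelmingly ungapped; the gap penalty of 2.0 would be
# applied per gap if they were).

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# penalty_matrix[srna_base, transcript_base]: the sRNA pairs antiparallel
# with the transcript, so "match" means Watson-Crick complement.
penalty_lookup <- function(w_mismatch = 1.0, w_gu = 0.5) {
  P <- matrix(w_mismatch, 4, 4, dimnames = list(names(BASE_CODE), names(BASE_CODE)))
  P["A", "T"] <- 0; P["C", "G"] <- 0; P["G", "C"] <- 0; P["T", "A"] <- 0
  P["G", "T"] <- w_gu   # sRNA G : target U
  P["T", "G"] <- w_gu   # sRNA U : target G
  P
}

#' Score sRNA target sites on a transcript
#'
#' @param srna sRNA sequence (18-26 nt).
#' @param transcript transcript sequence.
#' @param cutoff maximum expectation score of reported sites (default
#'   3.0).
#' @param seed_range sRNA positions (from the 5' end) where penalties are
#'   doubled (default 2-13).
#' @param w_mismatch,w_gu penalty weights.
#' @return data.frame of sites: `site_start`, `site_end` (0-based
#'   half-open transcript coords), `expectation`, `cleavage_pos` (0-based
#'   transcript coordinate of the base opposite sRNA position 10, the
#'   first base of the downstream cleavage fragment).
#' @export
score_target <- function(srna, transcript, cutoff = 3.0,
                         seed_range = c(2L, 13L),
                         w_mismatch = 1.0, w_gu = 0.5) {
  srna <- normalize_seq(srna)
  transcript <- normalize_seq(transcript)
  L <- nchar(srna)
  n <- nchar(transcript)
  if (L < 18 || L > 26) stop("score_target: sRNA must be 18-26 nt")
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      expectation = numeric(0), cleavage_pos = integer(0))
  if (n < L) return(empty)
  P <- penalty_lookup(w_mismatch, w_gu)
  s <- BASE_CODE[strsplit(srna, "")[[1]]]
  t <- BASE_CODE[strsplit(transcript, "")[[1]]]
  nw <- n - L + 1L
  expect <- numeric(nw)
  for (i in seq_len(L)) {
    # sRNA position i (1-based from 5') pairs transcript index
    # site_start + L - i (0-based), i.e. 1-based position ws + L - i
    # for window starting at 1-based ws.
    w <- if (i >= seed_range[1] && i <= seed_range[2]) 2 else 1
    tpos <- seq_len(nw) + (L - i)
    expect <- expect + w * P[cbind(s[i], t[tpos])]
  }
  keep <- which(!is.na(expect) & expect <= cutoff)
  if (length(keep) == 0) return(empty)
  site_start <- keep - 1L
  data.frame(site_start = site_start, site_end = site_start + L,
             expectation = expect[keep],
             cleavage_pos = site_start + L - 10L)
}

#' Predict triggers of phased siRNA loci
#'
#' A candidate sRNA is a trigger of a PGT locus when it has a target site
#' on the locus transcript whose cleavage position falls in the locus
#' register (within `tolerance` nt modulo the cycle). The hit model is
#' `two_hit` when the same sRNA has qualifying sites both upstream and
#' downstream of the register origin, else `one_hit`. Candidates must
#' themselves be expressed (total count >= `min_expression`).
#'
#' @param pgts locus table from [call_pgts()].
#' @param candidates data.frame of candidate sRNAs: `sequence`, `class`
#'   (`miRNA`/`isomiRNA`/`pha-siRNA`/`nonpha-siRNA`), `origin` (PGT id for
#'   siRNAs, `NA` otherwise), `total_count`.
#' @param index the `ref_index` (supplies locus transcripts).
#' @param cutoff expectation cutoff (default 3.0).
#' @param tolerance in-phase tolerance in nt (default 0; +/-1 supported).
#' @param cycle cycle length.
#' @param min_expression minimum trigger expression (default 2).
#' @return data.frame of assignments: `pgt_id`, `trigger`, `trigger_class`,
#'   `trigger_origin`, `site_start`, `site_end`, `expectation`,
#'   `cleavage_pos`, `in_phase`, `hit_model`.
#' @export
predict_triggers <- function(pgts, candidates, index, cutoff = 3.0,
                             tolerance = 0L, cycle = 21L,
                             min_expression = 2) {
  empty <- data.frame(pgt_id = character(0), trigger = character(0),
                      trigger_class = character(0), trigger_origin = character(0),
                      site_start = integer(0), site_end = integer(0),
                      expectation = numeric(0), cleavage_pos = integer(0),
                      in_phase = logical(0), hit_model = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pgts) == 0 || nrow(candidates) == 0) return(empty)
  candidates <- candidates[candidates$total_count >= min_expression, ,
                           drop = FALSE]
  candidates <- candidates[!duplicated(paste(candidates$sequence,
                                             candidates$class)), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pgts))) {
    pgt <- pgts[i, ]
    transcript <- as.character(index$ref[[pgt$contig_id]])
    for (j in seq_len(nrow(candidates))) {
      sites <- score_target(candidates$sequence[j], transcript, cutoff = cutoff)
      if (nrow(sites) == 0) next
      off <- (sites$cleavage_pos - pgt$register) %% cycle
      inph <- off <= tolerance | off >= cycle - tolerance
      if (!any(inph)) next
      hit_model <- if (any(sites$cleavage_pos <= pgt$register) &&
                       any(sites$cleavage_pos > pgt$register))
        "two_hit" else "one_hit"
      sel <- sites[inph, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        pgt_id = pgt$pgt_id,
        trigger = candidates$sequence[j],
        trigger_class = candidates$class[j],
        trigger_origin = candidates$origin[j],
        site_start = sel$site_start, site_end = sel$site_end,
        expectation = sel$expectation, cleavage_pos = sel$cleavage_pos,
        in_phase = TRUE, hit_model = hit_model,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$pgt_id, out$trigger, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify trigger assignments as initiator, cis or trans cleavage
#'
#' For each transcript the primary register is the one of its
#' lowest-p-value locus having a miRNA/isomiRNA trigger (or simply its
#' lowest-p locus when none has one). Then: a miRNA/isomiRNA trigger of
#' the primary-register locus is the `initiator`; a phased/non-phased
#' siRNA trigger originating from a locus on the same transcript is
#' `cis`; everything else (siRNAs from other PGTs, and miRNAs/isomiRNAs
#' acting on a non-primary register) is `trans`.
#'
#' @param assignments data.frame from [predict_triggers()].
#' @param pgts locus table from [call_pgts()] (maps loci to transcripts).
#' @return `assignments` with a `cleavage_mode` column.
#' @export
classify_cleavage <- function(assignments, pgts) {
  if (nrow(assignments) == 0) {
    assignments$cleavage_mode <- character(0)
    return(assignments)
  }
  if (any(is.na(assignments$trigger_class))) {
    stop("classify_cleavage: trigger class unknown")
  }
  sirna_classes <- c("pha-siRNA", "nonpha-siRNA")
  is_sirna <- assignments$trigger_class %in% sirna_classes
  if (any(is_sirna & (is.na(assignments$trigger_origin) |
                      !nzchar(assignments$trigger_origin)))) {
    stop("classify_cleavage: siRNA trigger with unknown PGT origin")
  }
  transcript_of <- stats::setNames(pgts$contig_id, pgts$pgt_id)
  # primary locus per transcript
  mir_pgts <- unique(assignments$pgt_id[assignments$trigger_class %in%
                                          c("miRNA", "isomiRNA")])
  primary <- character(0)
  for (tr in unique(pgts$contig_id)) {
    sub <- pgts[pgts$contig_id == tr, , drop = FALSE]
    with_mir <- sub[sub$pgt_id %in% mir_pgts, , drop = FALSE]
    pick <- if (nrow(with_mir) > 0) with_mir else sub
    primary[tr] <- pick$pgt_id[which.min(pick$p_value)]
  }
  tr_of_target <- transcript_of[assignments$pgt_id]
  tr_of_origin <- transcript_of[assignments$trigger_origin]
  is_primary <- assignments$pgt_id == primary[tr_of_target]
  mode <- character(nrow(assignments))
  mir <- assignments$trigger_class %in% c("miRNA", "isomiRNA")
  mode[mir & is_primary] <- "initiator"
  mode[mir & !is_primary] <- "trans"
  same <- !is.na(tr_of_origin) & tr_of_origin == tr_of_target
  mode[is_sirna & same] <- "cis"
  mode[is_sirna & !same] <- "trans"
  assignments$cleavage_mode <- mode
  assignments
}

#' Assemble the sRNA regulatory network
#'
#' Nodes are sRNA sequences and transcripts; directed edges run from a
#' trigger sRNA to the transcript of the PGT locus it cleaves (typed
#' `initiator`/`cis`/`trans`), and optionally from sRNAs to plain target
#' transcripts (type `target`). Cycles are legitimate (secondary siRNA
#' cascades can feed back) and are preserved.
#'
#' @param assignments classified assignments from [classify_cleavage()].
#' @param pgts locus table.
#' @param target_sites optional data.frame with `srna`, `transcript_id`,
#'   `expectation` for plain (non-trigger) target edges.
#' @return an [igraph::graph] with vertex attribute `kind`
#'   (`srna`/`transcript`) and edge attributes `type`, `expectation`,
#'   `pgt_id`.
#' @export
build_network <- function(assignments, pgts, target_sites = NULL) {
  edges <- data.frame(from = character(0), to = character(0),
                      type = character(0), expectation = numeric(0),
                      pgt_id = character(0), stringsAsFactors = FALSE)
  if (nrow(assignments) > 0) {
    transcript_of <- stats::setNames(pgts$contig_id, pgts$pgt_id)
    edges <- rbind(edges, data.frame(
      from = assignments$trigger,
      to = unname(transcript_of[assignments$pgt_id]),
      type = assignments$cleavage_mode,
      expectation = assignments$expectation,
      pgt_id = assignments$pgt_id, stringsAsFactors = FALSE))
  }
  if (!is.null(target_sites) && nrow(target_sites) > 0) {
    edges <- rbind(edges, data.frame(
      from = target_sites$srna, to = target_sites$transcript_id,
      type = "target", expectation = target_sites$expectation,
      pgt_id = NA_character_, stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to, edges$type), , drop = FALSE]
  srna_nodes <- sort(unique(edges$from))
  tx_nodes <- sort(unique(edges$to))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = c(srna_nodes, setdiff(tx_nodes, srna_nodes)),
                          kind = c(rep("srna", length(srna_nodes)),
                                   rep("transcript",
                                       length(setdiff(tx_nodes, srna_nodes)))),
                          stringsAsFactors = FALSE))
  g
}

#' Serialize a regulatory network deterministically
#'
#' Writes a GraphML file and an edge-list TSV.
#'
#' @param g graph from [build_network()].
#' @param graphml_path,edges_path output paths (`NULL` to skip either).
#' @return invisibly, the edge-list data.frame.
#' @export
write_network <- function(g, graphml_path = NULL, edges_path = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  el <- el[order(el$from, el$to, el$type), , drop = FALSE]
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) write_tsv_stable(el, edges_path)
  invisible(el)
}
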