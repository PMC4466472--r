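# Comparison of a pipeline run against the ground-truth manifest of the
# synthetic dataset: recovery rates for planted matures, PGT registers,
# trigger labels, isomiRs and tissue effects.

#' Evaluate a pipeline run against the planted ground truth
#'
#' @param result list from [run_all()].
#' @param manifest ground-truth manifest (default: the one inside
#'   `result`).
#' @param cycle phasing cycle length.
#' @return list of evaluation blocks:
#'   \describe{
#'     \item{mirna}{`precision`, `recall` of called mature sequences,
#'       `conservation_accuracy` over recovered matures.}
#'     \item{pgt}{`recall` of planted (transcript, register) pairs;
#'       `n_planted`, `n_recovered`.}
#'     \item{triggers}{`n_planted`, `n_recovered`, `label_accuracy`
#'       (fraction of recovered planted triggers whose cleavage mode
#'       matches the planted one), and the per-register detail table.}
#'     \item{isomir}{`recall` of planted isomiR sequences.}
#'     \item{de}{`recall` of planted tissue effects among `significant`
#'       calls.}
#'   }
#' @export
evaluate_run <- function(result, manifest = result$sim$manifest, cycle = 21L) {
  ## miRNA precision / recall
  truth <- vapply(manifest$planted_hairpins, function(h) h$mature, character(1))
  called <- result$mirna$annotations$mature_seq
  tp <- sum(called %in% truth)
  mir_eval <- list(
    precision = if (length(called) > 0) tp / length(called) else NA_real_,
    recall = tp / length(truth),
    n_called = length(called), n_planted = length(truth))
  ## conservation accuracy on recovered matures
  km <- manifest$known_mirnas
  if (!is.null(km)) {
    # matures of hairpins with a known relative are the conserved truth
    hp_ids <- vapply(manifest$planted_hairpins, function(h) h$id, character(1))
    cs_truth <- hp_ids %in% km$parent
    names(cs_truth) <- truth
    rec <- intersect(called, truth)
    if (length(rec) > 0) {
      pred <- result$mirna$annotations$conservation[
        match(rec, result$mirna$annotations$mature_seq)]
      mir_eval$conservation_accuracy <-
        mean((pred == "cs") == cs_truth[rec])
    }
  }

  ## PGT register recovery and trigger labels
  planted <- list()
  for (p in manifest$planted_pgts) {
    for (r in p$registers) {
      planted[[length(planted) + 1L]] <- data.frame(
        pgt = p$id, contig_id = p$contig_id,
        register = r$register_start,
        trigger = r$trigger, trigger_class = r$trigger_class,
        expected_mode = r$expected_mode, stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, planted)
  pgts <- result$pgts
  planted$recovered <- FALSE
  planted$called_pgt <- NA_character_
  planted$trigger_found <- FALSE
  planted$mode_called <- NA_character_
  for (i in seq_len(nrow(planted))) {
    hit <- which(pgts$contig_id == planted$contig_id[i] &
                   (pgts$register %% cycle) == (planted$register[i] %% cycle) &
                   pgts$locus_start <= planted$register[i] + cycle &
                   pgts$locus_end >= planted$register[i])
    if (length(hit) == 0) next
    planted$recovered[i] <- TRUE
    pid <- pgts$pgt_id[hit[1]]
    planted$called_pgt[i] <- pid
    tr <- result$triggers
    sel <- tr$pgt_id == pid & tr$trigger == planted$trigger[i] &
      tr$trigger_class == planted$trigger_class[i]
    if (any(sel)) {
      planted$trigger_found[i] <- TRUE
      planted$mode_called[i] <- tr$cleavage_mode[which(sel)[1]]
    }
  }
  pgt_eval <- list(recall = mean(planted$recovered),
                   n_planted = nrow(planted),
                   n_recovered = sum(planted$recovered))
  rec_trig <- planted[planted$recovered & planted$trigger_found, , drop = FALSE]
  trig_eval <- list(
    n_planted = nrow(planted),
    n_recovered = nrow(rec_trig),
    label_accuracy = if (nrow(rec_trig) > 0)
      mean(rec_trig$mode_called == rec_trig$expected_mode) else NA_real_,
    detail = planted)

  ## isomiR recovery
  iso_truth <- vapply(manifest$planted_isomirs, `[[`, character(1), "sequence")
  iso_truth <- setdiff(unique(iso_truth), truth)
  iso_eval <- list(
    recall = if (length(iso_truth) > 0)
      mean(iso_truth %in% result$isomirs$sequence) else NA_real_,
    n_planted = length(iso_truth))

  ## DE recovery
  de_truth <- manifest$tissue_effects$sequence
  cats <- result$de$categories
  de_eval <- list(
    recall = if (length(de_truth) > 0)
      mean(de_truth %in% cats$sequence[cats$category == "significant"])
    else NA_real_,
    n_planted = length(de_truth))

  list(mirna = mir_eval, pgt = pgt_eval, triggers = trig_eval,
       isomir = iso_eval, de = de_eval)
}
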