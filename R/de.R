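# Pairwise-tissue differential expression of sRNA read counts: pooled
# two-proportion Z-test (Kal et al. 1999) on raw counts against library
# totals, Benjamini-Hochberg FDR within each pair, fold-change
# categorization, and Z-score hierarchical clustering of the significant
# set.

#' Pooled two-proportion Z-test on tag counts (Kal's test)
#'
#' With proportions `p_i = count_i / total_i` and pooled `p0`, the
#' statistic is `z = (p_a - p_b) / sqrt(p0 (1 - p0) (1/total_a +
#' 1/total_b))`; the two-sided p-value is `2 (1 - Phi(|z|))`. Degenerate
#' pooled proportions (0 or 1) yield `z = 0`, `p = 1` by convention.
#'
#' @param count_a,count_b tag counts (vectorized).
#' @param total_a,total_b library totals (> 0).
#' @return data.frame with columns `z` and `p`.
#' @export
kal_test <- function(count_a, total_a, count_b, total_b) {
  if (any(total_a <= 0) || any(total_b <= 0)) {
    stop("kal_test: library totals must be positive")
  }
  if (any(count_a > total_a) || any(count_b > total_b)) {
    stop("kal_test: counts exceed library totals")
  }
  pa <- count_a / total_a
  pb <- count_b / total_b
  p0 <- (count_a + count_b) / (total_a + total_b)
  se <- sqrt(p0 * (1 - p0) * (1 / total_a + 1 / total_b))
  z <- ifelse(se > 0, (pa - pb) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(abs(z), lower.tail = FALSE), 1)
  data.frame(z = z, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, stable under input
#' order.
#'
#' @param p_values numeric vector in `[0,1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise differential expression over libraries
#'
#' Runs [kal_test()] for every requested library pair on raw counts
#' against the library totals, with BH FDR within each pair. Fold changes
#' are RPM ratios (larger over smaller); a zero denominator uses a
#' pseudo-RPM of `pseudo_rpm` and is flagged.
#'
#' @param reads an `srna_reads` collection with RPM populated.
#' @param library_totals named totals used as Kal-test denominators.
#' @param pairs list of 2-vectors of library ids (default: all pairs).
#' @param pseudo_rpm pseudo-RPM used for zero denominators (default 0.1).
#' @return data.frame with one row per sequence x pair: `sequence`,
#'   `lib_a`, `lib_b`, `count_a`, `count_b`, `rpm_a`, `rpm_b`, `z`, `p`,
#'   `q`, `fold_change`, `fold_pseudo` (flag).
#' @export
de_pairwise <- function(reads, library_totals, pairs = NULL, pseudo_rpm = 0.1) {
  libs <- colnames(reads$counts)
  if (is.null(pairs)) {
    pairs <- utils::combn(libs, 2, simplify = FALSE)
  }
  out <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    kt <- kal_test(reads$counts[, a], library_totals[[a]],
                   reads$counts[, b], library_totals[[b]])
    rpm_a <- reads$rpm[, a]; rpm_b <- reads$rpm[, b]
    hi <- pmax(rpm_a, rpm_b); lo <- pmin(rpm_a, rpm_b)
    pseudo <- lo == 0
    fold <- hi / ifelse(pseudo, pseudo_rpm, lo)
    nseq <- length(reads$sequence)
    out[[length(out) + 1L]] <- data.frame(
      sequence = reads$sequence,
      lib_a = rep(a, nseq), lib_b = rep(b, nseq),
      count_a = reads$counts[, a], count_b = reads$counts[, b],
      rpm_a = rpm_a, rpm_b = rpm_b,
      z = kt$z, p = kt$p, q = bh_fdr(kt$p),
      fold_change = fold, fold_pseudo = pseudo,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Categorize sequences from pairwise DE results
#'
#' `significant`: FDR q below `fdr_cut` in at least one pair.
#' `likely`: not significant, but expressed at or above `min_rpm` in at
#' least one library and changed at least `min_fold`-fold in at least one
#' pair. Everything else is `ns`.
#'
#' @param results data.frame from [de_pairwise()].
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param min_rpm expression floor for the `likely` rule (default 5 RPM).
#' @param min_fold fold-change floor for the `likely` rule (default 2).
#' @return data.frame: `sequence`, `min_q`, `max_rpm`, `max_fold`,
#'   `category`.
#' @export
categorize_de <- function(results, fdr_cut = 0.05, min_rpm = 5, min_fold = 2) {
  sp <- split(seq_len(nrow(results)), results$sequence)
  seqs <- names(sp)
  min_q <- vapply(sp, function(ix) min(results$q[ix]), numeric(1))
  max_rpm <- vapply(sp, function(ix)
    max(results$rpm_a[ix], results$rpm_b[ix]), numeric(1))
  max_fold <- vapply(sp, function(ix) max(results$fold_change[ix]), numeric(1))
  category <- ifelse(min_q < fdr_cut, "significant",
                     ifelse(max_rpm >= min_rpm & max_fold >= min_fold,
                            "likely", "ns"))
  out <- data.frame(sequence = seqs, min_q = min_q, max_rpm = max_rpm,
                    max_fold = max_fold, category = category,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Row-wise Z-score standardization and hierarchical clustering
#'
#' Standardizes each row of an RPM matrix to mean 0 and (sample) SD 1
#' (constant rows become all-zero), then clusters rows by complete-linkage
#' agglomeration on Euclidean distance and cuts the tree into `k_groups`
#' expression groups.
#'
#' @param rpm_matrix numeric matrix, rows = sequences, columns =
#'   libraries.
#' @param k_groups number of expression groups (default 5).
#' @return list with `z` (standardized matrix), `cluster_group` (integer
#'   per row; all 1 when fewer than 2 rows), `hclust` (or `NULL`).
#' @export
zscore_and_cluster <- function(rpm_matrix, k_groups = 5L) {
  rpm_matrix <- as.matrix(rpm_matrix)
  mu <- rowMeans(rpm_matrix)
  sdev <- apply(rpm_matrix, 1, stats::sd)
  z <- (rpm_matrix - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  if (nrow(z) < 2) {
    return(list(z = z, cluster_group = rep(1L, nrow(z)), hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "complete")
  k <- min(k_groups, nrow(z))
  list(z = z, cluster_group = stats::cutree(hc, k = k), hclust = hc)
}
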