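# isomiR classification: end-variant typing of reads deriving from
# accepted miRNA loci, multi-locus attribution, and length/abundance
# summaries.

#' Classify a pair of end offsets into an isomiR variant class
#'
#' Offsets are read coordinates minus canonical mature coordinates in the
#' precursor's 5'->3' orientation (`offset5 = read start - mature start`,
#' `offset3 = read end - mature end`).
#'
#' @param offset5,offset3 integer end offsets.
#' @param max_offset reads with either |offset| beyond this are not
#'   isomiRs of the reference sequence (default 5 nt).
#' @return one of `"mature"` (both zero), `"five_prime"`, `"three_prime"`,
#'   `"both"`, or `"other"` (offset out of range).
#' @export
classify_isomir_offsets <- function(offset5, offset3, max_offset = 5L) {
  stopifnot(length(offset5) == length(offset3))
  out <- rep("other", length(offset5))
  inr <- abs(offset5) <= max_offset & abs(offset3) <= max_offset
  out[inr & offset5 == 0 & offset3 == 0] <- "mature"
  out[inr & offset5 != 0 & offset3 == 0] <- "five_prime"
  out[inr & offset5 == 0 & offset3 != 0] <- "three_prime"
  out[inr & offset5 != 0 & offset3 != 0] <- "both"
  out
}

#' Classify a read against a canonical mature within its precursor
#'
#' Locates the read and the mature in the precursor (sense orientation,
#' templated variants only) and classifies the end variation. Reads
#' identical to the mature return class `"mature"` (not an isomiR); reads
#' not contained in the precursor, or with end offsets beyond
#' `max_offset`, return `"other"`.
#'
#' @param read read sequence.
#' @param parent_mature canonical mature sequence.
#' @param precursor precursor sequence (5'->3').
#' @param max_offset maximum end offset magnitude (default 5).
#' @return list with `variant_class`, `offset5`, `offset3` (offsets `NA`
#'   when the read is not contained in the precursor).
#' @export
classify_isomir <- function(read, parent_mature, precursor, max_offset = 5L) {
  read <- normalize_seq(read)
  parent_mature <- normalize_seq(parent_mature)
  precursor <- normalize_seq(precursor)
  mpos <- regexpr(parent_mature, precursor, fixed = TRUE)[1]
  rpos <- regexpr(read, precursor, fixed = TRUE)[1]
  if (mpos < 0) stop("classify_isomir: mature not found in precursor")
  if (rpos < 0) {
    return(list(variant_class = "other", offset5 = NA_integer_,
                offset3 = NA_integer_))
  }
  o5 <- rpos - mpos
  o3 <- (rpos + nchar(read)) - (mpos + nchar(parent_mature))
  list(variant_class = classify_isomir_offsets(o5, o3, max_offset),
       offset5 = as.integer(o5), offset3 = as.integer(o3))
}

#' Attribute an isomiR to all precursors that can produce it
#'
#' @param isomir isomiR sequence.
#' @param precursors named character vector of precursor sequences (sense
#'   orientation).
#' @return sorted character vector of precursor names containing the
#'   isomiR.
#' @export
attribute_multilocus <- function(isomir, precursors) {
  isomir <- normalize_seq(isomir)
  hit <- vapply(normalize_seq(precursors), function(p)
    grepl(isomir, p, fixed = TRUE), logical(1))
  sort(names(precursors)[hit])
}

#' Collect and classify isomiRs at accepted miRNA loci
#'
#' Every mapped read falling inside an accepted precursor window (on the
#' precursor's sense strand) that is not the annotated mature or star is
#' classified relative to the mature arm; reads varying around the star
#' arm instead are classified against the star and reported separately
#' (`arm = "star"`). Reads matching neither arm within the offset bound
#' are tallied as `"other"`.
#'
#' @param reads an `srna_reads` collection (RPM populated).
#' @param hits mapping table.
#' @param precursors accepted precursor table from [discover_mirnas()].
#' @param max_offset maximum end offset magnitude (default 5).
#' @return data.frame: `sequence`, `parent` (precursor id), `parent_mature`,
#'   `arm` (`mature`/`star`), `variant_class`, `offset5`, `offset3`,
#'   `total_count`, `total_rpm`, `source_precursors`.
#' @export
collect_isomirs <- function(reads, hits, precursors, max_offset = 5L) {
  empty <- data.frame(sequence = character(0), parent = character(0),
                      parent_mature = character(0), arm = character(0),
                      variant_class = character(0),
                      offset5 = integer(0), offset3 = integer(0),
                      total_count = numeric(0), total_rpm = numeric(0),
                      source_precursors = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(precursors) == 0) return(empty)
  prec_seqs <- stats::setNames(precursors$precursor_seq, precursors$precursor_id)
  rows <- list()
  for (i in seq_len(nrow(precursors))) {
    p <- precursors[i, ]
    sub <- hits[hits$contig_id == p$contig_id &
                  hits$start >= p$win_start & hits$end <= p$win_end &
                  hits$strand == p$strand, , drop = FALSE]
    sub <- sub[!duplicated(sub$sequence), , drop = FALSE]
    if (nrow(sub) == 0) next
    # position of the read inside the precursor string (0-based)
    if (p$strand == "+") {
      rs <- sub$start - p$win_start
    } else {
      rs <- p$win_end - sub$end
    }
    re <- rs + nchar(sub$sequence)
    m5 <- p$mature_offset; m3 <- p$mature_offset + p$mature_len
    cls <- classify_isomir_offsets(rs - m5, re - m3, max_offset)
    arm <- rep("mature", nrow(sub))
    o5 <- rs - m5; o3 <- re - m3
    if (!is.na(p$star_offset) && nzchar(p$star_seq)) {
      s5 <- p$star_offset; s3 <- p$star_offset + nchar(p$star_seq)
      scls <- classify_isomir_offsets(rs - s5, re - s3, max_offset)
      use_star <- cls == "other" & scls != "other"
      arm[use_star] <- "star"
      cls[use_star] <- scls[use_star]
      o5[use_star] <- (rs - s5)[use_star]
      o3[use_star] <- (re - s3)[use_star]
    }
    # exact mature and exact star reads are not isomiRs
    keep <- cls != "mature"
    if (!any(keep)) next
    ridx <- match(sub$sequence, reads$sequence)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = sub$sequence[keep],
      parent = p$precursor_id,
      parent_mature = p$anchor_seq,
      arm = arm[keep],
      variant_class = cls[keep],
      offset5 = o5[keep], offset3 = o3[keep],
      total_count = reads$total_count[ridx][keep],
      total_rpm = reads$total_rpm[ridx][keep],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$source_precursors <- vapply(out$sequence, function(s)
    paste(attribute_multilocus(s, prec_seqs), collapse = ","), character(1))
  out <- out[out$variant_class != "other", , drop = FALSE]
  out <- out[order(out$parent, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-by-class isomiR abundance summary
#'
#' Tabulates isomiR count, summed RPM and mean RPM per sequence length
#' (17-27 nt) and variant class, for all isomiRs and for the subset at or
#' above `min_rpm`.
#'
#' @param isomirs data.frame from [collect_isomirs()] (mature-arm isomiRs
#'   are summarized; pass a subset to change that).
#' @param min_rpm threshold for the high-expression panel (default 10
#'   RPM).
#' @return data.frame with columns `panel` (`all` / `ge_rpm`), `length`,
#'   `variant_class`, `n`, `rpm_sum`, `rpm_mean`.
#' @export
summarize_isomirs <- function(isomirs, min_rpm = 10) {
  classes <- c("five_prime", "three_prime", "both")
  lens <- 17:27
  grid <- expand.grid(length = lens, variant_class = classes,
                      stringsAsFactors = FALSE)
  panel <- function(df, label) {
    res <- grid
    res$panel <- label
    res$n <- 0L; res$rpm_sum <- 0; res$rpm_mean <- NA_real_
    if (nrow(df) > 0) {
      key <- paste(nchar(df$sequence), df$variant_class)
      gkey <- paste(res$length, res$variant_class)
      n <- tapply(rep(1L, nrow(df)), key, sum)
      s <- tapply(df$total_rpm, key, sum)
      idx <- match(names(n), gkey)
      ok <- !is.na(idx)
      res$n[idx[ok]] <- as.integer(n[ok])
      res$rpm_sum[idx[ok]] <- as.numeric(s[ok])
      res$rpm_mean <- ifelse(res$n > 0, res$rpm_sum / res$n, NA_real_)
    }
    res[, c("panel", "length", "variant_class", "n", "rpm_sum", "rpm_mean")]
  }
  rbind(panel(isomirs, "all"),
        panel(isomirs[!is.na(isomirs$total_rpm) &
                        isomirs$total_rpm >= min_rpm, , drop = FALSE],
              "ge_rpm"))
}
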