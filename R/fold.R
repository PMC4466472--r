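# Pluggable RNA secondary-structure backends. A backend is a function
# mapping a character vector of sequences to a data.frame with columns
# `structure` (dot-bracket) and `mfe` (kcal/mol, <= 0).

#' Thermodynamic MFE folding backend (ViennaRNA RNAfold)
#'
#' Folds sequences in one batch through the `RNAfold` executable.
#'
#' @param seqs character vector of DNA/RNA sequences.
#' @return data.frame with columns `structure` and `mfe`.
#' @export
fold_vienna <- function(seqs) {
  if (length(seqs) == 0) {
    return(data.frame(structure = character(0), mfe = numeric(0)))
  }
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("RNAfold executable not found on PATH")
  rna <- chartr("T", "U", normalize_seq(seqs))
  out <- system2(exe, args = c("--noPS"), input = rna, stdout = TRUE)
  struct_lines <- out[seq(2, length(out), by = 2)]
  m <- regmatches(struct_lines,
                  regexpr("^[.()]+ +\\( *-?[0-9.]+\\)$", struct_lines))
  structure <- sub(" .*$", "", struct_lines)
  mfe <- as.numeric(sub("^.*\\( *(-?[0-9.]+)\\)$", "\\1", struct_lines))
  data.frame(structure = structure, mfe = mfe, stringsAsFactors = FALSE)
}

#' Base-pair-maximization folding backend
#'
#' A simplified Nussinov-style dynamic program with a crude per-pair energy
#' assignment (GC -3, AU -2, GU -1 kcal/mol). Intended as a
#' dependency-free fallback for tests and small examples; hairpin quality
#' metrics (MFE/AMFE/MFEI) are calibrated for the thermodynamic backend.
#'
#' @param seqs character vector of sequences.
#' @param minloop minimum hairpin loop size.
#' @return data.frame with columns `structure` and `mfe`.
#' @export
fold_pairmax <- function(seqs, minloop = 3L) {
  if (length(seqs) == 0) {
    return(data.frame(structure = character(0), mfe = numeric(0)))
  }
  res <- lapply(normalize_seq(seqs), .nussinov_fold, minloop = minloop)
  data.frame(structure = vapply(res, `[[`, character(1), "structure"),
             mfe = vapply(res, `[[`, numeric(1), "mfe"),
             stringsAsFactors = FALSE)
}

#' Default folding backend
#'
#' Uses the thermodynamic backend when `RNAfold` is available, otherwise
#' the base-pair-maximization fallback (with a warning).
#'
#' @return a folding function.
#' @export
default_fold_backend <- function() {
  if (nzchar(Sys.which("RNAfold"))) fold_vienna
  else {
    warning("RNAfold not found; using base-pair-maximization fallback")
    fold_pairmax
  }
}

# Pair table from a dot-bracket string: integer vector p with p[i] = index
# of the partner of position i (1-based), or NA if unpaired.
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  p
}
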