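#' Antisense detection criteria
#'
#' The four conjunctive filters for calling a transcript antisense to a
#' CDS: opposite strand, alignment length >= 100 nt, E-value <= 1e-50,
#' identity >= 99\%.  A looser scan-stage E-value (1e-5) limits the
#' initial search; with the other filters in place it is effectively
#' redundant and kept for fidelity to the screening procedure.
#'
#' E-values use the Karlin--Altschul formula `E = K * m * n *
#' exp(-lambda * S)` with fixed constants for +1/-2 match/mismatch
#' scoring: `lambda = 1.33`, `K = 0.621`.
#'
#' @param min_align_len minimum alignment length (nt).
#' @param evalue_max filter-stage E-value cutoff.
#' @param evalue_scan scan-stage E-value cutoff.
#' @param min_identity minimum alignment identity.
#' @param lambda,K Karlin--Altschul constants.
#' @return list of class `antisense_criteria`.
#' @export
antisense_criteria <- function(min_align_len = 100L, evalue_max = 1e-50,
                               evalue_scan = 1e-5, min_identity = 0.99,
                               lambda = 1.33, K = 0.621) {
  structure(list(min_align_len = as.integer(min_align_len),
                 evalue_max = evalue_max, evalue_scan = evalue_scan,
                 min_identity = min_identity, lambda = lambda, K = K),
            class = "antisense_criteria")
}

karlin_evalue <- function(score, m, n, crit) {
  crit$K * m * n * exp(-crit$lambda * score)
}

#' Scan for antisense transcripts of a CDS set
#'
#' Aligns every CDS locally against the reverse complement of every
#' transcript (strand-aware: the libraries are strand-specific, so an
#' opposite-strand hit means a genuine antisense transcript) and reports
#' pairs passing all four filters.  Self-pairs are excluded; same-strand
#' duplicates never produce an opposite-strand alignment that passes.
#'
#' @param cds_set named character vector of coding sequences (sense).
#' @param transcripts named character vector of transcripts (sense).
#' @param crit an [antisense_criteria()].
#' @return data.frame: `cds_id`, `transcript_id`, `align_len`,
#'   `identity`, `evalue`, `score`.
#' @export
antisense_scan <- function(cds_set, transcripts,
                           crit = antisense_criteria()) {
  out <- list()
  for (ci in names(cds_set)) {
    for (ti in names(transcripts)) {
      if (ci == ti) next
      aln <- nt_local_align(cds_set[[ci]], revcomp(transcripts[[ti]]))
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (cols == 0) next
      ident <- Biostrings::nmatch(aln) / cols
      ev <- karlin_evalue(Biostrings::score(aln),
                          nchar(cds_set[[ci]]),
                          nchar(transcripts[[ti]]), crit)
      if (ev > crit$evalue_scan) next
      if (cols >= crit$min_align_len && ev <= crit$evalue_max &&
          ident >= crit$min_identity)
        out[[length(out) + 1]] <- data.frame(
          cds_id = ci, transcript_id = ti, align_len = cols,
          identity = ident, evalue = ev,
          score = Biostrings::score(aln), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(cds_id = character(0), transcript_id = character(0),
                      align_len = integer(0), identity = numeric(0),
                      evalue = numeric(0), score = numeric(0)))
  do.call(rbind, out)
}

#' Classify sense--antisense expression correlation
#'
#' Pearson r between the tissue profiles of each antisense transcript
#' and its sense gene; `positive` when r >= 0.9, `negative` when
#' r <= -0.9, `neutral` otherwise, `unassessed` when either profile is
#' missing or degenerate.
#'
#' @param pairs output of [antisense_scan()].
#' @param expression genes x tissues FPKM matrix covering both pair
#'   members.
#' @param r_cut correlation magnitude cutoff (default 0.9).
#' @return `pairs` with added `r` and `correlation_class`.
#' @export
antisense_correlation <- function(pairs, expression, r_cut = 0.9) {
  pairs$r <- NA_real_
  pairs$correlation_class <- "unassessed"
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$cds_id[i]; t <- pairs$transcript_id[i]
    if (!g %in% rownames(expression) || !t %in% rownames(expression))
      next
    pg <- expression[g, ]; pt <- expression[t, ]
    if (sd(pg) == 0 || sd(pt) == 0) next
    r <- cor(pg, pt)
    pairs$r[i] <- r
    pairs$correlation_class[i] <-
      if (r >= r_cut) "positive" else if (r <= -r_cut) "negative"
      else "neutral"
  }
  pairs
}
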