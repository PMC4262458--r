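#' Packaged CYP450 gene table
#'
#' The transcribed 116-row table of full-length *Salvia miltiorrhiza*
#' CYP450 genes (name, A/non-A type, clan, family, subfamily, protein
#' length, pI, molecular weight in kDa, predicted localization:
#' C = chloroplast, S = secreted, unknown).
#'
#' @return data.frame with 116 rows.
#' @export
cyp_gene_table <- function() {
  read_gene_table(system.file("extdata", "salvia_cyp450_gene_table.tsv",
                              package = "cypminer"))
}

#' Read a gene table TSV
#'
#' @param path TSV with columns `gene_name`, `type`, `clan`, `family`,
#'   `subfamily`, `length`, `pi`, `mw_kda`, `loc`.
#' @return validated data.frame.
#' @export
read_gene_table <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(clan = "character"))
  validate_gene_table(tbl)
  tbl
}

validate_gene_table <- function(tbl) {
  required <- c("gene_name", "type", "clan", "family", "subfamily",
                "length", "pi", "mw_kda", "loc")
  problems <- character(0)
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    problems <- c(problems, paste("missing columns:",
                                  paste(missing, collapse = ", ")))
  if (length(problems) == 0) {
    if (anyDuplicated(tbl$gene_name))
      problems <- c(problems, "duplicate gene names")
    if (!all(tbl$type %in% c("A", "non-A")))
      problems <- c(problems, "type must be A or non-A")
    bad_type <- (tbl$type == "A") != (tbl$clan == "71")
    if (any(bad_type))
      problems <- c(problems,
                    paste("type/clan inconsistent for:",
                          paste(tbl$gene_name[bad_type], collapse = ", ")))
    if (any(!is.finite(tbl$length) | tbl$length <= 0))
      problems <- c(problems, "nonpositive or missing lengths")
  }
  if (length(problems))
    stop("invalid gene table:\n  ", paste(problems, collapse = "\n  "))
  invisible(tbl)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize a CYP450 gene table
#'
#' Desk-scale summary of a classified gene set: gene count; protein
#' length mean (rounded half-up to an integer, the table convention),
#' minimum and maximum; counts of distinct families, subfamilies and
#' clans; per-family member counts split by A/non-A type; per-type and
#' per-localization counts.  Permutation-invariant in row order.
#'
#' @param tbl gene table (see [read_gene_table()]).
#' @return list of class `gene_table_summary`.
#' @export
summarize_gene_table <- function(tbl) {
  validate_gene_table(tbl)
  stopifnot(nrow(tbl) > 0)
  fam_counts <- function(type) {
    sub <- tbl[tbl$type == type, ]
    if (nrow(sub) == 0) return(integer(0))
    cnt <- table(sub$family)
    cnt[order(names(cnt))]
  }
  out <- list(
    n_genes = nrow(tbl),
    length_mean = round_half_up(mean(tbl$length)),
    length_min = min(tbl$length),
    length_max = max(tbl$length),
    n_families = length(unique(tbl$family)),
    n_subfamilies = length(unique(tbl$subfamily)),
    n_clans = length(unique(tbl$clan)),
    family_counts_A = fam_counts("A"),
    family_counts_nonA = fam_counts("non-A"),
    type_counts = table(tbl$type),
    loc_counts = table(tbl$loc))
  class(out) <- "gene_table_summary"
  out
}

#' @export
print.gene_table_summary <- function(x, ...) {
  cat("CYP450 gene table summary\n")
  cat("  genes:", x$n_genes, "\n")
  cat("  protein length (aa): mean", x$length_mean, " range",
      x$length_min, "-", x$length_max, "\n")
  cat("  families:", x$n_families, " subfamilies:", x$n_subfamilies,
      " clans:", x$n_clans, "\n")
  cat("  type:", paste(names(x$type_counts), as.integer(x$type_counts),
                       sep = "=", collapse = "  "), "\n")
  cat("  localization:", paste(names(x$loc_counts),
                               as.integer(x$loc_counts),
                               sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Run the full mining pipeline on a synthetic bundle
#'
#' Executes ORF curation, classification, characterization, expression
#' screening and the antisense scan on a generated bundle, then scores
#' every stage against the planted truth.  With the default noise-free
#' configuration all recovery metrics are 1.
#'
#' @param bundle a [make_bundle()] result (generated from `config` when
#'   omitted).
#' @param config a [sim_config()] used when `bundle` is missing.
#' @param r_cut co-expression cutoff.
#' @return list with per-stage outputs (`curation`, `classification`,
#'   `characterization`, `correlations`, `antisense`) and `recovery`
#'   (named metrics: curation precision/recall/F1, family and candidate
#'   recovery, antisense sensitivity/specificity, correlation-class
#'   counts).
#' @export
run_pipeline <- function(bundle = NULL, config = sim_config(),
                         r_cut = 0.9) {
  if (is.null(bundle)) bundle <- make_bundle(config)
  truth <- bundle$transcriptome$truth
  tx <- bundle$transcriptome$transcripts

  cur <- curate_transcripts(tx)
  cand <- cur[cur$candidate, ]
  proteins <- setNames(cand$protein, cand$transcript_id)
  status <- setNames(cand$status, cand$transcript_id)
  cls <- classify_proteins(proteins, bundle$panel, status = status)

  kept <- cls[cls$rank != "unrelated", ]
  chr <- characterize_proteins(setNames(proteins[kept$gene_id],
                                        kept$gene_id),
                               setNames(kept$cyp_type, kept$gene_id))

  M <- bundle$expression$fpkm
  rec <- marker_correlation(M, bundle$expression$marker, r_cut = r_cut)
  rec <- call_candidates(rec, bundle$expression$pathway_genes,
                         marker_id = bundle$expression$marker)

  pairs <- antisense_scan(bundle$transcriptome$cds, tx)
  pairs <- antisense_correlation(pairs, M, r_cut = r_cut)

  # ---- recovery against planted truth --------------------------------
  is_full_truth <- truth$id[truth$class == "full_cyp"]
  is_partial_truth <- truth$id[truth$class == "partial_cyp"]
  called_full <- cur$transcript_id[cur$status == "full" & cur$candidate]
  tp <- sum(called_full %in% is_full_truth)
  prec <- if (length(called_full)) tp / length(called_full) else NA
  recl <- if (length(is_full_truth)) tp / length(is_full_truth) else NA
  f1 <- if (is.na(prec) || is.na(recl) || prec + recl == 0) NA else
    2 * prec * recl / (prec + recl)
  partial_ok <- mean(cur$status[cur$transcript_id %in% is_partial_truth]
                     %in% c("partial", "flagged"))
  decoys <- truth$id[truth$class == "decoy"]
  decoys_blocked <- 1 - mean(decoys %in% kept$gene_id)

  # family recovery among full-length classified genes
  full_cls <- cls[cls$gene_id %in% is_full_truth, ]
  src_fam <- bundle$panel$family[match(truth$source_ref[
    match(full_cls$gene_id, truth$id)], bundle$panel$name)]
  family_recovery <- mean(full_cls$family == src_fam)

  planted_cand <- sort(bundle$expression$candidates)
  called_cand <- sort(rec$gene_id[rec$candidate])
  cand_exact <- identical(planted_cand, called_cand)

  as_truth <- truth$id[truth$class == "antisense"]
  as_called <- unique(pairs$transcript_id)
  sens <- if (length(as_truth)) mean(as_truth %in% as_called) else NA
  spec <- 1 - mean(setdiff(truth$id, as_truth) %in% as_called)

  true_pair <- paste(truth$antisense_of[match(as_truth, truth$id)],
                     as_truth)
  called_pos <- pairs$transcript_id[pairs$correlation_class == "positive" &
                                      paste(pairs$cds_id,
                                            pairs$transcript_id)
                                    %in% true_pair]
  called_neg <- pairs$transcript_id[pairs$correlation_class == "negative" &
                                      paste(pairs$cds_id,
                                            pairs$transcript_id)
                                    %in% true_pair]
  roles <- bundle$expression$profile_truth
  pos_truth <- roles$id[roles$role == "antisense_positive"]
  neg_truth <- roles$id[roles$role == "antisense_negative"]

  list(curation = cur, classification = cls, characterization = chr,
       correlations = rec, antisense = pairs,
       recovery = list(
         curation_precision = prec, curation_recall = recl,
         curation_f1 = f1, partial_recovery = partial_ok,
         decoys_blocked = decoys_blocked,
         family_recovery = family_recovery,
         candidates_exact = cand_exact,
         n_candidates_called = length(called_cand),
         antisense_sensitivity = sens, antisense_specificity = spec,
         n_positive_pairs = length(unique(called_pos)),
         n_negative_pairs = length(unique(called_neg)),
         positive_exact = setequal(called_pos, pos_truth),
         negative_exact = setequal(called_neg, neg_truth)))
}
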