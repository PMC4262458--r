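#' Curation thresholds for full/partial CYP calls
#'
#' Defaults follow the standard desk-curation rules for CYP450 mining:
#' a protein is full-length when it starts with M, ends at an in-frame
#' stop and its local alignment to the domain consensus covers at least
#' 85\% of the 463-residue model; coverage below 80\% (or a missing
#' start/stop) makes it partial; the 80--85\% band is flagged for manual
#' review.  Transcripts are merged with previously known sequences at
#' >= 97\% nucleotide identity over >= 300 aligned nucleotides.
#' `candidate_coverage_min` is the domain-scan gate: ORFs below it are
#' not considered CYP candidates at all (the stand-in for an upstream
#' profile-model screen).
#'
#' @param full_coverage_min,partial_coverage_max domain-coverage bounds.
#' @param domain_model_length length of the domain consensus (463).
#' @param merge_identity_min,merge_overlap_min transcript-merging cutoffs.
#' @param candidate_coverage_min minimum coverage to count as a CYP
#'   candidate.
#' @return list of class `curation_thresholds`.
#' @export
curation_thresholds <- function(full_coverage_min = 0.85,
                                partial_coverage_max = 0.80,
                                domain_model_length = 463L,
                                merge_identity_min = 0.97,
                                merge_overlap_min = 300L,
                                candidate_coverage_min = 0.20) {
  if (partial_coverage_max > full_coverage_min)
    stop("partial_coverage_max must be <= full_coverage_min")
  structure(list(full_coverage_min = full_coverage_min,
                 partial_coverage_max = partial_coverage_max,
                 domain_model_length = as.integer(domain_model_length),
                 merge_identity_min = merge_identity_min,
                 merge_overlap_min = as.integer(merge_overlap_min),
                 candidate_coverage_min = candidate_coverage_min),
            class = "curation_thresholds")
}

# translate one reading frame; codons containing N (or any non-ACGT
# base) become X, stops become "*"
translate_frame <- function(seq, frame) {
  n <- nchar(seq)
  starts <- seq(frame + 1, n - 2, by = 3)
  if (frame + 3 > n) return(character(0))
  codons <- substring(seq, starts, starts + 2)
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Find sense-strand open reading frames
#'
#' Scans the three sense-strand frames of an oriented transcript
#' (strand-specific libraries: the given strand is the sense strand) and
#' reports, per frame, every maximal M-to-stop ORF plus terminal open
#' fragments (edge fragments missing their start and/or stop).  The
#' longest candidate is flagged as the transcript's representative; ties
#' go to the lowest frame index, then the smallest start.
#'
#' @param transcript nucleotide sequence over A/C/G/T/N (single string).
#' @param id transcript identifier carried into the result.
#' @return data.frame with columns `transcript_id`, `frame`, `start`,
#'   `end` (0-based half-open, stop codon excluded), `protein`,
#'   `has_start`, `has_stop`, `representative`.
#' @examples
#' find_orfs("ATGAAATAA")   # one ORF, protein "MK"
#' @export
find_orfs <- function(transcript, id = "tx") {
  if (!nzchar(transcript)) stop("empty sequence")
  transcript <- toupper(transcript)
  out <- list()
  for (frame in 0:2) {
    aa <- translate_frame(transcript, frame)
    if (length(aa) == 0) next
    stops <- which(aa == "*")
    bounds <- c(0, stops, length(aa) + 1)  # segment delimiters
    n_seg <- length(bounds) - 1
    for (k in seq_len(n_seg)) {
      lo <- bounds[k] + 1; hi <- bounds[k + 1] - 1
      if (hi < lo) next
      seg <- aa[lo:hi]
      has_stop <- (bounds[k + 1] <= length(aa)) && aa[bounds[k + 1]] == "*"
      # 5'-edge open fragment (no start codon)
      if (k == 1 && seg[1] != "M") {
        out[[length(out) + 1]] <- data.frame(
          transcript_id = id, frame = frame,
          start = frame + 3 * (lo - 1), end = frame + 3 * hi,
          protein = paste(seg, collapse = ""),
          has_start = FALSE, has_stop = has_stop,
          stringsAsFactors = FALSE)
      }
      # maximal M-to-stop ORF (or M-to-edge fragment in the last segment)
      m <- which(seg == "M")
      if (length(m) > 0) {
        a <- lo + m[1] - 1
        out[[length(out) + 1]] <- data.frame(
          transcript_id = id, frame = frame,
          start = frame + 3 * (a - 1), end = frame + 3 * hi,
          protein = paste(seg[m[1]:length(seg)], collapse = ""),
          has_start = TRUE, has_stop = has_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      protein = character(0), has_start = logical(0),
                      has_stop = logical(0), representative = logical(0)))
  orfs <- do.call(rbind, out)
  len <- nchar(orfs$protein)
  ord <- order(-len, orfs$frame, orfs$start)
  orfs$representative <- FALSE
  orfs$representative[ord[1]] <- TRUE
  orfs
}

.b45_cache <- new.env(parent = emptyenv())
blosum45_matrix <- function() {
  if (is.null(.b45_cache$m)) {
    data("BLOSUM45", package = "Biostrings", envir = environment())
    .b45_cache$m <- BLOSUM45
  }
  .b45_cache$m
}

#' Domain-model coverage of a protein
#'
#' Fraction of the domain consensus covered by local alignment of the
#' protein against it — the deterministic proxy for a profile-model scan
#' when calling proteins full-length versus partial.  Two alignments are
#' used, mirroring how profile scanners separate detection from envelope
#' estimation: a detection alignment under stringent gap costs (BLOSUM45,
#' open 10 / extend 0.5) decides whether the protein matches the domain
#' at all (raw score below `min_score` means no significant match and
#' coverage 0); for significant matches, the covered span is then
#' measured under permissive gap costs (open 6 / extend 0.3), which lets
#' remote but genuine domain matches extend across the model the way a
#' profile alignment would.
#'
#' @param protein protein string.
#' @param consensus domain consensus (default: packaged 463-residue CYP
#'   consensus).
#' @param min_score detection-alignment score below which the protein is
#'   considered to have no domain match (coverage 0).
#' @return coverage fraction in \[0, 1\].
#' @export
domain_coverage <- function(protein, consensus = cyp_domain_consensus(),
                            min_score = 190) {
  if (!nzchar(protein)) {
    warning("empty protein: coverage 0")
    return(0)
  }
  detect <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(protein),
    subject = Biostrings::AAString(consensus),
    type = "local", substitutionMatrix = blosum45_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  if (Biostrings::score(detect) < min_score) return(0)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(protein),
    subject = Biostrings::AAString(consensus),
    type = "local", substitutionMatrix = blosum45_matrix(),
    gapOpening = 6, gapExtension = 0.3)
  covered <- Biostrings::width(Biostrings::subject(aln))
  covered / nchar(consensus)
}

#' Curate an ORF as full, partial or flagged
#'
#' Full-length requires a start codon, an in-frame stop and domain
#' coverage at or above `full_coverage_min`.  A missing start or stop, or
#' coverage below `partial_coverage_max`, makes the ORF partial.  ORFs
#' with start and stop whose coverage falls between the two bounds are
#' flagged for manual review rather than silently assigned either label.
#'
#' @param has_start,has_stop ORF start/stop flags (vectorized).
#' @param coverage domain coverage fractions.
#' @param th a [curation_thresholds()].
#' @return character vector: `"full"`, `"partial"` or `"flagged"`.
#' @export
curate <- function(has_start, has_stop, coverage,
                   th = curation_thresholds()) {
  ifelse(!has_start | !has_stop, "partial",
    ifelse(coverage >= th$full_coverage_min, "full",
      ifelse(coverage < th$partial_coverage_max, "partial", "flagged")))
}

#' Curate a transcript set end to end
#'
#' Runs [find_orfs()] on every transcript, measures domain coverage of
#' the representative ORF and assigns the full/partial/flagged status.
#' Transcripts whose representative ORF falls below
#' `candidate_coverage_min` are marked non-candidates (`candidate =
#' FALSE`) and excluded from downstream classification.
#'
#' @param transcripts named character vector of oriented transcripts.
#' @param consensus domain consensus protein.
#' @param th a [curation_thresholds()].
#' @return data.frame, one row per transcript: representative ORF
#'   coordinates, `protein`, `coverage`, `status`, `candidate`.
#' @export
curate_transcripts <- function(transcripts,
                               consensus = cyp_domain_consensus(),
                               th = curation_thresholds()) {
  rows <- lapply(names(transcripts), function(id) {
    orfs <- find_orfs(transcripts[[id]], id = id)
    rep <- orfs[orfs$representative, , drop = FALSE]
    if (nrow(rep) == 0)
      return(data.frame(transcript_id = id, frame = NA_integer_,
                        start = NA_integer_, end = NA_integer_,
                        protein = "", has_start = FALSE, has_stop = FALSE,
                        coverage = 0, status = "partial", candidate = FALSE,
                        stringsAsFactors = FALSE))
    cov <- domain_coverage(rep$protein, consensus)
    data.frame(rep[, c("transcript_id", "frame", "start", "end", "protein",
                       "has_start", "has_stop")],
               coverage = cov,
               status = curate(rep$has_start, rep$has_stop, cov, th),
               candidate = cov >= th$candidate_coverage_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge transcripts with previously known sequences
#'
#' Unifies transcript/known pairs that align locally at >=
#' `merge_identity_min` nucleotide identity over >= `merge_overlap_min`
#' aligned nucleotides under one gene id, keeping the longer sequence.
#' Every merge is logged.
#'
#' @param transcripts,known named character vectors of nucleotide
#'   sequences.
#' @param th a [curation_thresholds()].
#' @return list with `sequences` (merged set, named) and `log`
#'   (data.frame of merge decisions: `transcript`, `known`, `identity`,
#'   `overlap`, `merged`, `kept`).
#' @export
merge_with_known <- function(transcripts, known,
                             th = curation_thresholds()) {
  stopifnot(length(transcripts) > 0, length(known) > 0)
  log <- list()
  merged_into <- setNames(rep(NA_character_, length(transcripts)),
                          names(transcripts))
  sequences <- transcripts
  for (tx in names(transcripts)) {
    for (kn in names(known)) {
      aln <- nt_local_align(transcripts[[tx]], known[[kn]])
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- if (cols > 0) Biostrings::nmatch(aln) / cols else 0
      hit <- ident >= th$merge_identity_min && cols >= th$merge_overlap_min
      log[[length(log) + 1]] <- data.frame(
        transcript = tx, known = kn, identity = ident, overlap = cols,
        merged = hit,
        kept = if (!hit) NA_character_ else
          if (nchar(transcripts[[tx]]) >= nchar(known[[kn]])) tx else kn,
        stringsAsFactors = FALSE)
      if (hit && is.na(merged_into[tx])) {
        merged_into[tx] <- kn
        if (nchar(known[[kn]]) > nchar(transcripts[[tx]]))
          sequences[[tx]] <- known[[kn]]
      }
    }
  }
  list(sequences = sequences, log = do.call(rbind, log))
}
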