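#' Amino-acid alphabet used by the alignment kernel
#' @keywords internal
AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

.submat_cache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to the 20 standard residues plus X (scored as the
# column minimum, i.e. never rewarded), row/column order fixed.
blosum62_matrix <- function() {
  if (!is.null(.submat_cache$b62)) return(.submat_cache$b62)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  alpha <- c(AA_ALPHABET20, "X")
  m <- BLOSUM62[alpha, alpha]
  storage.mode(m) <- "double"
  .submat_cache$b62 <- m
  m
}

aa_index <- function(x) {
  alpha <- c(AA_ALPHABET20, "X")
  s <- strsplit(x, "")[[1]]
  s[!s %in% alpha] <- "X"
  idx <- match(s, alpha) - 1L
  idx
}

#' Glocal protein alignment (free end gaps)
#'
#' Aligns two protein sequences globally with end gaps free (overlap
#' alignment), BLOSUM62 scoring and affine gap penalties.  This is the
#' alignment underlying all identity measurements in the package.
#'
#' @param a,b protein sequences (single strings, standard residues;
#'   anything else is treated as `X`).
#' @param gap_open,gap_ext affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_ext`.
#' @return list with `score`, `matches`, `columns` (aligned columns,
#'   internal gaps included, end gaps excluded) and the 1-based aligned
#'   spans on each sequence.
#' @export
align_glocal <- function(a, b, gap_open = 11, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  align_overlap_cpp(aa_index(a), aa_index(b), blosum62_matrix(),
                    gap_open, gap_ext)
}

#' Pairwise amino-acid identity
#'
#' Fraction of identical residues over the aligned columns of a glocal
#' (end-gap-free global) BLOSUM62 alignment.  This is the identity that
#' the CYP nomenclature thresholds (40/55/97 percent) are applied to.
#' The denominator is configurable: `"aligned_columns"` (default) counts
#' every column of the alignment path including internal gaps;
#' `"shorter"` divides by the length of the shorter sequence.
#'
#' @param a,b protein sequences (single strings).
#' @param denominator identity denominator convention.
#' @return identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACDEF", "ACDEF")  # 1
#' pairwise_identity("ACDEF", "ACDEG")  # 0.8
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("aligned_columns", "shorter")) {
  denominator <- match.arg(denominator)
  aln <- align_glocal(a, b)
  if (aln$columns == 0) return(0)
  den <- switch(denominator,
                aligned_columns = aln$columns,
                shorter = min(nchar(a), nchar(b)))
  aln$matches / den
}

# nucleotide local alignment via Biostrings; shared by the antisense scan
# and transcript merging.  match +1 / mismatch -2, gap open 5 / extend 2.
nt_local_align <- function(pattern, subject, match = 1, mismatch = -2,
                           gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
}
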