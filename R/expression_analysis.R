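#' FPKM from fragment counts
#'
#' `FPKM = count / (length_kb * mapped_millions)` per gene and sample.
#'
#' @param counts genes x samples matrix of fragment counts.
#' @param gene_lengths per-gene transcript lengths in nucleotides (> 0).
#' @param library_sizes per-sample mapped fragment totals (> 0).
#' @return genes x samples FPKM matrix.
#' @examples
#' fpkm(matrix(10, 1, 1), 1000, 1e6)  # 10
#' @export
fpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("zero library size")
  sweep(counts / (gene_lengths / 1e3), 2, library_sizes / 1e6, "/")
}

#' Expressed/not-expressed flags and three-tissue Venn counts
#'
#' A gene is expressed in a tissue when its FPKM exceeds the cutoff
#' (FPKM <= 1 counts as not expressed, the study convention).  The Venn
#' regions partition the set of genes expressed anywhere.
#'
#' @param M genes x 3 FPKM matrix (tissue columns).
#' @param cutoff expression cutoff (default 1).
#' @return list with `flags` (logical matrix) and `venn` (named counts
#'   of the 7 regions, names like `"root"`, `"root&leaf"`,
#'   `"root&leaf&flower"`).
#' @export
expressed_flags <- function(M, cutoff = 1) {
  stopifnot(ncol(M) == 3)
  flags <- M > cutoff
  tis <- colnames(M)
  regions <- list()
  for (k in 1:3) for (cmb in asplit(combn(3, k), 2)) {
    nm <- paste(tis[unlist(cmb)], collapse = "&")
    inside <- rowSums(flags[, unlist(cmb), drop = FALSE]) == k &
      rowSums(flags[, -unlist(cmb), drop = FALSE]) == 0
    regions[[nm]] <- sum(inside)
  }
  list(flags = flags, venn = unlist(regions))
}

#' Log-transform and mean-center expression profiles
#'
#' `value = log(FPKM + 1) - mean over the three tissues of log(FPKM+1)`,
#' row-wise.  Log base 2 by default (the base changes heat-map values
#' but not Euclidean/Ward clustering topology).
#'
#' @param M genes x tissues FPKM matrix (values >= 0).
#' @param base logarithm base.
#' @return centered log matrix; every row sums to 0.
#' @export
transform_expression <- function(M, base = 2) {
  if (any(M < 0)) stop("negative FPKM")
  L <- log(M + 1, base = base)
  sweep(L, 1, rowMeans(L))
}

#' Hierarchical clustering of expression profiles (Ward, Euclidean)
#'
#' Agglomerates genes with Euclidean distance and the Ward criterion
#' (squared-distance "Ward.D2" update) and cuts the dendrogram into `k`
#' clusters labelled C1..Ck in dendrogram order.
#'
#' @param M centered log-expression matrix ([transform_expression()]).
#' @param k number of cluster labels to cut (default 6).
#' @return list with `hclust`, `clusters` (named C-labels), and `order`
#'   (gene ids in dendrogram order).
#' @export
hier_cluster <- function(M, k = 6) {
  if (nrow(M) < 2) stop("clustering requires >= 2 genes")
  hc <- hclust(dist(M), method = "ward.D2")
  k <- min(k, nrow(M))
  cl <- cutree(hc, k = k)
  # relabel clusters in dendrogram order
  first <- vapply(split(match(names(cl), hc$labels[hc$order]), cl),
                  min, numeric(1))
  lab <- setNames(paste0("C", rank(first)), names(first))
  list(hclust = hc, clusters = setNames(lab[as.character(cl)], names(cl)),
       order = hc$labels[hc$order])
}

#' Pearson correlation of every gene with a marker gene
#'
#' Standard product-moment correlation of each gene's three-tissue
#' profile with the marker's.  Zero-variance profiles get `r = NA` and
#' are recorded as not co-expressed with a reason.
#'
#' @param M genes x tissues FPKM (or transformed) matrix.
#' @param marker_id row name of the marker gene.
#' @param r_cut co-expression cutoff on r (>= semantics, default 0.9).
#' @return data.frame: `gene_id`, `r`, `co_expressed`, `reason`.
#' @export
marker_correlation <- function(M, marker_id, r_cut = 0.9) {
  stopifnot(marker_id %in% rownames(M))
  mp <- M[marker_id, ]
  if (sd(mp) == 0) stop("marker profile has zero variance")
  out <- lapply(rownames(M), function(g) {
    p <- M[g, ]
    if (sd(p) == 0)
      return(data.frame(gene_id = g, r = NA_real_, co_expressed = FALSE,
                        reason = "zero variance", stringsAsFactors = FALSE))
    data.frame(gene_id = g, r = cor(p, mp),
               co_expressed = cor(p, mp) >= r_cut, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call pathway-supported co-expression candidates
#'
#' A gene is a candidate when it is co-expressed with the marker
#' (`r >= r_cut`) and annotated to the target pathway — the
#' dual-evidence rule used to nominate biosynthesis genes.
#'
#' @param records output of [marker_correlation()].
#' @param pathway_genes gene ids annotated to the target pathway.
#' @param marker_id optional marker id to exclude from candidates.
#' @return `records` with added `pathway_member` and `candidate` flags.
#' @export
call_candidates <- function(records, pathway_genes, marker_id = NULL) {
  if (is.null(pathway_genes)) stop("missing pathway annotation")
  records$pathway_member <- records$gene_id %in% pathway_genes
  records$candidate <- records$co_expressed & records$pathway_member
  if (!is.null(marker_id))
    records$candidate[records$gene_id == marker_id] <- FALSE
  records
}

#' Relative expression by the 2^-ddCt method
#'
#' For every (gene, tissue, biological replicate): technical replicates
#' are averaged first, `dCt = Ct_target - Ct_control` within the sample,
#' `ddCt = dCt - mean dCt of the calibrator tissue`, and relative
#' expression is `2^-ddCt`.  Biological replicates are averaged last;
#' both per-replicate and tissue-mean values are returned.
#'
#' @param ct data.frame with `gene`, `tissue`, `bio_rep`, `tech_rep`,
#'   `ct`.
#' @param control endogenous control gene name (present in every
#'   sample).
#' @param calibrator_tissue tissue whose mean dCt is the ddCt baseline.
#' @return list with `per_rep` (gene, tissue, bio_rep, dct, ddct, rel)
#'   and `summary` (gene, tissue, rel_mean = mean of per-replicate
#'   relative expressions, rel_of_means = 2^-(mean ddCt)).
#' @export
ddct <- function(ct, control, calibrator_tissue) {
  stopifnot(all(c("gene", "tissue", "bio_rep", "tech_rep", "ct")
                %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  tech <- aggregate(ct ~ gene + tissue + bio_rep, data = ct, FUN = mean)
  ctrl <- tech[tech$gene == control, ]
  genes <- setdiff(unique(tech$gene), control)
  per <- list()
  for (g in genes) {
    tg <- tech[tech$gene == g, ]
    m <- merge(tg, ctrl, by = c("tissue", "bio_rep"),
               suffixes = c("", "_ctrl"))
    if (nrow(m) < nrow(tg))
      stop("control '", control, "' missing in some samples of ", g)
    m$dct <- m$ct - m$ct_ctrl
    cal <- m$dct[m$tissue == calibrator_tissue]
    if (length(cal) == 0) stop("calibrator tissue absent for ", g)
    m$ddct <- m$dct - mean(cal)
    m$rel <- 2^(-m$ddct)
    per[[g]] <- data.frame(gene = g, tissue = m$tissue,
                           bio_rep = m$bio_rep, dct = m$dct,
                           ddct = m$ddct, rel = m$rel,
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  s1 <- aggregate(rel ~ gene + tissue, data = per, FUN = mean)
  s2 <- aggregate(ddct ~ gene + tissue, data = per, FUN = mean)
  summary <- merge(s1, s2, by = c("gene", "tissue"))
  summary$rel_of_means <- 2^(-summary$ddct)
  names(summary)[names(summary) == "rel"] <- "rel_mean"
  list(per_rep = per, summary = summary[, c("gene", "tissue", "rel_mean",
                                            "rel_of_means")])
}

#' Concordance between RNA-Seq and qPCR tissue profiles
#'
#' A gene is rank-validated when the ordering of its three tissue means
#' agrees between platforms; the Pearson r of the two 3-point profiles
#' is reported alongside.  Tied means are flagged and ordered stably.
#'
#' @param rnaseq_profile,qpcr_profile named numeric vectors over the
#'   same three tissues.
#' @return list with `rank_match`, `r`, `tie`.
#' @export
concordance <- function(rnaseq_profile, qpcr_profile) {
  stopifnot(length(rnaseq_profile) == 3,
            setequal(names(rnaseq_profile), names(qpcr_profile)))
  q <- qpcr_profile[names(rnaseq_profile)]
  tie <- anyDuplicated(rnaseq_profile) > 0 || anyDuplicated(q) > 0
  rank_match <- identical(order(rnaseq_profile), order(q))
  r <- if (sd(rnaseq_profile) == 0 || sd(q) == 0) NA_real_ else
    cor(rnaseq_profile, q)
  list(rank_match = rank_match, r = r, tie = tie)
}

#' @importFrom stats aggregate
NULL
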