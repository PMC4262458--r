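msa_matrix <- function(msa) {
  if (inherits(msa, "AAStringSet")) msa <- as.character(msa)
  stopifnot(!is.null(names(msa)), length(unique(nchar(msa))) == 1)
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Poisson-corrected distance matrix from a protein MSA
#'
#' Pairwise deletion: for each sequence pair only columns where neither
#' sequence has a gap (`-`) or ambiguity (`X`) are compared.  With p the
#' proportion of differing shared columns, the distance is
#' `d = -ln(1 - p)` (Poisson correction for multiple substitutions).
#'
#' @param msa aligned sequences: named character vector of equal length,
#'   or an `AAStringSet`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
poisson_dist <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-" & m[i, ] != "X" & m[j, ] != "X"
    if (!any(ok))
      stop("no shared gap-free columns between ", rownames(m)[i],
           " and ", rownames(m)[j])
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 1)
      stop("saturated pair (p = 1): Poisson distance undefined between ",
           rownames(m)[i], " and ", rownames(m)[j])
    D[i, j] <- D[j, i] <- -log(1 - p)
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou--Nei Neighbor-Joining (via \pkg{ape}); negative branch lengths
#' are floored at zero (each flooring is reported).  Additive distance
#' matrices are recovered exactly.
#'
#' @param D symmetric distance matrix with >= 3 labelled taxa.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("Neighbor-Joining requires >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  tree <- ape::nj(D)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) floored at 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Bootstrap support for a Neighbor-Joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected NJ tree for each replicate and reports, for each
#' internal branch of the full-alignment tree, the percentage of
#' replicate trees containing the same bipartition.  Supports are stored
#' in `$node.label`.  Replicates whose resampled alignment yields an
#' undefined distance are dropped (the denominator shrinks accordingly).
#'
#' @param msa aligned sequences (named, equal length).
#' @param n_reps bootstrap replicates (study convention: 1000).
#' @param seed integer seed for column resampling.
#' @return `phylo` tree with `node.label` support percentages and an
#'   attribute `n_effective` (replicates actually used).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1) {
  m <- msa_matrix(msa)
  if (ncol(m) < 2) stop("alignment width must be >= 2")
  as_msa <- function(mm) setNames(apply(mm, 1, paste, collapse = ""),
                                  rownames(mm))
  ref <- nj_tree(poisson_dist(as_msa(m)))
  boots <- with_rng(seed, {
    out <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      cols <- sample(ncol(m), ncol(m), replace = TRUE)
      out[[r]] <- tryCatch(
        suppressMessages(nj_tree(poisson_dist(as_msa(m[, cols,
                                                       drop = FALSE])))),
        error = function(e) NULL)
    }
    out
  })
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(boots), 1)
  ref$node.label <- as.character(support)
  attr(ref, "n_effective") <- length(boots)
  ref
}

#' Collapse weakly supported branches
#'
#' Contracts internal branches whose bootstrap support is at or below
#' `threshold` percent into polytomies; branches supported by more than
#' `threshold` are retained with their lengths.
#'
#' @param tree `phylo` with numeric `node.label` supports.
#' @param threshold support percentage at or below which a branch is
#'   collapsed (default 50).
#' @return `phylo` tree, possibly multifurcating.
#' @export
collapse_weak_branches <- function(tree, threshold = 50) {
  stopifnot(!is.null(tree$node.label))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  weak_nodes <- which(!is.na(sup) & sup <= threshold) + ntip
  t2 <- tree
  internal <- t2$edge[, 2] > ntip
  drop <- internal & t2$edge[, 2] %in% weak_nodes
  if (!any(drop)) return(tree)
  # mark edges to contract with a sentinel length; di2multi removes
  # exactly the edges at or below tol, so retained lengths survive
  t2$edge.length[drop] <- -1
  ape::di2multi(t2, tol = -0.5)
}

#' Write a support-annotated tree in Newick format
#'
#' @param tree `phylo` tree (supports as `node.label`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
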