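#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study: the reference-panel tier
#' structure, the planted transcript classes, the three-tissue expression
#' design with a designated marker gene, and the qPCR replicate layout.
#' Defaults reproduce the noise-free study conditions used throughout the
#' test suite: 2 families x 2 subfamilies x 2 members in the panel, 20
#' planted full-length CYPs, 10 partial fragments, 15 antisense copies
#' (12 positively / 3 negatively correlated with their sense gene), and
#' 20 decoys.
#'
#' @param n_families,n_subfamilies_per_family,n_members_per_subfamily
#'   reference-panel shape.
#' @param n_full,n_partial,n_antisense,n_decoys planted transcript counts.
#' @param identity_targets protein identities (fractions in (0,1]) at
#'   which full-length ORFs are planted relative to their source panel
#'   entry; recycled over the planted genes.
#' @param tissues exactly three tissue labels.
#' @param r_target minimum Pearson correlation planted for co-expressed
#'   genes (before noise).
#' @param noise_sd log2-scale multiplicative noise on FPKM values.
#' @param n_coexpressed number of non-marker genes planted co-expressed
#'   with the marker.
#' @param n_pathway_coexpressed,n_pathway_other pathway-annotated genes
#'   inside and outside the co-expressed set; their intersection with the
#'   co-expressed set is the planted candidate set.
#' @param n_qpcr_genes genes measured in the synthetic qPCR table
#'   (marker included).
#' @param qpcr_sd_bio,qpcr_sd_tech Ct noise (cycles) at the biological
#'   and technical replicate level.
#' @param antisense_window planted antisense window length (>= 100 nt).
#' @param antisense_mut number of point mutations in each antisense copy
#'   (must keep identity >= 0.99).
#' @param seed integer seed; every generator derives child seeds from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 2, n_subfamilies_per_family = 2,
                       n_members_per_subfamily = 2,
                       n_full = 20, n_partial = 10, n_antisense = 15,
                       n_decoys = 20,
                       identity_targets = c(0.98, 0.75, 0.60),
                       tissues = c("root", "leaf", "flower"),
                       r_target = 0.9, noise_sd = 0,
                       n_coexpressed = 10,
                       n_pathway_coexpressed = 3, n_pathway_other = 2,
                       n_qpcr_genes = 19,
                       qpcr_sd_bio = 0, qpcr_sd_tech = 0,
                       antisense_window = 150, antisense_mut = 0,
                       seed = 101) {
  cfg <- list(n_families = n_families,
              n_subfamilies_per_family = n_subfamilies_per_family,
              n_members_per_subfamily = n_members_per_subfamily,
              n_full = n_full, n_partial = n_partial,
              n_antisense = n_antisense, n_decoys = n_decoys,
              identity_targets = identity_targets, tissues = tissues,
              r_target = r_target, noise_sd = noise_sd,
              n_coexpressed = n_coexpressed,
              n_pathway_coexpressed = n_pathway_coexpressed,
              n_pathway_other = n_pathway_other,
              n_qpcr_genes = n_qpcr_genes,
              qpcr_sd_bio = qpcr_sd_bio, qpcr_sd_tech = qpcr_sd_tech,
              antisense_window = antisense_window,
              antisense_mut = antisense_mut,
              seed = as.integer(seed))
  counts <- c("n_families", "n_subfamilies_per_family",
              "n_members_per_subfamily", "n_full", "n_partial",
              "n_antisense", "n_decoys")
  for (f in counts)
    if (cfg[[f]] < 0) stop("count '", f, "' must be nonnegative")
  if (n_families < 1) stop("n_families must be >= 1")
  if (any(identity_targets <= 0 | identity_targets > 1))
    stop("identity_targets must lie in (0, 1]")
  if (length(tissues) != 3) stop("exactly 3 tissues are required")
  if (r_target >= 1 && noise_sd > 0)
    stop("r_target >= 1 is unattainable with nonzero noise")
  if (antisense_window < 100)
    stop("antisense windows must be >= 100 nt to satisfy the length filter")
  if (antisense_mut / antisense_window > 0.01)
    stop("antisense_mut would drop planted identity below 0.99")
  if (noise_sd < 0 || qpcr_sd_bio < 0 || qpcr_sd_tech < 0)
    stop("noise parameters must be nonnegative")
  class(cfg) <- "sim_config"
  cfg
}

#' Packaged CYP domain consensus
#'
#' Returns the synthetic 463-residue CYP450 domain consensus shipped with
#' the package (a constructed stand-in for a profile-model consensus; the
#' file is swappable).  The four conserved motif islands (I-helix,
#' K-helix, PERF, heme-binding) are embedded at fixed positions.
#'
#' @return single protein string of length 463.
#' @export
cyp_domain_consensus <- function() {
  path <- system.file("extdata", "cyp_domain_consensus_synthetic.fasta",
                      package = "cypminer")
  as.character(Biostrings::readAAStringSet(path))[[1]]
}

# 1-based positions of the four motif islands in a protein; used by the
# generator to protect them from mutation.
motif_island_positions <- function(protein) {
  hits <- find_motifs(protein, cyp_type = "A")
  if (nrow(hits) < 4)
    hits <- rbind(hits, find_motifs(protein, cyp_type = "non-A"))
  pos <- integer(0)
  for (i in seq_len(nrow(hits)))
    pos <- c(pos, seq(hits$position[i] + 1,
                      hits$position[i] + hits$width[i]))
  sort(unique(pos))
}

#' Mutate a protein to a target identity
#'
#' Plants point substitutions (uniform over the 19 alternative residues)
#' at positions sampled outside `protected` until the Hamming identity to
#' the input equals `identity` (rounded to whole positions).  No indels
#' are introduced, so the planted identity is exact by construction.
#' Uses the R RNG stream in effect.
#'
#' @param protein protein string.
#' @param identity target identity fraction in (0, 1].
#' @param protected 1-based positions never mutated (e.g. motif islands).
#' @return mutated protein string.
#' @export
mutate_protein <- function(protein, identity, protected = integer(0)) {
  s <- strsplit(protein, "")[[1]]
  L <- length(s)
  n_mut <- round((1 - identity) * L)
  pool <- setdiff(seq_len(L), protected)
  if (n_mut > length(pool))
    stop("target identity unreachable with ", length(pool),
         " mutable positions")
  pos <- if (n_mut > 0) sample(pool, n_mut) else integer(0)
  for (p in pos) s[p] <- sample(setdiff(AA_ALPHABET20, s[p]), 1)
  paste(s, collapse = "")
}

# mutate exactly the given positions (to a different residue each)
mutate_at <- function(s_split, positions) {
  for (p in positions)
    s_split[p] <- sample(setdiff(AA_ALPHABET20, s_split[p]), 1)
  s_split
}

#' Generate a tiered CYP reference panel
#'
#' Builds a synthetic reference panel whose pairwise amino-acid
#' identities respect the nomenclature tier structure: members of the
#' same subfamily share >= 55\% identity, members of the same family but
#' different subfamilies fall in \[40, 55)\%, and members of different
#' families share < 40\%.  All entries derive from the packaged domain
#' consensus with the four motif islands held fixed, so every panel
#' protein carries the canonical CYP motifs.  The realized tier structure
#' is verified with [pairwise_identity()]; an unsatisfiable configuration
#' fails explicitly after bounded retries.
#'
#' Families are numbered CYP901, CYP902, ... and assigned to clans
#' cyclically, the first family to clan 71 (so A-type entries always
#' exist); subfamilies are lettered A, B, ...
#'
#' @param config a [sim_config()].
#' @return data.frame of class `reference_panel` with columns
#'   `name`, `protein`, `family`, `subfamily`, `clan`.
#' @export
make_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (attempt in 1:5) {
    panel <- with_rng(child_seed(config$seed, attempt),
                      build_panel_once(config))
    if (panel_tiers_ok(panel)) return(panel)
  }
  stop("infeasible tier structure: panel identities violate the ",
       "40/55 tier bands after bounded mutation attempts")
}

build_panel_once <- function(config) {
  cons <- cyp_domain_consensus()
  L <- nchar(cons)
  # protect the motif islands and the initiator M from mutation
  islands <- c(1L, motif_island_positions(cons))
  pool_all <- setdiff(seq_len(L), islands)
  n_sub <- config$n_subfamilies_per_family
  n_mem <- config$n_members_per_subfamily
  q <- 20                                     # member-level divergence
  d <- min(115L, floor(length(pool_all) / max(1, n_sub)) - n_mem * q)
  if (n_sub > 1 && d < 105)
    stop("infeasible tier structure: too many subfamilies/members for ",
         "the mutable position budget")
  clans <- c("71", "85", "72", "86", "97", "711", "727", "74", "51")
  out <- list()
  for (fam in seq_len(config$n_families)) {
    fam_label <- paste0("CYP", 900 + fam)
    clan <- clans[(fam - 1) %% length(clans) + 1]
    founder <- strsplit(cons, "")[[1]]
    founder <- mutate_at(founder,
                         sample(pool_all, round(0.55 * length(pool_all))))
    shuffled <- sample(pool_all)
    used <- 0L
    for (s in seq_len(n_sub)) {
      sub_label <- paste0(fam_label, LETTERS[s])
      P <- shuffled[(used + 1):(used + d)]; used <- used + d
      rep_s <- mutate_at(founder, P)
      for (k in seq_len(n_mem)) {
        Q <- shuffled[(used + 1):(used + q)]; used <- used + q
        member <- mutate_at(rep_s, Q)
        out[[length(out) + 1]] <- data.frame(
          name = paste0(sub_label, k),
          protein = paste(member, collapse = ""),
          family = fam_label, subfamily = sub_label, clan = clan,
          stringsAsFactors = FALSE)
      }
    }
  }
  panel <- do.call(rbind, out)
  if (anyDuplicated(panel$name)) stop("duplicate panel names")
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

panel_tiers_ok <- function(panel) {
  n <- nrow(panel)
  if (n < 2) return(TRUE)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- pairwise_identity(panel$protein[i], panel$protein[j])
    same_fam <- panel$family[i] == panel$family[j]
    same_sub <- panel$subfamily[i] == panel$subfamily[j]
    ok <- if (same_sub) id >= 0.55
          else if (same_fam) id >= 0.40 && id < 0.55
          else id < 0.40
    if (!ok) return(FALSE)
  }
  TRUE
}

# ---- nucleotide helpers -------------------------------------------------

DNA4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE),
                                collapse = "")

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

# back-translation with uniform synonymous codon choice
back_translate <- function(protein) {
  tab <- codon_table()
  s <- strsplit(protein, "")[[1]]
  paste(vapply(s, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) stop("cannot back-translate residue ", a)
    if (length(cods) == 1) cods else sample(cods, 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic transcriptome with planted truth
#'
#' Plants four transcript classes on the sense strand of a synthetic,
#' strand-specific assembly: full-length CYP ORFs back-translated from
#' panel-derived proteins mutated to controlled identities; partial
#' fragments missing their start or stop; antisense copies (reverse
#' complements of >= 100 nt CDS windows at >= 99 percent identity); and
#' random decoys.  A stop codon is planted in frame immediately upstream
#' of every full-length ATG so the planted ORF is exactly recoverable.
#'
#' @param panel a [make_reference_panel()] result.
#' @param config a [sim_config()].
#' @return list with `transcripts` (named character vector, sense
#'   orientation), `cds` (named vector of planted coding sequences,
#'   full-length genes only) and `truth` (data.frame with columns `id`,
#'   `class`, `source_ref`, `planted_identity`, `orf_start`, `orf_end`
#'   (0-based half-open, stop codon excluded), `antisense_of`,
#'   `window_len`).
#' @export
make_transcriptome <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"), nrow(panel) >= 1)
  with_rng(child_seed(config$seed, 11), {
    cons <- cyp_domain_consensus()
    islands <- c(1L, motif_island_positions(cons))
    transcripts <- character(0); cds <- character(0)
    truth <- list()
    tgt <- rep(config$identity_targets, length.out = max(1, config$n_full))

    for (i in seq_len(config$n_full)) {
      src <- panel[((i - 1) %% nrow(panel)) + 1, ]
      prot <- mutate_protein(src$protein, tgt[i], protected = islands)
      orf <- back_translate(prot)
      utr5 <- paste0(random_dna(sample(30:60, 1)), "TAA")
      utr3 <- random_dna(sample(60:120, 1))
      stopc <- sample(c("TAA", "TAG", "TGA"), 1)
      tx <- paste0(utr5, orf, stopc, utr3)
      id <- sprintf("FL%03d", i)
      transcripts[id] <- tx
      cds[id] <- paste0(orf, stopc)
      truth[[length(truth) + 1]] <- data.frame(
        id = id, class = "full_cyp", source_ref = src$name,
        planted_identity = 1 - round((1 - tgt[i]) * nchar(src$protein)) /
          nchar(src$protein),
        orf_start = nchar(utr5), orf_end = nchar(utr5) + nchar(orf),
        antisense_of = NA_character_, window_len = NA_integer_,
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(config$n_partial)) {
      src <- panel[((i - 1) %% nrow(panel)) + 1, ]
      prot <- mutate_protein(src$protein, 0.85, protected = islands)
      L <- nchar(prot)
      id <- sprintf("PT%03d", i)
      if (i %% 2 == 1) {   # stop-missing: ORF runs off the 3' end
        k <- round(runif(1, 0.45, 0.90) * L)
        frag <- substr(prot, 1, k)       # starts with the initiator M
        utr5 <- paste0(random_dna(sample(30:60, 1)), "TAA")
        tx <- paste0(utr5, back_translate(frag))
        orf_start <- nchar(utr5); orf_end <- nchar(tx)
      } else {             # start-missing: transcript begins mid-ORF
        k <- round(runif(1, 0.35, 0.70) * L)
        frag <- substr(prot, L - k + 1, L)
        frag_nt <- back_translate(frag)
        tx <- paste0(frag_nt, sample(c("TAA", "TAG", "TGA"), 1),
                     random_dna(sample(60:120, 1)))
        orf_start <- 0; orf_end <- nchar(frag_nt)
      }
      transcripts[id] <- tx
      truth[[length(truth) + 1]] <- data.frame(
        id = id, class = "partial_cyp", source_ref = src$name,
        planted_identity = NA_real_,
        orf_start = orf_start, orf_end = orf_end,
        antisense_of = NA_character_, window_len = NA_integer_,
        stringsAsFactors = FALSE)
    }

    n_as <- config$n_antisense
    if (n_as > 0 && config$n_full == 0)
      stop("antisense transcripts require planted full-length genes")
    for (i in seq_len(n_as)) {
      target_id <- names(cds)[((i - 1) %% length(cds)) + 1]
      cdsseq <- cds[[target_id]]
      w <- min(config$antisense_window, nchar(cdsseq))
      start <- sample(seq_len(nchar(cdsseq) - w + 1), 1)
      window <- substr(cdsseq, start, start + w - 1)
      if (config$antisense_mut > 0) {
        ws <- strsplit(window, "")[[1]]
        mp <- sample(length(ws), config$antisense_mut)
        for (p in mp) ws[p] <- sample(setdiff(DNA4, ws[p]), 1)
        window <- paste(ws, collapse = "")
      }
      id <- sprintf("AS%03d", i)
      # flank bases adjacent to the window are forced to mismatch the
      # continuing CDS bases, so a local alignment cannot extend past
      # the planted window and dilute its identity; the plant is then
      # verified against the scan itself (truth consistency)
      anti <- revcomp(window)
      ok <- FALSE
      for (try in 1:20) {
        f5 <- random_dna(sample(50:150, 1))
        f3 <- random_dna(sample(50:150, 1))
        nxt <- if (start + w <= nchar(cdsseq))
          revcomp(substr(cdsseq, start + w, start + w)) else NULL
        prv <- if (start > 1)
          revcomp(substr(cdsseq, start - 1, start - 1)) else NULL
        if (!is.null(nxt) && substr(f5, nchar(f5), nchar(f5)) == nxt)
          substr(f5, nchar(f5), nchar(f5)) <- setdiff(DNA4, nxt)[1]
        if (!is.null(prv) && substr(f3, 1, 1) == prv)
          substr(f3, 1, 1) <- setdiff(DNA4, prv)[1]
        cand <- paste0(f5, anti, f3)
        hit <- antisense_scan(cds[target_id], setNames(cand, id))
        if (nrow(hit) == 1 && hit$identity >= 0.99 &&
            hit$align_len >= 100) { ok <- TRUE; break }
      }
      if (!ok) stop("could not plant a filter-clean antisense copy for ",
                    target_id)
      transcripts[id] <- cand
      truth[[length(truth) + 1]] <- data.frame(
        id = id, class = "antisense", source_ref = NA_character_,
        planted_identity = 1 - config$antisense_mut / w,
        orf_start = NA_integer_, orf_end = NA_integer_,
        antisense_of = target_id, window_len = w,
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(config$n_decoys)) {
      id <- sprintf("DC%03d", i)
      transcripts[id] <- random_dna(sample(400:1200, 1))
      truth[[length(truth) + 1]] <- data.frame(
        id = id, class = "decoy", source_ref = NA_character_,
        planted_identity = NA_real_,
        orf_start = NA_integer_, orf_end = NA_integer_,
        antisense_of = NA_character_, window_len = NA_integer_,
        stringsAsFactors = FALSE)
    }

    list(transcripts = transcripts, cds = cds,
         truth = do.call(rbind, truth))
  })
}

#' Generate a three-tissue expression matrix with planted co-expression
#'
#' Assigns each planted transcript an FPKM profile over the three
#' tissues.  The first full-length gene is the designated marker (a
#' root-high profile); `n_coexpressed` further full-length genes receive
#' positively scaled copies of the marker profile (Pearson r = 1 before
#' noise); antisense transcripts receive profiles matching their planted
#' correlation class (the first 12 positive, remaining negative, to
#' mirror a 12/3 positive/negative split at the default count of 15);
#' all remaining transcripts draw from template profiles re-sampled until
#' their correlation with the marker is below 0.8.  Multiplicative
#' log2-normal noise of sd `noise_sd` is applied last.
#'
#' @param truth truth table from [make_transcriptome()].
#' @param config a [sim_config()].
#' @return list with `fpkm` (genes x 3 matrix), `marker` (gene id),
#'   `profile_truth` (data.frame: `id`, `role`, `planted_r`),
#'   `pathway_genes` (ids annotated to the target pathway) and
#'   `candidates` (planted co-expressed-and-pathway gene ids).
#' @export
make_expression <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(child_seed(config$seed, 23), {
    tissues <- config$tissues
    fl <- truth$id[truth$class == "full_cyp"]
    if (length(fl) < 1) stop("a marker gene requires >= 1 full-length gene")
    if (config$n_coexpressed + 1 > length(fl))
      stop("n_coexpressed exceeds the number of planted full-length genes")
    marker <- fl[1]
    coexp <- if (config$n_coexpressed > 0)
      fl[2:(1 + config$n_coexpressed)] else character(0)

    marker_prof <- c(120, 8, 4)              # root-high, like the pathway
    templates <- list(c(2, 60, 35), c(0.5, 30, 90), c(15, 14, 16),
                      c(0.2, 0.9, 40), c(55, 0.4, 18), c(8, 90, 0.7),
                      c(30, 25, 2), c(0.3, 0.3, 25))
    other_profile <- function() {
      repeat {
        p <- unlist(sample(templates, 1)) * runif(1, 0.5, 2)
        if (abs(cor(p, marker_prof)) < 0.8) return(p)
      }
    }

    ids <- truth$id
    M <- matrix(0, nrow = length(ids), ncol = 3,
                dimnames = list(ids, tissues))
    role <- setNames(rep("other", length(ids)), ids)
    planted_r <- setNames(rep(NA_real_, length(ids)), ids)

    M[marker, ] <- marker_prof
    role[marker] <- "marker"; planted_r[marker] <- 1
    for (g in coexp) {
      M[g, ] <- marker_prof * runif(1, 0.2, 3)
      role[g] <- "coexpressed"; planted_r[g] <- 1
    }
    for (g in setdiff(ids[truth$class != "antisense"],
                      c(marker, coexp))) M[g, ] <- other_profile()

    as_ids <- truth$id[truth$class == "antisense"]
    n_pos <- if (length(as_ids) >= 15) 12 else
      max(0, length(as_ids) - 3)            # keep a 12/3-style split
    for (i in seq_along(as_ids)) {
      sense <- truth$antisense_of[truth$id == as_ids[i]]
      p <- M[sense, ]
      if (i <= n_pos) {
        M[as_ids[i], ] <- p * runif(1, 0.3, 2)
        role[as_ids[i]] <- "antisense_positive"; planted_r[as_ids[i]] <- 1
      } else {
        M[as_ids[i], ] <- (max(p) + min(p) - p) * runif(1, 0.3, 2)
        role[as_ids[i]] <- "antisense_negative"; planted_r[as_ids[i]] <- -1
      }
    }

    if (config$noise_sd > 0)
      M <- M * 2^matrix(rnorm(length(M), 0, config$noise_sd), nrow(M))

    pathway <- c(sample(coexp, min(config$n_pathway_coexpressed,
                                   length(coexp))),
                 sample(setdiff(fl, c(marker, coexp)),
                        min(config$n_pathway_other,
                            length(setdiff(fl, c(marker, coexp))))))
    list(fpkm = M, marker = marker,
         profile_truth = data.frame(id = ids, role = role[ids],
                                    planted_r = planted_r[ids],
                                    stringsAsFactors = FALSE),
         pathway_genes = pathway,
         candidates = intersect(coexp, pathway))
  })
}

#' Generate a synthetic qPCR Ct table consistent with expression
#'
#' Inverts the 2^-ddCt model: each measured gene's Ct in a tissue is
#' `30 - log2(FPKM)`, the endogenous control is flat at Ct 18, and
#' Gaussian cycle noise is added at the biological and technical
#' replicate level (3 x 3 design).  Relative expressions recovered with
#' [ddct()] therefore equal the planted FPKM ratios up to noise.
#'
#' @param expr result of [make_expression()].
#' @param config a [sim_config()].
#' @return list with `ct` (data.frame: `gene`, `tissue`, `bio_rep`,
#'   `tech_rep`, `ct`), `control` (control gene name) and `genes`
#'   (measured gene ids, marker first).
#' @export
make_qpcr <- function(expr, config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(child_seed(config$seed, 37), {
    M <- expr$fpkm
    ok <- rownames(M)[apply(M, 1, function(x) all(x > 0))]
    pool <- setdiff(intersect(ok, grep("^FL", rownames(M), value = TRUE)),
                    expr$marker)
    n_extra <- min(config$n_qpcr_genes - 1, length(pool))
    genes <- c(expr$marker, sample(pool, n_extra))
    if (any(M[genes, ] <= 0))
      stop("nonpositive expression for a measured gene")
    control <- "ACT"
    rows <- list()
    for (g in c(genes, control)) for (t in config$tissues)
      for (b in 1:3) {
        base <- if (g == control) 18 else 30 - log2(M[g, t])
        bnoise <- rnorm(1, 0, config$qpcr_sd_bio)
        for (r in 1:3)
          rows[[length(rows) + 1]] <- data.frame(
            gene = g, tissue = t, bio_rep = b, tech_rep = r,
            ct = base + bnoise + rnorm(1, 0, config$qpcr_sd_tech),
            stringsAsFactors = FALSE)
      }
    list(ct = do.call(rbind, rows), control = control, genes = genes)
  })
}

#' Generate the full synthetic bundle
#'
#' Convenience wrapper running panel, transcriptome, expression and qPCR
#' generation under one configuration.
#'
#' @param config a [sim_config()].
#' @return list with components `config`, `panel`, `transcriptome`,
#'   `expression`, `qpcr`.
#' @export
make_bundle <- function(config = sim_config()) {
  panel <- make_reference_panel(config)
  txome <- make_transcriptome(panel, config)
  expr <- make_expression(txome$truth, config)
  qpcr <- make_qpcr(expr, config)
  list(config = config, panel = panel, transcriptome = txome,
       expression = expr, qpcr = qpcr)
}

#' Write a synthetic bundle to disk
#'
#' Emits `transcripts.fasta` (sense orientation), `panel.fasta`,
#' `panel.tsv`, `truth.tsv`, `expression.tsv` and `qpcr.tsv` into `dir`.
#' FASTA is wrapped at 60 columns; all TSV files carry header rows.
#'
#' @param bundle result of [make_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- Biostrings::DNAStringSet(bundle$transcriptome$transcripts)
  Biostrings::writeXStringSet(tx, file.path(dir, "transcripts.fasta"),
                              width = 60)
  pan <- Biostrings::AAStringSet(setNames(bundle$panel$protein,
                                          bundle$panel$name))
  Biostrings::writeXStringSet(pan, file.path(dir, "panel.fasta"),
                              width = 60)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(bundle$panel[, c("name", "family", "subfamily", "clan")], "panel.tsv")
  tsv(bundle$transcriptome$truth, "truth.tsv")
  expr <- data.frame(gene = rownames(bundle$expression$fpkm),
                     bundle$expression$fpkm, check.names = FALSE)
  tsv(expr, "expression.tsv")
  tsv(bundle$qpcr$ct, "qpcr.tsv")
  invisible(dir)
}
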