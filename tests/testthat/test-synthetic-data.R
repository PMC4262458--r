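# small configurations keep panel construction and verification fast
small_cfg <- function(...) {
  defaults <- list(n_families = 2, n_subfamilies_per_family = 2,
                   n_members_per_subfamily = 2, n_full = 6, n_partial = 4,
                   n_antisense = 4, n_decoys = 4,
                   n_coexpressed = 3, n_pathway_coexpressed = 2,
                   n_pathway_other = 1, n_qpcr_genes = 4, seed = 303)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_full = -1), "nonnegative")
  expect_error(sim_config(identity_targets = c(0.5, 1.2)), "identity_targets")
  expect_error(sim_config(tissues = c("a", "b")), "3 tissues")
  expect_error(sim_config(r_target = 1, noise_sd = 0.1), "unattainable")
  expect_error(sim_config(antisense_window = 80), ">= 100")
  expect_error(sim_config(antisense_mut = 5, antisense_window = 150),
               "0.99")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  b1 <- make_bundle(cfg); b2 <- make_bundle(cfg)
  expect_identical(b1$panel, b2$panel)
  expect_identical(b1$transcriptome, b2$transcriptome)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$qpcr, b2$qpcr)
})

test_that("a single-entry panel is produced without tier constraints", {
  cfg <- sim_config(n_families = 1, n_subfamilies_per_family = 1,
                    n_members_per_subfamily = 1, seed = 5)
  panel <- make_reference_panel(cfg)
  expect_equal(nrow(panel), 1)
  expect_equal(panel$clan, "71")
  expect_equal(nchar(panel$protein), 463)
})

test_that("panel pairwise identities fall in their prescribed tiers", {
  panel <- make_reference_panel(small_cfg())
  expect_equal(nrow(panel), 8)
  n <- nrow(panel)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # checked with the independent DP oracle, not the package kernel
    id <- oracle_glocal(panel$protein[i], panel$protein[j])$identity
    if (panel$subfamily[i] == panel$subfamily[j]) {
      expect_gte(id, 0.55)
    } else if (panel$family[i] == panel$family[j]) {
      expect_gte(id, 0.40); expect_lt(id, 0.55)
    } else {
      expect_lt(id, 0.40)
    }
  }
})

test_that("planted full-length identities are realized within 0.02", {
  cfg <- small_cfg(n_full = 5, n_partial = 0, n_antisense = 0,
                   n_decoys = 0, identity_targets = c(0.98, 0.60, 0.45),
                   n_coexpressed = 2, n_pathway_coexpressed = 1,
                   n_pathway_other = 0, n_qpcr_genes = 2)
  panel <- make_reference_panel(cfg)
  tx <- make_transcriptome(panel, cfg)
  truth <- tx$truth[tx$truth$class == "full_cyp", ]
  targets <- rep(c(0.98, 0.60, 0.45), length.out = 5)
  for (k in seq_len(nrow(truth))) {
    prot <- Biostrings::translate(Biostrings::DNAString(
      substr(tx$transcripts[[truth$id[k]]], truth$orf_start[k] + 1,
             truth$orf_end[k])))
    src <- panel$protein[panel$name == truth$source_ref[k]]
    realized <- oracle_glocal(as.character(prot), src)$identity
    expect_lt(abs(realized - targets[k]), 0.02)
  }
})

test_that("identity-1 plants translate exactly to their source protein", {
  cfg <- small_cfg(n_full = 1, n_partial = 0, n_antisense = 0,
                   n_decoys = 0, identity_targets = 1,
                   n_coexpressed = 0, n_pathway_coexpressed = 0,
                   n_pathway_other = 0, n_qpcr_genes = 1)
  panel <- make_reference_panel(cfg)
  tx <- make_transcriptome(panel, cfg)
  t1 <- tx$truth[1, ]
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(tx$transcripts[[t1$id]], t1$orf_start + 1, t1$orf_end))))
  expect_equal(prot, panel$protein[panel$name == t1$source_ref])
})

test_that("antisense plants are exact reverse complements of CDS windows", {
  cfg <- small_cfg(antisense_mut = 0)
  tx <- make_transcriptome(make_reference_panel(cfg), cfg)
  as_rows <- tx$truth[tx$truth$class == "antisense", ]
  for (k in seq_len(nrow(as_rows))) {
    w <- as_rows$window_len[k]
    expect_gte(w, 100)
    rc <- cypminer:::revcomp(tx$transcripts[[as_rows$id[k]]])
    # a full window of the transcript's revcomp must occur in the CDS
    found <- any(vapply(seq_len(nchar(rc) - w + 1), function(s)
      grepl(substr(rc, s, s + w - 1), tx$cds[[as_rows$antisense_of[k]]],
            fixed = TRUE), logical(1)))
    expect_true(found)
  }
})

test_that("noise-free expression plants exact correlation structure", {
  cfg <- small_cfg(noise_sd = 0)
  bundle <- make_bundle(cfg)
  M <- bundle$expression$fpkm
  pt <- bundle$expression$profile_truth
  mp <- M[bundle$expression$marker, ]
  for (g in pt$id[pt$role == "coexpressed"])
    expect_equal(cor(M[g, ], mp), 1)
  for (g in pt$id[pt$role == "antisense_negative"]) {
    sense <- bundle$transcriptome$truth$antisense_of[
      bundle$transcriptome$truth$id == g]
    expect_equal(cor(M[g, ], M[sense, ]), -1)
  }
})

test_that("co-expression screening recovers planted genes under noise", {
  # Monte-Carlo at a fixed seed: 50 planted co-expressed genes, small
  # noise; at least 90% recovered at r >= 0.9
  cfg <- sim_config(n_full = 60, n_coexpressed = 50, noise_sd = 0.1,
                    n_antisense = 0, n_partial = 0, n_decoys = 0,
                    n_qpcr_genes = 2, seed = 99)
  truth <- data.frame(id = sprintf("FL%03d", 1:60), class = "full_cyp",
                      source_ref = "x", planted_identity = 1,
                      orf_start = 0, orf_end = 3,
                      antisense_of = NA_character_,
                      window_len = NA_integer_)
  expr <- make_expression(truth, cfg)
  rec <- marker_correlation(expr$fpkm, expr$marker, r_cut = 0.9)
  planted <- expr$profile_truth$id[expr$profile_truth$role == "coexpressed"]
  recovered <- mean(rec$co_expressed[rec$gene_id %in% planted])
  expect_gte(recovered, 0.9)
})

test_that("noise-free qPCR tables invert the ddCt model exactly", {
  cfg <- small_cfg(qpcr_sd_bio = 0, qpcr_sd_tech = 0)
  bundle <- make_bundle(cfg)
  q <- bundle$qpcr
  res <- ddct(q$ct, control = q$control, calibrator_tissue = "root")
  M <- bundle$expression$fpkm
  for (g in q$genes) {
    s <- res$summary[res$summary$gene == g, ]
    rel <- setNames(s$rel_mean, s$tissue)
    expected <- M[g, ] / M[g, "root"]
    expect_equal(rel[names(expected)], expected, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("bundle files are written in standard formats", {
  dir <- withr::local_tempdir()
  bundle <- make_bundle(small_cfg())
  write_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(dir,
    c("transcripts.fasta", "panel.fasta", "panel.tsv", "truth.tsv",
      "expression.tsv", "qpcr.tsv")))))
  tx <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fasta"))
  expect_equal(length(tx), nrow(bundle$transcriptome$truth))
  expect_equal(unname(as.character(tx)),
               unname(bundle$transcriptome$transcripts))
})
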