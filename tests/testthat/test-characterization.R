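test_that("molecular weight matches the residue-mass model", {
  expect_equal(molecular_weight("G") * 1000, 75.0672, tolerance = 1e-6)
  # concatenation additivity: MW(a+b) = MW(a) + MW(b) - water
  set.seed(2)
  a <- random_protein(15); b <- random_protein(22)
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.0153 / 1000,
               tolerance = 1e-9)
  expect_error(molecular_weight(""), "empty")
  expect_warning(molecular_weight("GX"), "non-standard")
})

test_that("molecular weight agrees with an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(4)
  for (i in 1:10) {
    p <- random_protein(sample(20:200, 1))
    ref <- seqinr::pmw(strsplit(p, "")[[1]])
    expect_equal(molecular_weight(p) * 1000, ref, tolerance = 0.1)
  }
})

test_that("isoelectric point satisfies its defining property", {
  set.seed(8)
  for (i in 1:10) {
    p <- random_protein(sample(10:100, 1))
    pi <- isoelectric_point(p)
    s <- strsplit(p, "")[[1]]
    counts <- lapply(setNames(nm = names(cypminer:::PKA_SIDE)),
                     function(a) sum(s == a))
    expect_lt(abs(cypminer:::net_charge(counts, s[1], pi)), 1e-4)
    expect_gte(pi, 0); expect_lte(pi, 14)
  }
})

test_that("pI responds monotonically to basic and acidic residues", {
  set.seed(12)
  for (i in 1:5) {
    p <- random_protein(30)
    base <- isoelectric_point(p)
    expect_gte(isoelectric_point(paste0(p, "K")) + 1e-3, base)
    expect_lte(isoelectric_point(paste0(p, "D")) - 1e-3, base)
  }
})

test_that("pI bisection matches a dense grid scan", {
  set.seed(16)
  for (i in 1:50) {
    p <- random_protein(sample(8:60, 1))
    expect_lt(abs(isoelectric_point(p) - oracle_pi_grid(p)), 1e-3)
  }
})

test_that("motif scanning finds the four canonical patterns", {
  filler <- "LLLLLLLLLL"
  prot <- paste0(filler, "PFGAGRRICAG", filler, "FIPERF", filler,
                 "ETLR", filler, "AGHDT", filler)
  hits <- find_motifs(prot, "A")
  expect_setequal(unique(hits$motif),
                  c("heme", "PERF", "K-helix", "I-helix"))
  heme <- hits[hits$motif == "heme", ]
  expect_equal(heme$position, 10)
  expect_equal(heme$match, "PFGAGRRICAG")
  k <- hits[hits$motif == "K-helix", ]
  expect_equal(k$match[1], "ETLR")          # EXXR
  # context carries 5 flanking residues where available
  expect_equal(heme$context, paste0("LLLLL", "PFGAGRRICAG", "LLLLL"))
  # no K-helix without E..R spacing
  none <- find_motifs("LLLLLLRRRLLLEEE", "A")
  expect_false("K-helix" %in% none$motif)
})

test_that("non-A pattern variants match their consensus forms", {
  prot <- paste0("LLLLL", "AFTNGLRVCLG", "LLLLL", "FSPHRL", "LLLLL",
                 "AGHET", "LLLLL", "EQAR", "LLLLL")
  hits <- find_motifs(prot, "non-A")
  expect_setequal(unique(hits$motif),
                  c("heme", "PERF", "K-helix", "I-helix"))
})

test_that("motif logos count frequencies and information content", {
  logo <- motif_logo(rep("EALR", 10))
  expect_true(all(abs(colSums(logo$pfm) - 1) < 1e-12))
  expect_equal(logo$ic, rep(log2(20), 4), tolerance = 1e-12)

  # one varied column: hand-counted frequencies
  hits <- c(rep("EALR", 6), rep("ESLR", 4))
  logo2 <- motif_logo(hits)
  expect_equal(unname(logo2$pfm["A", 2]), 0.6)
  expect_equal(unname(logo2$pfm["S", 2]), 0.4)
  expect_equal(logo2$ic[2],
               log2(20) + 0.6 * log2(0.6) + 0.4 * log2(0.4))

  # a uniform column has zero information
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  logo3 <- motif_logo(paste0("E", aa20))
  expect_equal(logo3$ic[2], 0, tolerance = 1e-12)
  expect_error(motif_logo(c("EALR", "EAL")), "width mismatch")
})

test_that("every synthetic full-length CYP carries all four motifs", {
  cfg <- sim_config(n_families = 2, n_subfamilies_per_family = 2,
                    n_members_per_subfamily = 2, n_full = 6, n_partial = 0,
                    n_antisense = 0, n_decoys = 0, n_coexpressed = 2,
                    n_pathway_coexpressed = 1, n_pathway_other = 1,
                    n_qpcr_genes = 2, seed = 77,
                    identity_targets = c(0.98, 0.60, 0.45))
  panel <- make_reference_panel(cfg)
  tx <- make_transcriptome(panel, cfg)
  cur <- curate_transcripts(tx$transcripts)
  for (i in seq_len(nrow(cur))) {
    hits_a <- find_motifs(cur$protein[i], "A")
    hits_n <- find_motifs(cur$protein[i], "non-A")
    expect_equal(length(unique(hits_a$motif)), 4)
    expect_equal(length(unique(hits_n$motif)), 4)
  }
})
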