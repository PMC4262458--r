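test_that("FPKM follows its definition and scaling laws", {
  expect_equal(fpkm(matrix(10, 1, 1), 1000, 1e6)[1, 1], 10)
  expect_equal(fpkm(matrix(0, 1, 1), 500, 2e6)[1, 1], 0)
  m <- matrix(c(10, 20), 1, 2)
  f <- fpkm(m, 1000, c(1e6, 2e6))
  expect_equal(f[1, 2], f[1, 1])     # doubling library halves FPKM
  expect_error(fpkm(m, 1000, c(0, 1e6)), "library size")
})

test_that("expression flags use FPKM > 1 and Venn regions partition", {
  M <- matrix(c(1.0, 1.001, 5, 0,
                2.0, 0.5,   5, 0,
                0.1, 3.0,   5, 0), nrow = 4,
              dimnames = list(paste0("g", 1:4),
                              c("root", "leaf", "flower")))
  res <- expressed_flags(M)
  expect_false(res$flags["g1", "root"])   # FPKM = 1 is not expressed
  expect_true(res$flags["g2", "root"])    # 1.001 is
  expect_equal(sum(res$venn), sum(rowSums(res$flags) > 0))
  # toy enumeration: g1 leaf only? g1: root F leaf T flower F
  expect_equal(unname(res$venn["leaf"]), 1)
  expect_equal(unname(res$venn["root&leaf&flower"]), 1)  # g3
})

test_that("log transform centers rows exactly", {
  M <- matrix(c(5, 5, 5,
                0, 0, 7,
                1, 3, 9), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("r", "l", "f")))
  Tm <- transform_expression(M)
  expect_equal(unname(Tm[1, ]), c(0, 0, 0))
  expect_equal(unname(rowSums(Tm)), rep(0, 3), tolerance = 1e-12)
  r2 <- Tm[2, ]
  expect_equal(unname(r2[1]), unname(r2[2]))
  expect_gt(r2[3], 0); expect_lt(r2[1], 0)
  # hand-computed third row: log2(c(2,4,10)) - mean(log2(c(2,4,10)))
  expect_equal(unname(Tm[3, ]),
               log2(c(2, 4, 10)) - mean(log2(c(2, 4, 10))),
               tolerance = 1e-12)
  expect_error(transform_expression(matrix(-1, 1, 3)), "negative")
})

test_that("Ward clustering matches the naive oracle and is stable", {
  set.seed(33)
  X <- matrix(rnorm(15), nrow = 5,
              dimnames = list(paste0("g", 1:5), c("r", "l", "f")))
  res <- hier_cluster(X, k = 2)
  ref <- oracle_ward_merges(X)
  # same merge heights in the same order
  expect_equal(res$hclust$height, ref$heights, tolerance = 1e-9)
  # same clusters formed at each agglomeration step
  hc <- res$hclust
  got_merges <- list()
  members <- list()
  for (s in seq_len(nrow(hc$merge))) {
    m <- hc$merge[s, ]
    set <- c(if (m[1] < 0) -m[1] else members[[m[1]]],
             if (m[2] < 0) -m[2] else members[[m[2]]])
    members[[s]] <- set
    got_merges[[s]] <- sort(set)
  }
  expect_equal(got_merges, ref$merges)

  # identical rows merge first at height 0
  X2 <- rbind(X, g6 = X[1, ])
  h2 <- hier_cluster(X2)$hclust
  expect_equal(h2$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(h2$merge[1, ]), c(1, 6))

  # permutation invariance of topology (heights)
  perm <- sample(5)
  h3 <- hier_cluster(X[perm, ], k = 2)$hclust
  expect_equal(h3$height, res$hclust$height, tolerance = 1e-9)
  expect_error(hier_cluster(X[1, , drop = FALSE]), ">= 2")
})

test_that("Ward merge order matches the oracle on larger inputs", {
  set.seed(34)
  for (n in 6:8) {
    X <- matrix(rnorm(n * 3), nrow = n,
                dimnames = list(paste0("g", 1:n), c("r", "l", "f")))
    res <- hier_cluster(X)$hclust
    ref <- oracle_ward_merges(X)
    expect_equal(res$height, ref$heights, tolerance = 1e-9)
  }
})

test_that("marker correlation equals the product-moment formula", {
  set.seed(41)
  M <- matrix(runif(63, 0, 100), ncol = 3,
              dimnames = list(paste0("g", 1:21), c("r", "l", "f")))
  M["g1", ] <- c(50, 10, 5)
  rec <- marker_correlation(M, "g1")
  expect_equal(rec$r[rec$gene_id == "g1"], 1)
  for (g in paste0("g", 2:21)) {
    mp <- M["g1", ]; p <- M[g, ]
    manual <- sum((p - mean(p)) * (mp - mean(mp))) /
      sqrt(sum((p - mean(p))^2) * sum((mp - mean(mp))^2))
    expect_equal(rec$r[rec$gene_id == g], manual, tolerance = 1e-12)
  }
  # centered negation gives r = -1
  M2 <- rbind(M, neg = max(M["g1", ]) + min(M["g1", ]) - M["g1", ])
  rec2 <- marker_correlation(M2, "g1")
  expect_equal(rec2$r[rec2$gene_id == "neg"], -1)
  # zero-variance profile recorded, not crashed
  M3 <- rbind(M, flat = c(2, 2, 2))
  rec3 <- marker_correlation(M3, "g1")
  expect_true(is.na(rec3$r[rec3$gene_id == "flat"]))
  expect_match(rec3$reason[rec3$gene_id == "flat"], "variance")
})

test_that("candidates are exactly the co-expressed pathway members", {
  rec <- data.frame(gene_id = paste0("g", 1:6),
                    r = c(0.95, 0.95, 0.5, 0.92, -0.2, 0.91),
                    co_expressed = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                    reason = "")
  out <- call_candidates(rec, pathway_genes = c("g1", "g3", "g4"))
  expect_equal(out$gene_id[out$candidate], c("g1", "g4"))
  expect_true(all(out$candidate == (out$co_expressed & out$pathway_member)))
  expect_error(call_candidates(rec, NULL), "pathway")
})

test_that("ddCt reproduces hand-computed relative expressions", {
  mk <- function(gene, tissue, ct)
    expand.grid(gene = gene, tissue = tissue, bio_rep = 1:3,
                tech_rep = 1:3, stringsAsFactors = FALSE) |>
      transform(ct = ct)
  # gene with dCt equal across tissues -> all relative expressions 1
  ct <- rbind(mk("g1", "root", 24), mk("g1", "leaf", 24),
              mk("g1", "flower", 24),
              mk("ACT", "root", 18), mk("ACT", "leaf", 18),
              mk("ACT", "flower", 18))
  res <- ddct(ct, control = "ACT", calibrator_tissue = "root")
  expect_equal(res$summary$rel_mean, rep(1, 3))

  # ddCt = -2 -> relative expression 4
  ct2 <- rbind(mk("g1", "root", 22), mk("g1", "leaf", 24),
               mk("ACT", "root", 18), mk("ACT", "leaf", 18))
  res2 <- ddct(ct2, control = "ACT", calibrator_tissue = "leaf")
  expect_equal(res2$summary$rel_mean[res2$summary$tissue == "root"], 4)

  # 3x3 toy table with technical scatter averaging out
  ct3 <- rbind(mk("g1", "root", 20), mk("g1", "leaf", 23),
               mk("ACT", "root", 18), mk("ACT", "leaf", 18))
  ct3$ct <- ct3$ct + rep(c(-0.2, 0, 0.2), length.out = nrow(ct3))
  res3 <- ddct(ct3, control = "ACT", calibrator_tissue = "root")
  expect_equal(res3$summary$rel_mean[res3$summary$tissue == "leaf"],
               2^(-3), tolerance = 1e-9)
  expect_error(ddct(ct3[ct3$gene != "ACT", ], "ACT", "root"), "missing|absent")
})

test_that("concordance compares tissue rankings and correlation", {
  a <- c(root = 10, leaf = 5, flower = 1)
  expect_true(concordance(a, a)$rank_match)
  expect_equal(concordance(a, a)$r, 1)
  expect_false(concordance(a, rev(unname(a)) |> setNames(names(a)))$rank_match)
  expect_true(concordance(a, c(root = 3, leaf = 3, flower = 3))$tie)
})

test_that("most genes rank-validate under modest qPCR noise", {
  cfg <- sim_config(n_full = 20, n_partial = 0, n_antisense = 0,
                    n_decoys = 0, n_coexpressed = 5,
                    n_pathway_coexpressed = 2, n_pathway_other = 1,
                    n_qpcr_genes = 19, qpcr_sd_bio = 0.2,
                    qpcr_sd_tech = 0.1, seed = 55)
  truth <- data.frame(id = sprintf("FL%03d", 1:20), class = "full_cyp",
                      source_ref = "x", planted_identity = 1,
                      orf_start = 0, orf_end = 3,
                      antisense_of = NA_character_,
                      window_len = NA_integer_)
  expr <- make_expression(truth, cfg)
  q <- make_qpcr(expr, cfg)
  res <- ddct(q$ct, control = q$control, calibrator_tissue = "root")
  validated <- vapply(q$genes, function(g) {
    s <- res$summary[res$summary$gene == g, ]
    qp <- setNames(s$rel_mean, s$tissue)
    concordance(expr$fpkm[g, ], qp[colnames(expr$fpkm)])$rank_match
  }, logical(1))
  expect_gte(mean(validated), 0.8)
})
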