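make_counts <- function(n_genes, n_cells, n_detected) {
  # each cell detects exactly n_detected[i] genes (value 1), rest 0
  v <- matrix(0, n_genes, n_cells)
  for (i in seq_len(n_cells)) v[seq_len(n_detected[i]), i] <- 1
  v
}

test_that("filter_cells applies platform cutoffs with inclusive boundary", {
  m_ss2 <- toy_matrix(make_counts(3000, 3, c(2500, 2000, 1500)),
                      platforms = c(s1 = "smartseq2"))
  kept <- filter_cells(m_ss2)
  expect_identical(cell_ids(kept), c("c001", "c002"))

  m_umi <- toy_matrix(make_counts(1200, 2, c(1000, 999)))
  expect_identical(cell_ids(filter_cells(m_umi)), "c001")

  # all above both cutoffs: identity; counts match a naive re-count
  m_hi <- toy_matrix(make_counts(2500, 4, rep(2100, 4)),
                     platforms = c(s1 = "smartseq2"))
  expect_identical(filter_cells(m_hi)$values, m_hi$values)
  expect_equal(unname(detected_genes(m_hi)), unname(colSums(m_hi$values > 0)))

  expect_error(filter_cells(toy_matrix(make_counts(1200, 1, 5))),
               "all cells filtered")
})

test_that("filter_genes keeps top-k means with deterministic ties", {
  v <- rbind(g_a = c(5, 5), g_b = c(1, 1), g_c = c(3, 3))
  colnames(v) <- c("c1", "c2")
  m <- toy_matrix(v)
  expect_identical(gene_ids(filter_genes(m, k = 2)), c("g_a", "g_c"))
  expect_identical(filter_genes(m, k = 10)$values, m$values)
  # tie at the boundary: lexicographic gene id wins
  v2 <- rbind(zz = c(2, 2), aa = c(2, 2), bb = c(9, 9))
  colnames(v2) <- c("c1", "c2")
  expect_identical(gene_ids(filter_genes(toy_matrix(v2), k = 2)),
                   c("aa", "bb"))
  # synthetic matrix: exactly k genes survive
  sim <- gen_expression(sc_sim_config(n_cells = 40, n_genes = 500,
                                      n_signature_genes_per_state = 20,
                                      seed = 1))
  expect_equal(n_genes(filter_genes(sim$matrix, k = 300)), 300)
})

test_that("normalize_log implements log2(CPM/10 + 1)", {
  # CPM inputs pass through the transform directly
  v <- rbind(g1 = c(10, 0), g2 = c(20, 40))
  colnames(v) <- c("c1", "c2")
  m <- toy_matrix(v, unit = "cpm")
  out <- normalize_log(m)
  expect_equal(out$values["g1", "c1"], 1.0)       # log2(10/10 + 1) = 1
  expect_equal(out$values["g1", "c2"], 0.0)       # 0 -> 0
  expect_identical(out$unit, "lognorm")
  # counts (90, 10) -> CPM (9e5, 1e5) -> log2(90001), log2(10001)
  v2 <- matrix(c(90, 10), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  out2 <- normalize_log(toy_matrix(v2))
  expect_equal(unname(out2$values[, 1]), c(log2(90001), log2(10001)),
               tolerance = 1e-12)
  # strict monotonicity per entry
  expect_true(all(diff(normalize_log(
    toy_matrix(matrix(c(1, 5, 9), 3, 1), unit = "cpm"))$values[, 1]) > 0))
  # zero-count cell is named in the error
  v3 <- matrix(c(1, 0), 1, 2, dimnames = list("g1", c("good", "bad")))
  expect_error(normalize_log(toy_matrix(v3)), "bad")
})

test_that("center_within_sample centers per sample and is idempotent", {
  v <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  cen <- center_within_sample(toy_matrix(v, unit = "lognorm"))
  expect_equal(unname(cen$values[1, ]), c(-1, 0, 1))

  set.seed(20)
  v2 <- matrix(rexp(500 * 40, 1 / 50), 500, 40)
  m2 <- normalize_log(toy_matrix(v2, samples = rep(c("s1", "s2"), each = 20),
                                 platforms = c(s1 = "umi", s2 = "umi")))
  cen2 <- center_within_sample(m2)
  for (s in c("s1", "s2")) {
    mu <- rowMeans(cen2$values[, cen2$sample_of_cell == s])
    expect_lt(max(abs(mu)), 1e-9)
  }
  cen3 <- center_within_sample(cen2)
  expect_lt(max(abs(cen3$values - cen2$values)), 1e-12)
  # a single-cell sample centers to zero, with a warning
  expect_warning(center_within_sample(normalize_log(
    toy_matrix(matrix(1:6, 2, 3), samples = c("s1", "s1", "s2"),
               platforms = c(s1 = "umi", s2 = "umi")))), "single cell")
})

test_that("normalize_log on lognorm input is rejected", {
  m <- toy_matrix(matrix(1, 1, 2), unit = "cpm")
  expect_error(normalize_log(normalize_log(m)), "lognorm")
})

test_that("signature_score degenerate forms equal centered expression", {
  set.seed(8)
  v <- matrix(rexp(100 * 30, 1 / 20), 100, 30)
  m <- normalize_log(toy_matrix(v))
  cen <- center_within_sample(m)
  g <- gene_ids(m)[5]
  # single-gene signature, no controls
  expect_equal(signature_score(m, g, n_ctrl = 0),
               setNames(cen$values[g, ], cell_ids(m)))
  # signature = all genes, no controls -> per-cell mean centered expression
  expect_equal(signature_score(m, gene_ids(m), n_ctrl = 0),
               setNames(colMeans(cen$values), cell_ids(m)))
  expect_error(signature_score(m, c("nope1", "nope2")), "nope1")
})

test_that("state scoring is per sample and permutation-consistent", {
  sim <- gen_expression(sc_sim_config(n_cells = 120, n_genes = 600,
                                      n_signature_genes_per_state = 30,
                                      n_samples = 2, seed = 13))
  mlog <- normalize_log(sim$matrix)
  tab <- state_scores(mlog, sim$signatures, seed = 13)
  # permuting cell order permutes scores identically
  perm <- withr::with_seed(1, sample(n_cells(mlog)))
  mperm <- dmgquant:::subset_matrix(mlog, cells = perm)
  tab_perm <- state_scores(mperm, sim$signatures, seed = 13)
  expect_equal(tab_perm$opc_score, tab$opc_score[perm], tolerance = 1e-12)
  # duplicated sample gets identical scores in both copies
  v <- mlog$values[, mlog$sample_of_cell == "sample1"]
  dup <- expression_matrix(
    cbind(v, `colnames<-`(v, paste0(colnames(v), "_dup"))),
    sample_of_cell = rep(c("sA", "sB"), each = ncol(v)),
    platform_of_sample = c(sA = "umi", sB = "umi"), unit = "lognorm")
  tab_dup <- state_scores(dup, sim$signatures, seed = 13)
  expect_equal(tab_dup$opc_score[tab_dup$sample == "sA"],
               tab_dup$opc_score[tab_dup$sample == "sB"], tolerance = 1e-12)
  # ground truth: per-state mean of own-state score is the maximum
  for (st in c("OPC", "OC", "AC")) {
    own <- sim$true_state == st
    means <- c(OPC = mean(tab$opc_score[own]), OC = mean(tab$oc_score[own]),
               AC = mean(tab$ac_score[own]))
    expect_identical(names(which.max(means)), st)
  }
})

test_that("stemness_lineage matches the printed formulas", {
  tbl <- data.frame(opc_score = c(2, 0.5, 1),
                    oc_score = c(1, 1, -0.2),
                    ac_score = c(0.5, 1.5, -0.3))
  out <- stemness_lineage(tbl, jitter_eps = 0.05, seed = 1)
  expect_equal(out$stemness, c(1, -1, 1.2))
  expect_equal(out$lineage[1:2], c(1, -1.5))
  expect_true(out$jittered[3] && abs(out$lineage[3]) <= 0.05)
  expect_false(any(out$jittered[1:2]))
  # tie ac == oc resolves to OC (positive sign)
  tie <- stemness_lineage(data.frame(opc_score = 0, oc_score = 0.7,
                                     ac_score = 0.7))
  expect_equal(tie$lineage, 0.7)
  # brute-force agreement on 1000 random triples
  set.seed(77)
  trip <- matrix(rnorm(3000), ncol = 3)
  out2 <- stemness_lineage(data.frame(opc_score = trip[, 1],
                                      oc_score = trip[, 2],
                                      ac_score = trip[, 3]),
                           jitter_eps = 0.05, seed = 5)
  for (i in seq_len(nrow(trip))) {
    oracle <- stemness_lineage_oracle(trip[i, 1], trip[i, 2], trip[i, 3])
    expect_identical(out2$stemness[i], unname(oracle["stemness"]))
    if (is.na(oracle["lineage"])) {
      expect_true(out2$jittered[i] && abs(out2$lineage[i]) <= 0.05)
    } else {
      expect_identical(out2$lineage[i], unname(oracle["lineage"]))
    }
  }
})

test_that("highlight_cells uses a strict threshold on centered values", {
  v <- matrix(c(1.2, 1.0, 0.4), 1, 3,
              dimnames = list("CHRM1", c("a", "b", "c")))
  m <- toy_matrix(v, unit = "lognorm", centered = TRUE)
  expect_equal(unname(highlight_cells(m, "CHRM1", 1.0)),
               c(TRUE, FALSE, FALSE))
  expect_error(highlight_cells(m, "CHRM9"), "not in matrix")
  # all-negative gene yields no flags
  m$values["CHRM1", ] <- -abs(m$values["CHRM1", ])
  expect_false(any(highlight_cells(m, "CHRM1")))
  # threshold 0 on symmetric centered data flags about half the cells
  set.seed(4)
  sym <- toy_matrix(matrix(rnorm(2000), 1, 2000,
                           dimnames = list("g1", paste0("c", 1:2000))),
                    unit = "lognorm", centered = TRUE)
  expect_lt(abs(mean(highlight_cells(sym, "g1", 0)) - 0.5), 0.05)
})

test_that("pseudo_bulk averages malignant cells then log-transforms", {
  v <- matrix(c(10, 30, 999), 1, 3,
              dimnames = list("g1", c("m1", "m2", "nm")))
  m <- toy_matrix(v, unit = "cpm", malignant = c(TRUE, TRUE, FALSE))
  pb <- pseudo_bulk(m)
  expect_equal(pb["s1", "g1"], log2(3))  # mean(10, 30)/10 + 1
  # non-malignant cells do not affect the result
  v2 <- v; v2[1, 3] <- 0
  expect_equal(pseudo_bulk(toy_matrix(v2, unit = "cpm",
                                      malignant = c(TRUE, TRUE, FALSE))), pb)
  # random matrix vs a brute-force group-by oracle
  set.seed(6)
  vr <- matrix(rexp(50 * 30, 1 / 100), 50, 30)
  mal <- rep(c(TRUE, FALSE), 15)
  mr <- toy_matrix(vr, samples = rep(c("sa", "sb"), each = 15),
                   platforms = c(sa = "umi", sb = "umi"),
                   unit = "cpm", malignant = mal)
  pbr <- pseudo_bulk(mr)
  for (s in c("sa", "sb")) {
    sel <- mr$sample_of_cell == s & mal
    oracle <- log2(apply(vr[, sel, drop = FALSE], 1, mean) / 10 + 1)
    expect_lt(max(abs(pbr[s, ] - oracle)), 1e-12)
  }
  expect_error(pseudo_bulk(toy_matrix(v, unit = "cpm",
                                      malignant = rep(FALSE, 3))),
               "no malignant")
})

test_that("correlations match the textbook oracle and report bounds", {
  set.seed(15)
  n <- 30
  scores <- rnorm(n)
  v <- rbind(lin = 2 * scores + 1,          # r = 1 exactly
             noise = rnorm(n),
             anti = -scores)
  colnames(v) <- paste0("c", 1:n)
  m <- toy_matrix(v, unit = "lognorm", centered = TRUE)
  rep <- correlate_within_samples(m, scores)
  expect_equal(rep$mean_r[rep$gene == "lin"], 1, tolerance = 1e-12)
  expect_equal(rep$mean_r[rep$gene == "anti"], -1, tolerance = 1e-12)
  expect_true(all(abs(rep$mean_r) <= 1 + 1e-12))
  expect_equal(rep$mean_r[rep$gene == "noise"],
               pearson_oracle(v["noise", ], scores), tolerance = 1e-12)

  # across samples: linear pseudo-bulk gene gives r = 1, sign flip flips r
  pb <- cbind(gene1 = c(1, 2, 3, 4), gene2 = -c(1, 2, 3, 4))
  rownames(pb) <- paste0("s", 1:4)
  rep2 <- correlate_across_samples(pb, sample_scores = c(1, 2, 3, 4))
  expect_equal(rep2$mean_r, c(1, -1), tolerance = 1e-12)
  set.seed(16)
  pb3 <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  sc3 <- rnorm(8)
  rep3 <- correlate_across_samples(pb3, sc3)
  for (j in 1:5) {
    expect_equal(rep3$mean_r[j], pearson_oracle(pb3[, j], sc3),
                 tolerance = 1e-12)
  }
  expect_warning(
    correlate_across_samples(pb, c(1, 2, 3, 4),
                             study_of_sample = c("a", "a", "a", "b")),
    "skipped")
})

test_that("null receptor gene has near-zero mean within-sample correlation", {
  sim <- gen_expression(sc_sim_config(n_cells = 240, n_genes = 600,
                                      n_signature_genes_per_state = 30,
                                      n_samples = 4, state_effect = 0,
                                      seed = 21))
  mlog <- normalize_log(sim$matrix)
  opc <- signature_score(mlog, sim$signatures$OPC, seed = 21)
  cen <- center_within_sample(mlog)
  # per-sample r values for the (state-decoupled at effect 0) receptor
  rs <- sapply(unique(mlog$sample_of_cell), function(s) {
    sel <- mlog$sample_of_cell == s
    pearson_oracle(cen$values[sim$receptor_gene, sel], opc[sel])
  })
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 0.05)
})

test_that("fdr_adjust is exact BH with monotone step-up", {
  expect_equal(fdr_adjust(0.01)$q, 0.01)
  out <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q, rep(0.04, 4))  # hand BH: min over j>=i of p_j*4/j
  all1 <- fdr_adjust(rep(1, 5))
  expect_true(all(all1$q == 1) && !any(all1$significant))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  # random p-values: exact match to the brute-force oracle, q >= p,
  # monotone in p
  set.seed(30)
  p <- runif(200)
  out2 <- fdr_adjust(p)
  expect_equal(out2$q, bh_oracle(p), tolerance = 1e-15)
  expect_true(all(out2$q >= out2$p))
  expect_true(all(diff(out2$q[order(out2$p)]) >= -1e-15))
})
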