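test_that("QC applies the printed cell and gene rules at their boundaries", {
  # 5 genes detectable; thresholds scaled down via arguments to keep the
  # fixture small while exercising the same strict inequalities
  counts <- rbind(
    g1 = c(10, 10, 10, 10),
    g2 = c(10, 10, 10, 0),
    g3 = c(10, 10, 0, 0),
    g4 = c(10, 0, 10, 0),
    mt = c(0, 0, 0, 0)
  )
  data <- toy_dataset(counts, mito = c(F, F, F, F, T))
  out <- qc_filter_cells(data, min_genes = 3, max_genes = 10, min_cells = 1)
  # cell with 1 detected gene (< 3) removed; cells with exactly 3 retained
  expect_identical(out$cells$cell_id, c("c001", "c002", "c003"))
  expect_identical(attr(out, "qc_report")$cells_removed_low_genes, 1L)
})

test_that("mitochondrial ceilings are strict and fraction-specific", {
  # 100 total counts per cell; mito gene carries 6 / 7 / 20 / 21 of them
  mito_counts <- c(6, 7, 20, 21)
  counts <- rbind(
    g1 = 100 - mito_counts, g2 = rep(5, 4), g3 = rep(5, 4),
    mt1 = mito_counts
  )
  counts["g1", ] <- counts["g1", ] - 10   # keep totals at 100
  imm <- toy_dataset(counts, mito = c(F, F, F, T), fraction = "CD45pos")
  out <- qc_filter_cells(imm, min_genes = 1, min_cells = 1)
  # immune rule is > 6%: exactly 6% retained, 7% and above removed
  expect_identical(out$cells$cell_id, "c001")
  tum <- toy_dataset(counts, mito = c(F, F, F, T), fraction = "CD45neg")
  out_t <- qc_filter_cells(tum, min_genes = 1, min_cells = 1)
  # tumor rule is > 20%: 21% removed, 20% retained
  expect_identical(out_t$cells$cell_id, c("c001", "c002", "c003"))
})

test_that("genes below the 3-cell floor are dropped after cell filtering", {
  counts <- rbind(g1 = c(5, 5, 5, 5), g2 = c(5, 5, 5, 0), g3 = c(5, 5, 0, 0))
  data <- toy_dataset(counts)
  out <- qc_filter_cells(data, min_genes = 1, min_cells = 3)
  expect_identical(out$genes$gene_id, c("g1", "g2"))  # 3 cells retained, 2 dropped
})

test_that("QC is idempotent and errors when nothing survives", {
  cfg <- sim_config(seed = 2, n_cells = 200)
  data <- generate_sc_dataset(cfg)$data
  once <- qc_filter_cells(data)
  twice <- qc_filter_cells(once)
  expect_identical(as.matrix(once$rna), as.matrix(twice$rna))
  expect_identical(once$cells, twice$cells)
  expect_error(qc_filter_cells(data, min_genes = 10000), "every cell")
})

test_that("RNA normalization scales cells to 10,000 and logs", {
  counts <- cbind(a = c(19998L, 2L), b = c(5000L, 5000L))
  rownames(counts) <- c("g1", "g2")
  pre <- normalize_rna(counts, log = FALSE)
  expect_equal(unname(Matrix::colSums(pre)), c(1e4, 1e4))
  post <- normalize_rna(counts)
  # cell total 20,000 with gene count 2 -> scaled 1.0 -> ln(2)
  expect_equal(post["g2", "a"], log(2), tolerance = 1e-12)
  # cell already at total 10,000: scaling is the identity
  expect_equal(as.numeric(pre[, "b"]), c(5000, 5000))
  zero <- cbind(a = c(1L, 0L), z = c(0L, 0L))
  rownames(zero) <- c("g1", "g2")
  expect_error(normalize_rna(zero), "z")
})

test_that("CLR normalization is a per-cell centered transform", {
  m <- rbind(CD45 = c(5L, 7L, 0L), CD3 = c(5L, 1L, 0L), CD4 = c(5L, 19L, 3L))
  colnames(m) <- c("a", "b", "c")
  clr <- normalize_protein_clr(m)
  expect_equal(unname(colSums(clr)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(clr[, "a"]), rep(0, 3))          # equal markers -> all 0
  single <- matrix(4L, 1, 2, dimnames = list("CD45", c("a", "b")))
  expect_equal(unname(normalize_protein_clr(single)), matrix(0, 1, 2))
})

test_that("gating assigns compartments by the marker sign rules", {
  clr <- rbind(CD45 = c(2, 2, 2, -1), CD3 = c(1.5, 1.5, 1.5, 1),
               CD4 = c(1.2, 1.2, -0.5, 1), CD8 = c(-0.8, 0.9, 0.9, 1),
               CD20 = c(-1, -1, -1, -1))
  colnames(clr) <- sprintf("c%03d", 1:4)
  counts <- matrix(0L, 2, 4,
                   dimnames = list(c("g1", "CD68"), colnames(clr)))
  counts["g1", ] <- 10L
  data <- toy_dataset(counts)
  out <- gate_t_compartments(data, clr = clr, cd68_rna = rep(0, 4))
  # CD4+/CD8- -> CD4; double positive -> excluded; CD8 single -> CD8;
  # CD45- -> excluded
  expect_identical(out$cells$compartment,
                   c("CD4", "excluded", "CD8", "excluded"))
  # CD20 above threshold excludes
  clr2 <- clr; clr2["CD20", 1] <- 0.5
  out2 <- gate_t_compartments(data, clr = clr2, cd68_rna = rep(0, 4))
  expect_identical(out2$cells$compartment[1], "excluded")
  # CD68-high RNA excludes
  out3 <- gate_t_compartments(data, clr = clr, cd68_rna = c(2, 0, 0, 0))
  expect_identical(out3$cells$compartment[1], "excluded")
  expect_error(gate_t_compartments(data, clr = clr[-3, ], cd68_rna = rep(0, 4)),
               "CD4")
})

test_that("gating partitions every cell into exactly one compartment", {
  sc <- generate_sc_dataset(sim_config(seed = 8, n_cells = 300))
  out <- gate_t_compartments(qc_filter_cells(sc$data))
  expect_true(all(out$cells$compartment %in% c("CD4", "CD8", "excluded")))
  expect_identical(length(out$cells$compartment), ncol(out$rna))
})

test_that("rank-sum DE matches exhaustive enumeration on a 5v5 toy", {
  set.seed(42)
  x <- c(rnorm(5, 2), rnorm(5, 0))          # continuous: no ties
  expr <- matrix(x, nrow = 1, dimnames = list("g1", sprintf("c%d", 1:10)))
  labels <- rep(c("A", "B"), each = 5)
  de <- differential_expression(expr, labels, "A")
  # enumeration oracle: all C(10,5) assignments of ranks to group A
  r <- rank(x)
  u_obs <- sum(r[1:5]) - 5 * 6 / 2
  combos <- combn(10, 5)
  u_null <- apply(combos, 2, function(ix) sum(r[ix]) - 15)
  p_exact <- mean(abs(u_null - 12.5) >= abs(u_obs - 12.5))
  expect_equal(de$u, u_obs)
  expect_equal(de$p, p_exact, tolerance = 1e-12)
  # and agrees with the base-R exact test
  w <- wilcox.test(x[1:5], x[6:10], exact = TRUE)
  expect_equal(de$p, w$p.value, tolerance = 1e-12)
})

test_that("DE handles constant genes and tie correction", {
  expr <- rbind(flat = rep(1, 8), shifted = c(5, 6, 7, 8, 1, 2, 3, 4))
  colnames(expr) <- sprintf("c%d", 1:8)
  labels <- rep(c("A", "B"), each = 4)
  de <- differential_expression(expr, labels, "A")
  flat <- de[de$gene == "flat", ]
  expect_identical(flat$z, 0)
  expect_identical(flat$p, 1)
  expect_error(differential_expression(expr, labels, "C"), "absent")
  # tie-corrected z agrees with wilcox.test normal approximation
  tied <- rbind(g = c(1, 1, 2, 2, 3, 1, 1, 2, 3, 3))
  colnames(tied) <- sprintf("c%d", 1:10)
  lab <- rep(c("A", "B"), each = 5)
  d2 <- differential_expression(tied, lab, "A", exact_max_n = 0)
  w <- suppressWarnings(wilcox.test(tied[1, 1:5], tied[1, 6:10],
                                    exact = FALSE, correct = FALSE))
  expect_equal(d2$p, w$p.value, tolerance = 1e-10)
})

test_that("signature derivation ranks by z with the documented tie-breaks", {
  de <- data.frame(
    gene = c("bbb", "aaa", "ccc", "ddd"),
    z = c(2, 2, 3, 0), u = 0, p = 0.01, p_adj = 0.04,
    lfc = c(1, 1, 2, 0), stringsAsFactors = FALSE
  )
  sig <- derive_signature(de, k = 3)
  expect_identical(sig$genes, c("ccc", "aaa", "bbb"))  # lexicographic on tie
  expect_error(derive_signature(de, k = 10), "fewer than 10")
})

test_that("planted marker sets are recovered as the top-25 signature", {
  markers <- sprintf("GENE%04d", 1:25)
  spec <- list(
    list(name = "A", prop = 0.5, markers = markers, lfc = 8, conc = 50,
         compartment = "CD8", cytotoxic = TRUE),
    list(name = "B", prop = 0.5, markers = "CCR7", lfc = 4, conc = 50,
         compartment = "CD8", cytotoxic = FALSE))
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 100 + s, n_cells = 300, cluster_spec = spec,
                      chain_dropout = 0)
    sc <- generate_sc_dataset(cfg)
    norm <- normalize_rna(sc$data)
    de <- differential_expression(as.matrix(norm), sc$data$cells$cluster, "A")
    sig <- derive_signature(de, k = 25)
    if (setequal(sig$genes, markers)) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("signature scoring is an order-invariant arithmetic mean", {
  set.seed(7)
  expr <- matrix(rnorm(30 * 6), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  genes <- sprintf("g%02d", c(3, 9, 17, 21))
  s <- score_signature(expr, genes)
  oracle <- apply(expr[genes, ], 2, mean)
  expect_equal(s, oracle, tolerance = 1e-14)
  expect_equal(score_signature(expr, rev(genes)), s)          # gene order
  expect_equal(score_signature(expr[sample(30), ], genes), s) # extra genes
  flat <- matrix(2, 4, 3, dimnames = list(genes, c("a", "b", "c")))
  expect_equal(unname(score_signature(flat, genes)), rep(2, 3))
  z <- score_signature(expr, genes, standardize = TRUE)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(score_signature(expr, c(genes, "nope")), "nope")
})

test_that("HLA locus totals are row sums over the locus gene sets", {
  set.seed(3)
  expr <- matrix(rpois(5 * 4, 3), nrow = 5,
                 dimnames = list(c("HLA-A", "HLA-B", "HLA-C", "HLA-DRB1", "CD74"),
                                 sprintf("c%d", 1:4)))
  sets <- list(HLA_I = c("HLA-A", "HLA-B", "HLA-C"), HLA_II = "HLA-DRB1")
  out <- sum_hla_expression(expr, sets)
  expect_equal(out$totals["HLA_I", ],
               colSums(expr[c("HLA-A", "HLA-B", "HLA-C"), ]))
  expect_equal(out$totals["HLA_II", ], expr["HLA-DRB1", ])  # single gene
  zero <- expr; zero[, 1] <- 0
  expect_equal(unname(sum_hla_expression(zero, sets)$totals[, 1]), c(0, 0))
  expect_error(sum_hla_expression(expr, list(HLA_I = character())), "empty")
})
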