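test_that("clonotype calling filters unpaired and multi-chain cells", {
  rec <- rbind(
    paired_chains(c("c1", "c2"), c("CAAF", "CAAF"), c("CASSF", "CASSF")),
    data.frame(cell_id = "c3", locus = "TRA", junction_aa = "CAXF"),
    paired_chains("c4", "CABF", "CASSBF"),
    data.frame(cell_id = "c4", locus = "TRB", junction_aa = "CASSZF"),
    paired_chains("c5", "CACF", "CASSCF")
  )
  tab <- call_clonotypes(rec)
  rep <- attr(tab, "report")
  expect_identical(rep$n_removed_unpaired, 1L)     # c3: TRA only
  expect_identical(rep$n_removed_multichain, 1L)   # c4: two TRB chains
  expect_identical(sort(tab$cell_id), c("c1", "c2", "c5"))
  # identical TRA+TRB -> same clone, size 2
  expect_identical(tab$clone_id[tab$cell_id == "c1"],
                   tab$clone_id[tab$cell_id == "c2"])
  expect_identical(tab$clone_size[tab$cell_id == "c1"], 2L)
  expect_identical(tab$clone_size[tab$cell_id == "c5"], 1L)
  expect_error(call_clonotypes(rbind(rec, rec[1, ])), "duplicate")
  expect_error(call_clonotypes(rec[, 1:2]), "junction_aa")
})

test_that("expansion statistics count cells in expanded clones", {
  tab <- clonotypes_from_assignment(
    clone_of = c(1, 1, 1, 2, 2, 3, 4, 5),
    cluster_of = rep("A", 8))
  st <- expansion_stats(tab, list(A = tab$cell_id))
  expect_identical(st$n_clones, 5L)
  expect_identical(st$n_expanded_clones, 2L)
  expect_equal(st$frac_cells_expanded, 5 / 8)   # sizes (3,2,1,1,1)
  one <- clonotypes_from_assignment(rep(1, 4), rep("A", 4))
  expect_equal(expansion_stats(one, list(A = one$cell_id))$frac_cells_expanded, 1)
  singles <- clonotypes_from_assignment(1:4, rep("A", 4))
  expect_equal(expansion_stats(singles,
                               list(A = singles$cell_id))$frac_cells_expanded, 0)
  expect_error(expansion_stats(tab, list(empty = character())), "no cells")
})

test_that("Shannon entropy and its variance match brute-force summation", {
  expect_equal(shannon_entropy(7)$H, 0)                       # single clone
  expect_equal(shannon_entropy(rep(5, 4))$H, log(4))          # uniform max
  expect_equal(shannon_entropy(c(2, 1, 1))$H,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))      # 1.0397
  expect_equal(shannon_entropy(c(2, 1, 1))$H, 1.039721, tolerance = 1e-6)
  set.seed(17)
  for (i in 1:100) {
    counts <- sample(1:50, sample(2:30, 1), replace = TRUE)
    e <- shannon_entropy(counts)
    o <- oracle_entropy(counts)
    expect_equal(e$H, o$H, tolerance = 1e-10)
    expect_equal(e$variance, o$variance, tolerance = 1e-10)
    expect_lte(e$H, log(e$n_clones) + 1e-12)
  }
  expect_error(shannon_entropy(integer()), "empty")
})

test_that("merging clones never increases entropy", {
  set.seed(23)
  for (i in 1:50) {
    counts <- sample(1:40, sample(3:20, 1), replace = TRUE)
    h0 <- shannon_entropy(counts)$H
    merged <- c(counts[1] + counts[2], counts[-(1:2)])
    expect_lte(shannon_entropy(merged)$H, h0 + 1e-12)
  }
})

test_that("Hutcheson's t-test matches an independent formula oracle", {
  r <- hutcheson_t_test(c(10, 1, 1), c(4, 4, 4))
  expect_lt(r$t, 0)                       # rep1 is less diverse
  same <- hutcheson_t_test(c(3, 2, 1), c(3, 2, 1))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  # two single-clone repertoires: both H = 0 with zero variance -> t = 0, p = 1
  degen <- hutcheson_t_test(5, 9)
  expect_identical(degen$t, 0)
  expect_identical(degen$p, 1)
  set.seed(29)
  for (i in 1:100) {
    r1 <- sample(1:60, sample(2:25, 1), replace = TRUE)
    r2 <- sample(1:60, sample(2:25, 1), replace = TRUE)
    got <- hutcheson_t_test(r1, r2)
    e1 <- oracle_entropy(r1); e2 <- oracle_entropy(r2)
    t_o <- (e1$H - e2$H) / sqrt(e1$variance + e2$variance)
    df_o <- (e1$variance + e2$variance)^2 /
      (e1$variance^2 / sum(r1) + e2$variance^2 / sum(r2))
    expect_equal(got$t, t_o, tolerance = 1e-12)
    expect_equal(got$df, df_o, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(t_o), df_o), tolerance = 1e-12)
  }
})

test_that("clone-graph weights reproduce the shared-clone worked example", {
  # A has clones c1, c2; c1 also appears in B; B has only c1
  tab <- clonotypes_from_assignment(
    clone_of = c("c1", "c1", "c2", "c1"),
    cluster_of = c("A", "B", "A", "A"))
  g <- clone_sharing_graph(tab, prune_quantile = 0)
  wAB <- g$edges$weight[g$edges$source == "A" & g$edges$target == "B"]
  wBA <- g$edges$weight[g$edges$source == "B" & g$edges$target == "A"]
  expect_equal(wAB, 50)     # 1 of A's 2 clones shared
  expect_equal(wBA, 100)    # B's single clone is shared: asymmetric
  expect_false(any(g$edges$source == g$edges$target))
})

test_that("pruning removes the lowest quantile of nonzero weights", {
  # construct clusters whose outgoing weights are exactly 10/20/30/40%
  mk_cluster <- function(cl, n_clones, n_shared) {
    clones <- paste0(cl, seq_len(n_clones))
    clones[seq_len(n_shared)] <- paste0("S", seq_len(n_shared))
    clones
  }
  clone_of <- c(mk_cluster("a", 10, 1), mk_cluster("b", 10, 2),
                mk_cluster("c", 10, 3), mk_cluster("d", 10, 4),
                paste0("S", 1:4))
  cluster_of <- c(rep(c("A", "B", "C", "D"), each = 10), rep("HUB", 4))
  tab <- clonotypes_from_assignment(clone_of, cluster_of)
  g0 <- clone_sharing_graph(tab, prune_quantile = 0)
  to_hub <- g0$edges[g0$edges$target == "HUB" & g0$edges$source != "HUB", ]
  expect_setequal(to_hub$weight, c(10, 20, 30, 40))
  g1 <- clone_sharing_graph(tab, prune_quantile = 0.25)
  to_hub1 <- g1$edges[g1$edges$target == "HUB" & g1$edges$source != "HUB", ]
  expect_setequal(to_hub1$weight, c(20, 30, 40))   # weight 10 pruned
  expect_error(clone_sharing_graph(tab, prune_quantile = 1), "prune_quantile")
})

test_that("graph weights equal the set-intersection oracle on random instances", {
  set.seed(31)
  for (i in 1:50) {
    n_cells_i <- sample(20:60, 1)
    tab <- clonotypes_from_assignment(
      clone_of = sample(1:sample(5:50, 1), n_cells_i, replace = TRUE),
      cluster_of = sample(LETTERS[1:sample(2:6, 1)], n_cells_i, replace = TRUE))
    g <- clone_sharing_graph(tab, prune_quantile = 0)
    oracle <- oracle_graph_weights(tab)
    for (k in seq_len(nrow(g$edges))) {
      key <- paste(g$edges$source[k], g$edges$target[k], sep = "->")
      expect_equal(g$edges$weight[k], oracle[[key]])
    }
    # oracle zero/absent edges are absent from the graph too
    nonzero <- names(oracle)[unlist(oracle) > 0]
    expect_setequal(paste(g$edges$source, g$edges$target, sep = "->"), nonzero)
  }
})

test_that("planted expansion yields detectably lower cytotoxic entropy", {
  detected <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    sc <- generate_sc_dataset(sim_config(seed = 300 + s, n_cells = 400))
    tab <- call_clonotypes(sc$chains,
                           cell_meta = sc$truth[, c("cell_id", "cluster",
                                                    "compartment")])
    cd8 <- tab[tab$compartment == "CD8", ]
    cyto <- cd8$cluster %in% c("CD8_GZMB", "CD8_GZMK")
    r <- hutcheson_t_test(as.integer(table(cd8$clone_id[cyto])),
                          as.integer(table(cd8$clone_id[!cyto])))
    if (r$t < 0 && r$p < 0.01) detected <- detected + 1L
  }
  expect_gte(detected, ceiling(0.9 * n_rep))
})
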