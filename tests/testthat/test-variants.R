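test_that("the worked example yields its three variants, fully annotated", {
  f <- fig1_fixture()
  g <- f$graph
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  expect_identical(nrow(v), 3L)
  expect_identical(v$u, f$expected$u)
  expect_identical(v$v, f$expected$v)
  expect_identical(v$vtype, f$expected$vtype)
  # deletion (1,4): branch point is u, alternative allele empty
  expect_identical(v$branch[1], "1")
  expect_identical(v$ref_seq[1], "GTC")
  expect_identical(v$alt_seq[1], "")
  expect_identical(c(v$pos_u[1], v$pos_v[1]), c(2L, 7L))
  # replacement (7,8): both branches hang off node 2; off-reference v
  expect_identical(v$branch[2], "2")
  expect_identical(c(v$ref_seq[2], v$alt_seq[2]), c("G", "TT"))
  expect_true(v$non_reference[2])
  # insertion (9,3): empty reference allele, alt path 11-8-10-9
  expect_identical(v$branch[3], "2")
  expect_identical(v$ref_seq[3], "")
  expect_identical(v$alt_seq[3], "GACTGA")
  expect_false(v$non_reference[3])
  expect_true(all(v$size_class == "small"))
})

test_that("branch points match the ancestor-set oracle", {
  sim <- sim_small(seed = 11)
  tree <- build_tree(sim$graph)
  v <- call_variants(sim$graph, tree)
  for (i in seq_len(nrow(v))) {
    if (v$vtype[i] == "inversion") next
    expect_identical(v$branch[i], oracle_lca(tree, v$u[i], v$v[i]))
    if (v$vtype[i] == "deletion") expect_identical(v$branch[i], v$u[i])
    if (v$vtype[i] == "duplication") expect_identical(v$branch[i], v$v[i])
  }
})

test_that("the type table covers SNP, MNP, replacement, insertion, deletion", {
  cases <- list(
    list(mid = "T",  alt = "G",  type = "SNP"),
    list(mid = "AC", alt = "GT", type = "MNP"),
    list(mid = "A",  alt = "GT", type = "replacement"),
    list(mid = "",   alt = "AC", type = "insertion"),
    list(mid = "ACGTT", alt = "", type = "deletion"))
  for (cs in cases) {
    g <- site_graph(cs$mid, cs$alt)
    v <- call_variants(g, build_tree(g))
    expect_identical(nrow(v), 1L)
    expect_identical(v$vtype, cs$type)
    expect_identical(v$ref_seq, cs$mid)
    expect_identical(v$alt_seq, cs$alt)
    expect_identical(v$size_class, "small")
  }
})

test_that("size stratification uses combined allele length with the 50 bp threshold", {
  g30 <- site_graph(strrep("A", 30), "")  # 30 bp deletion: small
  v30 <- call_variants(g30, build_tree(g30))
  expect_identical(v30$size_class, "small")
  g50 <- site_graph(strrep("A", 49), "G")  # 49 + 1 = 50: large
  v50 <- call_variants(g50, build_tree(g50))
  expect_identical(v50$size_class, "large")
})

test_that("a tandem duplication back-edge is typed duplication", {
  nodes <- c(L = "AC", D = "GTT", R = "CA")
  edges <- data.frame(a = c("L", "D", "D"), a_side = "e",
                      b = c("D", "R", "D"), b_side = "s")
  g <- bd_graph(nodes, edges,
                list(bd_walk("REF", 0, "c", c("L", "D", "R"), rep("+", 3)),
                     bd_walk("S1", 1, "c", c("L", "D", "D", "D", "R"), rep("+", 5))),
                reference = "REF")
  v <- call_variants(g, build_tree(g))
  expect_identical(v$vtype, "duplication")
  expect_identical(v$ref_seq, "")
  expect_identical(v$alt_seq, "GTT")
  # three tandem copies traverse the back-edge twice
  expect_identical(genotype_walk(g$walks[[2]], v, build_tree(g)), 2L)
})

test_that("degenerate variants (identical alleles) are excluded but counted", {
  g <- site_graph("T", "T")
  v <- call_variants(g, build_tree(g))
  expect_identical(nrow(v), 0L)
  expect_identical(attr(v, "n_degenerate"), 1L)
})

test_that("terminal edges are excluded from the catalog", {
  # a second walk ending early creates a sink-terminus edge that is non-tree
  f <- fig1_fixture()
  g <- f$graph
  g$walks[[length(g$walks) + 1L]] <-
    bd_walk("short", 1L, "toy", c("1", "2", "3"), rep("+", 3))
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  expect_identical(nrow(v), 3L)  # still only the three real variants
  expect_gte(attr(v, "n_terminal"), 1L)
})

test_that("non-reference flags are monotone with reference membership", {
  for (s in c(2, 9)) {
    sim <- simulate_pangenome(sim_config(seed = s))
    tree <- build_tree(sim$graph)
    v <- call_variants(sim$graph, tree)
    on_ref <- v$v %in% tree$ref_path
    expect_true(all(!v$non_reference[on_ref]))
    expect_true(all(v$non_reference[!on_ref]))
  }
})

test_that("a planted inversion produces exactly two inversion edges on the carrier", {
  sim <- simulate_pangenome(sim_config(seed = 5, n_snp = 3, n_small_indel = 0,
                                       n_large_deletion = 0, n_nested_insertion = 0,
                                       n_inversion = 1))
  tree <- build_tree(sim$graph)
  v <- call_variants(sim$graph, tree)
  inv <- which(v$vtype == "inversion")
  expect_length(inv, 2L)
  expect_true(all(v$size_class[inv] == "large"))
  carrier <- strsplit(sim$truth$carriers[sim$truth$type == "inversion"][1], ",")[[1]]
  gt <- genotype_table(sim$graph, tree, v)
  expect_true(all(gt$CA[inv, paste0(carrier, "#1")] == 1L))
  others <- setdiff(colnames(gt$CA), paste0(carrier, "#1"))
  expect_true(all(gt$CA[inv, others] == 0L, na.rm = TRUE))
})

test_that("repeat motifs match the brute-force period oracle", {
  # stated rule instantiations
  g <- repeat_graph("CCGAT", "ATAT", "GGCCC")
  v <- call_variants(g, build_tree(g))
  expect_identical(v$tr_motif, "AT")
  g2 <- repeat_graph("CCCCC", "ATG", "CAACC")
  v2 <- call_variants(g2, build_tree(g2))
  expect_identical(v2$tr_motif, "")
  # downstream-only match
  g3 <- repeat_graph("CCCCC", "TGTG", "TGACG")
  v3 <- call_variants(g3, build_tree(g3))
  expect_identical(v3$tr_motif, "TG")
  # randomized alleles and flanks against the oracle
  set.seed(99)
  for (i in 1:40) {
    motif <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                   collapse = "")
    allele <- strrep(motif, sample(1:4, 1))
    up <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
    dn <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
    if (sample(c(TRUE, FALSE), 1)) up <- paste0(substring(up, 1, 6 - nchar(motif)), motif)
    g <- repeat_graph(up, allele, dn)
    v <- call_variants(g, build_tree(g))
    if (nrow(v) != 1L) next  # degenerate plant (allele equals flank context)
    expect_identical(v$tr_motif, oracle_motif(allele, up, dn))
  }
})

test_that("nearly identical alleles are flagged per the 10 bp / 1-edit rule", {
  df <- data.frame(
    ref_seq = c("ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGTA", "ACGTACGTACGT"),
    alt_seq = c("ACGTACTTACGT", "CGTACGTACGT", "ACGTACGTG", "TTTTTTTTTTTT"),
    stringsAsFactors = FALSE)
  expect_identical(flag_nia(df), c(TRUE, TRUE, FALSE, FALSE))
})
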