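test_that("the worked example forms a single superbubble holding all variants", {
  f <- fig1_fixture()
  tree <- build_tree(f$graph)
  v <- call_variants(f$graph, tree)
  bb <- detect_superbubbles(f$graph, tree, v)
  expect_length(bb, 1L)
  expect_setequal(bb[[1]]$variant_idx, 1:3)
  expect_identical(bb[[1]]$entry, "1")
  expect_identical(bb[[1]]$exit, "4")
  expect_identical(bb[[1]]$n_alt_alleles, 3L)
  expect_length(attr(bb, "unassigned"), 0L)
})

test_that("a reference-only graph has no superbubbles", {
  nodes <- stats::setNames(c("AC", "G", "TT"), c("1", "2", "3"))
  edges <- data.frame(a = c("1", "2"), a_side = "e", b = c("2", "3"), b_side = "s")
  g <- bd_graph(nodes, edges, list(bd_walk("REF", 0, "c", c("1", "2", "3"),
                                           rep("+", 3))), reference = "REF")
  tree <- build_tree(g)
  bb <- detect_superbubbles(g, tree, call_variants(g, tree))
  expect_length(bb, 0L)
})

test_that("well-separated SNPs give one biallelic bubble each (a partition)", {
  sim <- simulate_pangenome(sim_config(seed = 31, reference_length = 3000,
                                       n_snp = 6, n_small_indel = 0,
                                       n_large_deletion = 0, n_inversion = 0,
                                       n_nested_insertion = 0))
  tree <- build_tree(sim$graph)
  v <- call_variants(sim$graph, tree)
  bb <- detect_superbubbles(sim$graph, tree, v)
  expect_length(bb, 6L)
  expect_true(all(vapply(bb, function(b) length(b$variant_idx), 1L) == 1L))
  expect_true(all(vapply(bb, function(b) b$n_alt_alleles, 1L) == 1L))
  # every variant in exactly one bubble
  assigned <- unlist(lapply(bb, `[[`, "variant_idx"))
  expect_identical(sort(assigned), seq_len(nrow(v)))
  expect_length(attr(bb, "unassigned"), 0L)
})

test_that("the four triallelic structures are labelled per the degree and branch-point rules", {
  fx <- triallelic_fixtures()
  for (expected in names(fx)) {
    g <- fx[[expected]]
    tree <- build_tree(g)
    v <- call_variants(g, tree)
    expect_identical(nrow(v), 2L, label = expected)
    bb <- detect_superbubbles(g, tree, v)
    expect_length(bb, 1L)
    expect_identical(classify_triallelic(bb[[1]], tree, v), expected)
  }
  # guard: the rule is undefined off the two-variant case
  f <- fig1_fixture()
  tree <- build_tree(f$graph)
  v <- call_variants(f$graph, tree)
  bb <- detect_superbubbles(f$graph, tree, v)
  expect_error(classify_triallelic(bb[[1]], tree, v), "exactly 2")
})

test_that("insertion/deletion superbubble classes follow entry-exit adjacency", {
  fx <- triallelic_fixtures()
  cases <- list(nested = "insertion",      # entry-exit tree edge
                overlapping = "deletion",  # entry-exit variant edge
                properly_triallelic = "neither")
  for (nm in names(cases)) {
    g <- fx[[nm]]
    tree <- build_tree(g)
    v <- call_variants(g, tree)
    bb <- detect_superbubbles(g, tree, v)
    expect_identical(classify_indel_superbubble(bb[[1]], tree), cases[[nm]])
  }
  # a simulated replacement bubble is neither
  g <- site_graph("A", "GT")
  tree <- build_tree(g)
  bb <- detect_superbubbles(g, tree, call_variants(g, tree))
  expect_identical(classify_indel_superbubble(bb[[1]], tree), "neither")
})

test_that("allele counts match walk-subpath enumeration and imply multi-edge bubbles", {
  # five-allele site: four alternate branches over one reference base
  fwd <- function(n) rep("+", n)
  alts <- c(y1 = "G", y2 = "C", y3 = "AA", y4 = "CT")
  nodes <- c(A = "AC", x = "T", B = "GA", alts)
  edges <- rbind(
    data.frame(a = c("A", "x"), a_side = "e", b = c("x", "B"), b_side = "s"),
    do.call(rbind, lapply(names(alts), function(y)
      data.frame(a = c("A", y), a_side = "e", b = c(y, "B"), b_side = "s"))))
  walks <- c(list(bd_walk("REF", 0, "c", c("A", "x", "B"), fwd(3))),
             lapply(seq_along(alts), function(i)
               bd_walk(paste0("S", i), 1, "c", c("A", names(alts)[i], "B"), fwd(3))))
  g <- bd_graph(nodes, edges, walks, reference = "REF")
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  bb <- detect_superbubbles(g, tree, v)
  expect_length(bb, 1L)
  expect_identical(bb[[1]]$n_alt_alleles, 4L)
  expect_identical(length(bb[[1]]$variant_idx), 4L)
  summ <- bubble_summary(bb, tree, v)
  expect_identical(summ$n_variant_edges, 4L)
  # multiallelic implication holds across simulations
  for (s in c(4, 8)) {
    sim <- simulate_pangenome(sim_config(seed = s))
    tr <- build_tree(sim$graph)
    vv <- call_variants(sim$graph, tr)
    bs <- detect_superbubbles(sim$graph, tr, vv)
    sm <- bubble_summary(bs, tr, vv)
    expect_true(all(sm$n_variant_edges[sm$n_alt_alleles > 1] > 1))
    # non-reference variants only in multi-variant bubbles
    expect_true(all(sm$n_variant_edges[sm$n_non_reference > 0] >= 2))
  }
})
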