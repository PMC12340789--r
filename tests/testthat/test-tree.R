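test_that("the worked-example tree has exactly the three expected non-tree edges", {
  f <- fig1_fixture()
  tree <- build_tree(f$graph)
  nt <- tree$nontree[!tree$nontree$is_term, ]
  expect_identical(nrow(nt), 3L)
  expect_setequal(nt$key, pangtree:::edge_key(c("1", "7", "9"), "e",
                                              c("4", "8", "3"), "s"))
  # reference walk edges are all tree edges
  refw <- f$graph$walks[[1]]
  expect_true(all(pangtree:::walk_edge_keys(refw) %in% tree$tree_keys))
})

test_that("a linear reference-only graph yields no variant candidates", {
  nodes <- stats::setNames(c("AC", "G", "TT"), c("1", "2", "3"))
  edges <- data.frame(a = c("1", "2"), a_side = "e", b = c("2", "3"), b_side = "s")
  g <- bd_graph(nodes, edges, list(bd_walk("REF", 0, "c", c("1", "2", "3"),
                                           rep("+", 3))), reference = "REF")
  tree <- build_tree(g)
  expect_identical(nrow(tree$nontree[!tree$nontree$is_term, ]), 0L)
  expect_identical(unname(tree$position[c("1", "2", "3")]), c(2L, 3L, 5L))
})

test_that("non-terminal variant-edge count equals |E| - (|V| - 1) and is tie-break invariant", {
  for (s in 1:12) {
    sim <- sim_small(seed = s)
    g <- sim$graph
    count_variants <- function(graph) {
      tr <- build_tree(graph)
      v <- call_variants(graph, tr)
      nrow(v) + attr(v, "n_degenerate")
    }
    expected <- nrow(g$edges) - (length(g$nodes) - 1L)
    expect_identical(count_variants(g), expected)
    # shuffled edge insertion order must not change the count
    set.seed(1000 + s)
    g2 <- g
    g2$edges <- g2$edges[sample(nrow(g2$edges)), ]
    rownames(g2$edges) <- NULL
    expect_identical(count_variants(g2), expected)
  }
})

test_that("lca agrees with the brute-force ancestor-set oracle", {
  sim <- sim_small(seed = 7)
  tree <- build_tree(sim$graph)
  ids <- names(sim$graph$nodes)
  set.seed(7)
  for (i in 1:60) {
    a <- sample(ids, 1); b <- sample(ids, 1)
    expect_identical(tree_lca(tree, a, b), oracle_lca(tree, a, b))
  }
  expect_identical(tree_lca(tree, ids[5], ids[5]), ids[5])
  root_child <- tree$ref_path[1]
  expect_identical(tree_lca(tree, root_child, ids[10]), root_child)
  expect_error(tree_lca(tree, "nope", ids[1]), "unknown node")
})

test_that("node positions follow the deepest reference ancestor", {
  sim <- sim_small(seed = 3)
  g <- sim$graph
  tree <- build_tree(g)
  # reference nodes: cumulative end coordinates
  lens <- nchar(g$nodes[tree$ref_path])
  expect_identical(unname(tree$position[tree$ref_path]), unname(cumsum(lens)))
  # off-reference nodes: walk up the parent chain to the first reference node
  off <- setdiff(names(g$nodes), tree$ref_path)
  for (u in off) {
    x <- u
    while (!(x %in% tree$ref_path) && !is.na(tree$parent[[x]])) x <- tree$parent[[x]]
    expected <- if (x %in% tree$ref_path) tree$ref_end[[x]] else -1
    expect_identical(node_position(tree, u), as.integer(expected))
  }
})

test_that("orientation is forced by edge sides along the tree path", {
  f <- fig1_fixture()
  tree <- build_tree(f$graph)
  expect_true(all(tree$orientation[tree$ref_path] == "+"))
  # a node attachable only through a side-flipping edge is oriented reverse
  nodes <- c(A = "ACG", B = "TTT", C = "GGA")
  edges <- data.frame(a = c("A", "A", "C"), a_side = c("e", "e", "s"),
                      b = c("B", "C", "B"), b_side = c("s", "e", "s"))
  g <- bd_graph(nodes, edges,
                list(bd_walk("REF", 0, "c", c("A", "B"), c("+", "+")),
                     bd_walk("S1", 1, "c", c("A", "C", "B"), c("+", "-", "+"))),
                reference = "REF")
  tree <- build_tree(g)
  expect_identical(node_orientation(tree, "C"), "-")
  expect_identical(node_orientation(tree, "A"), "+")
})

test_that("disconnected components are anchored with position -1", {
  nodes <- c("1" = "AC", "2" = "G", x = "TT", y = "AA")
  edges <- data.frame(a = c("1", "x"), a_side = "e", b = c("2", "y"), b_side = "s")
  g <- bd_graph(nodes, edges,
                list(bd_walk("REF", 0, "c", c("1", "2"), c("+", "+")),
                     bd_walk("S1", 1, "c", c("x", "y"), c("+", "+"))),
                reference = "REF")
  tree <- build_tree(g)
  expect_true(all(c("x", "y") %in% names(tree$parent)[!is.na(tree$depth)]))
  expect_identical(node_position(tree, "x"), -1L)
  expect_identical(node_position(tree, "y"), -1L)
  # spanning: every node reaches the root through parent pointers
  for (u in names(g$nodes)) {
    x <- u; steps <- 0L
    while (!is.na(tree$parent[[x]])) { x <- tree$parent[[x]]; steps <- steps + 1L }
    expect_identical(x, tree$terminus[1])
  }
})

test_that("cyclic reference walks are rejected", {
  nodes <- c("1" = "AC", "2" = "G")
  edges <- data.frame(a = c("1", "2"), a_side = "e", b = c("2", "1"), b_side = "s")
  g <- bd_graph(nodes, edges,
                list(bd_walk("REF", 0, "c", c("1", "2", "1"), rep("+", 3))),
                reference = "REF")
  expect_error(build_tree(g), "revisits")
})
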