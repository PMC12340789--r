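test_that("the green walk has genotype [0,1,1] and the reference is all-zero", {
  f <- fig1_fixture()
  g <- f$graph
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  expect_identical(genotype_walk(g$walks[[2]], v, tree), f$green_genotype)
  expect_identical(genotype_walk(g$walks[[1]], v, tree), c(0L, 0L, 0L))
  expect_error(genotype_walk(bd_walk("x", 1, "c", "zz", "+"), v, tree),
               "unknown")
})

test_that("reference-edge counts follow the last edge of the reference path", {
  f <- fig1_fixture()
  g <- f$graph
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  green <- g$walks[[2]]
  # at (1,4) the green walk enters node 4 through tree edge (3,4): CR=1, CA=0
  expect_identical(reference_edge_count(green, v[1, ], tree), 1L)
  expect_identical(genotype_walk(green, v, tree)[1], 0L)
  # at (7,8) green takes the variant edge, not tree edge (11,8)
  expect_identical(reference_edge_count(green, v[2, ], tree), 0L)
  # homozygous-alt carrier of a planted SNP: CR=0, CA=1
  sim <- sim_small(seed = 21)
  tr <- build_tree(sim$graph)
  vv <- call_variants(sim$graph, tr)
  gt <- genotype_table(sim$graph, tr, vv)
  snp <- which(vv$vtype == "SNP")[1]
  tpos <- tr$position[vv$branch[snp]]
  carriers <- strsplit(sim$truth$carriers[sim$truth$pos == tpos &
                                            sim$truth$type == "SNP"], ",")[[1]]
  hid <- paste0(carriers[1], "#1")
  expect_identical(unname(gt$CA[snp, hid]), 1L)
  expect_identical(unname(gt$CR[snp, hid]), 0L)
  expect_identical(unname(gt$GT[snp, hid]), "1")
})

test_that("missingness is decided by position-interval overlap", {
  cov <- list(intervals = matrix(c(1, 50), ncol = 2), components = 1L)
  far <- list(pos_u = 100L, pos_v = 120L)
  expect_true(variant_missing(far, cov))
  cov2 <- list(intervals = matrix(c(110, 200), ncol = 2), components = 1L)
  expect_false(variant_missing(far, cov2))
  # unanchored variants fall back to component membership
  un <- list(pos_u = -1L, pos_v = -1L)
  expect_false(variant_missing(un, cov, component = 1L))
  expect_true(variant_missing(un, cov, component = 2L))
})

test_that("fragmented assemblies produce the missing pattern derived from node positions", {
  sim <- simulate_pangenome(sim_config(seed = 13, fragments_per_haplotype = 4))
  g <- sim$graph
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  gt <- genotype_table(g, tree, v)
  # oracle: recompute each haplotype's covered intervals directly from the
  # positions of every node its walks visit
  for (h in gt$haplotypes) {
    idx <- which(vapply(g$walks, walk_hap_id, "") == h)
    ivs <- do.call(rbind, lapply(idx, function(i) {
      w <- g$walks[[i]]
      pos <- tree$position[w$nodes]
      pos <- pos[pos >= 0]
      starts <- tree$ref_start[intersect(w$nodes, tree$ref_path)]
      if (length(pos) == 0L) return(NULL)
      c(min(c(pos, starts)), max(pos))
    }))
    for (i in seq_len(nrow(v))) {
      lo <- min(v$pos_u[i], v$pos_v[i]); hi <- max(v$pos_u[i], v$pos_v[i])
      expect_miss <- !any(ivs[, 1] <= hi & ivs[, 2] >= lo)
      expect_identical(unname(is.na(gt$CA[i, h])), expect_miss,
                       label = paste("hap", h, "variant", i))
    }
  }
  # GT missing iff both counts missing; otherwise 0/1 by CA
  expect_identical(gt$GT == ".", is.na(gt$CA) & is.na(gt$CR))
  expect_identical(unname(gt$GT[!is.na(gt$CA) & gt$CA > 0]),
                   rep("1", sum(gt$CA > 0, na.rm = TRUE)))
})

test_that("AN conservation: missing counts as zero", {
  sim <- simulate_pangenome(sim_config(seed = 17, fragments_per_haplotype = 3))
  tree <- build_tree(sim$graph)
  v <- call_variants(sim$graph, tree)
  gt <- genotype_table(sim$graph, tree, v)
  summed <- rowSums(gt$CR, na.rm = TRUE) + rowSums(gt$CA, na.rm = TRUE)
  expect_identical(as.integer(summed), gt$AN)
  expect_identical(gt$AN, gt$RC + gt$AC)
})

test_that("walks are reconstructible from their genotypes", {
  f <- fig1_fixture()
  g <- f$graph
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  # zero genotype: the unique tree path
  w0 <- reconstruct_walk(c(0L, 0L, 0L), "1", "6", tree, v)
  expect_identical(w0$nodes, as.character(1:6))
  # the green walk's genotype reproduces the green walk
  wg <- reconstruct_walk(c(0L, 1L, 1L), "1", "6", tree, v)
  expect_identical(wg$nodes, g$walks[[2]]$nodes)
  expect_identical(genotype_walk(wg, v, tree), c(0L, 1L, 1L))
  # infeasible: the replacement cannot be reached from node 4
  expect_error(reconstruct_walk(c(0L, 1L, 1L), "4", "6", tree, v), "no walk")
  # repeated visits are out of scope and error rather than guess
  expect_error(reconstruct_walk(c(2L, 0L, 0L), "1", "6", tree, v), "ambiguous")
})

test_that("equal endpoints and equal genotype imply the identical walk", {
  f <- fig1_fixture()
  g <- f$graph
  tree <- build_tree(g)
  v <- call_variants(g, tree)
  walks <- enumerate_walks(g, "1", "6")
  expect_gt(length(walks), 3)
  sig <- vapply(walks, function(w)
    paste(genotype_walk(bd_walk("e", 1, "c", w$nodes, w$orients), v, tree),
          collapse = ","), "")
  full <- vapply(walks, function(w) paste(w$orients, w$nodes, collapse = " "), "")
  split_by <- split(full, sig)
  for (grp in split_by) expect_identical(length(unique(grp)), 1L)
})
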