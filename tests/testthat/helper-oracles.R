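# Shared fixtures and independent oracles used across the test files.

# brute-force LCA: intersect full ancestor chains, take the deepest
oracle_lca <- function(tree, a, b) {
  chain <- function(x) {
    out <- character(0)
    while (!is.na(x)) { out <- c(out, x); x <- tree$parent[[x]] }
    out
  }
  common <- intersect(chain(a), chain(b))
  common[which.max(tree$depth[common])]
}

# structural equality of two graphs (node ids/sequences, canonical edges,
# walks up to list order)
graphs_equal <- function(g1, g2) {
  walk_sig <- function(w)
    paste(w$sample, w$hap, paste0(w$orients, w$nodes, collapse = ""))
  identical(g1$nodes[sort(names(g1$nodes))], g2$nodes[sort(names(g2$nodes))]) &&
    setequal(g1$edges$key, g2$edges$key) &&
    setequal(vapply(g1$walks, walk_sig, ""), vapply(g2$walks, walk_sig, ""))
}

# enumerate every walk between two oriented endpoints, traversing each
# directed edge at most once (termination bound); returns list of walks
enumerate_walks <- function(graph, start, end, max_len = 30L) {
  sides <- list()
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    k1 <- paste0(e$a, ":", e$a_side)
    k2 <- paste0(e$b, ":", e$b_side)
    sides[[k1]] <- rbind(sides[[k1]], data.frame(n = e$b, s = e$b_side, i = i))
    if (k2 != k1)
      sides[[k2]] <- rbind(sides[[k2]], data.frame(n = e$a, s = e$a_side, i = i))
  }
  out <- list()
  rec <- function(node, orient, used, nodes, orients) {
    if (node == end && orient == "+" && length(nodes) > 1L) {
      out[[length(out) + 1L]] <<- list(nodes = nodes, orients = orients)
      # a walk may also continue through the end node, so do not return
    }
    if (length(nodes) >= max_len) return()
    nb <- sides[[paste0(node, ":", ifelse(orient == "+", "e", "s"))]]
    if (is.null(nb)) return()
    for (j in seq_len(nrow(nb))) {
      ek <- paste0(nb$i[j], ">", node, nb$n[j])  # directed use of edge i
      if (ek %in% used) next
      rec(nb$n[j], ifelse(nb$s[j] == "s", "+", "-"), c(used, ek),
          c(nodes, nb$n[j]), c(orients, ifelse(nb$s[j] == "s", "+", "-")))
    }
  }
  rec(start, "+", character(0), start, "+")
  out
}

# three-node reference with one alternate bubble: ref L -> M -> R (M may be
# empty -> direct L-R edge), alt branch L -> A -> R (A empty -> direct edge);
# extra walks can force tree choices
site_graph <- function(mid, alt, n_alt_carriers = 1L) {
  nodes <- c(L = "ACGT", R = "TTGA")
  edges <- list()
  ref_steps <- "L"
  if (nzchar(mid)) {
    nodes <- c(nodes, M = mid)
    edges <- c(edges, list(c("L", "e", "M", "s"), c("M", "e", "R", "s")))
    ref_steps <- c(ref_steps, "M")
  } else {
    edges <- c(edges, list(c("L", "e", "R", "s")))
  }
  ref_steps <- c(ref_steps, "R")
  alt_steps <- "L"
  if (nzchar(alt)) {
    nodes <- c(nodes, A = alt)
    edges <- c(edges, list(c("L", "e", "A", "s"), c("A", "e", "R", "s")))
    alt_steps <- c(alt_steps, "A")
  } else {
    edges <- c(edges, list(c("L", "e", "R", "s")))
  }
  alt_steps <- c(alt_steps, "R")
  edf <- do.call(rbind, lapply(edges, function(x)
    data.frame(a = x[1], a_side = x[2], b = x[3], b_side = x[4],
               stringsAsFactors = FALSE)))
  walks <- c(list(bd_walk("REF", 0L, "c", ref_steps, rep("+", length(ref_steps)))),
             lapply(seq_len(n_alt_carriers), function(i)
               bd_walk(paste0("S", i), 1L, "c", alt_steps,
                       rep("+", length(alt_steps)))))
  bd_graph(nodes, edf, walks, reference = "REF", contig = "c")
}

# repeat-annotation fixture: reference P -> S with an insertion branch
# P -> I -> S; the insertion's upstream flank is the tail of P and its
# downstream flank starts at S
repeat_graph <- function(prefix, ins, suffix) {
  nodes <- c(P = prefix, S = suffix, I = ins)
  edges <- data.frame(
    a = c("P", "P", "I"), a_side = rep("e", 3),
    b = c("S", "I", "S"), b_side = rep("s", 3),
    stringsAsFactors = FALSE)
  walks <- list(
    bd_walk("REF", 0L, "c", c("P", "S"), c("+", "+")),
    bd_walk("S1", 1L, "c", c("P", "I", "S"), rep("+", 3)))
  bd_graph(nodes, edges, walks, reference = "REF", contig = "c")
}

# brute-force repeat-motif oracle on known flank strings
oracle_motif <- function(allele, upstream, downstream) {
  n <- nchar(allele)
  if (n == 0L) return("")
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    s <- substring(allele, 1L, p)
    if (strrep(s, n %/% p) != allele) next
    up <- if (nchar(upstream) >= p)
      substring(upstream, nchar(upstream) - p + 1L) else NA
    dn <- if (nchar(downstream) >= p) substring(downstream, 1L, p) else NA
    if ((!is.na(up) && up == s) || (!is.na(dn) && dn == s)) return(s)
  }
  ""
}

# walk concatenation in traversal orientation
walk_seq <- function(graph, w)
  paste(ifelse(w$orients == "+", graph$nodes[w$nodes],
               revcomp(graph$nodes[w$nodes])), collapse = "")

sim_small <- function(seed, ...) {
  simulate_pangenome(sim_config(reference_length = 600, n_haplotypes = 3,
                                n_snp = 4, n_small_indel = 2,
                                n_large_deletion = 1, n_inversion = 0,
                                n_nested_insertion = 0, seed = seed, ...))
}

# hand-built bubble fixtures instantiating the four triallelic structures
triallelic_fixtures <- function() {
  fwd <- function(n) rep("+", n)
  properly <- bd_graph(
    c(A = "AC", x = "T", B = "GA", y = "G", z = "C"),
    data.frame(a = c("A", "x", "A", "y", "A", "z"), a_side = "e",
               b = c("x", "B", "y", "B", "z", "B"), b_side = "s"),
    list(bd_walk("REF", 0, "c", c("A", "x", "B"), fwd(3)),
         bd_walk("S1", 1, "c", c("A", "y", "B"), fwd(3)),
         bd_walk("S2", 1, "c", c("A", "z", "B"), fwd(3))),
    reference = "REF")
  overlapping <- bd_graph(
    c(A = "AC", m1 = "T", m2 = "GG", B = "CA"),
    data.frame(a = c("A", "m1", "m2", "A", "A"), a_side = "e",
               b = c("m1", "m2", "B", "m2", "B"), b_side = "s"),
    list(bd_walk("REF", 0, "c", c("A", "m1", "m2", "B"), fwd(4)),
         bd_walk("S1", 1, "c", c("A", "m2", "B"), fwd(3)),
         bd_walk("S2", 1, "c", c("A", "B"), fwd(2))),
    reference = "REF")
  nested <- bd_graph(
    c(A = "AC", B = "GT", c1 = "TTG", c2 = "A", c2s = "C", c3 = "GAT"),
    data.frame(a = c("A", "A", "c1", "c1", "c2", "c2s", "c3"), a_side = "e",
               b = c("B", "c1", "c2", "c2s", "c3", "c3", "B"), b_side = "s"),
    list(bd_walk("REF", 0, "c", c("A", "B"), fwd(2)),
         bd_walk("S1", 1, "c", c("A", "c1", "c2", "c3", "B"), fwd(5)),
         bd_walk("S2", 1, "c", c("A", "c1", "c2", "c3", "B"), fwd(5)),
         bd_walk("S3", 1, "c", c("A", "c1", "c2s", "c3", "B"), fwd(5))),
    reference = "REF")
  interlocking <- bd_graph(
    c(A = "AC", r1 = "T", r2 = "GG", r3 = "A", B = "CA"),
    data.frame(a = c("A", "r1", "r2", "r3", "A", "r1"), a_side = "e",
               b = c("r1", "r2", "r3", "B", "r2", "B"), b_side = "s"),
    list(bd_walk("REF", 0, "c", c("A", "r1", "r2", "r3", "B"), fwd(5)),
         bd_walk("S1", 1, "c", c("A", "r2", "r3", "B"), fwd(4)),
         bd_walk("S2", 1, "c", c("A", "r1", "B"), fwd(3))),
    reference = "REF")
  list(properly_triallelic = properly, overlapping = overlapping,
       nested = nested, interlocking = interlocking)
}
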