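# Variant edges: every graph edge absent from the reference tree is a
# biallelic variant. For a non-inversion edge read as (u, v), the branch
# point is the lowest common ancestor of u and v in the tree; the reference
# allele is the tree path branch->v excluding both ends, and the alternative
# allele is the tree path branch->u excluding the branch point but including
# u. Sequences are read in tree orientation. Edges whose branch point or v
# is a terminus node are "terminal" (they track walk starts/ends, not
# biology) and are excluded, as are degenerate variants whose two alleles
# are identical.

# sequence of a tree-path node list, read in tree orientation
path_seq <- function(graph, tree, nodes) {
  if (length(nodes) == 0L) return("")
  seqs <- graph$nodes[nodes]
  seqs[is.na(seqs)] <- ""  # terminus nodes carry empty sequences
  o <- tree$orientation[nodes]
  flip <- which(o == "-")
  if (length(flip)) seqs[flip] <- revcomp(seqs[flip])
  paste(seqs, collapse = "")
}

#' Branch point of a non-inversion variant edge
#'
#' @param tree a `reference_tree`.
#' @param u,v the edge's nodes in directed (walk-traversal) reading.
#' @return node id of the lowest common ancestor of `u` and `v`.
#' @export
branch_point <- function(tree, u, v) tree_lca(tree, u, v)

# choose the directed reading (u, v) of a non-tree edge.
# Prefer the direction actually traversed by walks; with no traversals,
# prefer the direction in which both node traversals agree with the tree
# orientation; final tie-break is the smaller numeric u.
read_direction <- function(edge_row, tree, dir_counts) {
  a <- edge_row$a; as <- edge_row$a_side
  b <- edge_row$b; bs <- edge_row$b_side
  k1 <- dir_key(a, as, b, bs)  # u = a: leaves a via a_side, enters b via b_side
  k2 <- dir_key(b, bs, a, as)
  c1 <- if (k1 %in% names(dir_counts)) dir_counts[[k1]] else 0L
  c2 <- if (k2 %in% names(dir_counts)) dir_counts[[k2]] else 0L
  pick_a_first <- if (c1 != c2) c1 > c2 else {
    # tree-consistent reading: leaving u matches orient(u), entering v matches orient(v)
    cons1 <- as == exit_side(tree$orientation[[a]]) &&
      bs == entry_side(tree$orientation[[b]])
    cons2 <- bs == exit_side(tree$orientation[[b]]) &&
      as == entry_side(tree$orientation[[a]])
    if (cons1 != cons2) cons1 else node_num(a) <= node_num(b)
  }
  if (pick_a_first)
    list(u = a, u_side = as, v = b, v_side = bs, count = c1, both = c1 > 0 && c2 > 0)
  else
    list(u = b, u_side = bs, v = a, v_side = as, count = c2, both = c1 > 0 && c2 > 0)
}

#' Allele sequences of a non-inversion variant edge
#'
#' @param graph a `bdgraph`.
#' @param tree its `reference_tree`.
#' @param u,v the edge in directed reading (`u` carries the alternative path).
#' @return list with `ref_seq`, `alt_seq`, `ref_path`, `alt_path`,
#'   `branch` (node id).
#' @export
variant_alleles <- function(graph, tree, u, v) {
  bp <- branch_point(tree, u, v)
  ref_path <- if (bp == v) character(0) else {
    p <- path_down(tree, bp, v)
    p[-c(1L, length(p))]
  }
  alt_path <- if (bp == u) character(0) else path_down(tree, bp, u)[-1L]
  if (u == v && bp == u) alt_path <- u  # self-loop duplication repeats u itself
  list(ref_seq = path_seq(graph, tree, ref_path),
       alt_seq = path_seq(graph, tree, alt_path),
       ref_path = ref_path, alt_path = alt_path, branch = bp)
}

#' Classify a variant edge
#'
#' Inversions connect two nodes whose traversal flips relative to the tree
#' orientation at exactly one end. Among same-orientation edges: an edge
#' from a tree ancestor forward to a descendant is a deletion; from a
#' descendant back to an ancestor, a duplication; a crossing edge with an
#' empty reference allele is an insertion; equal-length crossing alleles
#' give a SNP (length 1) or MNP; anything else is a replacement.
#'
#' @param vr a single-variant row (list/one-row data frame) with fields
#'   `inversion`, `u`, `v`, `ref_seq`, `alt_seq` and the tree.
#' @param tree a `reference_tree`.
#' @return one of `"SNP"`, `"MNP"`, `"insertion"`, `"deletion"`,
#'   `"replacement"`, `"duplication"`, `"inversion"`.
#' @export
classify_variant <- function(vr, tree) {
  if (isTRUE(vr$inversion)) return("inversion")
  u <- vr$u; v <- vr$v
  if (u != v && is_ancestor(tree, u, v)) return("deletion")
  if (u == v || is_ancestor(tree, v, u)) return("duplication")
  if (nchar(vr$ref_seq) == 0L) return("insertion")
  if (nchar(vr$ref_seq) == nchar(vr$alt_seq)) {
    if (nchar(vr$ref_seq) == 1L) return("SNP") else return("MNP")
  }
  "replacement"
}

# does the directed reading flip either node relative to its tree orientation?
reading_flips <- function(tree, rd) {
  flip_u <- orient_exiting(rd$u_side) != tree$orientation[[rd$u]]
  flip_v <- orient_entering(rd$v_side) != tree$orientation[[rd$v]]
  c(flip_u, flip_v)
}

#' Call variants from the non-tree edges of a reference tree
#'
#' One variant per non-tree edge, excluding terminal edges (branch point or
#' `v` is a terminus) and degenerate variants (identical alleles). Inversion
#' edges are reported individually, with empty allele fields, and are never
#' forcibly paired.
#'
#' @param graph a `bdgraph`.
#' @param tree the `reference_tree` built on `graph`.
#' @return data frame of class `variant_table`; attributes `n_degenerate`
#'   and `n_terminal` record the excluded edge counts.
#' @export
call_variants <- function(graph, tree) {
  if (!identical(sort(setdiff(names(tree$parent), tree$terminus)),
                 sort(names(graph$nodes))))
    stop("tree and graph do not describe the same node set")
  dk <- unlist(lapply(graph$walks, walk_dir_keys))
  dir_counts <- as.list(table(dk))
  refw_idx <- which(vapply(graph$walks, `[[`, "", "sample") == graph$reference)
  ref_nodes <- unique(unlist(lapply(graph$walks[refw_idx], `[[`, "nodes")))

  nt <- tree$nontree
  n_term <- 0L; n_degen <- 0L
  rows <- vector("list", nrow(nt))
  for (i in seq_len(nrow(nt))) {
    rd <- read_direction(nt[i, ], tree, dir_counts)
    u <- rd$u; v <- rd$v
    if (u %in% tree$terminus || v %in% tree$terminus) { n_term <- n_term + 1L; next }
    flips <- reading_flips(tree, rd)
    inv <- flips[1L] != flips[2L]
    if (inv) {
      vr <- list(u = u, v = v, u_side = rd$u_side, v_side = rd$v_side,
                 inversion = TRUE, branch = NA_character_,
                 ref_seq = "", alt_seq = "",
                 ref_path = character(0), alt_path = character(0))
    } else {
      bp <- branch_point(tree, u, v)
      if (bp %in% tree$terminus) { n_term <- n_term + 1L; next }
      al <- variant_alleles(graph, tree, u, v)
      if (al$ref_seq == al$alt_seq) { n_degen <- n_degen + 1L; next }
      vr <- c(list(u = u, v = v, u_side = rd$u_side, v_side = rd$v_side,
                   inversion = FALSE), al)
    }
    vtype <- classify_variant(vr, tree)
    comb <- nchar(vr$ref_seq) + nchar(vr$alt_seq)
    rows[[i]] <- data.frame(
      key = nt$key[i], u = u, v = v,
      u_side = rd$u_side, v_side = rd$v_side,
      u_or = orient_exiting(rd$u_side), v_or = orient_entering(rd$v_side),
      branch = if (is.null(vr$branch) || is.na(vr$branch)) NA_character_ else vr$branch,
      ref_seq = vr$ref_seq, alt_seq = vr$alt_seq,
      vtype = vtype,
      size_class = if (vtype == "inversion") "large" else
        ifelse(comb >= 50L, "large", "small"),
      pos_u = tree$position[[u]], pos_v = tree$position[[v]],
      non_reference = !(v %in% ref_nodes),
      both_directions = rd$both,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(key = character(), u = character(), v = character(),
                      u_side = character(), v_side = character(),
                      u_or = character(), v_or = character(),
                      branch = character(), ref_seq = character(),
                      alt_seq = character(), vtype = character(),
                      size_class = character(), pos_u = integer(),
                      pos_v = integer(), non_reference = logical(),
                      both_directions = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # deterministic output order: by position then node ids
  out <- out[order(pmin(out$pos_u, out$pos_v), pmax(out$pos_u, out$pos_v),
                   node_num(out$u), node_num(out$v)), , drop = FALSE]
  rownames(out) <- NULL
  out$tr_motif <- vapply(seq_len(nrow(out)), function(i)
    annotate_repeat(out[i, ], graph, tree), "")
  out$nia <- flag_nia(out)
  class(out) <- c("variant_table", "data.frame")
  attr(out, "n_degenerate") <- n_degen
  attr(out, "n_terminal") <- n_term
  out
}

# upstream tree sequence ending at the last base of `node` (inclusive),
# of length at least `len`; NA when the tree runs out
upstream_seq <- function(graph, tree, node, len) {
  out <- ""
  nd <- node
  while (nchar(out) < len && !is.na(nd)) {
    if (!(nd %in% tree$terminus)) {
      s <- graph$nodes[[nd]]
      if (tree$orientation[[nd]] == "-") s <- revcomp(s)
      out <- paste0(s, out)
    }
    nd <- tree$parent[[nd]]
  }
  if (nchar(out) < len) return(NA_character_)
  substring(out, nchar(out) - len + 1L)
}

# downstream tree sequence starting at the first base of `node`, extended
# through single deterministic tree children when needed
downstream_seq <- function(graph, tree, node, len) {
  out <- ""
  nd <- node
  repeat {
    if (is.na(nd) || nd %in% tree$terminus) break
    s <- graph$nodes[[nd]]
    if (tree$orientation[[nd]] == "-") s <- revcomp(s)
    out <- paste0(out, s)
    if (nchar(out) >= len) break
    kids <- names(tree$parent)[!is.na(tree$parent) & tree$parent == nd]
    kids <- setdiff(kids, tree$terminus)
    if (length(kids) == 0L) break
    on_ref <- kids[kids %in% tree$ref_path]
    nd <- if (length(on_ref)) on_ref[1L] else kids[node_order_key(kids)[1L]]
  }
  if (nchar(out) < len) return(NA_character_)
  substring(out, 1L, len)
}

#' Tandem-repeat motif annotation of an indel
#'
#' An insertion or deletion is a local tandem-repeat change when its
#' non-empty allele equals a motif `s` repeated `n >= 1` times and the
#' adjacent tree sequence (the `|s|` bases immediately upstream of the
#' branch point, or immediately downstream starting at `v`) also equals
#' `s`. The shortest qualifying period is reported.
#'
#' @param variant one row of a [call_variants()] table.
#' @param graph,tree the graph and its reference tree.
#' @return the motif string, or `""` when the indel is not a repeat change.
#' @export
annotate_repeat <- function(variant, graph, tree) {
  if (!(variant$vtype %in% c("insertion", "deletion"))) return("")
  allele <- if (variant$vtype == "insertion") variant$alt_seq else variant$ref_seq
  n <- nchar(allele)
  if (n == 0L) return("")
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    s <- substring(allele, 1L, p)
    if (strrep(s, n %/% p) != allele) next
    up <- upstream_seq(graph, tree, variant$branch, p)
    if (!is.na(up) && up == s) return(s)
    dn <- downstream_seq(graph, tree, variant$v, p)
    if (!is.na(dn) && dn == s) return(s)
  }
  ""
}

#' Flag nearly identical alleles
#'
#' Allele pairs in which both alleles are at least 10 bp long and differ by
#' exactly one base (a substitution or a 1-bp indel) are flagged but kept.
#'
#' @param variants a [call_variants()] table.
#' @return logical vector, one entry per variant.
#' @export
flag_nia <- function(variants) {
  if (nrow(variants) == 0L) return(logical(0))
  vapply(seq_len(nrow(variants)), function(i) {
    r <- nchar(variants$ref_seq[i]); a <- nchar(variants$alt_seq[i])
    if (min(r, a) < 10L || abs(r - a) > 1L) return(FALSE)
    utils::adist(variants$ref_seq[i], variants$alt_seq[i])[1, 1] == 1L
  }, TRUE)
}
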