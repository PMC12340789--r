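# Reference tree construction.
#
# The reference tree is a bidirected spanning tree containing every node of
# the graph. It is rooted at a synthetic source terminus and includes the
# linear-reference walk as a branch, so every reference-walk edge is a tree
# edge. Four terminus nodes (two binodes, all with empty sequences) anchor
# walk starts, walk ends and disconnected components; edges incident to them
# never contribute alleles and are excluded downstream as "terminal" edges.
#
# Growth algorithm: seed the tree with the reference walk (rooted at the
# source binode), then expand greedily over edges that leave the tree through
# a tree node's exit side (so every root-to-node tree path is a valid
# bidirected walk). Candidate edges are ranked by (1) the number of haplotype
# walk traversals, so that common haplotypes tend to follow tree paths and
# common alleles become "reference"; (2) shallower parent depth;
# (3) smaller numeric child id; (4) child entry side "s" before "e". The
# resulting tree fixes an orientation, a depth and a linear-reference
# position for every node.

TERMINUS_IDS <- c("__term_src_a", "__term_src_b", "__term_snk_a", "__term_snk_b")

#' Build the reference tree of a pangenome graph
#'
#' @param graph a [bd_graph()] with a designated linear-reference walk.
#'   The reference walk must be simple (no repeated nodes) and is required
#'   to be a single walk (one contig) in this version.
#' @return an object of class `reference_tree` with fields `parent`,
#'   `parent_key`, `orientation`, `depth`, `position`, `dr` (tree-edge
#'   distance from the reference path), `ref_path`, `ref_end`/`ref_start`
#'   (per-reference-node base coordinates), `terminus`, `tree_keys`,
#'   `edges` (graph + terminus edges) and `nontree` (non-tree edge rows).
#' @export
build_tree <- function(graph) {
  if (length(graph$nodes) == 0L) stop("graph has no nodes")
  if (is.na(graph$reference)) stop("graph has no designated reference sample")
  samples <- vapply(graph$walks, `[[`, "", "sample")
  ref_idx <- which(samples == graph$reference)
  if (length(ref_idx) == 0L) stop("no walk found for reference sample")
  if (length(ref_idx) > 1L)
    stop("reference sample has multiple walks; one reference contig per graph is supported")
  refw <- graph$walks[[ref_idx]]
  if (anyDuplicated(refw$nodes))
    stop("reference walk revisits a node; cyclic reference paths are unsupported")
  if (any(TERMINUS_IDS %in% names(graph$nodes)))
    stop("node ids collide with reserved terminus ids")

  src_a <- TERMINUS_IDS[1]; src_b <- TERMINUS_IDS[2]
  snk_a <- TERMINUS_IDS[3]; snk_b <- TERMINUS_IDS[4]

  # terminus edges: source binode chain, sink binode chain, and one edge from
  # the source (sink) binode to the first (last) node of every walk
  firsts <- lapply(graph$walks, function(w)
    c(w$nodes[1L], entry_side(w$orients[1L])))
  n_last <- vapply(graph$walks, function(w) length(w$nodes), 1L)
  lasts <- lapply(graph$walks, function(w)
    c(w$nodes[length(w$nodes)], exit_side(w$orients[length(w$orients)])))
  term <- rbind(
    data.frame(a = src_a, a_side = "e", b = src_b, b_side = "s",
               stringsAsFactors = FALSE),
    data.frame(a = snk_a, a_side = "e", b = snk_b, b_side = "s",
               stringsAsFactors = FALSE),
    data.frame(a = src_b, a_side = "e",
               b = vapply(firsts, `[[`, "", 1L),
               b_side = vapply(firsts, `[[`, "", 2L), stringsAsFactors = FALSE),
    data.frame(a = vapply(lasts, `[[`, "", 1L),
               a_side = vapply(lasts, `[[`, "", 2L),
               b = snk_a, b_side = "s", stringsAsFactors = FALSE))
  term_df <- make_edge_df(term$a, term$a_side, term$b, term$b_side)
  edges <- rbind(graph$edges,
                 term_df[!(term_df$key %in% graph$edges$key), , drop = FALSE])
  edges <- edges[!duplicated(edges$key), , drop = FALSE]
  rownames(edges) <- NULL
  edges$is_term <- edges$a %in% TERMINUS_IDS | edges$b %in% TERMINUS_IDS

  # walk-traversal support per canonical edge (either direction)
  wk <- unlist(lapply(graph$walks, walk_edge_keys))
  support <- table(wk)
  esupp <- as.integer(support[edges$key])
  esupp[is.na(esupp)] <- 0L
  # walk starts, for anchoring unreachable components
  walk_starts <- unique(vapply(graph$walks, function(w) w$nodes[1L], ""))

  all_ids <- c(names(graph$nodes), TERMINUS_IDS)
  n_all <- length(all_ids)
  idx <- seq_len(n_all); names(idx) <- all_ids

  # incidence lists per node-side
  inc <- vector("list", 2L * n_all)
  side_slot <- function(node, side) 2L * (idx[node] - 1L) + ifelse(side == "e", 2L, 1L)
  for (i in seq_len(nrow(edges))) {
    sa <- side_slot(edges$a[i], edges$a_side[i])
    sb <- side_slot(edges$b[i], edges$b_side[i])
    inc[[sa]] <- c(inc[[sa]], i)
    if (sb != sa) inc[[sb]] <- c(inc[[sb]], i)
  }

  parent <- stats::setNames(rep(NA_character_, n_all), all_ids)
  parent_key <- stats::setNames(rep(NA_character_, n_all), all_ids)
  orientation <- stats::setNames(rep(NA_character_, n_all), all_ids)
  depth <- stats::setNames(rep(NA_integer_, n_all), all_ids)
  in_tree <- stats::setNames(rep(FALSE, n_all), all_ids)
  add_order <- character(0)
  tree_keys <- character(0)

  attach_node <- function(node, par, key, orient) {
    parent[node] <<- par
    parent_key[node] <<- key
    orientation[node] <<- orient
    depth[node] <<- if (is.na(par)) 0L else depth[[par]] + 1L
    in_tree[node] <<- TRUE
    add_order <<- c(add_order, node)
    if (!is.na(key)) tree_keys <<- c(tree_keys, key)
  }

  find_key <- function(n1, s1, n2, s2) edge_key(n1, s1, n2, s2)

  # seed: source binode, reference walk, sink binode
  attach_node(src_a, NA_character_, NA_character_, "+")
  attach_node(src_b, src_a, find_key(src_a, "e", src_b, "s"), "+")
  rn <- refw$nodes; ro <- refw$orients
  attach_node(rn[1L], src_b, find_key(src_b, "e", rn[1L], entry_side(ro[1L])), ro[1L])
  if (length(rn) > 1L) {
    for (k in 2L:length(rn)) {
      key <- find_key(rn[k - 1L], exit_side(ro[k - 1L]), rn[k], entry_side(ro[k]))
      if (!(key %in% edges$key))
        stop("reference walk step not backed by an edge (corrupt graph)")
      attach_node(rn[k], rn[k - 1L], key, ro[k])
    }
  }
  last <- length(rn)
  attach_node(snk_a, rn[last],
              find_key(rn[last], exit_side(ro[last]), snk_a, "s"), "+")
  attach_node(snk_b, snk_a, find_key(snk_a, "e", snk_b, "s"), "+")

  # candidate pool: edge index + the tree endpoint it extends from
  cand_e <- integer(0); cand_par <- character(0)
  push_candidates <- function(node) {
    es <- inc[[side_slot(node, exit_side(orientation[[node]]))]]
    if (length(es)) {
      cand_e <<- c(cand_e, es)
      cand_par <<- c(cand_par, rep(node, length(es)))
    }
  }
  for (nd in add_order) push_candidates(nd)

  synthetic_keys <- character(0)
  comp <- NULL  # lazily computed component membership (graph edges only)

  repeat {
    if (length(cand_e)) {
      # child = the edge endpoint opposite the recorded parent endpoint;
      # the edge must actually leave the parent through its exit side
      pa <- cand_par
      ei <- cand_e
      ch <- ifelse(edges$a[ei] == pa & edges$a_side[ei] ==
                     exit_side(orientation[pa]), edges$b[ei], edges$a[ei])
      ch_side <- ifelse(edges$a[ei] == pa & edges$a_side[ei] ==
                          exit_side(orientation[pa]), edges$b_side[ei], edges$a_side[ei])
      ok <- !in_tree[ch]
      cand_e <- ei[ok]; cand_par <- pa[ok]
      ch <- ch[ok]; ch_side <- ch_side[ok]
      if (length(cand_e)) {
        o <- order(-esupp[cand_e], depth[cand_par], node_num(ch), ch,
                   ifelse(ch_side == "s", 0L, 1L), node_num(cand_par))
        pick <- o[1L]
        attach_node(ch[pick], cand_par[pick], edges$key[cand_e[pick]],
                    orient_entering(ch_side[pick]))
        push_candidates(ch[pick])
        next
      }
    }
    left <- all_ids[!in_tree]
    if (length(left) == 0L) break
    # anchor an unreached component to the source terminus through its
    # lexicographically smallest walk-start node (smallest node otherwise)
    if (is.null(comp)) comp <- graph_components(graph)
    left_comp <- split(left, comp[left])
    grp <- left_comp[[1L]]
    anchors <- intersect(sort(grp), sort(walk_starts))
    anchor <- if (length(anchors)) anchors[1L] else sort(grp)[1L]
    key <- find_key(src_b, "e", anchor, "s")
    if (!(key %in% edges$key)) {
      newe <- make_edge_df(src_b, "e", anchor, "s")
      newe$is_term <- TRUE
      edges <- rbind(edges, newe)
      i <- nrow(edges)
      esupp <- c(esupp, 0L)
      sa <- side_slot(src_b, "e"); sb <- side_slot(anchor, "s")
      inc[[sa]] <- c(inc[[sa]], i); inc[[sb]] <- c(inc[[sb]], i)
      synthetic_keys <- c(synthetic_keys, key)
    }
    attach_node(anchor, src_b, key, "+")
    push_candidates(anchor)
  }

  # positions: for reference nodes the cumulative end coordinate; otherwise
  # inherited from the parent (position of the deepest reference ancestor)
  ref_len <- nchar(graph$nodes[rn])
  ref_end <- stats::setNames(cumsum(ref_len), rn)
  ref_start <- ref_end - ref_len + 1L
  position <- stats::setNames(rep(-1L, n_all), all_ids)
  dr <- stats::setNames(rep(NA_integer_, n_all), all_ids)
  on_ref <- stats::setNames(rep(FALSE, n_all), all_ids)
  on_ref[rn] <- TRUE
  for (nd in add_order) {
    if (on_ref[[nd]]) {
      position[nd] <- ref_end[[nd]]
      dr[nd] <- 0L
    } else if (!is.na(parent[[nd]])) {
      position[nd] <- position[[parent[[nd]]]]
      pdr <- dr[[parent[[nd]]]]
      dr[nd] <- if (is.na(pdr)) NA_integer_ else pdr + 1L
    }
  }

  nontree <- edges[!(edges$key %in% tree_keys), , drop = FALSE]
  rownames(nontree) <- NULL

  structure(list(parent = parent, parent_key = parent_key,
                 orientation = orientation, depth = depth,
                 position = position, dr = dr,
                 ref_path = rn, ref_orients = ro,
                 ref_end = ref_end, ref_start = ref_start,
                 ref_seq = paste(ifelse(ro == "+", graph$nodes[rn],
                                        revcomp(graph$nodes[rn])), collapse = ""),
                 terminus = TERMINUS_IDS, tree_keys = tree_keys,
                 synthetic_keys = synthetic_keys,
                 edges = edges, nontree = nontree,
                 reference = graph$reference, contig = graph$contig),
            class = "reference_tree")
}

#' @export
print.reference_tree <- function(x, ...) {
  cat(sprintf(
    "reference_tree: %d nodes (%d on reference), %d tree edges, %d non-tree edges\n",
    length(x$parent) - 4L, length(x$ref_path), length(x$tree_keys),
    nrow(x$nontree)))
  invisible(x)
}

check_tree_node <- function(tree, u) {
  if (!(u %in% names(tree$parent))) stop("unknown node: ", u)
}

#' Lowest common ancestor of two nodes in the reference tree
#' @param tree a `reference_tree`.
#' @param a,b node ids.
#' @return the id of the deepest node that is an ancestor of both.
#' @export
tree_lca <- function(tree, a, b) {
  check_tree_node(tree, a); check_tree_node(tree, b)
  while (a != b) {
    if (tree$depth[[a]] >= tree$depth[[b]]) a <- tree$parent[[a]]
    else b <- tree$parent[[b]]
    if (is.na(a) || is.na(b)) stop("nodes lie in different anchored trees")
  }
  a
}

# is `anc` an ancestor of `node` (inclusive)?
is_ancestor <- function(tree, anc, node) {
  while (!is.na(node)) {
    if (node == anc) return(TRUE)
    if (tree$depth[[node]] <= tree$depth[[anc]]) return(FALSE)
    node <- tree$parent[[node]]
  }
  FALSE
}

# node path descending from `anc` to `node` (both included)
path_down <- function(tree, anc, node) {
  out <- character(0)
  while (node != anc) {
    out <- c(node, out)
    node <- tree$parent[[node]]
    if (is.na(node)) stop("not an ancestor/descendant pair")
  }
  c(anc, out)
}

#' Linear-reference position of a node
#'
#' The 1-based coordinate of the last base of the deepest reference-path
#' node on the root-to-`u` tree path; for reference-path nodes this is the
#' cumulative end coordinate of the node itself. `-1` when no reference
#' ancestor exists (components anchored directly at the terminus).
#'
#' @param tree a `reference_tree`.
#' @param u node id.
#' @return integer position.
#' @export
node_position <- function(tree, u) {
  check_tree_node(tree, u)
  as.integer(tree$position[[u]])
}

#' Tree-assigned orientation of a node
#'
#' The orientation implied by traversing the unique root-to-`u` tree path;
#' reference-path nodes carry their reference-walk orientation.
#'
#' @param tree a `reference_tree`.
#' @param u node id.
#' @return `"+"` or `"-"`.
#' @export
node_orientation <- function(tree, u) {
  check_tree_node(tree, u)
  tree$orientation[[u]]
}

#' Dump the reference tree as a data frame
#' @param tree a `reference_tree`.
#' @param path optional TSV output path.
#' @return data frame of (node, parent, orientation, depth, position, dr).
#' @export
tree_dump <- function(tree, path = NULL) {
  ids <- setdiff(names(tree$parent), tree$terminus)
  df <- data.frame(node = ids, parent = unname(tree$parent[ids]),
                   orientation = unname(tree$orientation[ids]),
                   depth = unname(tree$depth[ids]),
                   position = unname(tree$position[ids]),
                   dr = unname(tree$dr[ids]), stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
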