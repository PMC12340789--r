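# Visualization-oriented graph simplification: (1) drop variant edges whose
# combined allele length is below a threshold (keeping only long,
# structurally informative variants), (2) iteratively delete tips --
# dead-end branches not contained in any cycle, found by repeated pruning of
# degree-1 nodes -- and (3) contract maximal non-branching paths into single
# nodes whose sequence is the concatenation of their parts. Reference-path
# nodes are never deleted, so the retained reference walk stays connected;
# contraction conserves total sequence length.

#' Simplify a pangenome graph for visualization
#'
#' @param graph a `bdgraph`.
#' @param tree the `reference_tree` built on `graph`.
#' @param variants the [call_variants()] table for this graph.
#' @param min_combined_allele_len variant edges with
#'   `nchar(ref)+nchar(alt)` strictly below this threshold (in bp) are
#'   removed; inversion edges are always kept.
#' @return a `bdgraph` (no walks) suitable for GFA export and Bandage;
#'   each node carries a `members` attribute listing the original node ids
#'   it contracts.
#' @export
simplify_graph <- function(graph, tree, variants, min_combined_allele_len = 1000) {
  if (min_combined_allele_len < 0) stop("threshold must be >= 0")
  drop_keys <- variants$key[variants$vtype != "inversion" &
                              nchar(variants$ref_seq) +
                              nchar(variants$alt_seq) < min_combined_allele_len]
  edges <- graph$edges[!(graph$edges$key %in% drop_keys), , drop = FALSE]
  nodes <- graph$nodes
  keep_always <- tree$ref_path

  # iterative tip pruning: remove non-reference nodes of total degree <= 1
  repeat {
    if (nrow(edges) == 0L) deg <- stats::setNames(rep(0L, length(nodes)), names(nodes))
    else {
      tab <- table(factor(c(edges$a, edges$b[edges$a != edges$b | edges$a_side != edges$b_side]),
                          levels = names(nodes)))
      deg <- stats::setNames(as.integer(tab), names(nodes))
    }
    tips <- setdiff(names(nodes)[deg <= 1L], keep_always)
    if (length(tips) == 0L) break
    nodes <- nodes[setdiff(names(nodes), tips)]
    edges <- edges[!(edges$a %in% tips | edges$b %in% tips), , drop = FALSE]
  }

  # contract non-branching joins: an edge whose two node-sides have no other
  # incident edge merges its nodes
  members <- as.list(names(nodes)); names(members) <- names(nodes)
  repeat {
    if (nrow(edges) == 0L) break
    side_count <- table(c(end_label(edges$a, edges$a_side),
                          end_label(edges$b, edges$b_side)))
    cand <- which(edges$a != edges$b &
                    side_count[end_label(edges$a, edges$a_side)] == 1L &
                    side_count[end_label(edges$b, edges$b_side)] == 1L)
    if (length(cand) == 0L) break
    i <- cand[1L]
    a <- edges$a[i]; as_ <- edges$a_side[i]
    b <- edges$b[i]; bs <- edges$b_side[i]
    # orient a so that it exits via as_, b so that it enters via bs
    sa <- if (as_ == "e") nodes[[a]] else revcomp(nodes[[a]])
    sb <- if (bs == "s") nodes[[b]] else revcomp(nodes[[b]])
    merged <- paste0(sa, sb)
    ma <- if (as_ == "e") members[[a]] else rev(members[[a]])
    mb <- if (bs == "s") members[[b]] else rev(members[[b]])
    new_id <- a
    nodes[[a]] <- merged
    members[[a]] <- c(ma, mb)
    nodes <- nodes[setdiff(names(nodes), b)]
    members[[b]] <- NULL
    edges <- edges[-i, , drop = FALSE]
    # rewire b's remaining edges: sides flip if b was reverse-complemented,
    # and map onto the merged node's outer sides
    flip_b <- bs != "s"
    remap <- function(n, s) {
      if (n == b) {
        s2 <- if (flip_b) ifelse(s == "s", "e", "s") else s
        # b's free side is its exit ("e" after orientation); a's free side is "s"
        list(n = new_id, s = s2)
      } else if (n == a) {
        s2 <- if (as_ != "e") ifelse(s == "s", "e", "s") else s
        list(n = new_id, s = s2)
      } else list(n = n, s = s)
    }
    if (nrow(edges)) {
      for (j in seq_len(nrow(edges))) {
        ra <- remap(edges$a[j], edges$a_side[j])
        rb <- remap(edges$b[j], edges$b_side[j])
        edges$a[j] <- ra$n; edges$a_side[j] <- ra$s
        edges$b[j] <- rb$n; edges$b_side[j] <- rb$s
      }
      edges <- make_edge_df(edges$a, edges$a_side, edges$b, edges$b_side)
      edges <- edges[!duplicated(edges$key), , drop = FALSE]
    }
    keep_always <- unique(ifelse(keep_always == b, new_id, keep_always))
  }
  out <- bd_graph(nodes, if (nrow(edges)) edges else NULL, list(),
                  NA_character_, graph$contig)
  attr(out, "members") <- members
  out
}
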