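# Pinch-point superbubbles. An anchor is a node at which every haplotype
# aligns: every walk whose linear coverage spans the node's reference
# interval visits it exactly once, in consistent (tree) orientation, and the
# reference visits it. Superbubbles are the regions between consecutive
# anchors that contain at least one variant edge; anchors are shared between
# neighbouring bubbles, interiors are disjoint. Only level-0 bubbles are
# produced; the hierarchical levels of snarl decompositions are out of
# scope. Variants in unanchored components (position -1) cannot be assigned
# and are reported via the `unassigned` attribute.

#' Detect pinch-point superbubbles
#'
#' @param graph a `bdgraph`.
#' @param tree the `reference_tree`.
#' @param variants a [call_variants()] table; defaults to calling it.
#' @return list of `superbubble` objects (fields `entry`, `exit`,
#'   `interior`, `variant_idx`, `variant_keys`, `n_alleles`,
#'   `n_alt_alleles`, `alleles`), with attribute `unassigned` holding the
#'   indices of variants not assignable to any bubble.
#' @export
detect_superbubbles <- function(graph, tree, variants = NULL) {
  if (is.null(variants)) variants <- call_variants(graph, tree)
  rp <- tree$ref_path
  if (length(rp) == 0L) return(structure(list(), unassigned = integer(0)))

  # per-walk visit counts (consistent orientation only) and coverage span
  nwalk <- length(graph$walks)
  spans <- matrix(FALSE, nwalk, length(rp), dimnames = list(NULL, rp))
  visits_ok <- matrix(0L, nwalk, length(rp), dimnames = list(NULL, rp))
  visits_any <- matrix(0L, nwalk, length(rp), dimnames = list(NULL, rp))
  for (i in seq_len(nwalk)) {
    w <- graph$walks[[i]]
    pos <- tree$position[w$nodes]
    anchored <- pos >= 0
    if (!any(anchored)) next
    nd <- w$nodes[anchored]
    lo <- min(ifelse(nd %in% rp, tree$ref_start[nd], pos[anchored]))
    hi <- max(pos[anchored])
    spans[i, ] <- tree$ref_start[rp] >= lo & tree$ref_end[rp] <= hi
    on <- w$nodes %in% rp
    if (any(on)) {
      cons <- w$orients == tree$orientation[w$nodes]
      t_ok <- table(w$nodes[on & cons])
      t_any <- table(w$nodes[on])
      visits_ok[i, names(t_ok)] <- as.integer(t_ok)
      visits_any[i, names(t_any)] <- as.integer(t_any)
    }
  }
  is_anchor <- vapply(seq_along(rp), function(j) {
    rel <- spans[, j]
    all(visits_ok[rel, j] == 1L & visits_any[rel, j] == 1L)
  }, TRUE)
  anchors <- rp[is_anchor]
  if (length(anchors) < 2L) return(structure(list(), unassigned = seq_len(nrow(variants))))

  # node membership: reference nodes between the anchors; off-reference
  # nodes by position (branch ancestor inside [entry, exit) )
  ids <- setdiff(names(tree$parent), tree$terminus)
  off <- setdiff(ids, rp)
  off_pos <- tree$position[off]
  a_end <- tree$ref_end[anchors]
  a_start <- tree$ref_start[anchors]
  rp_idx <- stats::setNames(seq_along(rp), rp)

  assigned <- rep(NA_integer_, nrow(variants))
  bubbles <- list()
  for (j in seq_len(length(anchors) - 1L)) {
    entry <- anchors[j]; exit <- anchors[j + 1L]
    interior_ref <- rp[(rp_idx[entry] + 1L):(rp_idx[exit] - 1L)]
    if (rp_idx[exit] == rp_idx[entry] + 1L) interior_ref <- character(0)
    interior_off <- off[off_pos >= a_end[j] & off_pos < a_start[j + 1L]]
    members <- c(entry, exit, interior_ref, interior_off)
    inb <- variants$u %in% members & variants$v %in% members
    if (!any(inb)) next
    vidx <- which(inb & is.na(assigned))
    assigned[vidx] <- length(bubbles) + 1L
    al <- bubble_alleles(graph, tree, entry, exit)
    bubbles[[length(bubbles) + 1L]] <- structure(
      list(entry = entry, exit = exit,
           interior = c(interior_ref, interior_off),
           variant_idx = vidx, variant_keys = variants$key[vidx],
           alleles = al$alleles, n_alleles = al$n,
           n_alt_alleles = al$n_alt),
      class = "superbubble")
  }
  structure(bubbles, unassigned = which(is.na(assigned)))
}

# distinct walk sub-paths between entry and exit (inclusive crossings)
bubble_alleles <- function(graph, tree, entry, exit) {
  subs <- character(0)
  ref_sub <- NA_character_
  for (w in graph$walks) {
    i_e <- which(w$nodes == entry & w$orients == tree$orientation[[entry]])
    i_x <- which(w$nodes == exit & w$orients == tree$orientation[[exit]])
    for (ie in i_e) {
      ix <- i_x[i_x > ie]
      if (length(ix) == 0L) next
      ix <- min(ix)
      if (ix - ie < 1L) next
      inner <- if (ix - ie == 1L) "" else
        paste(paste0(w$orients[(ie + 1L):(ix - 1L)],
                     w$nodes[(ie + 1L):(ix - 1L)]), collapse = ",")
      subs <- c(subs, inner)
      if (w$sample == graph$reference && is.na(ref_sub)) ref_sub <- inner
    }
  }
  u <- unique(subs)
  list(alleles = u, n = length(u),
       n_alt = length(setdiff(u, ref_sub)))
}

#' @export
print.superbubble <- function(x, ...) {
  cat(sprintf("superbubble %s..%s: %d interior nodes, %d variant edges, %d alt alleles\n",
              x$entry, x$exit, length(x$interior), length(x$variant_idx),
              x$n_alt_alleles))
  invisible(x)
}

# total edge degree of a node within the bubble subgraph
bubble_degree <- function(tree, bubble, node) {
  members <- c(bubble$entry, bubble$exit, bubble$interior)
  e <- tree$edges[!tree$edges$is_term, , drop = FALSE]
  sum((e$a == node & e$b %in% members) | (e$b == node & e$a %in% members &
                                            e$a != e$b))
}

#' Classify a triallelic (two-variant) superbubble
#'
#' Applies the taxonomy for bubbles with exactly two variant edges, in
#' order: *properly triallelic* when both the entry and the exit node have
#' total degree three within the bubble; *overlapping* when exactly one of
#' them does; *nested* when one variant edge has the bubble's entry as its
#' branch point and the bubble's exit as its end node; otherwise
#' *interlocking* (one edge branches at the entry, the other ends at the
#' exit).
#'
#' @param bubble a `superbubble` with exactly 2 variant edges.
#' @param tree the `reference_tree`.
#' @param variants the [call_variants()] table the bubble refers to.
#' @return one of `"properly_triallelic"`, `"overlapping"`, `"nested"`,
#'   `"interlocking"`.
#' @export
classify_triallelic <- function(bubble, tree, variants) {
  if (length(bubble$variant_idx) != 2L)
    stop("triallelic classification applies to bubbles with exactly 2 variant edges")
  v2 <- variants[bubble$variant_idx, ]
  deg_in <- bubble_degree(tree, bubble, bubble$entry)
  deg_out <- bubble_degree(tree, bubble, bubble$exit)
  if (deg_in == 3L && deg_out == 3L) return("properly_triallelic")
  if (xor(deg_in == 3L, deg_out == 3L)) return("overlapping")
  starts_at_entry <- !is.na(v2$branch) & v2$branch == bubble$entry
  ends_at_exit <- v2$v == bubble$exit
  if (any(starts_at_entry & ends_at_exit)) return("nested")
  "interlocking"
}

#' Classify a superbubble as an insertion, a deletion, or neither
#'
#' A bubble is an insertion when its entry and exit are adjacent via a
#' reference-tree edge, a deletion when adjacent via a variant edge. When
#' both edges exist the bubble is reported as a deletion with a warning.
#'
#' @param bubble a `superbubble`.
#' @param tree the `reference_tree`.
#' @return `"insertion"`, `"deletion"` or `"neither"`.
#' @export
classify_indel_superbubble <- function(bubble, tree) {
  e <- tree$edges
  direct <- (e$a == bubble$entry & e$b == bubble$exit) |
    (e$b == bubble$entry & e$a == bubble$exit)
  if (!any(direct)) return("neither")
  keys <- e$key[direct]
  tree_adj <- any(keys %in% tree$tree_keys)
  var_adj <- any(!(keys %in% tree$tree_keys))
  if (tree_adj && var_adj) {
    warning("bubble entry and exit adjacent via both tree and variant edges; ",
            "classified as deletion")
    return("deletion")
  }
  if (var_adj) return("deletion")
  "insertion"
}

#' Summary table of superbubbles
#'
#' One row per bubble with its variant-edge count, alternative-allele
#' count, indel class, triallelic class (for two-variant bubbles) and the
#' number of contained non-reference variants. Enforces the multiallelic
#' implication: a bubble with more than one alternative allele must contain
#' more than one variant edge.
#'
#' @param bubbles result of [detect_superbubbles()].
#' @param tree the `reference_tree`.
#' @param variants the matching [call_variants()] table.
#' @return data frame.
#' @export
bubble_summary <- function(bubbles, tree, variants) {
  rows <- lapply(bubbles, function(b) {
    data.frame(entry = b$entry, exit = b$exit,
               n_variant_edges = length(b$variant_idx),
               n_alt_alleles = b$n_alt_alleles,
               indel_class = classify_indel_superbubble(b, tree),
               triallelic_class = if (length(b$variant_idx) == 2L)
                 classify_triallelic(b, tree, variants) else NA_character_,
               n_non_reference = sum(variants$non_reference[b$variant_idx]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entry = character(), exit = character(),
               n_variant_edges = integer(), n_alt_alleles = integer(),
               indel_class = character(), triallelic_class = character(),
               n_non_reference = integer(), stringsAsFactors = FALSE)
  bad <- out$n_alt_alleles > 1L & out$n_variant_edges <= 1L
  if (any(bad))
    stop("internal inconsistency: multiallelic bubble with a single variant edge")
  out
}
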