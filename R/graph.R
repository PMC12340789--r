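# Bidirected graph data model.
#
# Every node has two sides: "s" (the side preceding base 1 of its sequence)
# and "e" (the side following its last base). Traversing a node forward ("+")
# means entering at "s" and leaving at "e"; traversing it reverse ("-") means
# the opposite, and reads the reverse complement. An edge joins two
# node-sides; it is stored as an unordered, canonicalized pair so that the
# GFA links `1 + 2 +` and `2 - 1 -` are the same object.

#' Flip an orientation
#' @param o character vector of orientations, `"+"` or `"-"`.
#' @return the opposite orientations.
#' @export
flip_orient <- function(o) ifelse(o == "+", "-", "+")

# side used when leaving / entering a node traversed with orientation o
exit_side  <- function(o) ifelse(o == "+", "e", "s")
entry_side <- function(o) ifelse(o == "+", "s", "e")

# orientation implied by entering (or leaving) a node at a given side
orient_entering <- function(side) ifelse(side == "s", "+", "-")
orient_exiting  <- function(side) ifelse(side == "e", "+", "-")

#' Reverse-complement DNA strings
#' @param x character vector over the ACGTN alphabet (may contain empty strings).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

end_label <- function(node, side) paste0(node, ":", side)

# canonical undirected key of an edge given its two ends
edge_key <- function(a, a_side, b, b_side) {
  ea <- end_label(a, a_side)
  eb <- end_label(b, b_side)
  ifelse(ea <= eb, paste0(ea, "|", eb), paste0(eb, "|", ea))
}

# directed traversal key: leaving node1 via side1, entering node2 via side2
dir_key <- function(n1, s1, n2, s2) paste0(n1, ":", s1, ">", n2, ":", s2)

make_edge_df <- function(a = character(), a_side = character(),
                         b = character(), b_side = character()) {
  if (length(a) == 0L)
    return(data.frame(a = character(), a_side = character(), b = character(),
                      b_side = character(), key = character(),
                      stringsAsFactors = FALSE))
  swap <- end_label(a, a_side) > end_label(b, b_side)
  if (any(swap)) {
    tmp_n <- a[swap]; tmp_s <- a_side[swap]
    a[swap] <- b[swap]; a_side[swap] <- b_side[swap]
    b[swap] <- tmp_n; b_side[swap] <- tmp_s
  }
  data.frame(a = a, a_side = a_side, b = b, b_side = b_side,
             key = edge_key(a, a_side, b, b_side),
             stringsAsFactors = FALSE)
}

clean_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%d %s(s) contain non-ACGTN symbols; mapped to N",
                    sum(bad), what), call. = FALSE)
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Construct a bidirected pangenome graph
#'
#' @param nodes named character vector: node id -> DNA sequence (ACGTN;
#'   other IUPAC codes are mapped to `N` with a warning).
#' @param edges data frame with columns `a`, `a_side`, `b`, `b_side`
#'   (`side` is `"s"` or `"e"`), or `NULL`.
#' @param walks list of walks as returned by [bd_walk()].
#' @param reference sample name of the linear-reference walk.
#' @param contig contig/chromosome label used for VCF output.
#' @return an object of class `bdgraph`.
#' @export
bd_graph <- function(nodes, edges = NULL, walks = list(), reference = NA_character_,
                     contig = "chr1") {
  if (is.null(names(nodes)) || anyNA(names(nodes)) || any(names(nodes) == ""))
    stop("nodes must be a named character vector of sequences")
  if (anyDuplicated(names(nodes)))
    stop("duplicate node ids")
  if (any(grepl("[:|><,\t ]", names(nodes))))
    stop("node ids must not contain ':', '|', '>', '<', ',' or whitespace")
  nodes[] <- clean_seq(nodes)
  if (is.null(edges)) {
    edf <- make_edge_df()
  } else {
    edf <- make_edge_df(as.character(edges$a), as.character(edges$a_side),
                        as.character(edges$b), as.character(edges$b_side))
    edf <- edf[!duplicated(edf$key), , drop = FALSE]
    rownames(edf) <- NULL
  }
  g <- structure(list(nodes = nodes, edges = edf, walks = walks,
                      reference = reference, contig = contig),
                 class = "bdgraph")
  validate_bdgraph(g)
  g
}

#' Construct a haplotype walk
#'
#' @param sample sample name.
#' @param hap haplotype index (integer; `0` for unphased paths).
#' @param contig contig label of the walk.
#' @param nodes character vector of node ids in traversal order.
#' @param orients character vector of orientations (`"+"`/`"-"`), same length.
#' @return a list of class `bdwalk`.
#' @export
bd_walk <- function(sample, hap, contig, nodes, orients) {
  stopifnot(length(nodes) >= 1L, length(nodes) == length(orients),
            all(orients %in% c("+", "-")))
  structure(list(sample = sample, hap = as.integer(hap), contig = contig,
                 nodes = as.character(nodes), orients = as.character(orients)),
            class = "bdwalk")
}

#' Haplotype label of a walk (`sample#hap`)
#' @param walk a `bdwalk`.
#' @return character scalar.
#' @export
walk_hap_id <- function(walk) paste0(walk$sample, "#", walk$hap)

# directed traversal keys of the consecutive steps of a walk
walk_dir_keys <- function(walk) {
  n <- length(walk$nodes)
  if (n < 2L) return(character(0))
  dir_key(walk$nodes[-n], exit_side(walk$orients[-n]),
          walk$nodes[-1L], entry_side(walk$orients[-1L]))
}

walk_edge_keys <- function(walk) {
  n <- length(walk$nodes)
  if (n < 2L) return(character(0))
  edge_key(walk$nodes[-n], exit_side(walk$orients[-n]),
           walk$nodes[-1L], entry_side(walk$orients[-1L]))
}

validate_bdgraph <- function(g) {
  ids <- names(g$nodes)
  if (nrow(g$edges) > 0) {
    miss <- setdiff(unique(c(g$edges$a, g$edges$b)), ids)
    if (length(miss))
      stop("edge endpoint(s) reference unknown node(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    if (!all(c(g$edges$a_side, g$edges$b_side) %in% c("s", "e")))
      stop("edge sides must be 's' or 'e'")
  }
  keys <- g$edges$key
  for (w in g$walks) {
    miss <- setdiff(unique(w$nodes), ids)
    if (length(miss))
      stop(sprintf("walk %s references unknown node(s): %s", walk_hap_id(w),
                   paste(utils::head(miss, 5), collapse = ", ")))
    wk <- walk_edge_keys(w)
    bad <- which(!(wk %in% keys))
    if (length(bad))
      stop(sprintf("walk %s step %d->%d does not follow an existing edge",
                   walk_hap_id(w), bad[1], bad[1] + 1L))
  }
  if (!is.na(g$reference) &&
      !(g$reference %in% vapply(g$walks, `[[`, "", "sample")) &&
      length(g$walks) > 0)
    stop("reference sample '", g$reference, "' has no walk in the graph")
  invisible(g)
}

#' @export
print.bdgraph <- function(x, ...) {
  cat(sprintf("bdgraph: %d nodes, %d edges, %d walks (reference: %s)\n",
              length(x$nodes), nrow(x$edges), length(x$walks),
              ifelse(is.na(x$reference), "<none>", x$reference)))
  invisible(x)
}

# igraph view of the node adjacency (sides collapsed), used for components
node_igraph <- function(g) {
  ids <- names(g$nodes)
  el <- cbind(g$edges$a, g$edges$b)
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
}

#' Connected-component membership of the graph's nodes
#' @param graph a `bdgraph`.
#' @return named integer vector of component ids.
#' @export
graph_components <- function(graph) {
  if (length(graph$nodes) == 0L) return(integer(0))
  memb <- igraph::components(node_igraph(graph))$membership
  memb[names(graph$nodes)]
}

#' Extract the connected component containing a node
#'
#' Walks are restricted to their maximal contiguous sub-walks inside the
#' component; sub-walks inherit the sample and haplotype of their parent walk.
#'
#' @param graph a `bdgraph`.
#' @param seed_node node id whose component is wanted.
#' @return a `bdgraph` restricted to the component of `seed_node`.
#' @export
extract_component <- function(graph, seed_node) {
  if (!(seed_node %in% names(graph$nodes)))
    stop("unknown node: ", seed_node)
  memb <- graph_components(graph)
  keep <- names(memb)[memb == memb[[seed_node]]]
  subset_graph(graph, keep)
}

subset_graph <- function(graph, keep) {
  keep <- as.character(keep)
  nodes <- graph$nodes[keep]
  edges <- graph$edges[graph$edges$a %in% keep & graph$edges$b %in% keep, ,
                       drop = FALSE]
  walks <- list()
  for (w in graph$walks) {
    inside <- w$nodes %in% keep
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      walks[[length(walks) + 1L]] <-
        bd_walk(w$sample, w$hap, w$contig, w$nodes[idx], w$orients[idx])
    }
  }
  ref <- graph$reference
  if (!is.na(ref) && !(ref %in% vapply(walks, `[[`, "", "sample")))
    ref <- NA_character_
  bd_graph(nodes, edges, walks, ref, graph$contig)
}

# numeric-aware node ordering used by deterministic tie-breaks
node_num <- function(id) {
  v <- suppressWarnings(as.numeric(id))
  v[is.na(v)] <- Inf
  v
}

node_order_key <- function(id) order(node_num(id), id)
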