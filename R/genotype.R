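# Genotypes. The genotype of a walk is the number of times it traverses
# each variant edge (in the variant's directed reading). The per-haplotype
# fields mirror the extended VCF: CA counts traversals of the variant edge,
# CR counts traversals of the last edge of the corresponding reference path
# (the tree edge into v), and both are missing when the variant's position
# interval falls entirely outside the haplotype's linear coverage.

variant_dir_keys <- function(variants) {
  dir_key(variants$u, variants$u_side, variants$v, variants$v_side)
}

# directed key of the tree edge (parent(v), v), traversed into v
reference_edge_key <- function(tree, v) {
  p <- tree$parent[[v]]
  if (is.na(p)) return(NA_character_)
  key <- tree$parent_key[[v]]
  # recover the side of the edge at each endpoint from the canonical key
  ends <- strsplit(key, "|", fixed = TRUE)[[1]]
  parts <- strsplit(ends, ":", fixed = TRUE)
  n1 <- parts[[1]][1]; s1 <- parts[[1]][2]
  n2 <- parts[[2]][1]; s2 <- parts[[2]][2]
  if (n1 == v && n2 == p) { tmp <- parts[[1]]; parts[[1]] <- parts[[2]]; parts[[2]] <- tmp }
  dir_key(parts[[1]][1], parts[[1]][2], parts[[2]][1], parts[[2]][2])
}

#' Genotype of a walk: traversal counts of each variant edge
#'
#' @param walk a [bd_walk()].
#' @param variants a [call_variants()] table.
#' @param tree the `reference_tree`.
#' @return integer vector, one entry per variant (directed traversals).
#' @export
genotype_walk <- function(walk, variants, tree) {
  miss <- setdiff(walk$nodes, setdiff(names(tree$parent), tree$terminus))
  if (length(miss)) stop("walk references node(s) unknown to the tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  keys <- walk_dir_keys(walk)
  vk <- variant_dir_keys(variants)
  as.integer(vapply(vk, function(k) sum(keys == k), 1L))
}

#' Traversal count of a variant's reference tree edge by one walk
#'
#' Counts how often the walk traverses the tree edge (parent(v), v) in the
#' direction entering `v`, i.e. the last edge of the variant's reference
#' path. Not defined for inversion edges.
#'
#' @param walk a [bd_walk()].
#' @param variant one row of a [call_variants()] table.
#' @param tree the `reference_tree`.
#' @return integer count.
#' @export
reference_edge_count <- function(walk, variant, tree) {
  if (isTRUE(variant$inversion == TRUE) || variant$vtype == "inversion")
    stop("reference edge counts are not defined for inversion edges")
  rk <- reference_edge_key(tree, variant$v)
  if (is.na(rk)) return(0L)
  sum(walk_dir_keys(walk) == rk)
}

#' Linear coverage and component footprint of each haplotype
#'
#' Per contiguous walk, the covered interval is `[min, max]` over the
#' reference coordinates of its anchored nodes (reference nodes span their
#' base interval; off-reference nodes count as a point at their position);
#' a haplotype's coverage is the union over its walks. Nodes with position
#' -1 contribute no interval but do mark the component as visited.
#'
#' @param graph a `bdgraph`.
#' @param tree the `reference_tree`.
#' @return named list (one entry per `sample#hap`) with elements
#'   `intervals` (two-column matrix lo,hi) and `components` (integer set).
#' @export
haplotype_coverage <- function(graph, tree) {
  comp <- graph_components(graph)
  out <- list()
  for (w in graph$walks) {
    hid <- walk_hap_id(w)
    if (is.null(out[[hid]]))
      out[[hid]] <- list(intervals = matrix(numeric(0), ncol = 2),
                         components = integer(0))
    pos <- tree$position[w$nodes]
    anchored <- pos >= 0
    if (any(anchored)) {
      nd <- w$nodes[anchored]
      lo <- ifelse(nd %in% tree$ref_path, tree$ref_start[nd], pos[anchored])
      out[[hid]]$intervals <- rbind(out[[hid]]$intervals,
                                    c(min(lo), max(pos[anchored])))
    }
    out[[hid]]$components <- union(out[[hid]]$components, unique(comp[w$nodes]))
  }
  out
}

#' Is a variant missing for a haplotype?
#'
#' TRUE when the variant's position interval `[min(pos), max(pos)]` does not
#' intersect any covered interval of the haplotype. Variants in unanchored
#' components (positions -1) are missing unless the haplotype has a walk in
#' that component.
#'
#' @param variant one row of a [call_variants()] table.
#' @param coverage one haplotype's entry of [haplotype_coverage()].
#' @param component integer component id of the variant's nodes (required
#'   only for unanchored variants).
#' @return logical.
#' @export
variant_missing <- function(variant, coverage, component = NA_integer_) {
  lo <- min(variant$pos_u, variant$pos_v)
  hi <- max(variant$pos_u, variant$pos_v)
  if (lo < 0) {
    if (is.na(component)) return(TRUE)
    return(!(component %in% coverage$components))
  }
  iv <- coverage$intervals
  if (nrow(iv) == 0L) return(TRUE)
  !any(iv[, 1] <= hi & iv[, 2] >= lo)
}

#' Per-haplotype genotype table for a variant catalog
#'
#' @param graph a `bdgraph`.
#' @param tree the `reference_tree`.
#' @param variants a [call_variants()] table.
#' @return list with matrices `CR`, `CA` (variants x haplotypes; NA =
#'   missing), character matrix `GT` (`"0"`, `"1"`, `"."`), and aggregate
#'   vectors `RC`, `AC`, `AN`. Haplotypes are ordered reference first.
#' @export
genotype_table <- function(graph, tree, variants) {
  haps <- unique(vapply(graph$walks, walk_hap_id, ""))
  ref_haps <- haps[startsWith(haps, paste0(graph$reference, "#"))]
  haps <- c(ref_haps, setdiff(haps, ref_haps))
  nv <- nrow(variants)
  CR <- matrix(0L, nv, length(haps), dimnames = list(NULL, haps))
  CA <- matrix(0L, nv, length(haps), dimnames = list(NULL, haps))

  vk <- variant_dir_keys(variants)
  rk <- vapply(variants$v, function(v) reference_edge_key(tree, v), "")
  rk[variants$vtype == "inversion"] <- NA_character_
  for (w in graph$walks) {
    hid <- walk_hap_id(w)
    keys <- walk_dir_keys(w)
    if (length(keys) == 0L) next
    tab <- table(keys)
    hit_a <- as.integer(tab[vk]); hit_a[is.na(hit_a)] <- 0L
    hit_r <- as.integer(tab[rk]); hit_r[is.na(hit_r)] <- 0L
    hit_r[is.na(rk)] <- 0L
    CA[, hid] <- CA[, hid] + hit_a
    CR[, hid] <- CR[, hid] + hit_r
  }
  RC <- as.integer(rowSums(CR)); AC <- as.integer(rowSums(CA))

  cov <- haplotype_coverage(graph, tree)
  comp <- graph_components(graph)
  for (h in haps) {
    cv <- cov[[h]]
    for (i in seq_len(nv)) {
      if (variant_missing(variants[i, ], cv, comp[[variants$u[i]]])) {
        CR[i, h] <- NA_integer_; CA[i, h] <- NA_integer_
      }
    }
  }
  GT <- matrix(".", nv, length(haps), dimnames = list(NULL, haps))
  GT[!is.na(CA) & CA > 0] <- "1"
  GT[!is.na(CA) & CA == 0] <- "0"
  list(haplotypes = haps, CR = CR, CA = CA, GT = GT,
       RC = RC, AC = AC, AN = RC + AC)
}

#' Reconstruct a walk from a genotype
#'
#' Inverts the genotype map for 0/1-valued genotypes whose variant-edge
#' visits admit a unique order: the walk follows the unique tree path from
#' `start` to the first visited edge's `u`, jumps to its `v`, and so on to
#' `end`. Inversion edges and repeated visits are outside this
#' reconstruction's scope. Infeasible genotypes raise a "no walk" error;
#' multiple feasible visit orders raise an ambiguity error rather than
#' guessing.
#'
#' @param genotype integer vector, one entry per variant (0 or 1).
#' @param start,end node ids of the walk's endpoints.
#' @param tree the `reference_tree`.
#' @param variants the [call_variants()] table the genotype refers to.
#' @return a [bd_walk()] (sample `"reconstructed"`).
#' @export
reconstruct_walk <- function(genotype, start, end, tree, variants) {
  stopifnot(length(genotype) == nrow(variants))
  check_tree_node(tree, start); check_tree_node(tree, end)
  if (any(genotype > 1L))
    stop("ambiguous genotype: repeated variant-edge visits are not supported")
  vis <- which(genotype == 1L)
  if (any(variants$vtype[vis] == "inversion"))
    stop("no walk: inversion edges cannot be reconstructed")
  k <- length(vis)
  feas_path <- function(a, b) is_ancestor(tree, a, b)
  perms <- if (k == 0L) list(integer(0)) else all_perms(vis)
  good <- list()
  for (p in perms) {
    ok <- TRUE
    prev <- start
    for (j in p) {
      if (!feas_path(prev, variants$u[j])) { ok <- FALSE; break }
      prev <- variants$v[j]
    }
    if (ok && !feas_path(prev, end)) ok <- FALSE
    if (ok) good[[length(good) + 1L]] <- p
  }
  if (length(good) == 0L) stop("no walk realizes this genotype between the given endpoints")
  if (length(good) > 1L) stop("ambiguous genotype: multiple feasible visit orders")
  p <- good[[1L]]
  nodes <- character(0)
  prev <- start
  for (j in p) {
    seg <- path_down(tree, prev, variants$u[j])
    nodes <- c(nodes, if (length(nodes)) seg[-1L] else seg)
    nodes <- c(nodes, variants$v[j])
    prev <- variants$v[j]
  }
  seg <- path_down(tree, prev, end)
  nodes <- c(nodes, if (length(nodes)) seg[-1L] else seg)
  bd_walk("reconstructed", 1L, tree$contig, nodes, tree$orientation[nodes])
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  if (length(x) > 7L) stop("too many visited variants to order")
  out <- list()
  for (i in seq_along(x))
    for (p in all_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}
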