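# GFA 1.0/1.1 reading and writing (S, L, W, P lines).
#
# W-lines are the preferred walk representation; P-lines are accepted and
# mapped to walks with haplotype index 0 (unphased). rGFA tags and GFA 2.0
# records are out of scope. Orientation in a GFA link `L a oa b ob` means:
# the edge joins the exit side of `a` traversed with `oa` to the entry side
# of `b` traversed with `ob`; this maps onto the canonical node-side pair
# representation, under which a link and its reverse-complement reading are
# one edge.

parse_walk_string <- function(s, line_no) {
  toks <- regmatches(s, gregexpr("[><][^><]+", s))[[1]]
  if (length(toks) == 0L || paste(toks, collapse = "") != s)
    stop(sprintf("GFA parse error at line %d: malformed walk string", line_no))
  list(nodes = substring(toks, 2L),
       orients = ifelse(substring(toks, 1L, 1L) == ">", "+", "-"))
}

#' Read a pangenome graph from a GFA file
#'
#' Accepts GFA 1.0/1.1 with S (segment), L (link), W (walk) and P (path)
#' lines. P-lines become walks with haplotype index 0. Sequences are
#' uppercased; non-ACGTN letters map to `N` with a warning.
#'
#' @param path path to a GFA file.
#' @param reference_name sample name of the linear-reference walk
#'   (must occur among the W/P lines if any walk lines are present).
#' @param contig contig label; defaults to the reference walk's SeqId when
#'   available.
#' @return a [bd_graph()] object.
#' @export
read_gfa <- function(path, reference_name = NA_character_, contig = NULL) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nodes <- character(0); node_ids <- character(0)
  ea <- c(); eas <- c(); eb <- c(); ebs <- c()
  walks <- list()
  ref_contig <- NULL

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rec <- f[[1]]
    if (rec == "H") next
    if (rec == "S") {
      if (length(f) < 3L)
        stop(sprintf("GFA parse error at line %d: S-line needs id and sequence", i))
      if (f[[3]] == "*")
        stop(sprintf("GFA parse error at line %d: S-line with '*' sequence unsupported", i))
      node_ids <- c(node_ids, f[[2]])
      nodes <- c(nodes, f[[3]])
    } else if (rec == "L") {
      if (length(f) < 5L || !all(c(f[[3]], f[[5]]) %in% c("+", "-")))
        stop(sprintf("GFA parse error at line %d: malformed L-line", i))
      if (length(f) >= 6L && !(f[[6]] %in% c("*", "0M")))
        stop(sprintf("GFA parse error at line %d: only blunt (0M/*) overlaps supported", i))
      ea <- c(ea, f[[2]]); eas <- c(eas, exit_side(f[[3]]))
      eb <- c(eb, f[[4]]); ebs <- c(ebs, entry_side(f[[5]]))
    } else if (rec == "W") {
      if (length(f) < 7L)
        stop(sprintf("GFA parse error at line %d: malformed W-line", i))
      wk <- parse_walk_string(f[[7]], i)
      walks[[length(walks) + 1L]] <-
        bd_walk(f[[2]], suppressWarnings(as.integer(f[[3]])), f[[4]],
                wk$nodes, wk$orients)
      if (!is.na(reference_name) && f[[2]] == reference_name && is.null(ref_contig))
        ref_contig <- f[[4]]
    } else if (rec == "P") {
      if (length(f) < 3L)
        stop(sprintf("GFA parse error at line %d: malformed P-line", i))
      steps <- strsplit(f[[3]], ",", fixed = TRUE)[[1]]
      o <- substring(steps, nchar(steps))
      if (!all(o %in% c("+", "-")))
        stop(sprintf("GFA parse error at line %d: malformed P-line step", i))
      walks[[length(walks) + 1L]] <-
        bd_walk(f[[2]], 0L, f[[2]], substring(steps, 1L, nchar(steps) - 1L), o)
      if (!is.na(reference_name) && f[[2]] == reference_name && is.null(ref_contig))
        ref_contig <- f[[2]]
    }
  }
  if (length(node_ids) == 0L) stop("GFA contains no S-lines: ", path)
  names(nodes) <- node_ids
  edges <- if (length(ea)) data.frame(a = ea, a_side = eas, b = eb, b_side = ebs,
                                      stringsAsFactors = FALSE) else NULL
  if (!is.null(edges)) {
    miss <- setdiff(unique(c(edges$a, edges$b)), node_ids)
    if (length(miss))
      stop("L-line references unknown segment(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  if (is.null(contig)) contig <- if (!is.null(ref_contig)) ref_contig else "chr1"
  bd_graph(nodes, edges, walks, reference_name, contig)
}

#' Write a pangenome graph to a GFA 1.1 file
#'
#' Emits S-lines (in node order), L-lines (canonical reading) and W-lines.
#' The written file re-parses to a structurally identical graph.
#'
#' @param graph a `bdgraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.1", con)
  ids <- names(graph$nodes)
  if (length(ids))
    writeLines(paste("S", ids, graph$nodes, sep = "\t"), con)
  if (nrow(graph$edges)) {
    e <- graph$edges
    # canonical end (a, a_side) is read as the link's source: leaving a via
    # a_side implies orientation; entering b via b_side likewise
    writeLines(paste("L", e$a, orient_exiting(e$a_side),
                     e$b, orient_entering(e$b_side), "0M", sep = "\t"), con)
  }
  for (w in graph$walks) {
    ws <- paste0(ifelse(w$orients == "+", ">", "<"), w$nodes, collapse = "")
    writeLines(paste("W", w$sample, w$hap, w$contig, 0,
                     sum(nchar(graph$nodes[w$nodes])), ws, sep = "\t"), con)
  }
  invisible(path)
}
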