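# Worked 11-node example graph.
#
# A small pangenome with a linear reference through nodes 1..6 and three
# variant edges under the forced reference tree:
#   * (1,4): a forward edge skipping nodes 2-3 -- a deletion;
#   * (7,8): a crossing edge between two off-reference branches -- a
#     replacement whose reference allele is off the linear reference;
#   * (9,3): a crossing edge closing an insertion branch back onto the
#     reference -- an insertion.
# The "green" haplotype routes 1-2-7-8-10-9-3-4-5-6 and has genotype
# [0,1,1] over the variant edges in catalog order (1,4), (7,8), (9,3).
# Two walks carry the insertion branch through nodes 11-8-10-9 so that the
# walk-support tie-break forces that branch into the tree (making node 7's
# two-base allele the alternative of the replacement).

#' The 11-node worked-example pangenome
#'
#' @return list with `graph` (a [bd_graph()]), and `expected`: the variant
#'   edges (`u`, `v`), their types, and the green walk's genotype.
#' @export
fig1_fixture <- function() {
  nodes <- c("1" = "AC", "2" = "GT", "3" = "C", "4" = "TA", "5" = "G",
             "6" = "CC", "7" = "TT", "8" = "AC", "9" = "GA", "10" = "T",
             "11" = "G")
  edges <- data.frame(
    a      = c("1", "2", "3", "4", "5", "1", "2", "7", "2", "11", "8", "10", "9"),
    a_side = rep("e", 13),
    b      = c("2", "3", "4", "5", "6", "4", "7", "8", "11", "8", "10", "9", "3"),
    b_side = rep("s", 13),
    stringsAsFactors = FALSE)
  fwd <- function(n) rep("+", n)
  walks <- list(
    bd_walk("GRCh38", 0L, "toy", as.character(1:6), fwd(6)),
    bd_walk("green", 1L, "toy",
            c("1", "2", "7", "8", "10", "9", "3", "4", "5", "6"), fwd(10)),
    bd_walk("alt_del", 1L, "toy", c("1", "4", "5", "6"), fwd(4)),
    bd_walk("alt_ins1", 1L, "toy",
            c("1", "2", "11", "8", "10", "9", "3", "4", "5", "6"), fwd(10)),
    bd_walk("alt_ins2", 1L, "toy",
            c("1", "2", "11", "8", "10", "9", "3", "4", "5", "6"), fwd(10)))
  graph <- bd_graph(nodes, edges, walks, reference = "GRCh38", contig = "toy")
  expected <- data.frame(
    u = c("1", "7", "9"), v = c("4", "8", "3"),
    vtype = c("deletion", "replacement", "insertion"),
    stringsAsFactors = FALSE)
  list(graph = graph, expected = expected,
       green_genotype = c(0L, 1L, 1L))
}
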