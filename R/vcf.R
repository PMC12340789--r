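# Extended VCF output. Canonical fields are kept but reinterpreted:
#
# * POS: for on-reference indels (insertion/deletion/duplication), the
#   position of node u — the base preceding the allele — with that base
#   prepended to both REF and ALT; otherwise one plus the position of u.
# * REF: must match the linear reference, so a variant whose reference
#   allele is off the linear reference gets REF '.' and carries the
#   tree-derived allele in the NR INFO field (no prepended base).
# * ID: the edge's oriented node ids in GFA style, e.g. ">7>8" ('<' for
#   reverse traversal).
# * QUAL is fixed at 60, FILTER at PASS; records are sorted by POS.
#
# INFO: NR, VT, DR (tree-edge distance of u and v from the reference path),
# RC, AC, AN, PV (= pos(u),pos(v)), TR_MOTIF, NIA. Per-haplotype FORMAT is
# GT:CR:CA with '.' for missing. Inversions carry no alleles in this
# version: REF '.', ALT '<INV>'.

PREPEND_TYPES <- c("insertion", "deletion", "duplication")

#' Build extended VCF records for a variant catalog
#'
#' @param graph a `bdgraph`.
#' @param tree the `reference_tree`.
#' @param variants a [call_variants()] table.
#' @param genotypes result of [genotype_table()] for the same catalog.
#' @return data frame of VCF columns plus one column per haplotype;
#'   attribute `unplaced` holds rows for variants in unanchored components
#'   (position -1), which are suppressed from the main file.
#' @export
vcf_records <- function(graph, tree, variants, genotypes) {
  nv <- nrow(variants)
  if (nv == 0L) {
    df <- data.frame(CHROM = character(), POS = integer(), ID = character(),
                     REF = character(), ALT = character(), QUAL = integer(),
                     FILTER = character(), INFO = character(),
                     FORMAT = character(), stringsAsFactors = FALSE)
    for (h in genotypes$haplotypes) df[[h]] <- character()
    attr(df, "unplaced") <- df
    return(df)
  }
  pos <- integer(nv); ref <- character(nv); alt <- character(nv)
  nr <- character(nv)
  base_at <- function(p) substring(tree$ref_seq, p, p)
  for (i in seq_len(nv)) {
    vt <- variants$vtype[i]
    if (vt == "inversion") {
      pos[i] <- variants$pos_u[i] + 1L
      ref[i] <- "."; alt[i] <- "<INV>"; nr[i] <- "."
    } else if (variants$non_reference[i]) {
      pos[i] <- variants$pos_u[i] + 1L
      ref[i] <- "."
      alt[i] <- if (nchar(variants$alt_seq[i])) variants$alt_seq[i] else "."
      nr[i] <- if (nchar(variants$ref_seq[i])) variants$ref_seq[i] else "."
    } else if (vt %in% PREPEND_TYPES) {
      pos[i] <- variants$pos_u[i]
      b <- base_at(pos[i])
      ref[i] <- paste0(b, variants$ref_seq[i])
      alt[i] <- paste0(b, variants$alt_seq[i])
      nr[i] <- "."
    } else {
      pos[i] <- variants$pos_u[i] + 1L
      ref[i] <- variants$ref_seq[i]
      alt[i] <- variants$alt_seq[i]
      nr[i] <- "."
    }
  }
  id <- paste0(ifelse(variants$u_or == "+", ">", "<"), variants$u,
               ifelse(variants$v_or == "+", ">", "<"), variants$v)
  info <- sprintf("NR=%s;VT=%s;DR=%s,%s;RC=%d;AC=%d;AN=%d;PV=%d,%d;TR_MOTIF=%s;NIA=%s",
                  nr, variants$vtype,
                  ifelse(is.na(tree$dr[variants$u]), ".",
                         as.character(tree$dr[variants$u])),
                  ifelse(is.na(tree$dr[variants$v]), ".",
                         as.character(tree$dr[variants$v])),
                  genotypes$RC, genotypes$AC, genotypes$AN,
                  variants$pos_u, variants$pos_v,
                  ifelse(nchar(variants$tr_motif) > 0, variants$tr_motif, "."),
                  ifelse(variants$nia, "yes", "no"))
  df <- data.frame(CHROM = graph$contig, POS = pos, ID = id, REF = ref,
                   ALT = alt, QUAL = 60L, FILTER = "PASS", INFO = info,
                   FORMAT = "GT:CR:CA", stringsAsFactors = FALSE)
  fmt_count <- function(x) ifelse(is.na(x), ".", as.character(x))
  for (h in genotypes$haplotypes)
    df[[h]] <- paste(genotypes$GT[, h], fmt_count(genotypes$CR[, h]),
                     fmt_count(genotypes$CA[, h]), sep = ":")
  unplaced <- variants$pos_u < 0 | variants$pos_v < 0
  main <- df[!unplaced, , drop = FALSE]
  main <- main[order(main$POS, main$ID), , drop = FALSE]
  rownames(main) <- NULL
  attr(main, "unplaced") <- df[unplaced, , drop = FALSE]
  main
}

vcf_header <- function(graph, tree, sample_cols) {
  c("##fileformat=VCFv4.2",
    "##source=pangtree",
    sprintf("##contig=<ID=%s,length=%d>", graph$contig, nchar(tree$ref_seq)),
    "##INFO=<ID=NR,Number=1,Type=String,Description=\"Reference-tree allele when the reference path is off the linear reference (REF is then '.'); '.' otherwise\">",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type: SNP, MNP, insertion, deletion, replacement, duplication, or inversion (inversions carry no alleles)\">",
    "##INFO=<ID=DR,Number=2,Type=String,Description=\"Distance from reference: number of reference-tree edges from node u and node v to their deepest linear-reference ancestor\">",
    "##INFO=<ID=RC,Number=1,Type=Integer,Description=\"Total traversals of the corresponding reference tree edge by all haplotype walks\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Total traversals of the variant edge by all haplotype walks\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total traversals of either edge (RC+AC)\">",
    "##INFO=<ID=PV,Number=2,Type=Integer,Description=\"Positions of variant-edge nodes u and v (last base of deepest reference ancestor; -1 if unanchored)\">",
    "##INFO=<ID=TR_MOTIF,Number=1,Type=String,Description=\"Tandem repeat motif when the indel is a local repeat expansion or contraction; '.' otherwise\">",
    "##INFO=<ID=NIA,Number=1,Type=String,Description=\"'yes' when both alleles are >=10 bp and differ by exactly one base\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"1 if CA>0, 0 if CA=0 and the site is covered, '.' if missing\">",
    "##FORMAT=<ID=CR,Number=1,Type=String,Description=\"Haplotype traversals of the reference tree edge (last edge of the reference path)\">",
    "##FORMAT=<ID=CA,Number=1,Type=String,Description=\"Haplotype traversals of the variant edge\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_cols), collapse = "\t"))
}

#' Write extended VCF records to a file
#'
#' @param records result of [vcf_records()] (sorted by POS).
#' @param path output path.
#' @param graph,tree the graph and tree the records came from (for header
#'   metadata).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, graph, tree) {
  if (is.unsorted(records$POS))
    stop("records must be sorted by POS")
  sample_cols <- setdiff(colnames(records),
                         c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER", "INFO", "FORMAT"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(vcf_header(graph, tree, sample_cols), con)
  if (nrow(records)) {
    body <- do.call(paste, c(unname(as.list(records)), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
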