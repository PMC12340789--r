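# Pangenome simulator with planted, ground-truth variants.
#
# A random linear reference is mutated by planting non-overlapping events
# (SNPs, small indels, large insertions/deletions, inversions, tandem
# duplications, an insertion carrying a nested SNP, and interlocking
# deletion pairs). The graph is then constructed *exactly*: the reference
# is split into segments at all event breakpoints, alternate segments and
# links are added, and each haplotype walk routes through the events it
# carries. Construction is deterministic given the seed, and every
# haplotype's walk concatenation equals the haplotype sequence built
# independently by direct string editing.

#' Simulation configuration
#'
#' @param reference_length reference length in bp.
#' @param n_haplotypes number of non-reference haplotypes (>= 3 when a
#'   nested insertion is requested, so the plain inner allele outnumbers
#'   the mutated one).
#' @param n_snp,n_small_indel,n_large_insertion,n_large_deletion numbers of
#'   planted events of each class.
#' @param n_inversion,n_tandem_dup,n_nested_insertion,n_interlocking_pair
#'   numbers of planted structural events (a nested insertion plants a SNP
#'   inside a large insertion; an interlocking pair plants two partially
#'   overlapping deletions on different haplotypes).
#' @param small_indel_max maximum small-indel length (bp).
#' @param large_insertion_len,large_deletion_len,inversion_len,
#'   tandem_dup_len,nested_insertion_len event lengths in bp.
#' @param fragments_per_haplotype number of contiguous walk fragments each
#'   non-reference haplotype is split into (assembly fragmentation).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(reference_length = 10000, n_haplotypes = 4,
                       n_snp = 20, n_small_indel = 5,
                       n_large_insertion = 0, n_large_deletion = 2,
                       n_inversion = 1, n_tandem_dup = 0,
                       n_nested_insertion = 1, n_interlocking_pair = 0,
                       small_indel_max = 5,
                       large_insertion_len = 300, large_deletion_len = 120,
                       inversion_len = 150, tandem_dup_len = 40,
                       nested_insertion_len = 60,
                       fragments_per_haplotype = 1, seed = 1) {
  cfg <- as.list(environment())
  rates <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(rates < 0)) stop("event counts must be >= 0")
  if (cfg$n_nested_insertion > 0 && cfg$n_haplotypes < 3)
    stop("nested insertions need at least 3 haplotypes")
  if (cfg$n_interlocking_pair > 0 && cfg$n_haplotypes < 2)
    stop("interlocking deletions need at least 2 haplotypes")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

# sample non-overlapping footprints [start, end] with a 3 bp gap
place_events <- function(lengths, L) {
  placed <- matrix(numeric(0), ncol = 2)
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in 1:2000) {
      s <- sample(3:(L - len - 3), 1L)
      e <- s + len - 1L
      if (nrow(placed) == 0L ||
          all(placed[, 2] + 3 < s | placed[, 1] - 3 > e)) {
        placed <- rbind(placed, c(s, e)); out[[i]] <- c(s, e); ok <- TRUE
        break
      }
    }
    if (!ok) stop("event placement failed: rates too high for reference length")
  }
  out
}

pick_carriers <- function(haps, k) sort(sample(haps, k))

#' Simulate a pangenome graph with planted variants
#'
#' @param config a [sim_config()].
#' @param gfa_path optional path; when given, the graph is written as GFA.
#' @return list with `graph` (a [bd_graph()]), `truth` (data frame of
#'   planted events: type, pos = last reference base before the allele,
#'   ref, alt, carriers, non_reference), and `hap_seqs` (haplotype
#'   sequences built independently by string editing; named by
#'   `sample#hap`).
#' @export
simulate_pangenome <- function(config, gfa_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  L <- config$reference_length
  refseq <- rand_dna(L)
  haps <- sprintf("S%02d", seq_len(config$n_haplotypes))
  max_carry <- max(1L, config$n_haplotypes %/% 2L)

  # event specs with footprints on the reference
  specs <- list()
  add_spec <- function(type, flen) {
    specs[[length(specs) + 1L]] <<- list(type = type, flen = flen)
  }
  for (i in seq_len(config$n_snp)) add_spec("SNP", 1L)
  for (i in seq_len(config$n_small_indel))
    add_spec(sample(c("small_ins", "small_del"), 1L),
             sample(seq_len(config$small_indel_max), 1L))
  for (i in seq_len(config$n_large_insertion)) add_spec("large_ins", 2L)
  for (i in seq_len(config$n_large_deletion))
    add_spec("large_del", config$large_deletion_len)
  for (i in seq_len(config$n_inversion))
    add_spec("inversion", config$inversion_len)
  for (i in seq_len(config$n_tandem_dup))
    add_spec("tandem_dup", config$tandem_dup_len)
  for (i in seq_len(config$n_nested_insertion)) add_spec("nested_ins", 2L)
  for (i in seq_len(config$n_interlocking_pair))
    add_spec("interlock", 3L * config$large_deletion_len)

  foot <- place_events(vapply(specs, function(s) as.integer(s$flen), 1L), L)
  ord <- order(vapply(foot, `[[`, 1, 1L))
  specs <- specs[ord]; foot <- foot[ord]

  # breakpoints (cut after base x) and per-event routing info
  cuts <- c(0L, L)
  events <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]; s <- foot[[i]][1]; e <- foot[[i]][2]
    ev <- list(type = sp$type, s = s, e = e)
    if (sp$type == "SNP") {
      cuts <- c(cuts, s - 1L, s)
      ev$ref_base <- substring(refseq, s, s)
      ev$alt_base <- other_base(ev$ref_base)
      ev$carriers <- pick_carriers(haps, sample(max_carry, 1L))
    } else if (sp$type == "small_ins" || sp$type == "large_ins") {
      cuts <- c(cuts, s)
      ev$ins_len <- if (sp$type == "small_ins") e - s + 1L else config$large_insertion_len
      ev$ins_seq <- rand_dna(ev$ins_len)
      ev$carriers <- pick_carriers(haps, sample(max_carry, 1L))
    } else if (sp$type == "small_del" || sp$type == "large_del") {
      cuts <- c(cuts, s - 1L, e)
      ev$carriers <- pick_carriers(haps, sample(max_carry, 1L))
    } else if (sp$type == "inversion") {
      cuts <- c(cuts, s - 1L, e)
      ev$carriers <- pick_carriers(haps, 1L)
    } else if (sp$type == "tandem_dup") {
      cuts <- c(cuts, s - 1L, e)
      ev$carriers <- pick_carriers(haps, sample(max_carry, 1L))
    } else if (sp$type == "nested_ins") {
      cuts <- c(cuts, s)
      l <- config$nested_insertion_len
      l1 <- max(1L, (l - 1L) %/% 2L); l3 <- max(1L, l - 1L - l1)
      ev$seq1 <- rand_dna(l1)
      ev$mid <- sample(c("A", "C", "G", "T"), 1L)
      ev$mid_alt <- other_base(ev$mid)
      ev$seq3 <- rand_dna(l3)
      cs <- pick_carriers(haps, 3L)
      ev$carriers <- cs            # all carry the insertion
      ev$snp_carriers <- cs[3L]    # one carries the inner SNP
    } else if (sp$type == "interlock") {
      dl <- (e - s + 1L) %/% 3L
      ev$a <- s - 1L; ev$b <- ev$a + dl; ev$c <- ev$b + dl; ev$d <- e
      cuts <- c(cuts, ev$a, ev$b, ev$c, ev$d)
      cs <- pick_carriers(haps, 2L)
      ev$carriers <- cs[1L]   # del1: (a, c]
      ev$carriers2 <- cs[2L]  # del2: (b, d]
    }
    events[[length(events) + 1L]] <- ev
  }
  cuts <- sort(unique(cuts))
  seg_start <- cuts[-length(cuts)] + 1L
  seg_end <- cuts[-1L]
  nseg <- length(seg_start)
  seg_of_start <- stats::setNames(seq_len(nseg), seg_start)
  seg_of_end <- stats::setNames(seq_len(nseg), seg_end)

  nodes <- substring(refseq, seg_start, seg_end)
  names(nodes) <- as.character(seq_len(nseg))
  next_id <- nseg
  new_node <- function(seq) {
    next_id <<- next_id + 1L
    nodes[as.character(next_id)] <<- seq
    as.character(next_id)
  }
  ea <- character(0); eas <- character(0); eb <- character(0); ebs <- character(0)
  add_edge <- function(n1, s1, n2, s2) {
    ea <<- c(ea, n1); eas <<- c(eas, s1); eb <<- c(eb, n2); ebs <<- c(ebs, s2)
  }
  for (j in seq_len(nseg - 1L))
    add_edge(as.character(j), "e", as.character(j + 1L), "s")

  # per-event alternate structure; `routes[[hap]]` collects (i1, i2, steps)
  routes <- lapply(stats::setNames(haps, haps), function(h) list())
  add_route <- function(hap, i1, i2, steps_n, steps_o) {
    routes[[hap]][[length(routes[[hap]]) + 1L]] <<-
      list(i1 = i1, i2 = i2, n = steps_n, o = steps_o)
  }
  truth <- list()
  add_truth <- function(type, pos, ref, alt, carriers, non_reference = FALSE) {
    truth[[length(truth) + 1L]] <<- data.frame(
      type = type, pos = pos, ref = ref, alt = alt,
      carriers = paste(carriers, collapse = ","),
      non_reference = non_reference, stringsAsFactors = FALSE)
  }
  seg_id <- function(i) as.character(i)

  for (ev in events) {
    if (ev$type == "SNP") {
      j <- seg_of_start[[as.character(ev$s)]]
      x <- new_node(ev$alt_base)
      add_edge(seg_id(j - 1L), "e", x, "s")
      add_edge(x, "e", seg_id(j + 1L), "s")
      for (h in ev$carriers) add_route(h, j, j, x, "+")
      add_truth("SNP", ev$s - 1L, ev$ref_base, ev$alt_base, ev$carriers)
    } else if (ev$type %in% c("small_ins", "large_ins")) {
      j <- seg_of_end[[as.character(ev$s)]]
      x <- new_node(ev$ins_seq)
      add_edge(seg_id(j), "e", x, "s")
      add_edge(x, "e", seg_id(j + 1L), "s")
      for (h in ev$carriers) add_route(h, j + 1L, j, x, "+")
      add_truth("insertion", ev$s, "", ev$ins_seq, ev$carriers)
    } else if (ev$type %in% c("small_del", "large_del")) {
      j1 <- seg_of_start[[as.character(ev$s)]]
      j2 <- seg_of_end[[as.character(ev$e)]]
      add_edge(seg_id(j1 - 1L), "e", seg_id(j2 + 1L), "s")
      for (h in ev$carriers) add_route(h, j1, j2, character(0), character(0))
      add_truth("deletion", ev$s - 1L, substring(refseq, ev$s, ev$e), "",
                ev$carriers)
    } else if (ev$type == "inversion") {
      j <- seg_of_start[[as.character(ev$s)]]
      stopifnot(seg_end[j] == ev$e)  # single segment by construction
      add_edge(seg_id(j - 1L), "e", seg_id(j), "e")
      add_edge(seg_id(j), "s", seg_id(j + 1L), "s")
      for (h in ev$carriers) add_route(h, j, j, seg_id(j), "-")
      add_truth("inversion", ev$s - 1L, NA_character_, NA_character_, ev$carriers)
      add_truth("inversion", ev$e, NA_character_, NA_character_, ev$carriers)
    } else if (ev$type == "tandem_dup") {
      j <- seg_of_start[[as.character(ev$s)]]
      add_edge(seg_id(j), "e", seg_id(j), "s")
      for (h in ev$carriers)
        add_route(h, j, j, c(seg_id(j), seg_id(j)), c("+", "+"))
      add_truth("duplication", ev$e, "", substring(refseq, ev$s, ev$e),
                ev$carriers)
    } else if (ev$type == "nested_ins") {
      j <- seg_of_end[[as.character(ev$s)]]
      i1 <- new_node(ev$seq1); i2 <- new_node(ev$mid)
      i2s <- new_node(ev$mid_alt); i3 <- new_node(ev$seq3)
      add_edge(seg_id(j), "e", i1, "s")
      add_edge(i1, "e", i2, "s"); add_edge(i1, "e", i2s, "s")
      add_edge(i2, "e", i3, "s"); add_edge(i2s, "e", i3, "s")
      add_edge(i3, "e", seg_id(j + 1L), "s")
      for (h in ev$carriers) {
        mid <- if (h %in% ev$snp_carriers) i2s else i2
        add_route(h, j + 1L, j, c(i1, mid, i3), c("+", "+", "+"))
      }
      add_truth("insertion", ev$s, "",
                paste0(ev$seq1, ev$mid, ev$seq3), ev$carriers)
      add_truth("SNP", ev$s, ev$mid, ev$mid_alt, ev$snp_carriers,
                non_reference = TRUE)
    } else if (ev$type == "interlock") {
      jA <- seg_of_start[[as.character(ev$a + 1L)]]  # (a,b]
      jB <- seg_of_start[[as.character(ev$b + 1L)]]  # (b,c]
      jC <- seg_of_start[[as.character(ev$c + 1L)]]  # (c,d]
      add_edge(seg_id(jA - 1L), "e", seg_id(jC), "s")       # del1 skips (a,c]
      add_edge(seg_id(jA), "e", seg_id(jC + 1L), "s")       # del2 skips (b,d]
      for (h in ev$carriers) add_route(h, jA, jB, character(0), character(0))
      for (h in ev$carriers2) add_route(h, jB, jC, character(0), character(0))
      add_truth("deletion", ev$a, substring(refseq, ev$a + 1L, ev$c), "",
                ev$carriers)
      add_truth("deletion", ev$b, substring(refseq, ev$b + 1L, ev$d), "",
                ev$carriers2)
    }
  }

  # haplotype walks: splice event routes into the reference segment chain
  walks <- list(bd_walk("REF", 0L, "chrS", as.character(seq_len(nseg)),
                        rep("+", nseg)))
  hap_seqs <- character(0)
  for (h in haps) {
    rt <- routes[[h]]
    if (length(rt)) rt <- rt[order(vapply(rt, `[[`, 1L, "i1"))]
    steps_n <- character(0); steps_o <- character(0)
    cur <- 1L
    for (r in rt) {
      if (r$i1 > cur) {
        steps_n <- c(steps_n, as.character(cur:(r$i1 - 1L)))
        steps_o <- c(steps_o, rep("+", r$i1 - cur))
      }
      steps_n <- c(steps_n, r$n); steps_o <- c(steps_o, r$o)
      cur <- r$i2 + 1L
    }
    if (cur <= nseg) {
      steps_n <- c(steps_n, as.character(cur:nseg))
      steps_o <- c(steps_o, rep("+", nseg - cur + 1L))
    }
    # independent sequence oracle: direct string editing, right to left
    seq <- refseq
    evs_h <- Filter(function(ev) h %in% c(ev$carriers, ev$carriers2,
                                          ev$snp_carriers), events)
    for (ev in rev(evs_h)) seq <- apply_event_string(seq, ev, h)
    hap_seqs[paste0(h, "#1")] <- seq

    nfrag <- min(max(1L, config$fragments_per_haplotype), length(steps_n))
    brk <- if (nfrag == 1L) list(seq_along(steps_n)) else
      split(seq_along(steps_n),
            cut(seq_along(steps_n), breaks = nfrag, labels = FALSE))
    for (part in brk) {
      walks[[length(walks) + 1L]] <-
        bd_walk(h, 1L, "chrS", steps_n[part], steps_o[part])
    }
  }

  graph <- bd_graph(nodes,
                    data.frame(a = ea, a_side = eas, b = eb, b_side = ebs,
                               stringsAsFactors = FALSE),
                    walks, reference = "REF", contig = "chrS")
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), pos = integer(), ref = character(),
               alt = character(), carriers = character(),
               non_reference = logical(), stringsAsFactors = FALSE)
  truth_df <- truth_df[order(truth_df$pos, truth_df$type), , drop = FALSE]
  rownames(truth_df) <- NULL
  if (!is.null(gfa_path)) write_gfa(graph, gfa_path)
  list(graph = graph, truth = truth_df, hap_seqs = hap_seqs,
       refseq = refseq, config = config)
}

# string-editing oracle for one event on one haplotype; events are applied
# right to left so earlier coordinates stay valid
apply_event_string <- function(seq, ev, hap) {
  splice <- function(s, e, repl)  # replace bases s..e (e < s inserts after e)
    paste0(substring(seq, 1L, s - 1L), repl,
           substring(seq, e + 1L, nchar(seq)))
  switch(ev$type,
    SNP = splice(ev$s, ev$e, ev$alt_base),
    small_ins = splice(ev$s + 1L, ev$s, ev$ins_seq),
    large_ins = splice(ev$s + 1L, ev$s, ev$ins_seq),
    small_del = splice(ev$s, ev$e, ""),
    large_del = splice(ev$s, ev$e, ""),
    inversion = splice(ev$s, ev$e, revcomp(substring(seq, ev$s, ev$e))),
    tandem_dup = splice(ev$e + 1L, ev$e, substring(seq, ev$s, ev$e)),
    nested_ins = splice(ev$s + 1L, ev$s,
                        paste0(ev$seq1,
                               if (hap %in% ev$snp_carriers) ev$mid_alt else ev$mid,
                               ev$seq3)),
    interlock = {
      if (hap %in% ev$carriers) splice(ev$a + 1L, ev$c, "")
      else if (hap %in% ev$carriers2) splice(ev$b + 1L, ev$d, "")
      else seq
    },
    seq)
}

#' Write a planted-truth catalog as a minimal VCF
#'
#' @param truth the `truth` data frame from [simulate_pangenome()].
#' @param path output path.
#' @param contig contig name.
#' @return `path`, invisibly.
#' @export
truth_vcf <- function(truth, path, contig = "chrS") {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pangtree-simulator",
               sprintf("##contig=<ID=%s>", contig),
               "##INFO=<ID=VT,Number=1,Type=String,Description=\"Planted event type\">",
               "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Carrier haplotypes\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t")), con)
  if (nrow(truth)) {
    ref <- ifelse(is.na(truth$ref) | truth$ref == "", ".", truth$ref)
    alt <- ifelse(is.na(truth$alt) | truth$alt == "", ".", truth$alt)
    writeLines(paste(contig, truth$pos, ".", ref, alt, 60, "PASS",
                     sprintf("VT=%s;CARRIERS=%s", truth$type, truth$carriers),
                     sep = "\t"), con)
  }
  invisible(path)
}
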