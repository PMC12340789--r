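---
title: "Defining variants in a pangenome graph against a reference tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining variants in a pangenome graph against a reference tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangtree)
```

## The model

A pangenome graph stores DNA on nodes; a haplotype is a *walk* that
traverses nodes in one of two orientations (the graph is bidirected,
respecting the symmetry between a sequence and its reverse complement).
Bubble-based variant definitions struggle exactly where pangenomes are most
useful: inside large insertions and tangled multiallelic regions, where two
non-reference sequences may differ by a single base that no linear-reference
coordinate can name.

`pangtree` instead fixes a **reference tree**: a spanning tree of the graph
that contains *every* node but only a subset of edges, and that includes the
linear-reference walk as one of its branches. The tree plays the role a
reference genome plays for linear calling — a point of comparison — while
the graph as a whole is analogous to a reference panel. Every graph edge
missing from the tree is a **variant edge**, and each variant edge is one
biallelic variant:

* the **branch point** of a non-inversion edge $(u, v)$ is the lowest common
  ancestor of $u$ and $v$ in the tree;
* the **reference allele** is the tree path from the branch point to $v$,
  excluding both ends; the **alternative allele** is the tree path from the
  branch point to $u$, excluding the branch point but including $u$;
* the **genotype of a walk** is the vector counting its traversals of each
  variant edge. Tree paths between two nodes are unique, so a walk is
  recoverable from its endpoints and its genotype — the variant edges act
  like a basis: differences between walks decompose uniquely over them.

Typing follows from tree topology: an edge that skips forward from an
ancestor to a descendant deletes the intervening path (deletion); one that
returns from a descendant to an ancestor re-traverses it (duplication); a
crossing edge with an empty reference allele is an insertion, otherwise a
replacement, refined to SNP (both alleles length 1) or MNP (equal lengths
> 1). Edges that cannot be traversed without flipping strand relative to
the tree's node orientations are inversions (see below).

Node positions make the catalog compatible with linear coordinates: the
position of a node is the last base of its deepest linear-reference ancestor
in the tree, so every variant edge carries an interval
$(\mathrm{pos}(u), \mathrm{pos}(v))$ even when both alleles lie entirely off
the linear reference.

## Worked example

```{r example}
fx <- fig1_fixture()
tree <- build_tree(fx$graph)
variants <- call_variants(fx$graph, tree)
variants[, c("u", "v", "vtype", "ref_seq", "alt_seq", "pos_u", "pos_v",
             "non_reference")]
green <- fx$graph$walks[[2]]
genotype_walk(green, variants, tree)
```

The replacement (7,8) lives between two off-reference branches: no
reference walk visits node 8, so its record gets `REF` `'.'` and carries the
tree-derived reference allele in the `NR` INFO field. This is the class of
variant that purely linear-reference approaches cannot express.

## Tree construction and its tunables

The tree is grown deterministically:

1. Four terminus nodes (two binodes with empty sequences) are added; the
   source binode connects to the first node of every walk, the sink binode
   to the last. The source anchors the root; walk boundaries and components
   disconnected from the reference hang off the termini rather than
   inventing positions. Edges into termini ("terminal edges") are excluded
   from the catalog — they mark assembly boundaries, not biology.
2. The linear-reference walk is seeded as a branch of the tree, which
   forces every reference edge to be a tree edge. The reference walk must
   be simple (the package refuses cyclic reference paths; per-chromosome
   graphs satisfy this).
3. Remaining nodes attach greedily through edges leaving the current tree
   via a node's exit side, so every root-to-node path is a traversable
   bidirected walk. Candidates are ranked by (a) the number of haplotype
   walk traversals of the edge, (b) shallower parent, (c) smaller numeric
   node id, (d) entry side `s` before `e`. Rule (a) is the scientifically
   load-bearing one: common haplotypes tend to follow tree paths, so common
   alleles become "reference" and rare ones "alternative".

Different legal tie-breaks give different trees and hence different (but
equally valid) variants; what is invariant is the *count* of non-terminal
variant edges, $|E| - (|V| - 1)$ per anchored component, which the test
suite checks across shuffled edge orders.

## Orientation and inversions

A spanning tree orients every node (the orientation implied by its unique
root path). We classify an edge as an inversion when its two ends attach to
two "out" sides or two "in" sides of tree-oriented nodes — equivalently,
when traversing it flips exactly one endpoint's orientation relative to the
tree. This formalization was chosen over the literal reading "an edge
between two nodes of different orientation" because the latter fails on the
common case where an inverted segment is a single shared node: both its
flanking edges connect forward-oriented reference nodes, yet each can only
be traversed by reversing strand mid-walk. Under our rule a simple planted
inversion yields exactly two inversion edges (delete the segment; insert
its reverse complement), both carried by the inverted haplotype, which is
the defining property we test. Inversion edges are reported individually
and never forcibly paired — pairing can fail around assembly gaps — and
they carry no allele fields; their VCF records use `ALT=<INV>` with
`REF='.'`, a declared convention. They are classified `large` by default.

## Genotypes, counts, and missingness

Per haplotype, `CA` counts traversals of the variant edge and `CR`
traversals of the last edge of the reference path (the tree edge into $v$,
in the direction entering $v$); aggregates are `AC`, `RC` and
`AN = AC + RC`. Assemblies are fragmented, so absence of both traversals
may mean a gap rather than a reference call: when the variant's position
interval lies entirely outside the union of a haplotype's walk coverage
intervals, `CR` and `CA` are missing. Coverage is the per-walk interval
`[min, max]` over anchored node positions — a position-based approximation
chosen over exhaustive traversal for cost. For variants in unanchored
components (position −1), missingness falls back to whether the haplotype
has any walk in that component, since positions are meaningless there.
`GT` is `1` if `CA > 0`, `.` if both counts are missing, and `0` otherwise —
including the covered-but-neither-edge case (e.g. a third allele through
the same region), which the stated rule leaves open; we close it as `0` so
that `GT` is missing exactly when both counts are.

`reconstruct_walk()` inverts the genotype map for 0/1 genotypes whose
variant visits admit a unique tree-descending order; repeated visits or
multiple feasible orders raise errors rather than guessing. The general
multiplicity-aware construction is an extension point.

## Superbubbles

The package detects level-0 pinch-point superbubbles from first principles
rather than consuming precomputed snarl files: an anchor is a node that the
reference visits and that every walk spanning its reference interval
visits exactly once in consistent orientation; bubbles are the regions
between consecutive anchors that contain at least one variant edge. Anchor
candidates are restricted to reference-path nodes — in a reference-anchored
graph every haplotype aligns at such pinch points, and it gives bubbles
well-defined linear coordinates. Variant edges are assigned to the bubble
whose member set contains both endpoints; the suite checks this is a
partition. Bubbles whose nodes are unanchored (position −1) are skipped and
reported via the `unassigned` attribute.

Two-variant (triallelic) bubbles are classified by applying the four rules
in order: *properly triallelic* (entry and exit both have total degree 3
inside the bubble), *overlapping* (exactly one does), *nested* (one variant
edge branches at the entry and ends at the exit), else *interlocking*.
"Degree" counts tree and variant edges within the bubble subgraph,
excluding edges that leave it — a declared convention. Ordered application
resolves the corner cases where a nested structure sits flush against a
bubble boundary and would otherwise match two rules. A bubble is an
*insertion* when entry and exit are adjacent via a tree edge, a *deletion*
when adjacent via a variant edge; if both edges exist it is reported as a
deletion with a warning (the tie is not specified anywhere and is rare).

## VCF encoding

The extended VCF keeps canonical semantics wherever possible: `REF` must
match the linear reference, so off-reference variants set `REF='.'` and
store the tree-derived allele in `NR`; on-reference indels get the usual
prepended flank base and `POS = pos(u)`, everything else
`POS = pos(u) + 1`. `DR` reports each node's distance from the reference
path measured in tree edges (base-pair distance would double-count shared
prefixes of branching paths; the choice is declared in the header).
Records for unanchored variants are suppressed from the main file and
returned via the `unplaced` attribute. One record per variant edge is
emitted — the representation is biallelic by construction, so multi-ALT
records never occur.

## The simulator

`simulate_pangenome()` is the package's ground-truth instrument. It drafts
a uniform-ACGT reference (default 10 kb), plants non-overlapping events —
SNPs, 1–5 bp indels, large insertions/deletions, inversions, tandem
duplications, an insertion with a nested SNP, interlocking deletion pairs —
and then builds the graph *exactly* by splitting the reference at all event
breakpoints, so recovery tests isolate the calling logic from aligner
artifacts. Carriers are minorities (at most half the haplotypes; inner
insertion alleles keep a strict plain-over-mutated majority) so that
walk-support tie-breaks make the planted reference route the tree route and
planted alleles are recovered verbatim. Each haplotype sequence is also
built independently by direct string editing, and tests require the walk
concatenation to reproduce it byte-for-byte.

What the simulator does *not* emulate: realistic mutation-rate spectra,
coalescent allele sharing between haplotypes, alignment or graph-induction
errors, overlapping events beyond the two named structures, and cyclic
reference paths. Passing recovery tests therefore demonstrates correctness
of the variant definition and calling machinery on faithful graphs, not
robustness to construction noise in real pangenomes.

Default study conditions used by the acceptance-style tests: 10 kb
reference, 4 haplotypes, 20 SNPs, 5 small indels, 2 large deletions
(120 bp), 1 inversion (150 bp), 1 nested insertion (60 bp); the tie-break
invariance property uses 100 rebuilds of 500 bp graphs with 2–5 SNPs and
optional structural events, and the genotype-basis check enumerates all
walks of graphs with at most 12 nodes. These sizes exercise every code path
while keeping the default suite fast.

## Numerical and degenerate-input choices

* Sequences are restricted to ACGTN; other IUPAC codes map to `N` with a
  warning, keeping SNP/MNP calls unambiguous.
* Variants whose two alleles are identical (degenerate) are dropped but
  counted, so edge-count invariants remain checkable.
* A non-tree edge is read in the direction walks actually traverse it; an
  edge traversed in both directions by different walks is emitted once in
  the majority direction and flagged `both_directions` (one variant per
  edge keeps the count invariant intact; the flag preserves the
  information).
* Repeat annotation returns the *shortest* period whose flank matches,
  scanning upstream before downstream; nearly identical alleles means both
  alleles ≥ 10 bp with Levenshtein distance exactly 1.
* `simplify_graph()` never removes reference-path nodes, so the retained
  reference stays connected; contraction only concatenates sequences, so
  total sequence length is conserved. The simplified graph drops walks —
  it is a visualization artifact, not an analysis substrate.

## Known limitations

One reference walk (one contig) per graph: multi-contig references should
be processed per component, mirroring per-chromosome extraction. Cyclic
reference paths are rejected. Walk reconstruction handles unique orderings
only. Hierarchical (level ≥ 1) bubbles are out of scope. Performance
targets are desk scale (graphs up to tens of thousands of nodes), not
whole-pangenome scale.
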