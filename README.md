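# pangtree

Reference-tree variant cataloguing for bidirected pangenome graphs.

## The problem

In a pangenome graph, nodes carry DNA sequences and each haplotype is a
walk through the graph. Structural variation makes many haplotypes align
poorly with any single linear reference, and bubble-based variant
definitions break down inside large insertions and tangled multiallelic
regions — two non-reference sequences can differ by a single base that has
no linear-reference coordinate at all. `pangtree` is for people who have a
pangenome graph in GFA (with W- or P-line haplotype walks) and want a
well-defined, biallelic, positioned, genotyped variant catalog out of it,
including variants whose reference allele is not on the linear reference.

## The method

`pangtree` defines variants against a **reference tree** `T`: a spanning
tree of the graph `G` that contains every node, includes the
linear-reference walk as a branch, and is rooted at a synthetic source
terminus. Every edge of `G` absent from `T` is a **variant edge** and is
one biallelic variant:

* the *branch point* of a non-inversion edge `(u, v)` is `lca_T(u, v)`;
* the reference allele is the tree path `branch → v` (both ends excluded),
  the alternative allele is `branch → u` (branch excluded, `u` included);
* edge types partition into deletion (`u` an ancestor of `v`), duplication
  (`v` an ancestor of `u`), insertion (crossing, empty reference allele),
  replacement / SNP / MNP (crossing, both alleles non-empty), and inversion
  (the edge cannot be traversed without flipping strand relative to the
  tree orientation);
* the node position `pos(u)` is the last base of `u`'s deepest
  linear-reference ancestor, so every variant has a coordinate interval
  `(pos(u), pos(v))` even off the linear reference;
* the genotype of a walk is its traversal count of each variant edge; a
  walk is recoverable from its endpoints plus genotype (the variant edges
  behave like a basis for differences between walks).

Per-haplotype fields `CA`/`CR` count traversals of the variant edge and of
the last reference-path edge, with position-interval missingness; the
catalog is serialized as an extended VCF (custom `NR`, `VT`, `DR`, `RC`,
`AC`, `AN`, `PV`, `TR_MOTIF`, `NIA` fields, `GT:CR:CA` sample columns).
Pinch-point superbubbles, a triallelic taxonomy
(properly-triallelic/overlapping/nested/interlocking), insertion/deletion
bubble classes, a visualization-oriented simplifier, and a planted-truth
pangenome simulator round out the package. See the vignette
(`vignettes/reference-tree-variants.Rmd`) for the full model description.

## Worked example

The package ships an 11-node example pangenome with a linear reference
through nodes 1–6, a deletion edge (1,4), an off-reference replacement
(7,8), and an insertion (9,3):

```r
library(pangtree)
fx <- fig1_fixture()
tree <- build_tree(fx$graph)
variants <- call_variants(fx$graph, tree)
variants[, c("u","v","vtype","ref_seq","alt_seq","pos_u","pos_v","non_reference")]
#>   u v       vtype ref_seq alt_seq pos_u pos_v non_reference
#> 1 1 4    deletion     GTC             2     7         FALSE
#> 2 7 8 replacement       G      TT     4     4          TRUE
#> 3 9 3   insertion          GACTGA     4     5         FALSE

genotype_walk(fx$graph$walks[[2]], variants, tree)  # the "green" haplotype
#> [1] 0 1 1
```

The green haplotype skips the deletion (entry 0), carries the replacement
and the insertion (entries 1 and 1). Writing the VCF:

```r
run_call(fx$graph, out = "toy.vcf")
#> 3 variants written to toy.vcf
#>   deletion     small=1 large=0
#>   insertion    small=1 large=0
#>   replacement  small=1 large=0
```

```text
toy  2  >1>4  CGTC  C        60  PASS  NR=.;VT=deletion;...;PV=2,7;...   GT:CR:CA ...
toy  4  >9>3  T     TGACTGA  60  PASS  NR=.;VT=insertion;...;PV=4,5;...  GT:CR:CA ...
toy  5  >7>8  .     TT       60  PASS  NR=G;VT=replacement;...;PV=4,4;.. GT:CR:CA ...
```

The third record is the off-reference variant: its reference allele `G` is
not on the linear reference, so `REF` is `'.'` and the allele lives in the
`NR` INFO field — the class of variant that motivates the whole approach.

A command-line front end is included:

```sh
Rscript inst/cli/pangtree.R call --gfa graph.gfa --reference GRCh38 --out out.vcf
Rscript inst/cli/pangtree.R bubbles  --gfa graph.gfa --reference GRCh38 --out bubbles.tsv
Rscript inst/cli/pangtree.R simplify --gfa graph.gfa --reference GRCh38 --out simple.gfa --min-allele-len 1000
Rscript inst/cli/pangtree.R simulate --out sim --seed 1
```

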