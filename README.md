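# radconcord

Concordance analysis of RADseq phylogenies across assembly parameters.

RADseq (restriction-site-associated DNA sequencing) assemblies depend
strongly on two pipeline parameters: the clustering similarity threshold
*c* used to call loci homologous, and the minimum number of accessions *m*
that must carry a locus for it to be retained. Raising *m* removes missing
data but discards loci and phylogenetic signal; lowering it keeps signal at
the cost of very sparse matrices. Studies therefore run the same accessions
through a grid of (*c*, *m*) settings and inference methods (concatenated
maximum likelihood, quartet-based coalescent methods) and ask which
relationships survive the sweep. `radconcord` is the analysis layer for
that workflow:

* **Locus-matrix diagnostics** — parse ipyrad-style `.loci` files, apply
  the *m* filter and the low-coverage accession filter, compute Table-style
  dataset statistics (total loci, mean loci per accession, variable sites,
  parsimony-informative sites), and pairwise shared/matching-locus
  matrices.
* **Rooting-subset selection** — pick outgroup accessions by shared-locus
  rules such as "shares ≥ 100 loci with ≥ 10 focal-genus accessions" or
  "has ≥ 2,000 total loci", the designs used to control missing-data
  artifacts when rooting.
* **Tree-ensemble summarization** — reduce many bootstrap-annotated trees
  to one classified summary tree. Every bipartition *b* observed in any
  analysis is graded against the ensemble:
  * `STRONG`: *b* resolved in every analysis with bootstrap support
    BSt > 90, allowing at most one analysis with BSt > 75;
  * `RESOLVED_VARIABLE`: *b* resolved in every analysis at any support,
    allowing at most one analysis where it is missing and every
    conflicting split there has BSt < 50;
  * `MAJORITY`: *b* resolved in a strict majority of analyses with no
    incompatible split resolved in as many or more;
  * `COLLAPSED`: none of the above — the region becomes a polytomy.
  Accepted splits are assembled greedily (class, then presence count, then
  mean support, then canonical key) into a possibly multifurcating tree
  whose construction is byte-reproducible.
* **Taxon cohesion** — monophyly of populations/subspecies/species on
  unrooted trees (split equality), tallies of strongly supported
  monophyletic groups across analyses, percent-change comparisons between
  parameter settings, and exact minimal-removal search for outlier
  accessions.
* **Synthetic studies** — a seeded generator produces a nested four-level
  taxonomy, a true tree with planted outlier accessions, NNI-perturbed
  analysis ensembles with support distributions for true versus perturbed
  branches, and locus matrices whose missingness decays with taxonomic
  distance — so the whole pipeline is testable without sequence archives.
* An inline-barcode FASTQ demultiplexer (fixed-length 5' barcodes, Hamming
  mismatch tolerance, conservative tie handling) covers the step upstream
  of assembly.

## Worked example

```r
library(radconcord)

cfg <- sim_config(seed = 42, n_individuals_per_population = 4, n_loci = 300)
sim <- simulate_all(cfg)          # taxonomy, truth, 10 analyses, loci

dataset_summary(sim$loci)
#> <dataset_summary> 96 accessions, 300 loci, 24 mean loci/accession,
#>                   9003 variable sites, 2963 PIS

n_loci(min_samples_filter(sim$loci, 8))   # the m = 8 filter
#> [1] 157

sm <- shared_loci(sim$loci, matching = FALSE)
summarize_sharing(sm, sim$taxonomy, "GenA")$mean_shared          # 2.3
summarize_sharing(sm, sim$taxonomy, "GenA", "GenB")$mean_shared  # 1.3

st <- build_summary_tree(sim$analyses)
st
#> <summary_tree> 96 tips over 10 analyses;
#>   branches: STRONG=90 RESOLVED_VARIABLE=2 MAJORITY=1 COLLAPSED=0

# the planted outlier accession is recovered exactly
po <- sim$truth$planted_outliers
find_outliers(st, tax_groups(sim$taxonomy, "population")[[po$source_population]],
              max_removals = 2)
#> $removals[[1]] "B_sp1_ss2_P2_i1"   $status "ok"
```

Interpretation: 300 simulated loci over 96 accessions are heavily
structured — within-genus accession pairs share on average nearly twice as
many loci as cross-genus pairs, and the *m* = 8 filter halves the matrix.
Summarizing the ten NNI-perturbed analyses recovers almost every true
branch as `STRONG` (supports were drawn from 91–100 on true branches), and
the one accession planted into a foreign clade is identified as the unique
minimal removal restoring its population's monophyly.

The same operations are scriptable from a shell through the thin CLI
wrapper:

```sh
Rscript inst/cli/radconcord.R run --config config.yaml --out out/
Rscript inst/cli/radconcord.R summarize --manifest out/analyses/manifest.tsv \
    --out summary/ --strong 90 --strong-exception 75 --gray-conflict 50
```

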