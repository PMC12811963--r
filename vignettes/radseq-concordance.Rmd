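---
title: "Methods: summarizing RADseq phylogenies across assembly parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summarizing RADseq phylogenies across assembly parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radconcord)
```

## The problem

Reduced-representation datasets trade marker number against completeness.
In an ipyrad-style assembly the clustering threshold *c* decides which
reads are homologous and the `min_samples_locus` parameter *m* decides how
much missingness a locus may carry before it is dropped. Neither choice is
innocent: tightening *m* from a few percent of accessions to half of them
can shrink a matrix from >100,000 loci to a few dozen, and with it the
number of strongly supported clades. The defensible summary of such a
study is therefore not any single tree but the set of relationships that
are stable across a parameter sweep and across inference methods.

`radconcord` implements that summary as a bipartition-level concordance
analysis, together with the locus-matrix filters and diagnostics that
define the sweep, monophyly accounting against a four-level taxonomy, and
a generator for synthetic studies with known truth.

## Locus-matrix operations

A `loci_dataset` maps, per locus, accession → aligned sequence. On top of
it:

* `min_samples_filter(ds, m)` retains exactly the loci carried by ≥ *m*
  accessions. This re-implements the assembly-side filter on parsed locus
  tables so it can be exercised and tested; equivalence with any
  particular assembler's internal filtering is *not* claimed (the
  assembler applies it before alignment trimming and paralog removal).
* `remove_low_coverage(ds, min_loci = 100)` drops accessions sequenced
  for fewer than `min_loci` loci, a standard manual pre-filter. It is a
  single pass with counts taken on the input: removal can empty loci, and
  we do not iterate the filter (the field practice it mirrors is a
  one-time removal).
* `dataset_summary()` counts variable and parsimony-informative sites.
  A state is an unambiguous nucleotide (A/C/G/T); gaps, `N` and IUPAC
  ambiguity codes are not states. This is the conservative convention;
  expanding ambiguities would count more sites but requires a model of
  what an ambiguity call means in the upstream consensus step.
* `shared_loci()` computes, for every accession pair, the number of loci
  both carry ("shared") and, optionally, the number of shared loci whose
  sequences agree at ≥ `identity_threshold` of the columns where both
  have unambiguous nucleotides ("matching", default threshold 1.0).
  "Matching" has no standard published definition, so the threshold is an
  explicit parameter and loci with zero comparable columns count as
  non-matching. Studies usually report only "shared" means; both layers
  are available.
* `coverage_percent(m, n)` is `100·m/n` rounded **half-up** to one
  decimal. Half-up (rather than R's banker's rounding) matches how such
  percentages are conventionally printed: 79 of 157 is 50.3, 4 of 157 is
  2.5. `percent_change()` uses the same convention at zero decimals.

### Rooting-subset selection

Outgroup sampling in sparse RADseq matrices is dangerous: with few shared
loci, rooting can be driven by shared missingness instead of signal.
`rooting_rule()` expresses the standard defensive designs — minimum shared
loci with a minimum number of partner accessions in a chosen scope, and/or
a minimum total locus count — and `select_rooting_accessions()` evaluates
them per accession with a per-genus report, so asymmetric designs
(filtering only the outgroup, or both genera) compose naturally. Rules
that instead demand very many shared loci with only a handful of partners
are expressible but documented as hazardous: they select for accessions
that share missing-data structure, which is exactly the artifact the
many-partner rules exist to avoid.

## Branch classification and the summary tree

All concordance is computed on unrooted bipartitions. For a candidate
split *b* and each analysis tree, *b* (restricted to that analysis's tips)
is either **present** (with that branch's bootstrap support), **absent**
(no incompatible split present — the region is simply unresolved there),
or **conflicting** (at least one incompatible split present; the maximum
support among them is recorded, the conservative reading of "the
conflicting relationship" in the singular). Analyses in which the
restriction is uninformative — they lack the relevant taxa — leave the
denominator entirely, because ensembles legitimately differ in a few
accessions.

The grades, in order of testing:

1. `STRONG`: present in all considered analyses with support > 90,
   allowing at most one analysis with support > 75 (both thresholds and
   the exception count are parameters of
   `classification_thresholds()`).
2. `RESOLVED_VARIABLE`: present in all analyses at any support, allowing
   at most one analysis where *b* is missing, provided every conflicting
   split there has support < 50 (vacuously true when the region is merely
   unresolved).
3. `MAJORITY`: present in a strict majority of analyses, and no
   incompatible split is present in as many or more analyses.
4. `COLLAPSED`: otherwise.

Three semantics deserve notice:

* **Unknown supports.** A branch may be resolved without a readable
  bootstrap label. Unknown support counts for *presence* but never
  satisfies a support threshold — neither the "> 90" of `STRONG` nor,
  symmetrically, the "< 50" of the gray exception (an unverifiable
  conflict blocks the exception). This is the conservative completion of
  the published rules, which do not discuss missing labels.
* **The exception counts.** The source rules say "with few exceptions";
  we implement configurable counts defaulting to one each, the reading
  that makes the footnotes exact.
* **The majority denominator.** A strict majority of *all* considered
  analyses is required, not merely of analyses that resolve the region;
  the alternative would let a split present in 2 of 10 analyses qualify.
  This is flagged as an interpretation and is a single comparison to
  change.

`build_summary_tree()` classifies every split observed anywhere in the
ensemble (restricted to the common tip set), then accepts candidates
greedily in priority order `STRONG` → `RESOLVED_VARIABLE` → `MAJORITY`,
within a class by descending presence count, then descending mean support,
then canonical key. The tie-break chain is total, so output is
byte-reproducible. A candidate incompatible with an accepted split is
dropped and logged. Accepted splits are pairwise compatible by
construction and assemble into a unique, possibly multifurcating tree;
`COLLAPSED` regions are polytomies — the *absence* of a branch, never an
annotated one. On ensembles of ≤ 8 tips the greedy acceptance is tested
against exhaustive enumeration of all maximal compatible subsets ranked by
the same priority; the two agree on every tested ensemble.

## Monophyly and outliers

On an unrooted tree a group is monophyletic iff some branch's bipartition
has one side exactly equal to the group (pendant branches serve for
complements of size one). Singletons and whole-tip-set groups are
*trivial*: counted as cohesive but excluded from tallies by default, since
published counts of "monophyletic taxa" do not state a singleton
convention and a pendant branch carries no bootstrap to be "strongly
supported" by. On multifurcating summary trees the same split-equality
rule applies, so an unresolved group is not monophyletic — consistent with
treating unresolved taxa as uncounted.

`find_outliers()` is an exact search: all subsets of the group up to
`max_removals`, smallest first, returning *all* co-minimal removal sets in
canonical order. Groups in these datasets are small (tens of accessions)
and real outliers are one or two tips, so exactness is affordable and
spares downstream interpretation from heuristic artifacts. The search
removes members of the group only; a foreign accession nested *inside* the
group's clade makes the group non-monophyletic in a way no within-group
removal can repair, and the function reports `none_within_budget` rather
than guessing.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all outputs are byte-identical
under a fixed seed (each generator stage derives its RNG stream from
`seed` plus a fixed offset).

* **Taxonomy**: `n_genera` (default 2, a focal genus plus an outgroup) ×
  species × subspecies × populations × individuals, with simulator-style
  codes (`GenA`, `A_sp1_ss2_P1_i1`).
* **True tree**: random bifurcating joins, nested so every taxonomy group
  is monophyletic; then `n_outlier_tips` accessions are regrafted as
  sister to a random accession of a population from a *different
  species*. Destination populations are never sources or reused, so each
  outlier disrupts exactly two groups per level and recovery is
  well-defined — the simulator plants clean, non-interacting anomalies on
  purpose.
* **Analysis ensembles**: each analysis applies Poisson(`perturbation_rate`,
  default 0.5) random NNI moves to the truth. NNI rather than SPR keeps
  perturbations local, which is what disagreements between assembly
  settings look like in practice, and exercises the classification
  boundaries. Branches whose split survives in the truth draw integer
  supports uniformly from 91–100; branches created by perturbation draw
  from 0–50. Those defaults put true branches above the `STRONG`
  threshold and perturbed ones below the gray-conflict ceiling *except*
  when a draw hits 50 exactly — deliberately leaving the boundary cases
  reachable. Metadata cycles over the canonical ten-analysis grid (ML and
  SVD over c80m04, c90m04, c90m08, c90m16, c95m04).
* **Loci**: per locus an origin population is drawn uniformly; accession
  *a* carries the locus with probability
  `coverage_mean · decay^d(a, origin)`, where `d` counts taxonomy levels
  of separation (0 within the population, 4 across genera). Missingness
  is therefore taxonomy-structured, not i.i.d. — loci drop out with
  phylogenetic distance, which is the central missing-data phenomenon
  under test. Defaults `coverage_mean = 0.5`, `decay = 0.5` give the
  realistic regime where mean per-accession coverage is a small fraction
  of total loci and within-genus sharing clearly exceeds cross-genus
  sharing; `decay = 0.2` produces the strong (> 3×) contrast used in the
  sharing tests. Sequences evolve down the true tree under uniform
  per-site substitution (`mutation_rate = 0.02` per branch, 64 bp loci) —
  enough to exercise variable/PIS counting; richer substitution models
  belong to the upstream inference this package consumes, not to it.
  `expected_pair_sharing()` gives the analytic expectation of the
  carriage model, and observed sharing is tested to sit within two
  standard errors of it.

What the generator does **not** emulate: coalescent gene-tree discordance
(perturbations are i.i.d. noise around one truth, not a species-tree
process), indels and alignment error, read-level artifacts, paralogy, and
any dependence of locus recovery on branch lengths. Passing the recovery
suites therefore shows the *bookkeeping* — classification, consensus
assembly, monophyly, outlier search — is correct under controlled
violations, not that any inference method would behave this way on real
reads.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes simulate/ingest → filter/stats → select-root →
summarize → monophyly from one YAML or list config, writing TSV/Newick/
JSON artifacts plus a manifest (package version, seed, config hash,
per-stage counts). Validation collects *all* config errors before
reporting. No output embeds a timestamp, so identical config + seed gives
byte-identical trees, tables and manifest — asserted by hashing whole
output directories twice in the tests. The CLI wrapper exits 0 on
success, 2 on config/usage errors, 3 on data-format errors and 4
otherwise.

The test suite sizes were chosen to finish in a couple of minutes on one
CPU while still being adversarial: 400 random trees of 4–50 tips against
the edge-deletion split oracle, 250 monophyly and 150 exhaustive outlier
verifications, 500 greedy-versus-exhaustive ensembles of 6–8 tips, 100
seeded recovery ensembles of 40 tips × 10 analyses (criterion: ≥ 95%
exact recovery; observed 100%), and 300–1,000-locus sharing simulations.

## Known limitations

* "Shared" versus "matching" loci: only presence-based sharing has a
  published reference value; the identity-verified layer is provided but
  its threshold is a modelling choice.
* The *m* filter operates on parsed locus tables; assembler-internal
  filtering interacts with other cleaning steps and may retain slightly
  different locus sets at the same *m*.
* Monophyly support on summary trees is the mean support of the witness
  branch across analyses, which is a summary statistic, not a bootstrap
  proportion.
* The exact outlier search is exponential in `max_removals`; budgets
  above ~3 on groups of more than ~25 tips are not sensible, and the
  planted-outlier recovery guarantees only cover non-interacting
  outliers.
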