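Package: radconcord
Title: Concordance Analysis of RADseq Phylogenies Across Assembly Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the sensitivity of RADseq phylogenies to
    assembly-parameter choices. Parses ipyrad-style locus files and applies
    the min_samples_locus (m) filter, computes coverage, variable-site,
    parsimony-informative-site and pairwise shared/matching-locus statistics,
    and selects outgroup accessions for rooting analyses by shared-locus
    rules. Summarizes ensembles of bootstrap-annotated trees from different
    assembly settings into a single classified consensus: branches are
    graded as strongly supported, resolved-but-variable, majority, or
    collapsed to polytomies according to bipartition presence and bootstrap
    thresholds across analyses. Includes monophyly and outlier-accession
    accounting against a four-level taxonomy, an inline-barcode FASTQ
    demultiplexer, and a seeded simulator that generates taxonomies,
    perturbed tree ensembles and structured-missingness locus matrices for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
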