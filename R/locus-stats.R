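#' Apply the min-samples-per-locus (m) filter
#'
#' Retains exactly those loci for which at least `m` accessions have
#' sequence data, mirroring the assembly-side `min_samples_locus` filter on
#' a parsed locus table. Locus order and the accession universe are
#' unchanged.
#'
#' @param ds A [loci_dataset()].
#' @param m Minimum number of accessions with data at a locus (>= 1).
#' @return The filtered `loci_dataset`.
#' @export
min_samples_filter <- function(ds, m) {
  stopifnot(inherits(ds, "loci_dataset"))
  if (length(m) != 1L || is.na(m) || m < 1) {
    abort_fmt("m must be a single count >= 1")
  }
  keep <- lengths(ds$loci) >= m
  loci_dataset(ds$loci[keep], accessions = ds$accessions)
}

#' Per-accession locus counts
#'
#' Number of loci in which each accession of the universe has a sequence
#' (the `sample_coverage` quantity); accessions with no loci report 0.
#'
#' @param ds A [loci_dataset()].
#' @return Named integer vector over the accession universe.
#' @export
accession_locus_counts <- function(ds) {
  stopifnot(inherits(ds, "loci_dataset"))
  counts <- setNames(integer(length(ds$accessions)), ds$accessions)
  seen <- unlist(lapply(ds$loci, names), use.names = FALSE)
  if (length(seen)) {
    tab <- table(seen)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Remove accessions sequenced for too few loci
#'
#' Drops every accession occurring in fewer than `min_loci` loci (default
#' 100, the usual manual pre-filter before phylogenetic analysis), deletes
#' them from every locus, and drops loci emptied by the removal. A single
#' pass is made: counts are taken on the input dataset.
#'
#' @param ds A [loci_dataset()].
#' @param min_loci Minimum locus count an accession must reach (>= 0).
#' @return A list with `dataset` (the reduced `loci_dataset`) and `removed`
#'   (named integer vector: removed accessions with their locus counts).
#' @export
remove_low_coverage <- function(ds, min_loci = 100) {
  stopifnot(inherits(ds, "loci_dataset"), min_loci >= 0)
  counts <- accession_locus_counts(ds)
  removed <- counts[counts < min_loci]
  keep <- setdiff(ds$accessions, names(removed))
  list(dataset = subset_accessions(ds, keep), removed = removed)
}

#' Restrict a locus dataset to an accession subset
#'
#' Deletes all other accessions from every locus and drops loci left empty;
#' the universe becomes `keep`.
#'
#' @param ds A [loci_dataset()].
#' @param keep Character vector of accession ids to retain.
#' @return The reduced `loci_dataset`.
#' @export
subset_accessions <- function(ds, keep) {
  stopifnot(inherits(ds, "loci_dataset"))
  keep <- unique(as.character(keep))
  loci <- lapply(ds$loci, function(l) l[names(l) %in% keep])
  loci_dataset(loci[lengths(loci) > 0L], accessions = keep)
}

# Per-column counts of unambiguous nucleotide states for one locus.
# Returns a 4 x L matrix of A/C/G/T counts; gaps, N and ambiguity codes
# are not states.
locus_state_counts <- function(seqs) {
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                ncol = length(seqs))
  vapply(c("A", "C", "G", "T"),
         function(b) rowSums(mat == b),
         numeric(nrow(mat)))
}

#' Dataset-level summary statistics
#'
#' The standard dataset descriptors for a locus matrix: accession count,
#' total loci, mean loci per accession, and the two site tallies. A
#' variable site is an aligned column with at least two distinct
#' unambiguous nucleotide states; a parsimony-informative site additionally
#' requires at least two states each present in at least two sequences.
#' Gaps, `N` and IUPAC ambiguity codes are not counted as states.
#'
#' @param ds A [loci_dataset()].
#' @return An object of class `dataset_summary`: list with `n_accessions`,
#'   `total_loci`, `mean_loci_per_accession`, `n_variable_sites`,
#'   `n_parsimony_informative_sites`, `n_columns`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "loci_dataset"))
  nvar <- 0L
  npis <- 0L
  ncol_total <- 0L
  for (l in ds$loci) {
    cc <- locus_state_counts(l)
    ncol_total <- ncol_total + nrow(cc)
    n_states <- rowSums(cc > 0L)
    nvar <- nvar + sum(n_states >= 2L)
    npis <- npis + sum(rowSums(cc >= 2L) >= 2L)
  }
  counts <- accession_locus_counts(ds)
  structure(list(n_accessions = length(ds$accessions),
                 total_loci = length(ds$loci),
                 mean_loci_per_accession =
                   if (length(counts)) mean(counts) else 0,
                 n_variable_sites = nvar,
                 n_parsimony_informative_sites = npis,
                 n_columns = ncol_total),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf(paste0("<dataset_summary> %d accessions, %d loci, ",
                     "%.0f mean loci/accession, %d variable sites, %d PIS\n"),
              x$n_accessions, x$total_loci,
              round_half_up(x$mean_loci_per_accession),
              x$n_variable_sites, x$n_parsimony_informative_sites))
  invisible(x)
}

#' Percent of the accession set covered by an m threshold
#'
#' The share of accessions a locus must cover to survive the `m` filter:
#' `100 * m / n`, rounded half-up to one decimal.
#'
#' @param m The min-samples threshold (1 <= m <= n).
#' @param n_accessions Number of accessions in the dataset.
#' @return Percentage with one decimal.
#' @export
coverage_percent <- function(m, n_accessions) {
  if (m < 1 || m > n_accessions) {
    abort_fmt("m must satisfy 1 <= m <= n_accessions (%d), got %s",
              n_accessions, format(m))
  }
  round_half_up(100 * m / n_accessions, 1)
}

# Pairwise identity of two aligned sequences over columns where both carry
# an unambiguous nucleotide; NA when no column is comparable.
pair_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(x[ok] == y[ok])
}

#' Pairwise shared- and matching-locus matrices
#'
#' For every pair of accessions, `shared` counts loci where both have
#' sequence data; `matching` additionally requires the two aligned
#' sequences to agree at a fraction `identity_threshold` or more of the
#' columns where both carry an unambiguous nucleotide. Shared loci with no
#' comparable column count as non-matching. Diagonals equal per-accession
#' locus counts.
#'
#' @param ds A [loci_dataset()].
#' @param identity_threshold Fraction in (0, 1]; default 1 (identical over
#'   comparable columns).
#' @param matching Compute the matching layer? (It is quadratic in carriers
#'   per locus; switch off for presence-only workflows.)
#' @return An object of class `shared_loci_matrix`: list with `accessions`,
#'   `shared`, `matching` (or `NULL`), `identity_threshold`.
#' @export
shared_loci <- function(ds, identity_threshold = 1.0, matching = TRUE) {
  stopifnot(inherits(ds, "loci_dataset"))
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort_fmt("identity_threshold must be in (0, 1]")
  }
  acc <- ds$accessions
  n <- length(acc)
  P <- matrix(0L, n, length(ds$loci), dimnames = list(acc, NULL))
  for (j in seq_along(ds$loci)) P[names(ds$loci[[j]]), j] <- 1L
  shared <- P %*% t(P)
  M <- NULL
  if (matching) {
    M <- matrix(0L, n, n, dimnames = list(acc, acc))
    for (l in ds$loci) {
      carriers <- names(l)
      if (length(carriers) < 2L) next
      prs <- combn(sort(carriers), 2L)
      for (k in seq_len(ncol(prs))) {
        i <- prs[1L, k]; j <- prs[2L, k]
        id <- pair_identity(l[[i]], l[[j]])
        if (!is.na(id) && id >= identity_threshold) {
          M[i, j] <- M[i, j] + 1L
          M[j, i] <- M[i, j]
        }
      }
    }
    diag(M) <- diag(shared)
  }
  structure(list(accessions = acc, shared = shared, matching = M,
                 identity_threshold = identity_threshold),
            class = "shared_loci_matrix")
}

#' Mean pairwise locus sharing within or between genera
#'
#' Averages the pairwise shared (or matching) locus counts over all
#' unordered within-genus pairs (`group_b = NULL`, `n(n-1)/2` pairs) or all
#' cross-genus pairs (`|A| * |B|` pairs).
#'
#' @param sm A [shared_loci()] matrix.
#' @param tax A [taxonomy_map()] covering the matrix accessions.
#' @param group_a Genus label of the (first) group.
#' @param group_b Optional second genus label for cross-group sharing.
#' @param layer `"shared"` (default) or `"matching"`.
#' @return List with `n_pairs`, `mean_shared`, `layer`, `groups`.
#' @export
summarize_sharing <- function(sm, tax, group_a, group_b = NULL,
                              layer = c("shared", "matching")) {
  stopifnot(inherits(sm, "shared_loci_matrix"))
  layer <- match.arg(layer)
  mat <- sm[[layer]]
  if (is.null(mat)) abort_fmt("matrix has no '%s' layer", layer)
  genus <- accession_groups(tax, sm$accessions, "genus")
  for (g in c(group_a, group_b)) {
    if (!g %in% tax$genus) abort_fmt("unknown genus label '%s'", g)
  }
  a <- sm$accessions[genus == group_a]
  if (length(a) == 0L) abort_fmt("no accessions of genus '%s' in the matrix", group_a)
  if (is.null(group_b)) {
    if (length(a) < 2L) abort_fmt("within-group sharing needs >= 2 accessions")
    sub <- mat[a, a, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    n_pairs <- length(a) * (length(a) - 1L) / 2
  } else {
    b <- sm$accessions[genus == group_b]
    if (length(b) == 0L) abort_fmt("no accessions of genus '%s' in the matrix", group_b)
    vals <- as.vector(mat[a, b, drop = FALSE])
    n_pairs <- length(a) * length(b)
  }
  list(n_pairs = n_pairs, mean_shared = mean(vals), layer = layer,
       groups = c(group_a, group_b %||% group_a))
}

#' Define a rooting-accession selection rule
#'
#' Encodes the shared-locus criteria used to pick accessions for rooting
#' datasets, e.g. "shared >= 100 loci with >= 10 accessions of the focal
#' genus" or "had >= 2000 total sequenced loci". At least one criterion must
#' be set; the shared-locus pair must be set together.
#'
#' Low partner-count variants that instead demand very many shared loci
#' (e.g. >= 500) with a handful of partners are expressible but are known to
#' select for shared missing-data structure rather than signal, and can
#' produce spurious rooting topologies; prefer many-partner rules.
#'
#' @param min_shared_loci Minimum shared loci with a partner accession.
#' @param min_partner_accessions Minimum number of partners reaching
#'   `min_shared_loci`.
#' @param partner_scope Where partners are counted: `"other_genus"` (the
#'   genus the accession does not belong to), `"focal_genus"`, or `"any"`.
#' @param min_total_loci Minimum total sequenced loci for the accession.
#' @return An object of class `rooting_rule`.
#' @export
rooting_rule <- function(min_shared_loci = NULL, min_partner_accessions = NULL,
                         partner_scope = c("other_genus", "focal_genus", "any"),
                         min_total_loci = NULL) {
  partner_scope <- match.arg(partner_scope)
  if (xor(is.null(min_shared_loci), is.null(min_partner_accessions))) {
    abort_fmt("min_shared_loci and min_partner_accessions must be set together")
  }
  if (is.null(min_shared_loci) && is.null(min_total_loci)) {
    abort_fmt("a rooting rule needs at least one criterion")
  }
  for (v in c(min_shared_loci, min_partner_accessions, min_total_loci)) {
    if (!is.null(v) && v < 0) abort_fmt("rule counts must be >= 0")
  }
  structure(list(min_shared_loci = min_shared_loci,
                 min_partner_accessions = min_partner_accessions,
                 partner_scope = partner_scope,
                 min_total_loci = min_total_loci),
            class = "rooting_rule")
}

#' Select accessions for a rooting dataset
#'
#' Evaluates a [rooting_rule()] for every accession of the focal and
#' outgroup genera present in the dataset and returns those satisfying all
#' set criteria. The per-accession report is broken down by genus and
#' criterion, so asymmetric designs (filtering outgroup accessions only, or
#' both genera) can be composed by the caller.
#'
#' @param ds A [loci_dataset()].
#' @param tax A [taxonomy_map()].
#' @param rule A [rooting_rule()].
#' @param focal_genus,outgroup_genus Genus labels.
#' @param sm Optional precomputed [shared_loci()] matrix (presence layer is
#'   enough).
#' @return List with `selected` (character vector) and `report`
#'   (data.frame: accession, genus, locus_count, partners_meeting,
#'   pass_total, pass_shared, selected).
#' @export
select_rooting_accessions <- function(ds, tax, rule, focal_genus,
                                      outgroup_genus, sm = NULL) {
  stopifnot(inherits(ds, "loci_dataset"), inherits(rule, "rooting_rule"))
  sm <- sm %||% shared_loci(ds, matching = FALSE)
  genus <- accession_groups(tax, sm$accessions, "genus")
  for (g in c(focal_genus, outgroup_genus)) {
    if (!g %in% tax$genus) abort_fmt("unknown genus label '%s'", g)
  }
  cand <- sm$accessions[genus %in% c(focal_genus, outgroup_genus)]
  counts <- diag(sm$shared)[match(cand, sm$accessions)]
  partners_of <- function(a) {
    g <- genus[[a]]
    pool <- switch(rule$partner_scope,
      other_genus = cand[genus[cand] == setdiff(c(focal_genus, outgroup_genus), g)],
      focal_genus = cand[genus[cand] == focal_genus],
      any = cand)
    setdiff(pool, a)
  }
  n_meeting <- vapply(cand, function(a) {
    if (is.null(rule$min_shared_loci)) return(NA_integer_)
    p <- partners_of(a)
    sum(sm$shared[a, p] >= rule$min_shared_loci)
  }, integer(1L))
  pass_total <- if (is.null(rule$min_total_loci)) rep(TRUE, length(cand)) else
    counts >= rule$min_total_loci
  pass_shared <- if (is.null(rule$min_shared_loci)) rep(TRUE, length(cand)) else
    n_meeting >= rule$min_partner_accessions
  sel <- pass_total & pass_shared
  report <- data.frame(accession = cand, genus = unname(genus[cand]),
                       locus_count = as.integer(counts),
                       partners_meeting = n_meeting,
                       pass_total = pass_total, pass_shared = pass_shared,
                       selected = sel, stringsAsFactors = FALSE,
                       row.names = NULL)
  list(selected = cand[sel], report = report)
}
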