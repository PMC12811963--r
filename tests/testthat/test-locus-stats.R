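# m-filter, coverage, site statistics, sharing matrices, rooting selection.

toy_ds <- function() {
  loci_dataset(list(
    c(A = "ACGT", B = "ACGT", C = "ACGA", D = "ACGT"),  # coverage 4
    c(A = "GGTT", B = "GGTA"),                          # coverage 2
    c(A = "TTAA")),                                     # coverage 1
    accessions = c("A", "B", "C", "D"))
}

test_that("min-samples filter keeps exactly loci with >= m accessions", {
  ds <- toy_ds()
  f2 <- min_samples_filter(ds, 2)
  expect_equal(lengths(f2$loci), c(4L, 2L))
  expect_identical(min_samples_filter(ds, 1)$loci, ds$loci)
  expect_equal(n_loci(min_samples_filter(ds, 5)), 0L)
  expect_equal(min_samples_filter(ds, 5)$accessions, ds$accessions)
  expect_error(min_samples_filter(ds, 0), "m must be")
})

test_that("m-filter is monotone: larger m gives nested locus subsets", {
  set.seed(3)
  for (rep in 1:10) {
    ds <- rand_loci(n_acc = 10, n_loci = 40)
    prev <- ds
    prev_keys <- seq_len(n_loci(ds))
    for (m in c(2, 4, 6, 8)) {
      f <- min_samples_filter(ds, m)
      keys <- which(lengths(ds$loci) >= m)
      expect_true(all(keys %in% prev_keys))
      prev_keys <- keys
      # counts only ever decrease under filtering
      expect_true(all(accession_locus_counts(f) <= accession_locus_counts(ds)))
    }
  }
})

test_that("low-coverage accession removal follows the locus-count threshold", {
  ds <- toy_ds()
  r <- remove_low_coverage(ds, min_loci = 2)
  expect_setequal(names(r$removed), c("C", "D"))
  expect_equal(r$dataset$accessions, c("A", "B"))
  # loci emptied by removal are dropped
  expect_equal(n_loci(r$dataset), 3L)
  r0 <- remove_low_coverage(ds, min_loci = 0)
  expect_identical(r0$dataset$loci, ds$loci)
  expect_length(r0$removed, 0L)
  rall <- remove_low_coverage(ds, min_loci = 99)
  expect_equal(n_loci(rall$dataset), 0L)
  expect_setequal(names(rall$removed), c("A", "B", "C", "D"))
})

test_that("an accession one locus short of the threshold is removed", {
  loci <- c(lapply(1:99, function(i) c(low = "ACGT", hi = "ACGT")),
            lapply(1:21, function(i) c(hi = "ACGT", other = "ACGT")))
  ds <- loci_dataset(loci)
  r <- remove_low_coverage(ds, min_loci = 100)
  expect_true("low" %in% names(r$removed))
  expect_equal(unname(r$removed["low"]), 99L)
  expect_false("hi" %in% names(r$removed))
})

test_that("locus counts sum to the per-locus coverages", {
  ds <- toy_ds()
  counts <- accession_locus_counts(ds)
  expect_equal(counts, c(A = 3L, B = 2L, C = 1L, D = 1L))
  expect_equal(sum(counts), sum(lengths(ds$loci)))
  empty <- loci_dataset(list(), accessions = c("A", "B"))
  expect_equal(accession_locus_counts(empty), c(A = 0L, B = 0L))
})

test_that("variable and parsimony-informative sites follow their definitions", {
  # columns: AACC (PIS), AAAC (variable only), AAAA, A-AC (variable only)
  ds <- loci_dataset(list(c(w = "AAAA", x = "AAA-", y = "CAAA", z = "CCAC")))
  s <- dataset_summary(ds)
  expect_equal(s$n_variable_sites, 3L)
  expect_equal(s$n_parsimony_informative_sites, 1L)
  ident <- loci_dataset(list(c(a = "ACGT", b = "ACGT", c = "ACGT")))
  si <- dataset_summary(ident)
  expect_equal(si$n_variable_sites, 0L)
  expect_equal(si$n_parsimony_informative_sites, 0L)
})

test_that("site statistics match the per-column oracle on random alignments", {
  set.seed(21)
  for (rep in 1:25) {
    ds <- rand_loci(n_acc = 6, n_loci = 10, len = 12)
    s <- dataset_summary(ds)
    oracle <- rowSums(vapply(ds$loci, oracle_site_counts, numeric(2)))
    expect_equal(s$n_variable_sites, unname(oracle["variable"]))
    expect_equal(s$n_parsimony_informative_sites, unname(oracle["pis"]))
    expect_lte(s$n_parsimony_informative_sites, s$n_variable_sites)
    expect_lte(s$n_variable_sites, s$n_columns)
    expect_lte(s$mean_loci_per_accession, s$total_loci)
  }
})

test_that("coverage percents round half-up to one decimal", {
  expect_equal(coverage_percent(4, 157), 2.5)
  expect_equal(coverage_percent(8, 157), 5.1)
  expect_equal(coverage_percent(16, 157), 10.2)
  expect_equal(coverage_percent(32, 157), 20.4)
  expect_equal(coverage_percent(79, 157), 50.3)
  expect_equal(coverage_percent(157, 157), 100.0)
  expect_error(coverage_percent(158, 157), "m must satisfy")
})

test_that("shared-locus matrices equal the presence-matrix oracle", {
  set.seed(5)
  for (rep in 1:8) {
    ds <- rand_loci(n_acc = sample(4:12, 1), n_loci = sample(20:60, 1))
    sm <- shared_loci(ds, matching = FALSE)
    expect_equal(sm$shared, oracle_shared(ds))
    expect_true(isSymmetric(sm$shared))
    expect_equal(diag(sm$shared), accession_locus_counts(ds)[ds$accessions])
  }
})

test_that("matching layer is bounded by shared and exact at identity 1", {
  ds <- loci_dataset(list(
    c(A = "ACGT", B = "ACGT"),    # identical -> matching
    c(A = "ACGT", B = "ACGA"),    # 3/4 identity -> not matching at 1.0
    c(A = "NNNN", B = "----"),    # no comparable columns -> non-matching
    c(A = "ACGT", C = "ACGT")))
  sm <- shared_loci(ds, identity_threshold = 1.0)
  expect_equal(sm$shared["A", "B"], 3L)
  expect_equal(sm$matching["A", "B"], 1L)
  expect_equal(sm$matching["A", "C"], 1L)
  expect_true(all(sm$matching <= sm$shared))
  # lower threshold admits the 0.75-identity locus
  sm75 <- shared_loci(ds, identity_threshold = 0.75)
  expect_equal(sm75$matching["A", "B"], 2L)
  # identical sequences everywhere: matching == shared
  ds2 <- loci_dataset(list(c(A = "AAAA", B = "AAAA"), c(A = "CCCC", B = "CCCC")))
  sm2 <- shared_loci(ds2)
  expect_equal(sm2$matching, sm2$shared)
})

test_that("pair counts and means follow the within/cross formulas", {
  tax <- toy_taxonomy()
  ds <- loci_dataset(list(
    c(camA1 = "AAAA", camA2 = "AAAA", camB1 = "AAAA"),
    c(camA1 = "CCCC", camB1 = "CCCC", outX1 = "CCCC"),
    c(outX1 = "GGGG", outX2 = "GGGG")),
    accessions = tax$accession)
  sm <- shared_loci(ds, matching = FALSE)
  within <- summarize_sharing(sm, tax, "Cam")
  expect_equal(within$n_pairs, 6)  # 4 choose 2
  cross <- summarize_sharing(sm, tax, "Cam", "Out")
  expect_equal(cross$n_pairs, 8)  # 4 x 2
  # two-member within group: the single pair's count
  tax2 <- taxonomy_map(data.frame(accession = c("outX1", "outX2"),
                                  population = "PX", subspecies = "sx",
                                  species = "spX", genus = "Out"))
  sm2 <- shared_loci(subset_accessions(ds, c("outX1", "outX2")),
                     matching = FALSE)
  w2 <- summarize_sharing(sm2, tax2, "Out")
  expect_equal(w2$n_pairs, 1)
  expect_equal(w2$mean_shared, 1)
  expect_error(summarize_sharing(sm, tax, "Nope"), "unknown genus")
})

test_that("rooting rules validate their criteria", {
  expect_error(rooting_rule(), "at least one criterion")
  expect_error(rooting_rule(min_shared_loci = 3), "set together")
  expect_error(rooting_rule(min_total_loci = -1), ">= 0")
  r <- rooting_rule(min_shared_loci = 100, min_partner_accessions = 10)
  expect_s3_class(r, "rooting_rule")
})

test_that("rooting selection matches an exhaustive check on a toy matrix", {
  tax <- toy_taxonomy()
  # camA1/camA2 share >= 3 loci with both outgroup accessions; camB* share none
  mk <- function(...) c(...)
  loci <- c(
    lapply(1:3, function(i) mk(camA1 = "AAAA", camA2 = "AAAA",
                               outX1 = "AAAA", outX2 = "AAAA")),
    lapply(1:2, function(i) mk(camA2 = "AAAA", outX1 = "AAAA")),
    list(mk(camB1 = "AAAA", camB2 = "AAAA")))
  ds <- loci_dataset(loci, accessions = tax$accession)
  sm <- shared_loci(ds, matching = FALSE)
  rule <- rooting_rule(min_shared_loci = 3, min_partner_accessions = 2)
  sel <- select_rooting_accessions(ds, tax, rule, "Cam", "Out")
  # exhaustive: which accessions share >= 3 loci with >= 2 other-genus partners
  genus <- setNames(tax$genus, tax$accession)
  expected <- Filter(function(a) {
    partners <- tax$accession[genus[tax$accession] != genus[[a]]]
    sum(sm$shared[a, partners] >= 3) >= 2
  }, rownames(sm$shared))
  expect_setequal(sel$selected, expected)
  expect_setequal(sel$selected, c("camA1", "camA2", "outX1", "outX2"))
  # pure total-loci rules
  all_in <- select_rooting_accessions(ds, tax, rooting_rule(min_total_loci = 0),
                                      "Cam", "Out")
  expect_setequal(all_in$selected, tax$accession)
  none <- select_rooting_accessions(ds, tax, rooting_rule(min_total_loci = 2000),
                                    "Cam", "Out")
  expect_length(none$selected, 0L)
})

test_that("rooting selection is idempotent on its own induced dataset", {
  set.seed(9)
  tax <- toy_taxonomy()
  for (rep in 1:10) {
    loci <- lapply(1:40, function(i) {
      who <- sample(tax$accession, sample(2:6, 1))
      setNames(rep("ACGT", length(who)), who)
    })
    ds <- loci_dataset(loci, accessions = tax$accession)
    rule <- rooting_rule(min_shared_loci = 2, min_partner_accessions = 2)
    s1 <- select_rooting_accessions(ds, tax, rule, "Cam", "Out")
    if (length(s1$selected) < 2) next
    ds2 <- subset_accessions(ds, s1$selected)
    s2 <- select_rooting_accessions(ds2, tax, rule, "Cam", "Out")
    expect_true(all(s2$selected %in% s1$selected))
  }
})
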