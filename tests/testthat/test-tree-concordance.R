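# Bipartition extraction, compatibility, branch classification, summary
# trees, induced group trees and cross-level consistency.

mk <- function(nwk, id = "a") read_analysis_tree(nwk, analysis_id = id)

strong_base <- function(s1 = 95, s2 = 95) {
  sprintf("(((A,B)%d,(C,D)%d)99,(E,F)99)99;", s1, s2)
}

ten <- function(nwk10 = NULL, base = strong_base()) {
  out <- lapply(1:10, function(i) mk(base, paste0("a", i)))
  if (!is.null(nwk10)) out[[10]] <- mk(nwk10, "a10")
  out
}

ab <- bipartition(c("A", "B"), c("C", "D", "E", "F"))

test_that("bipartition extraction matches the edge-deletion oracle", {
  set.seed(13)
  expect_equal(vapply(bipartitions(mk("((A,B),(C,D));"))$bips, `[[`, "", "key"),
               "A,B|C,D")
  cat5 <- bipartitions(mk("(((((A,B),C),D),E));"))
  expect_length(cat5$bips, 2L)
  star <- bipartitions(mk("(A,B,C,D,E,F);"))
  expect_length(star$bips, 0L)
  for (rep in 1:60) {
    phy <- rand_support_tree(sample(4:50, 1))
    keys <- sort(vapply(bipartitions(phy)$bips, `[[`, "", "key"))
    expect_identical(keys, oracle_split_keys(phy))
    expect_length(keys, length(phy$tip.label) - 3L)
  }
})

test_that("split compatibility follows the intersection rule", {
  b1 <- bipartition(c("A", "B"), c("C", "D", "E"))
  b2 <- bipartition(c("A", "B", "C"), c("D", "E"))
  b3 <- bipartition(c("A", "C"), c("B", "D", "E"))
  expect_true(are_compatible(b1, b2))
  expect_true(are_compatible(b2, b1))
  expect_false(are_compatible(b1, b3))
  expect_false(are_compatible(b3, b1))
  expect_true(are_compatible(b1, b1))
  b4 <- bipartition(c("A", "B"), c("C", "D"))
  expect_error(are_compatible(b1, b4), "different universes")
})

test_that("splits of one tree are pairwise compatible and reconstruct it", {
  set.seed(17)
  for (rep in 1:25) {
    phy <- rand_support_tree(sample(4:30, 1), p_na = 0)
    bp <- bipartitions(phy)$bips
    for (i in seq_along(bp)) {
      for (j in seq_len(i)) expect_true(are_compatible(bp[[i]], bp[[j]]))
    }
    # feeding the tree's own splits back through the summarizer is identity
    at <- analysis_tree(phy, analysis_id = "self")
    st <- build_summary_tree(list(at, at))
    expect_setequal(st$splits$key, vapply(bp, `[[`, "", "key"))
    expect_identical(sort(vapply(bipartitions(st)$bips, `[[`, "", "key")),
                     oracle_split_keys(phy))
  }
})

test_that("restriction intersects sides and flags degenerate results", {
  b <- bipartition(c("A", "B"), c("C", "D", "E"))
  r1 <- restrict_bipartition(b, c("A", "B", "C", "D"))
  expect_equal(r1$key, "A,B|C,D")
  expect_true(is_degenerate(restrict_bipartition(b, c("A", "C", "D"))))
  expect_error(restrict_bipartition(b, character(0)), "empty")
  expect_error(restrict_bipartition(b, c("A", "Z")), "not a subset")
  # composition: restricting twice equals one restriction to the intersection
  set.seed(19)
  for (rep in 1:50) {
    u <- sprintf("t%02d", 1:10)
    side <- sample(u, sample(3:7, 1))
    bb <- bipartition(side, setdiff(u, side))
    s1 <- sample(u, 8)
    s2 <- sample(s1, 6)
    r_two <- restrict_bipartition(bb, s1)
    r_two <- if (is_degenerate(r_two)) r_two else restrict_bipartition(r_two, intersect(s2, r_two$universe))
    r_one <- restrict_bipartition(bb, s2)
    if (is_degenerate(r_one)) {
      expect_true(is_degenerate(r_two))
    } else if (!is_degenerate(r_two)) {
      expect_identical(r_two$key, r_one$key)
    }
  }
})

test_that("branches present everywhere above 90 are STRONG", {
  res <- classify_branch(ab, ten())
  expect_equal(res$class, "STRONG")
  expect_equal(res$presence_count, 10L)
  expect_true(all(res$evidence$status == "present"))
})

test_that("STRONG exception band and its limits behave as specified", {
  a <- ten(); a[[10]] <- mk(strong_base(80, 95), "a10")
  expect_equal(classify_branch(ab, a)$class, "STRONG")
  # support exactly 75 fails the > 75 exception
  a75 <- ten(); a75[[10]] <- mk(strong_base(75, 95), "a75")
  expect_equal(classify_branch(ab, a75)$class, "RESOLVED_VARIABLE")
  # two analyses in the band exceed the allowance
  a2 <- ten(); a2[[9]] <- mk(strong_base(80, 95), "a9")
  a2[[10]] <- mk(strong_base(80, 95), "a10")
  expect_equal(classify_branch(ab, a2)$class, "RESOLVED_VARIABLE")
  # raising strong_min never converts non-STRONG to STRONG
  for (sm in c(91, 95, 99)) {
    th <- classification_thresholds(strong_min = sm)
    expect_true(classify_branch(ab, a2, th)$class != "STRONG")
  }
})

test_that("a single weak conflict leaves the branch RESOLVED_VARIABLE", {
  a <- ten("(((A,C)40,(B,D)30)99,(E,F)99)99;")
  res <- classify_branch(ab, a)
  expect_equal(res$class, "RESOLVED_VARIABLE")
  expect_equal(res$evidence$status[10], "conflicting")
  expect_equal(res$evidence$conflict_support[10], 40)
  # conflict at exactly 50 is not < 50: falls through to MAJORITY
  a50 <- ten("(((A,C)50,(B,D)30)99,(E,F)99)99;")
  expect_equal(classify_branch(ab, a50)$class, "MAJORITY")
  # an unknown-support conflict cannot be verified as weak
  aNA <- ten("(((A,C),(B,D)30)99,(E,F)99)99;")
  resNA <- classify_branch(ab, aNA)
  expect_true(resNA$evidence$conflict_unknown[10])
  expect_equal(resNA$class, "MAJORITY")
})

test_that("absence without conflict also counts toward the gray exception", {
  a <- ten("((A,B,C,D)99,(E,F)99)99;")  # 10th unresolved among A..D
  expect_equal(classify_branch(ab, a)$class, "RESOLVED_VARIABLE")
})

test_that("majority and collapsed follow presence counts of rivals", {
  rival <- "(((A,C)90,(B,D)90)99,(E,F)99)99;"
  mixed <- function(k) {
    lapply(1:10, function(i) {
      mk(if (i <= k) strong_base() else rival, paste0("a", i))
    })
  }
  m6 <- classify_branch(ab, mixed(6))
  expect_equal(m6$class, "MAJORITY")
  expect_equal(m6$rival_max_presence, 4L)
  expect_equal(classify_branch(ab, mixed(5))$class, "COLLAPSED")
  # 5/10 presence is not a strict majority even without rivals
  half <- lapply(1:10, function(i) {
    mk(if (i <= 5) strong_base() else "((A,B,C,D)99,(E,F)99)99;", paste0("a", i))
  })
  expect_equal(classify_branch(ab, half)$class, "COLLAPSED")
})

test_that("classification ignores analysis order", {
  set.seed(23)
  a <- ten("(((A,C)40,(B,D)30)99,(E,F)99)99;")
  ref <- classify_branch(ab, a)
  for (rep in 1:5) {
    perm <- sample(10)
    res <- classify_branch(ab, a[perm])
    expect_equal(res$class, ref$class)
    expect_equal(sort(res$evidence$support), sort(ref$evidence$support))
  }
})

test_that("analyses missing the split's taxa leave the denominator", {
  a <- ten()
  a[[10]] <- mk("((A,C,E)90,(D,F)90);", "a10")  # no B: AB|CDEF degenerate
  res <- classify_branch(ab, a)
  expect_equal(res$class, "STRONG")
  expect_equal(res$evidence$status[10], "excluded")
  expect_equal(res$n_considered, 9L)
})

test_that("identical resolved ensembles summarize to themselves, all STRONG", {
  a <- lapply(1:10, function(i) {
    mk("(((A,B)100,(C,D)100)100,((E,F)100,G)100,H)100;", paste0("a", i))
  })
  st <- build_summary_tree(a)
  expect_identical(sort(st$splits$key),
                   sort(vapply(bipartitions(a[[1]])$bips, `[[`, "", "key")))
  expect_true(all(st$splits$class == "STRONG"))
  expect_equal(nrow(st$dropped), 0L)
})

test_that("star ensembles give a star summary", {
  a <- lapply(1:10, function(i) mk("(A,B,C,D,E);", paste0("a", i)))
  st <- build_summary_tree(a)
  expect_equal(nrow(st$splits), 0L)
  expect_length(bipartitions(st)$bips, 0L)
})

test_that("summary-tree splits are pairwise compatible with STRONG everywhere present", {
  set.seed(29)
  for (rep in 1:10) {
    cfg <- sim_config(seed = rep, n_genera = 1, n_species = 2,
                      n_individuals_per_population = 2, n_analyses = 6,
                      perturbation_rate = 1, n_outlier_tips = 0, n_loci = 1)
    tax <- simulate_taxonomy(cfg)
    truth <- simulate_true_tree(tax, cfg)
    aset <- simulate_analysis_set(truth, cfg)
    st <- build_summary_tree(aset$analyses)
    bp <- st$accepted_bips
    for (i in seq_along(bp)) {
      for (j in seq_len(i)) expect_true(are_compatible(bp[[i]], bp[[j]]))
    }
    strong <- st$splits[st$splits$class == "STRONG", ]
    expect_true(all(strong$presence_count == strong$n_considered))
  }
})

test_that("supported-clade counting applies a strict known-support threshold", {
  t1 <- mk("(((A,B)95,(C,D)80)99,(E,F));")
  expect_equal(count_supported_clades(t1, 90), 2L)
  expect_equal(count_supported_clades(t1, 94), 2L)
  expect_equal(count_supported_clades(t1, 95), 1L)
  expect_equal(count_supported_clades(t1, 100), 0L)
  expect_equal(count_supported_clades(mk("(A,B,C,D,E);")), 0L)
})

test_that("induced group trees collapse monophyletic groups and prune the rest", {
  tax <- toy_taxonomy()
  t1 <- mk("(((camA1,camA2)99,(camB1,camB2)98)97,(outX1,outX2)96);")
  r <- induce_group_tree(t1, tax, "population")
  expect_setequal(tree_tips(r$tree), c("PA", "PB", "PX"))
  expect_length(r$unmapped_groups, 0L)
  # a group straddling the tree is unmapped and pruned
  qt <- quad_taxonomy()
  t2 <- mk("(((a1,a2)99,(c1,((b1,b2)98,c2)97)96)95,(d1,d2)94);")
  r2 <- induce_group_tree(t2, qt, "population")
  expect_equal(r2$unmapped_groups, "PC")
  expect_setequal(tree_tips(r2$tree), c("PA", "PB", "PD"))
  # identity grouping leaves the tree unchanged
  tax_id <- taxonomy_map(data.frame(
    accession = tree_tips(t1), population = tree_tips(t1),
    subspecies = tree_tips(t1), species = tree_tips(t1),
    genus = "G", stringsAsFactors = FALSE))
  r3 <- induce_group_tree(t1, tax_id, "population")
  expect_identical(sort(vapply(bipartitions(r3$tree)$bips, `[[`, "", "key")),
                   oracle_split_keys(t1$phylo))
})

test_that("group trees induced from the individual trees are self-consistent", {
  cfg <- sim_config(seed = 4, n_genera = 1, n_species = 2, n_analyses = 6,
                    n_individuals_per_population = 2,
                    perturbation_rate = 0, n_outlier_tips = 0, n_loci = 1)
  tax <- simulate_taxonomy(cfg)
  truth <- simulate_true_tree(tax, cfg)
  aset <- simulate_analysis_set(truth, cfg)
  gtrees <- lapply(aset$analyses[1:3], function(a) {
    induce_group_tree(a, tax, "population")$tree
  })
  chk <- check_cross_level_consistency(aset$analyses, gtrees, tax)
  expect_true(chk$consistent)
  expect_true(all(chk$report$status == "consistent"))
})

test_that("a swapped group pair conflicts with a strong individual split", {
  qt <- quad_taxonomy()
  ind <- lapply(1:4, function(i) {
    mk("(((a1,a2)99,(b1,b2)99)99,((c1,c2)99,(d1,d2)99)99);", paste0("i", i))
  })
  # group tree pairing PA with PC against the strong PA+PB | PC+PD split
  g_bad <- mk("((PA,PC)99,(PB,PD)99);", "g1")
  chk <- check_cross_level_consistency(ind, list(g_bad), qt, level = "population")
  expect_false(chk$consistent)
  expect_true(any(chk$report$status == "conflicting"))
  # a split involving an unknown group label is untestable, others still checked
  g_unknown <- mk("(((PA,PB)99,Ghost)98,(PC,PD)97);", "g2")
  g_ok <- mk("((PA,PB)99,(PC,PD)98);", "g3")
  chk2 <- check_cross_level_consistency(ind, list(g_unknown, g_ok), qt,
                                        level = "population")
  expect_true(any(chk2$report$status == "untestable"))
  expect_true(any(chk2$report$status == "consistent"))
  expect_false(any(chk2$report$status == "conflicting"))
})
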