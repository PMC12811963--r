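#' Branch-classification thresholds
#'
#' The bootstrap-percent rules used to grade a candidate branch across an
#' ensemble of analyses:
#' * `STRONG` ("thick black"): resolved in every analysis with support above
#'   `strong_min`, allowing at most `strong_exception_max_analyses` analyses
#'   whose support is only above `strong_exception_min`.
#' * `RESOLVED_VARIABLE` ("thick gray"): resolved in every analysis at any
#'   support, allowing at most `gray_exception_max_analyses` analyses where
#'   the branch is missing and every conflicting branch there has support
#'   below `gray_conflict_max`.
#' * `MAJORITY` ("dashed"): resolved in a strict majority of analyses with
#'   no rival branch resolved in as many or more.
#' * `COLLAPSED`: none of the above; the region becomes a polytomy.
#'
#' @param strong_min Bootstrap percent every analysis must exceed for a
#'   strongly supported branch (default 90).
#' @param strong_exception_min Floor for the tolerated weaker analyses
#'   (default 75).
#' @param strong_exception_max_analyses How many analyses may fall in the
#'   exception band (default 1).
#' @param gray_conflict_max Ceiling (exclusive) on conflicting-branch
#'   support in the tolerated unresolved analysis (default 50).
#' @param gray_exception_max_analyses How many analyses may lack the branch
#'   for `RESOLVED_VARIABLE` (default 1).
#' @param majority_fraction Fraction of analyses that must resolve the
#'   branch for `MAJORITY`; the comparison is strict (default 0.5).
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(strong_min = 90,
                                      strong_exception_min = 75,
                                      strong_exception_max_analyses = 1L,
                                      gray_conflict_max = 50,
                                      gray_exception_max_analyses = 1L,
                                      majority_fraction = 0.5) {
  if (!(0 <= gray_conflict_max && gray_conflict_max < strong_exception_min &&
        strong_exception_min < strong_min && strong_min <= 100)) {
    abort_fmt("thresholds must satisfy 0 <= gray_conflict_max < strong_exception_min < strong_min <= 100")
  }
  if (majority_fraction <= 0 || majority_fraction >= 1) {
    abort_fmt("majority_fraction must be in (0, 1)")
  }
  structure(list(strong_min = strong_min,
                 strong_exception_min = strong_exception_min,
                 strong_exception_max_analyses = as.integer(strong_exception_max_analyses),
                 gray_conflict_max = gray_conflict_max,
                 gray_exception_max_analyses = as.integer(gray_exception_max_analyses),
                 majority_fraction = majority_fraction),
            class = "classification_thresholds")
}

branch_classes <- c("STRONG", "RESOLVED_VARIABLE", "MAJORITY", "COLLAPSED")

# Precompute, for each analysis, its split table restricted to the part of
# `universe` the analysis actually samples.
ensemble_prep <- function(analyses, universe) {
  lapply(seq_along(analyses), function(k) {
    at <- analyses[[k]]
    tips <- sort(tree_tips(at))
    u <- intersect(universe, tips)
    id <- if (inherits(at, "analysis_tree")) at$meta$analysis_id else NULL
    list(id = id %||% paste0("analysis_", k), u = u,
         st = if (length(u) >= 4L) split_table(at, u) else NULL)
  })
}

# Per-analysis status of one candidate bipartition plus rival accounting.
# Statuses: present / absent / conflicting / excluded (degenerate
# restriction; such analyses leave the denominator).
branch_evidence <- function(b, prep, th) {
  nk <- length(prep)
  status <- character(nk)
  support <- rep(NA_real_, nk)
  conflict_support <- rep(NA_real_, nk)
  conflict_unknown <- rep(NA, nk)
  rivals <- vector("list", nk)
  for (k in seq_len(nk)) {
    p <- prep[[k]]
    if (is.null(p$st)) {
      status[k] <- "excluded"
      next
    }
    rb <- if (length(p$u) == length(b$universe)) b else {
      r <- restrict_bipartition(b, p$u)
      if (is_degenerate(r)) {
        status[k] <- "excluded"
        next
      }
      r
    }
    bm <- bip_to_mask(rb, p$st$universe)
    hit <- match(mask_key(bm), p$st$key)
    if (!is.na(hit)) {
      status[k] <- "present"
      support[k] <- p$st$support[hit]
    } else {
      inc <- which(incompatible_rows(p$st$mask, bm))
      if (length(inc) == 0L) {
        status[k] <- "absent"
      } else {
        status[k] <- "conflicting"
        s <- p$st$support[inc]
        conflict_unknown[k] <- anyNA(s)
        conflict_support[k] <- if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
        rivals[[k]] <- lapply(inc, function(i) {
          mask_to_bip(p$st$mask[i, ], p$st$universe)
        })
      }
    }
  }
  # rival presence counted on the tip set every considered analysis samples
  considered <- status != "excluded"
  rival_max <- 0L
  if (any(lengths(rivals) > 0L)) {
    u_min <- Reduce(intersect, lapply(prep[considered], `[[`, "u"))
    per_analysis_keys <- lapply(rivals, function(rr) {
      if (is.null(rr)) return(character())
      keys <- vapply(rr, function(r) {
        rs <- restrict_bipartition(r, intersect(r$universe, u_min))
        if (is_degenerate(rs)) NA_character_ else rs$key
      }, character(1L))
      unique(keys[!is.na(keys)])
    })
    all_keys <- unlist(per_analysis_keys, use.names = FALSE)
    if (length(all_keys)) rival_max <- max(table(all_keys))
  }
  list(evidence = data.frame(
         analysis_id = vapply(prep, `[[`, "", "id"),
         status = status, support = support,
         conflict_support = conflict_support,
         conflict_unknown = conflict_unknown,
         stringsAsFactors = FALSE),
       n_considered = sum(considered),
       presence_count = sum(status == "present"),
       rival_max_presence = as.integer(rival_max))
}

classify_from_evidence <- function(ev, th) {
  e <- ev$evidence[ev$evidence$status != "excluded", , drop = FALSE]
  n_tot <- nrow(e)
  n_pres <- sum(e$status == "present")
  if (n_tot == 0L || n_pres == 0L) return("COLLAPSED")
  if (n_pres == n_tot) {
    s <- e$support[e$status == "present"]
    weak <- !(!is.na(s) & s > th$strong_min)
    if (sum(weak) <= th$strong_exception_max_analyses &&
        all(!is.na(s[weak]) & s[weak] > th$strong_exception_min)) {
      return("STRONG")
    }
    return("RESOLVED_VARIABLE")
  }
  miss <- e[e$status != "present", , drop = FALSE]
  if (nrow(miss) <= th$gray_exception_max_analyses) {
    soft <- vapply(seq_len(nrow(miss)), function(i) {
      if (miss$status[i] == "absent") return(TRUE)
      isFALSE(miss$conflict_unknown[i]) &&
        !is.na(miss$conflict_support[i]) &&
        miss$conflict_support[i] < th$gray_conflict_max
    }, logical(1L))
    # absent with only weakly supported (or no) conflict: still "resolved
    # by all analyses except one" in the thick-gray sense
    if (all(soft)) return("RESOLVED_VARIABLE")
  }
  if (n_pres > th$majority_fraction * n_tot &&
      ev$rival_max_presence < n_pres) {
    return("MAJORITY")
  }
  "COLLAPSED"
}

#' Classify one candidate branch across an analysis ensemble
#'
#' For each analysis the candidate bipartition is restricted to that
#' analysis's tips and looked up in its splits: it is `present` (with that
#' branch's bootstrap support), `absent` (unresolved, no incompatible split
#' present), or `conflicting` (at least one incompatible split present; the
#' maximum support among them is recorded). Analyses in which the
#' restriction is uninformative are `excluded` from the denominator. The
#' grade is then assigned by the [classification_thresholds()] rules, in
#' order STRONG, RESOLVED_VARIABLE, MAJORITY, COLLAPSED. Unknown supports
#' never satisfy a support threshold; they count for presence only.
#'
#' @param b A [bipartition()] over (a subset of) the tips shared by the
#'   analyses.
#' @param analyses Nonempty list of `analysis_tree` objects.
#' @param th A [classification_thresholds()].
#' @return List with `class` (one of the four grades), `evidence` (per-
#'   analysis data.frame: `analysis_id`, `status`, `support`,
#'   `conflict_support`, `conflict_unknown`), `presence_count`,
#'   `n_considered`, `rival_max_presence`.
#' @export
classify_branch <- function(b, analyses, th = classification_thresholds()) {
  stopifnot(inherits(b, "bipartition"), length(analyses) >= 1L)
  prep <- ensemble_prep(analyses, b$universe)
  ev <- branch_evidence(b, prep, th)
  c(list(class = classify_from_evidence(ev, th)), ev)
}

#' Count strongly supported clades in one tree
#'
#' Number of internal branches whose known bootstrap support strictly
#' exceeds `threshold`. Unknown supports never count.
#'
#' @param tree An `analysis_tree`, `summary_tree` or `phylo`.
#' @param threshold Support threshold (default 90).
#' @return Integer count.
#' @export
count_supported_clades <- function(tree, threshold = 90) {
  st <- split_table(tree)
  sum(!is.na(st$support) & st$support > threshold)
}

# ---- summary-tree construction ----------------------------------------------

# Recursively nest accepted clades (sides away from the reference tip) into
# a node tree; pairwise-compatible clades excluding a common reference tip
# are always laminar.
nest_clades <- function(tipset, clades, ids) {
  sizes <- lengths(clades)
  maximal <- vapply(seq_along(clades), function(i) {
    !any(vapply(seq_along(clades), function(j) {
      j != i && sizes[i] < sizes[j] && all(clades[[i]] %in% clades[[j]])
    }, logical(1L)))
  }, logical(1L))
  covered <- character(0L)
  children <- list()
  ord <- order(vapply(clades[maximal], min, character(1L)))
  for (ix in which(maximal)[ord]) {
    inner <- which(sizes < sizes[ix] &
                     vapply(clades, function(cl) all(cl %in% clades[[ix]]),
                            logical(1L)))
    child <- nest_clades(clades[[ix]], clades[inner], ids[inner])
    child$split_id <- ids[ix]
    children[[length(children) + 1L]] <- child
    covered <- c(covered, clades[[ix]])
  }
  for (tip in setdiff(sort(tipset), covered)) {
    children[[length(children) + 1L]] <-
      list(tips = tip, split_id = NA_integer_, children = list())
  }
  list(tips = sort(tipset), split_id = NA_integer_, children = children)
}

node_newick <- function(node, label_fn) {
  if (length(node$children) == 0L) return(node$tips)
  inner <- vapply(node$children, node_newick, "", label_fn = label_fn)
  paste0("(", paste(inner, collapse = ","), ")",
         if (is.na(node$split_id)) "" else label_fn(node$split_id))
}

summary_newick <- function(x, classified = FALSE) {
  lab <- if (classified) {
    function(i) {
      ms <- x$splits$mean_support[i]
      sprintf("[&class=%s,support_mean=%s,presence=%d/%d]",
              x$splits$class[i],
              if (is.na(ms)) "NA" else format(round_half_up(ms, 1), nsmall = 1),
              x$splits$presence_count[i], x$splits$n_considered[i])
    }
  } else {
    function(i) {
      ms <- x$splits$mean_support[i]
      if (is.na(ms)) "" else format(round_half_up(ms, 1))
    }
  }
  paste0(node_newick(x$node_tree, lab), ";")
}

#' Build a classified summary tree from an analysis ensemble
#'
#' Collects every bipartition occurring in any analysis, restricted to the
#' common tip set, classifies each with [classify_branch()] semantics, and
#' assembles the accepted splits into one (possibly multifurcating) tree.
#' Candidates are accepted greedily in priority order STRONG >
#' RESOLVED_VARIABLE > MAJORITY; within a class by descending presence
#' count, then descending mean support, then canonical key, so the output
#' is byte-reproducible. A candidate incompatible with an already accepted
#' split is dropped and logged. COLLAPSED candidates are never branches:
#' their region remains a polytomy.
#'
#' @param analyses List of at least two `analysis_tree` objects.
#' @param th A [classification_thresholds()].
#' @return An object of class `summary_tree`: list with `phylo` (node
#'   labels are mean supports), `node_tree`, `universe`, `splits` (accepted
#'   splits with class and per-analysis tallies), `candidates` (all
#'   classified candidates), `evidence` (named list of per-analysis status
#'   tables), `dropped`, `thresholds`, `analysis_ids`.
#' @export
build_summary_tree <- function(analyses, th = classification_thresholds()) {
  if (length(analyses) < 2L) abort_fmt("need at least 2 analyses to summarize")
  universe <- Reduce(intersect, lapply(analyses, function(a) sort(tree_tips(a))))
  universe <- sort(universe)
  if (length(universe) < 4L) {
    abort_fmt("common tip set has %d tips; need at least 4", length(universe))
  }
  prep <- ensemble_prep(analyses, universe)
  masks <- do.call(rbind, lapply(prep, function(p) p$st$mask))
  if (is.null(masks) || nrow(masks) == 0L) {
    masks <- matrix(logical(), 0L, length(universe))
  }
  keys <- mask_key(masks)
  first <- !duplicated(keys)
  masks <- masks[first, , drop = FALSE]
  keys <- keys[first]
  ncand <- nrow(masks)
  evs <- vector("list", ncand)
  cls <- character(ncand)
  bips <- vector("list", ncand)
  for (i in seq_len(ncand)) {
    bips[[i]] <- mask_to_bip(masks[i, ], universe)
    evs[[i]] <- branch_evidence(bips[[i]], prep, th)
    cls[i] <- classify_from_evidence(evs[[i]], th)
  }
  mean_support <- vapply(seq_len(ncand), function(i) {
    e <- evs[[i]]$evidence
    s <- e$support[e$status == "present"]
    if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
  }, numeric(1L))
  presence <- vapply(evs, `[[`, integer(1L), "presence_count")
  n_cons <- vapply(evs, `[[`, integer(1L), "n_considered")
  bip_key <- vapply(bips, `[[`, "", "key")
  cand <- data.frame(key = bip_key, class = cls,
                     presence_count = presence, n_considered = n_cons,
                     mean_support = mean_support,
                     rival_max_presence = vapply(evs, `[[`, integer(1L),
                                                 "rival_max_presence"),
                     stringsAsFactors = FALSE)
  elig <- which(cls %in% c("STRONG", "RESOLVED_VARIABLE", "MAJORITY"))
  ord <- elig[order(match(cls[elig], branch_classes),
                    -presence[elig],
                    -ifelse(is.na(mean_support[elig]), -Inf, mean_support[elig]),
                    bip_key[elig])]
  accepted <- integer(0L)
  dropped <- integer(0L)
  for (i in ord) {
    if (length(accepted) == 0L ||
        !any(incompatible_rows(masks[accepted, , drop = FALSE], masks[i, ]))) {
      accepted <- c(accepted, i)
    } else {
      dropped <- c(dropped, i)
    }
  }
  accepted_row <- function(idx) {
    data.frame(cand[idx, , drop = FALSE], row.names = NULL)
  }
  splits <- accepted_row(accepted)
  clades <- lapply(accepted, function(i) universe[masks[i, ]])
  node_tree <- nest_clades(universe, clades, seq_along(accepted))
  nwk <- paste0(node_newick(node_tree, function(i) {
    ms <- splits$mean_support[i]
    if (is.na(ms)) "" else format(round_half_up(ms, 1))
  }), ";")
  phy <- ape::read.tree(text = nwk)
  ev_list <- setNames(lapply(evs, `[[`, "evidence"), bip_key)
  structure(list(phylo = phy, node_tree = node_tree, universe = universe,
                 splits = splits, candidates = cand,
                 accepted_bips = bips[accepted],
                 evidence = ev_list,
                 dropped = accepted_row(dropped),
                 thresholds = th,
                 analysis_ids = vapply(prep, `[[`, "", "id")),
            class = "summary_tree")
}

#' @export
print.summary_tree <- function(x, ...) {
  tab <- table(factor(x$splits$class, levels = branch_classes))
  cat(sprintf("<summary_tree> %d tips over %d analyses; branches: %s\n",
              length(x$universe), length(x$analysis_ids),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Collapse monophyletic groups of a tree to single group tips
#'
#' Every group (at the requested taxonomy level) that is monophyletic on
#' the input tree is collapsed to one tip carrying the group label; groups
#' that are not monophyletic are reported and their tips pruned. Supports
#' on surviving internal branches are retained.
#'
#' @param tree An `analysis_tree` (individual-level tips).
#' @param tax A [taxonomy_map()] covering every tip.
#' @param level Target level: `"population"`, `"subspecies"`, `"species"`
#'   or `"genus"`.
#' @return List with `tree` (induced `analysis_tree` over group labels) and
#'   `unmapped_groups` (character vector of non-monophyletic groups).
#' @export
induce_group_tree <- function(tree, tax, level) {
  phy <- get_phylo(tree)
  groups <- tax_groups(tax, level, accessions = phy$tip.label)
  is_mono <- vapply(names(groups), function(g) {
    r <- is_monophyletic(tree, groups[[g]])
    r$status %in% c("monophyletic", "trivial")
  }, logical(1L))
  unmapped <- sort(names(groups)[!is_mono])
  reps <- vapply(groups[is_mono], function(tt) sort(tt)[1L], "")
  if (length(reps) < 3L) {
    abort_fmt("induced tree would have %d groups; need at least 3", length(reps))
  }
  pruned <- ape::keep.tip(phy, unname(reps))
  pruned$tip.label <- names(reps)[match(pruned$tip.label, reps)]
  meta <- if (inherits(tree, "analysis_tree")) tree$meta else
    list(method = NA, c = NA, m = NA, analysis_id = NA)
  list(tree = analysis_tree(pruned, method = meta$method, c = meta$c,
                            m = meta$m, grouping = level,
                            analysis_id = paste0(meta$analysis_id %||% "tree",
                                                 "_", level)),
       unmapped_groups = unmapped)
}

#' Check grouped analyses against the individual-level summary
#'
#' Expands each bipartition of each group-level tree back to accession tip
#' sets and tests split compatibility against the accepted splits of the
#' individual-level summary tree. Splits involving a group label absent
#' from the taxonomy are untestable; so are splits that carry no
#' information once restricted to the summary's tips.
#'
#' @param individual A `summary_tree`, or a list of individual-level
#'   `analysis_tree` objects (summarized internally).
#' @param group_analyses List of group-level `analysis_tree` objects.
#' @param tax A [taxonomy_map()].
#' @param level Grouping level of the group trees; defaults to the first
#'   tree's `grouping` metadata.
#' @param th Thresholds used if `individual` must be summarized.
#' @return List with `report` (data.frame: `analysis_id`, `key`, `status`
#'   in consistent/conflicting/untestable) and `consistent` (TRUE iff no
#'   conflicts).
#' @export
check_cross_level_consistency <- function(individual, group_analyses, tax,
                                          level = NULL,
                                          th = classification_thresholds()) {
  summary <- if (inherits(individual, "summary_tree")) individual else
    build_summary_tree(individual, th)
  level <- level %||% group_analyses[[1L]]$meta$grouping
  level <- match.arg(level, c("population", "subspecies", "species", "genus"))
  acc_splits <- summary$accepted_bips
  rows <- list()
  for (gt in group_analyses) {
    st <- split_table(gt)
    gid <- if (inherits(gt, "analysis_tree")) gt$meta$analysis_id else "group_tree"
    for (i in seq_len(nrow(st$mask))) {
      side_g <- st$universe[st$mask[i, ]]
      other_g <- st$universe[!st$mask[i, ]]
      key <- mask_to_bip(st$mask[i, ], st$universe)$key
      known <- c(side_g, other_g) %in% tax[[level]]
      if (!all(known)) {
        rows[[length(rows) + 1L]] <-
          data.frame(analysis_id = gid, key = key, status = "untestable",
                     stringsAsFactors = FALSE)
        next
      }
      expand <- function(gl) {
        unlist(tax_groups(tax, level)[gl], use.names = FALSE)
      }
      ea <- expand(side_g)
      eb <- expand(other_g)
      common <- intersect(c(ea, eb), summary$universe)
      a2 <- intersect(ea, common)
      b2 <- intersect(eb, common)
      if (length(a2) < 2L || length(b2) < 2L) {
        rows[[length(rows) + 1L]] <-
          data.frame(analysis_id = gid, key = key, status = "untestable",
                     stringsAsFactors = FALSE)
        next
      }
      eb_bip <- bipartition(a2, b2)
      conflict <- any(vapply(acc_splits, function(s) {
        rs <- restrict_bipartition(s, intersect(s$universe, common))
        if (is_degenerate(rs)) return(FALSE)
        rb <- restrict_bipartition(eb_bip, rs$universe)
        if (is_degenerate(rb)) return(FALSE)
        !are_compatible(rb, rs)
      }, logical(1L)))
      rows[[length(rows) + 1L]] <-
        data.frame(analysis_id = gid, key = key,
                   status = if (conflict) "conflicting" else "consistent",
                   stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analysis_id = character(), key = character(),
               status = character(), stringsAsFactors = FALSE)
  list(report = report, consistent = !any(report$status == "conflicting"))
}
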