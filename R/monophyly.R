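#' Test monophyly of a tip set on an unrooted tree
#'
#' On an unrooted tree a group is monophyletic iff some branch's
#' bipartition has one side exactly equal to the group's tip set; pendant
#' branches serve for complements of size one. Groups of size one, or
#' equal to the whole tip set, are trivially monophyletic (`status =
#' "trivial"`, support not applicable).
#'
#' @param tree An `analysis_tree`, `summary_tree` or `phylo`.
#' @param tipset Character vector of tip labels, a subset of the tree tips.
#' @param group Optional group label carried into the result.
#' @return An object of class `monophyly_result`: list with `group`,
#'   `status` (`"monophyletic"`, `"not_monophyletic"`, `"trivial"`),
#'   `support` (numeric or `NA`), `witness` ([bipartition()] or `NULL`).
#' @export
is_monophyletic <- function(tree, tipset, group = NA_character_) {
  phy <- get_phylo(tree)
  tips <- phy$tip.label
  g <- sort(unique(as.character(tipset)))
  missing <- setdiff(g, tips)
  if (length(missing)) {
    abort_fmt("tipset labels absent from tree: %s",
              paste(missing, collapse = ", "))
  }
  n <- length(tips)
  res <- function(status, support = NA_real_, witness = NULL) {
    structure(list(group = group, tipset = g, status = status,
                   support = support, witness = witness),
              class = "monophyly_result")
  }
  if (length(g) <= 1L || length(g) == n) return(res("trivial"))
  comp <- sort(setdiff(tips, g))
  witness <- bipartition(g, comp)
  if (n <= 3L || length(comp) == 1L) {
    # a pendant branch isolates the single non-member; no internal branch,
    # hence no support, unless the rooted representation labels the clade
    support <- clade_support(phy, g)
    return(res("monophyletic", as.numeric(support), witness))
  }
  support <- clade_support(phy, g)
  hit <- !is.null(attr(support, "found")) && attr(support, "found")
  if (hit) res("monophyletic", as.numeric(support), witness)
  else res("not_monophyletic")
}

# Support of the branch isolating `g`, searched over the clades (and clade
# complements) of the rooted representation. Returns NA with attr found
# FALSE when no branch isolates g.
clade_support <- function(phy, g) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  sup <- node_supports(phy)
  comp <- sort(setdiff(labs, g))
  hits <- numeric(0L)
  found <- FALSE
  for (i in seq_along(pp)[-1L]) {
    cl <- sort(labs[pp[[i]]])
    if (identical(cl, g) || identical(cl, comp)) {
      found <- TRUE
      hits <- c(hits, sup[i])
    }
  }
  # pendant complement: the split exists even without an internal node
  if (!found && length(comp) == 1L) found <- TRUE
  out <- if (length(hits) == 0L || all(is.na(hits))) NA_real_ else
    max(hits, na.rm = TRUE)
  attr(out, "found") <- found
  out
}

#' @export
print.monophyly_result <- function(x, ...) {
  cat(sprintf("<monophyly_result> %s: %s (support %s)\n",
              if (is.na(x$group)) paste0("{", paste(x$tipset, collapse = ","), "}")
              else x$group,
              x$status, format(x$support)))
  invisible(x)
}

#' Taxon-cohesion report across an analysis ensemble
#'
#' Evaluates monophyly of every group at a taxonomy level, per analysis,
#' and tallies monophyletic and strongly supported monophyletic groups
#' ("strong" = monophyletic with known support strictly above
#' `support_threshold`). Groups of size one are trivially monophyletic and
#' excluded from tallies unless `include_trivial = TRUE` (they can never be
#' strongly supported: a pendant branch carries no bootstrap).
#'
#' @param analyses List of `analysis_tree` (or `summary_tree`) objects.
#' @param tax A [taxonomy_map()] covering every tip.
#' @param level `"population"`, `"subspecies"` or `"species"`.
#' @param support_threshold Bootstrap threshold for "strongly supported"
#'   (default 90, strict).
#' @param include_trivial Count single-member groups in the tallies?
#' @return An object of class `cohesion_report`: list with `results`
#'   (data.frame: analysis_id, group, size, status, support, strong) and
#'   `tallies` (data.frame: analysis_id, n_groups, n_monophyletic,
#'   n_strong).
#' @export
cohesion_report <- function(analyses, tax, level,
                            support_threshold = 90,
                            include_trivial = FALSE) {
  level <- match.arg(level, c("population", "subspecies", "species"))
  rows <- list()
  for (k in seq_along(analyses)) {
    at <- analyses[[k]]
    tips <- tree_tips(at)
    id <- if (inherits(at, "analysis_tree")) at$meta$analysis_id else
      paste0("analysis_", k)
    id <- id %||% paste0("analysis_", k)
    groups <- tax_groups(tax, level, accessions = tips)
    nontrivial <- lengths(groups) >= 2L & lengths(groups) < length(tips)
    if (!any(nontrivial)) {
      abort_fmt("level '%s' has zero nontrivial groups on analysis %s",
                level, id)
    }
    use <- if (include_trivial) groups else groups[nontrivial]
    for (g in names(use)) {
      r <- is_monophyletic(at, use[[g]], group = g)
      mono <- r$status %in% c("monophyletic", "trivial")
      rows[[length(rows) + 1L]] <- data.frame(
        analysis_id = id, group = g, size = length(use[[g]]),
        status = r$status, support = r$support,
        strong = mono && !is.na(r$support) && r$support > support_threshold,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  tallies <- do.call(rbind, lapply(split(results, results$analysis_id),
    function(d) data.frame(
      analysis_id = d$analysis_id[1L],
      n_groups = nrow(d),
      n_monophyletic = sum(d$status %in% c("monophyletic", "trivial")),
      n_strong = sum(d$strong),
      stringsAsFactors = FALSE)))
  rownames(tallies) <- NULL
  structure(list(results = results, tallies = tallies, level = level,
                 support_threshold = support_threshold),
            class = "cohesion_report")
}

#' @export
print.cohesion_report <- function(x, ...) {
  cat(sprintf("<cohesion_report> level=%s, %d analyses\n",
              x$level, nrow(x$tallies)))
  print(x$tallies)
  invisible(x)
}

#' Percent decrease between two counts
#'
#' `100 * (before - after) / before`, rounded half-up to whole percent; a
#' positive value is a decrease. Used to compare tallies (e.g. strongly
#' supported monophyletic groups) between parameter settings.
#'
#' @param count_before Baseline count (> 0).
#' @param count_after Comparison count.
#' @return Integer-valued percentage.
#' @export
percent_change <- function(count_before, count_after) {
  if (count_before <= 0) abort_fmt("count_before must be > 0")
  round_half_up(100 * (count_before - count_after) / count_before, 0)
}

#' Find minimal outlier-removal sets restoring monophyly
#'
#' Exact search over all subsets `S` of the group with `|S| <=
#' max_removals`, smallest first: `S` qualifies if the group minus `S` is
#' monophyletic on the tree with `S` pruned. All co-minimal sets are
#' returned in canonical (lexicographic) order; an empty set means the
#' group is already monophyletic.
#'
#' @param tree An `analysis_tree`, `summary_tree` or `phylo`.
#' @param tipset The group's tips (>= 2).
#' @param max_removals Search budget (default 3); must leave at least two
#'   group members.
#' @return List with `removals` (list of character vectors; empty when
#'   `status` is `"none_within_budget"`) and `status` (`"ok"` or
#'   `"none_within_budget"`).
#' @export
find_outliers <- function(tree, tipset, max_removals = 3L) {
  phy <- get_phylo(tree)
  g <- sort(unique(as.character(tipset)))
  if (length(g) < 2L) abort_fmt("tipset must have at least 2 tips")
  if (length(g) - max_removals < 2L) {
    abort_fmt("max_removals = %d would trivialize a group of %d",
              max_removals, length(g))
  }
  mono_after <- function(S) {
    sub <- if (length(S)) ape::drop.tip(phy, S) else phy
    if (is.null(sub) || length(sub$tip.label) < 3L) return(TRUE)
    r <- is_monophyletic(sub, setdiff(g, S))
    r$status %in% c("monophyletic", "trivial")
  }
  if (mono_after(character(0L))) {
    return(list(removals = list(character(0L)), status = "ok"))
  }
  for (k in seq_len(max_removals)) {
    subsets <- combn(g, k, simplify = FALSE)
    hits <- Filter(mono_after, subsets)
    if (length(hits)) {
      ord <- order(vapply(hits, paste, "", collapse = "\r"))
      return(list(removals = hits[ord], status = "ok"))
    }
  }
  list(removals = list(), status = "none_within_budget")
}
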