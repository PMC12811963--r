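#' Construct an analysis tree
#'
#' One inference result in a parameter-sweep ensemble: an unrooted topology
#' with integer bootstrap supports (0-100) on internal branches and the
#' assembly/inference metadata needed to interpret it (inference method,
#' clustering threshold `c`, min-samples threshold `m`, grouping level).
#' Supports live in `phylo$node.label`; an empty or non-numeric label is an
#' unknown support, which is distinct from 0.
#'
#' @param phy An [ape::phylo] object with at least 3 uniquely labelled tips.
#' @param method Inference method, `"ML"` or `"SVD"` (or `NA`).
#' @param c Clustering threshold used at assembly (metadata only).
#' @param m Min-samples-per-locus threshold used at assembly (metadata only).
#' @param grouping Grouping level of the tips: `"individual"`,
#'   `"population"`, `"subspecies"` or `"species"`.
#' @param analysis_id Free-text identifier for the analysis.
#' @return An object of class `analysis_tree`.
#' @export
analysis_tree <- function(phy, method = NA_character_, c = NA_integer_,
                          m = NA_integer_, grouping = "individual",
                          analysis_id = NA_character_) {
  stopifnot(inherits(phy, "phylo"))
  phy$tip.label <- gsub("\\s+", "_", phy$tip.label)
  if (length(phy$tip.label) < 3L) {
    abort_fmt("an analysis tree needs at least 3 tips, got %d",
              length(phy$tip.label))
  }
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup)) abort_fmt("duplicate tip labels: %s", paste(dup, collapse = ", "))
  sup <- node_supports(phy)
  bad <- which(!is.na(sup) & (sup < 0 | sup > 100))
  if (length(bad)) {
    abort_fmt("support %s outside 0..100", paste(sup[bad], collapse = ", "))
  }
  if (!is.na(method) && !method %in% c("ML", "SVD")) {
    abort_fmt("method must be 'ML' or 'SVD', got '%s'", method)
  }
  grouping <- match.arg(grouping,
                        c("individual", "population", "subspecies", "species"))
  structure(list(phylo = phy,
                 meta = list(method = method, c = as.integer(c),
                             m = as.integer(m), grouping = grouping,
                             analysis_id = analysis_id)),
            class = "analysis_tree")
}

#' @export
print.analysis_tree <- function(x, ...) {
  cat(sprintf("<analysis_tree> %d tips, %s, c=%s m=%s grouping=%s id=%s\n",
              length(x$phylo$tip.label), x$meta$method, x$meta$c, x$meta$m,
              x$meta$grouping, x$meta$analysis_id))
  invisible(x)
}

# Numeric supports from node labels; "" and non-numeric labels are unknown.
node_supports <- function(phy) {
  lab <- phy$node.label
  if (is.null(lab)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(lab))
}

# Accept an analysis_tree, summary_tree or bare phylo.
get_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (inherits(x, c("analysis_tree", "summary_tree"))) return(x$phylo)
  abort_fmt("expected an analysis_tree, summary_tree or phylo object")
}

tree_tips <- function(x) get_phylo(x)$tip.label

#' Parse a Newick string into an analysis tree
#'
#' Supports may appear as internal node labels (`)95`) and/or bracketed
#' comments (`)[95]` or `)[&support=95]`). When both are present on a node
#' the node label wins. Remaining comments are discarded. Tip-label
#' whitespace is normalized to underscores so tree tips compare equal to
#' taxonomy keys.
#'
#' @param text A Newick string, or a path to a file containing one tree.
#' @param ... Metadata passed on to [analysis_tree()] (`method`, `c`, `m`,
#'   `grouping`, `analysis_id`).
#' @return An `analysis_tree`.
#' @export
read_analysis_tree <- function(text, ...) {
  if (length(text) == 1L && !grepl("[(;]", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "")
  }
  text <- paste(text, collapse = "")
  check_newick_syntax(text)
  # promote a ')' comment to a node label when no label is present
  cleaned <- gsub("\\)\\[&?support=([0-9.]+)[^]]*\\]", ")\\1", text)
  cleaned <- gsub("\\)\\[([0-9.]+)\\]", ")\\1", cleaned)
  cleaned <- gsub("\\[[^]]*\\]", "", cleaned)
  phy <- ape::read.tree(text = cleaned)
  if (is.null(phy)) abort_fmt("could not parse Newick text")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    off <- regexpr(dup[1L], text, fixed = TRUE)
    abort_fmt("duplicate tip label '%s' (first at character %d)", dup[1L], off)
  }
  analysis_tree(phy, ...)
}

# Balanced-parenthesis pre-check with character offsets.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  neg <- which(depth < 0L)
  if (length(neg)) {
    abort_fmt("unbalanced parenthesis: unexpected ')' at character %d", neg[1L])
  }
  if (length(depth) && depth[length(depth)] != 0L) {
    abort_fmt("unbalanced parenthesis: %d '(' left open at end of text (character %d)",
              depth[length(depth)], length(depth))
  }
  invisible(TRUE)
}

#' Write a tree as Newick text
#'
#' Plain mode writes supports as internal node labels. Classified mode (for
#' [summary trees][build_summary_tree]) attaches a bracketed
#' `[&class=...,support_mean=...]` comment to each classified branch.
#'
#' @param x An `analysis_tree`, `summary_tree` or `phylo`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @param annotation_mode `"plain"` or `"classified"` (`summary_tree` only).
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(x, path = NULL, annotation_mode = c("plain", "classified")) {
  annotation_mode <- match.arg(annotation_mode)
  if (annotation_mode == "classified") {
    if (!inherits(x, "summary_tree")) {
      abort_fmt("classified output is only defined for summary trees")
    }
    txt <- summary_newick(x, classified = TRUE)
  } else if (inherits(x, "summary_tree")) {
    txt <- summary_newick(x, classified = FALSE)
  } else {
    txt <- ape::write.tree(get_phylo(x))
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read an ensemble of analysis trees via a manifest table
#'
#' The manifest is a TSV with columns `file`, `method`, `c`, `m`,
#' `grouping`, `analysis_id`; `file` is resolved relative to the manifest's
#' directory.
#'
#' @param manifest Path to the manifest TSV.
#' @return A list of `analysis_tree` objects, named by `analysis_id`.
#' @export
read_tree_manifest <- function(manifest) {
  tab <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  need <- c("file", "method", "c", "m", "grouping", "analysis_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort_fmt("manifest is missing columns: %s", paste(miss, collapse = ", "))
  }
  dir <- dirname(manifest)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    read_analysis_tree(file.path(dir, tab$file[i]),
                       method = tab$method[i], c = tab$c[i], m = tab$m[i],
                       grouping = tab$grouping[i],
                       analysis_id = tab$analysis_id[i])
  })
  names(out) <- tab$analysis_id
  out
}
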