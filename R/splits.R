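#' Construct a bipartition
#'
#' A canonical split of a tip-label set into two blocks, the unit of all
#' topology comparison here. The two sides are sorted and ordered so that
#' the side containing the alphabetically first tip of the universe comes
#' first; `(a|b)` and `(b|a)` therefore get the same canonical key.
#'
#' @param side_a,side_b Disjoint, nonempty character vectors of tip labels.
#' @return An object of class `bipartition` with elements `side_a`,
#'   `side_b`, `universe`, `key`.
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(side_a) == 0L || length(side_b) == 0L) {
    abort_fmt("both sides of a bipartition must be nonempty")
  }
  if (length(intersect(side_a, side_b))) {
    abort_fmt("bipartition sides overlap: %s",
              paste(intersect(side_a, side_b), collapse = ", "))
  }
  if (side_b[1L] < side_a[1L]) {
    tmp <- side_a; side_a <- side_b; side_b <- tmp
  }
  structure(list(side_a = side_a, side_b = side_b,
                 universe = sort(c(side_a, side_b)),
                 key = paste(paste(side_a, collapse = ","),
                             paste(side_b, collapse = ","), sep = "|")),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat("<bipartition>", x$key, "\n")
  invisible(x)
}

#' Test whether an object is a degenerate (uninformative) bipartition
#'
#' Restricting a split to a tip subset can leave fewer than two tips on one
#' side; the result then carries no topological information on that subset.
#'
#' @param x Result of [restrict_bipartition()].
#' @return `TRUE` for the degenerate marker.
#' @export
is_degenerate <- function(x) inherits(x, "degenerate_bipartition")

#' Restrict a bipartition to a tip subset
#'
#' Both sides are intersected with `tipset`. If either side is left with
#' fewer than two tips the restriction is uninformative and a degenerate
#' marker is returned.
#'
#' @param b A [bipartition()].
#' @param tipset Nonempty character vector, a subset of `b`'s universe.
#' @return A `bipartition`, or a `degenerate_bipartition` marker.
#' @export
restrict_bipartition <- function(b, tipset) {
  stopifnot(inherits(b, "bipartition"))
  tipset <- unique(as.character(tipset))
  if (length(tipset) == 0L) abort_fmt("cannot restrict to an empty tip set")
  extra <- setdiff(tipset, b$universe)
  if (length(extra)) {
    abort_fmt("tipset is not a subset of the bipartition universe: %s",
              paste(extra, collapse = ", "))
  }
  a <- intersect(b$side_a, tipset)
  bb <- intersect(b$side_b, tipset)
  if (length(a) < 2L || length(bb) < 2L) {
    return(structure(list(side_a = sort(a), side_b = sort(bb)),
                     class = "degenerate_bipartition"))
  }
  bipartition(a, bb)
}

#' Test split compatibility
#'
#' Two splits over the same tip universe are compatible iff at least one of
#' the four pairwise side intersections is empty; equivalently, iff they
#' can coexist as branches of a single tree.
#'
#' @param b1,b2 [bipartition()] objects over the same universe.
#' @return Logical.
#' @export
are_compatible <- function(b1, b2) {
  stopifnot(inherits(b1, "bipartition"), inherits(b2, "bipartition"))
  if (!identical(b1$universe, b2$universe)) {
    abort_fmt("bipartitions are over different universes; restrict first")
  }
  length(intersect(b1$side_a, b2$side_a)) == 0L ||
    length(intersect(b1$side_a, b2$side_b)) == 0L ||
    length(intersect(b1$side_b, b2$side_a)) == 0L ||
    length(intersect(b1$side_b, b2$side_b)) == 0L
}

#' Informative bipartitions of a tree
#'
#' One entry per internal branch of the unrooted topology; pendant (trivial)
#' splits are excluded. A fully resolved unrooted binary tree over `n` tips
#' yields exactly `n - 3` entries. When a rooted representation carries the
#' same split on both root edges, the two are merged and the larger known
#' support kept.
#'
#' @param tree An `analysis_tree`, `summary_tree` or `phylo`.
#' @return A list with `bips` (list of [bipartition()] objects) and
#'   `support` (numeric vector, `NA` for unknown).
#' @export
bipartitions <- function(tree) {
  st <- split_table(tree)
  bips <- lapply(seq_len(nrow(st$mask)), function(i) {
    mask_to_bip(st$mask[i, ], st$universe)
  })
  list(bips = bips, support = st$support)
}

# ---- internal mask-based split machinery ------------------------------------
#
# A split table holds every informative split of a tree, restricted to a
# sorted tip universe, as rows of a logical matrix. TRUE marks the side
# containing universe[1]; the key is the mask packed as a 0/1 string, so
# equality and hashing are cheap and canonical within one universe.

mask_key <- function(mask) {
  if (is.matrix(mask)) {
    apply(mask, 1L, function(r) rawToChar(as.raw(48L + as.integer(r))))
  } else {
    rawToChar(as.raw(48L + as.integer(mask)))
  }
}

mask_to_bip <- function(mask, universe) {
  bipartition(universe[mask], universe[!mask])
}

bip_to_mask <- function(b, universe) {
  if (!setequal(b$universe, universe)) {
    abort_fmt("bipartition universe does not match the requested universe")
  }
  mask <- universe %in% b$side_a
  if (mask[1L]) mask <- !mask
  mask
}

# Extract informative splits of a tree onto `universe` (default: all tips).
# Restriction happens at the mask level; rows that become uninformative are
# dropped and duplicates merged keeping the largest known support.
split_table <- function(tree, universe = NULL) {
  phy <- get_phylo(tree)
  tips <- phy$tip.label
  universe <- sort(universe %||% tips)
  extra <- setdiff(universe, tips)
  if (length(extra)) {
    abort_fmt("universe tips absent from tree: %s", paste(extra, collapse = ", "))
  }
  n <- length(universe)
  sup <- node_supports(phy)
  empty <- list(universe = universe,
                mask = matrix(logical(), 0L, n,
                              dimnames = list(NULL, universe)),
                support = numeric(), key = character())
  if (phy$Nnode < 2L || n < 4L) return(empty)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keep_cols <- match(universe, labs)
  rows <- lapply(seq_along(pp)[-1L], function(i) {
    m <- logical(length(labs))
    m[pp[[i]]] <- TRUE
    m[keep_cols]
  })
  mask <- do.call(rbind, rows)
  support <- sup[-1L][seq_len(nrow(mask))]
  flip <- mask[, 1L]
  mask[flip, ] <- !mask[flip, , drop = FALSE]
  rs <- rowSums(mask)
  keep <- rs >= 2L & rs <= n - 2L
  mask <- mask[keep, , drop = FALSE]
  support <- support[keep]
  if (nrow(mask) == 0L) return(empty)
  key <- mask_key(mask)
  if (anyDuplicated(key)) {
    agg <- tapply(support, key, function(s) {
      if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
    })
    first <- !duplicated(key)
    mask <- mask[first, , drop = FALSE]
    key <- key[first]
    support <- as.numeric(agg[key])
  }
  colnames(mask) <- universe
  list(universe = universe, mask = mask, support = as.numeric(support),
       key = key)
}

# Rows of 0/1 matrix M (splits) incompatible with mask vector b: all four
# intersection counts positive.
incompatible_rows <- function(M, b) {
  if (nrow(M) == 0L) return(logical(0L))
  n <- ncol(M)
  s11 <- as.vector(M %*% b)
  s10 <- rowSums(M) - s11
  s01 <- sum(b) - s11
  s00 <- n - s11 - s10 - s01
  s11 > 0 & s10 > 0 & s01 > 0 & s00 > 0
}
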