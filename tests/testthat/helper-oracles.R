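# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own split machinery: splits
# come from graph components after deleting one edge at a time (igraph).

# internal package helpers exercised directly by some tests
node_supports <- radconcord:::node_supports
split_table <- radconcord:::split_table
tree_tips <- radconcord:::tree_tips
round_half_up <- radconcord:::round_half_up
`%||%` <- radconcord:::`%||%`

# Random unrooted-ish tree with unique labels and random integer supports.
rand_support_tree <- function(n, p_na = 0.2) {
  phy <- ape::rtree(n, tip.label = sprintf("t%02d", seq_len(n)))
  lab <- as.character(sample(0:100, phy$Nnode, replace = TRUE))
  lab[runif(phy$Nnode) < p_na] <- ""
  lab[1L] <- ""
  phy$node.label <- lab
  phy
}

# All splits of a phylo as canonical "A,B|C,D" keys, via edge deletion and
# connected components. Includes only informative splits.
oracle_split_keys <- function(phy) {
  n <- length(phy$tip.label)
  g <- igraph::graph_from_edgelist(apply(phy$edge, 2L, as.character),
                                   directed = FALSE)
  internal <- which(phy$edge[, 2L] > n)
  keys <- character(0L)
  for (e in internal) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, as.character(phy$edge[e, ])))
    comp <- igraph::components(g2)$membership
    side <- as.integer(names(comp)[comp == comp[[as.character(phy$edge[e, 2L])]]])
    tips_a <- sort(phy$tip.label[side[side <= n]])
    tips_b <- sort(setdiff(phy$tip.label, tips_a))
    if (length(tips_a) < 2L || length(tips_b) < 2L) next
    if (tips_b[1L] < tips_a[1L]) { tmp <- tips_a; tips_a <- tips_b; tips_b <- tmp }
    keys <- c(keys, paste(paste(tips_a, collapse = ","),
                          paste(tips_b, collapse = ","), sep = "|"))
  }
  sort(unique(keys))
}

# Monophyly by the same edge-deletion route: some component equals the group.
oracle_is_monophyletic <- function(phy, g) {
  tips <- phy$tip.label
  g <- sort(g)
  if (length(g) <= 1L || length(g) == length(tips)) return(TRUE)
  if (length(setdiff(tips, g)) == 1L) return(TRUE)
  keys <- oracle_split_keys(phy)
  target <- paste(g, collapse = ",")
  any(vapply(strsplit(keys, "|", fixed = TRUE), function(sides) {
    any(sides == target)
  }, logical(1L)))
}

# Hamming distance between equal-length strings, character by character.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Per-column variable/PIS tally written independently of dataset_summary.
oracle_site_counts <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  nvar <- 0L
  npis <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) >= 2L) nvar <- nvar + 1L
    if (sum(tab >= 2L) >= 2L) npis <- npis + 1L
  }
  c(variable = nvar, pis = npis)
}

# Presence-matrix intersection oracle for shared loci.
oracle_shared <- function(ds) {
  acc <- ds$accessions
  out <- matrix(0L, length(acc), length(acc), dimnames = list(acc, acc))
  for (i in acc) for (j in acc) {
    out[i, j] <- sum(vapply(ds$loci, function(l) {
      i %in% names(l) && j %in% names(l)
    }, logical(1L)))
  }
  out
}

# Random loci dataset over a small accession pool.
rand_loci <- function(n_acc = 8, n_loci = 30, len = 10) {
  acc <- sprintf("s%02d", seq_len(n_acc))
  loci <- lapply(seq_len(n_loci), function(i) {
    k <- sample(seq_len(n_acc), 1L)
    who <- sample(acc, k)
    setNames(vapply(who, function(a) {
      paste(sample(c("A", "C", "G", "T", "-", "N"), len,
                   replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
            collapse = "")
    }, ""), who)
  })
  loci_dataset(loci, accessions = acc)
}

# Four populations of two accessions each, one genus.
quad_taxonomy <- function() {
  taxonomy_map(data.frame(
    accession = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    population = rep(c("PA", "PB", "PC", "PD"), each = 2),
    subspecies = rep(c("ssA", "ssB", "ssC", "ssD"), each = 2),
    species = rep(c("spAB", "spCD"), each = 4),
    genus = "G", stringsAsFactors = FALSE))
}

# Tiny fixed taxonomy: two genera, codes mirror the simulator's style.
toy_taxonomy <- function() {
  taxonomy_map(data.frame(
    accession = c("camA1", "camA2", "camB1", "camB2", "outX1", "outX2"),
    population = c("PA", "PA", "PB", "PB", "PX", "PX"),
    subspecies = c("ssA", "ssA", "ssB", "ssB", "ssX", "ssX"),
    species = c("spA", "spA", "spB", "spB", "spX", "spX"),
    genus = c("Cam", "Cam", "Cam", "Cam", "Out", "Out"),
    stringsAsFactors = FALSE))
}
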