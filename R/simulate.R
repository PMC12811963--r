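#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The generator emulates the
#' structure of a multi-genus RADseq sampling design: a nested four-level
#' taxonomy, a true tree on which every taxon is monophyletic except for a
#' few planted outlier accessions, an ensemble of analysis trees derived
#' from the truth by local NNI perturbations with bootstrap supports drawn
#' from stated distributions, and a locus matrix whose missingness is
#' taxonomy-structured: the probability that an accession carries a locus
#' decays geometrically with its taxonomic distance from the locus's origin
#' population, so within-genus sharing far exceeds cross-genus sharing.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_genera,n_species,n_subspecies_per_species,n_populations_per_subspecies,n_individuals_per_population
#'   Taxonomy shape (counts >= 1). `n_species` is per genus.
#' @param n_analyses Number of analysis trees in the ensemble.
#' @param perturbation_rate Expected number of NNI moves per analysis tree
#'   (Poisson).
#' @param support_true Integer range (lo, hi) of bootstrap supports on
#'   branches also present in the true tree (default 91-100).
#' @param support_perturbed Integer range for branches created by
#'   perturbation (default 0-50).
#' @param n_outlier_tips Number of accessions regrafted into a foreign
#'   clade (>= 0).
#' @param n_loci Number of simulated loci.
#' @param coverage_mean Probability that an accession of the origin
#'   population carries a locus.
#' @param cross_group_sharing_decay Multiplicative decay of carriage
#'   probability per taxonomy level separating an accession from the
#'   locus's origin population.
#' @param mutation_rate Per-site, per-branch substitution probability.
#' @param locus_length Aligned length of each simulated locus (bp).
#' @param analysis_grid data.frame with columns `method`, `c`, `m` cycled
#'   over the ensemble; the default is the canonical ten-analysis design
#'   (ML and SVD each over c80m04, c90m04, c90m08, c90m16, c95m04).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genera = 2L,
                       n_species = 3L,
                       n_subspecies_per_species = 2L,
                       n_populations_per_subspecies = 2L,
                       n_individuals_per_population = 2L,
                       n_analyses = 10L,
                       perturbation_rate = 0.5,
                       support_true = c(91L, 100L),
                       support_perturbed = c(0L, 50L),
                       n_outlier_tips = 1L,
                       n_loci = 500L,
                       coverage_mean = 0.5,
                       cross_group_sharing_decay = 0.5,
                       mutation_rate = 0.02,
                       locus_length = 64L,
                       analysis_grid = NULL) {
  counts <- c(n_genera = n_genera, n_species = n_species,
              n_subspecies_per_species = n_subspecies_per_species,
              n_populations_per_subspecies = n_populations_per_subspecies,
              n_individuals_per_population = n_individuals_per_population,
              n_analyses = n_analyses, n_loci = n_loci,
              locus_length = locus_length)
  bad <- names(counts)[counts < 1L]
  if (length(bad)) abort_fmt("counts must be >= 1: %s", paste(bad, collapse = ", "))
  if (n_outlier_tips < 0L) abort_fmt("n_outlier_tips must be >= 0")
  for (nm in c("coverage_mean", "cross_group_sharing_decay", "mutation_rate")) {
    v <- get(nm)
    if (v < 0 || v > 1) abort_fmt("%s must be in [0, 1]", nm)
  }
  if (perturbation_rate < 0) abort_fmt("perturbation_rate must be >= 0")
  for (rng in list(support_true, support_perturbed)) {
    if (length(rng) != 2L || rng[1L] > rng[2L] || rng[1L] < 0 || rng[2L] > 100) {
      abort_fmt("support ranges must be (lo, hi) within 0..100")
    }
  }
  analysis_grid <- analysis_grid %||% data.frame(
    method = rep(c("ML", "SVD"), each = 5L),
    c = rep(c(80L, 90L, 90L, 90L, 95L), 2L),
    m = rep(c(4L, 4L, 8L, 16L, 4L), 2L),
    stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 n_species = as.integer(n_species),
                 n_subspecies_per_species = as.integer(n_subspecies_per_species),
                 n_populations_per_subspecies = as.integer(n_populations_per_subspecies),
                 n_individuals_per_population = as.integer(n_individuals_per_population),
                 n_analyses = as.integer(n_analyses),
                 perturbation_rate = perturbation_rate,
                 support_true = as.integer(support_true),
                 support_perturbed = as.integer(support_perturbed),
                 n_outlier_tips = as.integer(n_outlier_tips),
                 n_loci = as.integer(n_loci),
                 coverage_mean = coverage_mean,
                 cross_group_sharing_decay = cross_group_sharing_decay,
                 mutation_rate = mutation_rate,
                 locus_length = as.integer(locus_length),
                 analysis_grid = analysis_grid),
            class = "sim_config")
}

#' Simulate a nested four-level taxonomy
#'
#' Deterministic label structure (`GenA_sp1_ss2_P01_i1`-style codes) with a
#' seed-dependent row order.
#'
#' @param cfg A [sim_config()].
#' @return A [taxonomy_map()].
#' @export
simulate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- list()
  for (g in seq_len(cfg$n_genera)) {
    genus <- paste0("Gen", LETTERS[g])
    for (s in seq_len(cfg$n_species)) {
      species <- sprintf("%s_sp%d", LETTERS[g], s)
      for (u in seq_len(cfg$n_subspecies_per_species)) {
        ssp <- sprintf("%s_ss%d", species, u)
        for (p in seq_len(cfg$n_populations_per_subspecies)) {
          pop <- sprintf("%s_P%d", ssp, p)
          for (k in seq_len(cfg$n_individuals_per_population)) {
            rows[[length(rows) + 1L]] <- data.frame(
              accession = sprintf("%s_i%d", pop, k),
              population = pop, subspecies = ssp, species = species,
              genus = genus, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  taxonomy_map(df[sample.int(nrow(df)), , drop = FALSE])
}

# Random binary join of subtree strings, all branch lengths 1.
rjoin <- function(parts) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    parts <- c(parts[-i],
               paste0("(", parts[i[1L]], ":1,", parts[i[2L]], ":1):1"))
  }
  parts
}

#' Simulate the true tree with planted outliers
#'
#' Builds a random bifurcating tree in which every taxonomy group at every
#' level is monophyletic, then regrafts `n_outlier_tips` accessions as
#' sister to a random accession of a population from a different species
#' (each outlier from a distinct source population with at least two
#' members). The planted outliers are recorded so recovery can be scored.
#'
#' @param tax A [taxonomy_map()] (typically from [simulate_taxonomy()]).
#' @param cfg The same [sim_config()].
#' @return An object of class `synthetic_truth`: list with `taxonomy`,
#'   `tree` (phylo), `planted_outliers` (data.frame: tip,
#'   source_population, destination_population, host_tip), `config`.
#' @export
simulate_true_tree <- function(tax, cfg) {
  stopifnot(inherits(tax, "taxonomy_map"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  pop_str <- vapply(split(tax$accession, tax$population),
                    function(a) rjoin(sort(a)), "")
  ssp_str <- vapply(split(unname(pop_str),
                          tax$subspecies[match(names(pop_str), tax$population)]),
                    rjoin, "")
  sp_str <- vapply(split(unname(ssp_str),
                         tax$species[match(names(ssp_str), tax$subspecies)]),
                   rjoin, "")
  gen_str <- vapply(split(unname(sp_str),
                          tax$genus[match(names(sp_str), tax$species)]),
                    rjoin, "")
  phy <- ape::read.tree(text = paste0(rjoin(unname(gen_str)), ";"))
  planted <- data.frame(tip = character(), source_population = character(),
                        destination_population = character(),
                        host_tip = character(), stringsAsFactors = FALSE)
  if (cfg$n_outlier_tips > 0L) {
    pop_of <- accession_groups(tax, tax$accession, "population")
    sp_of <- accession_groups(tax, tax$accession, "species")
    pop_sizes <- table(pop_of)
    movable_pops <- names(pop_sizes)[pop_sizes >= 2L]
    if (cfg$n_outlier_tips > length(movable_pops)) {
      abort_fmt("n_outlier_tips (%d) exceeds populations with movable tips (%d)",
                cfg$n_outlier_tips, length(movable_pops))
    }
    src_pops <- sample(movable_pops, cfg$n_outlier_tips)
    outliers <- vapply(src_pops, function(p) {
      sample(names(pop_of)[pop_of == p], 1L)
    }, "")
    # keep planted perturbations non-overlapping: a destination population
    # is never a source nor reused, so each outlier disrupts exactly two
    # groups per level and recovery is well defined
    used_pops <- src_pops
    for (j in seq_along(outliers)) {
      x <- outliers[[j]]
      hosts <- setdiff(names(sp_of)[sp_of != sp_of[[x]] &
                                      !(pop_of %in% used_pops)], outliers)
      if (length(hosts) == 0L) {
        abort_fmt("no destination population available for outlier %s", x)
      }
      h <- sample(hosts, 1L)
      used_pops <- c(used_pops, pop_of[[h]])
      phy <- ape::drop.tip(phy, x)
      phy <- phytools::bind.tip(phy, x, edge.length = 0.5,
                                where = which(phy$tip.label == h),
                                position = 0.5)
      planted <- rbind(planted, data.frame(
        tip = x, source_population = pop_of[[x]],
        destination_population = pop_of[[h]], host_tip = h,
        stringsAsFactors = FALSE))
    }
  }
  phy$node.label <- NULL
  structure(list(taxonomy = tax, tree = phy, planted_outliers = planted,
                 config = cfg),
            class = "synthetic_truth")
}

# Canonical split key of every internal node of a tree (NA for the root and
# for trivial splits), on the sorted full tip universe.
node_split_keys <- function(phy) {
  universe <- sort(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  ord <- match(universe, labs)
  n <- length(labs)
  keys <- rep(NA_character_, length(pp))
  for (i in seq_along(pp)[-1L]) {
    m <- logical(n)
    m[pp[[i]]] <- TRUE
    m <- m[ord]
    if (m[1L]) m <- !m
    s <- sum(m)
    if (s >= 2L && s <= n - 2L) keys[i] <- mask_key(m)
  }
  keys
}

#' Simulate an ensemble of perturbed analysis trees
#'
#' Each analysis tree is the true tree with a Poisson(`perturbation_rate`)
#' number of random NNI moves applied. Internal branches whose bipartition
#' survives in the true tree receive integer supports drawn uniformly from
#' `support_true`; branches created by perturbation draw from
#' `support_perturbed`. Method and assembly metadata cycle over
#' `cfg$analysis_grid`.
#'
#' @param truth A [simulate_true_tree()] result.
#' @param cfg The same [sim_config()].
#' @return List with `analyses` (named list of `analysis_tree`) and
#'   `perturbed` (named list: per analysis, the canonical keys of true-tree
#'   bipartitions it no longer contains).
#' @export
simulate_analysis_set <- function(truth, cfg) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  st_truth <- split_table(truth$tree)
  grid <- cfg$analysis_grid
  analyses <- list()
  perturbed <- list()
  for (i in seq_len(cfg$n_analyses)) {
    k <- rpois(1L, cfg$perturbation_rate)
    tr <- truth$tree
    if (k > 0L) tr <- phangorn::rNNI(truth$tree, moves = k)
    keys <- node_split_keys(tr)
    in_truth <- keys %in% st_truth$key
    lab <- character(length(keys))
    n_true <- sum(in_truth & !is.na(keys))
    n_pert <- sum(!in_truth & !is.na(keys))
    draw <- function(rng, n) {
      rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, n, replace = TRUE) - 1L
    }
    lab[in_truth & !is.na(keys)] <- as.character(draw(cfg$support_true, n_true))
    lab[!in_truth & !is.na(keys)] <-
      as.character(draw(cfg$support_perturbed, n_pert))
    tr$node.label <- lab
    row <- grid[(i - 1L) %% nrow(grid) + 1L, ]
    id <- sprintf("a%02d_%s_c%02dm%02d", i, row$method, row$c, row$m)
    analyses[[id]] <- analysis_tree(tr, method = row$method, c = row$c,
                                    m = row$m, grouping = "individual",
                                    analysis_id = id)
    lost <- setdiff(st_truth$key, keys)
    perturbed[[id]] <- vapply(lost, function(kk) {
      mask_to_bip(st_truth$mask[match(kk, st_truth$key), ],
                  st_truth$universe)$key
    }, "")
  }
  list(analyses = analyses, perturbed = perturbed)
}

# Taxonomy-level distance between each accession and each population:
# 0 same population, 1 same subspecies, 2 same species, 3 same genus,
# 4 different genus.
accession_pop_distance <- function(tax) {
  pops <- sort(unique(tax$population))
  prow <- tax[match(pops, tax$population), ]
  d <- matrix(4L, nrow(tax), length(pops),
              dimnames = list(tax$accession, pops))
  for (j in seq_along(pops)) {
    d[tax$genus == prow$genus[j], j] <- 3L
    d[tax$species == prow$species[j], j] <- 2L
    d[tax$subspecies == prow$subspecies[j], j] <- 1L
    d[tax$population == prow$population[j], j] <- 0L
  }
  d
}

# Evolve one locus down the tree under uniform substitution.
evolve_locus <- function(phy, L, mu) {
  bases <- c("A", "C", "G", "T")
  n <- length(phy$tip.label)
  seqs <- matrix(0L, n + phy$Nnode, L)
  seqs[n + 1L, ] <- sample.int(4L, L, replace = TRUE)
  edge <- reorder(phy, "cladewise")$edge
  for (e in seq_len(nrow(edge))) {
    s <- seqs[edge[e, 1L], ]
    mut <- which(runif(L) < mu)
    if (length(mut)) {
      s[mut] <- 1L + (s[mut] - 1L + sample.int(3L, length(mut), TRUE)) %% 4L
    }
    seqs[edge[e, 2L], ] <- s
  }
  setNames(vapply(seq_len(n), function(i) {
    paste(bases[seqs[i, ]], collapse = "")
  }, ""), phy$tip.label)
}

#' Simulate a locus dataset with taxonomy-structured missingness
#'
#' For each locus an origin population is drawn uniformly; each accession
#' carries the locus with probability `coverage_mean *
#' cross_group_sharing_decay^d`, where `d` is the number of taxonomy levels
#' separating the accession from the origin population (0 within the
#' population up to 4 across genera). Sequences evolve down the true tree
#' under uniform per-site substitution. Loci that end up with no carrier
#' are never observed and are dropped.
#'
#' @param truth A [simulate_true_tree()] result.
#' @param cfg The same [sim_config()].
#' @return A [loci_dataset()] whose accession universe is all simulated
#'   accessions.
#' @export
simulate_loci_dataset <- function(truth, cfg) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  tax <- truth$taxonomy
  phy <- truth$tree
  d <- accession_pop_distance(tax)
  P <- cfg$coverage_mean * cfg$cross_group_sharing_decay^d
  pops <- colnames(P)
  accs <- phy$tip.label
  P <- P[accs, , drop = FALSE]
  loci <- list()
  for (l in seq_len(cfg$n_loci)) {
    o <- sample(pops, 1L)
    carry <- runif(length(accs)) < P[, o]
    seqs <- evolve_locus(phy, cfg$locus_length, cfg$mutation_rate)
    if (!any(carry)) next
    loci[[length(loci) + 1L]] <- seqs[accs[carry]]
  }
  loci_dataset(loci, accessions = sort(accs))
}

#' Analytic expectation of pairwise locus sharing under the simulator model
#'
#' Expected number of loci carried by both accessions of each pair, given
#' the taxonomy-structured carriage model of [simulate_loci_dataset()]:
#' `n_loci * mean_o(p_i(o) * p_j(o))` over uniform origin populations. The
#' diagonal holds each accession's expected locus count.
#'
#' @param tax A [taxonomy_map()].
#' @param cfg A [sim_config()].
#' @return Symmetric numeric matrix over `tax$accession`.
#' @export
expected_pair_sharing <- function(tax, cfg) {
  d <- accession_pop_distance(tax)
  P <- cfg$coverage_mean * cfg$cross_group_sharing_decay^d
  E <- cfg$n_loci * (P %*% t(P)) / ncol(P)
  diag(E) <- cfg$n_loci * rowMeans(P)
  E
}

#' Run the full generator
#'
#' @param cfg A [sim_config()].
#' @return List with `config`, `taxonomy`, `truth`, `analyses`,
#'   `perturbed`, `loci`.
#' @export
simulate_all <- function(cfg) {
  tax <- simulate_taxonomy(cfg)
  truth <- simulate_true_tree(tax, cfg)
  aset <- simulate_analysis_set(truth, cfg)
  loci <- simulate_loci_dataset(truth, cfg)
  list(config = cfg, taxonomy = tax, truth = truth,
       analyses = aset$analyses, perturbed = aset$perturbed, loci = loci)
}
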