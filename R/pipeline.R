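#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list, fills in defaults, and returns the
#' normalized configuration together with the complete list of validation
#' errors (all problems are collected and reported together, not just the
#' first).
#'
#' @param x Path to a YAML config or a list with the same structure. Keys:
#'   `seed`; exactly one of `simulate` ([sim_config()] arguments) or
#'   `inputs` (paths `loci`, `taxonomy`, `manifest`); optional `m_values`,
#'   `min_accession_loci`, `thresholds`
#'   ([classification_thresholds()] arguments), `rooting` ([rooting_rule()]
#'   arguments plus `focal_genus`/`outgroup_genus`), `support_threshold`,
#'   `level`, `out_dir`.
#' @return List with `config` (normalized list) and `errors` (character
#'   vector, empty when valid).
#' @export
validate_config <- function(x) {
  errors <- character(0L)
  note <- function(msg) errors <<- c(errors, msg)
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) {
      return(list(config = NULL, errors = sprintf("config file not found: %s", x)))
    }
    yaml::read_yaml(x)
  } else if (is.list(x)) x else {
    return(list(config = NULL, errors = "config must be a path or a list"))
  }
  cfg$seed <- cfg$seed %||% 1L
  if (!is.numeric(cfg$seed)) note("seed must be an integer")
  has_sim <- !is.null(cfg$simulate)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim && has_inp) note("set either 'simulate' or 'inputs', not both")
  if (!has_sim && !has_inp) cfg$simulate <- list()
  if (has_inp) {
    for (key in c("loci", "taxonomy", "manifest")) {
      p <- cfg$inputs[[key]]
      if (is.null(p)) note(sprintf("inputs.%s is required", key))
      else if (!file.exists(p)) note(sprintf("inputs.%s not found: %s", key, p))
    }
  }
  if (!is.null(cfg$simulate)) {
    bad <- setdiff(names(cfg$simulate), names(formals(sim_config)))
    if (length(bad)) {
      note(sprintf("unknown simulate option(s): %s", paste(bad, collapse = ", ")))
    }
  }
  cfg$m_values <- cfg$m_values %||% c(4L, 8L, 16L, 32L)
  if (any(cfg$m_values < 1)) note("m_values must all be >= 1")
  cfg$min_accession_loci <- cfg$min_accession_loci %||% 100L
  if (cfg$min_accession_loci < 0) note("min_accession_loci must be >= 0")
  th <- tryCatch(do.call(classification_thresholds,
                         cfg$thresholds %||% list()),
                 error = function(e) {
                   note(conditionMessage(e))
                   NULL
                 })
  cfg$thresholds_obj <- th
  rt <- cfg$rooting %||% list(min_shared_loci = 100L,
                              min_partner_accessions = 10L,
                              partner_scope = "other_genus")
  rule_args <- rt[intersect(names(rt), names(formals(rooting_rule)))]
  cfg$rooting_rule <- tryCatch(do.call(rooting_rule, rule_args),
                               error = function(e) {
                                 note(conditionMessage(e))
                                 NULL
                               })
  cfg$rooting <- rt
  cfg$support_threshold <- cfg$support_threshold %||% 90
  cfg$level <- cfg$level %||% "population"
  if (!cfg$level %in% c("population", "subspecies", "species")) {
    note(sprintf("level must be population/subspecies/species, got '%s'", cfg$level))
  }
  list(config = cfg, errors = errors)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — data (simulate or ingest), locus
#' filtering/statistics, rooting-accession selection, ensemble
#' summarization, monophyly accounting — writing every stage's tables and
#' trees under `out_dir` plus a JSON run manifest. Reruns with an identical
#' configuration are byte-identical.
#'
#' @param config Path to a YAML config or a list (see [validate_config()]).
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  v <- validate_config(config)
  if (length(v$errors)) {
    abort_fmt("invalid configuration:\n- %s", paste(v$errors, collapse = "\n- "))
  }
  cfg <- v$config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort_fmt("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  stages <- list()
  write_manifest <- function(status) {
    m <- list(tool = "radconcord",
              version = as.character(utils::packageVersion("radconcord")),
              seed = cfg$seed, config_hash = cfg_hash, status = status,
              stages = stages)
    jsonlite::write_json(m, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    m
  }
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), c("thresholds_obj", "rooting_rule"))],
                   cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- list(status = "failed",
                              error = conditionMessage(res))
      write_manifest("incomplete")
      abort_fmt("stage '%s' failed: %s", name, conditionMessage(res))
    }
    stages[[name]] <<- c(list(status = "ok"), res)
    invisible(res)
  }
  msg <- function(...) message(sprintf(...))

  env <- new.env()
  run_stage("data", function() {
    if (!is.null(cfg$inputs)) {
      env$tax <- read_taxonomy(cfg$inputs$taxonomy)
      env$loci <- read_loci(cfg$inputs$loci)
      env$analyses <- read_tree_manifest(cfg$inputs$manifest)
      env$truth <- NULL
      list(source = "inputs", n_analyses = length(env$analyses),
           n_loci = n_loci(env$loci))
    } else {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim <- simulate_all(do.call(sim_config, sim_args))
      env$tax <- sim$taxonomy
      env$loci <- sim$loci
      env$analyses <- sim$analyses
      env$truth <- sim$truth
      write_taxonomy(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
      ape::write.tree(sim$truth$tree, file.path(out_dir, "truth.nwk"))
      adir <- file.path(out_dir, "analyses")
      dir.create(adir, showWarnings = FALSE)
      man <- data.frame(file = paste0(names(sim$analyses), ".nwk"),
                        method = vapply(sim$analyses, function(a) a$meta$method, ""),
                        c = vapply(sim$analyses, function(a) a$meta$c, 1L),
                        m = vapply(sim$analyses, function(a) a$meta$m, 1L),
                        grouping = vapply(sim$analyses, function(a) a$meta$grouping, ""),
                        analysis_id = names(sim$analyses),
                        stringsAsFactors = FALSE)
      for (id in names(sim$analyses)) {
        writeLines(write_newick(sim$analyses[[id]]),
                   file.path(adir, paste0(id, ".nwk")))
      }
      write_tsv(man, file.path(adir, "manifest.tsv"))
      write_loci(sim$loci, file.path(out_dir, "loci.loci"))
      jsonlite::write_json(
        list(planted_outliers = sim$truth$planted_outliers,
             perturbed = sim$perturbed),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
      list(source = "simulate", n_analyses = length(env$analyses),
           n_loci = n_loci(env$loci))
    }
  })

  run_stage("filter_stats", function() {
    lc <- remove_low_coverage(env$loci, cfg$min_accession_loci)
    env$base <- lc$dataset
    n_acc <- length(env$base$accessions)
    rows <- lapply(cfg$m_values[cfg$m_values <= max(1L, n_acc)], function(m) {
      fd <- min_samples_filter(env$base, m)
      s <- dataset_summary(fd)
      data.frame(m = m,
                 coverage_percent = coverage_percent(m, max(n_acc, m)),
                 n_accessions = s$n_accessions,
                 total_loci = s$total_loci,
                 mean_loci_per_accession =
                   round_half_up(s$mean_loci_per_accession),
                 n_variable_sites = s$n_variable_sites,
                 n_parsimony_informative_sites = s$n_parsimony_informative_sites)
    })
    tab <- do.call(rbind, rows)
    write_tsv(tab, file.path(out_dir, "dataset_summary.tsv"))
    counts <- accession_locus_counts(env$base)
    write_tsv(data.frame(accession = names(counts),
                         locus_count = as.integer(counts)),
              file.path(out_dir, "locus_counts.tsv"))
    write_tsv(data.frame(accession = names(lc$removed),
                         locus_count = as.integer(lc$removed)),
              file.path(out_dir, "removed_accessions.tsv"))
    list(n_accessions = n_acc, n_removed = length(lc$removed),
         n_m_values = nrow(tab))
  })

  run_stage("select_root", function() {
    genera <- unique(accession_groups(env$tax, env$base$accessions, "genus"))
    if (length(genera) < 2L || is.null(cfg$rooting_rule)) {
      write_tsv(data.frame(), file.path(out_dir, "rooting_selection.tsv"))
      return(list(skipped = "fewer than two genera"))
    }
    focal <- cfg$rooting$focal_genus %||% genera[1L]
    outg <- cfg$rooting$outgroup_genus %||% setdiff(genera, focal)[1L]
    sm <- shared_loci(env$base, matching = FALSE)
    within <- summarize_sharing(sm, env$tax, focal)
    cross <- summarize_sharing(sm, env$tax, focal, outg)
    write_tsv(data.frame(
      comparison = c(paste0("within_", focal), paste0(focal, "_vs_", outg)),
      n_pairs = c(within$n_pairs, cross$n_pairs),
      mean_shared = round_half_up(c(within$mean_shared, cross$mean_shared), 1)),
      file.path(out_dir, "sharing_summary.tsv"))
    write.table(sm$shared, file.path(out_dir, "shared_matrix.tsv"),
                sep = "\t", quote = FALSE)
    sel <- select_rooting_accessions(env$base, env$tax, cfg$rooting_rule,
                                     focal, outg, sm = sm)
    write_tsv(sel$report, file.path(out_dir, "rooting_selection.tsv"))
    list(focal = focal, outgroup = outg, n_selected = length(sel$selected),
         mean_shared_within = within$mean_shared,
         mean_shared_cross = cross$mean_shared)
  })

  run_stage("summarize", function() {
    st <- build_summary_tree(env$analyses, cfg$thresholds_obj)
    env$summary <- st
    writeLines(write_newick(st, annotation_mode = "classified"),
               file.path(out_dir, "summary_tree.nwk"))
    writeLines(write_newick(st), file.path(out_dir, "summary_tree_plain.nwk"))
    write_tsv(st$splits, file.path(out_dir, "summary_splits.tsv"))
    write_tsv(st$candidates, file.path(out_dir, "summary_candidates.tsv"))
    ev <- do.call(rbind, lapply(names(st$evidence), function(k) {
      data.frame(key = k, st$evidence[[k]], stringsAsFactors = FALSE)
    }))
    write_tsv(ev, file.path(out_dir, "summary_evidence.tsv"))
    cls <- table(factor(st$splits$class, levels = branch_classes))
    as.list(setNames(as.integer(cls), paste0("n_", tolower(names(cls)))))
  })

  run_stage("monophyly", function() {
    cr <- cohesion_report(env$analyses, env$tax, cfg$level,
                          support_threshold = cfg$support_threshold)
    write_tsv(cr$results, file.path(out_dir, "cohesion.tsv"))
    write_tsv(cr$tallies, file.path(out_dir, "cohesion_tallies.tsv"))
    groups <- tax_groups(env$tax, cfg$level,
                         accessions = env$summary$universe)
    out_rows <- list()
    for (g in names(groups)) {
      size <- length(groups[[g]])
      budget <- min(3L, size - 2L)
      if (budget < 1L) next
      r <- is_monophyletic(env$summary, groups[[g]], group = g)
      if (r$status %in% c("monophyletic", "trivial")) next
      fo <- find_outliers(env$summary, groups[[g]], max_removals = budget)
      out_rows[[g]] <- data.frame(
        group = g, size = size, status = fo$status,
        removal_sets = paste(vapply(fo$removals, paste, "", collapse = ","),
                             collapse = ";"),
        stringsAsFactors = FALSE)
    }
    outliers <- if (length(out_rows)) do.call(rbind, out_rows) else
      data.frame(group = character(), size = integer(), status = character(),
                 removal_sets = character(), stringsAsFactors = FALSE)
    rownames(outliers) <- NULL
    write_tsv(outliers, file.path(out_dir, "outliers.tsv"))
    list(level = cfg$level, n_groups = nrow(cr$results) /
           max(1L, nrow(cr$tallies)),
         n_outlier_groups = nrow(outliers))
  })

  invisible(write_manifest("complete"))
}
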