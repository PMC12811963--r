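#' Construct a taxonomy map
#'
#' Four-level classification of accessions: accession -> population ->
#' subspecies -> species -> genus. Drives grouping for induced trees,
#' monophyly accounting and rooting-rule selection.
#'
#' @param df A data.frame with character columns `accession`, `population`,
#'   `subspecies`, `species`, `genus`.
#' @return A data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(df) {
  need <- c("accession", "population", "subspecies", "species", "genus")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_fmt("taxonomy is missing required column(s): %s",
              paste(miss, collapse = ", "))
  }
  df <- df[, need]
  for (col in need) df[[col]] <- gsub("\\s+", "_", as.character(df[[col]]))
  dup <- unique(df$accession[duplicated(df$accession)])
  if (length(dup)) {
    abort_fmt("duplicated accession in taxonomy: %s", paste(dup, collapse = ", "))
  }
  for (col in c("population", "species", "genus")) {
    if (any(!nzchar(df[[col]]))) {
      abort_fmt("taxonomy column '%s' has empty values", col)
    }
  }
  structure(df, class = c("taxonomy_map", "data.frame"))
}

#' Read a taxonomy table
#'
#' @param path Path to a delimited text file with a header row containing
#'   `accession`, `population`, `subspecies`, `species`, `genus`.
#' @param delimiter Field delimiter (default tab; use `","` for CSV).
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path, delimiter = "\t") {
  taxonomy_map(read.delim(path, sep = delimiter, stringsAsFactors = FALSE,
                          colClasses = "character"))
}

tax_levels <- c("individual", "population", "subspecies", "species", "genus")

# Group label of each requested accession at a level ("individual" maps an
# accession to itself). Errors on accessions absent from the map.
accession_groups <- function(tax, accessions, level) {
  level <- match.arg(level, tax_levels)
  if (level == "individual") return(setNames(accessions, accessions))
  i <- match(accessions, tax$accession)
  if (anyNA(i)) {
    abort_fmt("accessions absent from taxonomy: %s",
              paste(accessions[is.na(i)], collapse = ", "))
  }
  setNames(tax[[level]][i], accessions)
}

#' Group accessions by taxonomy level
#'
#' @param tax A [taxonomy_map()].
#' @param level One of `"population"`, `"subspecies"`, `"species"`,
#'   `"genus"` (or `"individual"`, a no-op grouping).
#' @param accessions Optional subset of accessions to group (defaults to
#'   all accessions in the map).
#' @return Named list: group label -> character vector of accession ids.
#' @export
tax_groups <- function(tax, level, accessions = NULL) {
  accessions <- accessions %||% tax$accession
  g <- accession_groups(tax, accessions, level)
  split(names(g), unname(g))
}

#' Report tree/locus accessions missing from a taxonomy map
#'
#' @param tax A [taxonomy_map()].
#' @param accessions Accession ids seen in trees or locus files.
#' @return Character vector of ids absent from the map (possibly empty).
#' @export
unmapped_accessions <- function(tax, accessions) {
  sort(setdiff(accessions, tax$accession))
}

#' Write a taxonomy map as TSV
#' @param tax A [taxonomy_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
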