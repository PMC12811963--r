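#' Construct a locus dataset
#'
#' The substrate for all locus-matrix operations: an ordered list of loci,
#' each a named character vector mapping accession id to its aligned
#' sequence (uppercase IUPAC, `-` gap, `N`), plus the accession universe.
#' The universe may be wider than the union over loci (accessions can lose
#' all their loci under filtering yet remain part of the dataset).
#'
#' @param loci List of named character vectors; within one locus all
#'   sequences must have equal, positive length.
#' @param accessions Optional accession universe; defaults to the union of
#'   accession names over loci.
#' @return An object of class `loci_dataset`.
#' @export
loci_dataset <- function(loci, accessions = NULL) {
  loci <- lapply(loci, function(x) {
    x[] <- toupper(x)
    x
  })
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    if (length(l) < 1L || is.null(names(l)) || any(names(l) == "")) {
      abort_fmt("locus %d has no named sequences", i)
    }
    if (length(unique(nchar(l))) > 1L) {
      abort_fmt("locus %d has ragged sequence lengths", i)
    }
    if (nchar(l[1L]) < 1L) abort_fmt("locus %d has empty sequences", i)
    if (anyDuplicated(names(l))) {
      abort_fmt("locus %d lists an accession twice", i)
    }
  }
  seen <- unique(unlist(lapply(loci, names), use.names = FALSE))
  accessions <- sort(unique(c(accessions, seen)))
  missing <- setdiff(seen, accessions)
  if (length(missing)) {
    abort_fmt("locus accessions outside the universe: %s",
              paste(missing, collapse = ", "))
  }
  structure(list(loci = loci, accessions = accessions),
            class = "loci_dataset")
}

#' @export
print.loci_dataset <- function(x, ...) {
  cat(sprintf("<loci_dataset> %d loci, %d accessions\n",
              length(x$loci), length(x$accessions)))
  invisible(x)
}

#' Number of loci in a dataset
#' @param ds A `loci_dataset`.
#' @return Integer count.
#' @export
n_loci <- function(ds) length(ds$loci)

#' Read an ipyrad-style .loci file
#'
#' Blocks of `accession<whitespace>sequence` lines, each block terminated by
#' a line beginning `//` (trailing SNP-flag annotation after `//` is
#' ignored). A leading `>` on accession names is tolerated and stripped;
#' whitespace inside accession names is not possible in this dialect.
#'
#' @param path Path to a .loci file, or a character vector of lines.
#' @return A [loci_dataset()].
#' @export
read_loci <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(loci_dataset(list()))
  is_term <- startsWith(trimws(lines), "//")
  if (!is_term[length(lines)]) {
    abort_fmt("unterminated final locus block (no closing '//' line)")
  }
  block_id <- cumsum(c(TRUE, head(is_term, -1L)))
  loci <- list()
  ordinal <- 0L
  for (b in split(seq_along(lines), block_id)) {
    body <- b[!is_term[b]]
    if (length(body) == 0L) next
    ordinal <- ordinal + 1L
    fields <- regmatches(lines[body],
                         regexpr("^\\s*(\\S+)\\s+(\\S+)\\s*$", lines[body]))
    parts <- strsplit(trimws(lines[body]), "\\s+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      abort_fmt("locus %d: line %d is not 'accession sequence'",
                ordinal, body[bad[1L]])
    }
    acc <- sub("^>", "", vapply(parts, `[[`, "", 1L))
    seqs <- toupper(vapply(parts, `[[`, "", 2L))
    if (length(unique(nchar(seqs))) > 1L) {
      abort_fmt("locus %d has ragged sequence lengths", ordinal)
    }
    loci[[ordinal]] <- setNames(seqs, acc)
  }
  loci_dataset(loci)
}

#' Write a locus dataset in .loci format
#'
#' @param ds A [loci_dataset()].
#' @param path Output path; if `NULL`, the lines are returned invisibly
#'   instead of written.
#' @return The output lines, invisibly.
#' @export
write_loci <- function(ds, path = NULL) {
  stopifnot(inherits(ds, "loci_dataset"))
  width <- max(0L, nchar(unlist(lapply(ds$loci, names), use.names = FALSE)))
  lines <- unlist(lapply(ds$loci, function(l) {
    c(sprintf("%-*s %s", width, names(l), unname(l)), "//")
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines %||% character(), path)
  invisible(lines %||% character())
}
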