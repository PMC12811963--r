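#' Read a 4-line-record FASTQ file
#'
#' Minimal FASTQ reader for demultiplexing fixtures. Records must be exactly
#' four lines (`@id`, sequence, `+`, quality); qualities are carried through
#' untouched and never reinterpreted.
#'
#' @param path Path to an uncompressed FASTQ file, or a character vector of
#'   lines (useful for in-memory fixtures).
#' @return A data.frame of class `fastq_reads` with columns `id`, `seq`,
#'   `qual`.
#' @export
read_fastq <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) %% 4L != 0L) {
    abort_fmt("malformed FASTQ: %d lines is not a multiple of 4 (record %d is truncated)",
              length(lines), length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(fastq_reads(character(), character(), character()))
  idx <- 4L * (seq_len(n) - 1L)
  hdr <- lines[idx + 1L]
  seq <- lines[idx + 2L]
  sep <- lines[idx + 3L]
  qual <- lines[idx + 4L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    abort_fmt("malformed FASTQ: record %d does not start with '@'", bad_hdr[1L])
  }
  bad_sep <- which(!startsWith(sep, "+"))
  if (length(bad_sep)) {
    abort_fmt("malformed FASTQ: record %d separator line does not start with '+'", bad_sep[1L])
  }
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len)) {
    abort_fmt("malformed FASTQ: record %d sequence/quality length mismatch (%d vs %d)",
              bad_len[1L], nchar(seq[bad_len[1L]]), nchar(qual[bad_len[1L]]))
  }
  fastq_reads(sub("^@", "", hdr), seq, qual)
}

fastq_reads <- function(id, seq, qual) {
  structure(data.frame(id = id, seq = seq, qual = qual,
                       stringsAsFactors = FALSE),
            class = c("fastq_reads", "data.frame"))
}

#' Write FASTQ records
#'
#' @param reads A `fastq_reads` data.frame (see [read_fastq()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read an inline-barcode table
#'
#' Two-column table (`sample`, `barcode`, with header) mapping sample ids to
#' the fixed-length nucleotide barcodes ligated at the 5' end of each read.
#'
#' @param path Path to a TSV/CSV file, or a data.frame with columns
#'   `sample` and `barcode`.
#' @param delimiter Field delimiter when reading from file.
#' @return A validated data.frame of class `barcode_table`.
#' @export
read_barcodes <- function(path, delimiter = "\t") {
  tab <- if (is.data.frame(path)) path else
    read.delim(path, sep = delimiter, stringsAsFactors = FALSE)
  if (!all(c("sample", "barcode") %in% names(tab))) {
    abort_fmt("barcode table needs columns 'sample' and 'barcode'")
  }
  barcode_table(tab$sample, toupper(tab$barcode))
}

#' Construct a barcode table
#'
#' @param sample Character vector of unique sample ids.
#' @param barcode Character vector of same-length, unique A/C/G/T barcodes.
#' @return A data.frame of class `barcode_table`.
#' @export
barcode_table <- function(sample, barcode) {
  barcode <- toupper(barcode)
  if (anyDuplicated(sample)) abort_fmt("duplicate sample ids in barcode table")
  if (anyDuplicated(barcode)) abort_fmt("duplicate barcodes in barcode table")
  if (length(unique(nchar(barcode))) > 1L) {
    abort_fmt("barcodes must all have the same length")
  }
  if (any(grepl("[^ACGT]", barcode))) {
    abort_fmt("barcodes must use only A, C, G, T")
  }
  structure(data.frame(sample = sample, barcode = barcode,
                       stringsAsFactors = FALSE),
            class = c("barcode_table", "data.frame"))
}

# Hamming distance between each read prefix and one barcode.
prefix_distance <- function(prefixes, barcode) {
  bc <- strsplit(barcode, "", fixed = TRUE)[[1L]]
  pm <- matrix(unlist(strsplit(prefixes, "", fixed = TRUE), use.names = FALSE),
               nrow = length(bc))
  colSums(pm != bc)
}

#' Demultiplex FASTQ reads by inline barcode
#'
#' Assigns each read to the unique sample whose barcode matches the read's
#' first `L` bases within `max_mismatch` Hamming distance (`L` = barcode
#' length). The matched prefix is trimmed from both sequence and quality.
#' Reads matching no barcode, or tied between two or more barcodes at the
#' same best distance, are left in the `unassigned` stream untrimmed: ties
#' are never broken arbitrarily.
#'
#' @param reads A `fastq_reads` data.frame ([read_fastq()]).
#' @param table A `barcode_table`.
#' @param max_mismatch Maximum tolerated Hamming distance (default 0,
#'   i.e. exact prefix match).
#' @return A list with `samples` (named list of `fastq_reads`, one per
#'   sample, barcodes trimmed), `unassigned` (`fastq_reads`), and `counts`
#'   (named integer vector including `unassigned`). Assigned plus
#'   unassigned always equals the input read count.
#' @export
demultiplex_fastq <- function(reads, table, max_mismatch = 0L) {
  stopifnot(inherits(table, "barcode_table"), max_mismatch >= 0L)
  L <- nchar(table$barcode[1L])
  short <- which(nchar(reads$seq) < L)
  if (length(short)) {
    abort_fmt("read %d is shorter than the %d-bp barcode", short[1L], L)
  }
  n <- nrow(reads)
  assign_to <- rep(NA_integer_, n)
  if (n > 0L) {
    prefixes <- substr(reads$seq, 1L, L)
    d <- vapply(table$barcode, function(b) prefix_distance(prefixes, b),
                numeric(n))
    d <- matrix(d, nrow = n)
    best <- apply(d, 1L, min)
    nbest <- rowSums(d == best)
    ok <- best <= max_mismatch & nbest == 1L
    assign_to[ok] <- apply(d[ok, , drop = FALSE], 1L, which.min)
  }
  samples <- lapply(seq_len(nrow(table)), function(i) {
    r <- reads[which(assign_to == i), , drop = FALSE]
    fastq_reads(r$id,
                substr(r$seq, L + 1L, nchar(r$seq)),
                substr(r$qual, L + 1L, nchar(r$qual)))
  })
  names(samples) <- table$sample
  un <- reads[is.na(assign_to), , drop = FALSE]
  counts <- c(vapply(samples, nrow, integer(1L)), unassigned = nrow(un))
  list(samples = samples,
       unassigned = fastq_reads(un$id, un$seq, un$qual),
       counts = counts)
}
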