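#' Read-count table for one sequencing sample
#'
#' A read-count table maps every distinct read sequence observed in a sample
#' to its multiplicity.  It is the unit all downstream steps consume: error
#' rate estimation never looks at individual reads again, only at how often
#' each distinct sequence occurred.
#'
#' @param sequences Character vector of distinct read sequences (alphabet
#'   A, C, G, T, N), all of the same length.
#' @param counts Positive integer vector of multiplicities, parallel to
#'   `sequences`.
#'
#' @return An object of class `read_count_table`: a list with elements
#'   `entries` (named integer vector, names are sequences), `read_length`
#'   and `total_reads`.
#' @seealso [count_reads()], [rank_sequences()], [select_error_free()]
#' @export
#' @examples
#' read_count_table(c("ACGT", "TTTT"), c(2, 1))
read_count_table <- function(sequences, counts) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) {
    stop("a read-count table must contain at least one sequence")
  }
  if (length(sequences) != length(counts)) {
    stop("`sequences` and `counts` must have the same length")
  }
  if (anyDuplicated(sequences)) {
    stop("duplicate sequences in read-count table: ",
         paste(head(unique(sequences[duplicated(sequences)]), 3L),
               collapse = ", "))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("all sequences must have the same length (found lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("sequences may only contain A, C, G, T, N")
  }
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != round(counts))) {
    stop("all counts must be positive integers")
  }
  counts <- as.integer(round(counts))
  entries <- counts
  names(entries) <- sequences
  structure(
    list(entries = entries, read_length = lens[[1L]],
         total_reads = sum(counts)),
    class = "read_count_table"
  )
}

#' @export
print.read_count_table <- function(x, ...) {
  cat("Read-count table: ", length(x$entries), " distinct sequences, ",
      x$total_reads, " reads of length ", x$read_length, " bp\n", sep = "")
  invisible(x)
}

#' Tally a FASTQ file into a read-count table
#'
#' Parses a 4-line-record FASTQ file (plain or gzip-compressed) containing
#' equal-length reads and counts the multiplicity of every distinct
#' sequence.  Quality strings are ignored: the shadow-based estimators use
#' sequence identity only.
#'
#' @param fastq Path to a FASTQ file.  Reads must all have the same length;
#'   a read of deviating length is a hard error naming the offending
#'   record.
#'
#' @return A [read_count_table()] whose `total_reads` equals the number of
#'   FASTQ records.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII",
#'              "@r2", "ACGT", "+", "IIII",
#'              "@r3", "TTTT", "+", "IIII"), fq)
#' count_reads(fq)
count_reads <- function(fastq) {
  stopifnot(is.character(fastq), length(fastq) == 1L)
  if (!file.exists(fastq)) stop("FASTQ file not found: ", fastq)
  lines <- readLines(fastq)  # file() transparently decompresses gzip
  if (length(lines) == 0L) stop("empty FASTQ file: ", fastq)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L, "?)")
  }
  n_rec <- length(lines) %/% 4L
  heads <- lines[seq(1L, by = 4L, length.out = n_rec)]
  seps  <- lines[seq(3L, by = 4L, length.out = n_rec)]
  bad_head <- which(!startsWith(heads, "@"))
  if (length(bad_head)) {
    stop("malformed FASTQ record at line ", 4L * (bad_head[[1L]] - 1L) + 1L,
         ": header does not start with '@'")
  }
  bad_sep <- which(!startsWith(seps, "+"))
  if (length(bad_sep)) {
    stop("malformed FASTQ record at line ", 4L * (bad_sep[[1L]] - 1L) + 3L,
         ": separator does not start with '+'")
  }
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n_rec)])
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[[1L]])[[1L]]
    stop("unequal read lengths: record ", off, " has length ", lens[[off]],
         " but record 1 has length ", lens[[1L]])
  }
  tab <- table(seqs)
  read_count_table(names(tab), as.integer(tab))
}

#' Write or read a read-count table as TSV
#'
#' The on-disk dialect is a two-column tab-separated file, sequence first
#' and count second, with a header line `sequence<TAB>count`.  On reading,
#' the header is auto-detected so headerless files are accepted too.
#' `write_counts()` followed by `read_counts()` is the identity on the
#' table's entries.
#'
#' @param table A [read_count_table()].
#' @param path File path.
#'
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns a [read_count_table()].
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "read_count_table"))
  df <- data.frame(sequence = names(table$entries),
                   count = unname(table$entries))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- identical(tolower(first), "sequence\tcount")
  df <- read.delim(path, header = has_header,
                   colClasses = c("character", "numeric"))
  if (ncol(df) != 2L) stop("count file must have exactly 2 columns")
  names(df) <- c("sequence", "count")
  if (nrow(df) == 0L) stop("count file contains no entries: ", path)
  if (anyDuplicated(df$sequence)) {
    stop("duplicate sequence rows in count file: ",
         paste(head(unique(df$sequence[duplicated(df$sequence)]), 3L),
               collapse = ", "))
  }
  if (any(df$count != round(df$count))) {
    stop("non-integer count in count file")
  }
  read_count_table(df$sequence, df$count)
}

#' Rank the sequences of a sample by multiplicity
#'
#' Orders all distinct sequences by count, descending.  Ties are broken
#' lexicographically (C locale) so the ranking is deterministic across runs
#' and platforms.
#'
#' @param table A [read_count_table()].
#' @return A `data.frame` with columns `sequence` and `count`, counts
#'   non-increasing.
#' @export
rank_sequences <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  seqs <- names(table$entries)
  counts <- unname(table$entries)
  ord <- order(-counts, seqs, method = "radix")
  data.frame(sequence = seqs[ord], count = counts[ord],
             stringsAsFactors = FALSE)
}
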