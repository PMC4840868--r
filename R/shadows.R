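#' Select the presumed error-free sequences of a sample
#'
#' The shadow approach presumes that the most frequent distinct sequences in
#' a sample are error free: a sequencing error turns a copy of an abundant
#' sequence into a rare near-duplicate, so genuine template sequences
#' dominate the top of the frequency ranking.  By convention the top 1000
#' sequences are used.  Sequences containing an uncalled base (N) are never
#' eligible, because an uncalled position cannot anchor mismatch counting.
#'
#' @param table A [read_count_table()].
#' @param n_top Capacity of the error-free set (default 1000 sequences).
#'
#' @return An object of class `error_free_set`: a `data.frame` with columns
#'   `sequence` and `count`, at most `n_top` rows, counts non-increasing
#'   (ties broken lexicographically, as in [rank_sequences()]).
#' @export
select_error_free <- function(table, n_top = 1000L) {
  stopifnot(inherits(table, "read_count_table"),
            is.numeric(n_top), n_top >= 1)
  ranked <- rank_sequences(table)
  eligible <- ranked[!grepl("N", ranked$sequence, fixed = TRUE), ,
                     drop = FALSE]
  if (nrow(eligible) == 0L) {
    stop("no sequence without N available as an error-free anchor")
  }
  out <- head(eligible, n_top)
  rownames(out) <- NULL
  structure(out, class = c("error_free_set", "data.frame"),
            capacity = as.integer(n_top))
}

#' Hamming distance between two equal-length sequences
#'
#' Counts the positions at which two sequences differ.  A position holding
#' N in either sequence counts as a mismatch: an uncalled base is never
#' evidence of identity.
#'
#' @param a,b Single sequences of equal length.
#' @return Integer mismatch count.
#' @export
#' @examples
#' hamming("ACGT", "ACGA")  # 1
hamming <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  }
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  rn <- charToRaw("N")
  sum(ra != rb | ra == rn | rb == rn)
}

#' Shadow-pair observations
#'
#' A set of (n, s) observations: for each presumed error-free sequence, its
#' own count n and the total multiplicity s of its shadows -- the other
#' reads within a small number of substitutions of it.  This is the input
#' of every error-rate estimator in the package.
#'
#' @param n Error-free read counts (all >= 1).
#' @param s Shadow counts (all >= 0).
#' @param sequence Optional character vector of the anchoring sequences.
#'
#' @return An object of class `shadow_pairs`: a `data.frame` with columns
#'   `n` and `s` (and `sequence` if given), sorted by `n` ascending with a
#'   stable order among ties.
#' @export
shadow_pairs <- function(n, s, sequence = NULL) {
  if (length(n) == 0L) stop("at least one (n, s) pair is required")
  if (length(n) != length(s)) stop("`n` and `s` must have the same length")
  if (any(!is.finite(n)) || any(n < 1)) stop("all `n` must be >= 1")
  if (any(!is.finite(s)) || any(s < 0)) stop("all `s` must be >= 0")
  df <- data.frame(n = as.numeric(n), s = as.numeric(s))
  if (!is.null(sequence)) df$sequence <- as.character(sequence)
  ord <- order(df$n, method = "radix")  # stable among ties
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("shadow_pairs", "data.frame"))
}

#' @export
print.shadow_pairs <- function(x, ...) {
  cat("Shadow pairs: m = ", nrow(x), " observations, n in [",
      format(min(x$n)), ", ", format(max(x$n)), "], raw error rate ",
      format(sum(x$s) / (sum(x$s) + sum(x$n)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Count the shadows of each error-free sequence
#'
#' A shadow is a read differing from an error-free sequence by at most
#' `max_mismatch` substitutions (default 2) -- close enough that it
#' plausibly arose from that sequence by sequencing error.  Members of the
#' error-free set are excluded from shadow counting.  A read within range
#' of several error-free sequences contributes its multiplicity to exactly
#' one of them under the default `multiplicity = "unique"`: the nearest,
#' with ties resolved toward the higher-count (then lexicographically
#' smaller) anchor.  `multiplicity = "all"` instead credits every in-range
#' anchor, which double-counts shared shadows.
#'
#' @param table A [read_count_table()].
#' @param efset An [select_error_free()] result derived from `table`.
#' @param max_mismatch Maximum substitution distance (default 2).
#' @param multiplicity `"unique"` (default) or `"all"`, see above.
#'
#' @return A [shadow_pairs()] object with one row per error-free sequence,
#'   sorted by `n` ascending.
#' @export
assign_shadows <- function(table, efset, max_mismatch = 2L,
                           multiplicity = c("unique", "all")) {
  stopifnot(inherits(table, "read_count_table"),
            inherits(efset, "error_free_set"),
            is.numeric(max_mismatch), max_mismatch >= 1)
  multiplicity <- match.arg(multiplicity)
  max_mismatch <- as.integer(max_mismatch)
  anchors <- efset$sequence
  if (any(nchar(anchors) != table$read_length)) {
    stop("error-free set read length does not match the table")
  }
  cand <- setdiff(names(table$entries), anchors)
  s <- numeric(length(anchors))
  if (length(cand)) {
    counts <- as.numeric(table$entries[cand])
    if (multiplicity == "unique") {
      hit <- assign_nearest_anchor(cand, anchors, max_mismatch)
      keep <- !is.na(hit$index)
      if (any(keep)) {
        sums <- tapply(counts[keep], hit$index[keep], sum)
        s[as.integer(names(sums))] <- as.numeric(sums)
      }
    } else {
      s <- shadow_sums_all(cand, counts, anchors, max_mismatch)
    }
  }
  shadow_pairs(efset$count, s, sequence = anchors)
}

#' Write or read shadow pairs as TSV
#'
#' Two tab-separated columns `n` and `s`, one row per error-free sequence,
#' sorted by `n` ascending; header auto-detected on read.
#'
#' @param pairs A [shadow_pairs()] object.
#' @param path File path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` a
#'   [shadow_pairs()] object.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "shadow_pairs"))
  write.table(pairs[, c("n", "s")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^n\ts$", tolower(first))
  df <- read.delim(path, header = has_header,
                   colClasses = c("numeric", "numeric"))
  names(df) <- c("n", "s")
  shadow_pairs(df$n, df$s)
}
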