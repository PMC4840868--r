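# char-matrix helpers shared by the mutators -----------------------------

seqs_to_matrix <- function(seqs) {
  L <- nchar(seqs[[1L]])
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}

matrix_to_seqs <- function(mat) {
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# substitution targets: rows A,C,G,T,N -> 3 alternative bases each
# (an N flips to one of A,C,G uniformly; N is rare in fixtures)
ALT_BASE <- matrix(
  c("C", "G", "T",
    "A", "G", "T",
    "A", "C", "T",
    "A", "C", "G",
    "A", "C", "G"),
  nrow = 5L, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T", "N"), NULL)
)

# Flip each base of each read independently with its positional
# probability, to one of the 3 alternative bases uniformly.
mutate_reads <- function(seqs, profile) {
  if (length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[[1L]])
  if (length(profile) == 1L) profile <- rep(profile, L)
  if (length(profile) != L) {
    stop("error profile length (", length(profile),
         ") does not match read length (", L, ")")
  }
  mat <- seqs_to_matrix(seqs)
  nr <- nrow(mat)
  flip <- matrix(runif(nr * L), nr, L) <
    matrix(profile, nr, L, byrow = TRUE)
  if (any(flip)) {
    cur <- mat[flip]
    pick <- sample.int(3L, sum(flip), replace = TRUE)
    mat[flip] <- ALT_BASE[cbind(match(cur, rownames(ALT_BASE)), pick)]
  }
  matrix_to_seqs(mat)
}

#' Estimate a base-specific error profile from reads and a small reference
#'
#' Anchors each distinct read at its mismatch-minimal placement among all
#' windows of the reference (forward strand, exact substring indexing, so
#' the reference must be small -- PhiX-scale).  Reads whose minimal
#' placement is not unique are skipped and counted.  The per-position error
#' rate is the multiplicity-weighted fraction of anchored reads mismatching
#' the reference at that read position.
#'
#' @param reads A [read_count_table()], or a character vector of reads
#'   (each counted once).
#' @param reference A single reference sequence (up to about 1e6 bases).
#'
#' @return An object of class `base_error_profile`: list with `rate`
#'   (per-position substitution probability, length = read length),
#'   `n_anchored` and `n_skipped` (read copies).
#' @export
estimate_base_profile <- function(reads, reference) {
  if (inherits(reads, "read_count_table")) {
    seqs <- names(reads$entries)
    w <- as.numeric(reads$entries)
  } else {
    seqs <- as.character(reads)
    w <- rep(1, length(seqs))
  }
  stopifnot(length(seqs) > 0L, is.character(reference),
            length(reference) == 1L)
  L <- nchar(seqs[[1L]])
  R <- nchar(reference)
  if (R < L) stop("reference is shorter than the reads")
  windows <- substring(reference, 1:(R - L + 1L), L:R)
  hit <- anchor_min_mismatch(seqs, windows)
  anchored <- hit$unique
  if (!any(anchored)) stop("no read could be uniquely anchored to the ",
                           "reference")
  idx <- ifelse(anchored, hit$index, NA_integer_)
  mism <- mismatch_position_counts(seqs, w, windows, as.integer(idx))
  total <- sum(w[anchored])
  structure(
    list(rate = as.numeric(mism) / total,
         n_anchored = total, n_skipped = sum(w[!anchored])),
    class = "base_error_profile"
  )
}

#' @export
print.base_error_profile <- function(x, ...) {
  cat("Base error profile over ", length(x$rate), " positions: mean rate ",
      format(mean(x$rate), digits = 4), " (", format(x$n_anchored),
      " reads anchored, ", format(x$n_skipped), " skipped)\n", sep = "")
  invisible(x)
}

#' Inject per-position substitution errors into a read-count table
#'
#' Every read copy independently flips each base with the positional
#' probability given by `profile`, to one of the 3 other bases uniformly,
#' and the mutated reads are re-tallied.  Total read count is conserved.
#' This reproduces the calibration-style simulation in which reads mapped
#' without mismatches are taken as error free and errors are layered on at
#' pre-specified base-specific rates.
#'
#' @param table A [read_count_table()] of error-free reads.
#' @param profile Per-position substitution probabilities: a
#'   `base_error_profile`, a vector of length read_length, or a single
#'   rate applied at every position.
#' @param seed Optional integer seed.
#'
#' @return A new [read_count_table()] with the same `total_reads`.
#' @export
inject_errors <- function(table, profile, seed = NULL) {
  stopifnot(inherits(table, "read_count_table"))
  if (inherits(profile, "base_error_profile")) profile <- profile$rate
  stopifnot(is.numeric(profile), all(profile >= 0), all(profile <= 1))
  reads <- rep(names(table$entries), times = table$entries)
  mutated <- with_seed(seed, mutate_reads(reads, profile))
  tab <- table(mutated)
  read_count_table(names(tab), as.integer(tab))
}

#' Scatter polymorphisms over a set of sequences
#'
#' Substitutes random alternative bases at a fixed density: the number of
#' polymorphic positions is `round(rate * total bases)` (so one per 1000
#' bases yields exactly one substitution in a 1000-base sequence), with
#' positions drawn uniformly without replacement across all sequences.
#' The perturbed sequences play the role of the true error-free templates
#' in robustness simulations: a sample genome differs from any reference
#' by real variation, and error-rate estimates should not be thrown off by
#' it.
#'
#' @param seqs Character vector of sequences.
#' @param rate Polymorphisms per base (default 0.001 = 1 per 1000 bp).
#' @param seed Optional integer seed.
#' @return The perturbed character vector.
#' @export
apply_polymorphisms <- function(seqs, rate = 0.001, seed = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, rate >= 0)
  lens <- nchar(seqs)
  k <- round(rate * sum(lens))
  if (k == 0) return(seqs)
  with_seed(seed, {
    flat <- sample.int(sum(lens), k)
    seq_id <- findInterval(flat - 1L, cumsum(c(0L, lens)),
                           rightmost.closed = FALSE)
    pos <- flat - cumsum(c(0L, lens))[seq_id]
    for (i in seq_len(k)) {
      si <- seq_id[i]
      p <- pos[i]
      cur <- substr(seqs[si], p, p)
      row <- match(cur, rownames(ALT_BASE))
      if (is.na(row)) row <- 5L
      substr(seqs[si], p, p) <- ALT_BASE[row, sample.int(3L, 1L)]
    }
    seqs
  })
}

#' Scatter tandem base duplications over a set of sequences
#'
#' Duplicates `round(rate * total bases)` randomly chosen bases in place
#' (each selected base is doubled), truncating each sequence back to its
#' original length so fixed-length reads stay fixed length.  Two per 1000
#' bases yields exactly two duplicated positions in a 1000-base sequence.
#'
#' @param seqs Character vector of sequences.
#' @param rate Duplications per base (default 0.002 = 2 per 1000 bp).
#' @param seed Optional integer seed.
#' @return The perturbed character vector.
#' @export
apply_duplications <- function(seqs, rate = 0.002, seed = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, rate >= 0)
  lens <- nchar(seqs)
  k <- round(rate * sum(lens))
  if (k == 0) return(seqs)
  with_seed(seed, {
    flat <- sample.int(sum(lens), k)
    seq_id <- findInterval(flat - 1L, cumsum(c(0L, lens)),
                           rightmost.closed = FALSE)
    pos <- flat - cumsum(c(0L, lens))[seq_id]
    # apply positions within a sequence from right to left so earlier
    # insertions do not shift later ones
    ord <- order(seq_id, -pos)
    for (i in ord) {
      si <- seq_id[i]
      p <- pos[i]
      len0 <- nchar(seqs[si])
      dup <- paste0(substr(seqs[si], 1L, p), substr(seqs[si], p, len0))
      seqs[si] <- substr(dup, 1L, len0)
    }
    seqs
  })
}
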