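# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (character splits, double loops) so they share no code
# path with the package internals they check.

hamming_brute <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# all-pairs shadow counting: every candidate read scanned against every
# anchor; nearest anchor wins, ties to the earliest anchor in efset order
# (which is count-descending, then lexicographic)
assign_shadows_brute <- function(table, efset, max_mismatch = 2) {
  anchors <- efset$sequence
  cand <- setdiff(names(table$entries), anchors)
  s <- numeric(length(anchors))
  for (r in cand) {
    d <- vapply(anchors, function(a) hamming_brute(r, a), numeric(1))
    dm <- min(d)
    if (dm <= max_mismatch) {
      best <- which(d == dm)[1L]
      s[best] <- s[best] + table$entries[[r]]
    }
  }
  shadow_pairs(efset$count, s, sequence = anchors)
}

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  L <- nchar(seqs[[1L]])
  writeLines(as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs, "+",
                             strrep("I", L))), path)
  path
}

random_seqs <- function(k, len) {
  vapply(seq_len(k),
         function(i) paste(sample(c("A", "C", "G", "T"), len,
                                  replace = TRUE), collapse = ""),
         character(1))
}

# a random read-count instance for the shadow-assignment oracle: a few
# abundant anchors plus a cloud of mutated and unrelated reads
random_instance <- function(seed) {
  set.seed(seed)
  len <- sample(8:12, 1L)
  n_anchor <- sample(4:12, 1L)
  anchors <- unique(random_seqs(n_anchor, len))
  mutate1 <- function(s) {
    p <- sample.int(nchar(s), 1L)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1L)
    s
  }
  shadows <- unlist(lapply(rep(anchors, each = 8L), function(a) {
    s <- a
    for (i in seq_len(sample(1:3, 1L))) s <- mutate1(s)
    s
  }))
  noise <- random_seqs(sample(50:300, 1L), len)
  seqs <- unique(c(anchors, shadows, noise))
  counts <- sample(1:20, length(seqs), replace = TRUE)
  counts[seq_along(anchors)] <- sample(100:500, length(anchors))
  read_count_table(seqs, counts)
}
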