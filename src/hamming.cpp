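#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance with early exit once the count exceeds `cap`
// (returns cap + 1 in that case).  Strings must have equal length `len`.
static inline int hamming_capped(const char *a, const char *b, int len,
                                 int cap) {
  int d = 0;
  for (int i = 0; i < len; ++i) {
    if (a[i] != b[i] && ++d > cap) return d;
  }
  return d;
}

// For each read, find the nearest anchor within `max_mismatch`
// substitutions.  Anchors must be pre-ordered by the caller's tie-break
// (here: count descending, then sequence); among equidistant anchors the
// lowest index wins because only a strictly smaller distance replaces the
// incumbent.  Returns 1-based anchor indices (NA when no anchor is close
// enough) and the corresponding distances.
// [[Rcpp::export]]
List assign_nearest_anchor(CharacterVector reads, CharacterVector anchors,
                           int max_mismatch) {
  const int nr = reads.size(), na = anchors.size();
  if (nr == 0 || na == 0)
    return List::create(_["index"] = IntegerVector(0),
                        _["distance"] = IntegerVector(0));
  const int len = LENGTH(STRING_ELT(reads, 0));
  std::vector<const char *> ap(na);
  for (int j = 0; j < na; ++j) ap[j] = CHAR(STRING_ELT(anchors, j));
  IntegerVector idx(nr, NA_INTEGER), dist(nr, NA_INTEGER);
  for (int i = 0; i < nr; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int best = max_mismatch + 1, bj = -1;
    for (int j = 0; j < na; ++j) {
      int d = hamming_capped(r, ap[j], len, best - 1);
      if (d < best) {
        best = d;
        bj = j;
        if (best == 0) break;
      }
    }
    if (bj >= 0) {
      idx[i] = bj + 1;
      dist[i] = best;
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Multi-parent attribution: add each read's multiplicity to *every* anchor
// within `max_mismatch`, instead of only the nearest one.
// [[Rcpp::export]]
NumericVector shadow_sums_all(CharacterVector reads, NumericVector counts,
                              CharacterVector anchors, int max_mismatch) {
  const int nr = reads.size(), na = anchors.size();
  NumericVector out(na);
  if (nr == 0 || na == 0) return out;
  const int len = LENGTH(STRING_ELT(reads, 0));
  std::vector<const char *> ap(na);
  for (int j = 0; j < na; ++j) ap[j] = CHAR(STRING_ELT(anchors, j));
  for (int i = 0; i < nr; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    for (int j = 0; j < na; ++j) {
      if (hamming_capped(r, ap[j], len, max_mismatch) <= max_mismatch)
        out[j] += counts[i];
    }
  }
  return out;
}

// Mismatch-minimal placement of each read against a set of equal-length
// reference windows.  A read is "anchored" only when a single window
// attains the minimal distance.  Returns the best 1-based window index,
// the minimal distance, and whether the minimum was unique.
// [[Rcpp::export]]
List anchor_min_mismatch(CharacterVector reads, CharacterVector windows) {
  const int nr = reads.size(), nw = windows.size();
  const int len = nr > 0 ? LENGTH(STRING_ELT(reads, 0)) : 0;
  std::vector<const char *> wp(nw);
  for (int j = 0; j < nw; ++j) wp[j] = CHAR(STRING_ELT(windows, j));
  IntegerVector idx(nr), dist(nr);
  LogicalVector unique_min(nr);
  for (int i = 0; i < nr; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int best = len + 1, bj = -1, nbest = 0;
    for (int j = 0; j < nw; ++j) {
      int d = hamming_capped(r, wp[j], len, best);
      if (d < best) {
        best = d;
        bj = j;
        nbest = 1;
      } else if (d == best) {
        ++nbest;
      }
    }
    idx[i] = bj + 1;
    dist[i] = best;
    unique_min[i] = (nbest == 1);
  }
  return List::create(_["index"] = idx, _["distance"] = dist,
                      _["unique"] = unique_min);
}

// Per-position weighted mismatch tally of reads against their assigned
// reference window (idx 1-based, NA = skip read).
// [[Rcpp::export]]
NumericVector mismatch_position_counts(CharacterVector reads,
                                       NumericVector weights,
                                       CharacterVector windows,
                                       IntegerVector idx) {
  const int nr = reads.size();
  const int len = nr > 0 ? LENGTH(STRING_ELT(reads, 0)) : 0;
  NumericVector out(len);
  for (int i = 0; i < nr; ++i) {
    if (idx[i] == NA_INTEGER) continue;
    const char *r = CHAR(STRING_ELT(reads, i));
    const char *w = CHAR(STRING_ELT(windows, idx[i] - 1));
    for (int p = 0; p < len; ++p)
      if (r[p] != w[p]) out[p] += weights[i];
  }
  return out;
}
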