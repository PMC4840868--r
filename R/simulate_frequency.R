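#' Binned joint frequency model of read and shadow counts
#'
#' Builds the empirical joint distribution of (n, s) pairs used by the
#' frequency-based simulator.  The error-free read counts are binned with
#' pre-specified, typically unequal, widths (quantile-based by default,
#' because large counts are sparse and equal widths would leave almost
#' empty bins); within each read bin the shadow counts are binned with
#' equal widths.  The model stores the read-bin probabilities p_j and the
#' within-bin shadow probabilities q_kj.
#'
#' @param pairs A [shadow_pairs()] object.
#' @param read_bins Either `"quantile:M"` (edges at the empirical quantiles
#'   of n, default `"quantile:20"`) or an explicit strictly increasing
#'   numeric edge vector covering the range of n.
#' @param shadow_bins Number of equal-width shadow bins per read bin
#'   (default 30).
#'
#' @return An object of class `frequency_model`: list with `read_edges`
#'   (length M + 1), `read_probs` (p_j), `shadow_edges` ((L + 1) x M
#'   matrix, NA columns for empty read bins), `shadow_probs` (L x M matrix
#'   of q_kj) and `m_source` (number of source observations).  Bins are
#'   half-open `[lo, hi)` with the last bin closed.
#' @export
build_frequency_model <- function(pairs, read_bins = "quantile:20",
                                  shadow_bins = 30L) {
  stopifnot(inherits(pairs, "shadow_pairs"), shadow_bins >= 1)
  n <- pairs$n
  s <- pairs$s
  L <- as.integer(shadow_bins)
  if (is.character(read_bins)) {
    if (!grepl("^quantile:[0-9]+$", read_bins)) {
      stop("read_bins must be \"quantile:M\" or a numeric edge vector")
    }
    M_req <- as.integer(sub("^quantile:", "", read_bins))
    if (M_req < 1L) stop("at least one read bin is required")
    probs <- seq(0, 1, length.out = M_req + 1L)
    edges <- unique(as.numeric(quantile(n, probs, type = 7)))
  } else {
    edges <- as.numeric(read_bins)
    if (any(diff(edges) <= 0)) {
      stop("read bin edges must be strictly increasing")
    }
    if (edges[1L] > min(n) || edges[length(edges)] < max(n)) {
      stop("read bin edges do not cover the data range [", min(n), ", ",
           max(n), "]")
    }
  }
  if (length(edges) < 2L) edges <- c(edges[1L], edges[1L] + 1)
  M <- length(edges) - 1L
  j_idx <- findInterval(n, edges, rightmost.closed = TRUE)
  p <- tabulate(j_idx, nbins = M) / length(n)
  shadow_edges <- matrix(NA_real_, nrow = L + 1L, ncol = M)
  q <- matrix(NA_real_, nrow = L, ncol = M)
  for (j in seq_len(M)) {
    sj <- s[j_idx == j]
    if (length(sj) == 0L) next
    lo <- min(sj)
    hi <- max(sj)
    if (hi <= lo) hi <- lo + 1  # degenerate bin: unit-width support
    se <- seq(lo, hi, length.out = L + 1L)
    k_idx <- findInterval(sj, se, rightmost.closed = TRUE)
    shadow_edges[, j] <- se
    q[, j] <- tabulate(k_idx, nbins = L) / length(sj)
  }
  structure(
    list(read_edges = edges, read_probs = p, shadow_edges = shadow_edges,
         shadow_probs = q, m_source = length(n)),
    class = "frequency_model"
  )
}

#' @export
print.frequency_model <- function(x, ...) {
  cat("Frequency model: ", length(x$read_probs), " read bins x ",
      nrow(x$shadow_probs), " shadow bins, built from ", x$m_source,
      " pairs; analytic error rate ",
      format(model_expected_error_rate(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Draw synthetic read/shadow pairs from a frequency model
#'
#' Each pair is drawn by the two-uniform inverse-CDF scheme: U ~ U(0,1)
#' selects the read bin j through the cumulative p_j and n is drawn
#' uniformly within that bin's edges; V ~ U(0,1) then selects the shadow
#' bin k through the cumulative q_kj of bin j and s is drawn uniformly
#' within that shadow bin.  Values are continuous within their cell unless
#' `integer = TRUE` rounds them (with n floored at 1).
#'
#' @param model A [build_frequency_model()] result.
#' @param n_pairs Number of pairs to draw (the replicate studies use 1000).
#' @param integer Round draws to integer counts (default `FALSE`).
#' @param seed Optional integer seed.
#'
#' @return A [shadow_pairs()] object sorted by n ascending.
#' @export
sample_pairs <- function(model, n_pairs, integer = FALSE, seed = NULL) {
  stopifnot(inherits(model, "frequency_model"), n_pairs >= 1)
  p <- model$read_probs
  if (all(p == 0)) stop("model has no populated read bin")
  n_pairs <- as.integer(n_pairs)
  cum_p <- c(0, cumsum(p))
  cum_p[length(cum_p)] <- 1  # guard against rounding drift
  with_seed(seed, {
    U <- runif(n_pairs)
    V <- runif(n_pairs)
    j <- findInterval(U, cum_p, rightmost.closed = TRUE)
    lo_n <- model$read_edges[j]
    hi_n <- model$read_edges[j + 1L]
    n_new <- lo_n + runif(n_pairs) * (hi_n - lo_n)
    s_new <- numeric(n_pairs)
    for (jj in unique(j)) {
      sel <- which(j == jj)
      qj <- model$shadow_probs[, jj]
      cum_q <- c(0, cumsum(qj))
      cum_q[length(cum_q)] <- 1
      k <- findInterval(V[sel], cum_q, rightmost.closed = TRUE)
      lo_s <- model$shadow_edges[k, jj]
      hi_s <- model$shadow_edges[k + 1L, jj]
      s_new[sel] <- lo_s + runif(length(sel)) * (hi_s - lo_s)
    }
    if (integer) {
      n_new <- pmax(round(n_new), 1)
      s_new <- pmax(round(s_new), 0)
    }
    shadow_pairs(pmax(n_new, 1), pmax(s_new, 0))
  })
}

#' Expected error rate of a set of pairs
#'
#' The ratio sum(s) / (sum(s) + sum(n)): the fraction of reads that carry
#' errors if every shadow is an errored read and every error-free count a
#' correct read.  In simulation studies this is the truth against which the
#' estimators are judged.
#'
#' @param pairs A [shadow_pairs()] object.
#' @return A rate in `[0, 1)`.
#' @export
expected_error_rate <- function(pairs) {
  stopifnot(inherits(pairs, "shadow_pairs"))
  tot <- sum(pairs$s) + sum(pairs$n)
  if (tot <= 0) stop("all pairs are zero; the error rate is undefined")
  sum(pairs$s) / tot
}

#' Analytic expected error rate of a frequency model
#'
#' The large-sample limit of [expected_error_rate()] over draws from the
#' model: E(s) / (E(s) + E(n)) with expectations taken cell-by-cell at the
#' bin midpoints (draws are uniform within cells, so the midpoint is
#' exact).
#'
#' @param model A [build_frequency_model()] result.
#' @return A rate in `[0, 1)`.
#' @export
model_expected_error_rate <- function(model) {
  stopifnot(inherits(model, "frequency_model"))
  p <- model$read_probs
  mid_n <- (model$read_edges[-1L] + model$read_edges[-length(model$read_edges)]) / 2
  E_n <- sum(p * mid_n)
  L <- nrow(model$shadow_probs)
  E_s <- 0
  for (j in seq_along(p)) {
    if (p[j] == 0) next
    se <- model$shadow_edges[, j]
    mids <- (se[-1L] + se[-(L + 1L)]) / 2
    E_s <- E_s + p[j] * sum(model$shadow_probs[, j] * mids)
  }
  E_s / (E_s + E_n)
}

#' Serialize or load a frequency model as JSON
#'
#' @param model A `frequency_model`.
#' @param path File path.
#' @return `write_frequency_model()` returns `path` invisibly;
#'   `read_frequency_model()` returns a `frequency_model`.
#' @export
write_frequency_model <- function(model, path) {
  stopifnot(inherits(model, "frequency_model"))
  jsonlite::write_json(
    list(read_edges = model$read_edges, read_probs = model$read_probs,
         shadow_bins = nrow(model$shadow_probs),
         shadow_edges = as.vector(model$shadow_edges),
         shadow_probs = as.vector(model$shadow_probs),
         m_source = model$m_source),
    path, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_frequency_model
#' @export
read_frequency_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- length(x$read_probs)
  L <- as.integer(x$shadow_bins)
  structure(
    list(read_edges = as.numeric(x$read_edges),
         read_probs = as.numeric(x$read_probs),
         shadow_edges = matrix(as.numeric(x$shadow_edges), L + 1L, M),
         shadow_probs = matrix(as.numeric(x$shadow_probs), L, M),
         m_source = as.integer(x$m_source)),
    class = "frequency_model"
  )
}
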