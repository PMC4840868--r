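#' Generate a known-truth synthetic sequencing sample
#'
#' Builds a complete fixture for the shadow pipeline: a random reference, a
#' set of distinct source sequences drawn from it at random positions, a
#' skewed (power-law) abundance distribution over the sources, and
#' per-position substitution errors injected into every read copy.  The
#' return value carries a machine-readable truth record -- the parent of
#' every read and whether it acquired an error -- so pipeline output can be
#' checked against ground truth instead of eyeballed values.
#'
#' The defaults emulate a small short-read sample: 36 bp reads, a few
#' hundred template sequences with abundances falling off as rank^-alpha,
#' and a uniform per-base substitution rate of 0.001.
#'
#' @param n_reads Total reads (default 1e5).
#' @param read_length Read length in bases (default 36).
#' @param n_sources Number of distinct template sequences (default 200).
#' @param alpha Power-law abundance exponent: source i gets weight
#'   i^-alpha (default 1).
#' @param error_profile Per-base substitution probability: a single rate
#'   (default 0.001) or a vector of length `read_length`.
#' @param reference_length Length of the random reference the templates
#'   are cut from (default 5000 bases).
#' @param seed Optional integer seed; the same spec and seed reproduce the
#'   sample byte for byte.
#' @param fastq Optional path; when given, the FASTQ is written there.
#'
#' @return List with `reads` (mutated read sequences, in emission order),
#'   `fastq_lines` (4-line records), `fastq` (the path, or `NULL`), and
#'   `truth`: list with `parent` (template of each read), `has_error`
#'   (per-read flag), `error_fraction`, `sources` (data.frame of sequence,
#'   count, start), `reference` and `profile`.
#' @export
generate_sample <- function(n_reads = 1e5, read_length = 36L,
                            n_sources = 200L, alpha = 1,
                            error_profile = 0.001,
                            reference_length = 5000L, seed = NULL,
                            fastq = NULL) {
  stopifnot(n_reads >= 1, read_length >= 1, n_sources >= 1,
            reference_length >= read_length + n_sources)
  profile <- if (length(error_profile) == 1L) {
    rep(error_profile, read_length)
  } else {
    error_profile
  }
  stopifnot(length(profile) == read_length, all(profile >= 0),
            all(profile <= 1))
  with_seed(seed, {
    reference <- paste(sample(DNA_BASES, reference_length, replace = TRUE),
                       collapse = "")
    max_start <- reference_length - read_length + 1L
    starts <- sample.int(max_start, min(3L * n_sources, max_start))
    sources <- substring(reference, starts, starts + read_length - 1L)
    keep <- !duplicated(sources)
    sources <- sources[keep][seq_len(n_sources)]
    starts <- starts[keep][seq_len(n_sources)]
    if (anyNA(sources)) {
      stop("could not draw ", n_sources, " distinct source sequences; ",
           "increase reference_length")
    }
    w <- seq_len(n_sources)^(-alpha)
    counts <- as.vector(rmultinom(1L, n_reads, w / sum(w)))
    if (sum(counts) == 0L) stop("abundance law yielded zero reads")
    parents <- rep(sources, times = counts)
    parents <- parents[sample.int(length(parents))]  # shuffle read order
    reads <- mutate_reads(parents, profile)
    has_error <- reads != parents
    ids <- sprintf("@r%06d", seq_along(reads))
    qual <- strrep("I", read_length)
    fastq_lines <- as.vector(rbind(ids, reads, "+", qual))
    if (!is.null(fastq)) writeLines(fastq_lines, fastq)
    list(
      reads = reads, fastq_lines = fastq_lines, fastq = fastq,
      truth = list(
        parent = parents, has_error = has_error,
        error_fraction = mean(has_error),
        sources = data.frame(sequence = sources, count = counts,
                             start = starts, stringsAsFactors = FALSE),
        reference = reference, profile = profile
      )
    )
  })
}

#' Generate shadow pairs with a linear truth
#'
#' Draws (n, s) observations from the linear shadow model
#' s = intercept + slope * n + Normal(0, sigma), with s clamped at 0, for
#' estimator tests where the true error rate slope / (1 + slope) is known
#' in closed form.
#'
#' @param m Number of pairs (default 1000).
#' @param slope,intercept Linear coefficients (slope >= 0).
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param n_range Integer range the n are drawn from uniformly (default
#'   100..10000).
#' @param seed Optional integer seed.
#' @return A [shadow_pairs()] object with attribute `"truth"` = list of
#'   the generating parameters.
#' @export
generate_linear_pairs <- function(m = 1000L, slope = 0.25, intercept = 0,
                                  sigma = 5, n_range = c(100L, 10000L),
                                  seed = NULL) {
  stopifnot(m >= 4, slope >= 0, sigma >= 0, length(n_range) == 2L,
            n_range[1L] >= 1, n_range[2L] > n_range[1L])
  with_seed(seed, {
    n <- n_range[1L] +
      sample.int(n_range[2L] - n_range[1L] + 1L, m, replace = TRUE) - 1L
    s <- pmax(intercept + slope * n + rnorm(m, 0, sigma), 0)
    out <- shadow_pairs(n, s)
    attr(out, "truth") <- list(slope = slope, intercept = intercept,
                               sigma = sigma,
                               srer = slope / (1 + slope))
    out
  })
}

# the library of non-linear read-shadow shapes
nonlinear_shapes <- list(
  # shadows grow but flatten at high abundance
  saturating = function(n) 500 * n / (n + 2000),
  # straight line through the origin
  linear = function(n) 0.25 * n,
  # shadows *decrease* with abundance at low counts, then rise again --
  # the pattern seen in some mRNA-seq samples
  dip = function(n) 800 * exp(-n / 500) + 0.1 * n
)

#' Generate shadow pairs with a non-linear truth
#'
#' Draws (n, s) observations from a library of monotone, saturating and
#' locally decreasing read-shadow shapes, with optional Gaussian noise.
#' The read counts n are drawn log-uniformly over `n_range`, mirroring the
#' strongly skewed abundance spectra of real count data (many moderately
#' abundant sequences, few very abundant ones); together with the shape
#' library this emulates the non-linear patterns of real mRNA-seq and
#' resequencing samples that break the linear shadow model.
#'
#' @param shape `"saturating"`, `"linear"` or `"dip"`.
#' @param m Number of pairs (default 1000).
#' @param noise Gaussian noise standard deviation (default 0).
#' @param n_range Integer range for n (default 100..10000).
#' @param seed Optional integer seed.
#' @return A [shadow_pairs()] object with attribute `"truth_fun"` (the
#'   generating function s = f(n)).
#' @export
generate_nonlinear_pairs <- function(shape = c("saturating", "linear",
                                               "dip"),
                                     m = 1000L, noise = 0,
                                     n_range = c(100L, 10000L),
                                     seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(m >= 4, noise >= 0)
  f <- nonlinear_shapes[[shape]]
  with_seed(seed, {
    n <- round(exp(runif(m, log(n_range[1L]), log(n_range[2L]))))
    s <- pmax(f(n) + rnorm(m, 0, noise), 0)
    out <- shadow_pairs(n, s)
    attr(out, "truth_fun") <- f
    out
  })
}
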