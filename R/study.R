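#' Replicate simulation study of the shadow error-rate estimators
#'
#' Runs the full frequency-based simulation protocol: build (or accept) a
#' binned frequency model of read/shadow pairs, then for each replicate
#' draw `pairs_per_rep` pairs from it and compute the expected error rate
#' of the draw together with the SRER, cubic-spline EER and robust-spline
#' EER.  Reported are the medians over replicates and the absolute biases
#' |median estimate - median expected error rate|, plus interquartile
#' ranges as a labeled extra.  Replicates that fail (for example because a
#' degenerate draw breaks a spline fit) are excluded from the medians and
#' counted.
#'
#' Per-replicate seeds are `seed + replicate index` (counter scheme), so
#' any single replicate can be re-run in isolation and the whole study is
#' reproducible bit for bit from the master seed.
#'
#' @param pairs_source A [shadow_pairs()] object (a model is built from it
#'   with `read_bins` / `shadow_bins`) or a ready-made
#'   [build_frequency_model()] result.
#' @inheritParams build_frequency_model
#' @param replicates Number of replicates (the reference protocol uses
#'   1000).
#' @param pairs_per_rep Pairs drawn per replicate (reference protocol:
#'   1000).
#' @param lambda Spline smoothing parameter, see [fit_cubic_spline()].
#' @param eer_draws Read counts sampled per EER (default 1000).
#' @param seed Master seed (default 1).
#'
#' @return An object of class `study_summary`: list with `medians` (named:
#'   expected_er, srer, eer_cs, eer_rs), `biases` (srer, eer_cs, eer_rs),
#'   `iqr`, `replicates`, `n_failed`, `seed` and the per-replicate
#'   `results` data.frame.
#' @export
run_simulation_study <- function(pairs_source, read_bins = "quantile:20",
                                 shadow_bins = 30L, replicates = 1000L,
                                 pairs_per_rep = 1000L, lambda = "auto",
                                 eer_draws = 1000L, seed = 1L) {
  stopifnot(replicates >= 1, pairs_per_rep >= 1)
  model <- if (inherits(pairs_source, "frequency_model")) {
    pairs_source
  } else {
    build_frequency_model(pairs_source, read_bins = read_bins,
                          shadow_bins = shadow_bins)
  }
  seed <- as.integer(seed) %% 2000000000L
  res <- vector("list", replicates)
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    rep_seed <- seed + r
    row <- tryCatch({
      sp <- sample_pairs(model, pairs_per_rep, seed = rep_seed)
      est <- suppressWarnings(
        estimate_error_rates(sp, lambda = lambda, eer_draws = eer_draws,
                             seed = rep_seed)
      )
      data.frame(replicate = r, expected_er = est$expected_er,
                 srer = est$srer, eer_cs = est$eer_cs,
                 eer_rs = est$eer_rs)
    }, error = function(e) NULL)
    if (is.null(row)) n_failed <- n_failed + 1L else res[[r]] <- row
  }
  results <- do.call(rbind, res)
  if (is.null(results) || nrow(results) == 0L) {
    stop("every replicate failed; the model is degenerate for the ",
         "spline estimators")
  }
  med <- vapply(results[c("expected_er", "srer", "eer_cs", "eer_rs")],
                median, numeric(1))
  iqr <- vapply(results[c("expected_er", "srer", "eer_cs", "eer_rs")],
                function(v) diff(quantile(v, c(0.25, 0.75))), numeric(1))
  biases <- abs(med[c("srer", "eer_cs", "eer_rs")] - med[["expected_er"]])
  structure(
    list(medians = med, biases = biases, iqr = iqr,
         replicates = as.integer(replicates), n_failed = n_failed,
         seed = seed, results = results),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Simulation study (", x$replicates, " replicates, ", x$n_failed,
      " failed):\n", sep = "")
  cat(sprintf("  Expected ER %.4f\n", x$medians[["expected_er"]]))
  cat(sprintf("  SRER   %.4f (bias %.4f)\n", x$medians[["srer"]],
              x$biases[["srer"]]))
  cat(sprintf("  EER_CS %.4f (bias %.4f)\n", x$medians[["eer_cs"]],
              x$biases[["eer_cs"]]))
  cat(sprintf("  EER_RS %.4f (bias %.4f)\n", x$medians[["eer_rs"]],
              x$biases[["eer_rs"]]))
  invisible(x)
}

#' Full shadow pipeline on one sample
#'
#' Runs counts -> error-free selection -> shadow assignment -> error-rate
#' estimation on a single sample, given a FASTQ file, a count TSV, a
#' [read_count_table()] or ready-made [shadow_pairs()].
#'
#' @param input Sample input: path to a FASTQ (`.fastq`/`.fq`, optionally
#'   `.gz`) or count TSV, or a `read_count_table` / `shadow_pairs` object.
#' @param n_top Error-free set capacity (default 1000).
#' @param max_mismatch Shadow distance cutoff (default 2).
#' @inheritParams estimate_error_rates
#'
#' @return An `error_rate_estimate` (see [estimate_error_rates()]) with
#'   the derived `shadow_pairs` attached as attribute `"pairs"`.
#' @export
run_real_sample <- function(input, n_top = 1000L, max_mismatch = 2L,
                            lambda = "auto", eer_draws = 1000L,
                            seed = NULL) {
  pairs <- if (inherits(input, "shadow_pairs")) {
    input
  } else {
    table <- if (inherits(input, "read_count_table")) {
      input
    } else if (is.character(input) && length(input) == 1L) {
      if (grepl("\\.(fastq|fq)(\\.gz)?$", input, ignore.case = TRUE)) {
        count_reads(input)
      } else {
        read_counts(input)
      }
    } else {
      stop("`input` must be a file path, read_count_table or shadow_pairs")
    }
    efset <- select_error_free(table, n_top = n_top)
    assign_shadows(table, efset, max_mismatch = max_mismatch)
  }
  est <- estimate_error_rates(pairs, lambda = lambda,
                              eer_draws = eer_draws, seed = seed)
  attr(est, "pairs") <- pairs
  est
}
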