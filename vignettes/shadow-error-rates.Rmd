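---
title: "Estimating sequencing error rates from shadow counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sequencing error rates from shadow counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadowspline)
```

## The problem

Short-read sequencing platforms miscall bases at rates high enough to
matter for downstream analyses, and the error rate of a particular sample
is worth knowing before that sample is used.  Reference-based assessments
(count the mismatches of aligned reads) need a trustworthy reference and
an alignment step; *k*-mer spectrum methods are reference free but memory
hungry.  The shadow approach needs neither.  It rests on one observation:
when an abundant template sequence is read many times, each miscalled copy
becomes a rare sequence a base or two away from it — its **shadow** — so
the relationship between a template's abundance and the total abundance of
its shadows carries the error rate.

The pipeline is:

1. Tally a FASTQ sample of equal-length reads into distinct-sequence
   counts (`count_reads()`).
2. Presume the top *N* most frequent sequences error free (default
   *N* = 1000, `select_error_free()`); sequences containing an uncalled
   base N are never eligible, because an uncalled position cannot anchor
   mismatch counting.
3. For each error-free sequence *t* with count *n~t~*, count the
   multiplicity *s~t~* of the remaining reads within two substitutions of
   it (`assign_shadows()`).  Two is the conventional cutoff: reads further
   away (extensive polymorphism, isoforms, contaminants) are deliberately
   not treated as errors.
4. Estimate the error rate from the (*n*, *s*) observations.

A point the originators of the approach left open is what to do when one
read lies within two mismatches of several error-free sequences.  The
default here assigns each read's multiplicity to exactly one anchor — the
nearest, ties resolved toward the higher-count and then lexicographically
smaller anchor — because crediting every nearby anchor (available as
`multiplicity = "all"`) double-counts shared shadows and inflates the
total shadow mass.

## Estimators

**Linear model (SRER).**  If shadows accrue proportionally to abundance,
*s* = α + β·*n* + ε, then of every 1 + β reads attributable to a template,
β carry errors, so the per-read error rate is β/(1 + β).
`fit_shadow_linear()` estimates the line by Huber M-estimation (tuning
constant 1.345, MAD scale), since shadow counts are contaminated by
legitimate low-abundance sequences; a negative slope estimate is clamped
to zero before the transformation.  Exactly collinear data short-circuit
to the least-squares line, which is a fixed point of the reweighting.

**Spline model (EER).**  Real count data are often far from linear — in
some mRNA-seq samples the shadow counts *fall* as abundance rises through
the low-count range.  `fit_cubic_spline()` therefore models *s* as a
smooth function of *n*: the minimizer over all twice continuously
differentiable functions of

$$\sum_{i=1}^{m}\big(s_i - \hat U(n_i)\big)^2
  + \lambda \int \hat U''(n)^2\,dn,$$

which is a natural cubic spline.  From the fitted curve, the per-read
error rate at read count *x* is the cumulative ratio

$$ER(x) = \frac{\sum_{j \le t}\hat S_j}
               {\sum_{j \le t}\hat S_j + \sum_{j \le t} n_j},$$

where *t* indexes the observations with *n~j~* ≤ *x* and negative fitted
values are clamped at zero, so *ER* is always in [0, 1).  The sums run
over observed sequences (not over spline evaluations at unobserved
abscissae) because the definition indexes sequences; tied *n* values are
kept as separate cumulative terms here, and collapsed to their weighted
mean only inside the spline solver, which needs strictly increasing
abscissae.  The sample-level **empirical error rate (EER)** is the median
of *ER* evaluated at 1000 read counts drawn uniformly from the integers
in [*n*~1~, *n~m~*] (`sample_eer()`).  The phrase "counts from *n*~1~ to
*n~m~*" could also mean resampling the observed counts; both are
implemented, uniform integers being the default and `method = "observed"`
the alternative.  The median uses the midpoint convention.

**Robust spline.**  `fit_robust_spline()` iterates the weighted spline
with weights 1/|residual|, flooring residuals at
δ = 10^−6^·(max *s* − min *s*) so exactly fitted points do not get
infinite weight.  Iteration stops when the maximum relative change in
fitted values drops below 10^−6^ (at most 50 iterations; non-convergence
is flagged and warned, and the last iterate returned — with such
aggressive weights the fitted values can keep oscillating at the 10^−5^
level on noisy data, which is harmless for the medians downstream).  On
residual-free data every weight hits the floor and the robust fit equals
the cubic fit exactly; on curved noiseless data the equality holds to
smoothing-bias order (about 10^−4^ relative), because generalized
cross-validation does not interpolate such data exactly.

## Smoothing parameter

`lambda = "auto"` (the default everywhere) selects λ by generalized
cross-validation via `stats::smooth.spline`, the standard solver for this
criterion; the λ it reports lives on that solver's internally rescaled
axis.  A *numeric* λ is instead interpreted on the raw read-count scale
and solved by the package's own Reinsch-form solver: with *D* the
second-difference map and *C* the Gram matrix of interior second
derivatives,

$$(C + \lambda\, D W^{-1} D')\,\gamma = D y,\qquad
  f = y - \lambda\, W^{-1} D' \gamma .$$

This form is well conditioned at *both* extremes — λ = 0 returns the
interpolating natural spline and λ → ∞ converges to the weighted
least-squares line — whereas driving a generic banded
(W + λK) solve into the penalty-dominated regime loses accuracy long
before λ reaches interesting magnitudes.  Both limits are verified in the
test suite against independent constructions (`stats::spline` with
natural boundary conditions, and `lm`).  The robust iteration holds λ
fixed at the value chosen for the initial fit, so the reweighting changes
only the data weights, not the smoothness budget.

## The frequency-based pair simulator

To study estimator behavior under realistic count structure,
`build_frequency_model()` bins a pairs table into a joint distribution:
read-count bins with *unequal* widths (20 quantile-based bins by default,
because large counts are sparse and equal widths would leave nearly empty
bins), and within each read bin 30 equal-width shadow bins.  Bins are
half-open [lo, hi) with the last bin closed, so every observation lands
in exactly one cell; a bin whose observations are all identical gets a
unit-width support so sampling remains well defined.  The reference
protocol never published its bin counts or edge placements, so these
defaults are this package's own and both are overridable.

`sample_pairs()` draws each pair with two independent uniforms: *U*
selects the read bin through the cumulative *p~j~* and *n* is uniform
within that bin; *V* selects the shadow bin through the cumulative
*q~kj~* of that read bin and *s* is uniform within it.  Draws are
continuous within cells (the spline is indifferent); an integer-rounding
flag exists for count realism.  `model_expected_error_rate()` gives the
analytic large-sample error rate of the model (cell-midpoint
expectations, exact for uniform-within-cell draws), which the test suite
compares against the empirical rate of 10^5^ draws.

`run_simulation_study()` wraps the replicate protocol: per replicate,
draw 1000 pairs, compute the expected error rate Σ*s*/(Σ*s* + Σ*n*) of
the draw and the three estimates; report medians across replicates and
absolute biases |median estimate − median expected|, plus interquartile
ranges as a clearly-extra diagnostic.  "Median expected error rate" is
taken as the median across replicates of the per-replicate expected
rates.  Per-replicate seeds are master seed + replicate index, so any
replicate can be reproduced in isolation; failed replicates (degenerate
draws breaking a fit) are excluded from the medians and counted.

## The calibration simulator

`inject_errors()` implements the older calibration-style simulation:
every read copy independently flips each base with a per-position
probability, to one of the three other bases uniformly (no confusion
matrix is assumed).  `estimate_base_profile()` recovers such a profile
from reads and a *small* reference by anchoring each read at its
mismatch-minimal window (forward strand, exact substring indexing) and
tallying mismatches per read position; reads without a unique minimal
placement are skipped and counted.  Alignment to large genomes is out of
scope — for real data at that scale, pre-tallied per-position mismatch
counts can be supplied instead.

Two perturbations probe robustness to the sample genome differing from
any reference: `apply_polymorphisms()` substitutes bases at a fixed
density (default 1 per 1000 bases; the count is deterministic, the
positions random) and `apply_duplications()` doubles bases in place at 2
per 1000, truncating back to the original length so fixed-length reads
stay fixed length (the density is conventional; the in-place mechanics
are this package's choice).  Because the shadow machinery never consults
a reference, estimates are expected to be essentially unchanged under
both — the test suite checks the shift stays below 0.01 on seed-paired
runs.

## Synthetic fixtures and what they do not show

`generate_sample()` produces a complete known-truth sample: a random
reference, template sequences cut from it at random positions, power-law
abundances (weight rank^−α^, α = 1 by default), and per-position
substitution errors, together with the parent and error flag of every
read.  `generate_linear_pairs()` and `generate_nonlinear_pairs()` produce
pairs tables directly; the nonlinear generator draws *n* log-uniformly,
mirroring the strongly skewed abundance spectra of real samples.  That
skew matters: when read counts are spread uniformly, the
median-of-cumulative-*ER* statistic is structurally offset from the
pooled ratio for any non-proportional shape, and the spline's advantage
over the linear model disappears — the advantage lives in the regime,
universal in real data, where most templates are far less abundant than
the largest ones.

The fixtures emulate abundance skew, substitution errors and controllable
read-shadow shapes.  They do **not** emulate quality scores, indels,
platform-specific error spectra (e.g. position-dependent miscall biases
beyond the supplied profile), GC effects, or the repeat structure of real
genomes (the random reference makes near-duplicate templates rare, so
shadow attribution is cleaner than in, say, a transcriptome with
paralogs).  Passing tests therefore demonstrate correctness of the
machinery and of the estimators under the stated generative models, not
performance on any particular instrument's data.

## Numerical choices and problem sizes

* Ranking and tie-breaks are deterministic everywhere (counts descending,
  then C-locale lexicographic), so outputs are platform independent.
* All stochastic entry points accept `seed`; a non-NULL seed leaves the
  caller's RNG state untouched.
* The test suite and the reproduction script run at deliberately desk
  scale: samples of 10^5^ reads of 36 bp from 150–200 templates,
  pairs tables of m = 1000, 10^5^ simulator draws, and 200-replicate
  studies.  These sizes keep the full suite under a few minutes while
  leaving Monte-Carlo error well inside the asserted tolerances; the same
  functions run unchanged at the ~12-million-read scale of public SRA
  samples, where shadow assignment (the O(D·N·L) scan, implemented in
  C++) dominates run time.
* Tables 5–8-style real-sample analyses are a one-liner
  (`run_real_sample()` on a downloaded FASTQ or count file) but are not
  part of the test suite, which must run offline.

## Limitations

Only substitution errors are modeled: an indel shifts every downstream
base, pushing a read past the two-mismatch cutoff, so indel-heavy
platforms will look *cleaner* than they are.  The top-*N* presumption
fails for samples without abundant templates (e.g. whole-genome shotgun
at uniform low coverage).  Outlier pre-screening of the pairs table
(boxplot rule and similar) is deliberately left to the user, as are
quantile-regression and alternative-spline variants of the curve fit.
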