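test_that("robust linear fit recovers exact and flat relationships", {
  n <- seq(10, 100, by = 10)
  exact <- shadow_pairs(n, 2 + 0.5 * n)
  fit <- fit_shadow_linear(exact)
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
  expect_equal(fit$slope, 0.5, tolerance = 1e-8)
  expect_true(fit$converged)

  flat <- shadow_pairs(n, rep(7, 10))
  ffit <- fit_shadow_linear(flat)
  expect_equal(ffit$intercept, 7, tolerance = 1e-8)
  expect_equal(ffit$slope, 0, tolerance = 1e-8)

  expect_error(fit_shadow_linear(shadow_pairs(rep(5, 5), 1:5)),
               "degenerate")
  expect_error(fit_shadow_linear(shadow_pairs(c(1, 2), c(1, 2))),
               "at least 3")
})

test_that("robust fit agrees with OLS under symmetric noise", {
  p <- generate_linear_pairs(m = 1000, slope = 0.25, intercept = 0,
                             sigma = 5, seed = 201)
  fit <- fit_shadow_linear(p)
  ols <- coef(lm(s ~ n, data = p))[["n"]]
  expect_equal(fit$slope, 0.25, tolerance = 0.01)
  expect_equal(fit$slope, ols, tolerance = 0.005)
})

test_that("srer maps the slope through beta/(1+beta) with clamping", {
  mk <- function(b) structure(list(intercept = 0, slope = b,
                                   converged = TRUE, iterations = 1L),
                              class = "shadow_linear_fit")
  expect_equal(srer(mk(0)), 0)
  expect_equal(srer(mk(1)), 0.5)
  expect_equal(srer(mk(0.25)), 0.2)
  expect_equal(srer(mk(-0.3)), 0)  # negative slope clamps to zero rate
})

test_that("cubic spline reproduces affine data at any lambda", {
  n <- c(10, 25, 40, 70, 110, 160)
  line <- shadow_pairs(n, 3 + 0.2 * n)
  for (lam in c(0, 1, 1e6, "auto")) {
    fit <- fit_cubic_spline(line, lambda = if (identical(lam, "auto")) lam
                            else as.numeric(lam))
    expect_equal(fit$fitted, line$s, tolerance = 1e-6,
                 info = paste("lambda", lam))
  }
  expect_error(fit_cubic_spline(shadow_pairs(c(1, 2, 3), c(1, 2, 3))),
               "linear model")
})

test_that("lambda = 0 interpolates, matching an independent natural spline", {
  p <- shadow_pairs(c(10, 20, 35, 50, 70, 90, 120, 160, 200, 250),
                    c(3, 5, 4, 8, 7, 12, 15, 14, 20, 22))
  fit <- fit_cubic_spline(p, lambda = 0)
  expect_equal(fit$fitted, p$s, tolerance = 1e-10)
  xs <- seq(10, 250, length.out = 101)
  oracle <- spline(p$n, p$s, method = "natural", xout = xs)$y
  expect_equal(predict(fit, xs), oracle, tolerance = 1e-9)
})

test_that("huge lambda reproduces the least-squares line", {
  p <- generate_linear_pairs(m = 50, slope = 0.3, sigma = 20, seed = 31)
  fit <- fit_cubic_spline(p, lambda = 1e12 * diff(range(p$n)))
  ls_line <- fitted(lm(s ~ n, data = p))
  expect_lt(max(abs(fit$fitted - ls_line) / pmax(abs(ls_line), 1)), 1e-6)
})

test_that("spline evaluation refuses extrapolation", {
  p <- generate_nonlinear_pairs("saturating", m = 50, seed = 2)
  fit <- fit_cubic_spline(p)
  expect_error(predict(fit, min(p$n) - 1), "outside")
  expect_error(per_read_error_rate(fit, max(p$n) + 1), "outside")
})

test_that("robust spline equals the cubic spline on noiseless data", {
  # affine data: residuals are exactly zero, all weights hit the floor
  # and the two fits coincide to machine precision
  line <- shadow_pairs(c(10, 30, 60, 100, 150, 210), 2 + 0.3 *
                         c(10, 30, 60, 100, 150, 210))
  expect_equal(fit_robust_spline(line)$fitted,
               fit_cubic_spline(line)$fitted, tolerance = 1e-10)

  # curved noiseless data: agreement to smoothing-bias order
  p <- generate_nonlinear_pairs("saturating", m = 80, noise = 0, seed = 3)
  cs <- fit_cubic_spline(p)
  rs <- fit_robust_spline(p)
  expect_equal(rs$fitted, cs$fitted, tolerance = 1e-4)
  expect_true(rs$converged)

  const <- shadow_pairs(c(10, 20, 30, 40, 50), rep(6, 5))
  rc <- fit_robust_spline(const)
  expect_equal(rc$fitted, rep(6, 5), tolerance = 1e-6)
})

test_that("robust spline resists a single gross outlier", {
  clean <- generate_nonlinear_pairs("saturating", m = 60, noise = 5,
                                    seed = 17)
  ref <- fit_cubic_spline(clean)     # outlier-free oracle fit
  dirty <- clean
  k <- 30L
  dirty$s[k] <- dirty$s[k] * 20
  dirty <- shadow_pairs(dirty$n, dirty$s)
  cs <- fit_cubic_spline(dirty)
  rs <- suppressWarnings(fit_robust_spline(dirty))
  others <- setdiff(seq_len(60), k)
  dev_cs <- sum((cs$fitted[others] - ref$fitted[others])^2)
  dev_rs <- sum((rs$fitted[others] - ref$fitted[others])^2)
  expect_lt(dev_rs, dev_cs)
})

test_that("per-read error rate follows the cumulative-ratio definition", {
  # interpolating fit pins the fitted shadows to 1, 2, 3, 4 exactly
  p <- shadow_pairs(c(10, 20, 30, 40), c(1, 2, 3, 4))
  fit <- fit_cubic_spline(p, lambda = 0)
  expect_equal(per_read_error_rate(fit, 30), 6 / 66)
  expect_equal(per_read_error_rate(fit, 10), 1 / 11)
  # between observed counts the rate is a step function of included terms
  expect_equal(per_read_error_rate(fit, 35), 6 / 66)

  zero <- shadow_pairs(c(10, 20, 30, 40), rep(0, 4))
  zfit <- fit_cubic_spline(zero, lambda = 0)
  expect_equal(per_read_error_rate(zfit, c(10, 25, 40)), rep(0, 3))

  sym <- shadow_pairs(c(10, 20, 30, 40), c(10, 20, 30, 40))
  sfit <- fit_cubic_spline(sym, lambda = 0)
  expect_equal(per_read_error_rate(sfit, c(12, 40)), rep(0.5, 2))
})

test_that("per-read error rate always lies in [0, 1)", {
  for (seed in c(4, 8, 15)) {
    p <- generate_nonlinear_pairs("dip", m = 200, noise = 50, seed = seed)
    fit <- fit_cubic_spline(p)
    x <- seq(min(p$n), max(p$n), length.out = 200)
    er <- per_read_error_rate(fit, x)
    expect_true(all(er >= 0 & er < 1))
  }
})

test_that("sample_eer matches exhaustive enumeration and degenerate draws", {
  # constant-rate curve: s proportional to n makes ER constant
  p <- shadow_pairs(c(10, 20, 30, 40, 60), 0.1 * c(10, 20, 30, 40, 60))
  fit <- fit_cubic_spline(p, lambda = 0)
  out <- sample_eer(fit, draws = 200, seed = 5)
  expect_equal(out$eer, 0.1 / 1.1, tolerance = 1e-10)

  single <- sample_eer(fit, draws = 1, seed = 9)
  expect_equal(single$eer, single$samples$er[[1]])

  # median of 1000 uniform draws approximates the exhaustive median
  q <- generate_nonlinear_pairs("dip", m = 300, noise = 20, seed = 23)
  qfit <- fit_cubic_spline(q)
  est <- sample_eer(qfit, draws = 1000, seed = 77)
  all_counts <- ceiling(min(q$n)):floor(max(q$n))
  exhaustive <- median(per_read_error_rate(qfit, all_counts))
  expect_lt(abs(est$eer - exhaustive), 0.005)

  # reproducibility and the observed-count variant
  est2 <- sample_eer(qfit, draws = 1000, seed = 77)
  expect_identical(est$eer, est2$eer)
  obs <- sample_eer(qfit, draws = 500, method = "observed", seed = 1)
  expect_true(all(obs$samples$count %in% q$n))
})

test_that("EER and SRER agree in the noiseless linear regime", {
  p <- generate_nonlinear_pairs("linear", m = 400, noise = 0, seed = 12)
  est <- estimate_error_rates(p, eer_draws = 1000, seed = 3)
  expect_equal(est$eer_cs, est$srer, tolerance = 1e-3)
  expect_equal(est$eer_rs, est$srer, tolerance = 1e-3)
  expect_equal(est$srer, 0.25 / 1.25, tolerance = 1e-6)
})
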