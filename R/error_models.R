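#' Robust linear fit of shadows on error-free counts
#'
#' Fits the linear shadow model s = alpha + beta * n by Huber M-estimation
#' (tuning constant 1.345, MAD scale), the conventional robust choice: a
#' shadow count can be inflated by reads that are legitimate low-abundance
#' sequences rather than errors, and those act as outliers.  A design with
#' no variation in n is rejected.  When the data are exactly collinear the
#' least-squares line is returned directly (it is a fixed point of the
#' reweighting).
#'
#' @param pairs A [shadow_pairs()] object with at least 3 observations.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Convergence tolerance on the coefficients (default 1e-8).
#'
#' @return An object of class `shadow_linear_fit`: list with `intercept`,
#'   `slope`, `converged`, `iterations`.
#' @seealso [srer()]
#' @export
fit_shadow_linear <- function(pairs, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(pairs, "shadow_pairs"))
  n <- pairs$n
  s <- pairs$s
  if (length(n) < 3L) stop("at least 3 observations are required")
  if (diff(range(n)) == 0) {
    stop("degenerate design: all error-free counts are identical")
  }
  ols <- lm(s ~ n)
  scale0 <- max(abs(s), 1)
  if (max(abs(ols$residuals)) <= 1e-10 * scale0) {
    # exactly (or numerically) collinear: the OLS line is the Huber fit
    cf <- coef(ols)
    return(structure(list(intercept = unname(cf[[1L]]),
                          slope = unname(cf[[2L]]),
                          converged = TRUE, iterations = 0L),
                     class = "shadow_linear_fit"))
  }
  fit <- suppressWarnings(
    MASS::rlm(s ~ n, psi = MASS::psi.huber, k = 1.345,
              scale.est = "MAD", maxit = max_iter, acc = tol)
  )
  if (!isTRUE(fit$converged)) {
    warning("robust linear fit did not converge in ", max_iter,
            " iterations; returning the last iterate", call. = FALSE)
  }
  cf <- coef(fit)
  structure(list(intercept = unname(cf[[1L]]), slope = unname(cf[[2L]]),
                 converged = isTRUE(fit$converged),
                 iterations = length(fit$conv)),
            class = "shadow_linear_fit")
}

#' @export
print.shadow_linear_fit <- function(x, ...) {
  cat("Robust linear shadow fit: s = ", format(x$intercept, digits = 5),
      " + ", format(x$slope, digits = 5), " * n  (SRER = ",
      format(srer(x), digits = 5), ")\n", sep = "")
  invisible(x)
}

#' Shadow regression error rate (SRER)
#'
#' Under the linear shadow model the per-read error rate is
#' beta / (1 + beta), where beta is the slope of shadows on error-free
#' counts: of every 1 + beta reads attributable to a sequence, beta carry
#' errors.  A negative slope estimate is clamped to 0 because an error rate
#' cannot be negative.
#'
#' @param fit A `shadow_linear_fit`, or a [shadow_pairs()] object (which is
#'   fitted first).
#' @return A rate in `[0, 1)`.
#' @export
srer <- function(fit) {
  if (inherits(fit, "shadow_pairs")) fit <- fit_shadow_linear(fit)
  stopifnot(inherits(fit, "shadow_linear_fit"))
  b <- max(fit$slope, 0)
  b / (1 + b)
}

# ---- penalized natural cubic spline, Reinsch form -----------------------
#
# Exact minimizer of sum w_i (y_i - f(x_i))^2 + lambda * int f''(u)^2 du
# over natural cubic splines, solved in the Reinsch parameterization:
# with D the second-difference map and C the Gram matrix of the interior
# second derivatives (Green-Silverman), gamma solves
#   (C + lambda D W^-1 D') gamma = D y,   f = y - lambda W^-1 D' gamma.
# This form is well conditioned at *both* extremes: lambda = 0 returns the
# interpolating natural spline (f = y) and lambda -> Inf converges to the
# weighted least-squares line, without the numerical breakdown a direct
# (W + lambda K) solve suffers when the penalty dominates.
reinsch_spline <- function(x, y, w, lambda) {
  m <- length(x)
  stopifnot(m >= 4L, lambda >= 0)
  h <- diff(x)
  k <- m - 2L
  D <- matrix(0, k, m)
  for (i in seq_len(k)) {
    D[i, i]      <- 1 / h[i]
    D[i, i + 1L] <- -1 / h[i] - 1 / h[i + 1L]
    D[i, i + 2L] <- 1 / h[i + 1L]
  }
  C <- matrix(0, k, k)
  for (i in seq_len(k)) {
    C[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i < k) {
      C[i, i + 1L] <- h[i + 1L] / 6
      C[i + 1L, i] <- h[i + 1L] / 6
    }
  }
  Dy <- as.vector(D %*% y)
  A <- C + lambda * D %*% (t(D) / w)
  gam <- solve(A, Dy)
  f <- y - lambda * as.vector(t(D) %*% gam) / w
  list(x = x, y = f, h = h, M = c(0, gam, 0))
}

natural_spline_eval <- function(cf, xout, deriv = 0L) {
  x <- cf$x; y <- cf$y; h <- cf$h; M <- cf$M
  i <- findInterval(xout, x, all.inside = TRUE)
  hi <- h[i]
  A <- (x[i + 1L] - xout) / hi
  B <- (xout - x[i]) / hi
  if (deriv == 0L) {
    A * y[i] + B * y[i + 1L] +
      ((A^3 - A) * M[i] + (B^3 - B) * M[i + 1L]) * hi^2 / 6
  } else if (deriv == 1L) {
    (y[i + 1L] - y[i]) / hi -
      (3 * A^2 - 1) / 6 * hi * M[i] + (3 * B^2 - 1) / 6 * hi * M[i + 1L]
  } else if (deriv == 2L) {
    A * M[i] + B * M[i + 1L]
  } else {
    stop("deriv must be 0, 1 or 2")
  }
}

# Collapse tied n to their mean s with multiplicity weights (the spline
# solver needs strictly increasing abscissae; the ER formula keeps ties as
# separate observations).
collapse_ties <- function(pairs) {
  agg_s <- tapply(pairs$s, pairs$n, mean)
  agg_w <- tapply(pairs$s, pairs$n, length)
  x <- as.numeric(names(agg_s))
  ord <- order(x)
  list(x = x[ord], y = as.numeric(agg_s)[ord], w = as.numeric(agg_w)[ord])
}

new_shadow_spline <- function(method, lambda, backend, fit_obj, fitted,
                              pairs, iterations = 1L, converged = TRUE) {
  structure(
    list(method = method, lambda = lambda, backend = backend,
         fit = fit_obj, fitted = fitted,
         pairs = pairs, range = range(pairs$n),
         iterations = iterations, converged = converged),
    class = "shadow_spline"
  )
}

#' @export
print.shadow_spline <- function(x, ...) {
  cat("Shadow smoothing spline (", x$method, "), lambda = ",
      format(x$lambda, digits = 4), ", fitted on m = ", nrow(x$pairs),
      " pairs over n in [", format(x$range[1L]), ", ", format(x$range[2L]),
      "]\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted shadow spline
#'
#' Evaluates the fitted shadow curve (or its first or second derivative) at
#' read counts inside the observed range.  Extrapolation is refused: the
#' penalized spline is only defined between the smallest and largest
#' observed error-free counts.
#'
#' @param object A `shadow_spline` from [fit_cubic_spline()] or
#'   [fit_robust_spline()].
#' @param x Read counts in `[n_1, n_m]`.
#' @param deriv 0, 1 or 2.
#' @param ... Unused.
#' @return Numeric vector of fitted shadow counts (or derivatives).
#' @export
predict.shadow_spline <- function(object, x, deriv = 0L, ...) {
  rng <- object$range
  if (any(x < rng[1L] | x > rng[2L])) {
    stop("evaluation outside the fitted range [", rng[1L], ", ", rng[2L],
         "]")
  }
  if (object$backend == "reinsch") {
    natural_spline_eval(object$fit, x, deriv = as.integer(deriv))
  } else {
    predict(object$fit, x, deriv = as.integer(deriv))$y
  }
}

#' Cubic smoothing spline fit of the read-shadow relationship
#'
#' Models the shadow count as a smooth function of the error-free read
#' count by a natural cubic smoothing spline: the minimizer, over all twice
#' continuously differentiable functions, of the residual sum of squares
#' plus `lambda` times the integrated squared second derivative.  This
#' captures read-shadow relationships that are far from linear (common in
#' mRNA-seq and resequencing samples) without choosing knots.
#'
#' Tied n values are collapsed to their mean s with multiplicity weights
#' before solving; fitted values are reported at every original
#' observation.  `lambda = "auto"` (the default) selects the smoothing
#' parameter by generalized cross-validation through
#' [stats::smooth.spline()], whose reported `lambda` lives on that
#' solver's internal rescaled axis.  A numeric `lambda` is instead taken
#' on the raw read-count scale and solved exactly by the package's
#' Reinsch-form solver, which stays well conditioned from `lambda = 0`
#' (the interpolating natural spline) all the way to the huge-`lambda`
#' limit (the weighted least-squares line).
#'
#' @param pairs A [shadow_pairs()] object with at least 4 distinct n.
#' @param lambda `"auto"` (GCV) or a non-negative smoothing parameter.
#'
#' @return A `shadow_spline` object; see [predict.shadow_spline()].
#' @export
fit_cubic_spline <- function(pairs, lambda = "auto") {
  stopifnot(inherits(pairs, "shadow_pairs"))
  ct <- collapse_ties(pairs)
  if (length(ct$x) < 4L) {
    stop("fewer than 4 distinct read counts; use the linear model ",
         "(fit_shadow_linear) instead")
  }
  if (identical(lambda, "auto")) {
    fit <- smooth.spline(ct$x, ct$y, w = ct$w, cv = FALSE,
                         keep.data = FALSE)
    lam <- fit$lambda
    backend <- "smooth.spline"
    fitted <- predict(fit, pairs$n)$y
  } else {
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
              is.finite(lambda))
    fit <- reinsch_spline(ct$x, ct$y, ct$w, lambda)
    lam <- lambda
    backend <- "reinsch"
    fitted <- natural_spline_eval(fit, pairs$n)
  }
  new_shadow_spline("cubic", lam, backend, fit, fitted, pairs)
}

#' Robust smoothing spline fit of the read-shadow relationship
#'
#' Iteratively reweighted cubic smoothing spline with weights equal to the
#' inverse absolute residuals, so observations far from the current curve
#' (for example shadows inflated by legitimate low-abundance reads) are
#' progressively down-weighted.  Residuals are floored at
#' `delta = 1e-6 * (max s - min s)` before inversion so exactly fitted
#' points do not receive infinite weight; on noiseless data every weight
#' hits the floor and the fit equals the plain cubic spline.  The smoothing
#' parameter is chosen once on the initial unweighted fit (GCV if
#' `lambda = "auto"`) and held fixed across iterations.  Iteration stops
#' when the maximum relative change in fitted values drops below `tol`.
#'
#' @inheritParams fit_cubic_spline
#' @param max_iter Maximum reweighting iterations (default 50).
#' @param tol Relative fitted-value convergence tolerance (default 1e-6).
#'
#' @return A `shadow_spline` object with `iterations` and `converged`
#'   fields.
#' @export
fit_robust_spline <- function(pairs, lambda = "auto", max_iter = 50L,
                              tol = 1e-6) {
  stopifnot(inherits(pairs, "shadow_pairs"), tol > 0, max_iter >= 1)
  ct <- collapse_ties(pairs)
  if (length(ct$x) < 4L) {
    stop("fewer than 4 distinct read counts; use the linear model ",
         "(fit_shadow_linear) instead")
  }
  init <- fit_cubic_spline(pairs, lambda = lambda)
  if (identical(init$lambda, 0)) {
    # lambda = 0 interpolates: residuals are identically zero and the
    # reweighting scheme is a no-op
    out <- init
    out$method <- "robust"
    return(out)
  }
  lam <- init$lambda
  backend <- init$backend
  delta <- 1e-6 * diff(range(pairs$s))
  if (delta <= 0) delta <- 1e-6
  refit <- function(w) {
    if (backend == "reinsch") {
      reinsch_spline(ct$x, ct$y, w, lam)
    } else {
      smooth.spline(ct$x, ct$y, w = w, lambda = lam, keep.data = FALSE)
    }
  }
  eval_ct <- function(fit) {
    if (backend == "reinsch") natural_spline_eval(fit, ct$x)
    else predict(fit, ct$x)$y
  }
  fit <- init$fit
  fitted_ct <- eval_ct(fit)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    res <- ct$y - fitted_ct
    w <- ct$w / pmax(abs(res), delta)
    fit_new <- refit(w)
    fitted_new <- eval_ct(fit_new)
    rel <- max(abs(fitted_new - fitted_ct) / pmax(abs(fitted_ct), delta))
    fit <- fit_new
    fitted_ct <- fitted_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("robust spline did not converge in ", max_iter,
            " iterations; returning the last iterate", call. = FALSE)
  }
  fitted_full <- if (backend == "reinsch") {
    natural_spline_eval(fit, pairs$n)
  } else {
    predict(fit, pairs$n)$y
  }
  new_shadow_spline("robust", lam, backend, fit, fitted_full, pairs,
                    iterations = iter, converged = converged)
}

#' Per-read error rate at a given read count
#'
#' The per-read error rate at count x is the cumulative fitted shadow count
#' divided by the cumulative fitted shadow count plus the cumulative
#' error-free count, both summed over the observed sequences whose
#' error-free count does not exceed x.  It is the model-based analogue of
#' "errored reads over all reads" restricted to sequences of abundance up
#' to x, and unlike a regression slope it may vary with x.  Negative fitted
#' shadow values are clamped to 0 before summation.
#'
#' @param curve A fitted `shadow_spline`.
#' @param x Read count(s) within the fitted range `[n_1, n_m]`.
#' @return Rate(s) in `[0, 1)`, one per element of `x`.
#' @export
per_read_error_rate <- function(curve, x) {
  stopifnot(inherits(curve, "shadow_spline"))
  n <- curve$pairs$n
  rng <- curve$range
  if (any(x < rng[1L] | x > rng[2L])) {
    stop("read count outside the observed range [", rng[1L], ", ",
         rng[2L], "]")
  }
  cum_s <- cumsum(pmax(curve$fitted, 0))
  cum_n <- cumsum(n)
  t_idx <- findInterval(x, n)  # number of observations with n_j <= x
  num <- cum_s[t_idx]
  num / (num + cum_n[t_idx])
}

#' Sample-level empirical error rate (EER)
#'
#' Draws `draws` read counts (default 1000) and reports the median of the
#' per-read error rates evaluated at them, summarizing the whole fitted
#' error-rate curve in one number comparable to the SRER.  By default the
#' counts are drawn uniformly over the integers in `[n_1, n_m]`;
#' `method = "observed"` resamples the observed counts instead.
#'
#' @param curve A fitted `shadow_spline`.
#' @param draws Number of read counts to sample (default 1000).
#' @param method `"uniform"` (integers in the observed range, default) or
#'   `"observed"` (resample observed n).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return List with `eer` (the median, midpoint convention) and `samples`
#'   (data.frame of `count` and `er`).
#' @export
sample_eer <- function(curve, draws = 1000L, method = c("uniform",
                                                        "observed"),
                       seed = NULL) {
  stopifnot(inherits(curve, "shadow_spline"), draws >= 1)
  method <- match.arg(method)
  rng <- curve$range
  x <- with_seed(seed, {
    if (method == "uniform") {
      lo <- ceiling(rng[1L])
      hi <- floor(rng[2L])
      lo + sample.int(hi - lo + 1L, draws, replace = TRUE) - 1L
    } else {
      sample(curve$pairs$n, draws, replace = TRUE)
    }
  })
  er <- per_read_error_rate(curve, x)
  list(eer = median(er), samples = data.frame(count = x, er = er))
}

#' Estimate all shadow-based error rates for a sample
#'
#' Convenience wrapper running the three estimators on one set of shadow
#' pairs: the linear-model SRER and the cubic- and robust-spline EERs.
#' Also reports the raw ratio sum(s) / (sum(s) + sum(n)) of the pairs
#' themselves (the "expected" error rate of simulation studies).
#'
#' @inheritParams fit_cubic_spline
#' @param eer_draws Read counts sampled per EER (default 1000).
#' @param eer_method Draw distribution, see [sample_eer()].
#' @param seed Optional integer seed governing the EER draws.
#'
#' @return An object of class `error_rate_estimate`: list with `srer`,
#'   `eer_cs`, `eer_rs`, `expected_er`, `lambda_cs`, `lambda_rs`,
#'   `converged` (linear/robust-spline flags) and `samples` (per-count ER
#'   draws for both splines).
#' @export
estimate_error_rates <- function(pairs, lambda = "auto",
                                 eer_draws = 1000L,
                                 eer_method = "uniform", seed = NULL) {
  stopifnot(inherits(pairs, "shadow_pairs"))
  lin <- fit_shadow_linear(pairs)
  cs <- fit_cubic_spline(pairs, lambda = lambda)
  rs <- fit_robust_spline(pairs, lambda = lambda)
  e_cs <- sample_eer(cs, draws = eer_draws, method = eer_method,
                     seed = seed)
  e_rs <- sample_eer(rs, draws = eer_draws, method = eer_method,
                     seed = seed)
  structure(
    list(srer = srer(lin), eer_cs = e_cs$eer, eer_rs = e_rs$eer,
         expected_er = expected_error_rate(pairs),
         lambda_cs = cs$lambda, lambda_rs = rs$lambda,
         converged = c(linear = lin$converged,
                       robust_spline = rs$converged),
         samples = list(cubic = e_cs$samples, robust = e_rs$samples)),
    class = "error_rate_estimate"
  )
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat("Shadow-based error rate estimates:\n",
      "  SRER   (robust linear): ", format(x$srer, digits = 4), "\n",
      "  EER_CS (cubic spline) : ", format(x$eer_cs, digits = 4), "\n",
      "  EER_RS (robust spline): ", format(x$eer_rs, digits = 4), "\n",
      "  raw s/(s+n) ratio     : ", format(x$expected_er, digits = 4),
      "\n", sep = "")
  invisible(x)
}
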