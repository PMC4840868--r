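test_that("frequency model handles degenerate and tiny cases", {
  one <- shadow_pairs(rep(10, 5), rep(2, 5))
  m <- build_frequency_model(one, read_bins = "quantile:1",
                             shadow_bins = 1)
  expect_equal(m$read_probs, 1)
  expect_equal(m$shadow_probs[1, 1], 1)
  expect_equal(m$read_edges, c(10, 11))       # unit-width degenerate bin
  expect_equal(m$shadow_edges[, 1], c(2, 3))

  p4 <- shadow_pairs(c(1, 2, 3, 10), c(0, 1, 2, 3))
  m4 <- build_frequency_model(p4, read_bins = c(1, 5, 10),
                              shadow_bins = 2)
  expect_equal(m4$read_probs, c(0.75, 0.25))
})

test_that("frequency model rejects bad edges", {
  p <- shadow_pairs(c(1, 5, 9), c(0, 1, 2))
  expect_error(build_frequency_model(p, read_bins = c(2, 5, 9)),
               "cover")
  expect_error(build_frequency_model(p, read_bins = c(1, 5, 5, 9)),
               "strictly increasing")
})

test_that("cell counts equal a brute-force 2-D histogram", {
  p <- generate_nonlinear_pairs("dip", m = 800, noise = 40, seed = 55)
  m <- build_frequency_model(p, read_bins = "quantile:20",
                             shadow_bins = 30)
  M <- length(m$read_probs)
  L <- nrow(m$shadow_probs)
  # oracle: direct double loop over observations and cells
  counts <- matrix(0, L, M)
  rowtot <- numeric(M)
  for (i in seq_len(nrow(p))) {
    j <- NA
    for (jj in seq_len(M)) {
      lo <- m$read_edges[jj]; hi <- m$read_edges[jj + 1]
      if ((p$n[i] >= lo && p$n[i] < hi) ||
          (jj == M && p$n[i] == hi)) { j <- jj; break }
    }
    rowtot[j] <- rowtot[j] + 1
    for (kk in seq_len(L)) {
      lo <- m$shadow_edges[kk, j]; hi <- m$shadow_edges[kk + 1, j]
      if ((p$s[i] >= lo && p$s[i] < hi) ||
          (kk == L && p$s[i] == hi)) {
        counts[kk, j] <- counts[kk, j] + 1
        break
      }
    }
  }
  expect_equal(m$read_probs, rowtot / nrow(p))
  for (j in which(rowtot > 0)) {
    expect_equal(m$shadow_probs[, j], counts[, j] / rowtot[j],
                 info = paste("read bin", j))
  }
  expect_equal(sum(m$read_probs), 1)
})

test_that("sampling respects the cell structure", {
  one <- shadow_pairs(rep(10, 5), rep(2, 5))
  m1 <- build_frequency_model(one, read_bins = "quantile:1",
                              shadow_bins = 1)
  d <- sample_pairs(m1, 500, seed = 3)
  expect_true(all(d$n >= 10 & d$n < 11))
  expect_true(all(d$s >= 2 & d$s < 3))

  # an empty read bin is never drawn from
  p <- shadow_pairs(c(1, 2, 3, 4), c(1, 1, 2, 2))
  m2 <- build_frequency_model(p, read_bins = c(1, 5, 10),
                              shadow_bins = 2)
  expect_equal(m2$read_probs, c(1, 0))
  d2 <- sample_pairs(m2, 500, seed = 4)
  expect_true(all(d2$n < 5))

  d3 <- sample_pairs(m1, 100, integer = TRUE, seed = 5)
  expect_true(all(d3$n == round(d3$n)))
})

test_that("cell occupancy of draws matches p_j * q_kj", {
  p <- generate_nonlinear_pairs("saturating", m = 500, noise = 30,
                                seed = 21)
  m <- build_frequency_model(p, read_bins = "quantile:3",
                             shadow_bins = 4)
  nd <- 20000L
  d <- sample_pairs(m, nd, seed = 8)
  j <- findInterval(d$n, m$read_edges, rightmost.closed = TRUE)
  for (jj in seq_along(m$read_probs)) {
    pj <- m$read_probs[jj]
    if (pj == 0) next
    sel <- d$s[j == jj]
    k <- findInterval(sel, m$shadow_edges[, jj], rightmost.closed = TRUE)
    k[k < 1] <- 1; k[k > 4] <- 4
    for (kk in 1:4) {
      cell_p <- pj * m$shadow_probs[kk, jj]
      se <- sqrt(cell_p * (1 - cell_p) / nd)
      expect_lt(abs(sum(k == kk) / nd - cell_p), 4 * se + 1e-9)
    }
  }
})

test_that("expected error rate is the pooled shadow fraction", {
  expect_equal(expected_error_rate(shadow_pairs(c(9, 9), c(1, 1))), 0.1)
  expect_equal(expected_error_rate(shadow_pairs(c(5, 6), c(0, 0))), 0)
  p <- shadow_pairs(c(3, 8, 12), c(3, 8, 12))
  expect_equal(expected_error_rate(p), 0.5)
})

test_that("rebuilding a model from its own draws is self-consistent", {
  p <- generate_nonlinear_pairs("dip", m = 1000, noise = 30, seed = 11)
  m <- build_frequency_model(p)
  nd <- 50000L
  d <- sample_pairs(m, nd, seed = 2)
  m2 <- build_frequency_model(d, read_bins = m$read_edges,
                              shadow_bins = 30)
  se <- sqrt(m$read_probs * (1 - m$read_probs) / nd)
  expect_true(all(abs(m2$read_probs - m$read_probs) <= 4 * se + 1e-9))
  # reproducibility
  d2 <- sample_pairs(m, 100, seed = 42)
  d3 <- sample_pairs(m, 100, seed = 42)
  expect_identical(d2$n, d3$n)
  expect_identical(d2$s, d3$s)
})

test_that("frequency model JSON round trip preserves the model", {
  p <- generate_nonlinear_pairs("saturating", m = 300, noise = 20,
                                seed = 9)
  m <- build_frequency_model(p, read_bins = "quantile:5", shadow_bins = 6)
  path <- tempfile(fileext = ".json")
  write_frequency_model(m, path)
  m2 <- read_frequency_model(path)
  expect_equal(m2$read_edges, m$read_edges)
  expect_equal(m2$read_probs, m$read_probs)
  expect_equal(m2$shadow_probs, m$shadow_probs)
  expect_equal(model_expected_error_rate(m2),
               model_expected_error_rate(m))
})
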