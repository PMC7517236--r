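test_that("exponential counts are Poisson and Q_t(0) is the survival probability", {
  w <- wt_exp()
  q <- qtn_exact(w, t = 2, n_max = 30)
  expect_equal(q$prob[1], exp(-2))
  expect_equal(q$prob, dpois(0:30, 2))
  for (w in list(wt_exp(), wt_erl(2), wt_two(0.5))) {
    expect_equal(qtn_exact(w, 2, 40)$prob[1], wt_survival(w, 2))
  }
  expect_error(qtn_exact(w, t = -1), "positive")
  expect_warning(qtn_exact(wt_exp(), t = 10, n_max = 5), "truncates")
})

test_that("erlang counts: log-space partial sums equal the incomplete-gamma form", {
  ## independent oracle: difference of regularized upper incomplete gammas
  for (m in c(2L, 3L, 5L)) {
    w <- wt_erl(m)
    for (t in c(0.5, 2, 10)) {
      n <- 0:ceiling(4 * t + 20)
      viaSum <- exp(qtn_exact_log(w, t, n))
      viaGamma <- pgamma(t, shape = n * m + m, lower.tail = FALSE) -
        ifelse(n == 0, 0, pgamma(t, shape = pmax(n * m, 1), lower.tail = FALSE))
      ## the gamma-difference form cancels catastrophically deep in the
      ## tail (the log-sum does not), so the 1e-12 relative comparison is
      ## made where the difference is well conditioned
      main <- viaSum > 1e-6
      expect_equal(viaSum[main], viaGamma[main], tolerance = 1e-12)
      expect_lt(max(abs(viaSum - viaGamma)), 1e-15)
    }
  }
  expect_equal(exp(qtn_exact_log(wt_erl(2), 2, 1)), (10 / 3) * exp(-2),
               tolerance = 1e-12)
  expect_equal(exp(qtn_exact_log(wt_erl(2), 2, 0)),
               pgamma(2, 2, lower.tail = FALSE))
})

test_that("two-exponential counts telescope, normalize, and invert correctly", {
  ## degenerate mixture = Poisson
  w11 <- wt_two(1, 1)
  expect_equal(qtn_exact(w11, 2, 30)$prob, dpois(0:30, 2), tolerance = 1e-8)

  ## independent oracle: fixed-Talbot numerical Laplace inversion
  w <- wt_two(0.5, 1.5)
  q <- qtn_exact(w, t = 2)
  expect_equal(q$prob[1:13], qtn_talbot(w, 2, 0:12), tolerance = 1e-6)

  ## survival probability is the mixture tail
  expect_equal(q$prob[1], 0.5 * (exp(-2 / 0.5) + exp(-2 / 1.5)))
})

test_that("count mass sums to one for every family and time", {
  for (t in c(0.5, 2, 10)) {
    for (m in 1:3) {
      q <- qtn_exact(wt_erl(m), t)
      expect_lt(abs(sum(q$prob) + q$tail_mass - 1), 1e-8)
    }
    for (a in c(0.5, 1)) {
      q <- qtn_exact(wt_two(a), t)
      expect_lt(abs(sum(q$prob) + q$tail_mass - 1), 1e-6)
    }
  }
})

test_that("universal large-n law reduces correctly and is approached from the exact law", {
  ## exponential: reduces identically to the Poisson weight
  w <- wt_exp()
  expect_equal(qtn_large_n(w, 2, 1:20), dpois(1:20, 2), tolerance = 1e-12)

  ## erlang: reduces to the leading term e^-t t^(nm)/(nm)!
  for (m in c(2L, 3L)) {
    w <- wt_erl(m)
    n <- 1:20
    expect_equal(qtn_large_n(w, 2, n, log = TRUE),
                 -2 + n * m * log(2) - lgamma(n * m + 1), tolerance = 1e-12)
  }

  ## ratio exact/large-n decreases monotonically to 1 (erlang m = 2, t = 2)
  w2 <- wt_erl(2)
  n <- seq(10, 60, 5)
  ratio <- exp(qtn_exact_log(w2, 2, n) - qtn_large_n(w2, 2, n, log = TRUE))
  expect_true(all(ratio >= 1))
  expect_true(all(diff(ratio) < 0))
  expect_lt(abs(ratio[length(ratio)] - 1), 0.05)

  ## two-exponential: slow but real convergence; exact value at n = 40
  ## cross-validated against high-precision Laplace inversion (5.0221e-33)
  wx <- wt_two(0.5, 1.5)
  expect_equal(exp(qtn_exact_log(wx, 2, 40)), 5.02213860487e-33,
               tolerance = 1e-9)
  r40 <- exp(qtn_exact_log(wx, 2, 40)) / qtn_large_n(wx, 2, 40)
  expect_gt(r40, 0.5); expect_lt(r40, 2)
})

test_that("CLT count approximation has the renewal mean and variance", {
  ## erlang scale 1: mean t/m, variance t/m^2; peak value of the density
  w2 <- wt_erl(2)
  expect_equal(qtn_clt(w2, 400, 200), 1 / sqrt(2 * pi * 100))
  w1 <- wt_erl(1)
  expect_equal(qtn_clt(w1, 400, 0:800),
               dnorm(0:800, mean = 400, sd = sqrt(400)))
  ## central-region agreement with the exact law (m = 4, t = 400)
  w4 <- wt_erl(4)
  n <- 70:130
  ex <- exp(qtn_exact_log(w4, 400, n))
  expect_lt(max(abs(ex - qtn_clt(w4, 400, n))), 0.1 * max(ex))
})

test_that("counting rate functions vanish only at the typical count", {
  expect_equal(rate_In(1), 0)
  expect_equal(rate_count_time(1), 0)
  l <- exp(seq(log(0.05), log(20), length.out = 50))
  expect_true(all(rate_In(l[l != 1]) > 0))
  expect_true(all(rate_count_time(l[l != 1]) > 0))
  expect_error(rate_In(-1), "positive")

  ## Stirling-route reconstruction: exact = H/sqrt(2 pi m n) exp(-mn In(l))
  for (m in c(2L, 3L)) {
    w <- wt_erl(m)
    n <- ceiling(60 / m)  # nm >= 50
    t <- 2
    l <- t / (n * m)
    approx <- erlang_H(t, l, m) / sqrt(2 * pi * m * n) * exp(-m * n * rate_In(l))
    expect_equal(approx, exp(qtn_exact_log(w, t, n)), tolerance = 0.02)
  }
})

test_that("H correction factor: exact form, geometric limit, and their agreement", {
  expect_equal(erlang_H(2, 0.3, 1), 1)              # m = 1: empty sum
  expect_equal(erlang_H(2, 0.1, 3, form = "limit"), 1.11)
  ## exact -> limit as l -> 0 at fixed t, m
  l <- 10^seq(-1, -5, by = -1)
  gap <- abs(erlang_H(2, l, 2) - erlang_H(2, l, 2, form = "limit"))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 1e-6)
})
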