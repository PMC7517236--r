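test_that("lambert_w0 solves its defining equation across magnitudes", {
  z <- c(0, 1e-8, 0.1, 1, exp(1), 66625.895758693412, 10^seq(1, 14))
  w <- lambert_w0(z)
  expect_equal(w[z > 0] * exp(w[z > 0]), z[z > 0], tolerance = 1e-13)
  expect_identical(w[1], 0)
  expect_equal(lambert_w0(exp(1)), 1)
  expect_error(lambert_w0(-0.1), "z >= 0")
})

test_that("cumulant generating functions vanish at 0 and encode the count variance", {
  we <- wt_exp(); jg <- jp_gauss(); jl <- jp_latt()
  expect_equal(cgf(we, jg, 0, 2), 0)
  expect_equal(cgf(we, jl, 0, 2), 0)
  expect_equal(cgf(we, jl, 0, 2, deriv = 2L), 2)  # K''(0) = tbar
  ## erlang m = 1 is the exponential pair for all u
  u <- seq(-2, 2, 0.25)
  expect_equal(cgf(wt_erl(1), jg, u, 3), cgf(we, jg, u, 3), tolerance = 1e-14)
  expect_error(cgf(wt_two(0.5), jg, 1, 2), "no closed-form CGF")
})

test_that("closed-form saddles satisfy K'(u) = x to near machine precision", {
  pairs <- list(list(w = wt_exp(), j = jp_gauss(), x = seq(-30, 30, 0.5)),
                list(w = wt_exp(), j = jp_latt(), x = seq(-30, 30, 1)),
                list(w = wt_erl(3), j = jp_gauss(), x = seq(-30, 30, 0.5)))
  for (pr in pairs) {
    sp <- saddle_point(pr$w, pr$j, pr$x, t = 2)
    resid <- abs(cgf(pr$w, pr$j, sp$u_hat, 2, 1L) - pr$x)
    expect_lt(max(resid / pmax(1, abs(pr$x))), 1e-10)
    expect_true(all(sp$Kpp > 0))
    ## u_hat is odd in x (+0 normalises the signed zero at the origin)
    expect_equal(sp$u_hat + 0, -rev(sp$u_hat) + 0)
  }

  ## printed closed-form anchors
  expect_equal(saddle_point(wt_exp(), jp_gauss(), sqrt(exp(1)) * 2, 2)$u_hat, 1)
  sl <- saddle_point(wt_exp(), jp_latt(), 2, 2)
  expect_equal(sl$u_hat, log(1 + sqrt(2)))
  expect_equal(sl$Kpp, 2 * sqrt(2))
})

test_that("numeric root-solver reproduces the reconstructed closed forms", {
  ## dual route guarding the radical reconstruction of the printed saddles
  x <- c(-20, -5, -0.5, 0, 0.5, 5, 20)
  for (pr in list(list(w = wt_exp(), j = jp_gauss()),
                  list(w = wt_erl(2), j = jp_gauss()),
                  list(w = wt_exp(), j = jp_latt()))) {
    cf <- saddle_point(pr$w, pr$j, x, 2, method = "closed_form")
    nm <- saddle_point(pr$w, pr$j, x, 2, method = "numeric")
    expect_equal(cf$u_hat, nm$u_hat, tolerance = 1e-9)
  }
})

test_that("erlang saddle at m = 1 collapses onto the exponential pair", {
  x <- seq(-30, 30, 0.5)
  s1 <- saddle_point(wt_erl(1), jp_gauss(), x, 2)
  s0 <- saddle_point(wt_exp(), jp_gauss(), x, 2)
  expect_equal(s1$u_hat, s0$u_hat, tolerance = 1e-12)
  expect_equal(s1$log_density, s0$log_density, tolerance = 1e-12)
})

test_that("saddle density interpolates the Gaussian core and orders erlang tails", {
  we <- wt_exp(); jg <- jp_gauss()
  ## small-x regime: |x|/tbar <= 0.1 recovers the diffusive Gaussian to 1%
  x <- seq(0.02, 0.2, length.out = 10)
  expect_equal(saddle_log_density(we, jg, x, 2),
               dnorm(x, 0, sqrt(2), log = TRUE), tolerance = 1e-2)

  ## anti-bunching suppression: m = 2 tail below m = 1 at fixed tbar, large x
  tbar <- 2
  x <- seq(10, 30, 2)
  ld1 <- saddle_log_density(wt_erl(1), jg, x, tbar * 1)
  ld2 <- saddle_log_density(wt_erl(2), jg, x, tbar * 2)
  expect_true(all(ld2 < ld1))
})

test_that("universal tail parameters obey their defining relations", {
  tp <- tail_parameters(A = 0, C_A = 1, C_A1 = -1, beta = 2, delta = sqrt(2))
  expect_equal(c(tp$g0, tp$g1, tp$B), c(1, 1, 1))
  for (m in c(2L, 3L)) {
    tp <- tail_parameters_from(wt_erl(m), jp_gauss())
    expect_equal(tp$g0, 1 / sqrt(m))
    expect_equal(tp$g1, m)
    expect_equal(tp$B, sqrt(m))
  }
  expect_error(tail_parameters(0, 1, -1, beta = 0.5, delta = 1), "beta")
  expect_error(tail_parameters_from(wt_exp(), jp_latt()), "unbounded")
})

test_that("universal tail exponent equals the model-specific saddle exponents", {
  ## the module's central correctness gate, on a log grid of y = |x|/t
  y <- exp(seq(log(1), log(1000), length.out = 200))
  t <- 3
  jg <- jp_gauss()
  for (m in c(1L, 2L, 3L)) {
    w <- wt_erl(m)
    ut <- universal_tail_log(tail_parameters_from(w, jg), y * t, t)
    W <- lambert_w0(m * y^2)
    saddle_exponent <- -sqrt(m) * y * t * (sqrt(W) - 1 / sqrt(W)) - t
    expect_equal(ut, saddle_exponent, tolerance = 1e-12)
    ## and against the independent K(u_hat) - u_hat x route
    sp <- saddle_point(w, jg, y * t, t)
    expect_equal(ut, sp$K - sp$u_hat * y * t, tolerance = 1e-12)
  }
})

test_that("two-exponential tail formula approaches the exact series at large |x|", {
  w <- wt_two(0.5, 1.5); jg <- jp_gauss()
  x <- seq(10, 40, 5)
  ut <- universal_tail_log(tail_parameters_from(w, jg), x, 2)
  series <- propagator_series(w, jg, 2, x)$log_density
  gap <- abs(ut - series) / abs(series)
  expect_true(all(diff(gap) < 0))   # slow but monotone convergence
  expect_lt(gap[length(gap)], 0.15)
})

test_that("rate functions: identities, reductions and logarithmic growth", {
  l <- c(0.3, 0.7, 1, 2, 5, 10)
  expect_equal(rate_function("It_exp_gauss", l),
               l * rate_function("Ix_exp_gauss", l))
  expect_equal(rate_function("Ix_erlang", l, m = 1),
               rate_function("Ix_exp_gauss", l))
  expect_equal(rate_function("It_lattice", 1e-9), 0, tolerance = 1e-12)
  expect_error(rate_function("Ix_erlang", 1), "needs an integer m")
  expect_error(rate_function("Ix_exp_gauss", -1), "positive")

  ## exponential-with-log-correction growth: Ix ~ sqrt(W0(l^2)) ~ sqrt(2 ln l)
  lbig <- 10^(4:8)
  ratio <- rate_function("Ix_exp_gauss", lbig) / sqrt(2 * log(lbig))
  expect_true(all(diff(ratio) > 0))          # approaches 1 from below
  expect_true(all(ratio > 0.8 & ratio < 1))

  ## erlang tails are steeper for larger m at fixed l (suppression)
  expect_true(all(diff(sapply(1:4, function(m)
    rate_function("Ix_erlang", 5, m = m))) > 0))
})

test_that("S_m sums: closed forms, entirety, and large-argument asymptotics", {
  y <- seq(0, 10, 0.5)
  expect_equal(sm_sum(1, y), exp(y), tolerance = 1e-12)
  expect_equal(sm_sum(2, y^2), cosh(y), tolerance = 1e-12)
  ## negative arguments: S_2(-y^2) = cos(y)
  expect_equal(sm_sum(2, -(1:3)^2), cos(1:3), tolerance = 1e-12)
  r <- sm_sum(3, 1e3) / sm_sum(3, 1e3, asymptotic = TRUE)
  expect_gt(r, 0.9); expect_lt(r, 1.1)
  expect_error(sm_sum(2.5, 1), "integer")
  expect_error(sm_sum(2, -1, asymptotic = TRUE), "y > 0")
})

test_that("the dominant-term lower bound never exceeds the full series", {
  w <- wt_exp(); j <- jp_gauss()
  x <- seq(5, 30, 1)
  sp <- saddle_point(w, j, x, 2)
  p <- propagator_series(w, j, 2, x)
  single <- vapply(seq_along(x), function(i) {
    ns <- max(1, round(sp$n_star[i]))
    exp(qtn_exact_log(w, 2, ns)) * conditional_density(j, x[i], ns)
  }, numeric(1))
  expect_true(all(single <= p$density))
  ## n_star locates the integer argmax of the summand to within rounding
  i <- which(x == 15)
  ns <- round(sp$n_star[i])
  lt <- vapply((ns - 3):(ns + 3), function(n)
    qtn_exact_log(w, 2, n) + conditional_density(j, x[i], n, log = TRUE),
    numeric(1))
  expect_lte(abs(which.max(lt) - 4L), 1L)
})
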