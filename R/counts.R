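#' Exact renewal-count distribution Q_t(n)
#'
#' Probability of observing exactly `n` completed waiting intervals
#' (jumps) in `(0, t)` for an ordinary renewal process whose waiting-time
#' density is one of the three closed-form families.
#'
#' * **exponential**: Poisson counting,
#'   \eqn{Q_t(n) = \bar t^n e^{-\bar t}/n!} with \eqn{\bar t = t/\mu}.
#' * **erlang** (order m, scale \eqn{\theta}): with \eqn{t' = t/\theta},
#'   \eqn{Q_t(n) = e^{-t'} \sum_{j=nm}^{nm+m-1} t'^j/j!} for \eqn{n \ge 1}
#'   and \eqn{Q_t(0) = \Gamma(m,t')/\Gamma(m)}; assembled in log space so
#'   counts up to n of order 1e4 stay representable. Equivalent to the
#'   difference of regularized upper incomplete gamma functions at shapes
#'   \eqn{nm+m} and \eqn{nm} (thinning of a Poisson stream).
#' * **two_exponential**: \eqn{Q_t(n) = F_n(t) - F_{n+1}(t)} where
#'   \eqn{F_n} is the CDF of the sum of n mixture draws; \eqn{F_n} is
#'   expanded by the binomial theorem into Gamma(k, a) + Gamma(n-k, b)
#'   convolutions, each evaluated as an adaptive density-times-CDF
#'   quadrature. The telescoping form keeps every term non-negative and
#'   the truncated sum exactly normalized to \eqn{1 - F_{N+1}(t)}.
#'
#' The truncation `n_max`, when not supplied, starts at the long-time mean
#' count plus 12 standard deviations and is doubled until the neglected
#' tail mass is below 1e-10.
#'
#' @param model a `ctrw_waiting` object from [make_waiting_time()].
#' @param t observation time, positive.
#' @param n_max largest count to tabulate; `NULL` (default) chooses it
#'   automatically as above. A warning is issued if the neglected tail
#'   mass exceeds 1e-6.
#' @return an object of class `ctrw_counts`: list with `t`, `n`
#'   (`0:n_max`), `prob`, `method = "exact"`, `tail_mass`, and the model.
#' @examples
#' qtn_exact(make_waiting_time("exponential"), t = 2, n_max = 20)$prob[1] # exp(-2)
#' @seealso [qtn_exact_log()], [qtn_large_n()], [qtn_clt()]
#' @export
qtn_exact <- function(model, t, n_max = NULL) {
  stopifnot(inherits(model, "ctrw_waiting"))
  stop_if_not_positive(t, "t")
  auto <- is.null(n_max)
  if (auto) {
    n_max <- default_n_max(model, t)
    while (count_tail_bound(model, t, n_max) > 1e-10 && n_max < 1e6)
      n_max <- 2L * n_max
  }
  n <- 0:n_max
  prob <- if (model$family == "two_exponential") {
    qtn_two_exp(model, t, n_max)
  } else {
    exp(qtn_exact_log(model, t, n))
  }
  tail <- count_tail_bound(model, t, n_max)
  if (tail > 1e-6)
    warning(sprintf("n_max = %d truncates %.3g of the count mass", n_max, tail))
  structure(list(t = t, n = n, prob = prob, method = "exact",
                 tail_mass = tail, model = model),
            class = "ctrw_counts")
}

#' @export
print.ctrw_counts <- function(x, ...) {
  cat(sprintf("Renewal counts (%s), %s waiting, t = %g, n = 0..%d\n",
              x$method, x$model$family, x$t, max(x$n)))
  cat(sprintf("  mean count %.4g, total mass %.10f\n",
              sum(x$n * x$prob), sum(x$prob)))
  invisible(x)
}

#' Log of the exact count probability
#'
#' Vectorised over `n`; for the exponential and erlang families the value
#' is assembled fully in log space, which is what the tail analyses need
#' (probabilities far below the double-precision underflow threshold of
#' the linear scale). For the two-exponential family the linear quadrature
#' value is logged, which limits its reach to probabilities above ~1e-300.
#'
#' @inheritParams qtn_exact
#' @param n vector of non-negative integer counts.
#' @return numeric vector of \eqn{\log Q_t(n)}.
#' @export
qtn_exact_log <- function(model, t, n) {
  stopifnot(inherits(model, "ctrw_waiting"))
  stop_if_not_positive(t, "t")
  if (any(n < 0) || any(n != round(n))) stop("n must be non-negative integers")
  switch(model$family,
    exponential = stats::dpois(n, lambda = t / model$mean, log = TRUE),
    erlang = {
      ts <- t / model$scale
      m <- model$m
      vapply(n, function(ni) {
        if (ni == 0)
          return(stats::pgamma(ts, shape = m, lower.tail = FALSE, log.p = TRUE))
        j <- (ni * m):(ni * m + m - 1)
        -ts + logsumexp(j * log(ts) - lgamma(j + 1))
      }, numeric(1))
    },
    two_exponential = {
      N <- max(n)
      log(qtn_two_exp(model, t, N)[n + 1])
    })
}

## Mixture-convolution CDF F_n(t) for the two-exponential family and the
## telescoped count probabilities Q_t(n) = F_n - F_{n+1}, n = 0..n_max.
qtn_two_exp <- function(model, t, n_max) {
  Fn <- vapply(0:(n_max + 1), function(n) two_exp_cdf_n(model, t, n), numeric(1))
  pmax(-diff(Fn), 0)
}

## P(sum of n mixture waiting times <= t); binomial expansion over the
## number k of Exp(a) components.
two_exp_cdf_n <- function(model, t, n) {
  if (n == 0) return(1)
  a <- model$a; b <- model$b
  k <- 0:n
  lw <- lchoose(n, k) - n * log(2)
  terms <- vapply(k, function(ki) gamma_conv_cdf(ki, n - ki, a, b, t), numeric(1))
  sum(exp(lw) * terms)
}

## P(Gamma(p, scale = a) + Gamma(q, scale = b) <= t) for integer shapes,
## by adaptive quadrature of density(p, a) * CDF(q, b) over the region
## actually carrying gamma mass.
gamma_conv_cdf <- function(p, q, a, b, t) {
  if (p == 0 && q == 0) return(1)
  if (p == 0) return(stats::pgamma(t, shape = q, scale = b))
  if (q == 0) return(stats::pgamma(t, shape = p, scale = a))
  ## integrate the full window: the value can be far below any absolute
  ## gamma-quantile cutoff, so only a purely relative tolerance is safe
  f <- function(tau) stats::dgamma(tau, shape = p, scale = a) *
    stats::pgamma(t - tau, shape = q, scale = b)
  stats::integrate(f, 0, t, rel.tol = 1e-11, abs.tol = 0,
                   subdivisions = 400L)$value
}

## Starting truncation: long-time mean count + 12 sd (renewal CLT scales).
default_n_max <- function(model, t) {
  mu_n <- t / model$mean
  var_n <- max(t * model$var / model$mean^3, 1)
  max(8L, as.integer(ceiling(mu_n + 12 * sqrt(var_n))))
}

## Upper bound on the count mass beyond n_max.
count_tail_bound <- function(model, t, n_max) {
  switch(model$family,
    exponential = stats::ppois(n_max, t / model$mean, lower.tail = FALSE),
    ## P(n > N) = F_{N+1}(t) = P(Gamma((N+1)m) <= t)
    erlang = stats::pgamma(t, shape = (n_max + 1) * model$m,
                           scale = model$scale),
    ## each mixture draw dominates Exp(min(a, b)) stochastically
    two_exponential = stats::pgamma(t, shape = n_max + 1,
                                    scale = min(model$a, model$b)))
}

#' Universal large-n count law
#'
#' For any waiting-time density analytic at \eqn{\tau = 0} with leading
#' expansion \eqn{\psi(\tau) \sim C_A \tau^A + C_{A+1}\tau^{A+1}}, the
#' count probability for large n at fixed t follows
#' \deqn{Q_t(n) \sim [C_A \Gamma(1+A)]^{n} \frac{t^{n(1+A)}}
#'   {\Gamma(n(1+A)+1)} \exp(t C_{A+1}/C_A),}
#' evaluated in log space. Only the short-time data of \eqn{\psi} enter:
#' to pack many renewals into a fixed window every interval must be short.
#' The bracket's power n makes the exponential family reduce exactly to
#' the Poisson weight and the erlang family to
#' \eqn{e^{-t} t^{nm}/(nm)!}.
#'
#' @inheritParams qtn_exact_log
#' @param log if `TRUE` return \eqn{\log Q_t(n)}.
#' @return numeric vector, the asymptotic probabilities (or their logs).
#' @export
qtn_large_n <- function(model, t, n, log = FALSE) {
  stopifnot(inherits(model, "ctrw_waiting"))
  stop_if_not_positive(t, "t")
  if (any(n < 1)) stop("the large-n law needs n >= 1")
  A <- model$A
  lq <- n * (log(model$C_A) + lgamma(1 + A)) +
    n * (1 + A) * log(t) - lgamma(n * (1 + A) + 1) +
    t * model$C_A1 / model$C_A
  if (log) lq else exp(lq)
}

#' Gaussian (central-limit) approximation to the counts
#'
#' Renewal CLT: for \eqn{t \gg \langle\tau\rangle} the count is
#' approximately Gaussian with mean \eqn{t/\langle\tau\rangle} and
#' variance \eqn{t\,\mathrm{Var}(\tau)/\langle\tau\rangle^3}. For the
#' erlang family (scale 1) this is
#' \eqn{\exp(-(n - t/m)^2 m^2/(2t)) / \sqrt{2\pi t/m^2}}. Accurate only
#' in the central region; the far tail needs [qtn_large_n()] or the
#' saddle-point machinery.
#'
#' @inheritParams qtn_exact_log
#' @return numeric vector of Gaussian density values at the integers `n`.
#' @export
qtn_clt <- function(model, t, n) {
  stopifnot(inherits(model, "ctrw_waiting"))
  stop_if_not_positive(t, "t")
  stats::dnorm(n, mean = t / model$mean,
               sd = sqrt(t * model$var / model$mean^3))
}

#' Rate functions of the counting process
#'
#' `rate_In()` is the large-n rate function at fixed \eqn{l = t/(nm)}:
#' \eqn{I_n(l) = -\ln l + l - 1}, entering
#' \eqn{Q_t(n) \approx H(t,l) (2\pi m n)^{-1/2} e^{-mn I_n(l)}}.
#' `rate_count_time()` is the long-time rate at fixed
#' \eqn{\bar l = nm/t}: \eqn{\bar l \ln \bar l - \bar l + 1}. Both are
#' non-negative and vanish only at argument 1 (the typical count).
#'
#' @param l positive; `l = t/(nm)` (inverse scaled count).
#' @param lbar positive; `lbar = nm/t` (scaled count).
#' @return numeric vector of rate-function values.
#' @export
rate_In <- function(l) {
  if (any(l <= 0)) stop("l must be positive")
  -log(l) + l - 1
}

#' @rdname rate_In
#' @export
rate_count_time <- function(lbar) {
  if (any(lbar <= 0)) stop("lbar must be positive")
  lbar * log(lbar) - lbar + 1
}

#' Finite-time correction factor H(t, l) for erlang counts
#'
#' The Stirling-route representation of the erlang count probability
#' carries a prefactor
#' \deqn{H(t,l) = 1 + \sum_{j=1}^{m-1} \prod_{i=1}^{j}
#'   \frac{1}{1/l + i/t},}
#' with \eqn{l = t/(nm)}. As \eqn{l \to 0} (n large at fixed m) it
#' approaches the geometric sum \eqn{1 + l + \dots + l^{m-1}}, available
#' via `form = "limit"`.
#'
#' @param t positive observation time.
#' @param l positive; `t/(nm)`.
#' @param m erlang order, integer \eqn{\ge 1}.
#' @param form `"exact"` (default) for the finite-t product-sum,
#'   `"limit"` for the small-l geometric form.
#' @return numeric vector of H values (vectorised over `l`).
#' @export
erlang_H <- function(t, l, m, form = c("exact", "limit")) {
  form <- match.arg(form)
  stop_if_not_positive(t, "t")
  if (any(l <= 0)) stop("l must be positive")
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1")
  if (form == "limit")
    return(vapply(l, function(li) sum(li^(0:(m - 1))), numeric(1)))
  vapply(l, function(li) {
    h <- 1; prodterm <- 1
    for (j in seq_len(m - 1)) {
      prodterm <- prodterm / (1 / li + j / t)
      h <- h + prodterm
    }
    h
  }, numeric(1))
}

#' Numerical Laplace inversion of the count distribution
#'
#' Independent validation route for \eqn{Q_t(n)}: inverts
#' \eqn{\hat Q_s(n) = \hat\psi^n(s)\,(1-\hat\psi(s))/s} with the
#' fixed-Talbot contour (M-node midpoint rule on the deformed Bromwich
#' contour). Intended for cross-checking the closed-form/quadrature
#' routes at moderate n; accuracy is typically 1e-8 relative for smooth
#' transforms.
#'
#' @inheritParams qtn_exact_log
#' @param M number of Talbot nodes (default 64).
#' @return numeric vector of count probabilities.
#' @export
qtn_talbot <- function(model, t, n, M = 64L) {
  stopifnot(inherits(model, "ctrw_waiting"))
  stop_if_not_positive(t, "t")
  Fs <- function(s, ni) wt_laplace(model, s)^ni * (1 - wt_laplace(model, s)) / s
  r <- 2 * M / (5 * t)
  theta <- pi * seq_len(M - 1) / M
  cot <- 1 / tan(theta)
  s <- r * theta * (cot + 1i)
  sigma <- theta + (theta * cot - 1) * cot
  vapply(n, function(ni) {
    val <- 0.5 * exp(r * t) * Fs(r + 0i, ni)
    val <- val + sum(exp(t * s) * Fs(s, ni) * (1 + 1i * sigma))
    Re(val) * r / M
  }, numeric(1))
}
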