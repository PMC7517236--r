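## Supported (waiting, jump) pairs with closed-form cumulant generating
## functions. Everything is expressed in the rescaled time of the waiting
## family: tbar = t/mean for the exponential pairs, ts = t/scale for the
## erlang pair (whose CGF is the large-u asymptotic form).
cgf_pair <- function(waiting, jump) {
  key <- paste(waiting$family, jump$family, sep = "+")
  if (!key %in% c("exponential+gaussian", "exponential+lattice",
                  "erlang+gaussian"))
    stop(sprintf("no closed-form CGF for the pair '%s'; ", key),
         "use universal_tail_log() / propagator_series() instead")
  key
}

#' Cumulant generating function K(u) of the position at fixed t
#'
#' \eqn{K(u) = \ln \langle e^{u x(t)} \rangle}. Closed forms:
#'
#' * exponential waiting + gaussian jumps:
#'   \eqn{K(u) = -\bar t\,(1 - e^{\sigma^2 u^2/2})}, \eqn{\bar t = t/\mu};
#' * exponential waiting + lattice jumps:
#'   \eqn{K(u) = -\bar t\,(1 - \cosh u)};
#' * erlang waiting + gaussian jumps:
#'   \eqn{K(u) = -t' + t' e^{\sigma^2 u^2/(2m)}}, \eqn{t' = t/\theta}.
#'   This last form is a large-u asymptotic (a subleading \eqn{\ln m}
#'   term is dropped), valid precisely in the tail regime it is used for;
#'   it is exact for m = 1.
#'
#' The two-exponential mixture has no closed-form K here; its tail goes
#' through [universal_tail_log()].
#'
#' @param waiting a `ctrw_waiting` model.
#' @param jump a `ctrw_jump` model.
#' @param u numeric vector of tilt variables.
#' @param t observation time, positive.
#' @param deriv 0, 1 or 2: return K, K' or K''.
#' @return numeric vector.
#' @export
cgf <- function(waiting, jump, u, t, deriv = 0L) {
  key <- cgf_pair(waiting, jump)
  stop_if_not_positive(t, "t")
  s2 <- jump$variance
  switch(key,
    "exponential+gaussian" = {
      tb <- t / waiting$mean
      e <- exp(s2 * u^2 / 2)
      switch(as.character(deriv),
        "0" = -tb * (1 - e),
        "1" = tb * s2 * u * e,
        "2" = tb * s2 * e * (1 + s2 * u^2))
    },
    "exponential+lattice" = {
      tb <- t / waiting$mean
      switch(as.character(deriv),
        "0" = -tb * (1 - cosh(u)),
        "1" = tb * sinh(u),
        "2" = tb * cosh(u))
    },
    "erlang+gaussian" = {
      ts <- t / waiting$scale
      m <- waiting$m
      e <- exp(s2 * u^2 / (2 * m))
      switch(as.character(deriv),
        "0" = -ts + ts * e,
        "1" = ts * s2 * u / m * e,
        "2" = ts * s2 / m * e * (1 + s2 * u^2 / m))
    })
}

#' Saddle point of the tilted position distribution
#'
#' Solves \eqn{K'(\hat u) = x}. Closed forms on the principal Lambert
#' branch (all arguments non-negative by construction):
#'
#' * exponential + gaussian:
#'   \eqn{\hat u = \mathrm{sgn}(x) \sqrt{W_0((x/(\bar t\sigma))^2)}/\sigma};
#' * exponential + lattice: \eqn{\hat u = \mathrm{arcsinh}(x/\bar t)},
#'   with \eqn{K''(\hat u) = \sqrt{x^2 + \bar t^2}};
#' * erlang + gaussian:
#'   \eqn{\hat u = \mathrm{sgn}(x) \sqrt{m W_0(m x^2/(t'\sigma)^2)}/\sigma}.
#'
#' Each closed-form saddle is polished by two Newton steps on
#' \eqn{K'(u) = x}, so the returned \eqn{\hat u} satisfies the defining
#' equation to near machine precision regardless of the W evaluator's
#' internal tolerance. `method = "numeric"` instead brackets the root of
#' the strictly increasing \eqn{K'} (K is convex) and solves with
#' [stats::uniroot()]; the dual route exists so the reconstructed
#' radicals can be validated against the defining equation.
#'
#' `n_star` is the dominant term of the propagator series (the n at
#' which \eqn{Q_t(n) P(x|n)} peaks): for the exponential + gaussian pair
#' \eqn{n^* = |x| / (\sigma\sqrt{W_0(x^2/(\bar t \sigma)^2)})}, with the
#' analogous \eqn{|x|/(\sigma\sqrt{m W_0(m x^2/(t'\sigma)^2)})} for the
#' erlang pair; `NA` for the lattice (no closed form is used).
#'
#' @inheritParams cgf
#' @param x numeric vector of positions.
#' @param method `"closed_form"` (default) or `"numeric"`.
#' @return object of class `ctrw_saddle`: list of vectors `x`, `u_hat`,
#'   `K`, `Kpp`, `log_density`, `n_star`, plus `t` and the models.
#'   `log_density` is the saddle-point approximation
#'   \eqn{K(\hat u) - \hat u x - \frac12\ln(2\pi K''(\hat u))}.
#' @examples
#' w <- make_waiting_time("exponential"); j <- make_jump("gaussian")
#' saddle_point(w, j, x = sqrt(exp(1)) * 2, t = 2)$u_hat  # 1: W0(e) = 1
#' @export
saddle_point <- function(waiting, jump, x, t, method = c("closed_form", "numeric")) {
  key <- cgf_pair(waiting, jump)
  method <- match.arg(method)
  stop_if_not_positive(t, "t")
  sigma <- sqrt(jump$variance)
  n_star <- rep(NA_real_, length(x))

  if (method == "closed_form") {
    u <- switch(key,
      "exponential+gaussian" = {
        tb <- t / waiting$mean
        z2 <- (x / (tb * sigma))^2
        w <- lambert_w0(z2)
        n_star <- ifelse(x == 0, NA_real_, abs(x) / (sigma * sqrt(w)))
        sign(x) * sqrt(w) / sigma
      },
      "exponential+lattice" = asinh(x / (t / waiting$mean)),
      "erlang+gaussian" = {
        ts <- t / waiting$scale
        m <- waiting$m
        z2 <- m * (x / (ts * sigma))^2
        w <- lambert_w0(z2)
        n_star <- ifelse(x == 0, NA_real_, abs(x) / (sigma * sqrt(m * w)))
        sign(x) * sqrt(m * w) / sigma
      })
    ## Newton polish on K'(u) = x
    for (i in 1:2)
      u <- u - (cgf(waiting, jump, u, t, 1L) - x) / cgf(waiting, jump, u, t, 2L)
  } else {
    u <- vapply(x, function(xi) {
      if (xi == 0) return(0)
      g <- function(ui) cgf(waiting, jump, ui, t, 1L) - xi
      hi <- 1
      while (sign(g(sign(xi) * hi)) == sign(g(0)) && hi < 1e3) hi <- 2 * hi
      if (hi >= 1e3) stop("saddle root not bracketed: unsupported regime")
      stats::uniroot(g, sort(c(0, sign(xi) * hi)), tol = 1e-14)$root
    }, numeric(1))
  }
  K <- cgf(waiting, jump, u, t, 0L)
  Kpp <- cgf(waiting, jump, u, t, 2L)
  structure(list(x = x, t = t, u_hat = u, K = K, Kpp = Kpp,
                 log_density = K - u * x - 0.5 * log(2 * pi * Kpp),
                 n_star = n_star, waiting = waiting, jump = jump),
            class = "ctrw_saddle")
}

#' @export
print.ctrw_saddle <- function(x, ...) {
  cat(sprintf("Saddle-point solution, %s + %s, t = %g, %d position(s)\n",
              x$waiting$family, x$jump$family, x$t, length(x$x)))
  print(utils::head(data.frame(x = x$x, u_hat = x$u_hat, K = x$K,
                               Kpp = x$Kpp, log_density = x$log_density)))
  invisible(x)
}

#' Saddle-point log-density of the position
#'
#' Convenience wrapper: the large-deviation approximation
#' \eqn{\ln P(x,t) \approx K(\hat u) - \hat u x - \frac12 \ln(2\pi
#' K''(\hat u))}, with \eqn{K''} always taken from the closed-form second
#' derivative at \eqn{\hat u}.
#'
#' @inheritParams saddle_point
#' @return numeric vector of log-densities.
#' @export
saddle_log_density <- function(waiting, jump, x, t,
                               method = c("closed_form", "numeric")) {
  saddle_point(waiting, jump, x, t, method)$log_density
}

#' Universal exponential-tail parameters
#'
#' The large-|x| tail of P(x, t) for any waiting density analytic at 0
#' (expansion \eqn{C_A \tau^A + C_{A+1}\tau^{A+1}}) and any jump density
#' with \eqn{f(\chi) \sim \exp(-(|\chi|/\delta)^\beta)}, \eqn{\beta > 1},
#' is controlled by three derived constants:
#' \deqn{g_0 = (\beta(\beta-1)/(A+1))^{1/\beta}/\delta, \quad
#'   g_1 = [g_0 (A+1) / (C_A \Gamma(A+1))^{1/(1+A)}]^\beta, \quad
#'   B = g_0 (A+1)/\beta + g_0^{1-\beta}\delta^{-\beta}.}
#'
#' @param A non-negative integer, leading short-time power of the
#'   waiting density.
#' @param C_A positive leading coefficient.
#' @param C_A1 next coefficient (of \eqn{\tau^{A+1}}).
#' @param beta jump-tail exponent, > 1.
#' @param delta jump-tail scale, positive.
#' @return object of class `ctrw_tailpars`: list with the five inputs
#'   and `g0`, `g1`, `B`.
#' @seealso [tail_parameters_from()] to derive them from model objects,
#'   [universal_tail_log()] for the tail formula itself.
#' @export
tail_parameters <- function(A, C_A, C_A1, beta, delta) {
  if (A < 0 || A != round(A)) stop("A must be a non-negative integer")
  stop_if_not_positive(C_A, "C_A")
  if (beta <= 1) stop("beta must exceed 1")
  stop_if_not_positive(delta, "delta")
  g0 <- (beta * (beta - 1) / (A + 1))^(1 / beta) / delta
  g1 <- (g0 * (A + 1) / (C_A * gamma(A + 1))^(1 / (1 + A)))^beta
  B <- g0 * (A + 1) / beta + g0^(1 - beta) * delta^(-beta)
  structure(list(A = A, C_A = C_A, C_A1 = C_A1, beta = beta, delta = delta,
                 g0 = g0, g1 = g1, B = B),
            class = "ctrw_tailpars")
}

#' @rdname tail_parameters
#' @param waiting a `ctrw_waiting` model (supplies A, C_A, C_A1).
#' @param jump a `ctrw_jump` model with unbounded jumps (supplies
#'   beta, delta); the lattice family is rejected.
#' @export
tail_parameters_from <- function(waiting, jump) {
  stopifnot(inherits(waiting, "ctrw_waiting"), inherits(jump, "ctrw_jump"))
  if (!is.finite(jump$tail_beta))
    stop("universal tail parameters need an unbounded jump family")
  tail_parameters(waiting$A, waiting$C_A, waiting$C_A1,
                  jump$tail_beta, jump$tail_delta)
}

#' Universal exponential-tail log-density (exponent only)
#'
#' \deqn{\ln P(x,t) \approx -t\left[\frac{|x|}{t} Z\!\left(\frac{|x|}{t}\right)
#'   - \frac{C_{A+1}}{C_A}\right], \qquad
#'   Z(y) = B\,W_0[g_1 y^\beta]^{1/\beta} -
#'   g_0(A+1)\,W_0[g_1 y^\beta]^{-1/\beta}.}
#'
#' No prefactor is included: this is the rate-level exponent. With the
#' erlang specialization (\eqn{A = m-1}, \eqn{C_A = 1/(m-1)!},
#' \eqn{C_{A+1} = -C_A}, \eqn{\beta = 2}, \eqn{\delta = \sqrt2}) it
#' reduces algebraically to
#' \eqn{-\sqrt m |x|(\sqrt{W} - 1/\sqrt{W}) - t}, \eqn{W = W_0(m x^2/t^2)},
#' the erlang saddle exponent; at m = 1 to the exponential-waiting
#' exponent. Both identities are enforced by tests.
#'
#' @param tp a `ctrw_tailpars` object.
#' @param x numeric vector of positions, non-zero.
#' @param t observation time, positive.
#' @return numeric vector of log-density exponents.
#' @export
universal_tail_log <- function(tp, x, t) {
  stopifnot(inherits(tp, "ctrw_tailpars"))
  stop_if_not_positive(t, "t")
  if (any(x == 0)) stop("the tail formula needs x != 0")
  y <- abs(x) / t
  w <- lambert_w0(tp$g1 * y^tp$beta)
  Z <- tp$B * w^(1 / tp$beta) - tp$g0 * (tp$A + 1) * w^(-1 / tp$beta)
  -t * (y * Z - tp$C_A1 / tp$C_A)
}

#' Large-deviation rate functions of the position
#'
#' Rate functions in the scaled variable \eqn{l = |x| / \bar t} (position
#' over rescaled time \eqn{\bar t = t/\langle\tau\rangle}):
#'
#' * `"Ix_exp_gauss"`: \eqn{I_x(l) = 1/l + \sqrt{W_0(l^2)} -
#'   1/\sqrt{W_0(l^2)}}, the \eqn{\lim_{x\to\infty} -\ln P/|x|} for
#'   exponential waiting + gaussian jumps. Grows like
#'   \eqn{\sqrt{2\ln l}} for large l: exponential decay in |x| with a
#'   logarithmic correction.
#' * `"It_exp_gauss"`: \eqn{I_t(l) = l\,I_x(l)}, the
#'   \eqn{\lim_{t\to\infty} -\ln P/t} companion.
#' * `"It_lattice"`: \eqn{I_t(l) = 1 + l\,\mathrm{arcsinh}(l) -
#'   \sqrt{1+l^2}} for exponential waiting + lattice jumps.
#' * `"Ix_erlang"`: \eqn{I_x(l) = \sqrt m(\sqrt{W_0(l^2/m)} -
#'   1/\sqrt{W_0(l^2/m)}) + m/|l|}; requires `m`. Reduces to
#'   `"Ix_exp_gauss"` at m = 1; for fixed l it increases with m — the
#'   anti-bunched walk suppresses the exponential tail.
#'
#' @param kind one of the four strings above.
#' @param l positive scaled position \eqn{|x|/\bar t}.
#' @param m erlang order (only for `"Ix_erlang"`).
#' @return numeric vector of rate-function values.
#' @export
rate_function <- function(kind = c("Ix_exp_gauss", "It_exp_gauss",
                                   "It_lattice", "Ix_erlang"),
                          l, m = NULL) {
  kind <- match.arg(kind)
  if (any(l <= 0)) stop("l must be positive")
  switch(kind,
    Ix_exp_gauss = {
      sw <- sqrt(lambert_w0(l^2))
      1 / l + sw - 1 / sw
    },
    It_exp_gauss = l * rate_function("Ix_exp_gauss", l),
    It_lattice = 1 + l * asinh(l) - sqrt(1 + l^2),
    Ix_erlang = {
      if (is.null(m) || m < 1 || m != round(m))
        stop("'Ix_erlang' needs an integer m >= 1")
      sw <- sqrt(lambert_w0(l^2 / m))
      sqrt(m) * (sw - 1 / sw) + m / abs(l)
    })
}

#' Generalized exponential sums S_m(y)
#'
#' \eqn{S_m(y) = \sum_{n \ge 0} y^n/(nm)!}, the Mittag-Leffler value
#' \eqn{E_{m,1}(y)} at integer order: the generating function of the
#' erlang count weights. Closed forms: \eqn{S_1(y) = e^y} and
#' \eqn{S_2(y) = \cosh(\sqrt y)} for \eqn{y \ge 0} (equivalently
#' \eqn{S_2(y^2) = \cosh y}).
#' The entire series is summed directly with log-space terms; with
#' `asymptotic = TRUE` the large-y law \eqn{\exp(y^{1/m})/m} is returned
#' instead (y > 0).
#'
#' @param m positive integer order.
#' @param y numeric vector (any sign for the exact series; positive for
#'   the asymptotic form).
#' @return numeric vector of sum values.
#' @examples
#' sm_sum(2, 4)        # cosh(2)
#' sm_sum(3, 1e3, asymptotic = TRUE)
#' @export
sm_sum <- function(m, y, asymptotic = FALSE) {
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1")
  if (asymptotic) {
    if (any(y <= 0)) stop("the asymptotic form needs y > 0")
    return(exp(y^(1 / m)) / m)
  }
  vapply(y, function(yi) {
    if (yi == 0) return(1)
    total <- 0
    n <- 0
    repeat {
      lt <- n * log(abs(yi)) - lgamma(n * m + 1)
      term <- sign(yi)^n * exp(lt)
      total <- total + term
      ## stop once past the peak and terms are negligible
      if (n > abs(yi)^(1 / m) / m + 5 && abs(term) <= 1e-18 * abs(total))
        break
      n <- n + 1
      if (n > 1e5) break
    }
    total
  }, numeric(1))
}
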