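#' Jump-length models
#'
#' Two jump-length distributions \eqn{f(\chi)} with zero mean:
#'
#' * `"gaussian"`: \eqn{f(\chi) = e^{-\chi^2/(2\sigma^2)}/\sqrt{2\pi
#'   \sigma^2}} with `variance` \eqn{\sigma^2}. Its far tail matches
#'   \eqn{\exp(-(|\chi|/\delta)^\beta)} with \eqn{\beta = 2} and
#'   \eqn{\delta = \sqrt{2\sigma^2}}, the parameters entering the
#'   universal-tail formula.
#' * `"lattice"`: unit jumps \eqn{\pm 1} with probability 1/2 each (the
#'   symmetric simple random walk). The n-step law has bounded support,
#'   so the exponential-tail machinery for unbounded jumps does not apply
#'   and `tail_beta`/`tail_delta` are `NA`.
#'
#' @param family `"gaussian"` or `"lattice"`.
#' @param variance jump-length variance (gaussian only; lattice jumps
#'   have variance 1 by construction). Default 1.
#' @return an object of class `ctrw_jump` with fields `family`,
#'   `variance`, `tail_beta`, `tail_delta`.
#' @examples
#' make_jump("gaussian")$tail_delta  # sqrt(2)
#' @export
make_jump <- function(family = c("gaussian", "lattice"), variance = 1) {
  family <- match.arg(family)
  if (family == "gaussian") {
    stop_if_not_positive(variance, "variance")
    out <- list(family = family, variance = variance,
                tail_beta = 2, tail_delta = sqrt(2 * variance))
  } else {
    out <- list(family = family, variance = 1,
                tail_beta = NA_real_, tail_delta = NA_real_)
  }
  structure(out, class = "ctrw_jump")
}

#' @export
print.ctrw_jump <- function(x, ...) {
  cat("Jump model:", x$family, " variance =", x$variance, "\n")
  invisible(x)
}

#' Conditional n-step displacement law P(x | n)
#'
#' Law of the position after exactly `n` i.i.d. jumps.
#'
#' Gaussian jumps: \eqn{P(x|n) = e^{-x^2/(2n\sigma^2)}/\sqrt{2\pi n
#' \sigma^2}}. Lattice jumps: the symmetric binomial walk
#' \eqn{P(x|n) = 2^{-n} \binom{n}{(n+x)/2}}, non-zero only for integer x
#' with \eqn{|x| \le n} and \eqn{x \equiv n \pmod 2} (parity: after an
#' odd/even number of unit steps the position is odd/even, and the walker
#' cannot outrun its step count).
#'
#' @param jump a `ctrw_jump` object.
#' @param x numeric vector of positions (integers for the lattice).
#' @param n number of jumps, a single integer \eqn{\ge 1}; the n = 0 atom
#'   is handled by the propagator, not here.
#' @param log if `TRUE` return log-densities (`-Inf` off-support).
#' @return numeric vector of (log-)density/mass values.
#' @export
conditional_density <- function(jump, x, n, log = FALSE) {
  stopifnot(inherits(jump, "ctrw_jump"))
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  if (jump$family == "gaussian") {
    stats::dnorm(x, mean = 0, sd = sqrt(n * jump$variance), log = log)
  } else {
    if (any(x != round(x))) stop("lattice positions must be integers")
    ok <- abs(x) <= n & ((x - n) %% 2 == 0)
    ld <- rep(-Inf, length(x))
    ld[ok] <- stats::dbinom((n + x[ok]) / 2, size = n, prob = 0.5, log = TRUE)
    if (log) ld else exp(ld)
  }
}

#' Exact propagator P(x, t) by series over the number of jumps
#'
#' Composes the exact renewal-count weights with the conditional n-step
#' laws,
#' \deqn{P(x,t) = Q_t(0)\,\delta(x) + \sum_{n\ge1} Q_t(n) P(x|n),}
#' truncating the sum once both the remaining count mass and the largest
#' remaining summand on the grid fall below `tol` relative to the
#' accumulated density. The n = 0 delta term (walkers that never jumped)
#' is returned as the separate scalar `atom` and never folded into the
#' density grid — mixing an atom into a grid would corrupt normalization
#' checks.
#'
#' Truncation is driven by the count distribution plus the dominant-term
#' location \eqn{n^*(x_{\max})} of the tail, because for large |x| the
#' series is dominated by counts far beyond the typical one.
#'
#' @param waiting a `ctrw_waiting` model.
#' @param jump a `ctrw_jump` model.
#' @param t observation time, positive.
#' @param x numeric vector of evaluation points (integers for lattice).
#' @param tol relative truncation tolerance (default 1e-10).
#' @return object of class `ctrw_propagator`: list with `t`, `x`,
#'   `density`, `log_density`, `atom` (= survival probability),
#'   `n_truncation`, and the two models.
#' @examples
#' w <- make_waiting_time("exponential"); j <- make_jump("gaussian")
#' p <- propagator_series(w, j, t = 2, x = seq(-10, 10, 0.5))
#' p$atom  # exp(-2)
#' @export
propagator_series <- function(waiting, jump, t, x, tol = 1e-10) {
  stopifnot(inherits(waiting, "ctrw_waiting"), inherits(jump, "ctrw_jump"))
  stop_if_not_positive(t, "t")
  stop_if_not_positive(tol, "tol")
  if (jump$family == "lattice" && any(x != round(x)))
    stop("lattice propagator needs integer positions")

  ## counts needed: typical region + dominant tail term at the farthest x
  tbar <- t / waiting$mean
  sigma <- sqrt(jump$variance)
  xmax <- max(abs(x), sigma)
  z2 <- (xmax / (tbar * sigma))^2
  nstar <- if (z2 > 0) xmax / (sigma * sqrt(max(lambert_w0(z2), 1e-12)))
           else 0
  n_hi <- max(default_n_max(waiting, t),
              as.integer(ceiling(nstar + 12 * sqrt(nstar + 1))))

  repeat {
    lq <- qtn_exact_log(waiting, t, 0:n_hi)
    dens <- numeric(length(x))
    for (n in seq_len(n_hi)) {
      term <- exp(lq[n + 1] + conditional_density(jump, x, n, log = TRUE))
      dens <- dens + term
    }
    ## last included summand must be negligible everywhere on the grid
    last <- exp(lq[n_hi + 1] + conditional_density(jump, x, n_hi, log = TRUE))
    tail_mass <- count_tail_bound(waiting, t, n_hi)
    if (all(last <= tol * pmax(dens, .Machine$double.xmin)) &&
        tail_mass <= tol)
      break
    if (n_hi > 2e5)
      stop("propagator series truncation failed to converge")
    n_hi <- 2L * n_hi
  }
  structure(list(t = t, x = x, density = dens, log_density = log(dens),
                 atom = exp(lq[1]), n_truncation = n_hi,
                 waiting = waiting, jump = jump),
            class = "ctrw_propagator")
}

#' @export
print.ctrw_propagator <- function(x, ...) {
  tot <- if (x$jump$family == "lattice") sum(x$density)
         else pracma::trapz(x$x, x$density)
  cat(sprintf("Propagator: %s waiting + %s jumps, t = %g\n",
              x$waiting$family, x$jump$family, x$t))
  cat(sprintf("  grid n = %d, atom at origin = %.6g, series truncated at n = %d\n",
              length(x$x), x$atom, x$n_truncation))
  cat(sprintf("  grid mass + atom = %.8f\n", tot + x$atom))
  invisible(x)
}
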