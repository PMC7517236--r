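#' Waiting-time models for the wait-then-jump process
#'
#' Constructs a waiting-time distribution \eqn{\psi(\tau)} from one of the
#' three closed-form families used throughout the package:
#'
#' * `"exponential"`: \eqn{\psi(\tau) = e^{-\tau/\mu}/\mu} with mean `mean`.
#' * `"erlang"`: \eqn{\psi(\tau) = \tau^{m-1} e^{-\tau/\theta} /
#'   ((m-1)!\,\theta^m)}, the m-fold convolution of an exponential with
#'   scale `scale`; mean is \eqn{m\theta}. Renewals are anti-bunched
#'   (sub-Poissonian) for \eqn{m > 1}.
#' * `"two_exponential"`: the equal-weight mixture
#'   \eqn{\psi(\tau) = \frac12[e^{-\tau/a}/a + e^{-\tau/b}/b]}; mean is
#'   \eqn{(a+b)/2}. For \eqn{a \ne b} renewals are bunched
#'   (super-Poissonian).
#'
#' Besides the density the model carries the data that control the
#' large-count (and hence large-displacement) asymptotics: the leading
#' short-time expansion \eqn{\psi(\tau) \sim C_A \tau^A + C_{A+1}
#' \tau^{A+1}} as \eqn{\tau \to 0}. `A`, `C_A` and `C_A1` are filled
#' analytically per family:
#'
#' | family | A | C_A | C_A1 |
#' |---|---|---|---|
#' | exponential(mean \eqn{\mu}) | 0 | \eqn{1/\mu} | \eqn{-1/\mu^2} |
#' | erlang(m, scale \eqn{\theta}) | \eqn{m-1} | \eqn{1/((m-1)!\theta^m)} | \eqn{-C_A/\theta} |
#' | two_exponential(a, b) | 0 | \eqn{(1/a+1/b)/2} | \eqn{-(1/a^2+1/b^2)/2} |
#'
#' @param family one of `"exponential"`, `"erlang"`, `"two_exponential"`.
#' @param mean mean waiting time (exponential family only). Default 1.
#' @param m Erlang order, integer \eqn{\ge 1} (erlang only). Default 1.
#' @param scale Erlang per-stage scale \eqn{\theta} (erlang only). Default 1,
#'   matching the convention \eqn{\psi(\tau)=\tau^{m-1}e^{-\tau}/(m-1)!}.
#' @param a,b mixture component scales (two_exponential only). The mixture
#'   weight is fixed at 1/2. A common convention sets \eqn{a+b=2} so the
#'   mean is 1; that constraint is not enforced here.
#' @return an object of class `ctrw_waiting`: a list with fields `family`,
#'   `mean`, `var`, `m`, `scale`, `a`, `b`, `A`, `C_A`, `C_A1`.
#' @examples
#' w <- make_waiting_time("erlang", m = 3)
#' w$A            # 2
#' w$C_A          # 1/2
#' mandel_q_longtime(w)   # 1/3 - 1
#' @seealso [wt_pdf()], [wt_laplace()], [mandel_q_longtime()], [qtn_exact()]
#' @export
make_waiting_time <- function(family = c("exponential", "erlang", "two_exponential"),
                              mean = 1, m = 1L, scale = 1, a = NULL, b = NULL) {
  family <- match.arg(family)
  model <- switch(family,
    exponential = {
      stop_if_not_positive(mean, "mean")
      list(family = family, mean = mean, var = mean^2,
           A = 0L, C_A = 1 / mean, C_A1 = -1 / mean^2)
    },
    erlang = {
      stop_if_not_positive(scale, "scale")
      if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
        stop("erlang order 'm' must be an integer >= 1")
      m <- as.integer(m)
      list(family = family, m = m, scale = scale,
           mean = m * scale, var = m * scale^2,
           A = m - 1L,
           C_A = exp(-lgamma(m)) / scale^m,
           C_A1 = -exp(-lgamma(m)) / scale^(m + 1))
    },
    two_exponential = {
      if (is.null(a) || is.null(b)) stop("two_exponential requires 'a' and 'b'")
      stop_if_not_positive(a, "a"); stop_if_not_positive(b, "b")
      mn <- (a + b) / 2
      list(family = family, a = a, b = b,
           mean = mn, var = a^2 + b^2 - mn^2,   # E[tau^2] = a^2 + b^2
           A = 0L, C_A = (1 / a + 1 / b) / 2,
           C_A1 = -(1 / a^2 + 1 / b^2) / 2)
    })
  structure(model, class = "ctrw_waiting")
}

#' @export
print.ctrw_waiting <- function(x, ...) {
  cat("Waiting-time model:", x$family, "\n")
  cat("  mean =", x$mean, " var =", x$var, "\n")
  if (x$family == "erlang") cat("  order m =", x$m, " scale =", x$scale, "\n")
  if (x$family == "two_exponential") cat("  a =", x$a, " b =", x$b, "\n")
  cat("  short-time expansion: A =", x$A, " C_A =", x$C_A, " C_A1 =", x$C_A1, "\n")
  invisible(x)
}

#' Waiting-time density
#'
#' Evaluates \eqn{\psi(\tau)} for a model built by [make_waiting_time()].
#'
#' @param model a `ctrw_waiting` object.
#' @param tau numeric vector of non-negative times.
#' @return numeric vector of density values.
#' @export
wt_pdf <- function(model, tau) {
  stopifnot(inherits(model, "ctrw_waiting"))
  if (any(tau < 0)) stop("tau must be non-negative")
  switch(model$family,
    exponential = stats::dexp(tau, rate = 1 / model$mean),
    erlang = stats::dgamma(tau, shape = model$m, scale = model$scale),
    two_exponential =
      0.5 * (stats::dexp(tau, rate = 1 / model$a) +
             stats::dexp(tau, rate = 1 / model$b)))
}

#' Survival probability of the waiting time
#'
#' \eqn{\Pr(\tau > t)}, which is also the renewal count probability
#' \eqn{Q_t(0)} (no jump up to time t) and the weight of the immobile atom
#' at the origin of the propagator.
#'
#' @inheritParams wt_pdf
#' @param t numeric vector of non-negative times.
#' @return numeric vector of survival probabilities.
#' @export
wt_survival <- function(model, t) {
  stopifnot(inherits(model, "ctrw_waiting"))
  if (any(t < 0)) stop("t must be non-negative")
  switch(model$family,
    exponential = stats::pexp(t, rate = 1 / model$mean, lower.tail = FALSE),
    erlang = stats::pgamma(t, shape = model$m, scale = model$scale,
                           lower.tail = FALSE),
    two_exponential =
      0.5 * (stats::pexp(t, rate = 1 / model$a, lower.tail = FALSE) +
             stats::pexp(t, rate = 1 / model$b, lower.tail = FALSE)))
}

#' Laplace transform of the waiting-time density
#'
#' \eqn{\hat\psi(s) = \int_0^\infty \psi(\tau) e^{-s\tau} d\tau} for
#' \eqn{\mathrm{Re}(s) \ge 0}. Closed forms: exponential
#' \eqn{1/(1+s\mu)}; erlang \eqn{(1+s\theta)^{-m}}; two-exponential
#' \eqn{\frac12[1/(1+as) + 1/(1+bs)]}.
#'
#' @inheritParams wt_pdf
#' @param s numeric or complex vector. Real arguments must be
#'   non-negative; complex arguments are evaluated by analytic
#'   continuation of the rational closed forms (used by the Talbot
#'   inversion contour).
#' @return numeric or complex vector \eqn{\hat\psi(s)}.
#' @export
wt_laplace <- function(model, s) {
  stopifnot(inherits(model, "ctrw_waiting"))
  if (!is.complex(s) && any(s < 0)) stop("real s must be non-negative")
  switch(model$family,
    exponential = 1 / (1 + s * model$mean),
    erlang = (1 + s * model$scale)^(-model$m),
    two_exponential = 0.5 * (1 / (1 + model$a * s) + 1 / (1 + model$b * s)))
}

#' Long-time Mandel Q parameter of the renewal counts
#'
#' The Mandel parameter \eqn{Q = (\langle n^2\rangle - \langle n\rangle^2)
#' / \langle n\rangle - 1} of the number of renewals, in the long-time
#' limit where renewal theory gives
#' \eqn{Q \to \mathrm{Var}(\tau)/\langle\tau\rangle^2 - 1}.
#'
#' \eqn{Q = 0} for exponential waiting (Poisson counting), \eqn{Q = 1/m - 1}
#' for the Erlang family (anti-bunching: jump epochs effectively repel),
#' and \eqn{Q = 2(a-1)^2} for the two-exponential mixture with
#' \eqn{a + b = 2} (bunching: jumps arrive in groups).
#'
#' This is the long-time limit only; it is not a finite-time Q.
#'
#' @inheritParams wt_pdf
#' @return a single number, the limiting Mandel Q.
#' @export
mandel_q_longtime <- function(model) {
  stopifnot(inherits(model, "ctrw_waiting"))
  model$var / model$mean^2 - 1
}
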