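#' Principal-branch Lambert W function
#'
#' Solves \eqn{w e^w = z} for \eqn{z \ge 0} on the principal branch
#' \eqn{W_0}. All closed-form saddle points in this package live on this
#' branch and every code path passes non-negative arguments.
#'
#' Halley iteration from a logarithmic seed, with a relative convergence
#' test and an iteration cap, so that every non-negative double
#' terminates at machine precision (the iteration is cubically
#' convergent; 3-4 steps suffice in practice).
#'
#' @param z numeric vector, each element \eqn{\ge 0}.
#' @return numeric vector of the same length with \eqn{W_0(z)}.
#' @examples
#' lambert_w0(exp(1)) # == 1
#' @export
lambert_w0 <- function(z) {
  if (any(z < 0)) stop("lambert_w0() is defined here for z >= 0 only")
  vapply(z, function(zi) {
    if (zi == 0) return(0)
    w <- if (zi <= exp(1)) log1p(zi) else {
      lz <- log(zi)
      lz - log(lz)
    }
    for (i in 1:50) {
      ew <- exp(w)
      f <- w * ew - zi
      dw <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
      w <- w - dw
      if (abs(dw) <= 4 * .Machine$double.eps * (1 + abs(w))) break
    }
    w
  }, numeric(1))
}

## log(sum(exp(lx))) without overflow; lx may contain -Inf
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name))
  invisible(x)
}
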