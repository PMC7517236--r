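#' Seeded Monte Carlo simulation of the wait-then-jump process
#'
#' For each walker, waiting times are drawn from the waiting-time model
#' until their cumulative sum exceeds `t`; the number of completed
#' renewals is the jump count n, and the displacement is the sum of n
#' i.i.d. jump lengths. The process is the ordinary renewal process (the
#' first waiting time is drawn from \eqn{\psi} itself, no aging).
#'
#' Waiting draws are elementary per family: exponential via
#' [stats::rexp()]; erlang as the sum of m exponentials (exact, no
#' generic gamma sampler); the mixture by a fair Bernoulli branch
#' followed by the chosen exponential. Because the jumps are i.i.d. and
#' independent of the waiting times, the displacement is drawn from the
#' exact conditional n-step law (Normal(0, n sigma^2) resp.
#' 2 Binomial(n, 1/2) - n) in one call; the nontrivial renewal-counting
#' part is simulated waiting time by waiting time.
#'
#' One seeded stream drives a fixed vectorised round-based scheme, so an
#' identical `(seed, t, n_walkers, models)` call reproduces the ensemble
#' bitwise.
#'
#' @param waiting a `ctrw_waiting` model.
#' @param jump a `ctrw_jump` model.
#' @param t observation time, non-negative.
#' @param n_walkers number of independent walkers, \eqn{\ge 1}.
#' @param seed integer seed for the pseudo-random stream.
#' @return object of class `ctrw_ensemble`: list with `seed`, `t`,
#'   `n_walkers`, `counts` (integer vector), `displacements` (numeric
#'   vector), `waiting_family`, `jump_family`, and the models.
#' @examples
#' w <- make_waiting_time("exponential"); j <- make_jump("gaussian")
#' ens <- simulate_ctrw(w, j, t = 2, n_walkers = 1e4, seed = 1)
#' mean(ens$counts)  # close to 2
#' @export
simulate_ctrw <- function(waiting, jump, t, n_walkers, seed) {
  stopifnot(inherits(waiting, "ctrw_waiting"), inherits(jump, "ctrw_jump"))
  if (t < 0) stop("t must be non-negative")
  if (n_walkers < 1 || n_walkers != round(n_walkers))
    stop("n_walkers must be a positive integer")
  n_walkers <- as.integer(n_walkers)
  set.seed(as.integer(seed))

  draw_wait <- switch(waiting$family,
    exponential = function(k) stats::rexp(k, rate = 1 / waiting$mean),
    erlang = function(k) {
      rowSums(matrix(stats::rexp(k * waiting$m, rate = 1 / waiting$scale),
                     nrow = k, ncol = waiting$m))
    },
    two_exponential = function(k) {
      sc <- ifelse(stats::runif(k) < 0.5, waiting$a, waiting$b)
      stats::rexp(k) * sc
    })

  remaining <- rep(t, n_walkers)
  counts <- integer(n_walkers)
  active <- seq_len(n_walkers)
  while (length(active) > 0L && t > 0) {
    w <- draw_wait(length(active))
    done <- w > remaining[active]
    jumped <- active[!done]
    counts[jumped] <- counts[jumped] + 1L
    remaining[jumped] <- remaining[jumped] - w[!done]
    active <- jumped
  }

  x <- if (jump$family == "gaussian") {
    stats::rnorm(n_walkers, mean = 0, sd = sqrt(counts * jump$variance))
  } else {
    2 * stats::rbinom(n_walkers, size = counts, prob = 0.5) - counts
  }

  structure(list(seed = as.integer(seed), t = t, n_walkers = n_walkers,
                 counts = counts, displacements = x,
                 waiting_family = waiting$family, jump_family = jump$family,
                 waiting = waiting, jump = jump),
            class = "ctrw_ensemble")
}

#' @export
print.ctrw_ensemble <- function(x, ...) {
  cat(sprintf("CTRW ensemble: %d walkers, t = %g, %s waiting + %s jumps, seed %d\n",
              x$n_walkers, x$t, x$waiting_family, x$jump_family, x$seed))
  cat(sprintf("  mean count %.4g, var %.4g, mean x %.4g, var x %.4g\n",
              mean(x$counts), stats::var(x$counts),
              mean(x$displacements), stats::var(x$displacements)))
  invisible(x)
}

#' Empirical count distribution from a simulated ensemble
#'
#' @param ens a `ctrw_ensemble`.
#' @return a `ctrw_counts` object with `method = "empirical"`; `prob[i]`
#'   is the fraction of walkers with count `n[i] = i - 1`.
#' @export
empirical_qtn <- function(ens) {
  stopifnot(inherits(ens, "ctrw_ensemble"))
  if (ens$n_walkers == 0) stop("empty ensemble")
  nmax <- max(ens$counts)
  prob <- tabulate(ens$counts + 1L, nbins = nmax + 1L) / ens$n_walkers
  structure(list(t = ens$t, n = 0:nmax, prob = prob, method = "empirical",
                 tail_mass = 0, model = ens$waiting),
            class = "ctrw_counts")
}

#' Empirical displacement density from a simulated ensemble
#'
#' Histogram density of the displacements of the walkers that jumped at
#' least once; the never-jumped walkers are reported as the atom at the
#' origin, mirroring the series propagator's separation of the delta
#' term.
#'
#' @param ens a `ctrw_ensemble`.
#' @param bin_width positive bin width (use 1 for the lattice).
#' @return object of class `ctrw_propagator` with bin-centre `x`,
#'   histogram `density`, `atom`, and `counts_per_bin` for standard-error
#'   computations.
#' @export
empirical_density <- function(ens, bin_width) {
  stopifnot(inherits(ens, "ctrw_ensemble"))
  stop_if_not_positive(bin_width, "bin_width")
  moved <- ens$displacements[ens$counts > 0L]
  atom <- 1 - length(moved) / ens$n_walkers
  if (length(moved) == 0) {
    return(structure(list(t = ens$t, x = numeric(0), density = numeric(0),
                          log_density = numeric(0), atom = atom,
                          counts_per_bin = integer(0), n_truncation = NA,
                          waiting = ens$waiting, jump = ens$jump),
                     class = "ctrw_propagator"))
  }
  half <- bin_width / 2
  edges <- seq(floor(min(moved) / bin_width) * bin_width - half,
               max(moved) + bin_width, by = bin_width)
  h <- graphics::hist(moved, breaks = edges, plot = FALSE)
  dens <- h$counts / (ens$n_walkers * bin_width)
  structure(list(t = ens$t, x = h$mids, density = dens,
                 log_density = log(dens), atom = atom,
                 counts_per_bin = h$counts, n_truncation = NA,
                 waiting = ens$waiting, jump = ens$jump),
            class = "ctrw_propagator")
}

#' Empirical Mandel Q of the jump counts
#'
#' \eqn{\hat Q = s^2/\bar n - 1} from the sample mean and variance of the
#' counts, with a delta-method standard error built from the sample
#' central moments (the asymptotic covariance of \eqn{(\bar n, s^2)}).
#'
#' @param ens a `ctrw_ensemble`.
#' @return list with `Q` and `se`.
#' @export
empirical_mandel_q <- function(ens) {
  stopifnot(inherits(ens, "ctrw_ensemble"))
  n <- ens$counts
  N <- length(n)
  if (N < 2) stop("need at least two walkers")
  m1 <- mean(n)
  d <- n - m1
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  Q <- m2 / m1 - 1
  grad <- c(-m2 / m1^2, 1 / m1)
  covm <- matrix(c(m2, m3, m3, m4 - m2^2), 2, 2) / N
  list(Q = Q, se = sqrt(drop(t(grad) %*% covm %*% grad)))
}
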