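---
title: "Exponential tails of CTRW propagators: models, exact solutions, and large-deviation asymptotics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential tails of CTRW propagators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The continuous time random walk (CTRW) is a wait-then-jump process: a
particle starts at the origin, waits a random time $\tau \sim \psi(\tau)$,
jumps a random length $\chi \sim f(\chi)$, and renews. Its position at
time $t$ is $x(t) = \sum_{i=1}^{n} \chi_i$, where $n$ is the random
number of renewals completed in $(0,t)$. The density of positions
decomposes over the count,

$$P(x,t) \;=\; Q_t(0)\,\delta(x) \;+\; \sum_{n\ge 1} Q_t(n)\,P(x\mid n),$$

with $Q_t(n)$ the renewal-count probability and $P(x\mid n)$ the
$n$-step conditional law. Although the long-time limit is Gaussian
(CLT), at finite time the *far tail* of $P(x,t)$ decays exponentially in
$|x|$ with a logarithmic correction — the behaviour seen in
single-particle tracking in cells and glassy media. The mechanism is
count fluctuations: reaching a large $|x|$ in a fixed window requires
many more jumps than typical, and the probability of packing $n$ short
waits into $(0,t)$ is controlled entirely by the short-time behaviour of
$\psi$,

$$\psi(\tau) \sim C_A \tau^{A} + C_{A+1}\tau^{A+1}, \qquad \tau \to 0 .$$

This package implements that theory end to end for three exactly
solvable waiting families and two jump families, together with a seeded
Monte Carlo engine used as an independent stochastic oracle.

## Waiting-time families and what they encode

* **exponential** (mean $\mu$, default 1): Poisson counting, the
  memoryless baseline. $A=0$, $C_A = 1/\mu$, $C_{A+1} = -1/\mu^2$.
* **erlang** (order $m$, per-stage scale $\theta$, default $\theta=1$ so
  $\psi(\tau)=\tau^{m-1}e^{-\tau}/(m-1)!$): the $m$-fold convolution of
  an exponential. Since $\psi(0)=0$ for $m>1$, consecutive jumps repel —
  *anti-bunching*, long-time Mandel $Q = 1/m - 1 < 0$ — and the
  exponential tails of $P(x,t)$ are suppressed as $m$ grows.
* **two_exponential** (equal-weight mixture of scales $a<b$):
  $\psi(0) = (1/a+1/b)/2$ exceeds the Poisson value, jumps arrive in
  bursts — *bunching*, $Q = 2(a-1)^2 > 0$ when $a+b=2$ — and the tails
  are enhanced. The mixture weight is fixed at $1/2$; the convention
  $a+b=2$ (unit mean) is supported by a CLI flag (`--sum-to-two`) but
  deliberately not hard-coded, because it is a plotting convention, not
  a structural constraint.

The long-time Mandel parameter is computed as
$\mathrm{Var}(\tau)/\langle\tau\rangle^2 - 1$, which reproduces both
closed forms above exactly; it is exposed *only* as a long-time limit,
never as a finite-$t$ $Q$.

## Exact counting laws

`qtn_exact()` dispatches per family:

* exponential: the Poisson weights via `dpois()`;
* erlang (with $t' = t/\theta$): the partial Poisson sums
  $Q_t(n) = e^{-t'}\sum_{j=nm}^{nm+m-1} t'^j/j!$ for $n \ge 1$ and the
  regularized upper incomplete gamma $\Gamma(m,t')/\Gamma(m)$ at $n=0$,
  assembled with `lgamma()` and log-sum-exp so counts up to $\sim 10^4$
  remain representable. The equivalent incomplete-gamma difference form
  is kept as a *test oracle* only: it cancels catastrophically deep in
  the tail, the partial sum does not;
* two-exponential: $Q_t(n) = F_n(t) - F_{n+1}(t)$, where $F_n$ — the CDF
  of a sum of $n$ mixture draws — is expanded binomially into
  $\Gamma(k,a) + \Gamma(n-k,b)$ convolutions, each evaluated by adaptive
  quadrature of a gamma density against a gamma CDF
  (`integrate()`, relative tolerance $10^{-11}$, absolute tolerance 0).
  The telescoping form keeps all terms non-negative and makes the
  truncated sum exactly $1 - F_{N+1}(t)$, so normalization is limited
  only by quadrature error. A fixed-Talbot numerical Laplace inversion
  (`qtn_talbot()`) provides an independent validation route at moderate
  $n$; at $n = 40$, $t = 2$, $a = 0.5$ the quadrature value was also
  confirmed to 12 digits against a 60-digit high-precision inversion
  during development.

A purely relative quadrature tolerance matters here: the interesting
values reach $10^{-240}$ and below, far under any absolute cutoff one
might be tempted to use for the integration domain.

**Truncation rule.** When `n_max` is not supplied it starts at the
long-time mean count plus 12 standard deviations and doubles until a
family-specific analytic bound on the neglected tail is below
$10^{-10}$ (for the mixture the bound uses stochastic domination by the
smaller scale).

The universal large-$n$ law
$Q_t(n) \sim [C_A\Gamma(1+A)]^{n} t^{n(1+A)}/\Gamma(n(1+A)+1)\cdot
e^{tC_{A+1}/C_A}$ is implemented in log space. The power $n$ on the
bracket is fixed by two reductions that the tests enforce: the
exponential family must recover the Poisson weight exactly, and the
erlang family must recover its leading term $e^{-t}t^{nm}/(nm)!$.

The Stirling route
$Q_t(n) \approx H(t,l)(2\pi mn)^{-1/2}e^{-mn I_n(l)}$ with
$I_n(l) = -\ln l + l - 1$, $l = t/(nm)$, carries the finite-time factor
$H$ (`erlang_H()`), available both as the exact product-sum and as its
small-$l$ geometric limit $1 + l + \dots + l^{m-1}$. Both $l = t/(nm)$
and $\bar l = nm/t$ are exposed through separate functions
(`rate_In()`, `rate_count_time()`) to avoid silent reciprocals.

## Saddle-point tails and the universal formula

For pairs with a closed-form cumulant generating function
($K = -\bar t(1 - e^{u^2/2})$, $-\bar t(1-\cosh u)$, and the erlang
large-$u$ form $-t' + t' e^{u^2/(2m)}$), `saddle_point()` solves
$K'(\hat u) = x$ by the Lambert-$W_0$ closed forms and returns

$$\ln P(x,t) \approx K(\hat u) - \hat u x - \tfrac12\ln(2\pi K''(\hat u)).$$

Three numerical policies apply throughout:

1. **Principal branch only.** Every $W$ argument in the package is
   non-negative by construction.
2. **Closed forms must satisfy their defining equations.** Each
   reconstructed radical form is polished by two Newton steps on
   $K'(u)=x$ and is cross-checked in the test suite against a generic
   bracketed `uniroot()` solve of the same equation (`method =
   "numeric"`). This dual route is the package's guard against
   sign/radical mistakes in closed-form algebra; the residual tolerance
   is $10^{-10}$ relative.
3. **$K''$ comes from the analytic second derivative at $\hat u$**,
   never from a separately transcribed prefactor expression.

The Lambert $W_0$ evaluator is implemented in the package (Halley
iteration from a logarithmic seed, relative convergence test, iteration
cap). The iteration cap is not cosmetic: an unbounded Halley loop with
an absolute $10^{-15}$ exit test can limit-cycle on arguments whose
iterates oscillate at machine precision, which we observed in an
otherwise standard implementation at $z \approx 6.66\times 10^4$ —
an argument squarely inside our evaluation grids.

For *any* analytic-at-zero waiting density and jump tails
$f(\chi)\sim e^{-(|\chi|/\delta)^\beta}$, $\beta>1$, the tail exponent
takes the universal form (`universal_tail_log()`)

$$\ln P(x,t) \approx -t\Big[\tfrac{|x|}{t}\,Z\big(\tfrac{|x|}{t}\big) -
\tfrac{C_{A+1}}{C_A}\Big], \quad
Z(y) = B\,W_0[g_1y^\beta]^{1/\beta} - g_0(A+1)\,W_0[g_1y^\beta]^{-1/\beta},$$

with $g_0, g_1, B$ derived from $(A, C_A, \beta, \delta)$. For a
unit-variance Gaussian jump, $\delta = \sqrt2$ and $\beta = 2$ (so that
$e^{-(|\chi|/\delta)^\beta} = e^{-\chi^2/2}$). The central correctness
gate of the module — enforced at $10^{-12}$ over a 200-point log grid of
$y \in [1, 10^3]$ — is that this generic formula reproduces the erlang
saddle exponent $-\sqrt m |x|(\sqrt W - 1/\sqrt W) - t$,
$W = W_0(mx^2/t^2)$, for every $m$, and the exponential-waiting exponent
at $m = 1$. The two-exponential mixture, which has no closed-form $K$,
is handled by this universal route only; its convergence to the exact
series is slow for strong bunching (small $a$), which the tests assert
as a monotone-gap property rather than a tight tolerance.

The position rate function for the memoryless pair is
$I_x(l) = 1/l + \sqrt{W_0(l^2)} - 1/\sqrt{W_0(l^2)}$ with
$I_t(l) = l\,I_x(l)$; its large-$l$ growth is $\sqrt{2\ln l}$ —
exponential decay in $|x|$ up to a slowly varying correction. The tests
assert the asymptotic as $I_x(l)/\sqrt{2\ln l} \uparrow 1$, which the
saddle construction forces; a plain $\propto \ln l$ reading is ruled
out by differentiating the exponent.

## The simulator: what it emulates and what it does not

`simulate_ctrw()` draws, per walker, waiting times until they overshoot
$t$ (erlang waits as sums of $m$ exponentials — exact, no generic gamma
sampler; mixture waits by a fair Bernoulli branch then the chosen
exponential), giving the count $n$; the displacement is then drawn from
the exact conditional $n$-step law ($\mathcal N(0, n\sigma^2)$ or
$2\,\mathrm{Bin}(n,\tfrac12)-n$). Because jumps are i.i.d. and
independent of the waits, this is *identical in distribution* to
drawing $n$ jumps one by one; the nontrivial renewal-counting part is
simulated draw-by-draw. One seeded stream drives a fixed vectorised
round-based scheme: identical `(seed, t, n_walkers, models)` gives a
bitwise-identical ensemble. (A counter-based per-walker stream — which
would additionally make ensembles nest when `n_walkers` grows — has no
practical base-R implementation at $10^6$ walkers; reproducibility of
the *call*, which is what the tests and the acceptance script need, is
fully guaranteed by the scheme above.)

The generator emulates an **ordinary** renewal process started at
$t=0$ with uncorrelated jumps and waits. It does **not** emulate aged
or equilibrium initial conditions, waiting–jump coupling, localisation
noise between jumps, or heavy-tailed waiting times — all outside the
model class treated here. Tests passing against this generator
therefore demonstrate internal consistency of the formulas with the
model's own sampling scheme, not fidelity to any particular
experimental data set.

**Problem sizes.** The default suite simulates $2\times10^4$–$10^6$
walkers at $t = 2$ and $2\times10^4$ walkers at $t = 400\langle\tau\rangle$
for the Mandel-$Q$ limits; the acceptance script uses $10^5$ walkers per
$Q$ case and $10^6$ for the count histogram. Statistical checks use
3-standard-error bands on bins with expected count at least 20, and a
two-sample $\chi^2$ at $\alpha = 0.01$ for the erlang-vs-thinned-Poisson
equivalence.

## Propagator truncation

`propagator_series()` truncates the count sum only when *both* the
analytic tail-mass bound and the last included summand (evaluated on
the whole grid) are below the relative tolerance (default $10^{-10}$).
The starting order extends beyond the count-based rule to the
dominant-term location $n^*(x_{\max}) = |x|/(\sigma\sqrt{W_0
(x^2/(\bar t\sigma)^2)})$, because at large $|x|$ the series is
dominated by counts far beyond the typical one — a count-mass-only rule
would silently drop the entire tail. The $n=0$ atom (survival
probability) is returned as a separate scalar and never folded into the
density grid; mixing a point mass into a grid corrupts every
normalization check downstream, so plots and CSV outputs carry it as a
dedicated sidecar field.

## Interfaces and formats

The R functions are the primary interface. A thin command-line wrapper
(`inst/scripts/ctrw.R`, see `?run_ctrw_cli`) exposes `qtn`,
`propagator`, `tails`, `ratefn`, `simulate`, `figure-data` and
`compare`; outputs are comma-separated tables with `#`-prefixed
metadata lines and 17-significant-digit numerics, so re-reading
reproduces the doubles bit-exactly. Configuration files use YAML
(`waiting:`/`jump:` blocks; explicit flags override file values), YAML
being the structured format with an installed, dependency-light R
parser. Exit codes: 0 success, 1 user error, 2 numerical failure.

## Known limitations

* Two-exponential exact counts are computed on the linear scale, so
  probabilities below roughly $10^{-300}$ underflow; the erlang and
  exponential routes are fully log-space.
* The erlang CGF is a large-$u$ asymptotic (a $\ln m$ subleading term is
  neglected); `saddle_point()` for that pair is a tail approximation,
  exact at $m=1$.
* Lattice jumps have bounded support, so the universal-tail machinery
  (built for unbounded, faster-than-exponential jump tails) rejects
  them; their tails come from the closed-form $\cosh$ CGF instead.
* Jump tails with $\beta \le 1$ (sub-exponential, single-big-jump
  regime), heavy-tailed waiting densities with diverging mean, $d>1$,
  and aged initial conditions are out of scope.

```{r}
library(ctrwtails)
w <- make_waiting_time("erlang", m = 2)
j <- make_jump("gaussian")
p <- propagator_series(w, j, t = 2, x = seq(-30, 30, 0.1))
s <- saddle_point(w, j, x = 20, t = 2)
c(atom = p$atom, u_hat = s$u_hat, logP = s$log_density)
```
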