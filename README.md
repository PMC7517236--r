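# ctrwtails

Exact solutions and large-deviation tail asymptotics for the continuous
time random walk (CTRW) — the wait-then-jump model of particle
spreading used across single-particle tracking, glassy dynamics, and
intracellular transport. The package is for researchers who observe
that displacement histograms decay *exponentially* in |x| at finite
time (a Laplace-like tail) rather than as the Gaussian the central
limit theorem promises, and who want to compute, fit, or test that
behaviour quantitatively within the CTRW framework.

## The model and the mathematics

A walker starts at the origin, waits τ ~ ψ(τ), jumps χ ~ f(χ), and
renews; its position at time t is x(t) = Σᵢ χᵢ over the random number n
of jumps in (0, t). The propagator decomposes over the count,

    P(x,t) = Q_t(0) δ(x) + Σ_{n≥1} Q_t(n) P(x|n),

with Q_t(n) the renewal-count probabilities and P(x|n) the n-step
conditional law. The far tail of P(x,t) is governed by large count
fluctuations, and those are controlled by the short-time expansion
ψ(τ) ~ C_A τ^A + C_{A+1} τ^{A+1}. Writing K(u) for the cumulant
generating function of x(t), the tail follows the saddle-point form

    ln P(x,t) ≈ K(û) − ûx − ½ ln(2π K″(û)),   K′(û) = x,

with û given by closed forms in the Lambert W₀ function, e.g.
û = sgn(x) √W₀((x/t̄)²) for exponential waiting + Gaussian jumps. The
result is exponential decay in |x| with a logarithmic correction:
the rate function I_x(l) = 1/l + √W₀(l²) − 1/√W₀(l²) grows as
√(2 ln l). Anti-bunched waiting (Erlang order m, Mandel Q = 1/m − 1)
suppresses the tails; bunched waiting (two-exponential mixture,
Q = 2(a−1)² at unit mean) enhances them.

The package provides:

* **waiting-time models** (exponential, Erlang, two-exponential
  mixture) with densities, Laplace transforms, short-time coefficients
  (A, C_A, C_{A+1}) and long-time Mandel Q — `make_waiting_time()`,
  `wt_pdf()`, `wt_laplace()`, `mandel_q_longtime()`;
* **exact renewal counts** Q_t(n) for all three families (log-space
  partial Poisson sums, gamma-convolution quadrature, Talbot-inversion
  cross-check), the universal large-n law, the CLT approximation, the
  counting rate functions and the finite-time correction H(t,l) —
  `qtn_exact()`, `qtn_large_n()`, `qtn_clt()`, `rate_In()`,
  `erlang_H()`;
* **exact propagators** by the conditioning series, with the immobile
  atom kept separate — `propagator_series()`, `conditional_density()`;
* **large-deviation machinery**: closed-form CGFs and Lambert-W
  saddles, saddle-point densities, the universal exponential-tail
  formula Z(y) with derived constants (g₀, g₁, B), position/time rate
  functions, and the generalized exponential sums S_m(y) = Σ yⁿ/(nm)! —
  `cgf()`, `saddle_point()`, `universal_tail_log()`,
  `rate_function()`, `sm_sum()`;
* a **seeded Monte Carlo simulator** with empirical count/density/
  Mandel-Q summaries, used as an independent stochastic oracle —
  `simulate_ctrw()`, `empirical_qtn()`, `empirical_mandel_q()`;
* a thin **command-line interface** (`inst/scripts/ctrw.R`) and CSV
  table regeneration for the standard comparisons — `run_ctrw_cli()`,
  `figure_data()`.

## Worked example

Erlang-2 waiting (anti-bunched) with unit-variance Gaussian jumps at
t = 2:

```r
library(ctrwtails)
w <- make_waiting_time("erlang", m = 2)
j <- make_jump("gaussian")

p <- propagator_series(w, j, t = 2, x = seq(-30, 30, 0.1))
print(p)
#> Propagator: erlang waiting + gaussian jumps, t = 2
#>   grid n = 601, atom at origin = 0.406006, series truncated at n = 59
#>   grid mass + atom = 1.00000000

x <- c(10, 20, 30)
data.frame(x = x,
           exact_logP  = propagator_series(w, j, 2, x)$log_density,
           saddle_logP = saddle_log_density(w, j, x, 2),
           gauss_logP  = dnorm(x, 0, sqrt(2), log = TRUE))
#>    x exact_logP saddle_logP gauss_logP
#> 1 10     -20.38      -19.87     -26.27
#> 2 20     -47.08      -46.50    -101.27
#> 3 30     -76.58      -75.97    -226.27
```

Reading the output: 40.6% of walkers have not jumped by t = 2 (the
atom, reported separately from the density grid, equals the waiting
model's survival probability Γ(2,2)/Γ(2)). In the tail the Lambert-W
saddle approximation tracks the exact log-density to about 1–3%
(−46.5 vs −47.1 at x = 20), while the diffusive Gaussian is off by
more than a factor of two in log-density (−101 vs −47): the tail is
exponential, not Gaussian. The counting side of the same physics:

```r
mandel_q_longtime(w)
#> [1] -0.5
q <- empirical_mandel_q(simulate_ctrw(w, j, t = 800, n_walkers = 1e5, seed = 42))
sprintf("empirical Q at t = 800: %.4f +/- %.4f", q$Q, q$se)
#> [1] "empirical Q at t = 800: -0.4981 +/- 0.0022"
```

The m = 2 renewal process is sub-Poissonian (Q = 1/m − 1 = −0.5), and
the simulator recovers the limit within one standard error.

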