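## shared model fixtures (built in code, no stored data)
wt_exp <- function(mean = 1) make_waiting_time("exponential", mean = mean)
wt_erl <- function(m, scale = 1) make_waiting_time("erlang", m = m, scale = scale)
wt_two <- function(a, b = 2 - a) make_waiting_time("two_exponential", a = a, b = b)
jp_gauss <- function(variance = 1) make_jump("gaussian", variance = variance)
jp_latt <- function() make_jump("lattice")

## two-sample chi-squared statistic on pooled count histograms
two_sample_chisq <- function(n1, n2, min_expected = 10) {
  nmax <- max(n1, n2)
  h1 <- tabulate(n1 + 1L, nbins = nmax + 1L)
  h2 <- tabulate(n2 + 1L, nbins = nmax + 1L)
  keep <- (h1 + h2) >= 2 * min_expected
  ## pool sparse bins into the kept set's tails by truncation
  h1 <- h1[keep]; h2 <- h2[keep]
  N1 <- sum(h1); N2 <- sum(h2)
  p <- (h1 + h2) / (N1 + N2)
  stat <- sum((h1 - N1 * p)^2 / (N1 * p)) + sum((h2 - N2 * p)^2 / (N2 * p))
  list(stat = stat, df = sum(keep) - 1)
}
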