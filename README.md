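# wcusum — weighted CUSUM change-point tests

`wcusum` tests a series (or an n × q data matrix with rows as time points)
for a single change in mean, using cumulative-sum statistics with quadratic
weights that encode a prior guess of where the change sits.  It is aimed at
anyone screening sequential measurements for a distributional break —
frame-by-frame image summaries, per-interval counts, panel averages — when
there is side information that the break, if present, is early, central, or
late in the sequence.

## The statistic

For observations `Y_1, …, Y_n` the weighted CUSUM (WC) statistic is

    S_n(Y; τ, γ) = Σ_{k=1}^{n-1} w_k(τ)^{-1} | Σ_{i≤k} (Y_i − Ȳ) |^γ ,

with quadratic weights

    w_k(τ) = −(k − τ)² + max{τ², (n − τ)²}
           = (n+k)(n−k)   τ = 0      ("left")
             k(n−k)       τ = n/2    ("center", the likelihood-ratio weight)
             k(2n−k)      τ = n      ("right").

Because the statistic divides by the weights, the `left` scheme (small
weights at large k) is most powerful for changes near the **end** of the
series, `right` for changes near the **beginning**, and `center` for
central changes.  For γ = 2 and normal data, `S_n/σ²` is exactly a weighted
sum of independent χ²(1) variables with closed-form eigenvalues

    λ_k(n/2) = 1/(k(k+1)),    λ_k(0) = λ_k(n) = 1/(2k(2k+1)),

so p-values and critical values are computed by numerically inverting the
characteristic function (Imhof's method) — no simulation needed.  With
unknown variance the statistic is studentized by the plug-in variance of
the row means.  The change-point location is estimated by
`argmax_k w_k^{-1/2} |Σ_{i≤k}(Y_i − Ȳ)|`.

Variants: a graph-based test on shortest-Hamiltonian-path edge counts for
multivariate rows (`graph_wc_test`, permutation-calibrated), a Poisson
latent-effect version operating on log row means (`poisson_wc_test`), and a
self-normalized version that is pivotal under weak temporal dependence
(`selfnorm_wc`).

## Worked example

Forty time points, fifty replicates each, mean shift 0.4 after time 28 — a
late change, so the `left` weight is the natural choice:

```r
library(wcusum)
set.seed(42)
y <- gen_normal_shift(n = 40, q = 50, k_star = 28, delta = 0.4)
wc_test(y, tau = "left")
#> Weighted CUSUM change-point test (wc, tau = left)
#>   n = 40, q = 50; statistic = 2.706, sigma2 = 0.04673
#>   p-value = 8.937e-05; critical value (level 0.05) = 0.7921 -> reject
#>   estimated change point: k = 28
```

The studentized statistic 2.706 far exceeds the exact n = 40 critical value
0.792 (the 0.95 quantile of `Σ λ_k(0) Z_k²`), the p-value is ~9e-5, and the
estimated change point recovers the true k* = 28 exactly.

A small power study (rejection percentages over 200 simulated datasets,
shared across methods):

```r
power_study(40, 50, 20, 0.2, methods = c("wc_left", "wc_center", "wc_right"),
            reps = 200, seed = 1)
#>      method        model  n  q k_star delta reps level power_pct   se_pct
#> 1   wc_left normal_shift 40 50     20   0.2  200  0.05      95.0 1.541104
#> 2 wc_center normal_shift 40 50     20   0.2  200  0.05      95.5 1.465862
#> 3  wc_right normal_shift 40 50     20   0.2  200  0.05      95.0 1.541104
```

## Command line

A thin CLI wraps the same functions (installed under the package's `exec`
directory):

```sh
wcusum critval --tau center --n 20 --p 0.95        # -> 2.442
wcusum test --input data.csv --tau left --out result.json
wcusum graph-test --input data.csv --metric pseudo --calibration permutation
wcusum power-sim --config sim.yaml --out report.csv
wcusum make-data --model normal_shift --n 40 --q 50 --delta 0.2 --out data.csv
```

Exit codes: 0 success, 2 usage error, 3 data error, 4 numerical failure.

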