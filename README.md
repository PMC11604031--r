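# kldomain

Domain selection for Gaussian process data via the local Kullback–Leibler
divergence.

## What problem this solves, and for whom

Given two groups of curves recorded on a common grid of `p` time points —
e.g. ECG heartbeats of healthy subjects versus myocardial-infarction
patients — **where on the time axis do the two groups differ the most in
distribution?** Not which isolated time points (variable selection), and
not whether they differ at all (testing), but the *contiguous sub-interval
of a prescribed length* carrying the largest distributional difference.
The package is aimed at biostatisticians and functional-data analysts who
want an interpretable interval, an uncertainty statement for it, and a
classifier restricted to it.

Each group is modelled as a Gaussian process, so its restriction to the
grid is a `p`-variate normal `N(μ_ℓ, Σ_ℓ)`. For an index window `A` the
**local KL divergence** has the closed form

    KL_A(X‖Y) = ½ [ tr(Σ_{A,Y}⁻¹ Σ_{A,X}) − |A|
                    + Δ_Aᵀ Σ_{A,Y}⁻¹ Δ_A
                    + ln det Σ_{A,Y} − ln det Σ_{A,X} ],     Δ_A = μ_{A,Y} − μ_{A,X},

which responds simultaneously to mean differences (Mahalanobis term) and
covariance differences (trace and log-determinant terms). The **interval of
local maximum divergence** at length fraction `c` is the contiguous window
of `w = round(c·p)` points maximizing `KL_A` — found by an exhaustive
sliding-window scan over all `p − w + 1` candidates, on plug-in estimates
whose covariances are shrunk toward their diagonals
(`Σ̂_η = η Σ̂ + (1−η) diag Σ̂`, `η` chosen by cross-validation). Uncertainty
is quantified with a nonparametric bootstrap of the window center, and a
quadratic discriminant restricted to the selected window turns the interval
into a classifier.

## Worked example

Simulate the bundled variance-bump scenario (group X's covariance is
inflated around `t = 3π/4`), select the most divergent 10%-length interval,
and bootstrap its center:

```r
library(kldomain)

spec <- scenario_spec("B")                      # variance difference near 3π/4
data <- simulate_scenario(spec, n = 200, m = 200, grid = 100, seed = 42)

sel <- select_interval(data$x, data$y, c = 0.1,
                       shrinkage = shrinkage_config(seed = 42))
print(sel)
#> <kld_selection> c = 0.1 (w = 10 of 100 points)
#>   window [72, 81], center index 76.5 (t = 2.372), KL = 11.6154
```

The selector scanned all 91 windows of 10 grid points and picked
`[72, 81]` — its center `t = 2.372` sits next to the planted bump at
`3π/4 ≈ 2.356` (grid index 76). `KL = 11.6` is the local divergence of the
shrunken plug-in estimates on that window.

```r
boot <- kld_bootstrap(data$x, data$y, c = 0.1, B = 200, seed = 42,
                      shrinkage = shrinkage_config(eta = unname(sel$eta["x"])))
print(boot)
#> <kld_bootstrap> B = 200, alpha = 0.05, c = 0.1
#>   center median 2.372, CI [2.183, 2.813], confidence set [2.041, 2.955]
```

200 resampling rounds reselect the interval; the 95% percentile CI for its
center is `[2.183, 2.813]`, and dilating by the window half-width gives the
confidence set `[2.041, 2.955]` for the interval itself — the bump is
pinned down to about a sixth of the domain. A scree-style summary guides
the choice of `c` (`divergence_vs_length()`), and
`estimate_error()` / `error_vs_length()` report how a quadratic
discriminant restricted to the selected window classifies held-out curves.

Command-line wrappers for all stages (select / profile / bootstrap /
classify / simulate / montecarlo) live behind one entry point:

```sh
Rscript inst/cli/kldomain simulate --scenario B --n 200 --m 200 --p 100 --seed 42 --out out/
Rscript inst/cli/kldomain select --x out/curves.csv --c 0.1 --seed 42 --out out/
```

Readers accept wide CSV (curves in rows), long CSV (irregular designs,
smoothed onto a common grid), and UCR-style labeled time-series text such
as the ECG200 benchmark.

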