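# t2relax

Multi-component T2 relaxometry for multi-echo spin-echo MRI, with a
reproducibility toolbox: **t2relax** estimates the non-negative T2
spectrum of each voxel from its 32-echo decay, derives the
intra/extra-cellular T2 (**T2IE**) and the myelin water fraction
(**MWF**), and quantifies how reproducible those maps are across runs,
sessions, scanners and subjects.

It is written for quantitative-MRI researchers who want a complete,
testable estimation chain in R:

* **EPG forward model** — echo amplitudes of a CPMG train under
  imperfect refocusing via the extended phase graph recursion
  (stimulated-echo pathways included), vectorized over T2.
* **Dictionaries** — 60-point log-spaced T2 grid (10–2000 ms), flip-angle
  dictionary bank on a 0.33° grid, lazily cached.
* **Flip-angle mapping** — per-voxel effective refocusing angle from a
  Gaussian-smoothed copy of the data (NNLS residuals on a 15-angle
  coarse grid, cubic-spline interpolation, global minimum).
* **Spectral estimation** — three estimators behind one front door,
  `t2fit()`:
  * `chi2`: Tikhonov-regularized NNLS, lambda chosen so the data
    residual is a fixed factor (default 1.02) above the unregularized
    minimum;
  * `lcurve`: regularized NNLS at the maximum-curvature corner of the
    L-curve (Menger curvature, golden-section refinement);
  * `miml`: a 6×256 ReLU + softmax multilayer perceptron trained on
    synthetic signal/spectrum pairs with an L2 + Wasserstein loss.
* **Scalar maps** — T2IE as the amplitude-weighted geometric mean of the
  spectrum on the 40–200 ms window (scale-invariant and immune to
  out-of-window mass), and MWF.
* **Denoising arm** — wavelet-based noise estimation (Haar HHH MAD /
  0.6745) and 3D total-variation smoothing at weight 2·sigma
  (Chambolle's projection algorithm).
* **Synthetic study generator** — a 20-subject × 2-scanner × 2-session ×
  2-run study (160 scans) on a block phantom with known regional T2IE
  and a subject/site/session/run random-effects hierarchy, written as
  NIfTI + CSV.
* **Reproducibility statistics** — coefficient of variation by effect
  grouping, two-way random-effects single-measurement consistency ICC
  with F-based confidence intervals, and pairwise Wilcoxon rank-sum
  tests with Bonferroni correction.

The T2 spectrum model: the noiseless signal is `y = A(alpha) x` with
`A(alpha)[n, j] = EPG(TE_n; T2_j, alpha)` and `x >= 0`; the regularized
estimators solve

    min_x ||A x - y||^2 + lambda^2 ||x||^2   s.t.  x >= 0,

and T2IE is `exp( sum_{40<=T2_i<=200} x_i log T2_i / sum x_i )`.

## Worked example

Fit one synthetic voxel with the chi-square criterion and summarize it:

```r
library(t2relax)
p    <- t2_protocol()                 # 32 echoes, TE1 = dTE = 10.68 ms
g    <- t2_grid()                     # 60 log-spaced T2s, 10-2000 ms
A    <- build_dictionary(p, g, 160)   # EPG dictionary at FA = 160 deg
wtru <- dnorm(log(g), log(80), 0.1); wtru <- wtru / sum(wtru)
set.seed(1)
y    <- add_rician_noise(drop(A %*% wtru), 1 / 100)  # first-echo SNR 100

fit <- t2fit(y, fa = 160, protocol = p, method = "chi2")
summary(fit)
#> Multi-component T2 fit (chi2), FA key 159.96 deg
#>   grid: 60 points, 10-2e+03 ms
#>   lambda = 0.03593, data residual = 0.002404
#>   T2IE = 80.52 ms, MWF = 0.000, total weight = 0.9987
```

The true windowed geometric mean is 80 ms; the estimate lands within
0.7%. `plot(fit)` draws the spectrum with the 40/200 ms window marked,
and `simulate(fit, nsim, snr = …)` draws new Rician-noise echo trains
from the fitted spectrum.

A miniature end-to-end study — generate, analyze, report:

```r
bank <- fa_bank(p)
st   <- generate_study(make_design(4, 2, 2, 2), variance_components(),
                       phantom_spec(region_dim = 4), bank, seed = 7)
tab  <- analyze_study(st, bank, method = "chi2")   # scan x ROI T2IE table
repro_report(tab)
#> Reproducibility report
#>   median CoV (%) by effect:
#>     inter_run      0.207
#>     inter_session  0.433
#>     inter_scanner  0.242
#>     inter_subject  1.936
#>   ICC(C,1) by ROI:
#>     ROI 1: 0.906 [0.710, 0.993]
#>     ROI 2: 0.933 [0.780, 0.995]
#>     ROI 3: 0.946 [0.818, 0.996]
#>   pairwise rank-sum (Bonferroni):
#>     inter_run vs inter_scanner: p_adj = 1
#>     inter_run vs inter_session: p_adj = 0.146
#>     inter_run vs inter_subject: p_adj = 0.0004695 *
#>     inter_scanner vs inter_session: p_adj = 1
#>     inter_scanner vs inter_subject: p_adj = 0.005307 *
#>     inter_session vs inter_subject: p_adj = 0.001258 *
```

The report reads like the design that generated it: run-to-run
variability is smallest, session and scanner effects (equal in truth)
are statistically indistinguishable, and between-subject variability
dominates; at 4 subjects the run/session/scanner medians still bounce
around their common ordering, which is why the automated checks use 8
subjects and 20 replicates. `write_report()` persists the CSV tables, and
`run_pipeline(pipeline_config(...))` (or a YAML file via
`read_pipeline_config()`) drives the whole chain — generation, optional
TV denoising, flip-angle mapping, fitting, ROI tables, report — from one
seeded configuration.

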