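# dimorph

Statistical detection of size dimorphism in fragmentary morphometric
samples, built around the maxillary caniniform process of the Late
Triassic dicynodont *Placerias hesternus*.

A single quarry assemblage preserves dozens of isolated, often broken
maxillae, premaxillae, quadrates and fibulae. Whether the tusk-like
caniniform process comes in two discrete sizes — the classic signature of
a secondary sexual trait — is a statistical question about univariate
measurement distributions: is a set of log10 lengths better described by
one normal or by a two-component normal mixture, once the cost of three
extra parameters is paid at fossil sample sizes? `dimorph` is for
paleontologists and morphometricians who need that comparison, and its
surrounding workflow, as tested, reproducible code.

## What it computes

For each measurement \(x = \log_{10}(\text{mm})\), complete cases only:

- **Unimodal fit**: \(N(\mu, \sigma^2)\), \(k = 2\), closed-form ML.
- **Bimodal fit**: \(a\,N(\mu_1,\sigma_1^2) + (1-a)\,N(\mu_2,\sigma_2^2)\),
  \(k = 5\), multistart EM with a measurement-error-derived variance
  floor, label convention \(\mu_1 \le \mu_2\).
- **Model selection**: \(\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)\)
  (\(+\infty\) when \(n \le k+1\)), \(\Delta\mathrm{AICc}\), and Akaike
  weights \(w_i \propto e^{-\Delta_i/2}\).
- **Morph assignment**: posterior responsibility
  \(\gamma(x)\) of the large component; `large` / `small` only beyond a
  threshold \(\tau = 0.9\), `ambiguous` inside the overlap zone.
- **Multivariate corroboration**: column-standardized PCA, k-means with
  \(k = 2\) on the scores, cluster–morph concordance, a between-cluster
  separation gap, and measurement-subset reruns.
- **Allometry**: within-morph and pooled OLS on log-log pairs (adjusted
  \(R^2\) headline, two-sided slope p), and log-scale coefficients of
  variation per mixture component.
- **Synthetic populations**: a seeded generator reproducing the study
  conditions (sample sizes, the published caniniform mixture, calibrated
  breakage), plus a detection-rate experiment.

## Worked example

```r
library(dimorph)

# a synthetic quarry population at the study conditions
tab <- generate_population(synthetic_config(seed = 1))

# fit the caniniform length (jcp DV) on its complete cases
cc  <- complete_cases(tab, "maxilla", "jcp_DV")
x   <- log10_values(cc, "maxilla", "jcp_DV")
fit <- fit_bimodal(x, seed = 1)
print(fit)
#> Two-component normal mixture fit (n = 17)
#>   a = 0.5294
#>   component 1: mu = 2.11974 (131.75 mm), sd = 0.0225
#>   component 2: mu = 2.40286 (252.85 mm), sd = 0.0335
#>   logLik = 25.4360 (54 EM iterations, best of multistart)

asg <- assign_morphs(fit, x, tau = 0.9, specimen_id = cc$specimen_id)
attr(asg, "counts")
#>     small     large ambiguous
#>         9         8         0
```

The fitted mixture weight near 0.5 says the two morphs occur in roughly
equal numbers; the component means back-transform to millimetre morph
means; and at this separation no specimen falls in the ambiguity zone.
The full 25-measurement survey, `run_survey(tab, seed = 1)`, renders a
model-selection table whose first rows read

```
| Bone | Measurement | n | dAICc (uni) | weight (uni) | logLik (uni) | dAICc (bi) | weight (bi) | logLik (bi) |
| maxilla | jcp_DV | 17 | 22.7 | <0.001 | 8.8 | 0.00 | >0.999 | 25.4 |
| maxilla | jpp_ML | 29 | 4.78 | 0.08 | 32.7 | 0.00 | 0.92 | 39.1 |
```

— strong mixture support for the caniniform length and the coupled
maxilla width, while monomorphic measurements elsewhere in the table fall
to the unimodal side. The small-sample guard is explicit in the
criterion itself:

```r
compute_aicc(16.1, k = 5, n = 6)
#> [1] Inf
```

six specimens cannot support a five-parameter mixture, so such a row
prints `Inf` and the unimodal model takes all the weight regardless of
likelihood.

The numbered scripts under `analysis/` run the whole study-shaped
workflow (simulate → survey → assign morphs → PCA/k-means → allometry →
detection power), each printing a short narrative and writing tables
under `results/`.

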