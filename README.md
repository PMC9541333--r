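# specprep

Benchmarking spectral preprocessing algorithms for hyperspectral tissue
imaging with physically simulated diffuse-reflectance spectra.

## The problem

Hyperspectral images of resected tissue are used to delineate tumor from
healthy tissue, pixel by pixel, from the 400–1600 nm reflectance spectrum.
Two nuisance effects corrupt those spectra without any change in tissue
composition: **glare** — small-scale specular reflection off the rough,
wet tissue surface, adding a nearly wavelength-independent offset bounded
by the Fresnel reflection — and **sample-height variation**, which
rescales the spectrum multiplicatively as the surface moves relative to
the calibration plane. Practitioners apply one of a handful of standard
preprocessing algorithms before classification, but which one suits which
kind of tissue contrast is rarely examined.

`specprep` answers that question in a controlled setting. It is aimed at
researchers building tissue-classification pipelines who need to choose a
preprocessing step on grounds better than habit.

## What it computes

1. **Forward model.** Diffuse reflectance of homogeneous tissue from the
   diffusion approximation,
   `R = α′ / (1 + 2k(1−α′) + (1+2k/3)·√(3(1−α′)))` with transport albedo
   `α′ = μs′/(μs′+μa)`, power-law scattering `μs′ = a(λ/500)^−b`, and
   absorption composed from bundled water, fat, oxy-/deoxyhemoglobin and
   bilirubin tables. Each simulated measurement adds glare
   (`g·Rs`, `g ~ U(0,1)`), distance factors `1/d⁴` (diffuse) and `1/(4d²)`
   (glare) with `d ~ U(1, 1.2)`, and wavelength-dependent uniform noise.
2. **Preprocessing.** SNV, MSC, min–max, mean centering, AUC (L1) and
   single-wavelength normalization, and Savitzky–Golay first/second
   derivatives (199-sample window), applied tidily to labeled spectra.
3. **Separability.** The Szymkiewicz–Simpson overlap coefficient: at each
   wavelength, a shared 25-bin histogram over both tissue sets;
   `O(λ) = Σ min(c₁,c₂) / min(n₁,n₂)`; averaged over wavelengths and over
   all unique set pairs. Lower overlap = more separable tissue types.
   Improvement is quoted relative to the unprocessed baseline of the same
   run.

Four single-contrast scenarios (blood volume fraction, absorber
composition, scatter amplitude, scatter slope; five sets × 100 spectra
each) and a mixed healthy-vs-tumor scenario (1000 spectra per class drawn
from per-class optical-property ranges, 50 bins) are built in.

## Worked example

```r
library(specprep)

cfg <- acquisition_config()   # 400-1600 nm, 1 nm, 100 spectra per set
run <- run_scenario("bvf",
                    algorithms = c("snv", "msc", "auc", "first_derivative"),
                    config = cfg, seed = 42)
run
#> <scenario_run> scenario 'bvf', seed 42, 25 bins
#> # A tibble: 5 × 4
#>   algorithm        family       mean_overlap improvement_pct
#>   <chr>            <chr>               <dbl>           <dbl>
#> 1 none             baseline            0.580            0
#> 2 snv              scale+offset        0.120           80.3
#> 3 msc              scale+offset        0.119           80.6
#> 4 auc              scale               0.152           74.3
#> 5 first_derivative derivative          0.552            4.62
```

Reading: the five blood-volume-fraction tissue sets are almost
indistinguishable before preprocessing (mean pairwise overlap 0.58).
SNV and MSC, which cancel both the glare offset and the distance scaling,
collapse that to ≈ 0.12 (an 80 % improvement), AUC — scale-only — gets
close, while the first derivative barely helps: its smoothed local slopes
still inherit the distance scaling. `autoplot(run)` draws the annotated
5×5 overlap heatmap per algorithm; `tidy(run, pairs = TRUE)` returns the
per-pair values; `glance(run)` a one-row summary. `simulate_spectra()`,
`preprocess_spectra()` and `pairwise_overlap()` expose the same pipeline
piecewise for custom scenarios, and `ingest_spectra()` accepts external
labeled spectra tables (CSV) for the same analysis on real data.

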