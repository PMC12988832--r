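# paviq — photoacoustic ureter visibility: beamforming, ROI metrics, and dosimetry

`paviq` quantifies how visible the ureter is in dye-enhanced photoacoustic
imaging. Intraoperative ureter identification matters because accidental
ureteral injury is a recognized risk of pelvic surgery; methylene blue in
the urinary tract absorbs pulsed near-infrared light and emits acoustic
waves that a linear ultrasound array can receive alongside coregistered
B-mode imaging. This package implements the full analysis chain for such
data, for imaging scientists and surgical-guidance researchers:

* **Synthetic acquisition generator** — a tube-shaped absorber (ureter
  lumen plus adventitia lining) imaged by a 256-element, 21.33 MHz linear
  array; point sources with 1/r spreading emit a Gaussian-windowed
  sinusoid matched to the 15–29 MHz band, plus Gaussian channel noise.
  Deterministic given a seed.
* **Delay-and-sum beamforming** (compiled core) with one-way delays
  τₑ = √(z² + (x − xₑ)²)/c, linear interpolation, uniform apodization;
  axial analytic-signal envelope detection; normalization to the
  brightest pixel; 20·log₁₀ log compression at a configurable dynamic
  range.
* **Frame selection** — retain frames whose photoacoustic signal mask
  overlaps the segmented ureter mask; exclude stationary duplicates
  (mask IoU > 0.95 and envelope correlation > 0.99 against the previous
  kept frame).
* **ROI placement** — a 3 mm × 0.6 mm target ROI centered on the
  brightest in-mask pixel, walked one pixel at a time through eight
  directional offsets until fully contained in the ureter mask; a
  same-depth background ROI 0.54 mm from the right image edge.
* **Image-quality metrics** — contrast = 20·log₁₀(μₜ/μᵦ), SNR = μₜ/σᵦ,
  and gCNR = 1 − Σₖ min{hₜ(xₖ), hᵦ(xₖ)} over 256 shared bins on [0, 1].
* **Group statistics** — Shapiro–Wilk per time point, tie-corrected
  Kruskal–Wallis omnibus, Dunn's post hoc z tests with significance
  stars, and 1.5·IQR boxplot summaries.
* **Dosimetry** — per-pulse fluence over a fiber face, ratio to the
  25.2 mJ/cm² ANSI skin MPE at 750 nm, intraluminal dye concentration,
  and renal biomarker (BUN/SC) range checks.

Tabular results are tibbles throughout; fitted comparisons support
`tidy()`, `glance()`, and `autoplot()`.

## Worked example

Dosimetry is closed-form arithmetic:

```r
library(paviq)
fluence(laser_exposure(6.78, fiber_diameter = 5))
#> [1] 34.53026        # mJ/cm^2 per pulse
mpe_ratio(laser_exposure(15.89))
#> [1] 3.211393        # 3.2x the ANSI skin limit
intraluminal_concentration(dye_dose(0.5))
#> [1] 352.0795        # uM after dilution into a 22.2 mL lumen
```

Compare image-quality metrics across post-injection time points (here
from the grouped-sample generator; `run_pipeline()` produces the same
table from simulated channel data end to end):

```r
samples <- sample_metric_groups(default_group_spec("contrast_db"), seed = 1)
cmp <- compare_groups(samples, value = "value")
cmp
#> <pa_comparison> metric 'value', 6 groups, N = 287
#>   Kruskal-Wallis H = 181.01, df = 5, p = < 2.22e-16
#>   12 of 15 pairwise comparisons significant at alpha = 0.05
head(tidy(cmp), 3)
#> # A tibble: 3 x 5
#>   group1 group2     z  p_value significance
#>   <chr>  <chr>  <dbl>    <dbl> <chr>
#> 1 10     20     -9.08 1.09e-19 ****
#> 2 10     30     -7.00 2.61e-12 ****
#> 3 10     60     -1.44 1.50e- 1 ns
```

The H statistic says contrast distributions differ strongly across time
points; the pairwise rows show the 10-min baseline differs from the
20- and 30-min peak (stars) but not from 60 min (`ns`). `autoplot(cmp)`
draws the corresponding box-and-whisker figure.

The full chain on synthetic channel data:

```r
cfg <- pipeline_config(seed = 1, out_dir = "run1")
run <- run_pipeline(cfg)   # simulate -> beamform -> select -> ROI -> metrics -> stats
run$metrics                # per-frame contrast/SNR/gCNR tibble
run$counts                 # retained / duplicate / ROI-failed accounting
```

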