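# coccoxrf

Analysis of synchrotron micro-XRF elemental maps of single coccoliths —
the calcite platelets that coccolithophore algae build around their cells.
High-resolution (50 × 50 nm pixel) X-ray fluorescence maps of individual
platelets make it possible to ask, element by element, *where* a trace
element sits: substituted into the calcite lattice (like Sr, or selenite
replacing carbonate), riding the organic coating on the mineral surface
(Cl-like distributions), concentrated in a few contaminant particles, or
simply not interacting with the coccolith at all. `coccoxrf` implements
that whole chain of reasoning as a tested, reusable pipeline, together with
a ground-truthed synthetic coccolith simulator so every stage can be
exercised and validated without beamline data.

## What it computes

* **Spectrum fitting and quantification.** Per-pixel spectra are modeled as
  nonnegative combinations of Gaussian line-family templates (fixed
  energies, detector FWHM(E), within-family branching ratios) plus a
  low-order continuum, solved by Lawson–Hanson nonnegative least squares
  with Poisson (expectation-based) weighting. Elements lacking clear
  evidence in the specimen-summed spectrum (amplitude ≤ zσ) are dropped
  before the per-pixel fits, avoiding overfitting. A global flux–area
  factor *k* is calibrated against a certified standard by log-space least
  squares, after which `ppm_i = amplitude_i / (k · s_i · t_dwell)`.
* **Calcite masking and map statistics.** Pixels with Ca < 0.2 × 10⁵ ppm
  (membrane background, extreme rim) are excluded from all further
  calculations. Molar ratio maps are computed per pixel as
  `i/Ca = (ppm_i / A_i) / (ppm_Ca / A_Ca) × 1000` (mmol/mol), and specimen
  summaries report the mean of per-pixel ratios over the mask, the
  coccolith area, and Ca per area.
* **Transects and regions.** Polyline transects are sampled at one-pixel
  steps and banded by Ca concentration (background / 0.2–1 × 10⁵ /
  ≥ 1 × 10⁵ ppm); the mask is partitioned into tube, external rim and
  margin (distance-transform margin band plus a Ca-quantile tube), each
  region requiring at least 30 data points.
* **Partition coefficients.** `D_x = (x/Ca)_calcite / (x/Ca)_solution`,
  a dimensionless ratio of molar ratios against the culture medium.
* **Element localization verdicts.** Each detected element is classified
  as `lattice`, `surface`, `hotspot` or `absent` from quantitative map
  evidence: correlation with Ca, correlation with the Cl-like coat, the
  share of its mass in its top-1% brightest pixels, and an on/off-coccolith
  enrichment contrast. All thresholds are configuration, not constants.

The simulator builds placolith-type geometries (elliptical shields, thick
tube ring, central bar or bridge, optional outline irregularity emulating
stressed morphotypes), populates them with lattice / surface / hotspot /
absent element fields at declared i/Ca ratios (with an optional rimward
Sr/Ca gradient), and renders raw per-pixel spectra with instrument lines,
line overlaps (e.g. Pb-L on As-Kα) and Poisson counting noise at 200 ms
dwell — every quantity recorded as recoverable ground truth.

## Worked example

```r
library(coccoxrf)

tpl  <- specimen_template("control")            # 9 µm placolith with bar
spec <- simulate_specimen(tpl, seed = 1)$specimen
mask <- mask_calcite(spec)                      # Ca >= 0.2e5 ppm
stats <- specimen_stats(spec, mask = mask)
stats
#> <specimen_stats> n = 18772 px, area = 46.9 um^2, mean Ca = 1.53e+05 ppm
#>  element mean_ratio_mmol_per_mol    mean_ppm
#>       Sr              3.74802081  1226.78616
#>       Se              0.04703007    14.18310
#>       Cl            109.81764014 11306.39788
#>       ...

partition_table(stats)[1:2, c("element", "mean_ratio_mmol_per_mol", "D")]
#>   element mean_ratio_mmol_per_mol          D
#> 1      Sr              3.74802081 0.42542801
#> 2      Se              0.04703007 0.04798987

region_means(spec, segment_regions(spec, mask))
#>         region     n mean_ratio_mmol_per_mol mean_ca_ppm
#> 1         tube  3755                3.501947   273692.59
#> 2 external_rim 13166                3.783447   127568.10
#> 3       margin  1851                3.995232    90062.42

classify_specimen(spec, mask)[, c("element", "verdict", "r_with_ca")]
#>   element verdict   r_with_ca
#> 1      Sr lattice  0.99252545
#> 2      Se lattice  0.99390481
#> 3      Cl surface -0.04646682
#> 4      Fe surface -0.09305633
#> 5      Ni surface -0.13007648
#> 6       V  absent          NA
#> 7       W hotspot -0.06202484
```

Reading the numbers: the control specimen carries ~1.5 × 10⁵ ppm Ca over a
47 µm² platelet; its whole-coccolith Sr/Ca of 3.75 mmol/mol against the
default solution (Sr/Ca 8.81 mmol/mol) gives D_Sr ≈ 0.43, and Se/Ca
0.047 mmol/mol gives D_Se ≈ 0.048. Sr/Ca rises monotonically from tube
(3.50) to margin (4.00). Sr and Se co-distribute with Ca (r ≈ 0.99 →
lattice), Fe and Ni follow the Cl coat (surface), W sits in three bright
spots holding ~39% of its mass (hotspot), and V shows nothing (absent).

A pipeline run over a JSON config (simulate or read maps → optional
spectrum fit → analysis → partition → classification, with hash-stamped CSV
outputs) is one call:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "coccoxrf"),
             out_dir = "demo_out")
```

or, from a shell, via the thin CLI:

```sh
Rscript inst/cli/coccoxrf.R run --config inst/extdata/demo_config.json --out demo_out
```

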