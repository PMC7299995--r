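---
title: "Methods: single-coccolith micro-XRF map analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-coccolith micro-XRF map analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccoxrf)
```

`coccoxrf` analyzes per-pixel X-ray fluorescence maps of single coccoliths:
it quantifies spectra into ppm maps, restricts statistics to the calcite,
computes molar i/Ca ratios, transects, morphological region averages and
calcite–solution partition coefficients, and classifies each element's
localization. This vignette documents the models behind each stage, the
parameters that matter, the synthetic data the package validates itself
against, and the design choices made where the underlying methodology is
genuinely open.

## The quantification chain

A pixel's spectrum is modeled as

$$y(E) \;=\; b(E) \;+\; \sum_i a_i \sum_{\ell \in i} w_{i\ell}\,
\mathcal{N}\!\left(E;\, E_{i\ell},\, \sigma(E_{i\ell})\right),$$

where $a_i$ is the total counts in element $i$'s line family, $w_{i\ell}$
are fixed within-family branching ratios (Kα 0.88 / Kβ 0.12; Lα 0.75 /
Lβ 0.25), line energies come from the packaged library (K lines from Mg at
1.253 keV to Sr at 14.098 keV, plus W and Pb L lines), and the detector
response is

$$\mathrm{FWHM}(E) = \sqrt{\texttt{electronic\_noise\_eV}^2 +
\texttt{fano\_like\_slope}\cdot E}\,,$$

a two-parameter silicon-drift-detector model whose defaults (120 eV,
2.46 eV) give ≈170 eV at Mn Kα, leaving Ni Kα on the Cu Kα shoulder — the
worst realistic overlap the fitter must resolve. Only lines below the
incident (pink-beam) energy, 17.1 keV by default, are excitable.

**Fitting.** The continuum $b(E)$ is a degree-2 polynomial parameterized on
the Bernstein basis, whose nonnegative coefficients keep the continuum
nonnegative — physical for photon counts — and let the whole problem be a
single Lawson–Hanson nonnegative least squares (via `pracma::lsqnonneg`).
Poisson weighting uses the *fitted expectation* rather than the observed
counts: an unweighted pass is followed by one reweighted pass with
$w = 1/\max(\hat\mu, 1)$. Weighting by observed counts systematically
upweights downward fluctuations and biased low-count amplitudes by tens of
percent in our simulations; the expectation-weighted two-pass scheme brought
the simulate→fit→quantify loop to within ~1% of truth under Poisson noise
(the residual being nonnegativity truncation, which only matters for
amplitudes within a few σ of zero). Amplitude uncertainties come from the
weighted normal-equations covariance. Near-duplicate templates (column
correlation > 0.9999) abort the fit naming the offending pair.

**Evidence rule.** Elements are kept only when the specimen-summed spectrum
shows $a_i > z\,\sigma_{a_i}$ (default $z = 3$); the per-pixel fit is then
re-run with the retained set. Deciding on the summed spectrum and applying
the decision uniformly keeps pixels comparable across the map — per-pixel
inclusion would make maps of weak elements uninterpretable. The detector
channels Ar, Kr (hutch atmosphere), Si (detector) and Cu (TEM support grid)
are always fitted and never quantified. As and Pb-L are deliberately merged
into one "As" channel: with only low-intensity Pb L lines excitable and
Pb Lα sitting on As Kα, the two are not separable, so the channel is
reported as As and flagged with the possible Pb contribution wherever it is
classified.

**Calibration.** A certified standard measured under the same settings
fixes the one global flux–area scalar $k$ by minimizing
$\sum_i \left(\log\frac{a_i/(k\,s_i\,t)}{c_i}\right)^2$; the closed-form
solution is the log-space mean. Log space weights elements spanning orders
of magnitude evenly, which is the natural choice when the certificate mixes
matrix elements (Ca) with traces. Per-element residuals are reported so a
discrepant certificate line is visible. Quantified concentrations
$\mathrm{ppm}_i = a_i/(k\,s_i\,t)$ are invariant to the overall scale of
the sensitivity table as long as calibration and quantification share it.

## Map analysis

All statistics are restricted to the calcite mask, Ca ≥ 0.2 × 10⁵ ppm —
below that the membrane background and the extreme rim make ratios
unreliable. Molar ratios are per-pixel,
$(\mathrm{ppm}_i/A_i)/(\mathrm{ppm}_{Ca}/A_{Ca}) \times 1000$ mmol/mol,
and specimen averages are **means of per-pixel ratios**, not ratios of mean
ppm. The two differ whenever ratio and Ca covary (e.g. a rimward Sr/Ca
gradient): the packaged per-specimen summary table is internally consistent
only under the mean-of-ratios convention, which is therefore the one
implemented (`ratio_map`'s documentation carries a worked number showing
the distinction).

Transects sample nearest pixels at one-pixel steps with no interpolation,
preserving the per-pixel data model; samples are banded background /
low (0.2–1 × 10⁵ ppm) / high (≥ 10⁵ ppm) by their Ca value, and background
samples never enter derived statistics. Coordinates are 0-based, row-major,
pixel centers at integers.

The tube / external-rim / margin partition formalizes zones that are
otherwise defined only by eye on figures: the margin is the outer band of
the mask within `d_margin` pixels (default 4) of the outline by Euclidean
distance transform (central opening filled first, so only the true outer
outline counts); the tube is the masked pixels at or above the `q_tube`
Ca quantile (default 0.80, ties included in the tube); the external rim is
the remainder. Any region with fewer than 30 data points rejects the whole
partition — region means on fewer points are not reported at all, and
specimens flagged as tilted on the support are excluded from region
analysis outright rather than "corrected".

## Partition coefficients

$D_x = (x/\mathrm{Ca})_\text{calcite} / (x/\mathrm{Ca})_\text{solution}$,
a ratio of molar ratios. The alternative literal reading — a ratio of
absolute molar concentrations — would require the calcite density and is
inconsistent with the published pairing of calcite Sr/Ca 3.7 mmol/mol with
D_Sr 0.42; the ratio-of-ratios convention of the partitioning literature is
the only reading that reproduces it. The default solution table therefore
ships **reconstructed** values — Sr/Ca 8.81 mmol/mol (= 3.7/0.42) and Se/Ca
0.98 mmol/mol (= 0.047/0.048) — clearly marked as such in the file header
and meant to be overridden by a measured medium composition
(`solution_composition()` accepts ratio or molarity tables).

## Classification

The localization verdict formalizes expert map reading into an ordered
rule: undetected → `absent`; top-1%-mass fraction ≥ θ_spot → `hotspot`;
r(element, Ca) ≥ θ_lattice → `lattice`; r(element, Ca) < θ_surface with a
Cl-like distribution (r(element, Cl) ≥ θ_coat) → `surface`; a flat element
with on/off-coccolith mean contrast ≤ 1.5 → `absent` (no interaction);
anything else is decided by the larger correlation and flagged
low-confidence. Defaults: θ_lattice = 0.6, θ_surface = 0.3, θ_coat = 0.3,
θ_spot = 0.25. The published evidence itself is qualitative — Sr–Ca r of
0.98 and a Se–Ca r of ~0.7 both read as lattice, Fe/Ni/Zn "no correlation"
as surface — so any numeric boundary is a package choice; θ_lattice = 0.6
keeps a Se-like 0.7 on the lattice side while sitting far above every coat
correlation seen in simulation. All thresholds live in configuration, with
θ_surface < θ_lattice enforced at validation. Verdicts are invariant to
positive rescaling of an element map, since every ingredient is a
correlation, a mass fraction, or a mean ratio.

## The synthetic specimen generator

The generator is the package's test bed: it produces specimens whose
ground truth is known exactly, at the scale and statistical structure the
analysis assumes.

* **Geometry.** A placolith as an elliptical annulus: shields at
  `shield_thickness`, a tube ring at `tube_thickness`, a central opening
  crossed by a bar (along the major axis) or a bridge (two crossed
  diagonal struts; both shapes preserve the two-axis mirror symmetry of
  the ideal form). The control template is 9 × 7 µm at 50 nm pixels
  (≈19k calcite pixels, matching the 16k–35k points of real maps); the
  outline can be deformed by a seeded harmonic perturbation
  (`outline_irregularity`) to emulate malformed stressed morphotypes, and
  the bar is dropped in the high-stress template. The central structure is
  rendered at tube thickness, matching its thick appearance in maps and
  making a major-axis transect read background→low→high→low→background.
* **Concentrations.** Ca = `k_ca` × thickness (default 9 × 10⁴ ppm per
  thickness unit, putting the control mean at ≈1.5 × 10⁵ ppm, the scale of
  published control specimens, with shields in the low Ca band and the
  tube in the high band). Lattice elements follow Ca through a radial
  ratio profile interpolated from the tube (ρ = 1) to the margin (ρ = 0)
  on a normalized distance-transform coordinate; `radial_gradient` > 1
  reproduces the observed rimward Sr/Ca increase. Surface elements are
  smooth nonnegative random coats **sharing one specimen-wide latent coat
  field** (mixing weight 0.85): without a shared coat, "Fe follows Cl"
  would be untestable on synthetic data. Hotspot elements add a few
  Gaussian spots (default 3 spots, σ = 2 px, 2000 ppm peak on a 5 ppm
  baseline, putting ≈40% of the element's mass in its top-1% pixels).
  Multiplicative Gaussian noise (default CV 5% on trace elements, 2% on
  Ca) is applied last.
* **Coat correlation length.** The default is 4 px (200 nm). This was
  fixed by the prescribed simulation calibration: at 6 px a specimen
  carries too few independent coat patches and the 30-seed maximum
  |r(coat, thickness)| reached 0.40; at 4 px it is 0.28, comfortably
  below both the 0.3 decorrelation bound and θ_surface.
* **Spectra.** Expected counts are the template model above with
  amplitudes $k^\ast s_i\,\mathrm{ppm}_i\,t$ (defaults $k^\ast = 7.5$,
  $t = 0.2$ s, sensitivities increasing monotonically with Z from Mg to
  Sr — the true fundamental-parameter constants of a beamline are not
  public, so the table is configuration), instrument lines added uniformly
  over all pixels including background, a flat continuum (0.02
  counts/bin/pixel), and Poisson draws around the expectation; the
  noiseless expectation is stored alongside for testing. At these defaults
  a 10 ppm constant concentration is still recovered from a 2000-pixel
  summed spectrum, consistent with single-digit-ppm detection limits at
  realistic map sizes.
* **Determinism.** One top-level seed; geometry, fields, spectra and
  standard stages derive child streams by fixed offsets, and identical
  config + seed gives bit-identical output at every stage.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: secondary fluorescence and matrix absorption,
escape/sum peaks and pile-up, detector drift, the true multi-crystal
placolith microstructure (thickness is piecewise constant, not
crystallographic), chemical speciation, and any biology linking stress to
composition. Recovery results validate the *machinery* (masking, fitting,
calibration, statistics, classification), not the geochemical conclusions
one would draw from real specimens.

## Numerical choices and problem sizes

Energy axis 0.8–17.1 keV in 10 eV bins by default (tests use 20 eV, ~6
bins per FWHM, which loses nothing at SDD resolution); spectral simulation
and round-trip fitting run on reduced geometries (2.4 × 1.8 µm at 100 nm
pixels, ≈830 pixels) while map-level analyses run on full-size 50 nm
templates — the per-pixel NNLS is the only stage whose cost grows with
bins × pixels, and the reduced geometry exercises it end to end. The
shipped benchmark is 5 seeds × 3 condition templates (105 element
verdicts). Quantile type is R's default (type 7); tube ties are included
by using ≥ at the quantile value; undefined correlations (zero variance)
are NA sentinels, never 0 — a zero would silently read as "no
correlation", which is a different claim.

## Known limitations

* The tube/rim/margin construction is one admissible formalization of
  figure-defined zones; its two parameters are exposed in configuration.
* The merged As channel cannot separate As from Pb; it is flagged, never
  silently resolved.
* Whether published specimen averages include sub-threshold pixels is not
  documented; this package excludes them, consistent with the stated
  masking rule for "further calculations".
* The stress templates vary only thickness and shape regularity; whether
  real stressed coccoliths are thinner, more porous, or both is an open
  question the simulator does not resolve — it exposes a thickness knob
  only.
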