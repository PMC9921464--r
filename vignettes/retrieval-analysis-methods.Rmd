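---
title: "Methods: standardized analysis of explanted UHMWPE liners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized analysis of explanted UHMWPE liners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(explantr)
```

## Scope and model

Ultrahigh molecular weight polyethylene (UHMWPE) liners retrieved at
revision surgery degrade primarily by oxidation. Oxidative chain scission
triggers additional ("cold") crystallization, which in turn stiffens and
embrittles the material, so oxidation, crystallinity and microhardness are
mechanistically coupled. `explantr` implements the standardized measurement
and data-mining chain used in multi-center retrieval programs: infrared
(IR) line-scan indexing, microindentation, a validated per-liner database
and the statistics computed on it.

### IR indexes

Each spectrum of a line scan (a series of absorbance spectra measured at
increasing distance from the articulating surface, typically every 100 µm)
is reduced to three band-area ratios:

* oxidation index, `OI = A1720 / A1370` — carbonyl over reference
  methylene band (ASTM F2120 practice);
* trans-vinylene index, `VI = A965 / A1370` — C=C over reference band
  (ASTM F2381 practice), a proxy for absorbed radiation dose;
* crystallinity index, `CI = CA / (CA + 1)` with `CA = A1897 / A1303` —
  the crystalline-phase band over the amorphous-phase band, a
  semi-empirical proxy for crystalline volume fraction that is bounded in
  `[0, 1)` by construction.

Band areas are computed by the composite trapezoid rule on the native
wavenumber grid after subtracting a two-point linear baseline (the chord
joining the absorbance at the two window limits). The default windows are
carbonyl 1650–1800, reference 1330–1396, vinylene 950–980, crystalline
1850–1985 and amorphous 1250–1330 cm⁻¹; the literature fixes the band
centers but not the limits, so all windows are configurable. No peak
fitting is attempted: on a 2 cm⁻¹ grid the trapezoid rule reproduces
analytic Gaussian band areas to well below 0.5 %, which is the tolerance
the package's spectral oracle tests enforce. Negative areas, which occur
in noisy spectra after baseline subtraction, are clipped to zero and
flagged rather than propagated or raised.

### Depth profiles and the 15 standardized indexes

Per-spectrum indexes are assembled into OI, VI and CI depth profiles. OI
and CI profiles of oxidized liners typically show a "camel" shape — two
subsurface maxima near the two surfaces over a lower central plateau —
while VI profiles are flat. Each liner contributes two profiles per index
(unworn region U, worn region W), reduced to 15 standardized scalars:
maximum and central-region average of OI and CI for U, W and the combined
UW data, plus the central average of VI (VI maxima are not determined
because VI profiles are flat: 2 indexes × 3 regions × 2 statistics + 1
index × 3 regions = 15).

Three conventions were genuinely open and are fixed as follows:

* **Central region.** The averaging region is the central 50 % of the
  depth span, centred at mid-depth (`central_fraction = 0.5`,
  configurable). The field's practice shades a central region without
  quantifying it; 50 % keeps the averages clear of both subsurface peaks
  for all realistic profile geometries.
* **UW averages pool values.** The combined average is the mean of the
  pooled U and W central-region values, not the mean of the two regional
  means; with equal profile lengths the two coincide, and pooling is the
  natural estimator when they do not.
* **Edge artifacts.** Maxima are taken over the full profile by default;
  an `edge_exclude` parameter can drop points at each end, because
  surface-adjacent IR measurements can carry edge artifacts.

Severity classification of a maximum OI follows the established handbook
thresholds: below 1 the mechanical impact of oxidation is hard to
demonstrate ("low"); above 3 the load-bearing ability is compromised
("critical"). The thresholds are printed as strict inequalities, so the
boundary values 1 and 3 are assigned to the intermediate class.

### Microindentation

Vickers hardness from non-instrumented indents is the classical
`H_V = 1.8544 F/d²` (kgf/mm², 136° pyramid), with a megapascal
equivalent. Instrumented curves are evaluated with the Oliver–Pharr
method: the unloading branch is fitted with `P = B (h − h_f)^m` over the
98 %→40 % load fraction (the upper cut avoids the creep "nose" at peak
load, the lower cut the ill-conditioned tail), the contact stiffness
`S = dP/dh` at maximum depth gives the contact depth
`h_c = h_max − 0.75 P_max/S`, the projected area `A_p = 24.504 h_c²`, the
indentation hardness `H_IT = P_max/A_p`, and the indentation modulus via
`E_r = √π S / (2 β √A_p)` with β = 1.012 and the diamond-indenter
compliance removed (E_i = 1141 GPa, ν_i = 0.07, specimen ν = 0.46 for
UHMWPE). Martens hardness uses the surface-area coefficient 26.43;
indentation creep `C_IT` is the relative depth increase over the 6 s hold
at peak load; the elastic work fraction `η_IT` is the ratio of trapezoidal
work integrals of the unloading and loading-plus-hold branches. All
constants are standard instrumented-indentation values and are
configurable; none of them is specific to this package's data.

Replicate indents (the protocol requires at least 10 per surface;
fewer are flagged, not rejected) are aggregated per region × location, and
the region grid (max-oxidation and central locations × U/W/pooled UW)
yields six standardized values per property, mirroring the IR notation,
e.g. `HV(max,U)` … `HV(ave,UW)`. The Tabor relation for semicrystalline
polymers, `H ≈ 3Y`, provides a yield-stress estimate `Y = H/3`.

One property deserves a caveat: the ratio `H_M/H_IT` equals
`(24.504/26.43)(h_c/h_max)²` and is therefore a function of the modulus-
to-hardness ratio, not a universal constant. It is stable (within 10 %)
along a sweep where E and H co-vary as they do in real UHMWPE (tests use
E = 12.5 H); across an arbitrary Cartesian (H, E) grid it is not, and no
test asserts that.

### Database and statistics

Per-liner records follow a versioned schema: identification, anonymized
patient data, material data with controlled vocabularies (joint THR/TKR;
crosslinking none/HXL; sterilization HCHO/gIRR/EtO/gas-plasma/unknown;
failure reason wear/mechanical/infection/other), surgical data with sanity
ranges (age 0–120 y, BMI 10–80, in vivo time 0–720 months), the 15 index
columns and the 6 Vickers columns. Validation is total at the boundary:
every violated invariant of a row is reported with its row number, and
invalid rows are excluded, never silently dropped. Merging any number of
participant tables is additive; duplicate liner identifiers across files
abort the merge with the collision list (multi-center merges must surface
collisions, not deduplicate), and output is canonically sorted by
identifier so the merge is input-order invariant. Filtering takes
predicates over schema fields — e.g. `OI(max,UW) <= 4`, the conventional
exclusion of extremely oxidized liners whose scatter obscures correlation
structure — and records the before/after counts in the provenance.

Statistics mirror the standard retrieval-study toolbox: Pearson r with the
two-sided t-transform p-value; pairwise-complete correlation matrices
(micromechanics are typically measured on a subset of liners, so listwise
deletion would discard most records) rendered as heatmaps; power-law fits
`y = k xⁿ` for the CI–OI coupling by Levenberg–Marquardt in the original
space, initialized from log–log least squares (when the initialization
already interpolates the data, i.e. noise-free input, it is returned
directly — refining a zero-residual fit only feeds the optimizer a
singular gradient); boxplot statistics with type-7 quantiles and Tukey
1.5·IQR whiskers (a raw min/max whisker mode exists because the two
conventions coexist in practice); and two-group comparisons with Welch's
t-test by default (robust to the unequal variances typical of
sterilization groups — gamma-sterilized cohorts are much more dispersed
than EtO cohorts) or the Mann–Whitney test. Raw p-values are reported;
Benjamini–Hochberg adjustment is available but off by default, matching
field practice. Degenerate cases are defined, not crashed: both groups
constant and equal gives p = 1 by convention; constant columns make
correlation cells NA-flagged rather than erroring the whole matrix.

## Synthetic-data generators

No public retrieval data exist, so every stage is exercised against
generators whose structure is analytically known.

* **Line scans.** Spectra are sums of pure Gaussian bands on a flat zero
  baseline over 4000–400 cm⁻¹ at 2 cm⁻¹, so all band areas are analytic
  and index recovery has an exact oracle. The OI depth target is a camel:
  two Gaussian peaks (default apex OI 2.0 and 1.2 at 600 µm below each
  surface, width 350 µm) over a plateau (0.5), on an 8 mm section sampled
  every 100 µm. VI is constant (0.05) and CI = k·OIⁿ pointwise
  (k = 0.55, n = 0.12, chosen so CI spans the realistic 0.4–0.7 range and
  stays below 1 for any attainable OI). The worn scan's articulating-side
  peak amplitude is halved by default: highly oxidized material at the
  worn surface is removed by articulation. That factor is not derived from
  any measurement — it is a free parameter of the generator. Default band
  widths (σ = 10/6/3.5/10/6 cm⁻¹ for the 1720/1370/965/1897/1303 bands)
  keep every band > 4σ clear of its window edges, so the two-point
  baseline does not clip tails and the oracle error stays below 0.05 %.
* **Indentation curves.** A forward model inverts the Oliver–Pharr
  chain: Kick's-law loading `P = C h²`, logarithmic hold creep
  `h(t) = h₁ (1 + c ln(1+t))` (so `C_IT = 100 c ln(1+t_hold)` exactly),
  and power-law unloading whose B and h_f are constructed so that analysis
  of the noise-free curve returns the configured hardness and modulus
  identically. Round-trip recovery on a 5 × 5 grid over H ∈ [30, 120] MPa,
  E ∈ [400, 1500] MPa is exact to floating-point precision; the tested
  tolerances (1 % on H_IT, 2 % on E_IT) therefore guard the full fitting
  pipeline, not a numerical margin.
* **Cohorts.** Records draw sterilization labels from configurable
  weights (default gIRR 0.60 / EtO 0.25 / HCHO 0.15, echoing the
  historical mix in European retrieval collections), per-group OI(max,UW)
  distributions (gamma-sterilized liners oxidize most: mean 3.0, sd 1.5;
  EtO least: mean 0.6, sd 0.4), failure-reason offsets (mechanically
  failed liners carry the highest oxidation), CI coupled to OI by the
  power law, group-specific implantation-year windows (HCHO pre-1985, EtO
  post-2005) and lognormal in vivo times. For calibration studies an
  `exact_counts` mode fixes group sizes at their expected values.

What the generators deliberately do **not** emulate: physically detailed
oxidation kinetics, wear-scar geometry, hydroperoxide/secondary oxidation
chemistry, instrument drift, atmospheric (CO₂/H₂O) interference bands and
patient-level survival processes. Passing tests therefore demonstrate that
the analysis chain is correct and calibrated on data with the assumed
structure; they do not validate the chain against vendor spectra or real
retrievals, whose baselines and band shapes are messier than the
generator's.

## Numerical choices and degenerate inputs

* Band integration limits are interpolated onto the grid when they fall
  between samples; limits outside the spectrum range are an error.
* Zero reference band areas (A1370 or A1303) make the indexes undefined
  and raise an error naming the band; this happens for garbage input, not
  noise (noise clips to zero area only in the numerator bands).
* The unloading fit bounds the exponent in (1, 2.5] and the residual
  depth below the smallest fitted depth; non-convergence, non-positive
  stiffness or contact depth raise immediately.
* Merging validates every record; a single invalid record aborts database
  construction (tables loaded from files are screened row-wise first, so
  user-facing loads report rather than abort).
* Config files are plain key-value YAML; every generator config validates
  its fields and names the offending field in the error.
* One integer seed drives each generator call through an isolated RNG
  scope that restores the caller's RNG state.

## Problem sizes used by the test-suite

The suite runs on synthetic data sized for desk-scale reproduction: a
100-spectrum sweep for the spectral oracle, a 25-point grid for the
indentation round trip, 1,000 null cohorts of 30 + 30 liners for the
type-I calibration of the Welch test (accepted band 0.033–0.069 at
α = 0.05), 200 cohorts at a mean OI shift of 1.0 (sd 0.5) for power
(expected ≥ 0.95), and a 10⁵-replicate permutation oracle for the Pearson
p-value on a fixed 20-pair set. A cohort of 10,000 records checks the
group-frequency goodness of fit.

## Limitations

The package analyzes data; it does not acquire them. Sectioning,
microtoming, IR acquisition and indenter operation are out of scope, as
are DSC crystallinity, wear-geometry measurement and survival or
multifactor regression modelling. Real multi-center headline numbers
(group p-values, minimal OI in mechanical failures, correlation-matrix
summaries) depend on the actual retrieval collections and cannot be
reproduced from synthetic cohorts; the package reproduces the *protocol*
(counts, thresholds, calibrated statistics), not those findings.
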