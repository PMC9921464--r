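# explantr

Standardized retrieval analysis of explanted UHMWPE liners from total
joint replacements.

When a hip or knee replacement is revised, the removed ultrahigh
molecular weight polyethylene (UHMWPE) liner carries a record of its life
in vivo: oxidative degradation, the crystallinity increase that follows
it, and the resulting change in micromechanical properties. Multi-center
retrieval programs characterize every explant the same way so that data
from different hospitals and countries can be merged and mined.
`explantr` implements that standardized chain for researchers running or
joining such a program:

1. **IR indexing** — infrared line scans (absorbance spectra vs depth
   from the articulating surface) are reduced to depth profiles of the
   oxidation index `OI = A1720/A1370`, trans-vinylene index
   `VI = A965/A1370` and crystallinity index `CI = CA/(CA+1)`,
   `CA = A1897/A1303`, using baseline-corrected band areas; each liner
   yields 15 standardized indexes (max and central average per region U,
   W and combined UW) and an oxidation-severity class (low OI < 1,
   critical OI > 3).
2. **Microindentation** — Vickers hardness `H_V = 1.8544 F/d²` and, from
   instrumented load–depth–time curves, the Oliver–Pharr property set
   (`H_IT`, `E_IT`, `H_M`, creep `C_IT`, elastic work fraction `η_IT`),
   aggregated over replicate indents into six per-liner values per
   property, with the Tabor yield estimate `Y = H/3`.
3. **Retrieval database** — a versioned per-liner schema (patient,
   material, surgical and index fields with controlled vocabularies),
   row-validated template loading, collision-safe multi-file merge and
   predicate filtering (e.g. `OI(max,UW) <= 4`).
4. **Statistics** — Pearson correlations with p-values, pairwise-complete
   correlation-matrix heatmaps, power-law fits `CI = k·OIⁿ`, type-7
   quartile/Tukey boxplot statistics and Welch / Mann–Whitney group
   comparisons.
5. **Synthetic data** — generators for camel-shaped oxidation profiles,
   forward-modelled indentation curves and whole cohorts with
   sterilization/failure group structure, so the entire chain is testable
   without physical specimens.

See `vignettes/retrieval-analysis-methods.Rmd` for the models,
conventions and numerical choices.

## Worked example

```r
library(explantr)

# 1. a synthetic liner: camel OI profile (apex 2.0 / 1.2, plateau 0.5)
cfg  <- linescan_sim_config(oi_peak_heights = c(2.0, 1.2), noise_sd = 0, seed = 1)
pair <- generate_linescan_pair(cfg)
idx  <- extract_standard_indexes(build_profiles(pair$U), build_profiles(pair$W))
idx
#> <standard_index_set> 15 standardized indexes:
#>  OI(max,U)  OI(max,W) OI(max,UW)  OI(ave,U)  OI(ave,W) OI(ave,UW)  VI(ave,U)
#>     2.0006     1.2503     2.0006     0.5002     0.5002     0.5002     0.0500
#>  VI(ave,W) VI(ave,UW)  CI(max,U)  CI(max,W) CI(max,UW)  CI(ave,U)  CI(ave,W)
#>     0.0500     0.0500     0.5977     0.5649     0.5977     0.5061     0.5061
#> CI(ave,UW)
#>     0.5061
classify_oxidation_severity(idx[["OI(max,UW)"]])
#> [1] intermediate
```

The unworn maximum recovers the configured apex OI of 2.0; the worn
maximum is lower because the articulating-surface peak is attenuated
(material removal), and the combined maximum is their larger value.

```r
# 2. instrumented indentation round trip (targets: H_IT 60 MPa, E_IT 900 MPa)
res <- analyze_indentation_curve(generate_indentation_curve(indent_sim_config(seed = 1)))
#> H_IT = 60.0 MPa, E_IT = 900 MPa, H_M = 40.6 MPa, C_IT = 3.89 %, eta_IT = 0.326

# 3. a 120-liner cohort: sterilization group difference and OI-CI coupling
db  <- generate_cohort(cohort_sim_config(n_liners = 120, seed = 1))
rec <- db$records
compare_groups(rec[["OI(max,UW)"]][rec$sterilization == "gIRR"],
               rec[["OI(max,UW)"]][rec$sterilization == "EtO"],
               labels = c("gIRR", "EtO"))
#> <group_comparison> gIRR vs EtO (welch_t): means 3.35 / 0.88, p = 1.499e-20
fit_power_law(rec[["OI(ave,UW)"]], rec[["CI(ave,UW)"]])
#> <power_law_fit> y = 0.55 * x^0.12 (rss 5.24e-32)
nrow(filter_database(db, "OI(max,UW) <= 4")$records)
#> [1] 99
```

Gamma-sterilized liners carry far higher oxidation than ethylene-oxide-
sterilized ones (the generator reproduces that group structure), the
crystallinity index recovers its configured power-law coupling to OI
exactly on noise-free data, and the conventional exclusion of extremely
oxidized liners (`OI(max,UW) > 4`) drops 21 of 120 records here.

A command-line front end is installed with the package
(`exec/explantr`), with subcommands `simulate | index | indent | merge |
stats | report | pipeline`; `Rscript <lib>/explantr/exec/explantr
pipeline --config inst/extdata/demo_config.yaml --out out/ --seed 1`
runs the whole chain and writes a merged database, correlation heatmap,
group boxplots, a Markdown report and a JSON run manifest.

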