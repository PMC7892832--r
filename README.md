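# nmrflex

Quantitative analysis of structural flexibility and IgE binding for
near-identical isoforms of PR-10 allergens (the Bet v 1 / Cor a 1 protein
family, ~160 residues).

Allergen isoforms that are >97% identical in sequence can differ sharply
in how strongly patient IgE binds them. For the hazelnut Cor a 1.04 family
the explanation is dynamic, not structural: the isoforms share the same
fold, but the more flexible the backbone, the weaker the IgE binding.
nmrflex implements the full analysis chain behind that comparison as a
tested, reusable R package for NMR spectroscopists and allergy
researchers:

* **CPMG relaxation dispersion** — effective rates
  `R2,eff = -ln(I/I0)/T_relax`, exact two-site exchange fits
  (Bloch–McConnell propagation of in-phase magnetization through the
  pulse train; parameters `k_ex`, `p_b`, `Δω`, `R2,0`), F-test model
  selection against a flat profile, and the percentage of residues with
  dispersion amplitude `ΔR2,eff` above 1/3/5/10 s⁻¹ per isoform.
* **H/D exchange** — single-exponential decay fits of time-resolved
  SOFAST-HMQC intensities, censoring for too-fast/too-slow series, and
  the set of residues exchanging ≥4× faster in one isoform than another.
* **PFG diffusion** — Stejskal–Tanner attenuation fits
  `I(g) = I0·exp(-D γ²g²δ²(Δ-δ/3))`, Stokes–Einstein conversion
  `R_h = kT/(6πηD)`, and aggregation over the 20 best-fitting residues.
* **Structure ensembles** — multi-model PDB reading, Kabsch superposition,
  intra-ensemble pairwise RMSD (backbone/heavy) and cross-structure RMSD.
* **ELISA** — log-linear standard curve, specific-IgE quantification in
  kU/L, cohort box-plot summaries, Shapiro–Wilk / Friedman / Dunn-type
  post hoc / Spearman statistics.
* **Integration** — per-isoform flexibility vs cohort IgE medians as a
  Spearman rank comparison (`ρ = -1` = exact inverse ranking).
* **Synthetic data** — seeded generators for every stage with
  ground-truth sidecars, emulating the statistical structure of the
  study's data.

Everything is tidyverse-native: tables in, tibbles out, `tidy()`/
`glance()` on fitted objects, `autoplot()`/`plot_*()` for figures.

## Worked example

Generate a synthetic study, fit the diffusion panel, quantify the ELISA
cohort, and ask whether flexibility and IgE binding are inversely ranked:

```r
library(nmrflex)
library(dplyr)

spec <- synth_spec(seed = 1)

# hydrodynamic radius from the PFG panel (20 best of 30 residues)
pfg <- gen_pfg_table(spec)
pfg$records |> fit_pfg_table() |> aggregate_rh()
#> # A tibble: 1 × 3
#>   r_h_mean r_h_sd n_used
#>      <dbl>  <dbl>  <dbl>
#> 1     18.6 0.0263     20

# quantify the 22-patient ELISA plate and summarise the cohort
e <- gen_elisa_plate(spec)
ige <- e$plate |> quantify_plate() |> cohort_summary()
ige |> select(isoform, median, q25, q75, min, max)
#> # A tibble: 4 × 6
#>   isoform median   q25   q75   min   max
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0401     2.04  1.20  2.54  0.457  4.38
#> 2 0402     1.20  0.764 1.89  0.280  3.28
#> 3 0403     1.56  0.927 2.27  0.380  5.69
#> 4 0404     0.907 0.734 0.992 0.215  1.36

# combine with the flexibility metric (% residues with dR2eff > 1 1/s)
flex <- c("0401" = 33, "0402" = 59, "0403" = 50, "0404" = 68)
panel <- isoform_panel(flex, setNames(ige$median, ige$isoform))
inverse_relation(panel)
#> <rank_comparison>
#>   flexibility:  0404 > 0402 > 0403 > 0401
#>   IgE:          0401 > 0403 > 0402 > 0404
#>   Spearman rho = -1.000 (exact inverse ranking)
```

The hydrodynamic radius matches the monomeric PR-10 value (18.6 Å), the
quantified cohort medians land on the generator's targets (2.02, 1.21,
1.57, 0.88 kU/L) to within assay noise, and the two rankings are exact
inverses: the most flexible isoform binds IgE least.

The CPMG chain works the same way on intensity tables:
`read_cpmg_table()` → `dispersion_profiles()` →
`fit_dispersion_profiles()` → `flexibility_summary()`; see the vignette
(`vignettes/flexibility-ige.Rmd`) for the models, parameter defaults and
design rationale.

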