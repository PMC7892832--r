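---
title: "Quantifying structural flexibility and IgE binding of PR-10 allergen isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structural flexibility and IgE binding of PR-10 allergen isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrflex)
library(dplyr)
options(nmrflex.verbose = FALSE)
```

nmrflex implements the quantitative analysis chain used to compare
near-identical isoforms of a PR-10 food allergen (the hazelnut Cor a 1.04
family, Gly1–Cys160) along two axes: backbone structural flexibility
measured by NMR, and IgE-binding potential measured by ELISA across a
patient cohort. Its end point is a rank comparison of the two per-isoform
metrics, which for this allergen family is exactly inverse: the most
flexible isoform binds IgE the least. This vignette explains each model in
the chain, the tunable parameters and their defaults, what the synthetic
data emulate, and the numerical choices made where the design was open.

## CPMG relaxation dispersion and the two-site exchange model

Micro-to-millisecond conformational exchange adds an exchange contribution
to the effective transverse relaxation rate of each backbone amide
$^{15}$N. In a constant-time CPMG experiment the rate at pulse-train
field strength $\nu_\mathrm{CPMG} = (2\tau_\mathrm{CPMG})^{-1}$ is
computed from peak intensities as

$$R_{2,\mathrm{eff}}(\nu) = -\frac{1}{T_\mathrm{relax}}
  \ln\frac{I(\nu)}{I_0},$$

with $T_\mathrm{relax}$ = 30 ms by default and $I_0$ the reference plane
recorded without the relaxation delay (`compute_r2eff()`,
`dispersion_profiles()`). Repeat planes at the same $\nu$ are averaged
after conversion and their spread feeds the per-point uncertainty, floored
at $\max(1\%\,R_{2,\mathrm{eff}},\ 0.05\ \mathrm{s^{-1}})$ so single
planes never get infinite weight.

The dispersion model is two-site chemical exchange between a major state
*a* and a minor state *b* (population $p_b \le 0.5$, shift difference
$\Delta\omega$ in rad/s, exchange rate constant $k_\mathrm{ex}$, shared
intrinsic rate $R_{2,0}$). `simulate_r2eff_exact()` propagates the
Bloch–McConnell evolution of in-phase magnetization through the CPMG
element $(\delta - 180^\circ - \delta)^n$ exactly: free precession is a
2×2 complex matrix exponential, the 180° pulse is complex conjugation, and
because the pulse count $n = 2\nu T_\mathrm{relax}$ is rounded to the
nearest even integer the conjugations cancel pairwise, leaving the linear
two-block propagator $P = E\,\bar{E}\,\bar{E}\,E$. This is numerically
exact in all exchange regimes; the Carver–Richards approximation is not
used. The Luz–Meiboom fast-exchange closed form
(`luz_meiboom_r2eff()`) is kept solely as an independent test oracle; the
two agree to better than 5% of the exchange contribution whenever
$k_\mathrm{ex} \ge 10\,\Delta\omega$.

Two modelling simplifications are deliberate and documented as
limitations: both exchange states share one intrinsic rate $R_{2,0}$, and
$^1$H continuous-wave decoupling during the CPMG period is treated as
ideal (pure in-phase $^{15}$N evolution). Note also that monotonicity of
the dispersion profile in $\nu$ is a property of intermediate-to-fast
exchange only; in slow exchange ($k_\mathrm{ex} < \Delta\omega$) the exact
propagation genuinely oscillates at low field strengths, where few
refocusing pulses recouple the shift difference.

`fit_dispersion()` fits $(k_\mathrm{ex}, p_b, \Delta\omega, R_{2,0})$ by
weighted least squares in an unconstrained transformed space, seeded from
the best point of a coarse grid ($k_\mathrm{ex} \in \{100, 300, 1000,
3000\}$ s$^{-1}$, $p_b \in \{0.01, 0.05, 0.15\}$, $\Delta\omega \in
\{300, 1000, 3000\}$ rad/s). A flat single-rate model is fitted alongside,
and the exchange model is accepted only if an F-test at $\alpha = 0.05$
says it reduces $\chi^2$ significantly — ties default to "flat" so
flexibility is never overcounted. The dispersion amplitude is taken from
the fitted model, not raw endpoints:

$$\Delta R_{2,\mathrm{eff}} = R_{2,\mathrm{eff}}(\nu_{\min}) - R_{2,0},$$

where $\nu_{\min} = 1/T_\mathrm{relax}$ is the smallest field strength the
constant-time element supports (two pulses), serving as the numerical
stand-in for the zero-frequency extrapolation. Per-residue profiles are
fitted individually; grouped (global $k_\mathrm{ex}$) fitting would be a
natural extension but is not implemented.

`flexibility_summary()` reports, per isoform, the percentage of evaluable
residues whose amplitude exceeds each threshold (defaults 1, 3, 5,
10 s$^{-1}$). Both the number of residues with an evaluable profile
(`n_evaluated`, the denominator) and the number attempted are reported,
since the published percentages do not state which denominator was used.

## Hydrogen–deuterium exchange

After dilution into D$_2$O, each amide's peak intensity decays as
$I(t) = A e^{-kt} + c$. `fit_hdx_decay()` fixes $c = 0$ unless the series
has genuinely flattened at a plateau exceeding three times the noise
floor — a high but still-decaying tail is slow exchange, not a baseline.
Plane time stamps are acquisition midpoints (the acquisition convention is
not stated in the source protocols; midpoints are the unbiased choice),
with a configurable mixing dead time (default 60 s). Degenerate series
are censored rather than fitted: `too_fast` when the first plane is
already at the noise floor, `too_slow` when the series decays less than 5%
over the window.

`acceleration_ratio()` compares isoforms per residue as
$k_\mathrm{test}/k_\mathrm{ref}$. When the test residue exchanged within
the dead time, a lower bound $k_\mathrm{test} \ge \ln 2 / t_\mathrm{first}$
replaces the rate — the proton must have lost at least half its signal by
the first plane — so fast exchangers still enter the $\ge$ 4-fold
accelerated set (`accelerated_residue_set()`) instead of being dropped.
This censoring rule is this package's choice; the source analysis does not
state how such residues were treated. Intensities are never normalized
across series: only rate ratios are compared, so units cancel.

## PFG diffusion and the hydrodynamic radius

Stimulated-echo intensities attenuate with gradient strength $g$ as
$I(g) = I_0 \exp(-D\gamma^2 g^2\delta^2(\Delta - \delta/3))$. Taking logs
makes the fit linear in $D$, so `fit_diffusion()` is an ordinary linear
regression — exact, fast and free of starting-value issues. The basic
Stejskal–Tanner b-factor is used; stimulated-echo correction terms and
convection compensation are out of scope, and no internal reference or
co-solvent (9% D$_2$O) viscosity correction is applied. The gradient pulse
length $\delta$ is not stated in the source protocol and defaults to 4 ms
in the configuration; the diffusion time is $\Delta$ = 160 ms and the
gradient ladder is 2.0–24.5 G/cm in ten steps.

`stokes_einstein_radius()` converts $D$ to a hydrodynamic radius
$R_h = k_B T / (6\pi\eta D)$ (defaults 298.15 K, 0.890 mPa s).
`aggregate_rh()` averages the 20 residues with the smallest fit residual —
"RMSD" in the aggregation rule is read as the per-residue fit residual
RMS, following the protocol this experiment cites, since a structural RMSD
has no per-residue meaning here. A noiseless series at
$D = 1.3192\times10^{-10}$ m$^2$/s round-trips to $R_h$ = 18.6 Å, the
published monomer radius.

## Ensemble RMSD statistics

`read_pdb_ensemble()` parses multi-model PDB files (via bio3d), resolving
alternate locations to the highest occupancy and keeping hydrogens out of
both atom selections. `kabsch_rmsd()` is the SVD superposition with the
proper-rotation correction; tests verify it against a brute-force
multi-start rotation search. Pairwise ensemble RMSD superposes every model
pair independently (no mean-structure fit), on either the backbone
selection (N, CA, C — the published table does not define "backbone", and
O is excluded here; benchmark comparisons should carry a ±0.1 Å tolerance,
one reported decimal) or all heavy atoms, over all residues with no
ordered-residue trimming. Cross-structure comparisons take model 1 of each
deposition as the lowest-energy representative. The deposited ensembles
(6Y3H, 6Y3I, 6Y3K, 6Y3L) are not shipped; any local copy can be passed to
the same functions.

## ELISA quantification and cohort statistics

The standard curve is linear in $\log_{10}$ concentration after blank
subtraction — the "linear logarithmic" reading of the assay description —
fitted over the non-zero standards (100 down to 2 ng/mL). Specific IgE in
kU/L is obtained by inverting the curve for the triplicate mean and
applying two constants the assay description leaves implicit, both
config-exposed: 1 IU = 2.4 ng of IgE with kU/L ≡ IU/mL, and the 1:2 serum
dilution. Absorbances at or below blank report as below-detection rather
than negative; values above the top standard extrapolate with a flag.
Triplicate spread propagates through the inverse curve by the delta
method.

`compare_isoforms()` runs per-isoform Shapiro–Wilk tests, the Friedman
rank test across the complete patients-by-isoforms matrix, and pairwise
Dunn-type post hoc z-tests on mean within-patient ranks with Bonferroni
adjustment. The post hoc procedure in the original SPSS analysis is not
verifiable from its description, so printed pairwise p-values are not
reproduction targets; the implemented procedure is the standard
Friedman-aligned one and is validated against generator ground truth. A
perfectly rank-structured cohort of 22 patients and 4 isoforms attains the
maximum Friedman statistic $n(k-1) = 66$.

## The rank comparison

`isoform_panel()` pairs a per-isoform flexibility metric — by default the
percentage of residues with $\Delta R_{2,\mathrm{eff}} > 1$ s$^{-1}$, the
first-listed threshold, with all four thresholds also reported — with the
cohort median IgE. `inverse_relation()` reports both descending orders and
their Spearman correlation. With four isoforms a rank p-value is
meaningless, so none is reported; `is_exact_inverse` is true only for a
tie-free $\rho = -1$. Published values for this family give flexibility
ranking 0404 > 0402 > 0403 > 0401 against IgE ranking
0401 > 0403 > 0402 > 0404: exactly inverse.

```{r panel}
panel <- isoform_panel(
  c("0401" = 33, "0402" = 59, "0403" = 50, "0404" = 68),
  c("0401" = 2.02, "0402" = 1.21, "0403" = 1.57, "0404" = 0.88)
)
inverse_relation(panel)
```

## What the synthetic generators emulate

Raw spectra are not redistributable, so `synth_spec()` defines a seeded
synthetic study whose defaults are the study conditions, and every
generator emits a ground-truth sidecar for round-trip testing:

* **CPMG** (`gen_cpmg_table()`): per-isoform flexible fractions (0.33,
  0.59, 0.50, 0.68) realized exactly as `round(frac * 160)` residues at
  random positions — the fractions are conditions, not a sampling target.
  Flexible residues draw $k_\mathrm{ex} \in [300, 3000]$ s$^{-1}$,
  $p_b \in [0.01, 0.1]$, $\Delta\omega \in [300, 2500]$ rad/s (redrawn
  until the true amplitude lies in 1.5–15 s$^{-1}$, so the 1 s$^{-1}$
  threshold classifies cleanly under noise); rigid residues are
  single-state. These ranges are synthetic choices producing amplitudes
  spanning the reporting thresholds, not values inferred from data.
  Gaussian intensity noise defaults to 0.5% of the reference intensity,
  a realistic spectral signal-to-noise for concentrated samples.
* **H/D exchange** (`gen_hdx_tables()`): log-uniform reference rates over
  $[5\times10^{-5}, 4\times10^{-4}]$ s$^{-1}$ (half-lives within the
  ~100-min acquisition window), a designated residue set {9, 101, 107,
  154} accelerated 5-fold in the test isoform, plane durations 4.12 and
  3.8 min, SNR 20.
* **PFG** (`gen_pfg_table()`): 20 low-noise residues plus 10 high-noise
  outliers around the monomer diffusion coefficient; the best-20
  aggregation must exclude the outliers.
* **ELISA** (`gen_elisa_plate()`): a 22-patient × 4-isoform matrix with
  target medians (2.02, 1.21, 1.57, 0.88) kU/L hit exactly, the dominant
  within-patient ranking 0401 > 0403 > 0402 > 0404 in 91% of patients
  (the two exceptions put 0403 on top), log-normal patient reactivity
  (sdlog 0.5) that the low-binding isoform tracks only weakly (exponent
  0.35 — its values are uniformly low across sera), and triplicate
  absorbance noise of 0.004 around a curve with slope 0.40 per decade.
  Medians and rank structure are reconciled by alternating per-patient
  reordering with column rescaling until both hold.
* **Ensembles** (`gen_toy_ensemble()`): an idealized helical trace with
  N, CA, C, O and a CB dummy per residue; per-atom Gaussian displacements,
  larger on side chains, so backbone RMSD < heavy-atom RMSD by
  construction.

What passing these tests does and does not show: the suites demonstrate
that each estimator inverts its own forward model at realistic noise, that
censoring and model-selection rules behave as designed, and that the full
chain reproduces the published summary numbers when the data have the
published structure. They do not validate peak picking, overlap, baseline
or phase artifacts, intermediate three-site exchange, or assay
nonlinearity beyond the log-linear range — none of which the generators
emulate.

## Numerical choices and problem sizes

Dispersion fits use `nlminb` on transformed parameters (log rates and
shift, logistic population bounded at 0.5) with exponentials clamped to
keep line-search trials physical; non-finite trial models score a large
penalty rather than aborting. The acceptance-style suites fit 160 residues
× 4 isoforms for the flexibility summary, 50 noisy replicates for the
amplitude-recovery study, and 50 series for the H/D-exchange recovery
study — sizes chosen to keep the whole suite within a few minutes on one
CPU while leaving the statistics stable. All generator randomness is
seeded; identical seeds give bit-identical tables.
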