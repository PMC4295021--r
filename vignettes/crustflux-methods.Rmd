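---
title: "Methods: rates, energetics and diversity of sulfate reducers in crustal fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rates, energetics and diversity of sulfate reducers in crustal fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustflux)
```

`crustflux` quantifies microbial sulfate reduction in low-temperature
(< 100 °C) fluids of the upper basaltic ocean crust, sampled through
sealed borehole observatories. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Radiotracer rate model

A fluid subsample incubated with carrier-free ³⁵S-sulfate reduces a
fraction of the tracer to sulfide and other reduced inorganic sulfur
species, recovered by single-step acid chromium distillation (TRIS,
total reduced inorganic sulfur). The rate equation is

$$ SRR = [\mathrm{SO_4^{2-}}] \cdot 1.06 \cdot
   \frac{a_{TRIS}}{a_{TOT} \cdot t} $$

with the sulfate pool in nmol ml⁻¹, `t` in days, and 1.06 correcting
for the slower enzymatic turnover of ³⁵S relative to ³²S. The factor is
exposed as `fractionation` in `compute_srr()` for laboratories using a
different convention.

**Blank correction order.** The TRIS channel is corrected by the *sum*
of all background count rates (scintillation counter, distillation
blank, unreduced-tracer carryover, and a bottom-seawater contamination
term), clamped at zero; the total-activity channel is corrected for the
counter background only, since the other terms live in the distillate.
Corrected totals ≤ 0 indicate tracer accounting failure and raise an
error rather than producing a rate.

**Detection limit.** The minimum detectable rate is the rate equivalent
of a TRIS signal equal to `B + k·sqrt(B / t_count)`, where `B` is the
summed background count rate and `sqrt(B/t_count)` its Poisson standard
error over the counting window. The multiplier defaults to `k = 3`
(a conventional 3-sigma criterion; the underlying field protocol does
not fix a value, so it is a configuration parameter). The MDL is
monotone in every background term and scales as `1/(a_TOT · t)`, so
longer incubations and counting windows lower it — the reason the
cooler, more active fluid could be read after 3 days while the warmer
fluid needed 5.

**Endpoint vs time course.** Rates default to the fixed-endpoint form
(the field protocol used 3- and 5-day endpoints). When several time
points per vial are available, `mode = "timecourse"` fits the reduced
fraction against time by zero-intercept least squares (`stats::lm`)
and converts the slope; both modes agree exactly on noiseless linear
series.

**Temperature optima.** `find_topt()` reports all strict local maxima
of the aggregated rate-vs-temperature curve. Three conventions were
genuinely open and are resolved as follows: plateaus report their
lowest temperature (first reach of the maximal rate); endpoints count
as optima when they exceed their single interior neighbour, because
thermal-gradient blocks truncate rising segments at the grid edge
(the ~77 °C thermophilic peak sits near the top of a 10–86 °C grid);
and points below detection are excluded before peak-finding. With
multiple coexisting populations (mesophilic and thermophilic sulfate
reducers in the same fluid), each sufficiently separated population
contributes one optimum.

## Energetics model

The free energy of organotrophic sulfate reduction, with acetate as the
proxy for dissolved organic matter,

$$ \mathrm{CH_3COO^-} + \mathrm{SO_4^{2-}} \rightarrow
   2\,\mathrm{HCO_3^-} + \mathrm{HS^-}, \qquad
   \Delta G_r = \Delta G_r^\circ + RT \ln Q_r $$

is evaluated at fixed fluid composition across 0–100 °C.

**Standard state.** ΔG_r°(T) comes from a bundled reference table
(`inst/extdata/dgr0_acetate_sulfate.tsv`) generated once from
SUPCRT-compatible 25 °C standard-state properties of the four aqueous
ions by constant-ΔCp° integration, at a nominal 27 MPa
(ΔG_r°(25 °C) = −48.13 kJ mol⁻¹; the generation script and a
provenance manifest ship with the package). A full revised-HKF
equation-of-state stack is deliberately out of scope: over 0–100 °C and
the ~0.6 MPa pressure difference between the two boreholes, the table
reproduces the standard-state term well within the ~1 kJ mol⁻¹ level
that matters here, because ΔG_r is dominated by the RT ln Q term
(≈ −40 to −50 kJ mol⁻¹). Interpolation is monotone cubic
(`stats::splinefun`, `monoH.FC`), exact at table nodes.

**Activities.** Molalities times individual-ion activity coefficients
from the extended Debye–Hückel (B-dot) equation,
`log10 γ = −A z² √I / (1 + a°B√I) + ḃI`, with temperature-tabulated
A, B and ḃ and Kielland-style ion sizes bundled as TSV. Neutral species
get γ = 1. Molarity is treated as molality (< 3% error at these ionic
strengths and temperatures, below the chemistry's analytical
uncertainty).

**Open conversions, decided.** Two quantities the underlying field
data do not pin down are configuration parameters with documented
defaults. (1) DOC (µM carbon) maps to the acetate proxy *per carbon*
(DOC/2, acetate having two carbons) by default; `per_molecule` is
available, and reports state which was used. The borehole contrast is
insensitive to the choice since it rescales both fluids alike.
(2) Sulfide below detection is floored at 10⁻⁹ mol kg⁻¹ so ln Q stays
finite; the floor is configurable. Bicarbonate is taken as total
alkalinity (carbonate-dominated in these fluids); full carbonate
speciation is out of scope.

**Energy density.** ΔG_r (kJ per mol reaction) is normalized per kg of
fluid by the limiting reactant — the reactant minimizing c/|ν|, in both
fluids acetate (µM-level DOC vs mM-level sulfate):
`energy density = −ΔG_r · c_lim/|ν_lim|` in J kg⁻¹, reported
positive-exergonic while the per-mol ΔG_r keeps its thermodynamic sign.
Ties in c/|ν| resolve to the first reactant in the reaction's species
order. On the bundled chemistry the younger-crust fluid is ~1.9× more
energy dense than the older fluid at every temperature, which the
package's tests assert as an ordering and ratio-band property.

## qPCR quantification

Standard curves are ordinary least-squares fits of Cq on log₁₀(copies)
(≥ 3 distinct dilution levels, negative slope enforced, r² < 0.98
warned). Efficiency is `E = 10^(−1/slope) − 1`; perfect doubling gives
slope −3.3219. Unknowns are inverted through the curve and scaled by an
explicit volume chain (template µl → extract µl → filtered ml), since
published end results rarely record it; cells follow from an assumed
one dsrAB copy per sulfate-reducing cell, so reported cell densities
are maxima. Replicate reactions aggregate by mean Cq (SD retained);
Cq outside the calibrated range ± 2 cycles is flagged `extrapolated`,
not rejected. Cell-specific rates are `(SRR / cells) × 10⁶`
fmol cell⁻¹ d⁻¹; printed rounded inputs (0.05 nmol ml⁻¹ d⁻¹, 1.6×10⁴
cells ml⁻¹) give 3.125 and 40 fmol cell⁻¹ d⁻¹ — the package reports
computed values and does not force agreement with rounded published
ranges. Carbon mineralization uses 2 mol organic C per mol sulfate
(configurable), and the DOC-removal comparison is a plain log₁₀ ratio.

## Diversity analysis

Sequence sets are taken pre-aligned (the field workflow uses curated
reference alignments); de novo alignment is out of scope. `apply_mask()`
restricts to unambiguously aligned columns and drops records whose
retained non-gap length falls below a threshold, emulating the
discard of short fragments.

**Distances.** Uncorrected mismatch fractions over compared columns.
Both-gap and terminal-gap columns are skipped. Internal gaps follow the
`onegap` convention by default — a contiguous single-sequence gap run
counts as one mismatch over one column — matching the default of the
clustering tool standardly used for this analysis; `eachgap` and
`nogap` are available. `N` never matches and counts as a mismatch only
against a determined base.

**Clustering.** `average_neighbor_cluster()` is an authored
average-linkage (UPGMA) agglomerator that merges while the
size-weighted mean inter-cluster distance is at most the cutoff (0.03 ≈
97% similarity). Ties among equal-distance candidates resolve to the
pair with lexicographically smallest member ids, making results
deterministic and input-order invariant. The test suite proves
equivalence against an independent `stats::hclust`/`cutree` oracle on
200 random instances, perfect recovery of planted OTU structure, and
monotonicity of OTU counts in the cutoff.

**Estimators.** Chao1 uses the bias-corrected form
`S_obs + F₁(F₁−1)/(2(F₂+1))`. Simpson evenness is `(1/D)/S_obs` with
the unbiased finite-sample `D = Σ nᵢ(nᵢ−1)/(N(N−1))`; because the
unbiased D can make 1/D exceed S_obs for nearly even small samples, the
index is clamped at 1. The nonparametric Shannon index is the
Chao–Shen coverage-adjusted estimator (coverage `Ĉ = 1 − F₁/N`,
Horvitz–Thompson denominator `1 − (1 − Ĉpᵢ)^N`); it equals the plain
Shannon index only asymptotically, so the corresponding test asserts
near-equality at finite N rather than identity.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis
assumes, at the study's own conditions: 100 kBq ml⁻¹ tracer in 50 ml,
duplicate vials, 3–5 day endpoints, 26.2/17.2 mM sulfate, true rates of
order 0.01–0.14 nmol ml⁻¹ d⁻¹; a 14-increment 10–86 °C thermal grid
with population optima near 33, 50 and 74 °C (width ~6 °C — separations
comfortably exceeding twice the width, as required for resolvable
peaks); 10¹¹–10¹ copies µl⁻¹ qPCR dilution decades; and 268-nt masked
sequence fragments with within-OTU divergence 0.01 and between-OTU
divergence 0.10. Counting noise is Poisson on raw counts over a fixed
10-min counting window (free parameters of the simulator, as blank
magnitudes and counting times are unreported in the field protocol);
thermal responses are skewed Gaussians (independent left/right widths) —
the simplest shape reproducing multimodality, not a cardinal-temperature
growth model; sequence evolution is uniform substitution without indels
so the masked length stays constant; seawater contamination is a volume
fraction carrying an independent rate, feeding the detection-limit
background term.

Passing tests on these synthetics therefore demonstrate estimator
correctness — unbiased rate recovery (< 2% at ≥ 10⁴ expected TRIS
counts), exact qPCR inversion, perfect planted-OTU recovery — not
fidelity to real fluids: no distillation chemistry, amplification bias,
chimeras, primer mismatch, sulfide re-oxidation, or indel evolution is
simulated, and real measured rate-vs-temperature values, field qPCR
abundances and real-sequence OTU counts are not reproducible without
the physical samples.

## Problem sizes and determinism

The shipped tests and the acceptance script use deliberately desk-scale
problems — 100-seed rate-recovery ensembles, 200 random clustering
instances of ≤ 12 sequences, 40-sequence planted OTU sets, 2 °C
energetics grids — sizes at which the stochastic assertions are already
tight (Poisson SE of the ensemble mean ≈ 0.08%). Every stochastic
routine takes a seed; identical seeds give byte-identical outputs,
including the TSV/JSON bundles written by `write_sim_bundle()` and
`write_report()` (manifests record seed and configuration hash, never
timestamps).

## Known limitations

Single fixed-pressure standard-state table and no aqueous speciation
solver; energetics cover the acetate–sulfate couple only (no
H₂-based sulfate reduction); alkalinity-as-bicarbonate ignores borate
and silicate contributions; qPCR quantification starts from Cq values
(no raw fluorescence or melt-curve processing); clustering is exact
average linkage, O(n³) in sequences, adequate for clone libraries
(hundreds) but not amplicon surveys; and cell-specific rates inherit
the one-copy-per-cell assumption, so they are upper-bound estimates.
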