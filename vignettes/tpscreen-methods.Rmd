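---
title: "Screening for transformation products: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for transformation products: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpscreen)
```

# The problem and the model

Degradation experiments for organic micropollutants are run with parent
compounds spiked at several initial concentrations and analysed by LC-HRMS
before (0 h) and after (2 h) treatment. Two facts make transformation
products (TPs) findable among the tens of thousands of detected features:

1. **TP abundance is linear in the initial parent concentration.** A TP
   formed from a spiked parent inherits the concentration series; a
   background chemical does not. The prioritization model is ordinary
   least squares of replicate-mean feature intensity on the initial
   concentration, one fit per treatment condition, keeping features with a
   positive slope that is either significant (one-sided *p* ≤ α) or
   strongly linear (*R*² above a relaxed bound).
2. **Single-parent experiments disambiguate parentage.** A feature that
   appears in another parent's single-parent run is unlikely to descend
   from the parent under consideration, unless its mixture intensity
   dwarfs that run (5× rule) or it also appears in the parent's own
   single-parent run.

Everything downstream — suspect screening, candidate ranking,
identification levels, semi-quantitation — consumes the features that
survive these two arguments.

# Prioritization

`blank_subtract()` removes features whose maximum 2 h intensity is below
`blank_factor` (default 5) times their mean 0 h intensity; features absent
at 0 h are always kept, and the comparison is multiplicative so a zero
0 h mean needs no special-casing. Parents are exempt — they are tracked
for quantitation, not TP candidates.

`regress_concentration()` fits the concentration model **within each
photolytic condition** and keeps a feature when any condition shows the
trend. TP yields can differ several-fold between UV and UV/H₂O₂ — a TP of
a parent that barely degrades under UV alone may only trend in the
peroxide conditions — and pooling conditions would fold that treatment
effect into the residual, penalizing exactly those TPs. A pooled mode
(`by_condition = FALSE`) and a per-replicate mode are available for
sensitivity analysis.

Defaults (all config keys, echoed to the run log): α = 0.05 one-sided,
`r2_relaxed` = 0.7, detection floor 1000 counts, detection required in
≥ 2 of 3 concentration arms and ≥ 2 replicates of some arm, blank factor
5. Non-detections enter the regression as zeros only when the feature is
detected in at least `min_conc_levels` arms; otherwise the feature is
excluded, which prevents two-point artifacts. The relaxed *R*² branch
exists for saturation: a profile like (25 → 1000, 75 → 3000, 150 → 3100)
has a positive but non-significant slope and *R*² ≈ 0.68, so whether it
survives is governed by `r2_relaxed` — the default 0.7 is deliberately
close to that regime and is the single most consequential tuning constant
in the package.

# Chemistry engine

Formulas are element-count vectors with Hill-order rendering; the
monoisotopic mass table and isotope abundances are embedded (IUPAC-CIAAW
2021 values for H, C, N, O, F, Si, P, S, Cl, Br), so no network access is
ever needed. Isotope patterns are computed by per-element polynomial
convolution aggregated by nominal mass offset; the M+2 cluster of
sulfur-containing analytes (≈ 5.9 % for C₁₀H₁₁N₃O₃S) is what makes
quantitation on the M+2 channel possible for concentrations that saturate
the monoisotopic trace.

Structures are parsed from SMILES after OpenBabel canonicalization, into
a heavy-atom graph with implicit hydrogens; aromaticity is taken from the
canonical aromatic form so that bond-order matching is consistent across
inputs. Three structure metrics are implemented here because they carry
the ranking:

* **MCS fit** — exact maximum common connected induced subgraph
  (element- and bond-order-matched) by branch-and-bound in C++,
  deterministic tie-breaking, with a wall-clock budget (default 2 s/pair)
  after which the best size found so far is returned flagged as a lower
  bound. `fit = max(|MCS|/n_cand, |MCS|/n_parent)`; the direction is
  configurable because the field uses both conventions.
* **Fingerprint similarity** — hashed circular substructure fingerprints
  (radius 2, 2048 bits) with Tanimoto; ubiquity, not optimality, is the
  reason for this choice.
* **log P** — OpenBabel's atom-contribution model, cached per canonical
  SMILES, used only for the elution-order filter with a ±2 tolerance:
  reversed-phase elution order is a coarse constraint and prediction
  errors of 1–2 log units are routine, so the filter only removes
  candidates that are badly inconsistent, and fails open when prediction
  fails.

# Annotation

Formula enumeration solves the hydrogen count analytically inside a
nested loop over the heavier elements, with RDBE ≥ 0 and integer-RDBE
(even-electron) filters; fragment peaks are read as protonated neutral
subformulas of the precursor (a peak at 77.039 from an aniline precursor
is bookkept as C₆H₄ + H⁺, i.e. the phenyl cation). The in-silico
fragmenter breaks up to `frag_depth` bonds (acyclic bonds singly, ring
bonds pairwise, at most one ring opening per fragment set) and tolerates
±1 hydrogen rearrangement at match time — the conventional simplification
for bond-disconnection fragmenters. MS² background removal subtracts
peaks matched in flanking (off-peak) spectra within a factor
`background_factor` (default 2) and applies a 1 % relative-intensity
floor; the exact published background algorithm is not reproducible from
public material, so this documented stand-in keeps the interface and
accepts precomputed clean spectra.

# Ranking unknowns

Candidates are retrieved by accurate mass from a local candidate table (a
database snapshot; the package never queries services at run time),
filtered by element content and elution order, scored, thresholded and
cut to the top 25 by TP score. The TP score is the mean of the available
components with absent components dropped — a feature without MS² is
still rankable, only without annotation evidence. The weighting is
deliberately uniform; a weighted combiner is exposed in the internals but
uniform-mean is the documented default because nothing in the calibration
data justifies more structure.

Thresholds are derived from the suspect-matched candidates: each metric's
5th percentile over that calibration set. Two regimes are exposed because
the interpolated percentile and a retention guarantee disagree at small
*n*: `guarantee_retention = TRUE` (default) relaxes the raw percentiles
minimally until at least 95 % of the calibration records pass all
thresholds jointly; `FALSE` returns the raw interpolated percentiles.
Calibration is leave-one-out — a suspect never calibrates against itself,
otherwise the self-similarity of 1.0 drives the similarity threshold to
1.0 and eliminates every genuine unknown candidate.

# Identification and quantitation

Confidence levels follow the standard five-level communication scheme;
sub-levels of the tentative-structure tier are collapsed to "3b" and
reported as tentative. Standard confirmation requires |ΔRT| ≤ 0.1 min,
|Δm/z| ≤ 5 mDa and an isotope-pattern fit below 100, where the fit score
is 1000 × RMS deviation of fractional abundances over offsets 0–2 — a
documented stand-in for proprietary vendor scores, scaled so the
threshold of 100 corresponds to roughly 10 % per-peak deviations. Two
structure suspects with identical formula but different connectivity
matched to one feature cap the level at 3a (indistinguishable isomers);
the same structure assigned to two parents does not.

Calibration curves are unweighted OLS (1/x weighting optional) and are
rejected — never silently down-weighted — unless they have ≥ 5 points,
*R*² ≥ 0.99 and all relative residuals ≤ 30 %. Parent removal is
100 × (1 − mean(2 h)/mean(0 h)) with a pooled-variance two-sample t-test;
with a single replicate the removal is still reported but significance is
marked unavailable. Semi-quantitation uses TP standards when present and
otherwise a predicted response factor (default: the parent's), carrying a
factor-5 uncertainty band; mass balances divide summed TP molarity by
molar parent removal, with per-TP exclusion flags and an explicit policy
for TPs shared between parents (split equally by default, full
attribution with a warning as the alternative). A non-positive or
non-significant parent removal makes the balance undefined, reported as
such rather than as 0 or infinity.

# The synthetic experiment

`simulate_experiment()` generates the complete study design: mixtures at
25/75/150 µg/L (3 replicates) under UV, UV/H₂O₂ and UV/H₂O₂/NOM,
single-parent runs at 150 µg/L (2 replicates), dark controls (2
replicates), and a 0 h twin for every arm. Parents are the four studied
pharmaceuticals with plausible reversed-phase retention times. The
intensity model is

> intensity = response factor × concentration (µM) × lognormal(0, σ),

truncated at an optional saturation cap; TP molarity is parent molar
removal × yield, so planted TPs are exactly linear in the initial
concentration at σ = 0. Background features are present in all samples —
including 0 h — with arm-independent intensities, which is what blank
subtraction and the regression assume about real matrix chemicals. A TP
with the same structure formed from two parents (aniline in the demo)
becomes a single feature with summed intensity, reproducing the
shared-TP ambiguity that the balance bookkeeping must handle.

Defaults are the study conditions: removal fractions high (~0.8) for the
two photolabile parents and low (~0.1–0.3) for the other two, dark-control
losses small; curated TP yields sum to 0.5–0.6 per parent per photolytic
condition; extra formula-only TPs are planted at yield 0.04 with a
response factor at the upper end of the parents' range, i.e. detectably
above the intensity floor — the recall statements in the tests are about
the workflow's ability to recover detectable TPs, not about instrument
sensitivity. Noise σ defaults to 0.1 (≈ 10 % multiplicative error,
matching run-to-run repeatability of a few percent plus matrix
variability).

What the generator does **not** emulate: retention-time drift and peak
shape, correlated matrix suppression (NOM effects enter only as
multiplicative noise), kinetic time courses, in-source fragments and
adducts other than [M+H]⁺, and real MS² fragmentation physics (planted
spectra come from the package's own fragmenter plus m/z jitter, so
annotation scores on synthetic data are upper bounds). Passing tests
therefore demonstrate the statistical and combinatorial machinery, not
performance on vendor data.

# Numerical choices and scale

All m/z tolerances are absolute mDa (default 5), retention times minutes,
concentrations µg/L and molar units µM. Percentiles use the standard
linear-interpolation convention. OLS is closed-form (the designs are
3-point regressions vectorized over thousands of features); the test
suite checks it against an explicit normal-equations oracle at 1e-9. The
MCS search, the subgraph-enumeration brute force used as its oracle, and
the exhaustive formula-enumeration oracle are all exact on the sizes
tested (≤ 12 heavy atoms, < 300 Da). Problem sizes in the tests — 10,000
background features for prioritization, ~140 decoy structures per
feature for ranking — were chosen so the full suite completes in a few
minutes on one core while keeping every statistical claim at its stated
threshold.

# Known limitations

Aside from the generator's simplifications above: suspect deduplication
trusts OpenBabel's InChI connectivity block (tautomers may stay
separate); the fragmenter does not model rearrangement chemistry beyond
±1 H; the elution-order filter assumes reversed-phase chromatography;
thresholds derived from few suspect matches are noisy (they disable
themselves below 5 calibration records); and predicted-response-factor
quantitation inherits the documented factor-5 band, so mass balances
built on it are semi-quantitative by construction.
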