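---
title: "Methods: AQUA-based MRM quantification of H3K14 acetylation stoichiometry"
author: "aquaStoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AQUA-based MRM quantification of H3K14 acetylation stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaStoich)
```

## The measurement problem

Histone post-translational modifications are usually reported as relative
fold changes. Stoichiometry — the *fraction* of a site carrying the
modification — is a stronger quantity: it is comparable across samples,
instruments and studies. `aquaStoich` implements the targeted workflow that
delivers it for histone H3 lysine-14 acetylation (H3K14ac) in human
monocyte-derived macrophages, from transition design to condition-level
statistics.

The chemistry that makes a single-peptide readout possible is
propionylation. Trypsin will not cleave after a modified lysine, so
unmodified and acetylated H3 molecules would otherwise yield different
peptides. Derivatizing every free lysine (and reaction with the peptide
N-terminus) with propionic anhydride (+56.026215 Da) blocks cleavage at
lysine uniformly: both forms of H3 9–17 become the same nine-residue
peptide KSTGGKAPR, differing only in the K14 mark — acetyl
(+42.010565 Da) on the modified form, propionyl on the unmodified form.
The assay therefore monitors four species: K9[Poy]K14[Ac] and
K9[Poy]K14[Poy], each light (endogenous) and heavy
(a synthetic stable-isotope-labeled standard carrying
$^{13}\mathrm{C}_6{}^{15}\mathrm{N}_4$ arginine, +10.0083 Da, i.e. a
5 m/z shift at charge 2+).

Quantification follows the AQUA (absolute quantification) principle: the
heavy standard is chemically identical to the analyte, so their MRM peak
areas relate as their concentrations,

$$\mathrm{Abs} = \frac{A_\text{light}}{A_\text{heavy}} \times C_\text{heavy spike},$$

and the site stoichiometry is

$$\text{Stoichiometry (\%)} =
  \frac{\mathrm{Abs}^{\text{mod}}}{\mathrm{Abs}^{\text{mod}} +
  \mathrm{Abs}^{\text{unmod}}} \times 100 .$$

## Mass and transition arithmetic

`neutralMass()` is the canonical mass: sum of monoisotopic residue masses,
plus water, plus modification deltas, plus the heavy-label shift.
Fragment ions follow the standard rules: $y_n$ sums the $n$ C-terminal
modified residues plus water plus one proton per charge; $b_n$ sums the
$n$ N-terminal residues plus the protons. Two conventions matter:

* Some assay documentation reports "calculated monoisotopic molecular
  mass" as neutral mass plus one hydrogen *atom* (1.007825 Da);
  `tableMass()` reproduces that display convention while all internal
  math stays neutral.
* Printed m/z values are given to one decimal, rounded half away from
  zero; `mzRound()` implements exactly that and is used only for display
  and comparison. Declared (instrument-exported) Q3 values are accepted
  within the 0.25 m/z method-match tolerance, with a warning when they
  disagree with computation by more than 0.05 m/z
  (`checkDeclaredTransitions()`).

```{r masses}
p <- studyPeptides()
mzRound(tableMass(p$lightAc), 4)
mzRound(precursorMz(p$lightAc, 2))
mzRound(fragmentMz(p$lightAc, "y", 7))
```

### The isobaric positional isomer

K9[Ac]K14[Poy] — acetyl and propionyl swapped between the two lysines —
has exactly the same elemental composition as the target, hence the same
precursor m/z. Any product ion the two species share measures their *sum*,
not the target. `isobaricOverlapFilter()` screens candidate ions against
the isomer's fragments: y1–y3 (R, PR, APR) span neither lysine, are
identical in both forms, and are excluded; y4–y8 each contain exactly one
of the two lysines and therefore separate the forms by the
acetyl/propionyl difference of 14.016 Da.

```{r isobar}
iso <- modifiedPeptide("KSTGGKAPR", "1:Ac;6:Poy")
flt <- isobaricOverlapFilter(p$lightAc, iso,
                             data.frame(ion_type = "y", ion_index = 1:8))
flt$retained$ion_index
```

A design choice sits here. The default screen compares candidates against
the isomer's **y-ion series**: it asks whether a transition can
*distinguish* the positional isomers, which is the criterion the deployed
transition set (y6/y7/y8 for every peptide) satisfies. Screening against
the b-series as well (`isobarIonTypes = c("y", "b")`) is stricter: the
isomer's b7 ion lies only 0.011 m/z from the target's y7, a genuine
near-isobaric interference that a unit-resolution quadrupole cannot
separate. We expose both because the strict screen would reject ions the
deployed assay uses; in practice b-ion interference is intensity-limited
and is monitored instead through the transition-ratio QC below.

## The synthetic-data generator

No raw instrument data ships with the package; a generator produces peak
tables (and optionally chromatograms) with the statistical structure the
assay assumes, so every downstream stage is testable.

* **Design** (`assayDesign()`): seven calibration levels 0.5, 1.25, 5, 50,
  500, 1250, 2500 fmol/µL in five replicate injections, nine matrix
  blanks, QC at 12.5 fmol/µL, constant 100 fmol light internal standard
  in calibration runs, and a 50 fmol/µL heavy spike in donor runs.
* **Noise** (`noiseModel()`): peak areas are multiplied by a lognormal
  with mean exactly 1 ($\sigma^2 = \log(1 + cv^2)$, $\mu = -\sigma^2/2$),
  so mean areas are unbiased. The default `areaCv = 0.05` reflects a
  well-behaved targeted assay with replicate CVs of a few percent. The
  peptide-level area is split across y7/y8/y6 by fixed fractions
  (0.45/0.30/0.25, a typical intensity ordering) and each transition gets
  independent noise at half the peptide CV, giving transition-ratio QC
  realistic structure. Note a consequence: a light:heavy *ratio* of two
  independent 5 %-CV signals has CV $\sqrt{2}\times 5\% \approx 7.1\%$,
  and 5-replicate CV estimates scatter roughly between 3 % and 13 %.
* **Blanks** carry a small rectified-normal residual heavy signal
  (`blankAreaSd = 50` area units against a response of 1000 area units
  per fmol/µL), which places the blank-derived detection limit at the
  0.1–0.2 fmol/µL order a sensitive MRM assay achieves.
* **Retention time**: one jittered value per injection, shared by all
  transitions and label states — light and heavy co-elute by
  construction, which is what the coherence check verifies.
* **Donors** (`defaultDonorScenarios()`): six donors × three conditions
  (CIC, CIM, MIM: Meth exposure relative to HIV infection) × three
  technical replicates. Baseline stoichiometries span 10–35 % across
  donors; three donors respond to Meth exposure with an increase
  (CIM ×1.15, MIM ×1.40) and three with a decrease (×0.95, ×0.75),
  emulating the heterogeneous, donor-specific response patterns primary
  human cells show. Total peptide concentrations (60–160 fmol/µL) sit
  inside the validated linear range.

What the generator does **not** emulate: isotope envelopes, ion
suppression and matrix effects, carryover, drift within a batch, or
between-day variability. Passing tests therefore demonstrate that the
*computational* pipeline is correct and well-calibrated under the stated
noise model — not that any particular instrument meets these figures of
merit.

## Signal processing

Peptide areas are sums of transition areas (`sumTransitionAreas()`,
`peptideAreas()`); ratios are computed per injection and statistics taken
over injections, never as ratios of means (`computeRatios()`). A zero
heavy area flags the record rather than producing an infinite ratio;
flagged records are excluded downstream with a warning. A zero light area
is a valid observation (analyte below detection, ratio 0).

The trace integrator (`integratePeak()`) uses the trapezoid rule with a
baseline equal to the mean of the first and last three window samples and
clips negative net areas at zero. Commercial peak integration algorithms
are proprietary; at the signal-to-noise of this assay the choice is
second-order, and the integrator is validated against the closed-form
Gaussian mass (relative error below 0.2 % over random peaks) rather than
against any reference software. The default window is ±8 peak sigmas.

## Assay validation

The endogenous analyte is always present in the histone matrix, so the
calibration is **reversed**: the heavy standard is varied against a
constant light internal standard, and the curve is fit as unweighted
ordinary least squares of $\log_{10}(\text{heavy:light ratio})$ on
$\log_{10}(\text{nominal concentration})$ (`fitReverseCalibration()`).
$R^2$ is reported on the log-log scale — the scale of the fit. On
noiseless data the line is exactly slope 1 with intercept
$-\log_{10}(100)$, the light-standard equivalent concentration.

Figures of merit follow common targeted-proteomics validation practice:

* **LLOD**: blank mean + 3 × sample SD of the blank signal, converted to
  concentration through the curve (`estimateLlod()`). A `rule = "3sd"`
  variant is provided because the two formulations circulate in the
  literature; the fuller mean + 3 SD is the default.
* **Accuracy / precision** per level: mean back-calculated concentration
  as % of nominal, and %CV of the replicates (sample SD, $n-1$ — the
  population/sample choice is rarely stated in assay documents; we use
  sample SD throughout) (`accuracyPrecision()`).
* **LLOQ / ULOQ**: ULOQ is the highest level passing accuracy 85–115 %
  and CV < 20 %; LLOQ is the lowest level passing the relaxed 80–120 %
  band such that all interior levels up to the ULOQ pass strictly
  (`determineLloqUloq()`). The contiguity requirement is our decision —
  the endpoint definitions alone would admit a linear range with failing
  interior levels, which no reviewer would accept; non-contiguous pass
  patterns produce a warning and an LLOQ above the last interior failure.
  A stricter 15 % CV profile can be applied by passing `cvMax = 15`.
* **Specificity**: each transition's share of the total peptide area is
  compared with the mean share over calibration standards at or above the
  LLOQ; relative deviations above 30 % are flagged
  (`transitionRatioQc()`).
* **Selectivity**: an automated surrogate for visual blank inspection —
  blank signal in the analyte retention-time window must not exceed the
  LLOD signal (`selectivityCheck()`).

## Stoichiometry and statistics

Aggregation is two-tier, mirroring how cohort results are reported:
technical replicates → per-donor mean/SD/%CV, then donor means →
per-condition summaries (`aggregateStoichiometry()`). Conditions are
compared with Welch's unequal-variance two-sample t-test
(`welchTTest()`, `compareConditions()`), two-sided, significant at
p < 0.05:

* at the **donor level** the groups are the three technical replicates —
  a pseudo-replication caveat worth stating plainly: such p-values speak
  to measurement repeatability within a donor, not to biological
  variability;
* at the **cohort level** the groups are the six donor means per
  condition, the analysis that respects biological replication.

No multiple-testing correction is applied across the three pairwise
comparisons by default (matching common practice for three planned
comparisons); `adjust = "bonferroni"` is available. Abundances below the
LLOQ are retained rather than censored — censoring policies vary and the
package makes the limit available for the caller to apply. The degenerate
zero-variance case (noiseless replicates) is resolved analytically:
equal means give t = 0, p = 1; unequal means are reported as separated
with p = 0.

## Numerical choices and degenerate inputs

* Lognormal noise is parameterized mean-1 (see above); `cv = 0` returns
  exact ones so noiseless closure is bit-exact.
* Ratios cancel shared factors exactly in floating point (identical
  transition-fraction sums multiply both numerator and denominator), so
  the noiseless pipeline recovers ground truth to machine precision.
* Non-positive ratios are dropped from the log-log fit with a warning;
  fewer than three surviving levels is fatal.
* All-zero blanks give LLOD 0; fewer than three blanks is fatal.
* `mzRound()` rounds half away from zero; R's `round()` (banker's
  rounding) would mis-render printed transition-list values.

## Problem sizes

The test suite simulates the full design (49 calibration injections, 54
donor injections) wherever a property needs it, and uses 200 seeded
3-replicate recovery simulations at 5 % noise for the parameter-recovery
property (donor means within 3 percentage points of truth in ≥ 95 % of
runs). Monte-Carlo noise checks use a few hundred traces. The whole suite
runs in about a minute on one core.

## Worked run

```{r pipeline}
res <- runPipeline(seed = 20)
v <- res$validation[["K9[Poy]K14[Ac]"]]
c(llod = round(v$llod, 3), lloq = v$lloq, uloq = v$uloq,
  r2 = round(v$r_squared, 5))
head(res$aggregated$donor, 3)
res$comparisons$cohort
```

## Limitations

* Parameter recovery is demonstrated on synthetic data; agreement with
  the generator's noise model is necessary, not sufficient, for real-data
  validity.
* The isobaric screen considers the single declared positional isomer;
  other co-eluting matrix interferences are only caught by the
  transition-ratio and selectivity checks.
* Donor heterogeneity is user-specified, not estimated from data; no
  mixed-effects modeling of the donor random effect is attempted.
* The integrator assumes a single, approximately Gaussian peak inside the
  window; it is not a peak picker for full-gradient traces.
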