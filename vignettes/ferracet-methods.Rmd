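---
title: "ferracet: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ferracet: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferracet)
```

This vignette explains the science implemented by ferracet: the
stoichiometric model behind the electron bookkeeping, the kinetics
estimators and their numerical choices, the statistical conventions, the
heme-motif scanning semantics, and what the synthetic-data generator does
and does not emulate.

## The electron ledger

Acetogens growing on ethanol first oxidise it to acetate and H2, then fix
CO2 into additional acetate with those reducing equivalents:

$$2\,\mathrm{C_2H_5OH} + 2\,\mathrm{H_2O} \rightarrow 2\,\mathrm{CH_3COOH} + 4\,\mathrm{H_2}$$
$$4\,\mathrm{H_2} + 2\,\mathrm{CO_2} \rightarrow \mathrm{CH_3COOH} + 2\,\mathrm{H_2O}$$
$$2\,\mathrm{C_2H_5OH} + 2\,\mathrm{CO_2} \rightarrow 3\,\mathrm{CH_3COOH}$$

`electronLedger()` stores these as coefficient vectors and validates, at
construction, that every reaction balances C, H and O and that the overall
reaction is the species-wise sum of the halves. The electron-equivalent
coefficients follow directly: ethanol oxidation releases 4 e-/mol (2 H2),
acetate synthesis from CO2 sinks 8 e-/mol (4 H2), H2 carries 2 e-/mol, and
Fe(III) to Fe(II) is a one-electron reduction.

When an iron-amended culture produces less acetate than its matched
iron-free control, the deficit (in mol acetate) times 8 is the electron
flow diverted out of acetogenesis (`acetateDeficitElectrons()`); the ratio
of Fe(II)-electrons to diverted electrons (`diversionEfficiency()`) says
how much of that diverted flow reached iron. We return the exact quotient
and leave rounding to the caller: 58/248 is 0.2339, which one may well
report as "about 24%". Negative deficits — possible because replicate
noise is a few percent of the control acetate, the same order as the
deficit itself — are clamped to zero and flagged rather than raised.

Biomass electrons are deliberately not modelled: diverted electrons that
do not appear in Fe(II) are reported as unattributed, because the
measurements available (acetate, Fe(II)) cannot distinguish biomass
incorporation from other sinks.

Gas loadings use the ideal gas law with R = 8.314 J mol^-1 K^-1 and a
default temperature of 303.15 K (cultivation at 30 °C). Note that 80 kPa
partial excess of H2 (80% of 200 kPa) in a 48 mL headspace computes to
3.05 mmol; loadings quoted as "approximately 3.2 mmol per bottle"
presumably assume a slightly different headspace or temperature, so the
temperature is an explicit parameter rather than a constant.

Mineral loadings are matched on Fe(III) atoms: with 9 mM Fe(III) as the
reference, goethite (FeO(OH), one Fe(III) per unit) is loaded at 9 mmol/L
and hematite (Fe2O3, two) at 4.5 mmol/L (`mineralLoadingForFe()`); the
mineral table ships as an editable CSV.

## Kinetics estimators

**Rate.** The Fe(II) production rate is the ordinary least-squares slope
of total Fe(II) (mM) against time (days) inside the exponential-growth
window, reported with its standard error and R² (`fe2ProductionRate()`).
A linear slope in mM/day — not an exponential fit of Fe(II) itself — is
used because Fe(II) production tracks cumulative electron flux, which is
close to linear during active growth; it is also the unit in which such
rates are conventionally reported. Whether published rates derive from
regression or two-point differences is usually unstated; regression uses
all points and yields an uncertainty, so we use it.

**Window.** "Exponential phase" needs an operational definition; ours is
the contiguous window of observed timepoints (≥ 3) maximising the R² of a
straight-line fit of log10(cell density) versus time, with two numerical
safeguards chosen after examining the estimator's behaviour on noisy
series:

1. *Qualification.* A candidate window must contain the sampling interval
   with the fastest observed specific growth. The exponential phase, by
   definition, contains the moment of fastest growth; without this
   condition a chance-collinear stretch of stationary-phase counts
   (three or four noisy, nearly equal densities) can out-score the true
   window and contribute a near-zero slope.
2. *Tie handling.* Windows whose R² is within 0.005 of the maximum are
   ties — with 3-8 points, smaller differences in fit quality carry no
   statistical information — broken toward the longer window, then the
   earlier start.

A user-supplied fixed window overrides auto-selection. On noiseless
logistic series the safeguards never change the selection, and the
selector provably agrees with exhaustive enumeration of all contiguous
windows (property-tested against an independent enumeration oracle).

**Plateau and fractions.** Stationary accumulation is the mean of the last
two Fe(II) observations (`finalAccumulation()`; k configurable) — a
deliberately simple estimator matching how a single stationary value is
usually plotted. `fractionReduced()` is the plain percentage of the
Fe(III) input found as Fe(II); `partitionSediment()` computes
sediment-associated iron as total minus soluble, clamping and flagging
over-subtractions beyond the 0.05 mM tolerance used throughout for
iron-measurement consistency checks (below the replicate SD of the
ferrozine assay at these concentrations).

## Group statistics

`oneWayAnova()` is the classical fixed-effects one-way ANOVA (delegated to
`stats::aov`). `tukeyHsd()` computes the pairwise table directly from the
group summaries — mean difference, Tukey-Kramer standard error
$\sqrt{(MSE/2)(1/n_i+1/n_j)}$, studentized-range statistic and
`stats::ptukey` adjusted p — so that `stats::TukeyHSD` remains available
as an independent cross-check (the suite verifies agreement to 6
decimals, and that the simulated null family-wise error rate sits at the
nominal 0.05). Stars follow the figure convention *** p < 0.001,
** p < 0.01, * p < 0.05; alpha only affects flags, never the statistics.
Everything is two-sided.

## Heme-motif scanning

Heme *c* attaches at CxxCH: two cysteines forming thioether bonds and a
histidine axial ligand. The scanner knows the canonical motif and the
variants CxxxCH, CxxxxCH, CxxCK, AxxCH and FxxCH ("A/FxxCH" expanded
literally into two single-cysteine patterns). Semantics:

- Anchor residues match exactly; `x` accepts any standard residue or the
  ambiguity codes X/B/Z/U (which never satisfy an anchor). A `*`
  terminates the segment, so matches never straddle a stop.
- Default overlap policy is *non-overlapping greedy*, left to right with
  most-canonical-first precedence (CxxCH > CxxxCH > CxxxxCH > CxxCK >
  AxxCH/FxxCH): chemically, one cysteine cannot ligate two hemes. The
  *all-positions* policy reports every matching start and exists for
  sensitivity analysis; it is also the semantics against which the
  brute-force oracle tests run.
- Coordinates are 1-based; proteins only (inputs are predicted proteomes;
  no six-frame translation).

Classification: 0 motifs none, 1 monoheme, 2-5 multiheme, ≥ 6
multiheme-high. The multiheme threshold (≥ 2) is the usual MHC working
definition; the high tier marks the heme counts typical of dedicated EET
conduits. Localization predictions (TMHMM/SignalP-style) are consumed as
optional annotation only, never computed.

`panelPresence()` screens gene panels by Smith-Waterman local alignment
(BLOSUM62, gap open 11 / extend 1, via Biostrings) with Karlin-Altschul
E-values (gapped BLOSUM62-11/1 constants λ = 0.267, K = 0.041; raw m·n
search space — effective-length corrections are omitted, which is slightly
conservative at these scales). Presence requires E < 1e-4 and identity
strictly > 30%, plus — as a package extension — ≥ 50% query coverage,
because 30% identity over a ten-residue local hit is meaningless;
`strict_paper = TRUE` drops the coverage condition to reproduce the bare
two-threshold rule.

`assemblyStats()` reports contig count, total length, GC over unambiguous
bases, and N50 (scanning contigs by decreasing length until half the total
is covered).

## The synthetic-data generator

`generateCulture()` emulates the study conditions so every estimator can
be validated against known ground truth:

- logistic growth from 1.0 × 10⁶ cells/mL to a carrying capacity of
  2 × 10⁸ (ethanol) or 1 × 10⁸ cells/mL (H2) at µ = 1.0 or 0.8 /day —
  densities and timings that reproduce 14-day batch curves sampled every
  2 days;
- donor consumption (20 mM ethanol in 20 mL = 0.4 mmol, or 3.2 mmol H2
  per bottle) modelled as zero-order over an active-growth window. For
  logistic growth the time-integrated cell density — what uptake
  integrates — is effectively linear once density saturates, and the
  linear form makes the noiseless Fe(II) curve exactly linear on the ramp,
  so the OLS estimator must recover the configured rate to machine
  precision (a sharper test than approximate recovery);
- acetate = ethanol consumed + (donor electrons × (1 − f_div))/8; controls
  use f_div = 0, hence exactly 1.5 × ethanol consumed;
- Fe(II) = f_fe × f_div × cumulative donor electrons, capped at the
  Fe(III) input (with a warning when the cap binds). The fractions are
  solved algebraically per preset from the target plateau and the donor
  electron total, anchored to the organotrophic GT1 budget: 248 µmol
  diverted, of which 58 µmol (23.4%) appear as Fe(II), i.e. a 2.9 mM
  plateau and a 31 µmol acetate deficit against the control.

Presets cover four species × organotrophic/lithotrophic plus a dialysis
condition (120 mL medium, plateau at 0.2% of the Fe(III) input, the middle
of the observed 0.06-0.3% range). The two strongest reducers carry the
measured rates and plateaus (0.47/0.39 mM/day to 2.9 mM organotrophic;
0.24/0.23 mM/day to 1.9 mM lithotrophic). For the two weaker species no
rates are published, only the ordering and the fraction-reduced ranges
(13-33% organotrophic, 5-22% lithotrophic); their preset values (0.30 and
0.15 mM/day to 1.8 and 1.2 mM; 0.13 and 0.07 mM/day to 1.0 and 0.5 mM)
were fixed once inside those ranges.

**Noise model.** Concentrations receive i.i.d. additive Gaussian noise
with SD 0.1 mM by default, matching the printed replicate error bars
(±0.03-0.12 mM/day on rates). The noise is *not* truncated at zero: an
unbiased blank-subtracted assay can read slightly negative near zero, and
clamping would inflate the boundary observation (Fe(II) = 0 at t = 0) by
σφ(0) ≈ 0.04 mM, biasing the fitted rate by 2-4% — larger than the
calibration tolerance the estimators are held to. Soluble Fe(II) (drawn
around a 0.7 soluble fraction, reflecting reductive dissolution) is
clamped to the total for assay consistency; cell counts get multiplicative
lognormal noise (sdlog 0.05), since counting error scales with the count.
Controls carry structural zeros for Fe(II) (no iron, no assay).

What the generator does **not** emulate: lag phases, substrate inhibition,
stationary-phase (non-growth-coupled) iron reduction, magnetite formation
dynamics, pH/carbonate speciation, or correlated assay drift. Passing
tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to every behaviour of real cultures.

`generateProteome()` builds proteomes with known motif content: decoys are
rejection-sampled until they contain no match of any pattern under
all-positions scanning; planted proteins carry exactly the requested
non-overlapping motif copies at recorded positions (wildcard slots are
filled from residues that cannot complete another anchor, and the whole
protein is re-sampled if an accidental cross-boundary match appears).
Record order is shuffled and identifiers are opaque. Both generators are
byte-deterministic under a fixed seed, with the caller's RNG state left
untouched.

## Problem sizes used in the test suite

Property suites run at sizes chosen to make the checks sharp but quick:
motif-scanner oracle equivalence on 1,000 random sequences of 20-120
residues; assembly statistics on 20 random contig sets of up to 119
contigs; rate calibration on 200 simulated triplicates (600 series) at
noise SD 0.1, requiring the mean recovered rate within 2% of the preset;
Tukey null calibration on 10,000 simulated 4-group experiments.

## Known limitations

- The panel screen's E-values use uncorrected m·n search spaces and a
  single scoring scheme; it is a presence/absence screen, not a substitute
  for a full homology search pipeline.
- The lithotrophic "fraction of H2 electrons used for iron" depends on
  which denominator one takes (loaded vs consumed H2); the package exposes
  the raw quantities and takes no position, since loaded-H2 electron
  totals (6.4 mmol) give fractions far below commonly quoted ~10% values.
- Survey counts depend on the annotation (gene-calling) of the input
  proteome; the same genome annotated differently can shift MHC counts.
- The workflow's group statistics assume homoscedastic normal replicates,
  as Tukey HSD does; with n = 3 per group this is an act of faith
  inherited from the field's conventions, not something the data can
  verify.
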