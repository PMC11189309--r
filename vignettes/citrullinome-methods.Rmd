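---
title: "Methods: site-specific citrullinome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-specific citrullinome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citscape)
```

# Scope and model

citscape implements the quantitative analysis of proteome-wide
citrullination: the conversion of peptidyl-arginine to peptidyl-citrulline
by peptidylarginine deiminases (PADIs), detected by mass spectrometry as a
+0.9840 Da mass increment. The package covers the analysis layer between a
search engine's evidence table and biological conclusions: mass-shift
discrimination, localization filtering, quantification, stoichiometry,
inhibitor dose-response, structural context, PTM crosstalk, sequence
motifs, transcription-factor target scoring and peptide-microarray
autoantibody reactivity. It does not perform spectral searching, structure
prediction or disorder prediction; their outputs are consumed as inputs.

## Mass discrimination

Citrullination replaces the side-chain imine (=NH) with a carbonyl (=O):
a gain of one oxygen and loss of one N and one H, i.e.

$$\Delta m = m_\mathrm{O} - m_\mathrm{N} - m_\mathrm{H} = 0.984016\ \mathrm{Da}.$$

Deamidation of Asn/Gln produces the identical elemental change, so the two
cannot be separated by precursor mass; residue identity plus MS/MS
localization must do it. The nearby isotope shifts are
$^{13}\mathrm{C}-{}^{12}\mathrm{C} = 1.003355$ Da and
$^{15}\mathrm{N}-{}^{14}\mathrm{N} = 0.997035$ Da. At an instrument
accuracy of 2 mDa these three references are mutually separable;
`classify_shift()` assigns an observed shift to the unique reference within
tolerance and reports `ambiguous` otherwise — a tie is never broken by
nearest-wins, because the discrimination argument rests on separability at
the stated accuracy. Atomic masses are hard-coded from the IUPAC/CODATA
monoisotopic table at 6 d.p. so the derived constants are exact and testable
without a runtime chemistry dependency. MS/MS of citrullinated peptides
additionally shows a diagnostic neutral loss of isocyanic acid (HNCO,
43.005814 Da), tallied by `neutral_loss_summary()`.

## Localization filtering and quantification

Sites are built from PSM records with a two-tier rule using strict
inequalities: a site exists only if at least one supporting PSM has
localization probability > 0.90 (identification grade), and its intensities
pool all PSMs with localization > 0.75 (quantification grade) at the same
protein/position. Citrullination PSMs not on arginine are excluded and
counted as inconsistent rather than silently dropped. Replicate intensity
is the sum of contributing PSM intensities — the usual sites-table
convention; the alternative (maximum across PSMs) is defensible but sum
preserves the conservation property the tests assert. A replicate with no
accepted PSM is missing, never zero.

The site matrix is log2-transformed, median-centered per column, and
missing values are imputed from a down-shifted normal per column (width 0.3
column s.d., down-shift 1.8 s.d. — the standard left-censored imputation
for label-free data), under an explicit seed. The imputation mask is kept
alongside the values, and the core citrullinome (`core_sites()`) is called
on observed values only: a core site needs at least one *measured* value in
every condition.

## Stoichiometry and dose-response

Occupancy is computed as modified / (modified + unmodified) from matched
counterpart intensities. This formula is a package choice: the concept
(modification percentage of an arginine's protein copies) admits several
estimators and the counterpart-ratio form is the simplest that is
scale-invariant and bounded in [0, 1]. A missing counterpart with an
observed modified form yields occupancy 1 flagged as a boundary value; two
missing values yield NA, never 0.

Inhibitor response is modeled two ways, deliberately kept independent:

* `half_inhibition()` — model-free log-linear interpolation of the
  concentration at which the response crosses 50% of the control; the
  control (0 µM) is the reference and is not placed on the log axis.
* `fit_ic50()` — a four-parameter log-logistic fit
  $r(c) = b + (t - b)/(1 + (c/\mathrm{IC}_{50})^s)$ with the top $t$ fixed
  at the control response and the bottom constrained ≥ 0, via bounded
  Levenberg–Marquardt. Non-convergence (e.g. a flat series) is flagged and
  the interpolated value is reported as a fallback.

On noiseless slope-1 data the two agree within a few percent; the test
suite requires 25%.

## Structural and feature context

Fold enrichment of citrullination inside feature intervals uses

$$FE = \frac{Cit_i}{R_i}\cdot\frac{R_o}{Cit_o}$$

with $Cit$ the citrullinated and $R$ all arginines, inside (i) / outside
(o) the features, and a two-sided Fisher exact test on the corresponding
2×2 table of citrullinated vs unmodified arginines. Disorder regions are
maximal runs of per-residue score ≥ 0.5; long regions need ≥ 31 consecutive
residues, short regions 2–30, so the two classes partition all runs of
length ≥ 2.

The coordination number (burial proxy) counts Cα atoms within a closed
13 Å ball around a residue's Cα, excluding the residue itself; residues
with missing coordinates are skipped and counted, never treated as
distance 0. RSA profiles are compared on 50 half-open bins of width 0.02
(last bin closed at 1.0) with a two-tailed Spearman test on the paired
bin-frequency profiles — the paired structure is a package choice, the
test itself is standard. Residues predicted in several overlapping
segments take the median pLDDT and the secondary-structure label of the
most confident segment. Secondary-structure enrichment runs one Fisher
test per 8-state label per site group, BH-adjusted across the whole
family of tests.

## Crosstalk and motifs

Co-occurrence of two site sets (e.g. citrullination × arginine
mono-methylation) is an upper-tail hypergeometric test over a universe of
candidate arginines; the universe is configurable since published analyses
rarely state it, and the default here is all arginines detected in
proteins carrying either modification. Motif enrichment compares
position-specific amino-acid frequencies between foreground and background
windows (flank 7 for MS-derived motifs, 8 for 17-mer microarray peptides):
$z = (f_{fg} - f_{bg})/\sqrt{f_{bg}(1-f_{bg})/n_{fg}}$ with a two-tailed
normal p at α = 0.05; a foreground letter absent from the background is
flagged explicitly rather than given an infinite z.

## TF target scoring

Each target gene is scored $\log_2((f_c + \varepsilon_c)/(f_n +
\varepsilon_n))$, where $f_c$ and $f_n$ are the fractions of the whole
citrullinated and non-citrullinated TF groups regulating it. The log base
and the zero handling are package choices: base 2 for interpretability and
$\varepsilon = 0.5/|\mathrm{group}|$ (half a TF) per group, which preserves
the antisymmetry of the score under label swapping. Ties in the ranked
output are broken lexicographically for determinism.

## Microarray pipeline

Per chip, replicate spots of a sequence collapse to the median raw-mean
intensity, then log2. The two chips of each fluid are normalized by an
additive shift to their common mean-of-medians — symmetric by choice,
since only "normalized to each other" is specified upstream; the shift
preserves within-chip differences exactly. Pair ratios are cit log2 −
baseline log2 on the same chip, with the median across chips for pairs
present on both; z-scores standardize each fluid's ratios to mean 0, s.d.
1 across all pairs. "Most reactive" means highest z within fluid with a
lexicographic tie-break. Citrulline is encoded as lowercase `r`; the
baseline counterpart reverts every `r` to `R`. Spacing analysis counts
residues between consecutive citrullines (offsets 4 and 6 → gap 1) in
multi-citrullinated peptides. Abundance-stratified reactivity tests, per
stratum of most-abundant MS sites, whether stratum membership is enriched
in the top-reactivity set (default: top quartile by z) and reports the
signed −log10 Fisher p.

# The synthetic study

`synth_config()` defines the emulated study: 60 proteins of 150–400
residues at proteome-like composition (arginine ≈ 5.5%), 300 planted
citrullination sites and 100 deamidation decoys on N/Q, five conditions
(HL60, HL60+Ca 15′, NLC, NLC+Ca 15′, NLC+Ca 30′) in triplicate with log2
inductions 0–3, 20% of sites detectable in every condition (the planted
core), localization probabilities from Beta(20, 1), neutral-loss flags at
probability 0.8, log-normal intensity noise at 20% CV, per-condition
occupancies rising 0.07 → 0.16, and an inhibitor arm with true IC50 2 µM
(slope 1, quadruplicate, 10% CV). Structures are idealized: α-helices
(rise 1.5 Å, radius 2.3 Å, 100°/residue), extended segments (3.5
Å/residue), turn/bend linkers, and disordered blocks (score ≥ 0.5) in long
(≥ 31) and short (2–30) flavors; buried residues draw RSA around 0.10,
exposed around 0.50. Feature sampling biases sites into NLS intervals
(10×) and away from domains (0.3×). The microarray prints every peptide in
duplicate on two chips per fluid across four fluids, with a +1.5 log2
planted offset on each second chip, and plants reactivity only in the
anti-CCP-positive fluid: +2 log2 for Cit-Gly peptides, an
abundance-correlated term, and extra signal for gap-1-spaced
multi-citrullinated peptides.

Every generator is bit-reproducible under the config seed, and a ledger
records both the design and the realized draws (per-site maximum
localization, observed quantification patterns, the realized core set) so
that each pipeline stage can be checked against ground truth computed by
independent bookkeeping at generation time.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: chimeric/co-eluting spectra and false
localization, retention-time structure, shared peptides across proteins,
protein-level abundance changes confounding site quantification, missing
values that depend on intensity, isotype and affinity structure in the
antibody response, and real structural ensembles. The synthetic study
validates the statistical machinery, not instrument physics.

# Numerical choices and degenerate inputs

* Strict ">" threshold semantics everywhere the thresholds 0.90/0.75 appear.
* Mass-shift classification default tolerance 0.002 Da; ties → `ambiguous`.
* 4PL fitting: start at the interpolated half-inhibition (or geometric mean
  of positive doses), bounds bottom ≥ 0, IC50 > 0, slope > 0; a fit pinned
  at a degenerate IC50 or run on a flat series is reported as
  non-converged.
* Imputation is seeded; two runs with one seed are bit-identical, which is
  what makes the end-to-end summary byte-reproducible.
* Zero cells in enrichment tables: FE undefined (flagged) when $Cit_o = 0$
  or $R_i = 0$; the Fisher p is still computed.
* Empty inputs error early with the offending name (column, protein,
  condition) rather than propagating NA.

# Problem sizes

The suite and the acceptance script run the full synthetic study (60
proteins / 300 sites / ~3,500 PSMs), 100-replicate Monte-Carlo IC50
recovery, Fisher-vs-enumeration checks on several hundred random 2×2
tables with totals up to 60 plus exhaustive small totals, and 50-residue
coordinate clouds for the coordination-number oracle. These sizes keep a
full run in well under a minute of compute while leaving every statistical
check adequately powered; the published study's scale (14,056 sites on
4,008 proteins from deposited raw spectra) is not reproducible at desk
scale and is not attempted.

# Known limitations

* The occupancy estimator assumes a quantified unmodified counterpart from
  the same peptide species; ratio compression from co-eluting forms is not
  modeled.
* The motif statistic uses a normal approximation to the binomial; for
  foregrounds under ~30 windows it warns and should be read qualitatively.
* The Spearman comparison of RSA profiles is performed on binned frequency
  profiles; with 50 bins its p-values are comparative, not calibrated
  against per-residue resampling.
* Chip-pair normalization assumes the two chips share composition; with
  split designs (top/bottom 50% of sites on different chips) only the
  shared controls anchor the pair.
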