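# citscape

Site-specific, quantitative analysis of protein citrullination from
MaxQuant-style mass-spectrometry evidence tables, through to structural
context, autoantibody reactivity and transcription-factor target scoring.

Citrullination converts peptidyl-arginine to peptidyl-citrulline
(+0.9840 Da), removing the side chain's positive charge. It is catalyzed by
peptidylarginine deiminases (PADI4 in neutrophils), and citrullinated
proteins are the antigens behind anti-CCP/ACPA serology in rheumatoid
arthritis. The analytical difficulty is that deamidation of Asn/Gln causes
the *identical* precursor mass shift, and the natural isotope shifts
(¹³C +1.0034 Da, ¹⁵N +0.9970 Da) sit millidaltons away — so the analysis
must lean on precursor accuracy, MS/MS localization probability, residue
identity and the diagnostic neutral loss of isocyanic acid (HNCO,
43.0058 Da).

The package is organized as an analysis workflow: the computation lives in
the package (`R/`), and numbered drivers under `analysis/` run the study
stage by stage on a fully synthetic dataset with known ground truth.

## What it computes

| Stage | Core method |
|---|---|
| Mass calculus | Δm from monoisotopic atomic masses; shift classifier at 2 mDa tolerance, ties → ambiguous |
| Site filtering | identification at localization > 0.90, quantification pooled at > 0.75; median-centering; down-shifted-normal imputation (0.3 / 1.8 σ); core-site calling on observed values |
| Stoichiometry & dose | occupancy = mod/(mod+unmod); model-free half-inhibition; 4PL fit r(c) = b + (t−b)/(1+(c/IC₅₀)^s), top fixed at control, bottom ≥ 0 |
| Structure | FE = (Citᵢ/Rᵢ)·(Rₒ/Citₒ) + Fisher exact tests; disorder runs ≥ 31 (long) / 2–30 (short) at score ≥ 0.5; Cα coordination number at 13 Å; RSA histograms in 0.02 bins + Spearman; median pLDDT across segments; 8-state secondary-structure enrichment with BH |
| Crosstalk & motif | upper-tail hypergeometric site-overlap test; iceLogo-style per-position z = (f_fg−f_bg)/√(f_bg(1−f_bg)/n) |
| TF targets | per-gene log2 ratio of citrullinated vs non-citrullinated TF fractions, ranked |
| Microarray | median replicate collapse → log2 → symmetric chip-pair normalization → cit−baseline ratios → per-fluid z-scores; citrulline spacing; abundance-stratified reactivity |
| Synthetic data | every input above, generated with planted effects and a ground-truth ledger |

## Worked example

Run the staged analysis from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_sites.R
Rscript analysis/03_stoichiometry_dose.R
```

which prints (seed 1):

```
simulated 60 proteins, 3494 PSMs, 300 planted sites (100 core)
identified 300 sites (mean localization 99.31%), 100 core
neutral loss: 79.1% of spectra, 79.4% of intensity
ledger check - id set exact: TRUE; core set exact: TRUE
median occupancy per condition:
 condition median_occupancy
      HL60       0.06920269
 ...
  NLC_Ca30       0.16527107
IC50 fit: 1.81 uM (truth 2.0); half-inhibition 1.75 uM
```

Reading this: all 300 planted sites pass the 0.90 localization filter and
the 100-site basal core (sites measured in every condition) is recovered
exactly against the generator's ledger; ~79% of citrullinated spectra carry
the isocyanic-acid neutral loss (planted probability 0.8); occupancy rises
from ~7% in unstimulated cells to ~16.5% under differentiation + calcium
(planted 7% → 16%); and the fitted IC50 of the inhibitor arm lands near the
planted 2 µM. Stages 04–07 add the structural story (citrullination on
exposed, disordered arginines — NLS fold-enrichment ≈ 2.9, domain FE ≈
0.37, mean coordination number 8.8 vs 10.5 for background arginines), the
methylation-overlap and motif tests, TF target ranking, and the microarray
read-out in which a Cit-Gly (+1 glycine) recognition motif appears in the
anti-CCP-positive fluid only.

A one-call equivalent of the whole study is:

```r
library(citscape)
res <- run_citrullinome(run_config(seed = 1), out_dir = "results/run")
str(res$summary)
```

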