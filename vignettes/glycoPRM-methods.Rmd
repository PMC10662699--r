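---
title: "Serum glycoproteomics PRM pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum glycoproteomics PRM pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPRM)
```

## The problem this package addresses

Serum testing for prostate cancer rests on prostate-specific antigen
(PSA), which separates cancer (PCa) from benign prostatic hyperplasia
(BPH) poorly in the diagnostic "grey zone" (total PSA between 4 and
10 ng/mL). One strategy for a better serum test is to quantify a panel
of formerly N-glycosylated peptides — surrogates for mid- and
low-abundance glycoproteins — by parallel reaction monitoring (PRM)
after titanium-dioxide glycopeptide enrichment, and to combine those
peptide abundances with routine clinical variables in a multivariate
classifier.

glycoPRM implements the computational side of such a study end to end:

1. **Discovery-phase candidate filtering** — fold-change, p-value,
   sequon, length and missed-cleavage rules that turn differential
   peptide tables into a targeted-assay candidate list.
2. **Verification-phase run QC** — replicate concordance by the scaled
   relative difference (SRD) of reference-glycopeptide sums, and a 2-SD
   low-recovery rule.
3. **Normalization** — internal-standard (heavy peptide) correction and
   enrichment-efficiency normalization, then replicate averaging into a
   sample-by-feature matrix.
4. **Consensus feature selection** — five selectors, each capped at 20
   variables, combined by a 4-of-5 vote.
5. **Classification and voting** — five classifiers with bootstrap
   confidence intervals, DeLong comparison against the tPSA-only
   baseline, and hard/soft ensemble voting on grey-zone samples, plus a
   re-parameterized aggressive-vs-indolent (AG/NAG, by Gleason score)
   sub-analysis within the cancer group.

Because the measured cohort exists only as raw mass-spectrometry files,
every stage is exercised against a synthetic-data generator that
emulates the study design; the generator is first-class, tested code.

## The measurement model

For run $r$ of sample $i$ and target peptide $n$, the simulated light
(endogenous) XIC area is

$$L_{irn} = B_n \cdot \mathrm{FC}_n^{[i \in \mathrm{PCa}]} \cdot
  b_{in} \cdot E_{ir} \cdot \varepsilon_{irn},$$

where $B_n$ is a per-peptide baseline drawn log-uniformly across five
orders of magnitude (mirroring the dynamic range of the measured
panel), $\mathrm{FC}_n$ the planted case/control fold-change, $b_{in}$
lognormal biological (inter-individual) variation, $E_{ir}$ the
lognormal per-run enrichment-recovery factor — TiO~2~ glycopeptide
capture is the dominant source of run-to-run variability — and
$\varepsilon$ lognormal measurement noise. Heavy internal standards are
spiked *after* enrichment, so their areas $H_{irn}$ carry the spike
level and noise but no $E_{ir}$. Thirty reference glycopeptides scale
with the same $E_{ir}$; their per-run sum $C_{ir}$ is the recovery
readout.

Processing inverts this model:

* **SRD**: $(C_{i1} - C_{i2}) / (\bar{C_i}\sqrt{2})$, with
  $|\mathrm{SRD}| > 0.50$ (about a twofold recovery difference)
  discarding the lower-recovery replicate.
* **IS correction**: $L' = (H_m / H_n)\, L$, with $H_m$ the peptide's
  mean heavy area over the retained runs — a per-run instrument
  response factor multiplies $L$ and $H_n$ alike and cancels.
* **Enrichment normalization**: division by $C_{ir} / C_a$, cancelling
  $E_{ir}$; $C_a$ is the average reference sum over the retained run
  set and only fixes the unit of the output (hence the `c_a` argument
  of `assemble_matrix()`, used by the scale-invariance tests to hold
  the unit constant).
* **Replicate averaging** completes the matrix.

The end-to-end consequence, asserted to $10^{-9}$ relative tolerance in
the tests: multiplying one run's enrichment factor by $k$ leaves the
assembled matrix unchanged.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `p_max`, `fc_min`, `fc_rescue_min` | 0.1, 1.2, 1.08 | discovery filter thresholds; the rescue branch needs literature support |
| `max_length`, `max_missed_cleavages` | 25, 2 | assay-suitability limits; 2 matches the database-search allowance, and retained discovery candidates do contain peptides with one internal K |
| `srd_max`, `sd_mult` | 0.50, 2 | run-QC rules |
| `cap`, `min_votes` | 20, 4 | consensus feature selection |
| `holdout_greyzone`, `train_frac` | 20, 0.70 | split design (163 = 143 + 20; 143 at 70% = 100/43; 79 at 70% = 55/24) |
| `enrichment_cv` | 0.25 | run-to-run TiO~2~ recovery (lognormal sd); at this spread the one-sided 2-SD bound is meaningful (a heavier tail would push it below zero) |
| `biological_cv` | 0.30 | inter-individual variation of serum proteins, a typical ~30% CV |
| `measurement_cv`, `heavy_spike_cv` | 0.10, 0.05 | technical noise; the study reports only discovery-phase median CVs, so these are configurable defaults, not claimed study values |
| `frac_discordant_runs`, `frac_low_recovery_runs` | 0.10, 0.02 | injected failures; the emulated design lost ~10% of its 326 runs |

Clinical variables are lognormal, parameterized by matching each
group's median and interquartile range (markers of this kind are
strictly positive and right-skewed). Note that a lognormal matches a
median and an IQR *ratio*; printed IQR bounds that are asymmetric
around the median on the log scale (as real tPSA quartiles are) cannot
both be matched exactly, and the tests assert median and quartile-ratio
convergence accordingly. The free/total PSA ratio (ftPSA) is derived as
$100\,\mathrm{fPSA}/\mathrm{tPSA}$ times small lognormal noise so that
it remains consistent with its parts; its implied group medians
(≈17.8% PCa, ≈33.8% BPH) land close to the configured reference values
(16 and 35).

Planted fold-changes default to the discovery-table values mapped onto
the final 31-peptide verification panel (28 internal-standard
quantified, 3 label-free); peptides that entered the panel through the
qualitative deep-fractionation route default to 1.0. Aggressiveness
effects default to a moderate 1.2× on the peptides of the proteins in
the AG/NAG predictor, plus a 1.2× proPSA shift.

Injected discordant pairs multiply one replicate's enrichment factor so
the pair's SRD is exactly 0.6 before noise — a deterministic violation
of the 0.50 rule. Injected low-recovery runs scale a run's enrichment
to 5%; at most one injected failure per sample, so every subject stays
analyzable (in a duplicate design such a run also makes its pair
discordant, and the SRD rule, which takes precedence in the reason
taxonomy, catches it first; clean 2-SD exclusions arise in singleton
designs).

## Numerical and procedural choices

* **Sequon rule.** N-X-S/T with X ≠ P (the standard biochemical
  convention; a flag lifts the proline exclusion). A motif whose S/T
  lies beyond the tryptic C-terminus is invisible to a peptide-level
  scan — three peptides of the packaged candidate table are in this
  situation — so curated tables carry the annotated glycosite, and the
  filter prefers the annotation when present.
* **Boundary semantics.** Fold-change comparisons are inclusive (≥),
  since printed tables retain values sitting exactly on the thresholds
  (1.20 under "at least 1.2", 1.09 under "above 1.08").
* **QC order and statistics.** The mean and SD of the reference sums
  are computed over all runs before any exclusion, in a single pass;
  the 2-SD rule is one-sided (low recovery only). The surviving partner
  of a discordant pair is exempt from the 2-SD rule so the combined
  rules can never discard both replicates of a sample.
* **Missingness.** A peptide present in only one replicate is averaged
  over what is available; a peptide absent from all of a sample's runs
  is imputed at half the cohort minimum and flagged.
* **Selectors.** The chi-square selector scores min-max-scaled features
  (the statistic needs non-negative input). Recursive feature
  elimination uses an L2-logistic base estimator with balanced class
  weights and step size 1. The L1-logistic selector takes the nonzero
  coefficients at the 5-fold cross-validated one-standard-error
  regularization — the parsimonious standard choice — truncated to the
  cap by standardized coefficient magnitude. All rankings break ties by
  variable name for determinism.
* **Consensus saturation under the null.** Four of the five selectors
  are hard top-20 selectors; over 37 candidate variables they fill 20
  slots each no matter what, so under permuted labels the 4-of-5
  consensus still retains around ten variables (correlated marginal
  rankings overlap heavily). A capped-top-k consensus is a ranking
  filter, not a significance filter; the meaningful null guard —
  asserted in the tests — is that *planted* features are recovered
  only at chance rate under label permutation, far below the informed
  rate.
* **Classifiers.** Random forest with 500 trees; unpenalized logistic
  regression; k-nearest-neighbours with k = 5 on standardized features;
  radial-kernel support vector machine with Platt probabilities;
  decision tree grown without complexity penalty. All fits are seeded.
  Class metrics use a 0.5 probability cutoff; sensitivity takes the
  case group (PCa, or AG in the sub-analysis) as positive.
* **Confidence intervals** are stratified bootstrap over the test set
  (2000 resamples by default) — the predictions are resampled, not the
  fits.
* **Univariate baseline.** The tPSA comparison is the ROC of the raw
  tPSA values on the same test samples (a threshold family, no model);
  the DeLong test compares it with the random-forest scores on the
  identical samples.
* **Voting.** Models are refit on the full model-building set before
  voting on the grey zone; soft votes are weighted by each model's F1
  on the held-out test split. Ties break toward the case class —
  in a clinical triage setting a false negative is the costlier error.

## What the synthetic studies do and do not show

At the default study conditions (79 PCa / 84 BPH in duplicate, planted
discovery-scale fold-changes, configured clinical offsets), the
pipeline recovers the planted discriminative peptides — the nine panel
peptides with fold-change ≥ 1.2 — at an aggregate 4-of-5 consensus
rate of about 0.9, and the multivariate random forest beats the
tPSA-only baseline in essentially every seeded repetition. The
acceptance checks run ten seeded end-to-end studies (each a few
seconds), and `scripts/acceptance.R` runs fifty.

Two honest caveats. First, the weakest plants (fold-change 1.20–1.21
against 30% biological variation at n = 143) are individually recovered
in only ~60–80% of runs — that is the statistics of those effect sizes,
not a defect; the aggregate rate sits at the 0.9 boundary. Second,
recovery is quoted for the peptides only: the clinical PSA variables
are mutually collinear by construction (ftPSA is derived from fPSA and
tPSA), so their per-variable votes are not separately identifiable and
the selectors legitimately split votes among them — the same
vote-splitting visible in the study's own printed selection grid.

The generator emulates the *statistical* structure of the design:
group sizes, lognormal clinical markers, duplicate runs, enrichment
variability, planted failures. It does not emulate chromatographic peak
shapes, transition interference, retention-time drift, correlated
protein co-regulation, batch structure, or assay dropout patterns of
real serum PRM — so a passing synthetic suite validates the
*procedure* (formulas, rules, bookkeeping, learning machinery), not the
clinical performance of any particular panel. Accordingly the package
makes no attempt to reproduce the measured cohort's headline numbers
(multivariate AUC 0.93 vs tPSA 0.79, 17/20 grey-zone assignments,
AG/NAG AUC 0.69): those depend on data that only exist as raw MS
files. On synthetic data the separation is typically *larger* than in
the real cohort because independent lognormal features with clean
fold-changes are easier than real serum biology.

## Known limitations

* The final panel packaged here lists 31 peptides (28 IS-quantified,
  3 label-free). The printed tables support exactly these 31 sequences;
  published summary counts around the panel (32 peptides / 30 proteins /
  29 IS precursors) are not mutually reconstructible, so the protein
  count is always computed from the table, never asserted.
* Whether feature selection should see the full 143-sample
  model-building set (the default here) or only the 100-sample training
  split is a leakage-sensitivity question; both are supported
  (`select_features()` on any subset), and the default mirrors the
  two-stage description of the emulated design.
* Precursor-level accounting (charge states, oxidized forms) is not
  modeled; the simulation works at the peptide level.
* The pipeline's R functions are the interface; `run_pipeline()` plus
  the writers cover orchestration, and `scripts/acceptance.R` is the
  only shell entry point.
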