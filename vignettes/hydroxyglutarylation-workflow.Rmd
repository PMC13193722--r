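---
title: "Detecting chirally dependent protein O-2-hydroxyglutarylation: methods and design"
author: "hgmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chirally dependent protein O-2-hydroxyglutarylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgmod)
```

## The modification and its mass signature

2-hydroxyglutarate (2HG) is an oncometabolite: its D enantiomer accumulates
in IDH1/2-mutant tumours, its L enantiomer under hypoxia. Either can form an
ester with the hydroxyl of serine, threonine or tyrosine, adding a net
C5H6O4 group to the residue:

```{r}
mod_2hg()
```

All mass arithmetic is built on a fixed internal table of monoisotopic
atomic masses (NIST values, 9+ decimals), so every derived constant is
reproducible offline. The key constants, recomputed rather than stored:

* adduct mass `composition_mass("C5H6O4")` = `r sprintf("%.4f", composition_mass("C5H6O4"))` Da;
* channel-B neutral loss `composition_mass("C5H8O5")` = `r sprintf("%.4f", composition_mass("C5H8O5"))` Da
  (adduct + water, leaving a dehydro residue);
* the two channels differ by exactly one water;
* the d4 isotopologue (C5H2D4O4, from feeding deuterated 2HG) shifts the
  adduct by `r sprintf("%.4f", d4_shift())` Da — the nominal "+4 Da" of
  heavy/light pairs.

Because D2HG and L2HG are enantiomers, they are strictly mass-identical;
chirality is never encoded in any mass and appears only in the experimental
design labels used by the quantification stage. Esterification could engage
either carboxyl of 2HG; the two products are mass-identical, so the adduct
is modelled as a single net composition. Cysteine carbamidomethylation
(+57.0215 Da, from chloroacetamide alkylation) is a fixed modification,
default on, toggleable everywhere via `carbamidomethyl = FALSE`.

## In silico digestion

`trypsin()` cuts after K/R with the Keil rule (no cleavage before proline;
the field-standard convention, switchable off). `gluc()` defaults to
phosphate-buffer specificity (cuts after both E and D), because the
sequential protocol this models adds GluC in phosphate buffer; bicarbonate
mode (E only) is selectable. `sequential_digest()` applies trypsin then
GluC, composing coordinates back to the protein frame; with no missed
cleavages this provably equals cutting at the union of both site sets, and
the test suite checks that equivalence against an independent position-wise
cutter on random sequences.

Missed cleavages default to 2 per protease (typical search-engine
settings; the underlying protocol does not state a value). Coordinates are
1-based inclusive throughout, the R/Bioconductor idiom; user-facing site
labels ("S719") are 1-based in any convention, so outputs are unaffected.

`predict_redigest_loss()` explains why sequential digestion loses many
peptides found with trypsin alone: re-cleaving a modified tryptic peptide
with GluC often leaves the modification on a fragment that is too short to
identify (default threshold < 7 residues) or that has lost every basic
residue (K/R/H) and thus ionizes poorly.

## Fragmentation and diagnostic neutral losses

`theoretical_fragments()` generates b/y ions only (HCD/CID-style; annotated
spectra of this modification show b/y plus losses, so a-ions and internal
ions are omitted). For every ion whose residue span covers a modified site,
two neutral-loss variants are added: channel A subtracts the full adduct
(restoring the unmodified backbone mass — a useful identity, checked in the
tests) and channel B subtracts adduct + water. For d4-labelled peptides the
deuteriums leave with the adduct, so heavy loss masses shift by +4.0251 Da
and the loss-variant ions of a heavy/light pair coincide exactly — which is
why pair validation (below) expects the +4 shift only on intact
mod-containing ions. Fragment charges default to {1, 2} for precursor
charge >= 2, else {1}.

## Spectrum matching, localization, loss detection, pairing

The matcher is a self-contained scorer sufficient for validating the
pipeline on synthetic data, not a full search engine: candidates within a
precursor tolerance (default 20 ppm) are scored by the sum of
log(1 + relative intensity) over theoretical ions matched greedily at
10 ppm (TIMS-TOF-class accuracy), each peak used once; ties break by fewer
modifications, then sequence.

Site localization is Ascore-like: for each candidate S/T/Y site the score
is the number of matched *site-determining* ions — ions (including loss
variants) whose m/z differs between site hypotheses — and `delta_score` is
best minus runner-up, with an `Inf` sentinel for single-site peptides. A
site is treated as confidently localized when `delta_score >= 1`
(configurable downstream).

`detect_neutral_loss()` checks charge-reduced precursor-loss positions at
every charge up to the precursor charge, plus all fragment loss variants,
and records presence and the maximum relative abundance per channel.
Relative abundance is expressed as a fraction of the base peak (a design
choice; any other baseline would rescale the bins). Frequencies are binned
as high (> 5%), mid (1–5%], low (0–1%], absent, with the 5% boundary
falling in the mid bin.

`find_isotope_pairs()` validates heavy/light duos by three simultaneous
criteria: precursor masses differing by 4.0251 Da per modification (10 ppm),
retention times within 1 min, and fragment-ladder consistency — every
shared unshifted ion identical, every shared intact mod-containing ion
shifted by 4.0251/z. The d4 reagent is racemic, so pairs validate the
modification chemistry, not its chirality; accordingly no PSM field carries
an enantiomer label.

## Quantification and the chirality call

Peak areas are normalized to total ion current (`tic_normalize()`: divide
by the column TIC, rescale by the median TIC). `classify_modified()`
implements the published decision rule: a peptide responds when fold change
> 1.2 AND p < 0.05, with no multiple-testing adjustment by default (a
Benjamini–Hochberg option exists but is off, matching the stated rule).

Two statistical choices deserve explanation:

* **Test scale.** The t-test runs on log-transformed areas by default.
  Peak areas — real and simulated — are lognormal, so the t-test's
  normality and equal-variance assumptions hold on the log scale and fail
  on the raw scale; log-intensity testing is also what the standard LFQ
  tools do. Fold change is still reported as the ratio of raw-scale
  replicate means. Raw-scale testing remains available
  (`log_transform = FALSE`) and is pinned by a worked-oracle test.
* **Pooled vs Welch.** The default is the pooled-variance (Student) test.
  With n = 3 per group the Welch–Satterthwaite approximation is markedly
  conservative (measured type I error ≈ 0.033 at nominal 0.05, because the
  estimated df is random between 2 and 4), while replicate groups share a
  common CV by design, making the pooled test exact. Welch is available
  via `var_equal = FALSE`.

`chirality_call()` assigns an enantiomer per peptide: a dose series
"responds" when >= 2 nonzero dose levels pass the rule against vehicle and
fold changes are non-decreasing in dose. Monotonicity is enforced with a
20% relative tolerance (`mono_tol = 0.2`): at CV 0.15 with n = 3 the
difference of two log fold changes has an SD of about 0.12, so a strict
non-decreasing rule would reject roughly a quarter of genuinely monotone
peptides per adjacent dose pair; the tolerance is sized to that noise
scale. Calls are D (only the D series responds), L, shared (both), or
ambiguous.

`high_confidence_filter()` retains peptides with the same non-ambiguous
call in >= 2 independent dataset groups and drops conflicting calls. This
is a deliberate, simple stand-in for a more elaborate cross-validation
workflow whose exact rules are not public; treat its output as "replicated
and consistent", nothing stronger. `overlap_sets()`, `occupancy()`
(modified/(modified+unmodified)) and `paired_rt_test()` (paired two-tailed
t-test on RT differences; zero-variance inputs return a degenerate flag
instead of a p-value) complete the reporting toolkit.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the emulated study conditions: 3 biological
replicates per condition; dose gradients 0/5/10/20 (arbitrary units
mirroring mM) for each enantiomer against one shared vehicle; modification
sites sampled S:T:Y at 0.6:0.3:0.1 (the observed serine > threonine >
tyrosine pattern); lognormal replicate noise at CV 0.15; 20% spurious
MS/MS peaks and intensity jitter CV 0.2; neutral-loss emission
probabilities 0.95/0.85 per channel with relative abundances 0.5–15% of
the base peak (most identifications show losses, some at low abundance);
and a +1.5 min retention-time shift for modified peptides on top of a
hydropathy-sum gradient surrogate.

Planted top-dose fold changes are drawn Uniform(2, 4) — the magnitude range
shown by responsive peptides under dose-gradient treatment — and the
dose-response interpolates log-linearly in log1p(dose) from 1 at dose 0 to
the true value at the top dose (the data show monotone trends but no
functional form; any smooth monotone interpolant would do). The abundance
matrix also carries 800 background peptide rows that never respond: in
real label-free runs the TIC is dominated by the unmodified bulk proteome,
and without that bulk the planted effects would inflate the normalizer
itself (by about 14% at the top dose) and TIC normalization would absorb
part of the very signal under study. Background rows double as an
in-matrix null: their false-call rate is directly observable.

Not emulated: chromatographic peak shapes, isotope envelopes, ion-mobility
separation, m/z calibration error (synthetic peak positions are exact, so
matching tests exercise tolerance logic only through spurious peaks),
missing values, and between-replicate batch structure. Passing tests
therefore demonstrate the pipeline's internal correctness and statistical
calibration under its own noise model — not performance on real data,
where search-engine scoring and FDR control (out of scope here) dominate.

Determinism: every generator stage derives an independent stream from
`config$seed` and restores the caller's RNG state; the same config is
byte-identical across runs, and the ground-truth ledger is a separate
return value that analysis functions never accept as input.

## Numerical and edge-case choices

* Masses are compared/reported at 4 decimals, matching how the constants
  are printed in the literature; internal arithmetic is full double
  precision.
* Noiseless replicate groups (CV 0) make the t statistic undefined; the
  classifier then reports p = 0 when means differ and p = 1 when equal,
  so noiseless fixtures behave as the limits of the noisy case.
* A zero control mean leaves the fold change undefined; the peptide is
  flagged and excluded from calls rather than guessed.
* Subtraction of elemental compositions that would go negative, unknown
  element symbols, modifications on non-target residues, duplicate sites,
  out-of-range sites, non-positive TICs and empty charge sets are all hard
  errors naming the offending entity.
* Matching ties break deterministically (score, then fewer modifications,
  then sequence); localization ties break toward the smaller site index.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from code:
200 random proteins for the digestion oracle; 1000 null peptides for
t-test calibration; 200 planted peptides (about 90 D / 90 L / 20 shared)
for end-to-end enantiomer recovery; 300 noisy spectra for localization
recovery; 20–25 peptides for the clean-limit neutral-loss, isotope-pair
and RT checks. These sizes give binomial standard errors comfortably
inside the asserted margins while keeping a full run in tens of seconds.

## Known limitations

* The matcher has no decoy model or FDR estimate; scores are comparable
  only within a spectrum's candidate set.
* Localization uses matched-ion counts, not probabilistic scoring; with
  few site-determining ions, `delta_score` saturates at small integers.
* One variable modification per peptide is assumed throughout the
  localization and pairing logic (multiply-modified peptides are supported
  in mass/fragment arithmetic only).
* The high-confidence filter is a consistency heuristic, not a validated
  error-control procedure.
* Occupancy is semi-quantitative: it ignores ionization-efficiency
  differences between modified and unmodified forms.
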