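---
title: "Cross-reactive epitope discovery with a degenerate TCR recognition motif"
author: "mimoScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-reactive epitope discovery with a degenerate TCR recognition motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimoScan)
```

## The problem

A single T-cell receptor (TCR) can be polyspecific: it recognises many
different peptides that share a few key residues -- a recognition motif --
rather than one exact sequence. For an autoreactive, HLA-C\*06:02-restricted
TCR this matters clinically, because environmental proteins (food crops,
microbiota, pathogens) may carry peptides that satisfy the same motif and
thereby trigger or sustain the autoimmune response as mimotopes of the self
antigen.

`mimoScan` implements the full computational side of such a study:

1. **Motif inference** (`inferCriticalPositions`, `buildFrequencyModel`,
   `deriveRecognitionMotif`): which nonamer positions are functionally
   critical, and which residues are tolerated there.
2. **Proteome scanning** (`compileSearchPatterns`, `scanProteome`,
   `completeNonamer`, `curateHits`, `rankHits`): find every peptide in a
   protein database that satisfies the motif, complete it to the nonamer
   register, and filter on curation rules.
3. **Assay statistics** (`stimulationIndex`, `compareTwoGroups`,
   `compareMultipleGroups`): the nonparametric statistics used for
   proliferation and CD137 activation readouts.
4. **Diet-cohort analysis** (`classifyResponse`, `classifySerology`,
   `serologyResponseAssociation`, `summarizeCohort`): response
   classification and serology association for a gluten-free-diet cohort.
5. **Synthetic data** (`generateProteome`, `generateAssayDataset`,
   `generateCohortTable`): seeded generators with ground truth, so every
   stage is testable end to end without laboratory data or downloads.

## The motif model

Peptides presented by HLA-C\*06:02 are nonamers (positions P1--P9); in the
octamer register the NH~2~-terminal residue corresponds to P2 and P1 is
absent. A `RecognitionMotif` assigns each position one of:

* **fixed** -- a single allowed residue (a singleton allowed set),
* **allowed** -- a small residue set,
* **free** -- unconstrained,

plus an independent **forbidden** map used at the curation stage, and role
annotations (HLA anchor at P2 and P9, auxiliary anchor at P7, TCR contacts
at P5 and P8). The worked motif throughout this vignette is the
five-position constraint set derived from alanine-scanning mutagenesis and
the stimulatory ligand panel of an autoreactive psoriatic TCR:

```{r motif}
motif <- RecognitionMotif(
  allowed = list(P2 = "R", P5 = c("R", "N", "Q"), P7 = c("R", "L"),
                 P8 = "R", P9 = c("L", "M", "V", "F", "I")),
  forbidden = list(P6 = "R"),
  annotations = c(P2 = "HLA anchor", P5 = "TCR contact",
                  P7 = "auxiliary anchor", P8 = "TCR contact",
                  P9 = "HLA anchor"))
motif
```

### Critical-position inference

An alanine scan reports residual activation (as a fraction of the
CD3-normalised response) after substituting each position.
`inferCriticalPositions` thresholds this profile: the default
`abolition_threshold = 0.2` separates "completely abolished" near-zero
responses from tolerated substitutions; it is a unitless fraction of the
positive-control response. Positions missing from the profile are reported
as untested, never silently treated as critical. When a position is probed
with several substitutions (anchor-exchange panels at P2/P9), the alanine
row defines the profile value, because criticality is defined on the
alanine substitution; tolerated anchor exchanges instead widen the allowed
set.

### Frequency model and logo numerics

`buildFrequencyModel` counts residues per nonamer position across the
stimulatory ligands; octamers contribute to P2--P9 only. The per-column
information content is $IC_j = \log_2 20 - H_j$ bits with $H_j$ the Shannon
column entropy -- the sequence-logo column height. Two numerical choices are
deliberate:

* **pseudocount default 0**: ligand panels are small (tens of peptides) and
  the published logos are unsmoothed observation summaries. The knob exists
  (`pseudocount`) and should be positive whenever frequencies feed log-odds
  scores (`rankHits`), where a zero frequency would give $-\infty$.
* **no small-sample entropy correction**: with a handful of sequences the
  correction would dominate the signal, and the allowed sets are taken from
  observation unions, not from IC.
* a column with no observations and pseudocount 0 (P1 under an all-octamer
  panel) has `NA` frequencies and `NA` IC rather than an arbitrary value.

### From frequencies to the motif

`deriveRecognitionMotif` constrains exactly the critical positions. The
default `allowed_fraction_threshold = 0` admits every residue observed at
least once among stimulatory ligands -- published allowed sets for such
panels are observation unions, and any frequency cut-off would have to be
justified against a panel too small to estimate frequencies reliably. The
threshold is exposed for larger panels. A threshold that empties a position
is an error, not a silent free position.

## Pattern compilation and scanning

`compileSearchPatterns` expresses the motif in the octamer register
(pattern character $i$ = nonamer position $P_{i+1}$) as plain strings over
residue letters and the wildcard `X`; a PROSITE-bracket dialect is provided
for interchange. Two policies exist because published search matrices are
often a curated subset of the combinatorial space:

* `"cartesian"` enumerates the full allowed-set product
  ($3 \times 2 \times 5 = 30$ patterns for the motif above);
* `"explicit"` takes a configured list and validates each pattern against
  the motif, erroring on an unlicensed residue and flagging (not rejecting)
  a wildcard at a constrained position, which published matrices sometimes
  use at the auxiliary anchor P7.

```{r patterns}
pats <- compileSearchPatterns(motif, "explicit", combinations = c(
  "RXXRXXRL", "RXXNXRRL", "RXXRXRRL", "RXXNXLRL",
  "RXXRXLRL", "RXXQXLRL", "RXXRXLRM", "RXXRXRRM"))
pats[, c("pattern", "P5", "P7", "P9", "wildcard_relaxed")]
```

`scanProteome` tests every octamer window of every protein (overlaps
included, deterministic protein-then-offset order). Windows containing
non-standard codes (X, B, Z, U, O) are skipped and counted rather than
expanded -- a conservative choice that avoids inventing residues; the counts
are reported so a heavily masked proteome is visible. `completeNonamer`
supplements P1 from the natural protein sequence; a hit at offset 0 keeps
its nonamer absent and is flagged `no_P1` but retained, because octamers
lacking P1 can still stimulate. Coordinates are 0-based half-open
internally and 1-based inclusive in TSV output.

`curateHits` applies forbidden-residue rules (default: Arg at P6, which
blocks activation even in motif-positive peptides) and returns an explicit
kept/removed partition with named reasons -- curation is auditable, never
destructive. P3/P4 preferences are handled by `rankHits` as log-odds
against a background composition, with deterministic tie-breaking; no
default preference weights are shipped because they are panel-specific.

`expectedBackgroundMatchRate` gives the analytic per-window false-positive
rate: the product over constrained positions of the allowed-set mass. For
the motif above under a uniform composition this is
$\frac{1 \cdot 3 \cdot 2 \cdot 1 \cdot 5}{20^5} = 9.375\times10^{-6}$,
about 94 expected matches per $10^7$ windows -- the property the synthetic
proteome generator is checked against.

External peptide--HLA affinity prediction is a pluggable hook
(`annotateHlaBinding`): the built-in surrogate is the anchor-residue filter
(P2 = Arg, P9 in {L, M, V, F, I}); a user-supplied predictor annotates
scores and its failures flag hits `binding_unscored` instead of dropping
them.

## Assay statistics

The stimulation index (SI) is the central stimulated readout over the mean
unstimulated control: the **median** for cpm triplicates (robust to a
single aberrant well of a radioactive count), the **mean** for CD137
percentage duplicates (two values have no useful median). SI is
scale-invariant, so instrument gain cancels.

Group comparisons are the field's nonparametric defaults: two-sided
Mann-Whitney U for two groups, Kruskal-Wallis H (tie-corrected) for more,
Bonferroni correction ($\min(1, m\,p)$) across the family of peptides
tested within a readout. The family size is configurable because it is a
study-design choice. The exact Mann-Whitney enumeration is used up to a
combined $n = 12$ without ties, the tie-corrected normal approximation with
continuity correction beyond -- exactness where it is cheap, the standard
approximation where laboratory group sizes (tens of subjects) make it
accurate. `type1AndPowerSummary` closes the loop: under the null generator
the rejection rate at $\alpha = 0.05$ must sit in the binomial band around
0.05.

## Cohort analysis

The gluten-free-diet module consumes a patient table with the published
column structure. `classifyResponse` implements the PASI 75-or-better rule
(classes PASI75/PASI90 = responder); `pasiPercentImprovement` computes
$100(b - f)/b$ with thresholds at $\ge 75$ and $\ge 90$ percent for
prospective data. `classifySerology` calls a patient elevated when **any
available titer** reaches 10 U/ml (inclusive) -- this rule agrees with the
categorical screen for every patient with printed titers, including the one
whose combined IgG+IgA (11.1) sits above threshold while the IgA alone (2)
does not. Titer-less patients fall back to the screen (a configurable
exclusion flag exists). `serologyResponseAssociation` reports the 2x2
Fisher exact test on both bases, because either could anchor a
does-serology-predict-response claim; on the shipped table both give the
same table and $p = 0.266$ -- serology does not predict diet response.

## What the synthetic generators emulate -- and what they do not

All generators take a mandatory seed and use R's default Mersenne-Twister
stream, restoring the caller's RNG state; the same seed gives byte-identical
output.

* **Proteomes**: i.i.d. background residues (uniform by default, any
  composition suppliable) with motif-language nonamers planted at recorded,
  non-overlapping coordinates (a collision is an error). Real proteomes
  have domain structure, repeats and biased local composition; what passing
  planted-recovery tests show is that the scanner is exhaustive, not that
  real-proteome hit *counts* will match the uniform-background analytics.
* **Assays**: per-subject log-normal baselines (sdlog 0.6), multiplicative
  group effects, replicate-level log-normal noise (sdlog 0.5) -- counts are
  positive and right-skewed, so log-normal is the natural family. Defaults
  mirror the published cohort sizes (41 patients / 12 controls for
  proliferation; CD137 percentages are clipped to [0, 100]). Real assays
  have plate effects and occasional failed wells; the exclusion rule
  (`excludeFailedControls`) is exercised on synthetic data only.
* **Cohorts**: independent response and serology draws by default, with
  verbatim class/screen injection to reproduce a known table. No
  time-to-event structure is simulated.

Because per-subject laboratory values are not published, group-level
significance claims are validated only against these generators -- the
package reproduces the published *worked examples* (counts, patterns,
verdicts) exactly, and validates the *machinery* by calibration.

## Problem sizes and determinism

The test suite and the acceptance script use: 100 random sequences of
200--3000 residues for scanner-oracle equivalence, $10^7$ uniform windows
for the background-rate check (99% binomial interval around 93.75 expected
matches), 30 planted instances across 15 synthetic proteins for
sensitivity, 2000 replicates at $n = 10 + 10$ for type-I calibration, and
full enumeration up to $6 + 6$ for Mann-Whitney exactness. These sizes give
stable verdicts in seconds on a single core while keeping every stochastic
check inside a pre-registered confidence band; none of the bands were
widened after the fact.

## Known limitations

* The motif model is position-independent: it cannot express residue
  covariation between positions (the forbidden-P6 rule is a first-order
  patch for one such effect, and motif-positive peptides are still not
  guaranteed agonists).
* The anchor surrogate is a filter, not an affinity model; quantitative
  HLA binding needs an external predictor through the hook.
* The cohort module is descriptive (counts and one exact test); it is not
  a causal or survival analysis, and with 13 patients it is not powered to
  settle the serology question it reports on.
* Ambiguity codes are skipped, not expanded; a proteome rich in X runs
  conservative.
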