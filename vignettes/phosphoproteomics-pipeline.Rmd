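---
title: "Methods: 4-plex iTRAQ phosphopeptide quantification and differential calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4-plex iTRAQ phosphopeptide quantification and differential calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phospipe)
```

## Scope and data model

`phospipe` implements the downstream analysis of a 4-plex iTRAQ
phosphoproteomics experiment on urinary extracellular vesicles: three
biological groups (normal control NC, diabetes DM, diabetic nephropathy
DN) plus a pooled reference share the four reporter channels 114–117 of
every MS/MS spectrum.  The package starts where a database search engine
stops — its inputs are spectra (MGF), scored peptide-spectrum matches
(PSM tables, TSV), a protein database (FASTA with reversed decoys), and
the reagent purity matrix (CSV) — and ends with a table of differential
phosphopeptides per group comparison.

The unit of inference throughout is the *unique phosphopeptide*, keyed by
(sequence, number of phospho groups).  Positional isomers of one sequence
are one peptide; the same sequence carrying one versus two phosphates is
two.  Non-phospho variable modifications (oxidation, deamidation) do not
enter the key, because they describe the same phosphorylation event on
the same sequence.

## Stage by stage

### Mass bookkeeping and acquisition filters

Theoretical monoisotopic masses use the standard residue table plus one
water, with accurate modification deltas (carbamidomethyl 57.02146,
deamidation 0.98402, oxidation 15.99491, phospho 79.96633, iTRAQ 4-plex
144.10207 Da).  Nominal integer deltas are available through
`compute_peptide_mass(..., nominal = TRUE)` for fidelity against reports
that print them; at the 0.6 Da precursor tolerance the two conventions
validate the same PSMs for tryptic-length peptides.  Precursor charge is
restricted to the acquisition range 2+..4+ before any statistics are
computed.

### Target–decoy FDR

The false-discovery proportion at score cutoff $c$ is estimated as
$\widehat{FDR}(c) = \#\{\text{decoys} \ge c\} / \#\{\text{targets} \ge
c\}$, the simple target–decoy ratio.  The retained set is every target
rank-1 PSM at or above the *lowest observed score* whose estimate is at
most the bound (1% by default).  At tied scores, decoys and targets are
counted together on both sides, so a decoy tied with the candidate cutoff
counts against it — the conservative reading.  Decoys are never retained.
When no cutoff satisfies the bound the result is an empty set with cutoff
$+\infty$, not an error.  The implementation is a single sorted cumulative
scan; the test suite checks it against a literal brute-force scan over
every candidate cutoff on a thousand seeded instances.

### MD-score localization

For each unique phosphopeptide, candidate site placements are gathered
from all target PSMs of the same key (including rank-2 hits).  The MD
score is the Mascot-style score difference between the best placement and
the best placement with a *different* site set.  Placements with MD at or
above the cutoff (default 10) are confident.  Two deliberate readings of
under-specified corners:

* A peptide with a single observed placement (no positional isomer is
  possible, or no competitor was ever matched) is treated as unambiguously
  localized.  This matches standard MD-score practice; the alternative —
  discarding all singletons — would throw away most of the site-level
  results for no gain in error control.
* Ambiguous peptides (MD below cutoff) keep their rank-1 positions for
  reporting, are excluded from site-level summaries, but still carry
  through quantification, which keys on (sequence, phospho count) and is
  therefore indifferent to the exact site.

A related note on thresholds: the localization cutoff is 10 on the MD
(score-difference) scale, and 1.5 is the *fold-change* threshold of the
differential stage.  Descriptions that attach "1.5" to site localization
conflate the two scales; the package keeps them strictly separate.

### Reporter quantification

Reporter extraction takes, per channel, the most intense peak within
±0.1 Da of the reporter mass (4-plex monoisotopic defaults 114.1112,
115.1083, 116.1116, 117.1150; configurable).  Isotope impurity correction
solves the linear system $P\,x = \text{raw}$, where column $j$ of the 4×4
purity matrix gives the fraction of reagent $j$'s signal observed in each
channel.  Correction precedes normalization because impurity bleed is a
property of the raw reagent signal.  Exact solutions with small negative
components (noise around empty channels) are clamped to zero and counted.

Normalization factors equalize the channel totals of a designated
reference analysis (in this design, the phosphopeptide-depleted IMAC
supernatant run, which should be identical across channels up to loading
differences): $f_c = \bar T / T_c$.  When no reference run is supplied,
the factors are computed from the phosphopeptide data's own channel
totals — a documented fallback that additionally assumes most peptides
are unregulated.  Scans are corrected and normalized individually; sums
come after.

### Sum-then-ratio aggregation

A peptide observed in several MS/MS scans gets one ratio: channel
intensities are accumulated across its scans first, and the group ratio
is the ratio of the sums.  This weights scans by signal rather than
averaging per-scan ratios (the mean of ratios of the two scans
(10, 20) and (30, 40) is 0.625; the ratio of sums is 40/60 ≈ 0.667) and is
markedly more stable for weak scans.  Peptides whose denominator sums to
zero are flagged and excluded from statistics rather than silently given
infinite folds.

### The error model

Per comparison, the null distribution of log2 ratios is modelled as a
robust normal fitted on all quantified peptides: location is the median,
spread is 1.4826 × the median absolute deviation, so that a modest
fraction of genuinely regulated peptides does not inflate the null.  The
p-value of a peptide is the two-sided normal tail of its standardized
log-ratio.  A spread below `sigma_floor` (degenerate inputs, e.g.
noise-free simulations) is floored with a warning.

Because peptides are quantified over different numbers of scans, their
ratios have different precisions: a ratio summed over three scans is
roughly $\sqrt{3}$ times tighter than a one-scan ratio.  The pipeline
therefore fits the scale family $x_i \sim N(\mu, \sigma^2/w_i)$ with
weights $w_i$ = scan count: residuals are standardized by $\sqrt{w_i}$
before the MAD, and p-values use the same weighting.  Without this, the
marginal ratio distribution is a scale mixture of normals and a single
global sigma mis-sizes the tails (measured type-I ≈ 0.065 instead of
0.05 on null simulations; weighted ≈ 0.051).  `fit_error_model()` without
weights remains the plain global fit for users who want it.

No multiple-testing correction is applied by default — differential
calling mirrors the raw `p < 0.05` convention of the underlying study
design — but Benjamini–Hochberg is one argument away
(`adjust = "BH"`).  The fold threshold (1.5) is applied symmetrically on
the linear scale: `up` requires fold ≥ 1.5, `down` requires
fold ≤ 1/1.5.  Both peptide-level and protein-level tallies are reported,
since a "significant phosphoprotein" count and a "significant
phosphopeptide" count genuinely differ when one protein contributes
several peptides.

## The synthetic experiment

`generate_experiment()` produces a complete, deterministic experiment
from one seed, emulating the study conditions end to end:

* proteins drawn from a residue-frequency model (uniform draws weighted
  by proteome-like frequencies; a real FASTA can be digested instead),
  tryptic digestion with the K/R-not-before-P rule;
* 2,000 unique phosphopeptides by default, 85%/15% singly/doubly
  phosphorylated, 1–3 MS/MS scans each (exercising sum-then-ratio);
* 50 regulated peptides at 2-fold between the DN and DM channels, half
  up and half down;
* reporter intensities = truth × purity mixing × multiplicative
  log-normal noise with CV 0.1 (mean-preserving);
* decoy PSMs from reversed sequences at 10% of rank-1 PSMs, scored from
  a clearly lower distribution (targets ~ N(40, 8), decoys ~ N(20, 6),
  truncated at 0) so the 1% FDR cutoff lands between the two;
* positional-isomer competitor hits at rank 2 for 30% of eligible
  peptides, at a score gap ~ N(15, 5) truncated at 0, straddling the MD
  cutoff of 10;
* a reference run whose channel totals are equal in truth (the pooled
  supernatant analog), noise aside — so with zero noise the
  normalization factors are exactly 1 and planted folds are recovered
  exactly;
* channel map 114 = NC, 115 = DM, 116 = DN, 117 = reference.  The real
  assignment in any given study is configuration, not biology, so the
  generator fixes one and records it in the ground truth.

What it deliberately does **not** model: fragment-ion ladders and peak
shapes (spectra carry reporter peaks plus decorative fragments),
chromatographic effects, peptide-specific ionization efficiency,
ratio compression from co-isolation, or missing channels.  Passing the
recovery suites therefore demonstrates the correctness of the
*computational* chain under its stated noise model — not that real uEV
data would behave this well.  In particular, real iTRAQ ratios are
compressed by co-fragmentation, so real-data fold thresholds bite harder
than the simulation suggests.

## Numerical and design choices

* Score distributions, noise model and scans-per-peptide were fixed once
  as representative of a well-behaved Sciex 5600 experiment and are all
  configurable in `sim_config()`.
* The FDR cutoff scan, impurity solve (`solve()` on the 4×4 system),
  and normalization are exact linear algebra; the only tolerance-bearing
  steps are peak matching (±0.1 Da) and precursor validation (±0.6 Da).
* Ties in the FDR scan are broken conservatively (see above);
  deterministic ordering everywhere else comes from sorted keys, so
  collapsing and quantification are permutation-invariant and reruns are
  byte-identical.
* Degenerate inputs: empty candidate lists, zero denominators, all-decoy
  tables, and sub-floor spreads each have a defined, tested behaviour
  (error, flag, empty-set, and floored warning respectively).
* Problem sizes in the test and acceptance suites — 1,000 FDR instances
  up to 10,000 PSMs, a 5,000-peptide null experiment, and the
  2,000-peptide recovery experiment — were chosen as the smallest sizes
  at which the binomial noise of the measured rates is comfortably inside
  the asserted bands.

## Orchestration

`run_pipeline()` executes validate → charge filter → FDR → collapse →
localize → extract/correct/normalize → aggregate → error model →
differential calls → summaries, recording record counts in and out of
every stage, and returns a classed result with `print()`, `summary()` and
`plot()` (volcano).  `run_pipeline_files()` is the same pipeline from
file paths to result tables plus a JSON run manifest (counts, thresholds,
seed), and the stage functions are all exported, so any segment can be
run file-to-file from R or `Rscript`.  The package is deliberately a
library rather than a shell tool: the R session is its command line.

## Known limitations

* Protein inference is a provided peptide→accession map (first accession
  wins); there is no parsimony inference.
* The error model is global (optionally precision-weighted); the
  per-peptide replicate t-test across scans is not currently exposed.
* Only the 4-plex channel geometry is implemented and tested; the
  structures would extend to 8-plex/TMT but nothing asserts it.
* Localization is a hard MD threshold, not a posterior probability
  (no Ascore/PTM-score).
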