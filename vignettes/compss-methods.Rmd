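---
title: "Scoring and filtering generated enzyme sequences with compss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and filtering generated enzyme sequences with compss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compss)
```

## The problem

Generative protein models — family-trained GANs, masked language models
resampled over an MSA, ancestral reconstruction — produce thousands of
candidate enzyme sequences, of which only a fraction express, fold and show
activity in vitro. Screening is expensive, so the practical question is
triage: which computable properties of a candidate predict activity, and
how should they be combined into a selection filter whose benefit can be
measured against matched negative controls?

`compss` implements that machinery end to end: the individual metrics, the
calibration of a language-model score threshold on natural sequences, the
multi-stage filter with seeded draws and identity-matched controls, the
statistics used to evaluate the metrics, and the analysis of the
spectrophotometric assays that define "active". A deterministic mock
scorer and seeded fixture generators make every stage testable offline.

## Metrics and their rationale

**Tandem repeats.** Long repeats are a characteristic artefact of language-
model sampling. `kmerRepeatScore(s, k)` finds, over every start offset and
every k-mer (homopolymer k-mers included), the maximal number of contiguous
exact copies, and scores it `-1 × units`; only complete copies count. Thus
`AAAAAA` scores −6, −3, −2, −1 for k = 1..4 and `LALALALA` scores −1, −4,
−1, −2. The quality check fails a single-residue run longer than 3 residues
or a 2-mer tandem spanning more than 4 residues. Because 2-mer tandems have
even spans, the smallest failing span is 6 (three units); a homopolymer run
of 5 trips only the 1-mer rule. Limits for 3-/4-mers are off by default
(`filterPolicy(extraRepeatLimits=)` adds them), since only the 1- and 2-mer
rules are part of the standard check list.

**Charge.** `chargeProfile()` counts K and R against D and E; histidine,
cysteine and tyrosine are excluded, consistent with the integer-count
definition of net charge at neutral pH used in this setting (no pKa model;
that is deliberately out of scope).

**Alignment metrics.** `globalAlign()` performs optimal global alignment
under an affine gap model where a gap of length L costs
`open + L × extend` (defaults 10 and 2, so a length-1 gap costs 12) — the
convention of the FASTA-suite global aligners. The engine is
`Biostrings::pairwiseAlignment()`; the test suite checks it against an
independently written Gotoh dynamic programme. Identity is
`matches / alignment length` with gap columns counted as non-matching,
including terminal gaps by default (`includeTerminalGaps = FALSE` gives the
other convention, since tools differ on this point).
`closestTraining()` maximises the raw score over the training set, breaking
ties toward the lexicographically smaller id so runs are reproducible.
`mutantPositionMean()` averages the substitution-matrix score over
mismatched, gap-free columns and reports an explicit missing value when a
pair has no mismatches — averaging over zero columns is undefined, and
silently returning 0 would bias metric tables. BLOSUM62 ships with
Biostrings; other matrices (e.g. PFASUM15) are read from NCBI-format text
files with `readSubstitutionMatrix()` and must be supplied by the user.

**Top-k homology.** `topkMeanHomology()` averages the k (default 30) best
per-reference scores. Two backends exist: the internal one uses
global-alignment raw scores; the `phmmer` adapter shells out to the HMMER
executable and averages bit scores. The scales differ, so one table must
never mix backends; the function neither converts nor mixes them.

**Language-model scores.** The scorer contract is a single generic:
log-probability of the observed residue at requested positions, with the
set of masked positions passed explicitly. `averageLogProb()` pools either
one unmasked pass or, under `maskSchedule(m)`, m passes in which pass j
masks positions j, j+m, j+2m, ... — every position is scored exactly once
and positions masked together are at least m apart. `msaContextScore()`
builds an MSA of the query and its 31 nearest training sequences (nearest
by alignment score; a star alignment onto query coordinates, or a custom
aligner such as an external MSA tool) and scores the query row with six
passes at interval six. The shipped `pssmScorer()` is a position
probability matrix with pseudocount α — context-free, so masked and
unmasked scores coincide, which the tests exploit as an invariant; real
models attach through the same generic via adapters.

**Generation.** `iterativeMaskSample()` resamples a seed MSA one position
at a time from the scorer's distribution until every position of the
target row(s) has been redrawn. Two modes mirror the two standard
schedules: resampling every row of one shared MSA, and resampling one
sequence at a time against its most similar rows. Position visit order is
randomised within a sweep (the order is not specified by any convention,
so it is seeded rather than fixed); temperature scales the distribution as
p^(1/T) with T below 1e-8 giving the greedy argmax. The number of sweeps
per row is a parameter (`nIter`, default 1), as the saturation point is a
modelling choice rather than a defined quantity.

**Structure metrics.** `shrakeRupley()` is the classic test-point SASA
algorithm: each atom's sphere, expanded by the 1.4 A water probe, is
covered with 960 near-uniform points (a Fibonacci lattice; the count and
probe are configurable), and the accessible fraction scales the expanded-
sphere area. Radii are the standard Bondi heavy-atom values; hydrogens,
absent from predicted structures, are ignored rather than folded into
united-atom radii. Polar atoms are N, O and S — the default classifier
family of the common SASA tools — and `percent_polar = 100·polar/total`;
the classification is configurable because "polar" is convention, not
physics. Exactly coincident duplicate atoms count once. The suite checks
the isolated-atom closed form (4π(r+1.4)²), point-count stability, and a
frozen cross-check against an independent implementation on a committed
tripeptide file. `meanConfidence()` averages per-residue confidences read
from the B-factor field (the pLDDT convention); per-residue values are the
mean over the residue's atoms, which is robust to writers that vary the
value within a residue, with an atom-level view exposed as well.
Inverse-folding and relax-energy scores are adapter contracts only: the
package defines the call signature, caching and length validation, not the
models.

## Calibration and the filter

The language-model cutoff is calibrated on natural sequences:
`percentileThreshold(scores, p, "top")` returns the k-th largest score
with `k = max(1, ⌊np/100⌋)` — the stringent lower-interpolation reading
under which at most p% of the calibration set passes (and never zero).
With scores 1..10 and p = 10, the cutoff is 10 and exactly one sequence
passes. The default p = 10 on held-out natural sequences deliberately errs
stringent, since in practice the calibration scores come from untested
naturals.

`runCompss()` then applies, in order: identity to the closest training
sequence within [0.50, 0.80] — both endpoints inclusive, as the failure
condition is strictly-outside; the calibrated cutoff; and the quality
checks, with every violated criterion listed, not just the first. Of the
survivors, a seeded sample of 200 is ranked by structure score, the top 40
kept (candidates with missing structure scores are set aside and reported,
the window back-filling from below), and 18 drawn for the bench. Each
selection is paired with a control drawn without replacement from the
filter-failing pool within |Δidentity| ≤ 0.01; selections with an empty
in-tolerance pool are reported unmatched rather than silently dropped. One
seed drives every draw and is recorded in the report, so identical seeds
reproduce identical selections. Per-model or per-family stratification is
expressed by running the pipeline once per stratum. When the transmembrane
adapter is absent the check is recorded unknown and not counted against a
sequence, with a logged note.

## Evaluation statistics

`aucRoc()` uses the rank-sum identity U/(n₁n₀) on mid-ranks, so tied pairs
contribute one half — the Mann–Whitney convention — and an orientation
flag handles lower-is-better metrics as data rather than code.
`fisherExactTwoTailed()` uses the probability-mass two-tailed definition
(all tables with the observed margins at most as probable as the observed
one), the mainstream-software convention; the suite checks it against
exhaustive enumeration for every table with n ≤ 12. `quadrantAnalysis()`
splits the plane of two metrics at their medians (boundary points go to
the upper/right quadrant — a documented tie-break, since medians of even
samples frequently coincide with data points) and reports per-quadrant
counts, active fractions and within-quadrant correlations, the analysis
used to show that two metrics contribute orthogonally. Wilcoxon uses exact
enumeration for small tie-free samples and the tie-corrected normal
approximation with continuity correction otherwise.

## Assay analysis

Absorbance converts to NADH concentration via Beer–Lambert
`c = A/(d·ε)`, ε = 6.22 mM⁻¹cm⁻¹, d = 0.29 cm (100 µl in a 96-well
plate). An MDH sample is called active when its endpoint absorbance is
significantly lower than the negative control's — a one-sided Welch t-test
at α = 0.05 (the direction is dictated by the chemistry: activity consumes
NADH; Welch because replicate variances of different enzymes differ). SOD
inhibition is `((A−B)−(C−D))/(A−B)×100` at the 20-minute reading, with
values outside [0, 100] reported as-is with a flag. Specific activity in
MDH mode is the per-replicate concentration drop between 0 and 90 s —
after subtracting the no-substrate control per timepoint and substituting
the negative-control mean for t₀ values below 275 µM (fast enzymes exhaust
substrate before the first read; the floor applies only at t₀ and only in
MDH mode) — averaged over replicates and divided by the wild-type mean.

## The synthetic fixtures, and what passing tests show

`makeFamily()` emulates the study conditions at desk scale: a
methionine-initiated consensus of 120 residues; 12 training sequences at
~90% identity to it; 50 natural test sequences (doubling as the
calibration set — sized so the top-decile order statistic is stable, as it
is for the hundreds-strong held-out natural splits such campaigns
calibrate on); and 400 candidates derived from training sequences at
target identities drawn from the 70–80% band. Substitution-only mutation
makes realised alignment identity track the target tightly. Injected
defects (missing start methionine, homopolymer run, dimer tandem, charge
shift, out-of-band identity) occupy disjoint windows and are rejection-
sampled so each remains individually detectable and clean candidates are
genuinely clean; out-of-band candidates skip the substitution-heavy
defects so their label stays truthful. Mock language-model and structure
scores are Gaussian with defect-free candidates centred above defective
ones, and planted activity follows the stated rule: candidates that are
defect-free, in band and at or above the top-decile-of-naturals score
threshold — the same stringency the filter calibrates — are active with
probability 0.8, others 0.3, bracketing the selected-versus-control
contrast a successful filter should recover.

The fixtures deliberately omit much of real data: no phylogenetic
structure (mutations are i.i.d., not tree-correlated), no insertions or
deletions, context-free mock scorers rather than epistasis-aware models,
and physically implausible ideal-helix structures. Green tests therefore
demonstrate that the machinery — scoring, calibration, staging, matching,
statistics — is correct and reproducible, not that any particular metric
predicts activity for a real enzyme family; that question needs real
models and bench data.

`makePlate()` generates triplicate absorbance series (exponential NADH
depletion for MDH, linear formazan formation scaled by inhibition for
SOD, Gaussian noise, seeded) with the control wells each analysis needs. A
note on calls: a zero-activity sample versus the negative control is a
null hypothesis test, so at α = 0.05 one in twenty such calls is a false
positive by construction — tests assert relative quantities rather than
the binary call on null data.

## Numerical choices and degenerate inputs

Alignment tie-breaks follow the engine's deterministic backtrace, and
closest-hit ties break lexicographically. Mid-rank ties give AUC and
Spearman their standard tie behaviour; a constant vector makes Spearman
undefined and returns NA with a message. `percentileThreshold` never
passes zero sequences (k ≥ 1). Fisher comparisons use the engine's 1e-7
relative tolerance on probability ties. SASA treats a test point exactly
on a neighbour's surface as buried (with a 1e-9 relative guard) and
exposes exactly one of two coincident identical atoms. Sequences
containing X can be read, flagged and repeat/charge-scored but are
rejected by alignment metrics, which require the standard alphabet.
Empty calibration sets, single-class AUC inputs, missing metrics in the
filter, and degenerate SOD baselines (A ≤ B) are errors, not silent NAs.

## Problem sizes

The shipped tests run the whole pipeline at the scales above (400
candidates, 12 training sequences, 120 residues, five seeds for the
end-to-end enrichment property, 1,000 random sequences for the repeat
oracle, 200 pairs for the alignment oracle, all n ≤ 12 tables for Fisher),
chosen so the full suite exercises every stage in a few minutes on one
core. All sizes are ordinary function arguments; nothing in the
implementation depends on them.

## Known limitations

No pKa-based charge; no approximate (imperfect) tandem repeats; no
internal transmembrane/signal-peptide predictor, phmmer replacement, MSA
tool, structure predictor or energy function — these are adapter hooks by
design; one control per selection (no many-to-one matching); no multiple-
testing correction or AUC confidence intervals; mmCIF and multi-model
ensembles are out of scope.
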