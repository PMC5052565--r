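---
title: "Coding-potential classification of partial-length transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding-potential classification of partial-length transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsieve)
```

## The problem

Transcriptome assemblies mix long noncoding RNAs (lncRNAs) with
protein-coding mRNAs, and a large share of the assembled mRNAs are
*partial-length*: the short-read assembler failed to reconstruct the 5'
and/or 3' end, so the start and/or stop codon is missing. Coding-potential
classifiers built mainly on ORF properties misclassify these fragments,
because the very definition of the ORF hinges on the codons that are
absent. `lncsieve` classifies transcripts with features that degrade
gracefully under truncation, alongside the classical ORF features that
remain the strongest evidence on full-length input.

## Features

All features derive from a single trained object, the **hexamer table**:
in-frame (codon-phased, step 3) hexamer frequencies `F(h)` counted over
coding CDS training sequences and `F'(h)` over noncoding training
sequences, each normalized to sum to one, and a per-hexamer log-ratio
score `ln(F(h)/F'(h))`. Hexamers unseen in the CDS class but present in
noncoding sequences — typically those beginning with a stop codon — get
the clamp value −10 (natural-log units); the converse gets +10; hexamers
unseen in both get 0. The finite clamp matters: it lets the
maximum-subarray recursion below terminate a run at a stop codon without
propagating infinities, while still making stop codons prohibitively
expensive inside a putative coding region. The clamp magnitude is a
parameter of `build_hexamer_table()`; ±10 is far beyond any log-ratio
observable from realistic training sizes, so in practice it acts only on
structurally impossible hexamers. Hexamers containing `N` are skipped in
counting and in frame-score means; in the positional score array used by
the subarray scan they are kept at score 0, so they contribute nothing to
any sum but preserve positional contiguity.

The per-frame **hexamer score** `S_i` (frames `i = 1..3`) is the mean
score of the codon-phased hexamers in that frame, and
`S_m = max(S_1, S_2, S_3)`. The **hexamer score distance**

```
D = ( Σ_{i=1..3} (S_m − S_i) ) / 2
```

is the mean excess of the best frame over the other two: zero exactly
when no frame stands out (as in noncoding sequence), large when one frame
carries concentrated codon structure. Other contrasts (e.g. the gap to
the runner-up) would serve the same purpose; this definition was chosen
because it is symmetric in the two non-maximal frames and is recorded in
the model provenance so any future alternative versions the model file.

**Exon group.** With a GTF, `S_m`, `D` and the GC fraction are computed
per exon and the per-feature maxima over exons are used — coding exons
give a strong signal even when the transcript also has long noncoding
exons. Without annotation the transcript is one exon and the group
degrades to transcript-level values, so bare FASTA input is always
accepted. The FASTA is assumed to be the sense (transcript) sequence;
the annotation contributes exon lengths and order only (reversed for
minus-strand transcripts), never a reverse complement.

**MCSS group.** The *maximum coding subsequence* of a frame is the
contiguous run of in-frame hexamers with maximal summed score, found by
the prefix-sum form of Kadane's maximum-subarray recursion (vectorized;
ties resolve to the earliest maximal end, then the earliest start, and
frame ties to the lowest frame, so output is deterministic). The run is
required to be nonempty so the MCSS length and score are defined for
noncoding input too: on such input the scan returns the least-negative
single element. A run of `k` hexamers spans `k + 1` codons, hence the
reported length `3k + 3` nt. The **coding score percentage**
`S_m / (S_1 + S_2 + S_3)` is guarded: when the denominator is
non-positive (no frame shows net coding signal) the feature takes 1.0,
keeping it bounded and monotone-ish without infinities. The MCSS needs
neither ATG nor stop, which is exactly why it survives truncation.

**ORF group.** The putative ORF is the longest ATG-initiated,
frame-consistent stretch over the three forward frames, ending at the
first in-frame stop (inclusive) or — supporting 3'-truncated input — at
the last complete codon of the sequence. Ties break to the smaller start,
then the smaller frame. The group contributes ORF length, ORF coverage
(length / transcript length), the Fickett TESTCODE statistic of the ORF
subsequence (published position-asymmetry and composition lookup tables
and weights), and the hexamer score and distance of the ORF subsequence,
whose frame 0 is the codon frame by construction. With no ATG anywhere,
length and coverage are 0 while the remaining three fall back to
whole-transcript values — a transcript without any ORF still has
composition worth scoring.

## Classifier

A ridge (L2) logistic regression on the 11 features, fit with
`glmnet` (`alpha = 0`). The inverse regularization strength `C`
(`lambda = 1/(nC)`) is selected from a 10-point log-spaced grid,
`1e-4` to `1e4`, by stratified k-fold cross-validation (default 10
folds, fold assignment seeded and restored so callers' RNG streams are
untouched) maximizing held-out accuracy at cutoff 0.5; exact ties go to
the smaller `C`, i.e. the more strongly regularized model. Accuracy is
the selection metric because the training classes are balanced by
construction and the deployed decision is itself an accuracy-type call
at a cutoff. Features enter unscaled by default — they are already on
comparable, bounded-ish scales, and unscaled weights stay interpretable;
`standardize = TRUE` stores training means/sds in the model and applies
them at prediction. Near-zero penalties on separable data cannot
converge to a finite optimum; the grid's small-lambda end is therefore
fitted with a raised iteration cap and the CV selection (which almost
always prefers stronger regularization under the tie rule) is unaffected.

The model file is a single human-readable JSON with a format-version
tag, the weights, the chosen `C`, the cutoff, the feature order, full
provenance (training sizes, seed, grid, per-`C` CV accuracies, the
distance and CSP conventions) and, normally, the embedded hexamer table
plus its FNV-1a content digest — one file suffices for prediction, and
a model applied with a foreign table is detected by digest mismatch.
Serialization keeps about 15 significant digits, so reloaded models
reproduce probabilities to ~1e-15 rather than bit-exactly; all
determinism guarantees (thread invariance, repeated prediction from one
loaded model) are exact.

The decision cutoff is an operating point, not part of the likelihood:
0.5 unless calibrated. `best_accuracy_cutoff()` sweeps the midpoints
between consecutive sorted unique scores (plus both extremes) — the
exhaustive set of distinct decision rules — and returns the smallest
maximizer, snapped to a reporting grid only when that changes nothing.
The shipped species presets (human 0.5654, mouse 0.4567) are the
operating points calibrated for the reference human/mouse models.

## Evaluation

`confusion_metrics()` reports ACC, Sn, Sp, PPV, NPV and MCC with coding
as the positive class; degenerate ratios (zero denominators) are
reported as `NaN` with a flag rather than imputed. `roc_auc()` is the
normalized Mann–Whitney statistic with midrank tie handling (0.5 credit),
identical to the trapezoidal area under the empirical ROC;
`roc_points()` emits the curve for external plotting.

## The synthetic generator

`generator_config()` / `generate_dataset()` produce the three classes
the classifier must separate, with known ground truth:

* **Full-length coding**: 5'UTR + `ATG` + a stop-free body of codons
  drawn from a fixed nonuniform codon distribution + stop codon + 3'UTR.
  Defaults: CDS 300–1500 nt, UTRs 30–300 nt each, 1–8 exons with
  boundaries drawn uniformly. The codon weights decay exponentially over
  the 61 sense codons (max/min ratio ≈ 3.3) — codon bias of roughly
  mammalian magnitude, chosen once so the benchmark sits in a regime
  where the task is clearly solvable (full-length AUC ≈ 1) but not
  saturated, leaving truncation effects and feature-group differences
  visible.
* **Partial-length coding**: a configurable fraction of coding
  transcripts lose a random prefix crossing the start codon (`cut5`), a
  random suffix crossing the stop (`cut3`), or both (`cut_both`); the
  default `mix` draws a mode per transcript so a partial set contains
  all three truncation classes, as assembly output does. Cuts land at
  arbitrary nucleotides (not codon boundaries), the surviving CDS span
  and frame are recorded in the truth table, and draws violating the
  200-nt length floor are redrawn with bounded retries.
* **Noncoding**: i.i.d. bases (default, slightly AT-rich) or a
  first-order Markov chain, 260–2100 nt.

Every transcript exceeds 200 nt — the conventional lncRNA length floor,
enforced here as a generator guarantee and available as a filtering
predicate, not hard-wired into the data types.

What the generator does *not* emulate: genomic repeats, sequencing
error, selenoproteins and other non-standard gene models, pseudogenes
(coding-like composition without function), real UTR composition, and
lncRNAs harbouring long spurious ORFs beyond what random composition
produces. Passing the synthetic benchmark therefore demonstrates the
machinery — feature correctness, learnability, the truncation-robustness
ranking of feature groups — not performance on curated annotation;
models for real use should be trained on GENCODE/Ensembl-style sets via
`train_command()`.

## Reference experiment and problem sizes

`synthetic_benchmark()` is the package's reference experiment: 500 + 500
full-length training transcripts, 200 + 200 test transcripts with half
of the coding ones truncated, hexamer table from the training CDS,
full and per-group models, AUC measured separately on the full-length
and partial-length coding subsets (each against all noncoding test
transcripts). These sizes give AUC standard errors of well under 0.01
while keeping the whole experiment at around a minute on one CPU; the
test suite uses smaller sizes (30–300 transcripts) per property. At
these settings the expected pattern is: full-length AUC ≈ 1, partial
strictly lower (≈ 0.98–0.99), ORF-group-only model clearly lower still
on the partial subset — the ordering that motivates combining all three
feature groups.

The acceptance-script simulation of classifier recovery uses features
from a known 11-weight logistic model with true weights
`2·(4,−4,3,−3,3,−3,2,−2,2,−2,1)` on standard-normal features (linear
predictor SD ≈ 18): a strongly separated regime in which near-perfect
held-out discrimination is attainable and sign recovery of all weights
is expected at n = 2000.

## Parallelism

Feature cost scales with transcript length, so `--threads k` splits
records by longest-processing-time greedy scheduling: sort by length
descending, always assign to the lightest worker — worker totals are
then nearly equal in total nucleotides. Workers are forked processes
over disjoint subsets with no shared state, and results are merged by
original index, so output is byte-identical for any thread count.

## Known limitations

* Only the forward strand is scanned (assembler output is sense-strand;
  antisense misassemblies will be scored on the wrong strand).
* The hexamer table is species-specific in real use; applying a table
  across distant taxa shifts the score scale (the digest check flags
  mismatched table/model pairs, not mismatched species).
* Fickett TESTCODE uses the published lookup tables; extremely short
  (< ~50 nt) windows quantize coarsely.
* The `0.5654`/`0.4567` presets apply to the reference human/mouse
  models; a newly trained model should be calibrated with
  `best_accuracy_cutoff()` on a held-out full-length set.
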