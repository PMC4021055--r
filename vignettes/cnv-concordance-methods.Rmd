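---
title: "Harmonizing multi-caller CNV calls and validating them by relatedness"
author: "CNVconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-caller CNV calls and validating them by relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNVconcord)
```

## The problem

Array-based CNV calling infers integer copy-number states (0, 1, 2, 3, 4+)
from probe intensities. Different algorithms — hidden-Markov-model callers
and segmentation callers — applied to the *same* arrays produce materially
different call sets: different counts, breakpoints, sizes and sometimes
opposite gain/loss assignments. Two consequences follow. First, integrating
several callers requires a harmonization step (adjacent-fragment merging and
cross-caller event matching) before any comparison is meaningful. Second,
because no ground truth exists for real samples, individuals of known
genetic relatedness provide an external yardstick: monozygotic (MZ) twins
share 100% of their germline genome, parent–child pairs 50%, unrelated
individuals 0%, so germline CNV calls of a faithful caller must track those
fractions. CNVconcord implements both the harmonization machinery and the
relatedness-based validation, plus a simulator that generates multi-caller
call sets over a pedigree with known truth.

## Data model

The central container is the `CNVCallSet`: every call of one
(sample, program), held as a `GRanges` on autosomes "1".."22" with
1-based inclusive coordinates and metadata columns `state` (0–4, with 4
encoding "4 or more"), `nMarkers` (supporting consecutive array markers),
`status` (the gain/loss binarization: 0/1 → LOSS, 2 → NEUTRAL, 3/4 → GAIN)
and `mergedFrom`. All comparisons downstream of filtering operate on
`status`, not on exact states — a state-1 and a state-0 call at the same
locus are the same loss. Coordinates are 1-based inclusive because every
length in the method is `end − start + 1`; BED interchange converts to
0-based half-open at the boundary (via rtracklayer). Sex chromosomes are
excluded at ingestion (and counted, not silently dropped): the relatedness
logic assumes biallelic autosomal inheritance.

## Inclusion filters

`filterCalls()` retains calls with

* `nMarkers >= 10` (inclusive — "a minimum of 10"),
* length strictly greater than 1 kb (exclusive — "greater than 1 kb"; a
  1000 bp call is dropped, a 1001 bp call kept),
* non-neutral status.

Each dropped call is tallied under the first filter it fails (markers,
length, neutral, in that order), so drop counts plus the retained count
always equal the input count. Calls lacking marker counts are an error
rather than a silent pass while the marker filter is active: segmentation
callers do not always export marker support, and the user must decide
explicitly (`minMarkers = 0`) rather than have the filter quietly vacuous.

## Adjacent-call merging

Callers fragment single CNV events into several adjacent calls. Two calls
of one (sample, program) merge when (1) they are adjacent on the same
chromosome with no other call of any status between them, (2) they share
gain/loss status, and (3) for consecutive segments A (call), B (gap),
C (call), the gap fraction |B| / |A+B+C| is at most 0.20.

For longer runs the rule extends cumulatively: a chain A..K merges only if,
at each extension, the *sum of all internal gaps* divided by the full chain
span stays at or below the threshold. The phrase "20% or less length
between one and all of the others" admits a second reading — every pairwise
gap fraction ≤ 20% — but the cumulative form is the more direct reading of
extending the same formula over the whole event, and it is the stricter of
the two (a chain of many small gaps cannot creep past 20% total); we adopt
it.

One subtlety makes the implementation iterate the scan to a fixed point:
a chain that fails the cumulative test can still merge *after* its prefix
has been merged, because a merged call has absorbed its internal gaps —
they are part of the call now, not gaps. A single left-to-right pass would
therefore not be idempotent; repeating the pass until nothing changes is,
and the fixed point has the property that no two surviving same-status
neighbours satisfy the merge criteria. The property-based tests assert
idempotence, conservation (`mergedFrom` totals equal the input call count;
output coverage is input coverage plus exactly the absorbed gaps, with all
output boundaries drawn from input boundaries) and threshold monotonicity
on a thousand random call sets.

Merged calls need a copy-number state even though downstream comparisons
use only gain/loss: we store the state of the largest constituent (dominant
evidence) and sum the marker counts. Overlapping same-status calls from one
program — degenerate input, but it occurs — merge unconditionally (gap 0).
Merging never crosses programs or samples; cross-program identity is the
job of event grouping, below.

## Reciprocal overlap and event identity

Two calls x and y overlap reciprocally at threshold t when the intersection
L covers at least t of *each* call: `L / length(x) >= t` and
`L / length(y) >= t`, with t = 0.50 by default and the boundary inclusive
(exactly half-covered on both sides passes). A pass additionally requires
matching gain/loss status: perfectly coincident calls of opposite status
are different events. The asymmetry guard matters: a small call nested in a
large one yields O = 1.0 on one side and a small fraction on the other, and
fails.

Within an individual, calls from all programs form a graph with
passing-RO edges; its connected components are the events
(`buildEventGroups`). Components rather than cliques: a chain of partially
overlapping calls is one event even when its distal members do not overlap
each other directly. This mirrors how merged-event tools built on the same
RO criterion behave, and it guarantees a partition — every call belongs to
exactly one event. The accelerated candidate generation uses the
interval index of `GenomicRanges::findOverlaps`; the test suite checks it
against an exhaustive all-pairs oracle on a thousand random instances.

`vennPartition()` assigns each event to the subset of programs contributing
a member call and reports **both** event counts and constituent-call
counts. The two scales differ systematically — one event called by four
programs is four calls — and published summaries mix them, so the package
always emits both; constituent-call counts over all subsets sum exactly to
the post-merge call total. The cross-program question is within-individual,
so `vennAcrossSamples()` groups per sample and sums subset counts over
samples, preventing calls of different individuals from bridging events.

## The difference statistic d

For two individuals A and B compared within one program,

\[ d = \frac{\text{unshared calls}}{\text{total calls across A and B}}
     = \frac{n_A + n_B - 2s}{n_A + n_B} \]

where s is the number of shared call pairs. Shared pairs are counted by a
**one-to-one maximum-cardinality matching** over the passing-RO candidate
pairs (`matchPairwise`): without the one-to-one constraint, one fragmented
call could be counted as "shared" several times and d would be biased
downward. Maximality is a design choice — the method's description does not
fix a multiplicity rule — and the most favourable consistent one; ties are
broken toward larger `min(O_A, O_B)`, then genomic order, by solving a
maximum-weight bipartite matching (igraph) with weights
`K + min(O_A, O_B)`, K exceeding the largest possible cardinality so that
cardinality always dominates. Brute-force enumeration on small instances
verifies maximality in the tests. d is symmetric, lies in [0, 1], is 0 iff
the matching covers every call on both sides and 1 iff nothing is shared.
Comparisons never cross programs (refusing, not silently mixing), and a
pooled-across-programs d is deliberately not defined: between-caller
disagreement would masquerade as between-individual difference.

`groupDifferenceSummary()` averages pair-level d within each
(relatedness group, program), reporting the mean with both the sample SD
and the SEM (`sd / sqrt(n)`); with the typical three comparisons per group
the two dispersions differ by √3 and figures conventionally show SEM, so
both are available.

## The simulator

`simulateDataset()` emulates the study design end to end so every pipeline
stage can be validated against known truth.

**Truth model.** Founders draw `nCnvsPerFounder` non-overlapping loci,
placed uniformly with chromosome probability proportional to length on a
22-autosome genome of GRCh37-scale sizes, each a heterozygous gain or loss
with equal probability. Lengths are log-uniform over 2 kb–5 Mb: the method
gives no generative length model, and log-uniform populates all size bins
from kb-scale to Mb-scale instead of concentrating mass at one scale. A
`populationSharedFraction` of the per-founder count (default 0.1) is drawn
once and carried by *all* founders, emulating common copy-number
polymorphisms (population frequency above one percent) that would otherwise
be absent from a rare-variant-only model. MZ co-twins replicate their twin
exactly; an optional Poisson `deNovoPerTwin` count (default 0) models
somatic mosaicism between co-twins, which is real but small. Children
inherit each parental CNV independently with probability 0.5 (loci shared
by both parents transmit once); inherited loci keep their cohort-wide locus
id, so identity-by-descent is traceable in tests.

**Caller error model.** Each (individual, caller) emission applies, in
order: Bernoulli detection at `sensitivity`; Gaussian breakpoint jitter
(`jitterSd`, clamped to chromosome bounds, minimum emitted length 1001 bp
so the >1 kb filter is satisfiable); status flip with `stateFlipProb`;
fragmentation with `fragProb` into two pieces separated by a gap of 2–15%
of the span — within reach of the 20% merge rule by construction — applied
only when both pieces exceed 1 kb (otherwise the length filter would orphan
one piece and "re-joining" would be undefined); and Poisson(`fpRate`)
uniformly placed false calls. Marker counts are synthesized at one marker
per kb with a floor of 10 — a convenience density so that default filters
retain emitted calls, not a claim about any real array's probe map.

**Default conditions.** The default pedigree is the study shape: six MZ
twin pairs plus both parents for twin pairs 2 and 3 (n = 16). The default
`nCnvsPerFounder = 80` matches the scale of the HMM callers' observed
~78 calls per individual. The four default profiles comprise three
HMM-like callers (sensitivity 0.88–0.92, false-positive load 6–10 per
genome, jitter 1.5–3 kb) and one segmentation-like caller whose calls are
dominated by caller-specific false positives (fpRate 240, yielding ~310
calls per individual): independent false positives across callers are
exactly what produces one caller's low overlap with all others. These
profiles are chosen for test power and qualitative fidelity to the
described between-caller differences, not as quantitative estimates of any
specific product — the study gives no caller error rates.

**What the simulator does not model.** No probe-level intensities (LRR/BAF),
no batch or wave artifacts, no correlated false positives between callers,
no homozygous events, no sex chromosomes, and breakpoint errors are
Gaussian rather than probe-grid-quantized. Passing tests therefore show the
*integration logic* is correct under a realistic error structure; they do
not certify performance on any real caller's output.

## Validation conditions used by the test suite

The acceptance tests run the pipeline under two regimes, with sizes chosen
to keep the whole suite at desk scale:

* **Noise-free recovery** — a perfect caller (sensitivity 1, no jitter, no
  fragmentation, no false positives) over 50 twin families (two founder
  parents, a child, the child's MZ co-twin; 200 parent–child pairs) in a
  rare-variant regime: 10 CNVs per founder, no population-shared loci.
  Rarity is the operative condition: d(unrelated) = 1 exactly requires that
  no two independent founders' CNVs pass 50% RO by chance, which holds only
  when variants are sparse relative to the genome. Expected outcome:
  d(MZ) = 0 for every twin pair, d(unrelated) = 1 for each of the three
  unrelated comparisons (three, as in the study design), and mean
  parent–child d within 0.05 of 0.5 (each parental CNV transmits with
  probability one half; the ratio's slight convexity keeps the mean a touch
  above 0.5).
* **Noisy ordering** — one caller with sensitivity 0.9, 5 kb jitter, 20%
  fragmentation and 10 false positives per genome over 100 replicate
  16-individual cohorts at the default conditions: the relatedness ordering
  d(MZ) < d(parent–child) < d(unrelated) must hold in at least 95 of 100
  replicates. Noise compresses the d range (MZ pairs no longer reach 0
  because each twin's calls are independently corrupted) but must not
  scramble the ordering.
* **Fragment re-joining** — at least 99% of simulator-fragmented calls
  (gap ≤ 15% of span by construction) are re-merged into a single call by
  the default 20% rule; the residue comes from rare interference, e.g. a
  false-positive call landing between two fragments and breaking
  adjacency.

## Numerical and degenerate-input choices

* Size-distribution bins are right-closed, `(lo, hi]`, so the conventional
  "1–100 kb" / "100 kb–1 Mb" / "1–10 Mb" labels partition cleanly and a
  call of exactly 100 kb falls in the lower bin; an underflow bin keeps
  counts summing to the input even for sub-kb calls. The boundary
  convention is ours — published size categories rarely state one.
* d is undefined when both call sets are empty; that is an explicit error,
  never a silent 0.
* Group summaries with a single pair report `NA` dispersion, flagged by
  `n_pairs = 1`; empty groups are omitted with a warning.
* The merge threshold is validated to [0, 1); the RO threshold is a
  parameter (default 0.50) surfaced through every interface for
  sensitivity analyses.
* Sub-seeds for each (individual, caller) emission are derived
  arithmetically from the cohort seed, keeping every value below 2^31;
  identical configurations reproduce byte-identical output files.

## Limitations

The harmonization rules (10 markers, >1 kb, 20% gap, 50% RO) are the
standard operating point of this workflow, not universal constants; all are
parameters. The one-to-one matching rule and the cumulative chain rule are
documented design choices where the method's prose is ambiguous. Relatedness
validation treats germline sharing as ground truth and will mis-score true
de novo and somatic-mosaic events as caller error — at realistic rates this
is a small perturbation, and the simulator exposes `deNovoPerTwin` to
explore it.
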