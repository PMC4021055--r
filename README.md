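# CNVconcord

Copy-number variant (CNV) calls made by different programs on the *same*
microarray data disagree substantially: call counts, breakpoints and even
gain/loss assignments vary from caller to caller, and only a small fraction
of calls is reproduced by every program. CNVconcord is an R package for the
people who have to deal with that — analysts integrating CNV call tables
from several callers (HMM-based callers such as PennCNV, Birdsuite/Genotyping
Console or Partek, and segmentation callers such as Golden Helix CNAM) who
want to harmonize the call sets, quantify between-caller concordance, and
use individuals of known genetic relatedness as a biological yardstick for
caller quality.

## What it computes

The workflow, in its canonical order:

1. **Inclusion filters** (`filterCalls`) — keep calls with copy-number state
   0, 1, 3 or 4+ (state 2 is diploid/neutral), supported by ≥ 10 consecutive
   array markers, and strictly longer than 1 kb.
2. **Adjacent-call merging** (`mergeAdjacent`) — calls from one
   (sample, program) that are adjacent on a chromosome (no other call
   between them, criterion 1), share gain/loss status (criterion 2) and are
   separated by a gap of at most 20% of the combined span (criterion 3) are
   merged into one event. For consecutive segments A (call), B (gap),
   C (call), the gap fraction is |B| / |A+B+C| on 1-based inclusive
   coordinates; chains of more than two calls are extended under the
   cumulative gap fraction, re-checked at each extension.
3. **Reciprocal-overlap matching** (`reciprocalOverlap`, `buildEventGroups`) —
   two calls x and y are the same event when

       O(A) = L / (x_end − x_start + 1) ≥ 0.5   and
       O(B) = L / (y_end − y_start + 1) ≥ 0.5

   where L is their overlap in bp, *and* their gain/loss statuses match.
   Within an individual, calls from different programs are grouped into
   events as the connected components of the passing-RO graph.
4. **Cross-program partition** (`vennPartition`, `vennAcrossSamples`) —
   every event is assigned to the subset of programs that called it,
   reported both as event counts and as constituent-call counts (one
   four-program event contains four calls).
5. **The difference statistic d** (`pairwiseDifference`,
   `groupDifferenceSummary`) — for two individuals compared within one
   program, d = unshared calls / total calls across the pair, with shared
   calls counted through a one-to-one maximum-cardinality RO matching.
   d = 0 for identical call sets, 1 for fully discordant ones. Monozygotic
   (MZ) twins share 100% of their genome, parent–child pairs 50%, unrelated
   pairs 0% — so a biologically faithful caller should show
   d(MZ) < d(parent–child) < d(unrelated).

A pedigree-aware simulator (`simConfig`, `simulateDataset`) generates
multi-caller call tables with known truth — shared loci at 100%/50%/0%
expected sharing, per-caller sensitivity, false-positive load, breakpoint
jitter, fragmentation and status flips — so the whole pipeline is testable
at desk scale without array data.

## A worked example

Using the miniature two-sample, two-program call table shipped with the
package:

```r
library(CNVconcord)

calls <- readCallTable(system.file("extdata", "example_calls.tsv",
                                   package = "CNVconcord"))
S4Vectors::metadata(calls)$excludedRows   # 1 (a chromosome-X row: autosomes only)

merged <- mergeAdjacent(filterCalls(calls))
cnvCalls(merged[["S1|PC"]])
```

```
GRanges object with 2 ranges and 4 metadata columns:
      seqnames        ranges strand |     state  nMarkers      status mergedFrom
  [1]        1 100000-179999      * |         1        57        LOSS          2
  [2]        2 500000-739999      * |         3       210        GAIN          1
```

Sample S1's two PennCNV loss fragments on chromosome 1 (gap 12 kb over an
80 kb span, gap fraction 0.15 ≤ 0.20) were merged into one call
(`mergedFrom = 2`, marker counts summed); a 9-marker call and the X-row were
dropped upstream. Cross-program agreement and the pairwise difference:

```r
vennAcrossSamples(merged)
#   programSet nPrograms eventGroups calls
# 1     AGC+PC         2           3     6
# 2         PC         1           1     1

pairwiseDifference(merged[["S1|PC"]], merged[["S2|PC"]])
#   sample_a sample_b program_id shared_pairs unshared total   d
# 1       S1       S2         PC            1        2     4 0.5
```

Three events were recovered by both programs (6 of the 7 post-merge calls);
between S1 and S2, PennCNV shares one call pair out of four calls total, so
d = 0.5: half the calls across the pair are unshared.

For shell use, the same stages are available as subcommands of
`inst/cli/cnvconcord.R` (`filter`, `merge`, `match`, `events`, `venn`,
`dstat`, `summarize`, `simulate`, `pipeline`), each a thin wrapper over the
functions above.

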