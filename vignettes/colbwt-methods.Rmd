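---
title: "Methods: co-linear BWT indexing and chain statistics"
author: "colbwt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-linear BWT indexing and chain statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colbwt)
```

## The problem

Classifying long, error-bearing reads against a pangenome with a compressed
full-text index is usually done with matching statistics (MS) or
pseudo-matching lengths (PML): per-position lengths of exact matches between
read and reference. These are *fine-grained* signals — they say how long each
match is, but not whether successive matches land in mutually consistent
(co-linear) places in the reference. Alignment-based classifiers recover that
information by chaining seed hits, at a super-linear cost in the number of
seeds. This package implements an index, the co-linear BWT (col-BWT), that
emits a coarse co-linearity signal — *chain statistics* — during the same
linear-time pass that computes PMLs.

The idea: multi-maximal unique matches (multi-MUMs) of the collection —
matches occurring exactly once in each of the $d$ documents and extendable in
neither direction — occupy $d$-wide windows of the suffix array. Forward
stepping (FL) from such a window sweeps a sequence of contiguous,
single-symbol $d$-blocks of the BWT ("tunnel columns"). Marking those blocks
with the multi-MUM's identifier turns the run-length BWT into an array of
sub-runs carrying ids. A query that tracks one BWT position per step can then
report, for free, the id of the region its current occurrence lies in. Two
adjacent match peaks in a read whose boundary ids agree are co-linear with
respect to the pangenome, without any chaining computation.

## Pipeline and data structures

`colbwtBuild()` runs, in order:

1. **Concatenation** (`concatText`). Documents are joined with $d-1$ distinct
   separator symbols (ranked by document index) plus one terminal sentinel,
   all sorting below the DNA alphabet. Distinct separators make
   cross-document suffix comparisons well defined and guarantee that no
   match can span a document boundary. N is an ordinary fifth symbol on the
   index side.
2. **Suffix structures** (`buildSuffixStructures`): suffix array by prefix
   doubling (counting sort, $O(n\log n)$, in C++), LCP by Kasai, document
   array from the boundary map, BWT by definition. At the scales this
   package targets (up to a few hundred kilobases per build) this direct
   construction replaces the prefix-free-parsing machinery used by
   production-scale builders; the contract downstream is identical.
3. **Run-length BWT and move tables** (`runLengthEncode`, `buildMoveTables`).
   LF is answered from a run-indexed table (`lfPos`, plus a destination-run
   pointer that is fast-forwarded), the move-structure contract of constant
   amortized work per step; FL is served from the same $r$ intervals
   re-sorted by F-position. `flRange` maps a whole interval and reports
   whether its image is contiguous.
4. **Thresholds** (`computeThresholds`). For each symbol and each pair of
   successive runs of that symbol, the smallest position attaining the LCP
   minimum strictly between the two runs. These direct the repositioning on
   mismatch during the query.
5. **Multi-MUM finding** (`findMultiMUMs`). A $d$-window of the SA starting
   at rank $i$ is a multi-MUM iff $w=\min(\mathrm{LCP}[i+1..i+d-1])$ exceeds
   both flanking LCP entries, the $d$ document indices are distinct, the $d$
   BWT symbols are not all equal, no suffix starts in a separator, and
   $w \ge \max(\texttt{minMumLen},1)$. Everything is vectorized with rolling
   minima; a quadratic brute-force enumerator (`bruteForceMultiMUMs`) serves
   as the independent test oracle.
6. **Tunnels** (`buildTunnels`). Multi-MUMs are processed in descending
   width (ties by ascending SA rank) and forward-stepped: a step is accepted
   while the FL image is contiguous, the step count stays within the match
   width, and no image position was claimed by an earlier tunnel; the first
   violation ends the tunnel (a claim collision truncates it). Longest-first
   processing maximizes expected coverage and is deterministic. Mode
   `"all"` drops the claim check and lets the last writer own overlapped
   positions.
7. **Sub-run splitting** (`buildColBWTSubruns`). Sampled tunnel columns
   (offsets $0, s, 2s, \dots$ from each tunnel's first column) are marked
   with the binned id; runs are split only at marked-column edges. The
   sub-run count obeys $r' \le r + 2\cdot(\text{distinct marked column
   starts})$.

## Query and classification

`queryPmlCid()` processes a read right to left with one tracked BWT position.
If the tracked position's BWT symbol equals the next read symbol the match
extends by one LF step; otherwise the thresholds pick the nearer run of the
wanted symbol (at-or-above the threshold goes to the run above), the length
resets, and one LF step restarts at length 1. The chain id recorded at
position $i$ is the sub-run id of the tracked position after the step. Work
is at most two index steps per read position, which the tests assert as a
step-count contract.

`extractPeaks()` segments the PML array into maximal left-to-right
decreasing-by-one ramps; each ramp is one uninterrupted match chain.
`colinearPairs()` first drops peaks below the significant-peak threshold
(small chance matches), then calls consecutive survivors co-linear when the
last nonzero id of the first equals the first nonzero id of the second.

`calibrateNull()` reverses uniform reference substrings (composition
preserved, homology destroyed) and queries them: $k$ is the largest PML
occurring at least `minCount` times; the significant-peak threshold defaults
to $\lceil (k+1)/2 \rceil$ (two such peaks jointly exceed $k$); `rhoNull` is
the per-base rate of co-linear pairs under the null. `classifyRead()` then
produces four verdicts: the windowed baseline (strict majority of
non-overlapping 150 bp windows containing a PML $> k$), scheme (a)
(co-linear pair rate strictly above `rhoNull`), scheme (b) (windowed rule on
PMLs augmented by merging co-linear pairs), and scheme (c) = baseline OR
(a).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minMumLen` | 1 (library), 20 (CLI `build`/`mums`) | minimum multi-MUM width indexed; 20 matches common practice for pangenome match finding, 1 is the correctness-oriented library default |
| `sampleRate` (s) | 1 | mark every s-th tunnel column; a match extending ≥ s steps inside a tunnel still meets a mark, so s at or below the significant-peak threshold preserves pair calling |
| `idBits` | 8 | stored id width; ids are binned to $1 + ((\mathrm{id}-1) \bmod (2^{\text{bits}}-1))$ with 0 reserved for unmarked, so equality of stored ids can produce false positives but never false negatives |
| `window` | 150 bp | classification window |
| `minCount` | 5 | occurrences defining the null threshold PML k |
| `nNull`, `lenNull` | 500 × 2000 bp | null extraction sizes |

## The synthetic generator

`simulatePangenome()` draws one uniform base genome and mutates each
haplotype independently (SNVs at `snvRate`, uniform alternative base;
optional geometric-length indels, off by default since the peak experiments
use SNVs only). `simulateReads()` samples positive reads from the haplotypes
with per-base SNV errors and negative reads from an unrelated random genome.
This emulates what the method needs — a mutation-structured collection and
error-bearing long reads — but not real pangenome structure: real haplotypes
share segregating variants, so their *union* mutation density grows far more
slowly with $d$ than under independent mutation, and real nanopore errors
are indel-rich and context dependent. Consequently the synthetic experiments
exercise the contracts of the method (coverage arithmetic, id propagation,
scheme algebra), not its absolute headline accuracy on real data.

The experiment drivers are `runPeakExperiment()` (co-linear pair-calling
accuracy over reads of known origin, where every adjacent significant-peak
pair within a read is truth-positive) and `runDepletionExperiment()`
(host-depletion style labeled mixture with per-scheme accuracy, sensitivity
and specificity). Problem sizes used by the shipped experiments are 8
haplotypes × 50 kb with 500 × 5 kb reads (peak experiment) and 2000 + 2000
× 1 kb reads (depletion experiment); each completes in about a minute on one
core.

A structural consequence worth knowing when interpreting the peak
experiment: with independent per-haplotype mutation at rate $\mu$, the union
density across $d$ haplotypes is $1-(1-\mu)^d$, and shared exact segments —
hence multi-MUM widths and tunnel lengths — average only
$1/(1-(1-\mu)^d)$ bases. At $\mu = 0.01,\ d = 8$ that is ≈13 bp, so with id
sub-sampling $s=10$ most junctions between adjacent peaks are not flanked by
two samples of the same tunnel and cannot be identified as co-linear. The
package reports what it measures under those conditions; pair-calling
accuracy approaches 1 only as the divergence drops toward real-pangenome
levels and $s$ shrinks, which the paired-comparison tests exercise.

## Numerical and design choices

* **Coordinates.** R-side structures are 1-based and closed (idiomatic R);
  the C++ kernels are 0-based; BED-like TSV exports are 0-based half-open.
* **Threshold tie-break**: smallest argmin position; any argmin preserves
  PML correctness, the choice only fixes determinism.
* **Jump landing**: last position of the preceding run when jumping up,
  first position of the following run when jumping down; the initial tracked
  position is the start of the last run of the read's final symbol. Fixed
  for determinism; they affect which chain id is observed, not PML
  correctness.
* **Mismatch tie rule**: at-or-above the threshold jumps up(ward in
  position); fixed and documented since implementations differ.
* **N in reads** always mismatches and resets, even though N is indexable
  on the reference side.
* **Truncation priority**: descending width then ascending SA rank; the
  non-overlapping property holds under any order, longest-first simply
  keeps long tunnels intact.
* **Sampling phase**: offset 0 (the tunnel's first column) is always marked,
  so matches touching a tunnel head still meet a mark.
* **Peak adjacency**: peaks below the significance threshold are removed
  before pairing, i.e. small chance matches cannot break the adjacency of
  two genuine peaks.
* **Merged PMLs** in scheme (b): positions spanning a co-linear pair get
  $\max(\mathrm{PML}[i],\ \mathrm{end}_2 - i + 1)$ — augmentation is
  monotone.
* **Majority rule**: strictly more than half of the windows; a final
  partial window counts as a window; a read shorter than one window is a
  single partial window.
* **Degenerate inputs**: empty reads give empty results; reads with no
  indexable symbol give all-zero PML/CID; a single-document collection can
  be concatenated but not multi-MUM-indexed (d ≥ 2 is a contract).

## Oracles and what passing tests show

Every nontrivial operation is checked against an independent oracle built
in code: naive suffix sorting for SA/LCP/BWT, brute-force FL for range
stepping and contiguity, exhaustive LCP re-scans for thresholds, substring
enumeration for multi-MUMs, full-array simulation for tunnels, binary-search
matching statistics (themselves verified against a double-loop scan and
direct text decoding) for PML bounds, and per-position tunnel membership
maps for chain-id soundness. The structural results — window disjointness,
$u \le n/d$, $u \le r$, tunnel disjointness as a cardinality identity,
column starts $\le n/d$, the $r'$ bound, single-symbol columns of height
$d$, and scheme (c) = baseline OR (a) — are asserted on every randomized
build in the suite. Passing these shows the implementation honors the
method's contracts; it does not by itself certify classification accuracy
on real pangenomes, which depends on multi-MUM coverage of real data.

## Known limitations

* Direct SA/LCP construction keeps the whole text and arrays in memory;
  builds are intended for hundreds of kilobases, not gigabases.
* Multi-MUM coverage — and with it the usefulness of chain statistics —
  degrades quickly as collections diverge or grow; partial multi-MUMs
  (present in $d-k$ documents), mark smearing, and MEM relaxations are out
  of scope.
* locate() queries, suffix-array sampling, and streaming/adaptive-sampling
  classification are not implemented; the classifier consumes whole reads.
* The reverse-complement strand is indexed only when `revcomp = TRUE`
  (each document is then forward + reverse complement joined without a
  separator); the shipped experiments simulate forward-strand reads and
  omit it.
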