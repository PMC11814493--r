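---
title: "Methods: de novo telomeric repeat discovery and its error sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo telomeric repeat discovery and its error sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloscan)
```

## The discovery procedure

Telomeric repeats are short units (usually 5–12 nt, G-rich on one strand)
arrayed in long tandem runs at chromosome ends. `explore()` finds candidate
units without prior knowledge of the repeat:

1. **Chunking.** For each k in `[k_min, k_max]`, a sequence of length n is
   cut into `floor(n / k)` non-overlapping chunks at fixed phase 0; a
   trailing remainder is ignored.
2. **Run collapse.** Maximal groups of ≥ 2 identical consecutive chunks
   become tandem runs. Chunks containing a character outside A/C/G/T (N or
   another ambiguity code) never join a run; they terminate any run at
   their boundary. Each chunk is compared only with its successor, so the
   scan costs one chunk comparison per chunk — a single pass.
3. **Thresholding.** Runs with fewer than `threshold` chunks are dropped.
   The threshold is expressed in chunk units (a run of 50 six-mers spans
   300 nt), not nucleotides.
4. **Tallying.** Each surviving run adds its *chunk count* — the number of
   repeat units it spans — to the tally of its unit. Tallying units rather
   than runs weights long telomeric arrays more heavily, which matches how
   the table is used: as a relative-abundance ranking of candidates.
5. **Canonical merge.** Tallies are re-keyed by the canonical form of the
   unit: the lexicographically smallest string (plain byte order on
   uppercase A < C < G < T) among all rotations of the unit and all
   rotations of its reverse complement. This merges entries that are the
   same repeat read in a different phase or from the other strand. A unit
   that is a multiple of a shorter unit (a dimer such as `AACCCTAACCCT`) is
   *not* reduced to its primitive root; at chunk sizes that are multiples of
   the true period the array is legitimately read as its dimer or trimer,
   and those rows are reported as they are found.

Fixed-phase chunking is a deliberate simplification: phase-shifted copies of
the same array produce runs of rotated units, and the canonical merge
aggregates them anyway, so rescanning at all k phases would add cost without
changing the ranking. The one thing fixed phase does lose is runs whose
period is not aligned to the chunk grid at any scanned k; those are rare for
the short periods relevant here.

The minimal-rotation step uses Booth's linear-time algorithm; the test suite
checks it against exhaustive enumeration of all 2k rotation/strand
candidates.

### Parameters

* `k_min`, `k_max` (default 5–12): almost all known telomeric units are
  under 15 nt, so 4–15 is the sensible discovery range; the bounds are not
  enforced. Scanning a range matters because the true period is unknown and
  because multiples of it also show up (see above).
* `threshold` (default 100 chunk units): a genuine telomere contributes
  runs of hundreds to thousands of units, whereas background microsatellite
  runs are short. The default is conservative; 50+ keeps the candidate map
  small (the final merge is quadratic in the number of distinct units), and
  lowering it is the documented fallback when nothing is reported.

## Windowed search

`search_motif()` counts exact occurrences of a user motif and of its
reverse complement in non-overlapping windows (default width 10 000 nt, an
adopted convention) tiling each sequence from offset 0. All overlapping
occurrences count; a match belongs to the window containing its start, so
window counts partition the genome-wide match list exactly — an invariant
the tests assert. Matching is delegated to `Biostrings::matchPattern()`;
characters outside A/C/G/T never match any motif position. The TSV emits
both the 0-based window start and the exclusive end, which doubles as the
1-based inclusive end familiar from genome-browser coordinates.

## The clade table

`inst/extdata/clade_repeats.tsv` records canonical repeats reported for
clades surveyed across chromosomally complete reference assemblies:
Chordata `AACCCT` (the `TTAGGG` family), Arthropoda `AACCT`, flowering
plants (`Magnoliopsida`) `AAACCCT`, Vespidae `AACCCAGACCC`, and the genus
*Bombus* with a compound landscape of `AACCCG`, `AACCT` and `AACCCT`.
Loading validates that every entry equals its own canonical form. Because
compound landscapes are real, several rows may share a clade name;
uniqueness is enforced on the (clade, repeat) pair, and `find_clade()` runs
one search per recorded repeat.

## Plotting

`plot_svg()` writes plain SVG 1.1 with inline styling, one track per
sequence (descending length, capped at 25 by default), one polyline vertex
per window. The plotted quantity is `forward_count + reverse_count`: a
telomere may be assembled on either strand, and a single line per
chromosome is the readable form. Output is byte-deterministic — no
timestamps, no generated identifiers, all coordinates formatted to a fixed
two decimals — so plots can be diffed and regression-tested.

## The error simulation

`simulate_telomere()` builds a clean array by tiling the unit to the target
length, then visits each position independently: with probability `rate` it
suffers one event — substitution (uniform over the other three bases),
insertion (uniform base after the position) or deletion — chosen by the
model's event mix. `run_grid()` crosses array lengths {600, 12 000,
30 000} nt with rates {0, 0.1, 1, 1.5, 2, 5, 10}% and evaluates each
condition by pooling all replicates into one multi-record `explore()` call
(k 4–12, threshold 50). Two summaries are reported per grid: the number of
conditions whose most abundant canonical unit (compared across all k
jointly, ties to the lexicographically smallest) equals the true canonical
repeat, and the number of conditions where the true repeat is absent from
the output at every k.

Choices worth stating:

* **Event mix.** The reference configuration uses a uniform 1/3
  substitution / insertion / deletion split — the least-assumption default
  when no platform error profile is being imitated, and one that includes
  the indel component real long-read data has. The mix is exposed as
  parameters, and `scripts/sensitivity.R` sweeps substitution-only,
  indel-only and skewed mixes so the dependence of the two summary counts
  on this choice is measurable rather than assumed.
* **Replicates.** The tests and the acceptance script use 200 replicates
  per condition, a desk-scale choice documented here once; condition-level
  outcomes, not per-replicate counts, are the quantities of interest, and
  they are stable at this size.
* **Seeding.** Per-condition seeds are derived arithmetically from the
  grid seed, so a grid is bit-reproducible and conditions are independent
  of evaluation order.

### What the simulation does and does not emulate

The generator produces pure single-unit arrays with independent per-base
errors. It emulates the dominant failure mode of discovery — run
fragmentation by errors — and how it scales with rate and array length. It
does **not** emulate platform-specific error structure (homopolymer-biased
indels, quality-correlated bursts), higher-order repeat mixtures,
subtelomeric degenerate repeats, or interstitial telomeric sequence. This
matters for interpreting the grid: under independent uniform errors, a
*competing* unit can only out-rank the true repeat if the error process
manufactures a long tandem array of some other period, which at a run
threshold of 50 chunks is vanishingly unlikely at any rate. Consequently,
in this harness the top-ranked unit equals the true canonical repeat in
exactly the conditions where anything is reported at all, and the two
summary counts are complementary. Error processes with strongly correlated
edits (e.g. recurrent single-base dropout within a homopolymer, which turns
a 6-mer array locally into a 5-mer array) would break that complementarity
and let near-variant substrings such as `ACCCT` dominate; passing the grid
here therefore demonstrates robustness to *independent* noise, not to
platform-correlated noise.

The monotone decay of recovered repeat counts with error rate, the
zero-error recovery at every length, and the absence of the true repeat
only at rates ≥ 2% are all asserted or computed by the test suite and the
acceptance script; nothing beyond those computations is claimed.

## Degenerate inputs and numerical conventions

* Coordinates are 0-based half-open internally everywhere.
* `detect_runs()` with fewer than two chunks returns an empty table, as
  does `explore()` on an empty record set; neither is an error.
* Tie-breaks are always lexicographic on the unit, after count ordering.
* `merge_counts()` refuses mixed-length keys; canonicalization refuses
  non-A/C/G/T characters — both are caller errors, not silent drops.
* FASTA records are loaded into memory as a whole table (the R idiom for
  downstream data-frame work) rather than streamed record-by-record;
  per-record memory is bounded by the largest sequence, but file-level
  memory grows with the file. For gigabase-scale input, process files in
  batches.

## Test scales

Property tests run at fixed seeds with: 10^4 random units (k ≤ 20) for the
canonical-form oracle, 10^3 random repeat-rich sequences (n ≤ 500, k ≤ 6)
for the run-detection oracle, 10^3 random (sequence, motif) pairs for the
matcher oracle, and the full 21-condition grid at 200 replicates for the
simulation summaries. These sizes are the package's documented choices for
routine verification; larger runs only tighten stochastic margins.

## Known limitations

* Higher-order repeats (alternating multi-unit blocks, as in *Bombus*)
  fragment single-unit runs and weaken discovery; the harness does not
  simulate them beyond what the clade table documents.
* Telomeres maintained by non-repeat mechanisms (retrotransposon-based, as
  in *Drosophila*) are invisible to this approach, as are very long fungal
  or plant units above the scanned k range.
* Discovery scans the whole sequence, not chromosome ends specifically; on
  assemblies with large interstitial satellite arrays, candidates should be
  validated by `search_motif()` + `plot_svg()` before being accepted as
  telomeric.
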