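# teloscan

Telomeric repeats — short, G-rich units such as `TTAGGG` tandemly arrayed at
eukaryotic chromosome ends — are a key line of evidence when judging whether
an assembled chromosome is complete from telomere to telomere. `teloscan` is
an R package (with a command-line interface) for working with them:

* **de novo discovery** of candidate repeat units in FASTA input,
* **windowed search** for a known motif on both strands,
* a bundled **clade → repeat lookup table**,
* deterministic **SVG line plots** of repeat density along each sequence,
* a **simulation harness** measuring how sequencing error and array length
  affect discovery.

## The algorithm

For each k-mer length *k* in a user-chosen range, each sequence is cut into
non-overlapping chunks of *k* nucleotides (fixed phase, starting at offset
0). Maximal groups of ≥ 2 identical consecutive chunks are collapsed into
tandem runs; runs shorter than a threshold *T* (in chunk units) are
discarded; the surviving runs contribute their unit counts to a tally keyed
by the repeat unit. Finally, tallies are merged under the **canonical form**
of each unit:

> canonical(u) = min over lexicographic order of { all rotations of u } ∪
> { all rotations of the reverse complement of u }

so that, e.g., `TTAGGG`, `GTTAGG` and `CCCTAA` all aggregate under
`AACCCT`. The scan is a single pass per sequence (O(n) per k), and the
canonical merge makes the output independent of the phase and strand on
which a telomere happened to be assembled. Units that are multiples of a
shorter unit (dimers such as `AACCCTAACCCT`) are deliberately *not* reduced
to their primitive root — they are reported as distinct candidates.

## Worked example

```r
library(teloscan)

# a 100-copy TTAGGG array
recs <- data.frame(id = "tel1", seq = strrep("TTAGGG", 100))
explore(recs, explore_config(k_min = 5, k_max = 12, threshold = 50))
#>   canonical_repeat_unit kmer_length count
#> 1                AACCCT           6   100
#> 2          AACCCTAACCCT          12    50

# windowed search for the motif (and its reverse complement)
search_motif(recs, "TTAGGG", window = 300)
#>     id window_start window_end forward_count reverse_count
#> 1 tel1            0        300            50             0
#> 2 tel1          300        600            50             0

lookup_clade("Chordata")[, c("clade", "repeat_unit", "n_species")]
#>      clade repeat_unit n_species
#> 1 Chordata      AACCCT        21
```

The discovery table reports the array once as the canonical 6-mer `AACCCT`
(100 units) and once as its dimer at k = 12 — both correct readings of the
same array at different chunk sizes. The same functionality is available
from the shell via the installed script, e.g.
`exec/teloscan explore genome.fa --minimum 5 --maximum 12 --threshold 100`.

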