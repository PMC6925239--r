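---
title: "Detecting the 28S rRNA hidden break: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the 28S rRNA hidden break: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiddenbreak)
```

## The model

Many animals post-transcriptionally cleave their mature 28S rRNA into
two halves, 28Sα and 28Sβ, which stay hydrogen-bonded until denatured
(the "hidden break"). If a species carries the break, RNA extracted from
it contains essentially no molecules covering the excised interval.
Mapping paired-end RNA-Seq reads onto the species' 28S sequence
therefore produces three diagnostic per-position profiles:

1. **depth**: the number of mapped reads covering each position, which
   collapses over the excised interval;
2. **log₂ forward/reverse strand ratio**: in an FR paired-end library,
   positions near the 3′ end of a source molecule can only be reached by
   reverse-oriented mates and positions near its 5′ end by forward ones,
   so the ratio dips immediately 5′ of the break and rises immediately
   3′ of it;
3. **spanning pairs**: the number of read pairs whose outermost fragment
   interval covers each position — zero across a true break.

The candidate region is located by two conserved 20-mers that flank the
protostome break; they are searched by Hamming distance
(`find_marker()`, `locate_break_region()`). The verdict is a function of
the depth profile only; the strand ratio is reported as confirmatory
evidence (it is noisier than depth), and the spanning-pair profile is
reported but unused (it is nearly collinear with depth).

### The drop score

With flank windows $F$ abutting the outer marker edges and inter-marker
region $R$,

$$s = \frac{\min_{i \in R} d_i}{\mathrm{median}_{i \in F}\, d_i}.$$

The median is robust to local coverage spikes in the flanks, the minimum
is what the eye responds to in a coverage plot, and the ratio makes the
score invariant under uniform depth scaling, so no normalization of the
library is needed. The verdict bands are:

| condition | verdict |
|---|---|
| flank median < `min_flank_depth` (20) | `low_coverage` |
| $s \le$ `t_present` (0.10) | `present` |
| $s \ge$ `t_absent` (0.50) | `absent` |
| otherwise | `ambiguous` |

Visual calls in the literature have no quantitative threshold; these
bands are this package's own formalization. The deliberately wide
ambiguous buffer absorbs sampling noise — at 50× depth a no-break region
minimum occasionally dips below half the flank median by chance, and an
`ambiguous` outcome there is preferable to a false `present`. The
inferred break interval is the maximal contiguous run inside $R$ with
depth $\le$ `t_present` × flank median; ties for the region minimum are
broken leftmost.

## Parameters that matter

* `max_mismatch = 4` per 20-mer (20%). Exact matching cannot locate the
  markers across divergent bilaterian 28S sequences; at 4 mismatches the
  expected number of chance hits on a ~4 kb molecule is still ≪ 1
  (binomial tail of ≥16 matches in 20 at p = 1/4, ×4000 offsets ≈ 4·10⁻⁴).
  `N` counts as a mismatch, never a wildcard, so masked sequences cannot
  create spurious hits. With multiple equally good hits, the leftmost
  5′-marker hit and rightmost 3′-marker hit are chosen — the outermost,
  region-maximizing (conservative) reading of "the region between".
* `flank_len = 500` nt: long enough for a stable median at modest depth,
  short enough to stay on the same molecule arm.
* Aligner: seeds of `k = 21` tiled non-overlapping across the read
  (⌊len/k⌋ seeds, i.e. 4 for a 100 nt read), ungapped extension,
  acceptance at ≤ `max_mismatch_frac = 0.05` of the read length, ties
  broken by leftmost position then forward strand. Tiling all
  non-overlapping seeds guarantees that any read with fewer than
  ⌊len/k⌋ substitutions retains one error-free seed, which makes the
  seed search provably equivalent to a brute-force best-Hamming scan in
  the error regime the package targets — this is checked against an
  independent oracle in the tests.
* Proper-pair insert bounds `[50, 1200]` nt: generous around typical
  RNA-Seq fragment sizes; properness only gates the optional
  `proper_only` depth mode and the SAM flag, not the default profiles.
* `pseudocount = 1` in the log₂ strand ratio keeps zero-count positions
  finite; positions with no covering read at all are additionally
  flagged `no_data` rather than silently reported as balanced.
* Strand profile window: break-region midpoint ± 300 nt, the
  conventional interval for strand-ratio inspection around the break.
* `strand_mode`: `"strand"` partitions reads by alignment orientation
  (SAM flag 0x10); `"pairrank"` reproduces the first-in-pair /
  second-in-pair filter (the samtools `-f 67` / `-f 131` idiom). For an
  FR library the two coincide in expectation; both are provided because
  the flag idiom and the strand language are both in circulation, and
  neither interpretation is asserted to be the other's intent.

## The simulator: what it emulates, and what it does not

`simulate_reads()` draws fragments uniformly from the molecule set —
the whole molecule, or 28Sα/28Sβ after `cleave()`, each weighted by its
length (times `intact_fraction` weighting), so per-base coverage is
uniform across fragments. Inserts are Normal(`insert_mean = 250`,
`insert_sd = 30`) truncated to `[read_len, molecule length]`; mate 1 is
the sense strand of the fragment's 5′ end and mate 2 the reverse
complement of its 3′ end (unstranded FR geometry, which is exactly what
produces the strand-ratio dip/rise without modelling library
chemistry); errors are i.i.d. substitutions at `error_rate = 0.01`.
Defaults — 100 nt reads, 50× depth, 4 kb references, complete cleavage
(`intact_fraction = 0`) — represent a routine short-read RNA-Seq
experiment over a typical 28S.

It does **not** model RNA degradation, secondary-structure or GC
fragmentation bias, indels, quality-score structure, or partial
processing gradients. Passing the end-to-end tests therefore shows that
the statistical machinery recovers a clean cleavage signal at realistic
depth and error rates — not that every real library (degraded, shallow,
or contaminated with genomic rDNA reads) will be callable; real data
can and do fall into the `ambiguous` and `low_coverage` categories.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; every user-facing
  report is 1-based inclusive, the citation convention for rRNA
  positions.
* All sequences are normalized to uppercase RNA (`T → U`, anything
  outside `{A,C,G,U}` → `N`) on input, because the marker constants and
  public 28S sequences circulate in mixed alphabets.
* A zero-width inter-marker region scores the single boundary position;
  a marker pair at a molecule edge gives a degenerate flank and the call
  is downgraded to `ambiguous`; a missing marker yields the verdict
  `no_markers` (a data outcome, not an error).
* Welch's *t* uses sample variances and the Welch–Satterthwaite degrees
  of freedom, erroring on two zero-variance samples; the two-sided
  p-value comes from `stats::pt`.
* Overlapping motif occurrences are counted (`UAAU` in `UAAUAAU` is 2);
  presence/absence summaries are insensitive to this choice.
* SAM import consults columns 1–9 + SEQ only; M/=/X/D/N consume
  reference, I/S query, H/P neither. Reads equally good at several
  positions map leftmost, deterministically.

## Validation strategy and problem sizes

Every non-trivial operation is tested against an independent oracle:
the marker scan against a per-offset character-comparison scan (and
`Biostrings::matchPattern`), the aligner against a brute-force
best-Hamming scan over all offsets and strands, motif counting against
an all-offsets scan, and Welch's *t* against `stats::t.test` to 1e-10.
End-to-end recovery uses 20 break + 20 no-break libraries at 50× and 1%
error on 4.1 kb synthetic references (`make_test_reference()`: 2 kb
random arms around marker5 + spacer + marker3, resampled until each
marker is unique); verdicts must be 40/40 correct with the inferred
break within ±5 nt of the simulated excised interval. These sizes give
each library ~1,000 read pairs, ample for a stable flank median while
keeping the full suite fast.

## Known limitations

* The aligner is ungapped and single-reference: no spliced or indel
  alignment, no competitive mapping against other transcripts. External
  aligners can be substituted via SAM import.
* Marker search is substitution-only; a 28S with an insertion inside a
  marker will show elevated mismatches or drop to `no_markers`.
* Cohort deduplication is keep-first per user-supplied species label;
  no taxonomy resolution is attempted.
* Drops in coverage *outside* the inter-marker region are deliberately
  not interpreted.
* Cross-species comparisons of marker distances ignore phylogenetic
  non-independence; the Welch test treats sequences as i.i.d. samples.
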