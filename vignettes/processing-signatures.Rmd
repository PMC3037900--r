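---
title: "Detecting piRNA processing signatures: methods and design"
author: "piRNApatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting piRNA processing signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRNApatterns)
```

## The signatures

Ping-pong amplification leaves a geometric fingerprint in small-RNA
libraries. A piRNA bound by a Piwi protein cleaves its complementary
target between the bases paired to piRNA nucleotides 10 and 11; the 3'
fragment of the target becomes a secondary piRNA whose 5' end therefore
overlaps the guide's 5' end by 10 nt. In genome coordinates, reads from
opposite strands related this way have 5' ends offset by Δ = 9. The 5'
fragment of the cleaved target is not always lost: libraries that retain
reads below 23 nt show a second population, sharply peaked at 19 nt,
sitting immediately upstream of the secondary piRNA with its 3' end
defined by the same cleavage. Relative to the guide's 5' end, the 19-mer's
5' end lies 28 nt away — 19 (its own length) plus 9. These are the P9 and
P28 patterns; a locus carrying both, with the 19-mer directly abutting the
secondary piRNA, is a *triplex* locus.

The pipeline operates on mapped, collapsed reads. Following standard
practice for this analysis, only reads that mapped uniquely (one locus)
and perfectly (edit distance zero) are used, and the mitochondrial
chromosome is excluded; the filter accounting is logged so real-data runs
can be compared with published per-library tables out of band.

## The distance spectrum

All offset arithmetic runs over strand-resolved weight maps:
`weight+(i)` is the summed copy number of reads with a (0-based) 5' end
at plus-strand position *i*, and likewise `weight-(i)`. The pair count at
offset Δ is

$$\mathrm{pairs}(\Delta) = \sum_i \min\bigl(weight^+(i),\; weight^-(i+\Delta)\bigr),$$

i.e. a locus with 3 sense copies and 7 antisense copies contributes
exactly 3 pairs at its offset. The minimum is deliberate: multiplying the
two counts would let a handful of hyper-abundant loci dominate the
histogram. The even stricter `locusSpectrum()` counts each qualifying
position pair once; on clean data both place their maxima at the same
offsets. The minimum is taken *after* per-position aggregation within a
length class — weights first, min second — which matters whenever several
sequences share a 5' end.

Length matters only through class membership. The presets mirror the
standard read subsets: `all_15_35`, `long_long` (23–32 nt on both
strands, isolating P9), `long_short` (23–32 vs 15–22) and `long_19`
(23–32 vs exactly 19 nt, isolating P28). For the asymmetric presets the
two class assignments (long-on-plus and long-on-minus) are both computed
and summed, so Δ always means (minus-strand 5') − (plus-strand 5')
regardless of which strand carries the short read.

The default offset window is Δ ∈ [−20, 50]. Both signature offsets (9
and 28) sit comfortably inside with margin on both sides, and the
negative half is retained because the strand-swap symmetry
(swap maps, negate Δ) is a useful internal check. The window is a plain
argument for users who want a wider view. When a spectrum is identically
zero its argmax is reported as `NA` rather than an arbitrary offset; ties
resolve to the smallest offset, which keeps repeated runs deterministic.

## Sites, centers and triplexes

`detectP9Sites()` and `detectP28Sites()` enumerate the loci behind the
two peaks, carrying every member sequence with its copy number (several
long reads may share a 5' end; they form one site). The short class for
P28 detection defaults to exactly 19 nt — the by-product length is
essentially invariant — but is configurable: beta-eliminated libraries,
in which unmethylated RNAs lose one 3' nucleotide, shift the by-product
to 18 nt, and `shortLen = 18` reproduces that analysis. For spectra and
cleavage-pair extraction the short side defaults to the full 15–22 nt
interval instead, because there the question is the length *distribution*
rather than site membership.

Co-localization is tested positionally. Each site is anchored at
`floor((fp_plus + fp_minus)/2)`, the nucleotide midway between the two
members' 5' ends. The floor convention is load-bearing: a P9 interval has
odd span (offset 9), so rounding its midpoint down places the P9 center
of a plus-strand-19-mer triplex 9 nt downstream of the P28 center and 10
nt upstream for the minus-strand case, giving the characteristic
asymmetric peak pair at lags −9 and +10. Rounding up would mirror the
pair to −10/+9. Cross-correlation itself is the raw sliding dot product
of binary indicator vectors within a ±50 window, accumulated per
chromosome; no normalization is applied because the readout is the peak
*position*, which affine rescaling cannot move.

`detectTriplexes()` matches P9 against P28 sites exactly: the P28 long
member must coincide with the P9 member opposite the 19-mer, and one
19-mer's span must end exactly one nucleotide before the same-strand
piRNA's 5' end. No tolerance window is offered — the geometry being
tested is exact, and fuzzy matching would blur the distinction between a
triplex and two unrelated sites.

## Locus statistics

**Strand bias.** P28 sites are ordered by chromosome and center
coordinate, and the sequence of orientations (T = 19-mer on plus, B = on
minus) is treated as a two-state Markov chain; transitions are counted
only between consecutive sites on the same chromosome, and estimates are
the maximum-likelihood row normalizations, e.g.
$p_{T\to T} = n_{T\to T} / (n_{T\to T} + n_{T\to B})$. A state never
observed leaves its row undefined (`NA`, flagged as such in the TSV) —
not 0/0. The sort key could equally be the 19-mer's 5' end; the two
orderings differ only if distinct sites interleave within 14 nt, which
non-overlapping loci cannot do. Center order was chosen as the more
symmetric convention.

**Composition.** At triplex loci the piRNA opposite the 19-mer is the
presumed cleavage guide, and its position-1 nucleotide composition is
tallied separately from the same-strand (secondary) piRNA's. By default
each distinct member sequence casts one vote; copy-number weighting is
available, and the report emits both, since either convention is
defensible and the contrast between the two groups — strong 1U on the
guide side, weaker on the secondary side — is the scientific readout in
either weighting.

**Length pairs.** Every opposite-strand pair in which a 15–22 nt read's
3' end lies 10 nt downstream of a 23–32 nt read's 5' end (in the long
read's own orientation) yields one cleavage pair; the 2-D tally over
(product length, guide length) is the raw matrix behind the familiar
contour plot, and its product-length marginal is the by-product length
histogram. "Downstream" for a minus-strand guide at 5' coordinate *g*
means genomic coordinate *g* − 10; this is the convention that makes the
28 = 19 + 9 identity hold.

## The simulator

`simulateDataset()` generates what the analysis assumes as input:
collapsed, uniquely and perfectly mapped reads of 15–35 nt on synthetic
chromosomes. Planted triplex loci emit three reads in the exact
geometry above (19-mer, secondary piRNA abutting it, guide on the other
strand at 5'-to-5' offset 28); P9-only loci emit a duplex without the
by-product; background reads are uniform in position, strand and length.
Defaults are the conditions the analysis is characterized by: by-product
length 19, guide 1U probability 0.78, same-strand 1U probability 0.44,
strand-stay probability 0.982, and geometric copy numbers with mean 3
(so the weighted-minimum rule is exercised with unequal weights). Guide
and secondary piRNA lengths are drawn uniformly from 23–32 nt: observed
guide-length distributions are broad across this range with no canonical
parametric form, and a uniform draw exercises every length bin of the
histogram. Loci are placed on a 128-nt grid, which is at least twice the
maximal read extent, so planted configurations can never overlap; a
configuration that does not fit raises an error suggesting a longer
chromosome rather than silently clustering loci.

Reads carry their own sequences — random bases apart from the biased
first position — and no reference genome is simulated, since no analysis
stage needs flanking sequence. The simulator is deliberately clean: no
sequencing errors, no multi-mappers, no adapter remnants, no overlap
between planted loci, and plus/minus reads at one locus are not actually
complementary. Passing tests on simulated data therefore demonstrate the
*geometric and statistical correctness* of the detectors and estimators,
not robustness to alignment artifacts or to genomes where piRNA clusters
overlap repeats; on real libraries the upstream mapping filter carries
that burden.

## Numerical and interface conventions

* Coordinates are 0-based in every reported table and in the BED-like
  dialect; the in-memory `GRanges` container keeps Bioconductor's
  1-based convention, and `fivePrimeEnd()` is the single point of
  conversion. A minus-strand read's 5' end is its highest genomic
  coordinate; this is fixed, not configurable, because all offset
  arithmetic depends on it.
* SAM input is converted with the standard 1-based rules; minus-strand
  sequences are reverse-complemented back into read orientation.
  Copy numbers use the collapsed-FASTA `*_xN` name convention; a
  missing `NH` tag falls back to query-name collisions for multi-mapper
  detection.
* Degenerate inputs are defined, not errors: empty maps give all-zero
  spectra, empty site lists give empty center sets and empty reports,
  and an empty simulated dataset round-trips through the fixture files.
* All site and triplex tables are sorted by chromosome and coordinate,
  so outputs are byte-identical across runs and input permutations.

## Problem sizes

The shipped tests validate each operation against independent
brute-force oracles (exhaustive all-pairs spectra on instances of up to
50 occupied positions, quadratic scans for P9 sites and cleavage pairs)
and run the full pipeline on planted datasets of 100–500 triplex loci,
with parameter-recovery checks on 2,000-site Markov chains and
1,000+ triplex composition tallies — sizes at which binomial sampling
error is well below the assertion tolerances while the whole suite runs
in well under a minute.

## Limitations

The package consumes mapped reads; it does not align, trim or handle
color space. No significance model is attached to spectra or to the
cross-correlation (peak positions, not p-values, are the readout), sites
are not clustered into piRNA clusters, and no genome annotation overlap
is computed. Real-data headline counts (loci per library, fraction of
reads in the two peaks) depend on the specific library and mapping
pipeline and are reported by `runReport()` for out-of-band comparison
rather than asserted by the test suite.
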