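# piRNApatterns

Genome-wide detection of piRNA processing signatures in mapped small-RNA
sequencing reads.

In animal germ lines, Piwi-associated small RNAs (piRNAs, typically
23–32 nt) silence retrotransposons through the ping-pong amplification
cycle: a piRNA guides cleavage of a complementary transcript between the
bases paired to its nucleotides 10 and 11, defining the 5' end of a
secondary piRNA on the opposite strand. The hallmark of this cycle is a
10-nt overlap between the 5' ends of reads from opposite genomic strands
— an offset of Δ = 9 between 5' coordinates. Libraries that keep reads
below the piRNA size range additionally show a second, equally sharp
signature: short by-products, almost always exactly 19 nt, whose 3' end
lies opposite position 11 of the guide piRNA and whose 5' end sits 28 nt
from the guide's 5' end. `piRNApatterns` finds both patterns, tests
whether they co-occur, and summarizes the loci that carry them.

For readers of small-RNA libraries (SAM/BAM or a BED-like TSV dialect of
collapsed reads), the package provides:

* **5'-offset distance spectra.** For strand-resolved weight maps
  `weight±(i)` (summed copy numbers of reads with a 5' end at position
  *i*), the pair count at offset Δ is the weighted minimum

      pairs(Δ) = Σᵢ min( weight⁺(i), weight⁻(i + Δ) )

  so a locus with 3 sense and 7 antisense copies contributes 3 pairs —
  abundant reads cannot dominate the histogram. A stricter locus-count
  variant and length-class presets (all 15–35 nt; 23–32 vs 23–32;
  23–32 vs 15–22; 23–32 vs exactly 19 nt) reproduce the standard
  analyses.
* **Site detection.** P9 sites (two long reads at Δ = 9), P28 sites (a
  19-mer and a long read at Δ = 28, tagged P28T/P28B by the 19-mer's
  strand), and guide/product cleavage pairs (product 3' end opposite
  guide position 11).
* **Co-localization.** Floor-midpoint centers of P9 and P28 sites,
  their positional cross-correlation (peaks at lag −9 for P28T and +10
  for P28B when the patterns share loci), and exact triplex loci:
  guide piRNA + secondary piRNA + 19-mer immediately upstream of the
  secondary piRNA.
* **Locus statistics.** A two-state Markov model of 19-mer strand bias
  along chromosomes (maximum-likelihood transition probabilities),
  position-1 nucleotide composition of triplex piRNAs split by strand
  relative to the 19-mer (the 1U bias contrast), and the guide/product
  length-pair histogram.
* **A synthetic-data generator** that plants triplex loci, ping-pong
  duplexes and uniform background reads with a ground-truth table, so
  the whole pipeline is testable without any downloads.

## Worked example

```r
library(piRNApatterns)

cfg <- simulationConfig(nTriplexLoci = 300, nBackgroundReads = 2000, seed = 42)
ds  <- simulateDataset(cfg)
res <- runReport(ds$reads, "demo_out")
#> total mappers: 2900 records, 8585 read copies
#> perfect unique mappers: 2900 records, 8585 read copies
#> P9 loci: 300; P28 loci: 300 (135 P28T, 165 P28B)
#> triplex loci: 300

res$spectra$long_long
#> DistanceSpectrum (pairs mode): delta -20..50, preset long_long
#>   total count 566; argmax at delta = 9
res$spectra$long_19
#> DistanceSpectrum (pairs mode): delta -20..50, preset long_19
#>   total count 534; argmax at delta = 28
```

The two spectra peak at Δ = 9 (ping-pong duplexes) and Δ = 28 (19-mer
by-products); all 300 planted triplex loci are recovered despite the
2,000 uniform background reads. The strand-bias model and composition
report recover the simulation parameters (stay probability 0.982,
guide 1U 78%, same-strand 1U 44%) within sampling error:

```r
res$strandBias
#> MarkovStrandBias: 300 sites, 298 transitions
#>   transition probabilities:
#>        T      B
#> T 0.9701 0.0299
#> B 0.0244 0.9756
res$composition$unweighted
#>         group          A          C          G         U n_members n_weight
#> 1 same_strand 0.13666667 0.19000000 0.19333333 0.4800000       300       300
#> 2    opposite 0.06666667 0.07333333 0.07333333 0.7866667       300       300
```

`runReport()` writes every table (spectra, site lists, cross-correlation,
triplexes, transitions, composition, length histogram, summary) as TSV
into the output directory. The same stages are available from the shell
via the thin CLI at
`system.file("scripts", "pirnapatterns.R", package = "piRNApatterns")`,
with subcommands `simulate`, `spectrum`, `sites`, `colocalize`,
`strandbias`, `composition` and `report`.

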