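# mrakit

Design and validation toolkit for **Multiplex Restriction Amplicon
Sequencing (MRASeq)** genotyping panels.

MRASeq reduces genome complexity by PCR instead of restriction
digestion/ligation: primers anchored 3' in PstI (CTGCAG) and MspI (CCGG)
recognition sites amplify the 60–250 bp genomic inserts between
neighbouring sites, and a second PCR on a universal M13 tail adds the
sequencing adapter and a per-sample barcode. Because a primer is just the
recognition site preceded by the 6–12 adjacent genomic bases, a handful of
primer pairs — or one IUPAC-degenerate pair — can amplify thousands of loci
in a large genome. The approach needs no enzymatic library steps and yields
reads a GBS-style SNP caller (e.g. TASSEL) can consume after light
preprocessing.

`mrakit` is for anyone designing such a panel from a reference genome, or
validating one without wet-lab iteration:

* **mining** — `find_amplicons()` locates every restriction-delimited
  amplicon target (length window, no intervening sites, either
  orientation), with spacing (`gap_stats()`), per-Mb density
  (`amplicon_density()`) and length-spectrum (`length_spectrum()`)
  summaries;
* **primer ranking** — `count_primer_pairs()` tallies genome-wide amplicon
  counts per distinct restriction-anchored k-mer primer pair under a
  nearest-neighbour Tm screen (`nn_tm()`, SantaLucia–Hicks parameters with
  Owczarzy salt correction; thresholds 38 °C for 12-mers, 50 °C for
  16-mers); `top_pairs()` extracts ranked pools;
* **degenerate design** — `consensus_degenerate()`, `iupac_degeneracy()`,
  `iupac_expand()` for dMRASeq primer sets with exact degeneracy
  arithmetic; `build_fusion_primers()` assembles the two-step-PCR fusion
  oligos (M13 tail, trP1B, Ion-A constants included);
* **in-silico PCR** — `predict_amplicons()` evaluates a specific pool or a
  degenerate pair against any genome; `simulate_library()` emits barcoded
  variable-length reads with the full construct structure plus a truth
  table;
* **read preprocessing** — `strip_intervening()` excises tail + spacer so
  reads start `barcode + remnant site` (quality strings co-edited),
  `pad_polya()` appends the 80-A tail short reads need to survive tag-based
  callers;
* **genotype filtering** — `marker_stats()` / `filter_markers()` apply
  call-rate (MCR), minor-allele-frequency and heterozygosity thresholds to
  HapMap- or VCF-imported matrices; `simulate_ril_matrix()` provides
  synthetic biparental material.

A synthetic-genome generator (`generate_genome()`) plants amplicon
constructs at recorded coordinates in motif-free background, so every
pipeline stage can be tested for exact recovery against known truth.

## Worked example

```r
library(mrakit)

# a 3-chromosome synthetic reference with six planted amplicon targets
gen <- generate_genome(n_chrom = 3, chrom_len = 6000, gc = 0.45,
                       planted = c(100, 120, 150, 90, 180, 130), seed = 101)
gen$genome
#> mra_genome with 3 sequence(s), 18,000 bp total
#>   chr1: 6000 bp
#>   chr2: 6000 bp
#>   chr3: 6000 bp

amp <- find_amplicons(gen$genome)          # PstI/MspI, 60-250 bp inserts
head(as.data.frame(amp), 3)
#>   chrom insert_start insert_end orientation insert_len left_site right_site
#> 1  chr1         1901       2001     A-first        100      PstI       MspI
#> 2  chr1         4079       4169     A-first         90      PstI       MspI
#> 3  chr2         1831       1951     A-first        120      PstI       MspI

gap_stats(amp)                             # start-to-start spacing per chrom
#>   chrom n mean_gap sd_gap max_gap
#> 1  chr1 2     2178     NA    2178
#> 2  chr2 2     2152     NA    2152
#> 3  chr3 2     2196     NA    2196

# rank specific 12-mer primer pairs (77-202 bp window, Tm >= 38 degC)
pc <- count_primer_pairs(gen$genome, kA = 12, kB = 12)
as.data.frame(pc)[, c("a_primer", "b_primer", "count", "cum_share")]
#>       a_primer     b_primer count cum_share
#> 1 ACAAACCTGCAG CCCCTAGCCCGG     1       0.5
#> 2 GCTGGACTGCAG CCCTGGTCCCGG     1       1.0

nn_tm("AAAAAACTGCAG")                      # anchored primer Tm, degC
#> [1] 34.66866

# a dMRASeq pair: degeneracies 48 (PstI side) x 384 (MspI side)
iupac_degeneracy("NNVCTGCAG") * iupac_degeneracy("NNNVMCCGG")
#> [1] 18432
```

Each row of the mined table is one amplifiable locus (0-based half-open
insert coordinates, sites excluded). The pair-count table says which primer
pairs recur — on a real genome the top pairs recur tens of thousands of
times, which is what makes a small pool viable. The degeneracy product is
the number of concrete oligo sequences in a degenerate pair's synthesis
mix.

A command-line wrapper covering the same flow (simulate-genome, mine,
rank-pairs, preprocess, filter-geno) is installed at
`system.file("cli", "mrakit", package = "mrakit")`.

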