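---
title: "Designing multiplex restriction amplicon panels with mrakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multiplex restriction amplicon panels with mrakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrakit)
```

## The method

Multiplex Restriction Amplicon Sequencing (MRASeq) is a PCR-based
genome-complexity-reduction genotyping platform. Instead of digesting and
ligating DNA as genotyping-by-sequencing (GBS) does, it amplifies the short
genomic *inserts* that lie between a PstI site (CTGCAG) and a nearby MspI
site (CCGG). The primers are anchored: each ends 3' in the recognition site
itself, preceded by the 6–12 genomic (or degenerate) bases adjacent to the
site, so a primer pair selectively amplifies the loci whose flanks it
matches. A second PCR on a universal M13 tail adds the sequencing adapter
and a per-sample barcode, producing a GBS-compatible library with no
enzymatic steps.

`mrakit` implements the computational machinery around that assay:

1. **Amplicon mining** (`find_amplicons`) — all genomic segments flanked by
   one site of each enzyme, with insert length (sites excluded) inside a
   window, no intervening site of either enzyme, in either orientation.
2. **Primer ranking** (`count_primer_pairs`, `top_pairs`) — genome-wide
   tallies of identical restriction-anchored primer pairs under a
   nearest-neighbour Tm screen, exploiting the observation that a few flank
   contexts recur thousands of times in large genomes.
3. **Degenerate design** (`consensus_degenerate`, `iupac_degeneracy`) — IUPAC
   consensus primers with exact degeneracy accounting.
4. **In-silico PCR and library simulation** (`predict_amplicons`,
   `simulate_library`) — which loci a pool or degenerate pair amplifies, and
   reads with the full two-step-PCR construct structure.
5. **Read preprocessing** (`strip_intervening`, `pad_polya`) — rewriting raw
   reads into the barcode + remnant-site layout GBS SNP callers key on.
6. **Genotype filtering** (`marker_stats`, `filter_markers`) — call-rate,
   minor-allele-frequency and heterozygosity filters with per-criterion
   accounting.

## Mining definitions

An amplicon's coordinates are the insert only, 0-based and half-open;
restriction sites are excluded from the length, matching the assay's length
accounting. The default mining window is 60–250 bp (PCR-amplifiable,
sequencer-sized inserts); primer-pair counting uses a tighter 77–202 bp
window by default.

* *Intervening site*: any occurrence of either recognition motif whose
  interval intersects the insert. The two flanking sites themselves are
  exempt, so partially overlapping site occurrences at the flanks do not
  disqualify a locus, but opposite-type occurrences that overlap *each
  other* cannot delimit an amplicon and are tallied in the
  `skipped_overlap` attribute instead.
* *Orientation*: PstI and MspI recognitions are palindromic, so orientation
  is recorded purely from forward-strand order of the two site types
  (`A-first` / `B-first`). For non-palindromic enzymes both strands are
  scanned and occurrences merged per locus.
* Recognition sites containing `N` never match — conservative on gapped
  assemblies.
* Spacing statistics (`gap_stats`) use start-to-start distances between
  consecutive inserts on a chromosome. Start-to-start differs from
  end-to-start by roughly one insert length and is the definition we fix
  because it is insensitive to the length of the upstream insert.
* The length spectrum's linear trend is ordinary least squares of count on
  integer insert length; we report r² as the squared correlation, defining
  it as 0 for a perfectly flat spectrum (no explainable variance) instead of
  leaving a 0/0.

A same-type pair of adjacent sites (PstI…PstI) is never an amplicon: the
two-enzyme chemistry requires one primer of each kind. Loci discoverable in
"both orientations at once" cannot arise with two distinct enzymes — each
locus has exactly one site type on each side — so mined counts involve no
orientation deduplication.

## Nearest-neighbour Tm

`nn_tm` uses the unified SantaLucia–Hicks dinucleotide enthalpies/entropies
with terminal initiation terms, the CT/4 duplex convention for
non-self-complementary primers (CT for palindromes, with the symmetry
entropy penalty), and the Owczarzy inverse-temperature salt correction
covering monovalent cations, free Mg²⁺ and dNTP chelation
(Ka = 3·10⁴ M⁻¹). Defaults — 50 mM monovalent, 1.5 mM total Mg²⁺, 0.2 mM
dNTP, 200 nM primer — describe standard PCR-like conditions; all are
exposed through `thermo_params()` because only the screening thresholds
matter downstream and published pair counts are mildly sensitive to the
ionic assumptions. Reverse-complement symmetry is exact by construction of
the parameter table.

The screen thresholds are anchored at 38 °C for 12-mers and 50 °C for
16-mers. For intermediate lengths `tm_threshold()` interpolates linearly
(3 °C per added base) and holds 50 °C above 16 — a documented,
configurable choice; only the two anchors are externally specified.

The test suite cross-checks `nn_tm` against an independently coded
implementation (Biopython's `MeltingTemp`, values frozen at
`tests/testthat/tm_reference.tsv` over 1,001 primers); agreement is within
0.12 °C, the residual being dominated by the gas-constant precision each
implementation carries.

## Primer-pair counting

Each qualifying amplicon contributes exactly one count to its
(A-primer, B-primer) key, so pair counts always sum to the number of
qualifying amplicons — a conservation law asserted throughout the tests.
The A primer is always the PstI-side sequence regardless of which site
comes first on the forward strand: palindromic sites make orientation
chemically irrelevant to the primer pair. Primers containing `N` are
unsynthesizable and excluded. Ranking is by count descending with a
lexicographic (A, B) tie-break so tables are reproducible. We count
distinct (A, B) pairs; pairs sharing a single primer are not collapsed.

Degenerate sets are built by `consensus_degenerate` — the per-position
IUPAC union of the chosen specific primers. The union is minimal per
position but can over-cover across positions (the {AC, GT} → RY example has
degeneracy 4 for 2 inputs); this is inherent to single-oligo degenerate
synthesis.

## The synthetic-data generator

`generate_genome` emulates a reference genome with a *known* amplicon
content: background DNA is drawn at the requested GC and re-sampled
per window until it contains no occurrence of either recognition motif on
either strand, then `site + insert + site` constructs are planted at
recorded coordinates (inserts are themselves motif-free, and junctions are
patched if a boundary-spanning occurrence appears). Consequently the motif
occurrence set equals the planted-site set exactly, and mining can be
scored for exact precision/recall against the truth table.

Two spacing parameters shape realism versus testability: `margin` (default
30 bp) guarantees primer-extractable flanks at chromosome ends, and
`min_gap` (default 260 bp) keeps consecutive constructs farther apart than
the default mining window, so the spacing between two plants can never
itself qualify as an amplicon. What the generator deliberately does *not*
emulate: genome-scale motif densities (real backgrounds contain sites every
few hundred bases), repeat structure, assembly gaps, and centromeric
density gradients. Passing the recovery tests therefore demonstrates the
correctness of the mining logic, not performance claims about any real
genome; the random-background oracle tests (motifs permitted everywhere)
cover the dense-site regime instead.

`mutate_genome` derives biparental material: substitutions at a fixed rate
with recorded positions/alleles, optionally masked away from recognition
sites so both parents keep identical amplicon content.

## Library simulation and preprocessing

Reads follow the two-step-PCR construct: `barcode + M13 tail + spacer +
CTGCAG + insert + CCGG + revcomp(spacer_B) + revcomp(trP1B)`, with the
insert presented PstI-side-first (reverse-complemented for B-first loci)
because sequencing proceeds from the barcoded adapter. Per-amplicon depth
is negative-binomial (`dispersion = 0` gives fixed depth for exact
round-trip tests); read lengths are truncated normal with a 25-nt floor,
clipped to the construct; sequencing noise is substitution-only (no
homopolymer indels), flagged by a low quality character against an
otherwise constant high quality — downstream GBS callers ignore quality by
default, so the string carries provenance rather than calibration.

`strip_intervening` rewrites `barcode + tail + spacer + full site` into
`barcode + remnant`, editing the quality string at identical offsets (the
remnant keeps the quality of the site bases it derives from). The default
remnant is `TGCAG` — the recognition minus its leading base, the
GBS-caller keying convention — with the full-site alternative available by
configuration since the assay literature does not pin the definition down.
Barcode matching is exact and longest-first; unmatched reads are dropped
(default) or passed, and every disposition is tallied so input = emitted +
dropped always holds. Reads already in barcode + remnant form are
recognized as conforming and kept, which makes the transform idempotent —
running the preprocessor twice is safe.

`pad_polya` appends 80 A bases (quality `!`) so short amplicon reads
survive the 64-base minimum that tag-based SNP callers impose.

## Genotype filters

`marker_stats` uses standard biallelic accounting: homozygotes contribute
two copies of their allele, heterozygotes one of each, all over non-missing
calls. The minimum call rate (MCR) is defined as the fraction of samples
with a non-missing call — note this is a *call-rate*, not an
allele-carriage, definition; the two are sometimes conflated in assay
descriptions, and call-rate is the reading consistent with tag-based SNP
pipelines. `filter_markers` applies MCR ≥, MAF ≥ and heterozygosity ≤
thresholds (defaults 0.2 / 0.2 / 0.1, the biparental setting; MAF 0.05
suits natural populations), attributing each removed marker to the first
criterion it fails in the order MCR → MAF → het.

`simulate_ril_matrix` draws independent markers (no linkage) with
configurable residual heterozygosity, missingness and a MAF sampler
(default uniform 0.2–0.5, typical of segregating biparental markers); it
exists to give the filters a material whose expected statistics are known.

## Problem sizes and numerical choices

The test suite and the acceptance script work at desk scale: 100 random
50-kb genomes for the brute-force mining oracle, 50 planted genomes with
10–50 amplicons each for recovery, 1,001 primers for the Tm cross-check,
and a 100,000-read library for the end-to-end preprocessing round trip —
sizes chosen so the full suite runs in well under a minute per property
while still exercising every code path. Degeneracy identities are verified
by exhaustive expansion up to degeneracy 1,024. Coordinates are 0-based
half-open everywhere internally; exported HapMap/BED-adjacent text uses the
convention of each format, noted per column.

## Limitations

* No mismatch thermodynamics, hairpin/dimer screening, or off-site binding:
  matching is anchored flank identity, the selectivity mechanism of the
  assay; primer QC beyond Tm follows standard design guidelines and is out
  of scope.
* No PCR efficiency or amplification-bias modeling; depth overdispersion is
  a statistical stand-in.
* Substitution-only error model (no Ion-style homopolymer indels).
* SNP calling itself (TASSEL/BWA) is consumed, not reimplemented: the
  package produces caller-compatible reads and filters caller output.
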