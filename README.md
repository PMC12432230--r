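# lineprimer

Design and in-silico validation of PCR primers that preferentially amplify
individual **subfamilies of a highly homologous repeat lineage**, modelled on
the human LINE1 L1PA series (L1PA17, the oldest, through L1PA2 to the
human-specific, retrotransposition-competent L1HS).

## The problem

LINE1 subfamilies arose as successive waves of retrotransposition: each
subfamily's consensus differs from its neighbours by a sprinkling of
substitutions, and the thousands of genomic copies of each subfamily have
diverged further, individually and mostly with 5'-truncation. Conventional
primer design fails here — almost any primer on a LINE1 consensus matches
thousands of loci across many subfamilies. What *can* discriminate a
subfamily is a **subfamily-specific base**: an alignment column where that
subfamily's consensus base differs from every other subfamily in the
comparison set. A primer pair whose two footprints each cover such a base —
ideally at the 3' terminus, where a mismatch blocks extension — amplifies
predominantly the intended subfamily.

`lineprimer` automates that workflow end to end:

1. **diagnose** — align subfamily consensuses (star-progressive
   Needleman–Wunsch, or accept an external MSA), find discriminating columns
   for a chosen target relative to an explicit comparison set, and enumerate
   candidate regions of ≤ 200 bp with discriminating bases at both ends;
2. **design** — enumerate every primer-footprint placement in a region under
   length (18–22 nt), %GC (35–60), optional Tm and product-size constraints,
   ranked by Tm balance; %GC = 100·(G+C)/N, Tm by the Wallace rule
   2(A+T)+4(G+C) or the SantaLucia unified nearest-neighbor model;
3. **in-silico PCR** — mismatch-tolerant (Hamming ≤ `max_mismatch`),
   3'-anchored (`anchor_len` exact terminal bases) binding-site search on
   both strands, paired into products within a size window;
4. **score / validate** — assign predicted amplicons and sequenced fragment
   intervals to annotation categories by majority overlap (per subfamily,
   `other_LINE1`, `non_LINE1`), build the four standard annotation tracks
   (all elements, genomic complement, full-length > 6 kb, full-length ∩
   intact), call "amplified loci" (merged intervals with ≥ 3 supporting
   fragments), and sum per-locus FPKM = 10⁹·c/(L·T) by subfamily.

A seeded simulator (`sim_params()`, `simulate_lineage()`, `plant_copies()`,
`simulate_fragments()`) generates a diverging consensus lineage, a genome
with planted, individually diverged and 5'-truncated copies, matching
annotation, and fragment sets, so the whole pipeline is testable with no
downloads.

## Worked example

```r
library(lineprimer)

# the packaged reference panel of six L1PA subfamily-selective primer pairs
panel <- l1pa_primer_panel()
head(panel[, c("pair", "orientation", "target", "seq", "gc_percent")], 4)
#>   pair  orientation target seq                    gc_percent
#> 1 P1    F           L1HS   GACATCTACACCGAAAACCC         50
#> 2 P1    R           L1HS   TCGTCAAAATCATTCTCCATCC       40.9
#> 3 P2    F           L1PA3  ACCAGCCACTGCAAAATC           50
#> 4 P2    R           L1PA3  CCAATTTGCCAGTCTGTGTC         50

melting_temperature(panel$seq[1], "wallace")       # 60
melting_temperature(panel$seq[1], "nn_santalucia") # 53.57911

# full pipeline on a simulated lineage: 6 subfamilies, 7-kb consensus,
# 2% divergence per lineage step, 30 copies each at 3% copy divergence
run <- run_pipeline(run_config(seed = 1), outdir = tempfile())
glance(run)
#>   target best_pair  n_amplicons target_percent target_or_adjacent_percent
#> 1 SF01   SF01_pair3          12            100                        100
```

`target_percent` is the share of predicted amplicons assigned to the target
subfamily's annotation (here: all 12 products of the best pair land on SF01
copies — the youngest subfamily, the analogue of L1HS). `run$report` holds
the full per-category breakdown, `run$pair_scores` the same summary for
every evaluated pair, and the output directory contains each stage's
plain-text files (`consensus.fa`, `annotation.bed`, `primers.tsv`,
`amplicons.bed`, `report.tsv`, ...) plus a manifest of md5 checksums;
rerunning the same config reproduces them byte-identically.

## Scope

The package consumes consensus FASTA, genome FASTA, RepeatMasker `.out` or
BED annotation, aligned FASTA, and fragment/locus BED. Read QC, mapping and
alignment filtering are upstream of it (fragment intervals come in as BED),
and wet-lab steps are out of scope by nature. Internal coordinates are
uniformly 0-based half-open; conversion from the 1-based-inclusive `.out`
convention happens only in the parser.
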