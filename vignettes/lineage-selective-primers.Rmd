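---
title: "Designing subfamily-selective PCR primers for repeat lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing subfamily-selective PCR primers for repeat lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A repeat lineage such as LINE1 L1PA is a series of subfamilies of decreasing
evolutionary age. Each subfamily has a consensus sequence; adjacent
consensuses differ by substitutions accumulated between retrotransposition
waves, and the genomic copies of each subfamily have diverged further from
their own consensus, mostly with additional 5'-truncation. Two properties of
this system drive everything in `lineprimer`:

* **within-lineage homology is extreme** — a primer placed arbitrarily on
  one consensus usually matches most subfamilies, so selectivity cannot come
  from placement alone;
* **subfamily identity is carried by sparse diagnostic bases** — alignment
  columns where one subfamily's consensus base differs from every other
  subfamily in the comparison set.

`lineprimer` formalises "subfamily-specific" as: *the target's residue is a
base (not a gap) and differs from the residue of every other member of an
explicit comparison set*. The comparison set is a parameter because
specificity is inherently relative — a primer discriminating the youngest
subfamily from its five nearest relatives is a different problem from
discriminating the two oldest members of the lineage, and the two problems
use different alignments. A gap in a *non-target* row counts as different
(a base versus its absence is discriminating for hybridisation); a gap or
`N` in the *target* row never does, since the primer must physically cover
a defined base.

Candidate amplicon regions are windows of at most `max_region_len` (default
200 bp, the size class favoured for qPCR amplicons) containing diagnostic
positions near both ends, such that the forward primer footprint can cover
the left one and the reverse primer footprint the right one. The region
extends one maximal footprint length beyond each diagnostic position so
every placement covering it remains available, including the placement that
puts the diagnostic base at the primer's 3' terminus.

## Alignment

`progressive_align()` performs star-progressive alignment seeded on the
first (youngest) consensus: every other sequence is aligned to it by global
Needleman–Wunsch with a linear gap penalty (defaults match +1, mismatch −1,
gap −2 per gap character), and the pairwise alignments are merged under
"once a gap, always a gap". The pairwise step is exact (tested against an
exhaustive enumeration of all monotone alignments on short sequences); the
star merge is a heuristic that is exact when the lineage diverges by
substitutions only — which is precisely what the simulator produces, keeping
every downstream coordinate mapping testable. For real consensuses with
indels, an externally computed MSA (e.g. Clustal Omega output) can be
supplied through `accept_external_msa()` and is validated into the same
shape.

## Primer arithmetic

%GC is `100 (G+C)/N`, reported rounded half-up to one decimal — the
convention of primer tables (note R's own `round()` rounds half to even,
which would print 45.45 % as 45.4 rather than 45.5).

Two melting-temperature methods are implemented and clearly labelled,
because commercial design tools use unpublished variants and their printed
Tm values are not generally reproducible:

* `wallace`: `2(A+T) + 4(G+C)` — the rule of thumb, adequate for ranking;
* `nn_santalucia`: unified nearest-neighbor thermodynamics (dinucleotide
  ΔH/ΔS sums plus terminal initiation terms), entropic salt correction
  `0.368 (N−1) ln[Na+]`, and `Tm = 1000 ΔH / (ΔS_salt + R ln(Ct/4)) −
  273.15` for a non-self-complementary oligo in excess over template.
  Defaults: 50 mM Na⁺, 500 nM total primer. The implementation is verified
  in the test suite against values frozen from an independent
  implementation of the same parameter set.

`design_pairs()` enumerates all footprint placements satisfying the
constraints (length 18–22 nt, %GC 35–60, optional Tm window, product length
50–200 bp by default) and ranks deterministically by |Tm_F − Tm_R|, then
combined distance of both %GC values from 50 %, then leftmost placement.
There is no hairpin/dimer screen in this version; that is a deliberate
omission, noted under limitations.

**Open design choice — how many diagnostic bases, and where?** At minimum
each footprint must cover one diagnostic position anywhere (the function
default). `require_diag_in_3prime_k = k` additionally demands a diagnostic
base within the last `k` bases of the 3' end. The *pipeline* default sets
`k = anchor_len = 5`: placing the discriminating base in the 3' terminus is
the classic allele-specific-PCR design, and it composes with the in-silico
PCR matcher's exact 3' anchor so that a non-target subfamily (which by
definition mismatches at the diagnostic base) cannot form a product at all.
This was chosen as the package's design policy on first principles, not
fitted to any dataset; turning it off reverts to "anywhere in the
footprint".

## In-silico PCR

A binding site is a genomic window whose Hamming distance to the primer is
at most `max_mismatch` (default 2) *and* whose last `anchor_len` (default 5)
primer bases match exactly — mismatches at the 3' end abolish polymerase
extension, which is the physical basis for anchoring there. Matching is
substitution-only (no indels), both strands are scanned, and `N` in the
genome never matches. Products pair a left-primer site with a downstream
opposite-strand right-primer site within `min_product`–`max_product`
(defaults 40–1000 bp; the ceiling mirrors the usual paired-end insert-size
bound). Both product orientations are emitted, because a repeat copy on the
minus strand presents the primer pair in the mirrored arrangement.

The production implementation seeds candidates from exact anchor hits
(`Biostrings::matchPattern`) and verifies the full primer; its entire
correctness surface is equivalence with `brute_force_pcr_oracle()`, an
independent position-by-position rescan with no seeding, asserted in the
test suite over hundreds of seeded random genomes across the
`max_mismatch` × `anchor_len` grid.

## Scoring and the fragment readout

`assign_interval()` assigns an interval to the annotation record with the
largest base-pair overlap; ties break by longer annotation record, then
lexicographic name, which makes assignment invariant to annotation order
(asserted on shuffled inputs). Categories are the lineage subfamilies plus
`other_LINE1` (majority overlap with a repeat outside the configured
lineage) and `non_LINE1` (no overlap). Percentages are rounded half-up to
one decimal; a zero-interval input returns an explicit empty report rather
than dividing by zero.

`build_annotation_tracks()` produces the four standard summary tracks: all
elements (merged), their genomic complement, full-length elements (record
length strictly greater than `full_length_min` — 6 kb for genomic LINE1s;
at simulator scale the pipeline uses 90 % of the consensus length, since a
toy consensus is shorter than 6 kb), and the subset of full-length elements
intersecting an externally supplied intact-locus list. `call_amplified_loci()`
merges overlapping fragments and retains maximal intervals with at least
`min_support = 3` overlapping fragments ("at least three" is inclusive;
support counts fragments overlapping the merged interval, not nested
sub-interval logic). For RNA-seq-style counting,
`count_fragments_by_category(stranded = TRUE)` credits only strand-matched
overlaps; the default is unstranded, appropriate for double-stranded PCR
products. `fpkm_per_subfamily()` computes per-locus
FPKM = 10⁹·count/(length·total) and sums member loci per subfamily — the
formula is identical to RPKM when fragments rather than reads are counted,
and the package names the quantity FPKM for that reason.

## The simulator: what it emulates, and what it does not

`sim_params()` defaults define the reference simulation the package is
tested under: 6 subfamilies, 7 kb consensus, 2 % substitution per lineage
step, 30 copies per subfamily at 3 % copy divergence, 50 % of copies
5'-truncated by a uniform 10–90 % of their length, on a 300 kb random
background. These values sit in the realistic range for a young LINE1-like
lineage at desk scale: per-step consensus divergence of a few percent,
copy-level divergence below the step divergence for young subfamilies, and
a majority of truncated copies. Copies are spliced into the background at
random positions on random strands, so planted intervals never overlap by
construction and annotation coordinates are exact.

Deliberate simplifications, hence what passing tests do *not* show about
real data:

* substitutions only — no indels, target-site duplications, poly-A tails or
  inversions; real L1 copies have all of these, which mainly degrades the
  MSA stage (mitigated by accepting external MSAs);
* uniform substitution matrix — no transition/transversion or CpG bias,
  although CpG decay is a major force in real L1 aging;
* uniform random background — no flanking repeats, so the simulated
  `non_LINE1` category is cleaner than the real genomic complement, where
  degraded unannotated LINE1 fragments absorb off-target products;
* genome and copy numbers three orders of magnitude below hg38 scale, so
  genome-wide selectivity percentages reported on real data are not
  reproduced here, only the qualitative behaviour (the target plus its
  adjacent subfamily dominate the predicted amplicons).

## Numerical and determinism choices

* Coordinates are 0-based half-open everywhere inside the package;
  conversion to/from the 1-based inclusive RepeatMasker convention happens
  only in `read_repeatmasker_out()` (and is involutive).
* All stochastic functions take a seed (or a `sim_params` carrying one) and
  restore the caller's RNG state; `run_pipeline()` reruns byte-identically
  under one config, which the manifest of md5 checksums makes checkable.
* Ties are broken deterministically at every ranking point (alignment,
  region ordering, pair ranking, interval assignment), so outputs are
  reproducible across sessions.
* Degenerate inputs are explicit: empty amplicon or fragment sets yield an
  empty report with `total = 0` and `NA` percentages; all-zero fragment
  weights, zero locus lengths and zero totals are errors, not silent zeros.
* The test suite and examples run the reference simulation (7 kb × 6
  subfamilies) once and keep all other fixtures at hundreds of bp to a few
  kb — sizes chosen so the whole suite exercises every stage, including the
  exhaustive PCR oracle at 10 kb genome scale, in about a minute.

## Limitations

No thermodynamic secondary-structure or primer-dimer screening; no
indel-tolerant site matching; no multi-mapper reassignment or read mapping
(fragment intervals are consumed as BED, produced upstream by standard
tools); sub-element labelling of amplicons (5'UTR/ORF1/ORF2) would require
a consensus feature map and is out of scope. Printed Tm values from
commercial tools are not a reproduction target; only the two documented
methods are.
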