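---
title: "Methods: chloroplast indel markers for the continental origin of white oak wood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloroplast indel markers for the continental origin of white oak wood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakorigin)
```

## The problem

White oaks (*Quercus* sect. *Quercus*) dominate the temperate hardwood trade,
and timber regulations oblige traders to document where a shipment grew.
Wood anatomy cannot separate white oak species, let alone continents, but the
chloroplast genome can: it is uniparentally inherited, has a small effective
population size, and accumulates small insertion/deletion differences between
continental lineages. `oakorigin` implements the desk side of a marker
pipeline built on that idea:

1. merge per-sample chloroplast SNP/indel call tables (as exported by a
   read-mapping caller) into one annotated multi-individual **variant
   matrix**;
2. screen two sample groups for **fixed differences** and triage indel
   candidates by size and repeat context;
3. simulate the five-locus PCR / PCR-RFLP **genotyping assay** in silico;
4. **assign** a continental origin (Asia / Europe / North America) from an
   observed fragment-length profile, requiring concordant independent
   markers; and
5. quantify the residual **risk** that a marker believed fixed is in fact
   segregating, using exact binomial bounds for zero observed events.

A seeded synthetic-data generator produces references, haplotypes and pooled
variant tables, so every stage is testable without sequencing data.

## The marker panel

The packaged panel (`default_panel()`) covers five chloroplast intergenic
spacers amplified with dye-labeled primers. Four are pure length markers;
the fifth (trnDT) is a PCR-RFLP marker read after HinfI digestion:

| locus     | dye  | Asia  | Europe | North America | diagnostic gap |
|-----------|------|-------|--------|---------------|----------------|
| psaI-ycf4 | FAM  | 174   | 178    | 178           | 4 bp (Asia)    |
| psbE-petL | VIC  | 179   | 185    | 185           | 6 bp (Asia)    |
| trnLF     | PET  | 135   | 135    | 130           | 5 bp (N. Am.)  |
| trnCD     | FAM  | 123   | 123    | 115           | 8 bp (N. Am.)  |
| trnDT     | PET  | 86/71 | 86/101 | 88/101        | RFLP + 2 bp    |

trnDT entries are the dye-labeled HinfI fragments. All three continental
lineages share one HinfI site (at 86 bp from the 5' end in Old World
amplicons, shifted to 88 bp by a 2-bp insertion in North America). Asian
lineages carry a SNP that creates a second site; because both trnDT primers
are PET-labeled, only the two terminal fragments of the resulting three are
visible, and the Asia-diagnostic labeled fragment is the 71-bp piece — the
internal 30-bp fragment carries no dye and never appears on the trace. The
5'→3' fragment order in the Asian amplicon is therefore 86, 30, 71.

No single locus separates all three continents on its own (psaI-ycf4 and
psbE-petL split Asia from the rest; trnLF and trnCD split North America from
the rest; trnDT separates all three), which is why the classifier votes
across loci.

## The variant matrix

`merge_variant_tables()` combines validated per-sample call tables into one
row per distinct `(reference, position, type, length)` event. Two samples
with the same event share a row even when their alternative alleles differ —
the per-sample cells stay comparable — while events differing in type or
span occupy separate rows. Coordinates are 1-based and closed; insertions
are anchored at the reference base immediately left of the inserted
sequence, deletions at their first deleted base, which gives every event an
unambiguous single-integer anchor.

Three summary statistics are computed per row:

* **deviating alleles** — the number of samples calling the variant;
* **reference-matching alleles with minimal coverage** — samples without a
  call whose read depth at the position reaches `min_cov` (default 8). Below
  that, or without coverage tables, the cell is `NO-DATA` rather than
  silently reference;
* **mean forward/reverse balance** — for each supporting call
  `min(F, R) / (F + R)`, averaged over calls with any support. The source
  material names this statistic and its intent (flagging one-strand-only
  support, a signature of systematic sequencing error) but no formula or
  cutoff; `min/(F+R)` is this package's definition (0.5 = perfectly
  balanced, 0 = one strand only), and rows below a configurable 0.2 are
  flagged `critical_balance`.

**Flanking sequences** for primer design follow a dual-threshold rule with
defaults of 75 bp (upper) and 50 bp (lower): per side, with `d` the distance
to the nearest other variant on that side, `d ≤ 50` yields no flank,
`50 < d ≤ 75` yields 50 bp, and otherwise 75 bp, truncated at contig ends.
Distances are measured between variant anchors per side independently — the
rule's purpose is to guarantee variant-free primer landing sites, and
per-side measurement retains the maximal clean sequence on the unobstructed
side.

The matrix CSV stores, in order: reference name, position, variant length,
calling type, reference allele; then per individual the alternative allele,
coverage and alt-read frequency; then the summary statistics and flanks.
Per-individual frequencies are part of the persisted format because the
95–100% fixation screen operates on them downstream; omitting them would
make the write/read cycle lossy.

## Marker discovery

`fixed_differences()` screens two matrices symmetrically: a row qualifies
when one group calls the variant at 95–100% frequency in every deviating
sample while the other group has no call at that position. Pooled samples
fit naturally — a pool is one "sample" whose frequency reflects the pool.

`select_indel_markers()` then applies the triage rules that matter for a
length-read assay:

* indels in a **repeat context** are removed. A homopolymer indel (single
  repeated base whose reference run reaches 5) or a microsatellite indel (an
  integer number of copies of a 2–6 bp motif tandemly repeated ≥ 3 times in
  phase) mutates by replication slippage and is length-polymorphic within
  populations. The run/copy thresholds are this package's operational
  definitions;
* indels below `min_length_diff_bp` are removed as unresolvable or
  unreliable on the intended detection platforms. There is deliberately no
  default: 4 bp suits a within-hemisphere screen, 2 bp a New World / Old
  World screen, and forcing the caller to choose avoids a silently wrong
  threshold;
* SNP/MNP candidates are reported but kept at status `candidate`: not
  preferred for length assays, yet available for PCR-RFLP design (the trnDT
  marker is exactly such a rescued SNP).

## The in-silico assay

`amplify()` locates the forward primer on the top strand and the reverse
primer's reverse complement downstream of it; the amplicon spans the two
primers' 5' ends inclusive, so its length is the value a sequencer reports.
Primer location demands a unique best hit: a missing site degrades to
missing data (a failed PCR), while two equally good sites raise an error,
because the product would be undefined. Mismatch tolerance defaults to 0;
raising it emulates permissive annealing on degraded timber DNA.

`digest()` cuts at every top-strand occurrence of the recognition site
(IUPAC-aware, e.g. GANTC for HinfI) at the enzyme's cut offset, assuming
complete digestion; partial digests are out of scope. For a site that is its
own reverse-complement class, top-strand scanning finds the same sites as
double-strand scanning, but note that HinfI's staggered cut (G^ANTC, 3-nt
5' overhangs) means the bottom-strand fragment boundaries are offset by
3 bp; the lengths modeled here are top-strand lengths, which is what a
dye-on-primer capillary trace sizes. The package's tests verify fragment
conservation (lengths always sum to the amplicon) and the mirrored-offset
strand symmetry.

`visible_fragments()` keeps the fragments that retain an amplicon end whose
primer carries a dye — internal fragments are invisible. Capillary sizing
bias (dye-dependent mobility shifts, e.g. FAM peaks reading ~3 bp short) is
not baked into expectations; it is an instrument property, exposed as a
per-dye offset at assignment time.

## Continent assignment

`locus_vote()` declares a continent compatible with an observation iff every
fragment length expected for that continent at that locus is matched within
a sizing tolerance (default 1 bp). Two guards matter:

* if one observed length sits within tolerance of two *different* expected
  lengths (e.g. 87 bp between the Old World 86 and the North American 88 at
  trnDT), the locus cannot be read reliably and is declared uninformative —
  it neither supports nor vetoes anything;
* an expected length shared verbatim by several continents (135 bp at trnLF
  for Asia and Europe) is not ambiguous; the locus simply votes for both.

`assign_continent()` intersects the informative votes. The verdict is a
continent only when the intersection is a single continent *and* at least
`min_markers` (default 2) independent loci were informative; one marker is
never enough evidence for a forensic claim. An empty intersection is
`inconsistent` (conflicting markers — a mixed sample, contamination, or a
haplotype outside the reference panel), and fewer informative loci than
required is `insufficient`. The packaged table of 13 validated white oak
species profiles (`read_species_profiles()`; blank trnDT cells are missing
data) all classify to their continent of record with at least two
informative markers — the classifier's reference check.

## Fixation risk

A marker scored as fixed in a reference collection of `n` individuals may
still segregate at low frequency. The exact (Clopper–Pearson) upper bound
for zero observed carriers has closed form `1 − α^(1/n)` (one-sided) or
`1 − (α/2)^(1/n)` (two-sided); `upper_bound_zero_observed()` implements it,
and the tests cross-check against the independent beta-quantile form
`qbeta(1 − α/2, 1, n)`. Two-sided is the default because that is what the
conventional "95% CI" of the standard calculators reports; sidedness is a
flag since either convention is defensible for an upper risk bound.

Because assignment demands two concordant markers, `combined_risk()`
multiplies per-marker bounds: for the European collection (962 individuals
for the four shared length markers, 115 for trnDT) the two-marker combined
risk is `(1 − 0.025^(1/962)) × (1 − 0.025^(1/115))` ≈ 1.21 × 10⁻⁴, i.e.
about 0.012%. The product assumes marker independence; chloroplast loci are
physically linked and co-inherited, so the product understates the risk of
a shared introgressed haplotype — treat it as the sampling-risk component
only. Bounds decrease monotonically in `n` and in the number of markers,
and for large `n` the two-sided bound approaches `−ln(0.025)/n ≈ 3.69/n`,
the two-sided analogue of the rule of three.

## The synthetic generator

`generate_reference()` builds a 20 kb random backbone with the five locus
cassettes embedded in forward orientation; the Asian haplotype serves as the
reference, mirroring the use of an Asian chloroplast assembly as the mapping
reference. 20 kb is a deliberate desk-scale stand-in for the ~135 kb
single-copy plastome: it leaves kilobases of inter-locus backbone (so flank
and noise behavior is realistic) while keeping the full pipeline fast enough
to run hundreds of times in a test session. Per-continent cassettes realize
the panel's expected amplicon lengths exactly; indel windows sit inside
fixed non-repetitive contexts so that repeat triage classifies them `none`,
and the trnDT cassette plants its restriction sites (shared site at 86 bp;
the Asian site-creating SNP; the North American 2-bp insertion) after
scrubbing chance GANTC occurrences. Construction is verified by running the
full in-silico assay on all three haplotypes; on the astronomically rare
chance collision (a duplicate primer site, say) the builder re-draws
deterministically from a derived sub-seed rather than failing silently.

`simulate_variant_tables()` emulates two 20-individual pools mapped against
the Asian reference. The European pool carries six planted fixed
differences at 95–100% frequency — the 4-bp and 6-bp spacer insertions, the
trnDT SNP, plus three decoys the triage rules must reject: a 1-bp insertion
in a planted 7-T homopolymer and two 2-bp deletions. Noise calls are
private SNPs at 0.05/kb per sample with frequencies drawn uniformly on
[5, 90)% — deliberately bounded away from 95% so the screen boundary is
never straddled by chance; boundary behavior is tested with explicitly
planted 94% and 95% calls instead. Coverage is negative-binomial
(mean 40, size 10, floored at 4) and supporting reads split between strands
as Binomial(0.5). Coverage tables are emitted sparsely, at variant positions
only: that is all the reference-match rule consumes.

All randomness derives from one master seed; component `k` uses the sub-seed
`(seed × 1000003 + k) mod 2147483629`, so reference construction and table
simulation are independently reproducible and two runs under one seed write
byte-identical files.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level artifacts (the caller is assumed upstream),
mapping bias around indels, heteroplasmy, within-continent haplotype
diversity beyond the planted variants, chimeric amplicons, and partial
digestion. The 13-species profile table exercises the classifier against
published fragment lengths, but a new geographic lineage outside the
reference panel would surface as `inconsistent` or `ambiguous`, not as a
wrong continent — which is the designed failure mode.

## Numerical choices and degenerate inputs

* Frequency windows are closed on both ends; 94.999% fails a 95% screen.
* A balance is undefined (NA, not 0) when no call has strand support.
* Flanks truncate at contig ends and exclude the focal footprint
  (`length` bases for SNP/MNP/deletion, the anchor base for insertions).
* Zero restriction sites yield a single fragment carrying both ends; digest
  lengths always sum to the amplicon length by construction.
* An empty call set merges to a valid empty matrix; a profile that shares no
  locus with the panel is an error rather than a vacuous verdict.
* Ties in primer matching are errors, never arbitrary picks.

## Problem sizes

The default test and verification runs use the 20 kb reference, two pools of
20 samples, and property suites over ≤ 5-sample random call sets with ≤ 30
variants against brute-force recounts — sizes chosen so the entire suite,
including several full pipeline executions, completes in well under a
minute while still exercising every rule boundary stated above.
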