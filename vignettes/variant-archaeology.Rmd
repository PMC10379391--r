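---
title: "Variant archaeology: methods and design notes"
author: "PaleoVar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant archaeology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PaleoVar)
```

# The question and the two-arm design

A germline variant observed in modern humans can in principle be ancient
— maintained across species by descent, in which case orthologous loci
in other vertebrates should carry the same alternate allele — or recent,
having arisen within human history, in which case it should surface in
ancient human genomes only close to the present. PaleoVar operationalizes
both tests for a single locus (the worked example is PALB2, whose
truncating variants predispose to breast, ovarian and pancreatic cancer
and, biallelically, to Fanconi anemia):

* **Cross-species arm.** Project each catalogued variant through a
  multi-species alignment; a species *shares* the variant iff its
  aligned base equals the human alternate allele. Comparing the
  per-species sharing-rate distributions of pathogenic (PV) and benign
  (BV) variants asks whether pathogenic alleles look conserved.
* **Paleogenomic arm.** Genotype the locus in dated ancient samples,
  intersect with the catalog, and date each variant by its oldest
  carrier. This *arisen time* is a lower bound on the allele's age: a
  carrier dated 9,860 BP proves the allele existed then, but silence in
  older samples proves nothing, because ancient-genome availability
  collapses beyond ~10,000 BP.

# Catalog construction

Variants enter as HGVS cDNA strings plus a ClinVar-style significance
label. Three filters apply in order, each exclusion logged with a
machine-readable reason so the kept/excluded partition always sums to
the input:

1. *Significance*: only Pathogenic/Likely pathogenic (PV) and
   Benign/Likely benign (BV) survive; uncertain, conflicting and
   free-text labels are excluded. Matching is case-insensitive and
   exact on the canonical strings; the combined export forms
   ("Pathogenic/Likely pathogenic") map to their class.
2. *Span*: only events touching a single base pair are kept — SNVs and
   1-bp deletions/duplications/insertions. Multi-base events are
   excluded by design (`hgvsExcludedError`), not treated as parse
   failures.
3. *Mapping*: the 1-based cDNA anchor (with optional signed intron
   offset, e.g. `c.211+1`, `c.49-1`) is converted to a 0-based genomic
   position through the transcript's exon structure. Minus-strand
   transcripts have alleles complemented onto the forward strand.
   Intron-offset variants are retained — a third of benign variants in
   a typical catalog are intronic.

Numerical conventions: genomic coordinates are 0-based half-open
internally, HGVS anchors stay 1-based at the interface; insertions are
anchored at the base *after* which material is inserted and deletions at
the deleted base, which makes 1-bp semantics unambiguous; when a
reference sequence is available, indels are left-normalized against
homopolymer runs (the VCF convention) so the catalog and the ancient
caller agree on coordinates. Duplicate genomic variants with conflicting
PV/BV classes are a hard error; concordant duplicates collapse.

The domain map used for PALB2 (coiled-coil 25–132, ETGE 205–222, ChAM
1183–1338, WD40 2557–3561 in 1-based cDNA coordinates) is a synthetic
reconstruction: the literature gives residue ranges, not nucleotide
bounds, so the packaged boundaries were chosen to agree with the
published residue ranges and with the domain label of every variant in
the packaged carrier table. They are a fixture, not an annotation.

# Cross-species projection

The alignment is consumed in MAF form. Only `s` rows are used; `e`/`i`
status and `q` quality lines carry no sequence and are ignored. Blocks
are indexed by reference coordinates (binary search over block starts,
then a precomputed offset-to-column map), which the tests hold equal to
a naive scan over every block and column. Two reading conventions
matter:

* The printed row text *is* the alignment frame: for `-` strand rows
  MAF stores the reverse complement of the source, so the column
  character is already what aligns to the reference forward strand. The
  strand and start fields only matter for recovering source
  coordinates; the synthetic emitter and its oracle test exercise that
  arithmetic explicitly.
* Soft-masked lower-case bases are uppercased before comparison —
  masking is annotation, not sequence. A species appearing twice in one
  block keeps its first row (with a warning).

Sharing calls are ternary. For SNVs: the species base equals the human
alternate allele → `shared`; equals the reference or any third base →
`not_shared`; gap, `N` or no alignment → `no_alignment`. `N` could
defensibly count as `not_shared`; we chose `no_alignment` because an
ambiguity code carries no evidence either way. For 1-bp indels the call
additionally requires clean context, mirroring the manual curation such
events normally receive: a deletion is shared iff the species shows a
gap against the deleted base (anywhere in its homopolymer run, since
catalog indels are left-normalized) *and* the `k` nearest reference
bases on each side align identically (`k = 3` by default); an
insertion/duplication is shared iff the species carries the extra base
in a reference-gap column immediately after the anchor under the same
flank rule. Missing or gapped flanks give `no_alignment`, mismatched
flanks `not_shared` — so raising `k` can only downgrade calls, never
manufacture sharing.

Per-species sharing rates divide shared counts by the *full* catalog
size of the class, keeping `no_alignment` cells in the denominator;
that matches how such rates are defined when comparing species with
unequal alignment coverage, and the alternative (coverage-restricted
denominators) is available by filtering the summary. Both "variants
shared with ≥ 1 species" and "species sharing ≥ 1 variant" are
reported, since headline counts can be quoted in either convention.

# The ancient-carrier arm

A full mapping/duplicate-marking/GATK pipeline is deliberately not
reproduced. The caller is an explicit threshold rule on pileup
observations — minimum base quality 20, minimum alt-supporting depth 2,
depth below 3 flagged `low_depth` but still reported because ancient
data are sparse — so that every accept/reject decision is explainable
and testable. Diploid genotypes are not modeled: the analysis consumes
presence/absence of the alternate allele ("carriers").

Post-mortem cytosine deamination is the dominant artifact: it converts
C to U (read as T) near read termini, and appears as G>A in the
reference frame on reverse-orientation reads. A C>T call is flagged
`damage_suspect` iff *every* supporting observation sits on a forward
read within `w = 2` bases of its 5' end (symmetrically for G>A on
reverse reads); a single interior or opposite-orientation supporting
read rescues the call. Flagged calls matching a pathogenic variant are
dropped by default (and logged), since a false C>T would manufacture a
pathogenic carrier; benign matches are kept because the benign arm is a
control. Distances are stored in the read's own orientation, matching a
single-stranded library's damage geometry.

Carrier records join calls to the catalog on normalized
`(pos, ref, alt)`; timelines group carriers per variant, date the
variant by its oldest carrier, and sort by carrier count (descending)
then cDNA anchor (ascending). Censored dates ("older than 10,000 BP")
carry a numeric floor plus an open-ended flag; maxima and the recency
cutoff treat the floor, so a censored entry counts as beyond the
10,000-year cutoff but never outranks a genuine 32,895 BP date. In
timeline-only inputs (a published carrier table) only the oldest
carrier of each variant is dated; undated carriers count as within the
cutoff, which is exactly the arithmetic that yields the published
64-of-71 (90.1%) figure and is conservative in the direction of
recency. Temporal percentages are computed on carriers, mutation-type
and domain percentages on variants.

# The rate comparison

PV and BV per-species sharing rates are compared with a two-sided
Mann-Whitney U test. Sidedness is two-sided because the hypothesis is
"different", not directional; alpha is fixed at 0.05. Ties are handled
with midranks; the exact mode builds the null distribution of U by
dynamic programming over the pooled midrank multiset (used
automatically up to 20 observations; the tests hold it equal to full
enumeration up to 6 + 6), and the large-sample mode uses the normal
approximation with tie-corrected variance and continuity correction.
`stats::wilcox.test` cannot compute exact p-values under ties, which is
why the exact engine is in-package; on tie-free inputs the two agree to
machine precision. Species with zero alignment coverage enter as rate 0
by default (configurable), since dropping them would silently condition
on alignability.

# What the synthetic generator emulates — and what it does not

The generator exists so that every stage has inputs with known truth:

* **Sequences** evolve along a user-supplied newick tree under a
  rate-normalized HKY-style model with equal base frequencies
  (equivalently K80), transition/transversion rate ratio `kappa = 4`
  (a typical mammalian value), an optional CpG transition multiplier
  (deamination hotspots; off by default), and Poisson 1-bp indels at
  0.003 events/site/unit branch length. Every residue carries a
  persistent column key, so the true multiple alignment is exact, not
  re-estimated. The default tree has eight taxa spanning
  primate-to-fish divergences on a fixed topology.
* **MAF emission** splits the truth alignment at randomized reference
  positions and annotates each non-reference species, with probability
  0.3, on the `-` strand — the aligned text is unchanged and the
  implied source is the reverse complement, which is how strand
  representation works in real MAF. Emission is the identity under
  projection: `getBase()` over the emitted file equals the truth
  matrix.
* **Catalogs** are planted with class-specific shared fractions
  (defaults 0.15 for PV, 0.9 for BV, echoing the order of magnitude
  separating the two classes in real data), plus uncertain-significance
  decoys for the filter to drop. Indel variants are planted only at
  sites the alignment supports cleanly; if fewer exist than requested
  the generator warns rather than fabricating ambiguous sites, while an
  unsatisfiable SNV request is a hard generation error.
* **Ancient cohorts** draw dates uniformly over 270–48,426 BP (the
  span of the real resource; a list can be supplied instead), sample
  reads at mean coverage 8 with read length 60 and base error 0.002,
  and apply terminal deamination at rate 0.2 within 2 bases of the
  read-frame 5' terminus (C>T on forward reads, reference-frame G>A on
  reverse reads). Carriers are haploid — every read of a carrier shows
  the allele — because the pipeline models carrier status, not
  genotype.

Not emulated: alignment estimation error (the emitted MAF is the true
alignment, so `no_alignment` cells arise only from genuine gaps and
block structure, never from misalignment), read mapping and duplicate
artifacts, contamination, reference bias, calibrated radiocarbon
uncertainty, and population structure among the simulated samples.
Passing tests therefore certify the pipeline's logic — filters,
coordinate arithmetic, projection, calling, dating, statistics — under
a faithful input contract, not the robustness of the upstream aligners
and mappers the real analysis depends on.

# Determinism and problem sizes

Every generator entry point reseeds from `cfg$seed` (with small fixed
offsets per stage), so a fixed configuration reproduces byte-identical
outputs; the test suite asserts this at file level. The packaged test
and acceptance runs use locus lengths of 0.8–1.5 kb, eight species,
cohorts of 10–20 samples at 8x coverage, and exhaustive projection
checks over all species and positions of a 1 kb alignment — sizes
chosen so that the whole suite exercises every code path in well under
a minute per file while keeping planted-effect statistics
(sensitivity ≥ 0.95, planted PV-vs-BV p < 0.05) comfortably away from
their thresholds.

# Known limitations

* The HGVS parser covers the single-base dialect the analysis needs;
  UTR-anchored positions (`c.-12`, `c.*45`) are rejected rather than
  mapped.
* Indel sharing requires single-block context; an indel whose flanks
  straddle a block boundary reports `no_alignment` even if a wider
  view would resolve it.
* The caller ignores indels in pileups; catalog indels can therefore be
  dated only through timeline-only inputs.
* Arisen times inherit the point-estimate convention of their sources;
  no calibration intervals are propagated.
* With only the oldest carrier dated in timeline-only inputs, the
  within-cutoff carrier count is an upper bound under the documented
  undated-carriers-are-recent convention.
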