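---
title: "Detecting horizontal transfer of transposable elements from sample sequences"
author: "htte package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transfer of transposable elements from sample sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htte)
```

## The problem

Horizontal transfer (HT) moves DNA across mating barriers. In plants the
best-documented cargo is transposable elements (TEs), LTR-retrotransposons in
particular: an element that crossed from one lineage into another recently will
be far more similar between the two genomes than their vertically inherited
sequence is. That contrast is the whole signal. If two lineages separated long
ago, their orthologous coding sequence has drifted to some modal identity (on
the order of 85–90% for grasses separated >50 My), while a recently transferred
element still aligns at 97–100%.

`htte` implements both screening strategies built on this contrast, for the
setting where the putative donor side is represented only by *sample
sequences* — low-depth (~2.3x), unassembled, single-end shotgun reads of
~150 bp — and the recipient side by assembled genomes:

* **Targeted screen** (`targeted_scan()`): reads carrying the reverse
  transcriptase (RT) domain are pulled out of the sample sequences with a
  profile scan, clustered into families, and used as anchors. Each RT anchor
  with a strong genomic hit (>85% identity over >=140 bp) nominates a locus;
  the locus plus 10 kb of flank on each side is then probed with *all* sample
  reads, the best nonoverlapping read hits are kept (>=100 bp matched, <=75 bp
  mutual overlap), the element boundaries are annotated, and an HT is called
  when at least 10 distinct reads land inside the element with unweighted mean
  identity above 97%.
* **Nontargeted screen** (`nontargeted_scan()`): reads are chopped to 50 bp and
  placed end-to-end with at most 3 mismatches — an exact 94% identity floor,
  `kmismatch_identity_floor(50, 3)`. Densely mapped regions (mapped bases >500,
  gaps <150 bp) are excised with 20 kb flanks, re-probed with the full-length
  reads, and called when reads above the 97% threshold cover more than 500 bp.
  Candidates matching organelle/rRNA/conserved-gene references or
  low-complexity sequence are filtered out (`apply_filters()`).

Downstream, calls are clustered into families (`cluster_sequences()`), merged
into events (`merge_calls_to_events()`), counted conservatively
(`minimum_event_count()`), direction-tested (`nesting_test()`), dated
relatively (`upgma_history()`), and verified at the insertion junctions
(`junction_report()`).

## Threshold calibration

The 97% call threshold is only meaningful relative to the vertical background,
so `calibrate_divergence()` measures that background directly: sample reads are
aligned to the recipient's coding sequences, reduced to best nonoverlapping
hits per CDS, and binned into a percent-identity histogram. The histogram peak
is read as the modal vertical divergence; `validate_threshold()` accepts a
threshold when the histogram shows a genuine peak (modal bin at least twice
the median occupied bin — a flat histogram locates no speciation point), the
threshold clears that peak by at least 5 percentage points, and the fraction
of calibration hits above it stays below 5%. These margins are package
decisions — the underlying argument is qualitative (the threshold must sit
far above the speciation peak, with a thin tail) — and all are parameters. Paralog hits are deliberately *not* removed: for short unassembled
reads, paralogs cannot be told apart from orthologs, so the histogram simply
includes them.

Two numerical details of the histogram are worth knowing. First, read-length
granularity makes some 1% bins lumpy: a 150-bp hit can only take identities
`100*(150-k)/150`, so adjacent bins capture different numbers of attainable
mismatch counts and the apparent mode can hop between such bins on small
panels. Second, best-nonoverlapping selection keeps the best-scoring read per
position, which biases the retained identities slightly upward (about half a
percentage point at 2.3x coverage). Both effects shrink as the number of
calibration hits grows; the package's validation pools hits over replicate
scenarios before locating the peak.

## The alignment engine

All screens run on a built-in seed-and-extend local aligner (`local_align()`):
exact 11-mer seeds, ungapped x-drop extension on both strands, a +1/−2
match/mismatch scheme, a raw-score floor of 60 (strictly above), and a
Karlin–Altschul e-value ceiling of 1e−8 with the search space frozen to the
supplied target set. Two deliberate choices:

* **Ungapped extension.** The synthetic-data generator is substitution-only
  (below), and the thresholds throughout the method are stated purely in
  percent identity, so gapped extension adds machinery without changing any
  decision. Gap penalties remain part of the score scheme so that externally
  produced gapped hits (imported with `read_hits()`, 12-column tabular format)
  score consistently. Any stage can run from imported hits instead of the
  built-in engine.
* **HSP extent.** By default an HSP spans the full x-drop-extended region
  rather than being cut back to the score-maximal endpoints. Trimming
  preferentially removes terminal mismatches and inflates HSP identity by
  1–2%, which would shift the calibration peak off the true divergence;
  untrimmed HSPs estimate divergence without bias. Where boundary precision
  matters more than identity fidelity — locating LTR direct repeats — the
  trimmed mode is used (`align_params(trim = TRUE)`), and recovers planted
  element boundaries exactly on simulated data.

The 50-bp pass uses a separate exact mapper (`map_kmismatch()`): pigeonhole
chunk lookup plus full verification, so it provably reports *every* end-to-end
placement with at most k mismatches (tested against a brute-force scan of all
offsets).

## Domain detection

RT reads are found by translating each read in six frames and scanning with a
position-specific score matrix (`build_profile()`, `scan_reads()`); any
placement containing a stop codon is discarded, and partial profile/read
overlaps down to 25 aa are scored so that a 150-bp read overlapping just part
of the domain still registers. A full profile HMM with insert/delete states
would add little for <=50-aa translated reads; HMMER-style domain tables can be
substituted where available. Each profile's threshold is calibrated on random
reads to a 0.1% false-positive rate (`calibrate_threshold()`), and the package
ships synthetic profiles for the five canonical domains (gag, AP, IN, RT, RH)
that match the simulator's synthetic domain consensus — they are stand-ins, and
biological work should use profiles built from curated domain alignments.

Element annotation (`annotate_te()`) combines the domain placements with an
LTR pair found by ungapped self-comparison of the locus (a direct repeat
>=100 bp at >=85% identity flanking the domain block); element boundaries are
the outer LTR edges, elements without a detectable second LTR are flagged
incomplete rather than dropped.

## Event accounting and direction

Calls are merged into events under a deliberately conservative rule: two calls
merge only if they share a repeat cluster *and* either the same donor taxon
(with the recipient copies grouped in one clade of the cluster's tree) or the
same recipient taxon (with the donor copies forming one clade). Because
transferred copies are expected to nest *inside* the donor family's diversity,
the clade tests prune the opposite side's tips first; this is what lets a
shared-recipient pair whose donors sit together merge, while a shared-recipient
pair whose donors occupy different parts of the cluster stays split. Without a
tree the rule degrades to shared cluster + shared taxon and the merged events
are flagged `phylo_verified = FALSE`. The minimum event count is then one event
per HT cluster plus one per singleton — a floor, since lineage sorting and
non-amplifying transfers hide events.

Direction comes from `nesting_test()`: recipients are nested in donors when
the recipient tips form a clade whose attachment node shows donor tips on at
least two sides, at least one side carrying two or more. The final condition is
what makes the test directional: it demands that the donor family's
diversification predate the transfer, and it is why a balanced two-against-two
split or a single outgroup tip cannot fake nesting.

Relative activity history (`upgma_history()`) is average-linkage (UPGMA)
agglomeration on identity distances (`100 − %identity`) with node heights taken
as half the merge distance, so heights read directly as per-lineage divergence;
the raw merge distances are also reported since either convention is defensible
for plotting "branching points". The histogram of heights in 1% bins (always
summing to n−1) is the family's amplification profile.

## Junction verification

A genuine integration leaves three marks that `junction_report()` checks:
terminal `TG...CA` LTR motifs at the element boundaries; a 4–6 bp target-site
duplication (TSD) anchored immediately at the junctions (`detect_tsd()` — the
window is configurable, 4–6 bp being the LTR-retrotransposon norm); and reads
spanning each host/element junction with at least 20 aligned bp on both sides
(`junction_support()`). Presence/absence in relatives (`ortholog_presence()`)
is decided by anchoring the element's 1-kb flanks in the other genome:
`present` if the element aligns between the anchors (>85% identity over >50%
of its length), `absent` if the anchors adjoin with less than 10% of the
element length between them, `unresolved` otherwise. This is flank-anchored
pairwise comparison, not whole-genome synteny — sufficient for single-locus
verification, not a collinearity browser.

## The synthetic-data generator

`build_ht_scenario()` produces the fixture every stage is tested on: an
ancestral random genome; a donor diverged from it by `vertical_divergence`
(default 14%, i.e. an 86% orthologous background); a synthetic
LTR-retrotransposon (`make_te()`: identical LTRs starting `TG` and ending
`CA`, five encoded domains, RT carrying the YxDD motif) resident in the donor;
a copy transferred into the recipient at `ht_divergence` (default 1.5%) with a
5-bp TSD; optional post-transfer amplified copies at 0.5% mutual divergence
(matching the 98.9–100% homolog identities typical of recent amplification);
CDS-like calibration windows cut from the recipient; and donor reads of 150 bp
at 2.3x coverage (`shred()`). All truth coordinates are exact, and identical
configurations produce byte-identical output.

The mutation model is substitution-only with an exact realized count
(`round(pct/100 * len)` positions, each changed to a different base), which
keeps identity arithmetic exact for testing; there is no indel, no
sequencing-error, no paired-end and no repeat-landscape model. Consequently,
passing tests demonstrate the pipeline's *decision logic* — thresholds,
boundaries, accounting, direction — under clean divergence, not robustness to
assembly artifacts, indel-rich alignment, or genuine repeat families; for real
data the alignment stage is expected to be swapped for a production aligner
via the hit-import path.

## Problem sizes and numerical choices

The bundled validation runs at desk scale, chosen to keep the full suite
comfortably reproducible on one CPU: 100-kb genomes with 20 replicate seeds
for the planted-recovery study (smaller 30-kb scenarios for unit tests),
2 000 random reads per profile-threshold calibration, 30 replicates for the
nesting-direction simulation, and 1 000 fuzzed cases for the threshold-sweep
monotonicity property. Boundary conventions follow the stated inequalities
literally: score strictly >60, identity strictly >85/>97, mapped span strictly
>500 bp, gaps strictly <150 bp, overlap <=75 bp inclusive, and at least 10
*distinct* supporting reads counted after overlap pruning. Cluster naming is
deterministic (size-ranked, ties by smallest member id), UPGMA/NJ tie-breaks
are fixed by label order, and negative NJ branch lengths are clamped to zero
with a warning.

## Known limitations

* HT between closely related lineages is out of reach by construction: the
  method cannot distinguish recent transfer from recent common ancestry, and
  the calibration explicitly warns when the threshold sits too close to the
  vertical peak.
* Event counts are minima; sensitivity claims apply to the synthetic
  conditions stated above.
* The built-in aligner favors correctness and hermetic tests over speed; for
  genome-scale work, import external hits.
* Synthetic domain profiles detect the simulator's domains, not real ones.
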