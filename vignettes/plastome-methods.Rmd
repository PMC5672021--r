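---
title: "Comparative plastome architecture and marker selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome architecture and marker selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastome)
```

# Scope

`plastome` re-implements, as a tested pipeline, a comparative analysis of
annotated circular chloroplast genomes: detection of the quadripartite
LSC/IRa/SSC/IRb layout and of the gene context at the four single-copy/IR
junctions; inversion and breakpoint detection from signed gene orders;
fragmentation into coding and non-coding regions with reference-based
homology grouping; alignment with conserved-block and outlier-sequence
filtering; assembly of five partition schemes; distance-based tree
inference with bootstrap; and Kendall–Colijn tree comparison feeding a
standardized ranking of candidate phylogenetic markers. A seeded
synthetic-plastome generator plants every quantity of interest (IR
boundaries, rearrangements, homologies, the species tree), so each stage
is validated against known truth without downloading data.

# The quadripartite model and IR detection

A plastome is modeled as a circular sequence carrying a large single-copy
region (LSC, ~80–90 kb in typical angiosperms), a small single-copy
region (SSC, ~12–18 kb), and two identical inverted-repeat copies (IR,
~20–31 kb each) separating them. `find_inverted_repeats()` locates the
maximal pair of disjoint intervals whose sequences are reverse
complements by exact k-mer seeding (default k = 21) between the sequence
and its reverse complement: window pairs (i, j) that are reverse
complements satisfy i + j = constant, so true repeats appear as long runs
of verified hits along one "anti-diagonal". The run bounds give the
repeat arms directly in the exact case; a mismatch-tolerant extension
mode (`max_mismatch_frac` > 0) is available for unpolished assemblies.
Finished plastome IRs are identical, so the default demands exact copies.

The canonical presentation places the LSC (the longer single-copy gap)
at position 0 with the order LSC–IRa–SSC–IRb. Of the two strand choices,
the one whose single-copy regions carry more forward-strand genes wins;
ties fall back to lexicographic comparison of the two candidate
sequences. The vote deliberately spans LSC *and* SSC: the IR contributes
equally to both orientations, and a vote over one compartment alone can
be tipped by a handful of strand-flipping rearrangements.

Junction context (`junction_context()`) reports, for each of the four
boundaries, the nearest feature on each flank with a signed distance in
bp — negative values mean the feature overlaps the junction by that many
bases, the diagnostic used to compare IR boundary shifts across species.

# Gene-order comparison

Rearrangements are detected at the granularity of annotated loci, not
nucleotides: gene-order maps are robust to spacer divergence.
`detect_blocks()` restricts two signed gene orders to their shared loci
and decomposes the target into maximal runs that are either collinear
(order- and strand-consistent with the reference) or inverted (reversed
order, flipped strand). A collinear block whose flanking blocks changed
relative to the reference is flagged as displaced (a translocation). No
minimal rearrangement scenario is attempted; the decomposition and the
orientation-aware circular breakpoint count (`breakpoint_count()`) are
the reported statistics.

Two conventions matter here. First, IR-duplicated loci carry
compartment-aware copy tags (IRa vs IRb) so each copy matches its
positional counterpart. Second, a whole-genome strand flip is treated as
presentational: the target is also read in the opposite frame (which
swaps IRa/IRb identity and re-rotates LSC-first), and the frame giving
the more parsimonious decomposition is used. Without this, a genome that
canonicalizes in the opposite orientation — which single-gene strand
flips can cause — would appear massively rearranged.

An inversion of IR-interior content surfaces in *both* IR copies of
every descendant, so one planted IR event is counted twice in gene-order
comparisons; this mirrors how parallel IR rearrangements present in real
linear gene maps.

# Fragmentation and homology grouping

One IR copy (IRb) is excluded before fragmentation to avoid duplicating
data. Coding regions are the spliced exon sequences of CDS/tRNA/rRNA
features; introns, intergenic spacers and pseudogene sequences are
non-coding. Overlapping neighbors are cut at the midpoint of their
overlap so no base is emitted twice (verified by a disjointness audit in
the tests), and regions shorter than 50 bp are dropped — the bound is
inclusive, a 50 bp region is retained.

Homology across taxa is assigned by global similarity to a designated
reference genome: each non-reference region goes to the same-role
reference region of highest Needleman–Wunsch global similarity, if that
similarity reaches 0.65. The alignment costs are pinned (match +1,
mismatch −1, gap open −4, gap extend −1) and exposed as configuration:
reproducibility requires explicit costs, and similarity is the fraction
of identical positions over the alignment length including gaps. A
mathematically exact prefilter (`min(len)/max(len) >= threshold` is
necessary for the similarity to reach the threshold) avoids needless
alignments. Regions failing the threshold are reported as unassigned,
never silently dropped; one member per genome is enforced by
best-score-wins.

# Alignment, block filtering, outlier removal

`multiple_align()` is a center-star progressive aligner: the member with
the highest summed pairwise alignment score is the center, all others are
aligned to it pairwise, and the pairwise alignments merge under
once-a-gap-always-a-gap. Coding mode uses a higher gap-open cost (8)
than non-coding mode (4), emulating a strict global strategy for coding
sequence versus a long-gap-tolerant strategy for spacers. The tests hold
the center-star result to within 2x of the exact minimal sum-of-pairs
cost on small instances (an exhaustive three-sequence dynamic program is
the oracle). An external aligner can be substituted via `external=`; its
output is ingested into the same alignment form.

`block_filter()` implements conserved-block selection: with n rows, a
column is conserved when one residue occurs in more than n/2 rows and
highly conserved at 0.85·n; any gap makes a column non-conserved
(the strictest gap rule); runs of more than 8 contiguous non-conserved
columns are rejected; surviving blocks are trimmed to highly conserved
flanks and must be at least 10 columns. The operation is idempotent.

`remove_outlier_rows()` scores each row by mean pairwise identity over
shared non-gap columns and removes rows below
`max(0.5, mean − 2·sd)`, capped at ⌈n/3⌉ removals. Identity is computed
over shared non-gap columns only, so length variation is not mistaken
for non-homology; uniformly diverged sets are untouched.

The "edited" non-coding pathway — a deterministic proxy for manual
curation — removes outliers, re-aligns the survivors, and applies no
block filter; a user-supplied curated alignment short-circuits it. The
"filtered" pathway applies the block filter and then outlier removal.

# Partition schemes and variability

Five schemes are assembled: coding; non-coding (edited); non-coding
(filtered); and the two coding + non-coding combinations. Per scheme the
concatenated length, variable-site count (a column with at least two
distinct unambiguous nucleotides; gaps and N ignored) and percent
variation (one decimal, half-up — the presentation used in published
tables) are reported; combined-scheme statistics are exactly the sums of
their parts. Because generator spacers evolve at 1.5x the coding rate,
non-coding schemes show higher percent variation than coding ones, the
pattern observed in real plastome partitions.

# Trees and the Kendall–Colijn comparison

Built-in tree inference is deliberately simple: JC69-corrected distances
(p the mismatch fraction over pairwise comparable sites;
d = −(3/4)·ln(1 − 4p/3); saturation p ≥ 3/4 is an error naming the pair)
and neighbor joining, with negative branch lengths clamped to zero and
the deficit recorded. Tree inference is not this package's contribution;
externally computed newick trees can be used wherever a tree is
expected. Bootstrap support is column resampling with replacement;
support is the percentage of replicate trees containing each bipartition
of the point estimate.

The Kendall–Colijn vector of a rooted tree has one entry per tip pair —
(1−λ)·(edge count from root to MRCA) + λ·(path length root to MRCA) —
plus one entry per tip ((1−λ) + λ·pendant length); the distance between
two trees on the same tips is the Euclidean norm of the vector
difference. λ = 0 is purely topological, λ = 1 purely branch-length.
The implementation is checked against exhaustive MRCA-depth enumeration
for all tree sizes up to six tips and against metric axioms on random
tree pairs.

# Marker ranking

For each candidate region the pipeline computes percent variation and
the two KC distances (λ = 0 and λ = 1) between the region's tree and the
reference (best-scheme) tree, on the pruned ingroup. Metrics are
standardized to [0, 1] with 1 = best: variation ascending,
distances descending (so a topologically identical tree scores 1). The
composite is the unweighted mean (weights configurable) and regions rank
by descending composite. When a metric is constant across regions the
standardization is degenerate; affected scores are set to 1 with a
warning. Candidate regions are non-coding groups whose median unaligned
length lies in the 500–1100 bp PCR-amplicon window and which overlap no
detected rearrangement breakpoint ("recombination free" operationalized
as breakpoint-overlap-free — a proxy, and labeled as such).

One documented tension: a region evolving at 3x the background rate
maximizes variation and usually recovers the reference topology, but its
branch lengths genuinely sit ~3x above the reference scale, so its λ = 1
score standardizes to ~0 and its composite is capped near 2/3 under equal
weights. In clean simulations such a region therefore ranks high but not
reliably first; what does hold (and is tested) is that the *top-ranked*
marker's tree is topologically identical to the true tree in ≥ 90% of
seeds. In real candidate pools the λ = 1 maximum tends to come from
noisy, information-poor regions rather than from fast clean ones, which
is why fast regions can still top real rankings.

# The synthetic generator

The generator models a genome as an ordered element list (genes with
exon/intron parts, and spacers) laid out LSC | IR | SSC; IRb is
materialized at instantiation as the exact mirror of the IR elements, so
the two IR copies evolve in lockstep by construction (one mutation
appears in both copies), reflecting plastome IR homogenization. Two
profiles exist: `default` instantiates ~150–160 kb genomes with LSC
~85 kb, SSC ~13 kb and IR ~30 kb (the ranges of finished angiosperm
plastomes); `reduced` is a faithful ~25–30 kb desk-scale layout used
throughout the tests. Where the study conditions fix a value (compartment
ranges, the 50 bp/0.65/500–1100 thresholds, spacer-restricted structural
change) the generator uses it; remaining choices (spacer length ranges,
gene counts, 80/20 LSC strand bias, branch-length scales of 0.02 within
the ingroup and 0.05–0.1 to outgroups, 1.5x spacer rate) were fixed once
at values typical of real plastome data sets.

Structural events operate on whole elements: inversions reverse a
spacer-bounded run (endpoints therefore fall in non-coding sequence, as
observed in real plastomes), gene loss deletes a locus, pseudogenization
flags one. IR expansion consumes sequence from the SSC head into the IR
(duplicating it into both copies; a gene split by the boundary leaves
truncated pseudogene copies, emulating boundary pseudogenes) while the
mirror copy overwrites an equal amount of spacer at the SSC tail — so
the SSC shrinks by twice the shift, each IR grows by the shift, total
length is unchanged and the IR mirror invariant survives. Substitutions
follow JC69 (K80 optional) with the closed-form per-branch mutation
probability p = 3/4·(1 − e^(−4t/3)); indels are spacer-restricted by
default with geometric lengths.

One numerical subtlety: the first/last base of each single-copy
compartment is kept non-complementary to its junction partner, so the
maximal inverted repeat of the instantiated sequence is *exactly* the
planted IR — otherwise boundary bases would chance-extend the repeat by
a few bases and exact-recovery checks would be meaningless.

What the generator does not model: base-composition heterogeneity,
rate variation across sites, recombination within a genome, sequencing
error, or annotation error. Passing tests demonstrate correctness of the
algorithms against planted truth under these idealizations, not
robustness to mis-annotated or low-quality real assemblies (the
mismatch-tolerant IR mode and the outlier/block filters are the
provisions for those).

# Determinism, problem sizes, configuration

Every stochastic step is seeded and the pipeline is byte-identical
across reruns of one configuration (verified file-by-file in the tests).
The test suite and the acceptance script run the generator at desk
scale: reduced-profile genomes, 4–6 ingroup taxa plus 1–3 outgroups for
end-to-end runs, 20-seed sweeps for recovery and calibration statistics,
and 10–20 bootstrap replicates; the `default` profile is exercised for
template construction and IR detection at full ~150 kb scale. The
pipeline configuration is one flat YAML document (`default_config()`
lists every key with the analysis defaults: 50 bp region floor, 0.65
similarity, 500–1100 bp marker window, 1 kb minimum IR); the
configuration is echoed verbatim into the output directory of every run.

# Known limitations

- Homology grouping requires a reference genome; no de novo clustering.
- The center-star aligner is an approximation; for publication-grade
  alignments plug in an external aligner.
- NJ + JC69 is a desk-scale stand-in for likelihood-based inference;
  the comparison and ranking metrics accept externally computed trees.
- "Recombination free" and "edited by hand" are operationalized proxies
  (breakpoint-overlap-free; outlier-removal + re-alignment).
- Trans-spliced loci are handled as separate annotated features; the
  generator does not plant a trans-splicing event.
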