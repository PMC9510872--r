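---
title: "Methods: anchor-guided assembly finishing and satellite clustering"
author: "anchorfill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-guided assembly finishing and satellite clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`anchorfill` implements the computational core of finishing a
telomere-to-telomere (T2T) plant genome assembly and characterising its
centromeric satellite architecture. A draft assembly built from noisy long
reads typically carries scaffolding gaps (N-runs) inside centromeres; more
accurate donor contigs (e.g. HiFi assemblies) cover those regions but are
not ordered. The package (i) splices donor sequence into the draft where
independent anchor sequences (BAC-like clones) place it unambiguously,
(ii) validates the result structurally against clone libraries and
statistically with k-mer consensus quality, and (iii) analyses the repeat
architecture of the finished centromeres: satellite monomer decomposition,
mixture-model clustering, pairwise identity structure, telomere arrays, CpG
methylation and CENH3 ChIP enrichment per satellite cluster.

Everything is testable offline through a seeded simulator that generates
ground-truthed genomes in the same data regime.

# Anchor-guided patching

## Model

A gap is a maximal N-run of at least 10 bp (shorter runs are treated as
incidental ambiguity calls, not scaffolding gaps). For each gap we search
for two anchor sequences that align

* to the draft scaffold, one entirely left and one entirely right of the
  gap,
* to a single donor contig,
* with identity above the gate (default 0.999, i.e. the "> 99.9%"
  convention for accepting a BAC anchor placement), and
* *concordantly*: same relative order and same relative orientation of the
  two anchor placements on draft and donor. We give the word
  "concordantly" exactly this operational meaning.

Identity is column-inclusive ("BLAST identity"): matched columns divided
by all alignment columns, counting inserted and deleted bases in the
denominator. This is the strictest common convention and keeps the 0.999
gate meaningful for gap-containing alignments; every hit carries a CIGAR
from which the identity is recomputable.

An anchor is *usable* only when its best placement covers at least 90% of
the anchor at the identity gate, and no second placement on the same
target reaches identity 0.98 over half of the anchor. This guards against
satellite-internal anchors placing a patch at the wrong array position.
Uniqueness is judged per target sequence (the draft scaffold, each donor
contig separately): overlapping donor contigs legitimately share anchors,
and pooling them would veto perfectly good placements.

Among qualifying pairs the one minimising the summed gap-to-anchor
distance wins. Two patch modes exist: `span` (default) replaces only the
draft span between the inner anchor boundaries — the minimal footprint —
while `whole_contig` replaces the entire scaffold with the donor contig,
reproducing the more aggressive strategy of replacing gap-containing
contigs wholesale. Patches are applied right-to-left per scaffold;
`apply_patch` stores 20 bp of flanking context at planning time and
refuses to run if the draft has changed since (stale-plan guard). A
liftover table (segment + offset) maps old to new coordinates; replaced
segments map to nothing. When several patch plans overlap, the plan with
the higher combined anchor identity is kept and the conflict is reported.

## Alignment engine

The shared local aligner is seed-and-extend: exact 15-mer seeds, grouped
by diagonal band, each candidate window aligned with an affine-gap
Smith–Waterman (Gotoh) in C++ with full traceback (match +1, mismatch −2,
gap of length L costs 3 + L). Two details matter:

* A seedless pair falls back to one full DP only below ~4.5 million
  cells; larger seedless pairs are reported as "no hit". Seedless long
  pairs are in practice unrelated sequences, and an unconditional
  fallback would make anchor scanning quadratic in donor length.
* Hits shorter than 30 columns (twice the seed length) are suppressed by
  default; chance perfect micro-alignments of 10–20 bp otherwise appear
  in self-comparisons.
* For satellite monomer decomposition the aligner optionally extends each
  hit outward, indel-free, until the whole query is covered
  (`extend_full_query`). A plain local alignment clips copies whose
  terminal bases are substituted, which would shift monomer boundaries
  and break tiling. The pre-extension ("core") span is retained per hit
  and used for the query-coverage gate, so truncated copies are still
  rejected.

On pairs up to 2 kb the aligner is checked in the test suite against
`Biostrings::pairwiseAlignment` under the same scoring scheme — the
independent exhaustive-DP oracle — for both score and identity.

# Clone validation

A clone is *resolved* when at least 99.5% of its length aligns to a single
contig (inclusive threshold: attaining 99.5% exactly counts). Aligned
bases are counted on the clone axis after merging overlapping hit
intervals per contig, so tandem-repeat multi-hits cannot inflate coverage.
The resolution rate is reported as a percentage rounded half-up to two
decimals; the mean primary-hit identity is reported both length-weighted
(default) and unweighted, since either convention is defensible.

# k-mer consensus quality

With T total assembly k-mer instances and B of them absent from the read
k-mer set, the per-base error probability is

$$E = 1 - (1 - B/T)^{1/k}, \qquad QV = -10\log_{10}E,$$

the standard k-mer survival model (an erroneous base corrupts up to k
overlapping k-mers). Accuracy is the Phred error expressed as a
percentage, $100 - 10^{QV/-10}\times 100$, printed at six decimals
(half-up). Defaults: k = 21 (odd so canonicalisation — the lexicographic
minimum of a k-mer and its reverse complement — is unambiguous); B = 0
caps QV at 99 with an explicit flag; k-mer completeness counts distinct
reliable read k-mers (multiplicity ≥ 2 by default, rarer k-mers being
sequencing errors) found in the assembly.

# Satellite monomers and clustering

Monomer decomposition aligns the consensus (the bundled 178-bp
centromeric satellite preset, retention range 165–185 bp, 90% consensus
coverage; a 490–510 bp preset serves ~0.5-kb 5S rDNA units) against the
genome on both strands, resolves overlaps greedily by score (a retained
hit suppresses hits overlapping it by more than 10% of their own length),
and reports monomers in consensus orientation.

Rather than a full progressive multiple alignment, monomers are each
aligned to the consensus and projected onto its columns (deletions as
gaps; insertions collapsed into per-row annotations so every monomer is
reconstructable). For near-fixed-length satellite monomers this
consensus-anchored strategy is accurate and linear-time; an external MSA
in aligned FASTA can be imported for exact parity with a conventional
aligner. Sequences whose matched columns cover less than half of the
consensus are excluded with a warning — the ratio is taken over the
longer of monomer and consensus, because a short local island of high
identity in an unrelated sequence must not pass.

Clustering fits, for each K, a mixture of per-column independent
multinomials over {A,C,G,T,−} by EM. Numerical choices:

* initialisation by k-means++-style prototypes (squared Hamming distance
  weighting). Uniform random responsibilities leave every component at
  the column-mean profile — a saddle point EM cannot leave — and plain
  random prototypes frequently miss one of the planted families;
* 10 restarts, 200 iterations, relative tolerance 1e-6, Laplace-style
  pseudocount 0.5 on the category counts; seeded, so results are
  reproducible and permutation-stable up to relabeling;
* BIC(K) = −2 log L + p log n with p = (K−1) + 4Km;
* model selection by the *BIC inflection*: the K maximising the discrete
  second difference BIC(K−1) − 2·BIC(K) + BIC(K+1). A single-component
  fit is added below the evaluated range so its lower edge (K = 2 in the
  default 2–10 range) is itself eligible as the inflection; without it a
  two-family dataset could never select K = 2;
* an all-identical input short-circuits to the degenerate result
  (K* = min of the range, one effective cluster, flagged).

With hundreds of monomers and m ≈ 178 columns the BIC penalty dominates
the curve, so BIC may increase monotonically; the inflection criterion is
deliberately about curvature, not the argmin.

Pairwise identity heatmaps cut a region into consecutive windows
(default 5 kb) and fill a symmetric matrix with best local-alignment
identities (0 when no alignment of at least a fifth of the window
qualifies; diagonal 1).

# Telomeres, novel regions, epigenomic summaries

Telomere arrays are grown copy by copy from each sequence end (unit
`CCCTAAA` at 5', its reverse complement at 3') with a two-state scan that
admits interrupted copies while the purity — exact-unit bases over array
span — stays at or above 0.8. Defaults of at least 10 units within
1000 bp of the end ignore unplaced interstitial fragments. Novel regions
are the exact complement of merged alignment coverage per sequence;
covered and novel lengths partition each sequence by construction.

Methylation calls (position, read, state) aggregate to per-site
frequencies; region summaries report the mean frequency and the fraction
of sites *strictly* above 0.8, the usual convention for centromeric CpG
tracks. ChIP enrichment counts reads per satellite-cluster region by read
midpoint (unambiguous for boundary-spanning reads), converts to CPM with
each sample's total read count as denominator, and reports
(treatment CPM + 0.5) / (control CPM + 0.5). Using the sample-wide total
(rather than renormalising within the analysed regions) keeps a planted
3× binding preference recoverable as a ratio near 3; the pseudocount
keeps empty regions finite and flagged.

# The simulator

`simulate_bundle()` emits, deterministically per (config, seed): a truth
genome (telomeric ends, unique arms, a centromere-like region of
clustered monomer arrays interrupted by LTR-like segments), a degraded
draft with planted N-gaps and optional substitution errors, donor contigs
covering each gap with flanks, anchors, and truth tables (monomers with
cluster labels, gaps, telomeres). Named RNG substreams per component mean
adding one component never perturbs another's draws. An internal audit
(truth monomers re-extracted from the genome; gaps verified as N-runs)
runs before a bundle is returned.

Default study conditions: 4 clusters × 100 monomer copies, 8 diagnostic
substitutions per cluster consensus, 0.5% per-copy random substitutions,
50 telomere units per end, 3 gaps of 2–5 kb, 1 kb anchors placed 200 bp
from gap edges, 2.5 kb donor flanks. Gaps are planted in unique spacer
segments interleaved between satellite blocks: at this scale a 1 kb
anchor inside a tandem array can never place uniquely, whereas real BAC
anchors (~100 kb) reach out of the array into unique flanking sequence —
the spacer is the honest toy-scale analogue of that reach. ChIP reads are
drawn per-base uniformly with per-cluster weights; methylation sites get
binomial calls at 30× coverage.

What the simulator does *not* emulate: realistic long-read error
profiles, higher-order repeat structure, segmental duplications, copy
number variation of monomers within an array, or chimeric/misjoined
donors. Passing the round-trip tests therefore demonstrates the
correctness of the patching logic and the recoverability of planted
signal under clean conditions, not performance on arbitrary real
assemblies.

# Problem sizes in tests

The test suite and acceptance script run at desk scale, chosen to
exercise every code path with comfortable margins: simulated chromosomes
of 50–110 kb, 100 kb genomes for QV recovery (5–10 replicate genomes per
substitution rate), 400 monomers for cluster recovery, 20–50 k reads per
ChIP sample, and alignment oracle pairs of 2 kb. Genome-scale quantities
reported for real assemblies (tens of thousands of monomers, megabase
centromeres) are outside desk scope and are covered by these
property-level recoveries instead.

# Known limitations

* The aligner reports one best alignment per candidate window; split or
  chimeric alignments are out of scope.
* Liftover tables from multi-patch runs are per-patch (applied
  right-to-left); they are exact for each patch against the assembly
  state it was applied to, and bijective outside replaced spans, but are
  not composed into a single old-to-final table.
* The multinomial mixture treats columns independently; it ignores
  linkage between variant sites, which real satellite families have. It
  is a transparent surrogate for evolutionary mixture models, chosen
  because its likelihood, BIC and labels are exactly reproducible.
* The 165–185 bp retention filter is applied to the genomic hit length,
  not the consensus-projected length; the two differ only for indel-rich
  copies.
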