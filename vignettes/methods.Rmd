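---
title: "Comparative inference of recent subtelomeric NL-cluster evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative inference of recent subtelomeric NL-cluster evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant disease-resistance (*R*) gene clusters of the NBS-LRR (NL) family
evolve quickly, and nowhere faster than in subtelomeres, where satellite
arrays, retroelements and frequent double-strand-break repair drive
duplication, loss and pseudogenization. Given two annotated haplotypes of
such a cluster — two genotypes drawn from recently diverged lineages —
`subtelscope` reconstructs what happened since their split: which genes are
orthologs, which were lost or duplicated in one lineage, which
pseudogenization events predate the split, how intensely unequal
recombination has chewed on the local LTR retroelements, and by which
repair pathway (NHEJ or HR) each segmental duplication was stitched in.

Every inference is comparative and rests on one calibration: the silent
divergence of genes that cannot confuse orthology.

## Ks estimation (NG86 + Jukes–Cantor)

For a pair of coding sequences we count synonymous and nonsynonymous sites
and differences with the Nei–Gojobori (1986) method: each codon position
contributes a synonymous-site fraction equal to the share of its 3
possible single-base changes that preserve the amino acid (changes to stop
codons count as nonsynonymous); codons differing at several positions are
resolved by averaging over all minimal mutational pathways, excluding
pathways through stop codons (if all are blocked, the differences count as
nonsynonymous). Proportions are corrected for multiple hits with
Jukes–Cantor, $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; a proportion at
or above $3/4$ is flagged saturated rather than extrapolated. Gapped codon
columns are excluded pairwise (the classical default; whether the original
analyses used pairwise or complete deletion is not stated anywhere we
could follow, so the choice is recorded here). Stop-containing columns,
including the terminal stop, are excluded from counting.

Alignment is protein-guided: conceptual translations (premature stops kept
as `*`) are aligned globally with BLOSUM62 and affine gaps (open 10,
extend 0.5) and back-mapped onto codons. Annotated pseudogenes with
frameshifts (CDS length not divisible by 3) cannot be translated in one
frame, so such pairs fall back to a global nucleotide alignment
(EDNAFULL-style scores: match 5, mismatch −4, gap open 10, extend 0.5)
whose codon columns are read in the frame of the intact member. The
mismatch penalty matters: with weaker scoring, diverged paralogs shred
into cheap gap columns that hide mismatches and deflate Ks; the
EDNAFULL ratio keeps a mismatch strictly cheaper than the gap pair that
could replace it. When *both* members are frameshifted no common true
reading frame exists at all; such estimates are flagged frame-uncertain,
and the pair classifier refuses to base a sub-threshold (recent) call on
them unless the pair's nucleotide identity independently corroborates
recent divergence (≥0.96).

## Threshold calibration and event inference

Low-copy anchor genes present in both genotypes are paired by
reciprocal-best global identity, and the orthology threshold is set to the
**maximum** anchor Ks — the literal rule of the analysis this package
operationalizes, not a mean-plus-k-standard-deviations construction. Any
homolog pair at or below that threshold diverged no earlier than the
lineage split the anchors date.

Collinear blocks chain anchor pairs whose order is conserved (same or
fully reversed); spans extend outward to the nearer of the contig end or
the next conflicting anchor. Within blocks, cross-genotype pairs of the
same subfamily are orthologs when Ks is at or below the threshold,
nucleotide identity is at least 0.96, and the pair wins reciprocal-best
matching by Ks (ties resolved toward higher identity and flagged). The
comparison is inclusive at the threshold so that the degenerate case of
identical inputs — Ks and threshold both exactly zero — classifies every
gene as an ortholog, as it must.

Events then follow mechanically: a blocked gene with neither an ortholog
nor a recent paralog witnesses a loss in the other lineage; a
within-genotype pair below the threshold is a recent duplication, its
direction read from which member still has an ortholog; an ortholog pair
with both members pseudogenized was pseudogenized before the split
(`shared`), with exactly one member, after it (lineage-specific). Genes
outside any block are reported unresolved, never guessed. Pseudogene
status itself is annotation-level: ATG start but premature stop and/or
frameshift (length ≢ 0 mod 3); no ATG start means a gene segment.
Subfamily membership, where not provided, is assigned by ≥72% global
identity to the best exemplar.

## Repeat landscape

Satellite blocks are found by matching the monomer consensus (528 bp by
default) on both strands at ≥70% identity over at least half a monomer and
chaining matches closer than one monomer length; the unit count is the
number of chained matches. A consensus-plus-identity scan replaces the
original profile-HMM search; block and unit semantics are preserved and a
profile input remains a possible extension.

LTR elements are seeded from exemplar hits (blastn), projected back to
full-exemplar boundaries (local alignments erode mismatched ends, which
would otherwise shift every boundary by a base or two). Two
same-orientation hits spanning 1–15 kb flanked by an exact target-site
duplication (TSD, 4–6 bp, ±2 bp boundary slack) form an intact element; a
lone hit with its own TSD is a solo-LTR — the scar left when unequal
intra-strand recombination between an element's two LTRs deletes its
body; a lone hit without a TSD is reported truncated. The I/S ratio
(intact/solo) is the package's proxy for local unequal-recombination
intensity; it is undefined, and flagged rather than raised, when no
solo-LTR exists.

## Segmental duplications and junction repair

Satellite blocks and NL genes are hard-masked (N) before the
duplication search, which reports local alignments with more than 90%
identity over at least 500 bp, canonicalized so the search is symmetric in
its arguments. For each duplication the inserted copy is recognized by
recipient retrieval: the copy whose flanks map contiguously (without the
tract between them) in the other genotype is the hybrid, and the mapped
region is the putative recipient molecule.

Junction resolution scans every split point in a window around each tract
boundary and takes the changepoint maximizing per-base agreement with the
recipient on one side and the donor on the other (leftmost on ties, which
makes the call deterministic under microhomology, where an interval of
split points is equivalent). The microhomology *m* is the maximal run of
positions on which donor and recipient agree spanning the changepoint. A
transition region is the maximal interval around the junction in which
donor–recipient identity in 10-bp sliding windows stays at or above 0.70.
Classification: HR when a transition of ≥50 bp at ≥0.70 identity spans the
junction (homology extending beyond the boundary); NHEJ when *m* ≤ 10 bp
and no qualifying transition exists; ambiguous otherwise — including
microhomologies longer than 10 bp, which this classifier declines to
attribute. Without a recipient the analysis degrades to hybrid-versus-donor:
the junction comes from the donor-similarity boundary, *m* is unavailable,
and an abrupt identity drop (≤0.6 mean over the 200-bp window outside the
tract) with no transition is read as NHEJ — the same identity-profile
criterion a manual analysis applies when the recipient molecule cannot be
retrieved. The numeric cutoffs (10 bp; 50 bp/0.70) are this package's
operational rendering of a classification that is done by inspection in
practice; they separate the canonical exemplars (3-nt microhomology versus
a 130-bp transition at 80% identity) with wide margin, and all are exposed
in `analysis_config()`. A single duplication may legitimately receive
different classes at its X and Y junctions.

## The simulator and what passing tests mean

`generate_locus_pair()` builds an ancestral locus — low-copy anchor genes
interleaved with two CNL subfamily arrays and a pair of TNLs, separated by
intergenic spacers — and evolves two descendants. Defaults are the study
conditions the analysis is designed for: 12 anchor pairs at mean Ks
0.0177; 15 ancestral CNLs per subfamily (900-bp CDS; paralog backbones at
Ks 0.10–0.60, a free choice since only a lower bound is known for
within-genotype paralog divergence); 6 + 3 lineage-specific losses (clean
deletions including 1 kb of flank); 4 shared and 7 + 6 lineage-specific
pseudogenizations (premature stop or 1-bp frameshift, 50/50); one recent
ectopic duplication at extra Ks 0.005; 2 + 1 segmental duplications of
2-kb tracts with NHEJ or HR junctions; per genotype 10 intact LTR
elements, 5 solo-LTRs (4–6-bp TSDs) and 2 satellite blocks of 6–12
monomers at 15% per-unit divergence.

Divergence is substitution-only (uniform choice among the 3 alternative
bases, matching the JC correction downstream): anchors evolve
synonymous-only to per-pair targets; CNLs evolve proportionally at
Ka/Ks 0.2; spacers and pseudogenes evolve neutrally. Anchor targets follow
a fixed relative-rate profile with mean 1 and maximum 2.79 — reproducing a
calibration in which anchors span roughly 0.005–0.05 while the CNL
ortholog divergence sits at the mean, safely below the anchor maximum, as
observed in the system this models. Two deliberate fidelity guards: (i)
targeted mutation reverts its final substitution when the previous state
estimated closer to the target, so realized Ks is unbiased rather than
carrying a half-step overshoot; (ii) a shared pseudogene's start codon and
planted lesion are protected from later neutral evolution, since those
bases *are* the planted truth the recovery tests score against. LTR
insertion sites sit on an evenly spaced spacer grid so that distinct
elements are always farther apart than the intact-pairing window — the
clean-plant regime under which exact I/S recovery is a meaningful
requirement.

What the simulator does **not** emulate: indel evolution beyond the
planted frameshifts, recombination and gene conversion between paralogs,
rate variation along genes, nested or fragmented repeats, assembly gaps,
and compositional bias (all sequence is uniform random). Passing the
recovery tests therefore shows the inference rules are implemented
correctly and are stable under substitution noise at realistic divergences
— not that the pipeline is robust to every artifact of real BAC or WGS
sequence.

## Numerical choices and problem sizes

Reciprocal-best matching is greedy in (Ks, −identity) order, which equals
reciprocal-best on one-to-one truth and resolves ties deterministically.
Pair classification prescreens candidates by shared-8-mer fraction and
skips full alignment below an estimated ~89% identity; a pair below the Ks
threshold necessarily sits above ~94% identity, so the screen cannot lose
a candidate, and it keeps the full two-genotype comparison (~600 same-
subfamily pairs) to a few seconds. The test suite runs the full default
simulation over 30 seeds for ledger recovery and 100 planted junctions for
the repair-pathway checks; unit tests use a reduced locus (4 anchors, 6
CNLs) that exercises the same machinery. These sizes were chosen so the
whole suite completes in minutes on a single core while keeping every rate
estimate's sampling error well inside the asserted bounds.

## Known limitations

Homology searches run through the NCBI BLAST+ `blastn` binary, which must
be on the PATH. Junction coordinates assume no indels between hybrid,
donor and recipient in the scanned windows (substitution-only divergence;
true for the simulator, approximate for real data). Block extension
beyond terminal anchors — to contig end or next conflicting anchor — is one
of several defensible conventions and shifts block-span totals
accordingly. Absolute dating (converting Ks to years) is annotation, not
computation, and is deliberately absent. Genes in regions absent from one
assembly are reported unresolved rather than counted as losses.
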