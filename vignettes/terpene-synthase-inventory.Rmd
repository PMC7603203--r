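---
title: "Building and interrogating a fungal terpene synthase inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and interrogating a fungal terpene synthase inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsinv)
```

## Scope and model

Fungal genomes encode large families of terpene synthases (TSs): terpene
cyclases that convert linear prenyl pyrophosphates (GPP, FPP, GGPP) into
cyclic scaffolds, and prenyl transferases that build those precursors or
prenylate proteins. `tpsinv` implements the desk-scale analytical core of a
TS inventory study in *Trichoderma*: every component of the analysis that
acts on sequences, annotations, coordinates or Ct values is implemented and
testable on deterministic synthetic inputs, while the external heavy
machinery a genome-scale study would invoke (InterProScan, antiSMASH,
Bayesian tree inference) is deliberately out of scope.

The pipeline has five analytical stages:

1. **Motif scanning.** Catalytic metal-binding motifs are short
   aspartate-rich consensus strings. We formalise the field's notation as a
   grammar (`D[DE]xx[DE]`: literals, `x` wildcard, bracketed alternatives)
   and match it exactly. Class I motifs (DDxxD/DDxxE family) mark
   ionization-dependent catalysis; Class II motifs (DxDD, DxDTT)
   protonation-dependent catalysis; a protein carrying both kinds is called
   bifunctional. Accessory motifs (the QW structural repeat, the
   NDLFSFYKE triad of trichodiene synthase, the NSD/DTE triad) are reported
   but never change the fold call.
2. **Transmembrane evidence.** Squalene synthase is membrane-anchored
   through a C-terminal helix of 23 residues. Detection is the classical
   Kyte–Doolittle sliding window: window 19 residues, mean-hydropathy
   threshold 1.6, search region restricted to the C-terminal half, and the
   reported segment is the longest run of residues covered by
   above-threshold windows.
3. **Rule classification.** Each protein is assigned to the first taxonomy
   group (in precedence order) whose required domain accessions, motifs,
   and TM evidence are satisfied; failing all rules yields `unclassified`,
   which is always reported, never dropped.
4. **Phylogenetic assignment.** A reference-guided check: global pairwise
   alignment (BLOSUM62, affine gaps 10/0.5), p-distances, neighbor joining,
   nonparametric bootstrap over alignment columns, and clade-membership
   labeling of a query at a support threshold of 50.
5. **Cluster context and expression.** Biosynthetic-cluster extraction by
   intergenic-gap chaining around an anchor gene, role assignment, synteny
   comparison by reciprocal best hits, and the Livak `2^-ddCt` relative
   expression pipeline with per-gene ANOVA/Tukey statistics.

## The functional taxonomy

The default taxonomy has exactly 15 terminal groups. The underlying survey
names more functional labels than groups; we resolve this by making
protein-prenylation enzymes one leaf with subtypes (GGTase I, GGTase II,
FTase, distinguished by their PANTHER subfamily accessions) and the
polyprenyl-synthase superfamily one leaf with subtypes (GGPP synthase, FPP
synthase, indole diterpene synthase, chimeric-like). This matches the
granularity at which the families cluster phylogenetically while keeping
the count of 15; the taxonomy is a plain TSV and fully swappable.

```{r}
default_taxonomy()
```

Precedence resolves overlaps between rules sharing a domain (the TRI5
superfamily, Pfam PF06330, contains four leaves distinguished by motif
content: the DDSRE/DDSIE + NDLFSFYKE signature of trichodiene synthase,
the D[DE]HFD motif of longiborneol synthase, then the two uncharacterized
groups by their DDxxE / DDxxD variants). Phylogenetic evidence is advisory:
when `assign_by_reference()` disagrees with the rule label, the rule label
wins — the rules are deterministic and auditable, and no principled
conflict-resolution procedure exists for the synthetic setting.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every claim in the test suite is evaluated.

**Protein panels.** Each group's proteins are a uniform random background
with the group's motif instances planted verbatim at fixed fractional
offsets (the class-defining motif at 60% of the length, companions nearby,
the TM block in the final 10% — concrete conventions for the "C-terminal"
statements in the literature). Two deliberate choices:

- *The background alphabet excludes D, N and Q.* Every bundled motif
  grammar begins with one of those letters, so with this alphabet planted
  motifs are the only motif signal and classification of an unmutated
  panel inverts the generator exactly. With a full 20-letter background,
  spurious aspartate-rich windows arise at a rate of several percent per
  400-residue protein (a DDxxE window has probability 20^-3 per position),
  which would make exact label recovery impossible by construction rather
  than by any fault of the classifier. The mutation model substitutes from
  the same alphabet and never touches planted windows, so label recovery
  stays perfect as the mutation rate rises — the degradation tests verify
  non-increase, not decay.
- *The TM helix is moderately hydrophobic with polar flanks.* The planted
  anchor is 23 alanines (Kyte–Doolittle 1.8, just above the 1.6 threshold)
  guarded by glutamates, and the rest of the fixture's C-terminal half is
  drawn from polar residues, as around a real single-pass membrane anchor.
  A window containing even one guard residue falls below threshold
  (mean (18 × 1.8 − 3.5)/19 ≈ 1.52), so the covered run is exactly the 23
  planted residues at any seed. A strongly hydrophobic helix (poly-leucine)
  would be detected too, but above-threshold windows overhang its ends and
  the covered run then exceeds the helix length — the alanine construction
  is the one whose detected extent equals the biological claim.

**The anchored locus.** The default layout places the anchor (`tri5`) and
six flanking genes — Zn2-C6 transcription factor (A), oxygenase (B),
alpha-beta hydrolase (C), oxygenase (D), MFS transporter (E), carbonic
anhydrase (F) — on one contig with intergenic gaps of 1.5–2 kb and a total
span of exactly 21.2 kb. Gap chaining with the default 3 kb threshold
recovers precisely this cluster; a boundary rule equivalent to antiSMASH's
is not attempted, and on real genomes the recovered span would depend on
the threshold.

**Ct tables.** The reference gene sits at a base level of 20 cycles and
targets at 24 (the Livak statistic is invariant to both); a planted fold
lowers the target's Ct by `log2(fold)` in that condition. Biological
variation is a Gaussian offset shared by all genes within a (condition,
replicate) — which therefore cancels exactly in dCt — and technical noise
is a per-well Gaussian, both with SD `noise_sd`. At `noise_sd = 0` the
pipeline recovers planted folds to floating-point accuracy; that is the
regime in which the bundled fold-change checks (18.7, 2.7, 134, 0.03) are
run. Non-detections are an empty Ct field, mirroring "transcripts not
detected" without inventing a cycle cutoff.

What the generator does **not** emulate: indels and rate-heterogeneous
sequence evolution, nucleotide-level gene structure, compositional bias,
primer-efficiency artefacts. Passing tests therefore demonstrate
correctness of the computations under clean planted signals, not
robustness to every pathology of real data.

## Numerical and procedural choices

- Positions are 1-based inclusive everywhere, matching GFF3.
- The ambiguity code `X` in input sequences matches only the `x` wildcard:
  an unknown residue cannot certify a catalytic aspartate.
- Overlapping motif matches are all reported; counting "two DDxxD motifs"
  requires it.
- Neighbor joining breaks Q-criterion ties by the lowest (row, column)
  pair; negative branch lengths are clamped to zero with the deficit moved
  to the sister edge, preserving the joined pair's path length. Distances
  are p-distances (1 − identity/100); no rate correction is applied or
  needed for clade-membership decisions on synthetic fixtures.
- Percent identity divides by the alignment columns remaining after
  trimming terminal gap runs by default; the `full` convention (all
  columns) is available through `alignment_params()` since published
  identity figures rarely state which denominator was used. The argument
  order is canonicalized internally because co-optimal alignments returned
  for (a, b) and (b, a) can differ.
- Bootstrap resampling uses one RNG stream seeded once, and taxa are
  ordered alphabetically before tree building, so supports do not depend
  on leaf input order.
- ANOVA on expression runs per gene across conditions (matching per-gene
  star annotations in this literature) and on the ddCt (log2) scale, where
  additive Ct noise is homoscedastic; folds themselves are log-normal.
  Stars follow p ≥ 0.05 ns, < 0.05 `*`, < 0.01 `**`, < 0.001 `***`, with
  the boundary p = 0.05 not significant. When all groups have zero
  variance and equal means the F statistic is undefined; the result is
  flagged `degenerate` and reported not significant.
- Technical replicates aggregate by the arithmetic mean of detected wells;
  a cell is absent when at least half its technical replicates are
  non-detections (the `majority` rule; `all` is available). The rule is
  this package's convention — the source literature only states that
  transcripts were not detected.

## Problem sizes

The bundled test suite runs at deliberately small scale: panels of 15–300
proteins of 400 residues, trees of up to 8 taxa, bootstrap with 50–100
replicates on alignments of ~100 columns, Ct tables of up to 200
biological replicates. These sizes exercise every code path; all
operations scale to larger inputs in the obvious polynomial way
(pairwise alignment is quadratic in sequence length, NJ cubic in taxa).

## Known limitations

- Motif detection is exact consensus matching, not profile HMM scoring; a
  diverged motif that no longer matches its consensus string is missed.
  The grammar table is user-replaceable but position-specific scoring is a
  non-goal.
- The 15-group partition is one consistent reading of the survey
  literature, not a community standard; the taxonomy file exists precisely
  so it can be revised.
- Cluster extraction by gap chaining has no notion of promoter sharing,
  co-expression or biosynthetic logic; it reproduces compact clusters and
  nothing more.
- `assign_by_reference()` assumes the references are alignable full-length
  homologs; with references of wildly different lengths the guide-order
  progressive aligner (consensus-profile based) is cruder than a modern
  MSA program.
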