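---
title: "Methods: genome-wide MYB family analysis with mybfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide MYB family analysis with mybfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybfam)
```

## The biological problem

MYB proteins form one of the largest transcription-factor families in
plants. They are defined by a DNA-binding domain of up to four imperfect
repeats of about 52 amino acids, each folding into three alpha-helices whose
second and third helices form a helix-turn-helix; three regularly spaced
tryptophans per repeat build the hydrophobic core. Most plant MYBs carry two
repeats (R2 and R3, jointly spanning roughly 104 residues including the
linker) and regulate development, specialised metabolism and stress
responses. Atypical classes carry three repeats (MYB3R, cell-cycle
regulators), four repeats (MYB4R), or a CDC5-type architecture.

`mybfam` packages the full analysis a genome-wide family survey needs:
repeat detection and family classification from a predicted proteome,
per-position conservation of the repeats (sequence-logo data), functional
motif and diagnostic-residue annotation, chromosomal distribution and
tandem-duplication analysis from gene models, landmark-anchored clade
assignment on neighbor-joining trees, and organ-expression summaries from
RNA-seq count matrices. A first-class synthetic-data module generates
proteomes, gene models and count matrices with known ground truth, so every
stage is testable without any external download. The package ships a
transcription of a published 75-gene sugar-beet family catalogue
(`read_family_catalogue()`) as a worked, fully reproducible example of the
genome-context statistics.

## Repeat detection: the scoring profile

The membership rule for the family is *two or more MYB repeats*. Instead of
a translated-BLAST search against a genome assembly, detection operates on
the predicted proteome with one position-specific scoring profile per repeat
kind, built from a small aligned seed:

$$ s_{k}(a) \;=\; \log\frac{c_{k}(a) + \lambda\, b_a}{n + \lambda} \;-\; \log b_a $$

where $c_k(a)$ counts residue $a$ in seed column $k$, $b_a$ is the
background frequency (average protein composition), and $\lambda$ is a
pseudocount (default 1). A window's score is the sum over its positions; the
expected score of a background window is $-\mathrm{KL}(b\,\|\,q_k) \le 0$
at every position.

Windows are fixed-width: 53 positions for R2 and 51 for R3, matching the
canonical numbering below. Indels within one repeat are deliberately not
modelled — deletions or insertions inside the repeat are rare, the seed is
fixed-width, and fixed windows make every downstream coordinate exact. A
window becomes a hit when

1. its score reaches the profile threshold, and
2. the tryptophan landmarks hold: strict `W` at local positions 7, 26 and 45
   of R2 and at 26 of R3, while the first R3 tryptophan (canonical 60)
   tolerates F/I/L/Y and the last (canonical 98) tolerates F or C. These
   substitution sets mirror what is observed in plant families: the W60
   position is routinely replaced by another bulky hydrophobic residue, and
   position 98 occasionally carries F or (exceptionally) C.

Overlapping candidates are resolved greedily by descending score, ties to
the leftmost start — deterministic and exactly reproducible by the
brute-force oracle used in the tests.

**Threshold.** No numeric cutoff is inherited from the literature, so the
default is calibrated from an explicit null: the 99.9th percentile of the
maximum window score over 1000 length-300 proteins drawn from the background
composition (fixed internal seed, so the default profiles are deterministic;
see `calibrate_threshold()`). Because a hit additionally needs three
correctly spaced tryptophan-class residues, the joint false-positive rate on
background sequence is far below the score tail alone, which is why the test
suite can demand *zero* hits on hundreds of fresh decoys while keeping 100%
sensitivity on planted repeats at a 5% per-position substitution rate.

**Seed alignments.** The shipped seeds (`seed_r2_synthetic.afa`,
`seed_r3_synthetic.afa`) are synthetic stand-ins written for this package:
they carry the canonical landmark architecture and the invariant and highly
conserved residues of the plant R2R3 domain (D11, C43, R46; E64, G76, R89,
T90; canonical numbering), but they are not a published alignment. Both
`build_profile()` and `default_myb_profiles()` accept user seeds, and any
serious application to a new proteome should rebuild the profiles from
curated repeats of a related species.

## Canonical numbering and classification

The combined domain is numbered 1–104: R2 occupies canonical 1–53 and R3
canonical 54–104 (local window position + 53). `extract_domain()` returns
the 104-residue domain and the canonical-to-protein coordinate map; repeats
planted or detected at any offset yield identical canonical coordinates,
which the tests exploit ("diagnostics are invariant to the flanks").

Family classes follow the repeat count: 0 hits — not a MYB; 1 —
single-repeat (excluded from the multi-repeat family set); 2 — R2R3; 3 —
MYB3R; 4 or more — MYB4R. A repeat immediately upstream of an R2–R3 pair in
a three-repeat protein is relabelled R1-like. CDC5-like proteins are defined
by homology rather than repeat count, so any multi-repeat protein whose
full-length global-alignment identity (Needleman–Wunsch, BLOSUM62, affine
gaps 10/1, identity over the alignment span) to the CDC5 landmark exceeds
40% is reclassified CDC5-like. The shipped CDC5 landmark is again a
*synthetic* stand-in whose repeats are deliberately diverged (about 50%
identity to the consensus) so that ordinary R2R3 proteins fall well under
the cutoff; replace it with a real CDC5 ortholog for production use.

## Conservation profiling

Because all windows of one repeat kind share coordinates by construction,
the cross-family "alignment" is landmark-anchored column stacking
(`align_repeats()`), not a general MSA. This is a deliberate design choice:
a general aligner introduces tool- and version-dependent gap placement that
makes per-position tallies irreproducible, while stacked fixed windows make
the conservation analysis exact. The cost is that repeats with true indels
are not representable; they are outside the model by the fixed-width
decision above.

`position_frequencies()` tallies relative frequencies with gaps excluded
from the denominator (the convention of logo tools) and reports per-position
information content $I_k = \log_2 20 - H_k$ in bits, without a small-sample
correction. Conservation classes: *invariant* means the modal residue has
frequency exactly 1; *highly conserved* means modal frequency at or above a
cutoff, default 0.9 — the published analyses name the class without
quantifying it, so the cutoff is exposed. `export_logo_data()` emits
`frequency × information` stack heights, which any logo renderer can draw.

## Motifs and diagnostic residues

Patterns use a Prosite-style notation: `[DE]Lx2[RK]x3Lx6Lx3R` is the
bHLH-interaction consensus of the R3 repeat, read with exact wildcard
counts, total width 20. R2R3 proteins carrying it can recruit bHLH
cofactors (anthocyanin-type regulation); flavonol regulators characteristically
lack it.

The subgroup-7 (flavonol regulator) C-terminal motif is `GRTxRSxMK`. The
best-documented positive example in the Caryophyllales literature matches as
`GRTSRWAMQ`, which differs from the pattern at *two* fixed positions
(S6→W, K9→Q) even though it is described as a single substitution. The
wildcard placement intended by that description cannot be recovered, so two
variants ship and neither is asserted as authoritative: `sg7` (strict
pattern, default tolerance 2) and `sg7_loose` (`GRTxRSxMx`, final position
free, tolerance 1, under which the example is a true one-substitution
match). The SG7-2 motif `[W/x][L/x]LS` is searched only in the last 10
residues ("very C-terminal" is not quantified; the window is a parameter),
with a tier recording whether the preferred W/L residues are realised.

Diagnostic residues are read off the canonical domain: position 44 (DNA
contact in the R2 third helix), 60 and 98 (the substitutable tryptophans)
and 89, where A marks anthocyanin-type and G proanthocyanidin-type
regulators, and I marks the atypical betalain-candidate clade. At position
98, W is canonical and F is a rare but literature-known replacement; any
other residue — including the scannable cysteine substitution — raises the
`anomaly_98` flag. The flag therefore highlights exactly the case worth
manual follow-up while the scanner still reports the repeat.

## Genome context

`read_gene_models()` parses GFF3 gene/mRNA/exon features (1-based inclusive
coordinates externally; coordinates are normalized so start ≤ end with the
orientation kept in `strand`). Exon categories are 1, 2, 3 and >3 — three
exons with two introns being the conserved rule for this family.

Chromosomal distribution counts genes assigned to a chromosome without
position ("un" labels) toward that chromosome and pools unplaced scaffolds
("rnd" labels) into an *unanchored* bucket, matching the accounting used
for the published catalogue. Gene density is reported both as genes/Mb and
Mb/gene when lengths are supplied, because the published "one gene every
10.5 Mb" figure does not state its denominator convention.

Tandem sister pairs are all same-chromosome/scaffold gene pairs whose
normalized start-to-start distance (minimum coordinate of each gene —
strand-independent) is at most 105 kb. That default is the smallest round
threshold that, on the shipped catalogue, separates the three reported
pairs (closest non-pair: 109,425 bp). An optional intervening-gene filter
drops pairs with an annotated gene between them when a full annotation is
available.

## Phylogeny and clade assignment

Distances over an alignment use pairwise deletion of gap columns;
`p = mismatches / compared sites`, Poisson-corrected as `d = −ln(1 − p)`.
The correction diverges as p→1, so p is capped at 0.95 (d ≈ 3.0); a pair
with zero comparable sites is an error naming the pair. The intended input
is the canonical 104-position domain block: full-length alignments of the
highly variable C-terminus are aligner-dependent and not reproducible from
a fixed-width model, though any user-supplied alignment is accepted.

`neighbor_joining()` is the classical agglomerative algorithm (Q-criterion,
standard branch-length formulas, negative branch lengths clamped at zero)
with a deterministic tie-break: among minimal Q pairs, the lexicographically
smallest pair of subtree leaf labels wins. NJ is exact on additive matrices;
the tests verify topology recovery up to 8 taxa against topology
enumeration, and cross-check random matrices against an independent NJ
implementation.

Bootstrap resampling draws alignment columns with replacement from one
seeded RNG stream; each original internal edge is scored by the percentage
of replicate trees containing the same bipartition. Bipartition keys are
canonicalised by the side containing the lexicographically smallest taxon,
which makes supports invariant to taxon input order.

Clade labels transfer from landmarks: a query joins clade X when the
smallest supported (≥ 50% by default) bipartition side containing it and at
least one landmark contains landmarks of clade X only. Mixed-clade sides and
unsupported placements leave the query unassigned — deliberately
conservative, because forcing a label for ambiguous placements is exactly
the failure mode a landmark scheme should avoid. A query whose smallest
supported side contains only other queries is flagged as a *novel-clade
candidate*: the species-specific-expansion pattern (two family members
clustering apart from all landmarks) that in sugar beet marks the
betalain-candidate clade.

## Expression

Size factors are the median-of-ratios estimator: the per-gene reference is
the geometric mean across samples over genes with no zero count, and a
sample's factor is the median of count/reference. The implementation follows
that definition literally (arithmetic median of the ratios); the DESeq2
function computing the same estimator is used as an independent cross-check
in the tests and agrees to within its log-scale median interpolation on
even gene counts. Factors are identifiable only up to the reference scale,
so recovery tests compare ratios after removing the common geometric mean.

Presence calls use a threshold on normalized values, default 0 — "any
detected expression counts", matching a heatmap convention where black is
exactly zero. The threshold is exposed because published per-organ expressed
counts depend on an unstated cutoff; such tallies are threshold-sensitive
and are not treated as reproducible targets here.

Gene ordering uses centroid-linkage hierarchical clustering of
`log2(x + 1)` values under squared Euclidean distance (`hclust`,
`method = "centroid"`). Centroid linkage can produce non-monotone merge
heights; that is inherent to the method and left visible. The distance is
fixed to Euclidean: the clustering tool used in the original analyses
defaults to correlation-based metrics for other linkages, but centroid
linkage is conventionally Euclidean, and the choice is recorded here rather
than hidden. The pseudo-count default of 1 handles exact zeros. An
O(n³) naive implementation in the test suite reproduces the full merge
sequence for n ≤ 12.

## The synthetic-data module

`generate_proteome()` plants repeat copies of the seed consensus into
background-composition flanks, with a per-position substitution rate;
strict landmarks never mutate and the W60/W98-class landmarks substitute
only within their allowed sets, so planted repeats always satisfy the
landmark rules by construction and ground truth records every substitution.
Decoys are drawn from the profile's background frequencies, *not* uniformly
— uniform decoys would understate the false-positive rate of a scanner
whose scores are log-odds against that background. Architectures: R2R3
(R2+R3 contiguous), MYB3R (an R3-modelled R1-like repeat upstream), MYB4R
(two R2+R3 blocks), single-repeat, and decoy.

`generate_gene_models()` writes byte-stable GFF3 with 150 bp exons and
200 bp introns from a layout table (overlapping requested gene bodies are
an error); `random_gene_layout()` provides seeded random layouts.
`generate_counts()` draws negative-binomial counts
(`variance = mu + phi mu^2`) around log-uniform per-gene base means scaled
by planted per-sample factors, with optional organ-restricted and silent
genes. The default dispersion is 0.05 (a biological CV of ~22%), the regime
of low-variability isogenic material such as a double-haploid reference
line; with 500 genes this puts the median-of-ratios ratio error comfortably
within the 5–10% recovery bands the tests assert. Dispersion is a parameter,
and raising it to field-experiment levels (0.2 and up) will widen those
errors roughly with $\sqrt{\phi}$.

What the generator does *not* emulate: repeat indels, compositional bias of
real proteomes (low-complexity regions, signal peptides), nucleotide-level
gene structure (no splice signals), correlated expression programs across
organs, and library-level artefacts (GC bias, gene-length effects). Passing
the recovery tests therefore demonstrates algorithmic correctness under the
stated model, not performance on arbitrary real proteomes — for those, the
profile seed should be rebuilt from curated repeats as described above.

## Problem sizes and determinism

The test suite and the acceptance script run synthetic studies at the sizes
the analyses were designed around: 100 planted MYB proteins plus 100 decoys
for scanner recovery, 500-gene count matrices for size-factor recovery,
100 bootstrap replicates on small alignments, NJ recovery to 8 taxa, and
clustering oracles to 12 genes. Every stochastic stage takes an explicit
integer seed; generators save and restore the caller's RNG state, and the
pipeline driver (`run_pipeline()`) rejects configurations without a seed
whenever a stochastic stage would run.

## Known limitations

* Fixed-width repeat windows cannot represent repeats with internal indels;
  such proteins may be missed or mis-anchored.
* The shipped seed alignments and the CDC5 landmark are synthetic
  stand-ins; results on real proteomes depend on replacing them with
  curated sequences.
* Clade assignment requires the landmark set to span the clades of
  interest; queries in unrepresented clades are reported unassigned or as
  novel-clade candidates rather than labelled.
* Expression handling assumes one sample per organ (no replicate modelling,
  no differential testing or dispersion estimation).
* Maximum-parsimony trees and raw-read processing are out of scope; the
  expression module starts from a count matrix.
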