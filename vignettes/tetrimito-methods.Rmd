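---
title: "Methods: comparative mitogenomics with tetrimito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with tetrimito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrimito)
```

# Scope and data model

tetrimito analyses annotated insect mitochondrial genomes: circular
molecules of roughly 14–18 kb carrying 13 protein-coding genes (PCGs), 22
tRNAs, 2 rRNAs and one AT-rich control region. Internally every feature
lives in 0-based half-open coordinates on the forward (major) strand;
GenBank's 1-based inclusive convention is converted only at the flat-file
boundary. A gene that spans the replication origin is stored as a single
feature with `wraps_origin = TRUE` and an ordered pair of spans, never as
two features — this keeps gene identity intact for gap scanning and
extraction, and makes circular arithmetic unambiguous. Gene symbols are
normalised through a bundled, editable synonym table (`gene_synonyms()`);
unknown symbols are kept verbatim with a warning rather than rejected,
because annotation vocabulary varies widely across GenBank submitters.
Ambiguous bases (N) are legal in sequences but excluded from every
composition denominator.

# Composition statistics

`base_composition()` reports per-base percentages over unambiguous bases,
AT%/GC%, and the strand skews AT-skew = (A−T)/(A+T), GC-skew =
(G−C)/(G+C). A zero denominator yields `NA`, not 0 — a window of all G/C
has no defined AT-skew. `sliding_window_profile()` uses a 100-nt window by
default (the convention for circular mitogenome content plots); the step
defaults to the window size (non-overlapping) because no particular step
is canonical, and windows wrap the origin on circular records so that
`ceiling(L/step)` windows anchored at position 0 tile the genome.

# Codon-usage bias

All codon statistics run under NCBI translation table 5 (invertebrate
mitochondrial) by default — the code under which tetrigid PCGs are read,
with AGA/AGG as serine (an 8-codon family), ATA as Met and TGA as Trp,
hence 62 sense codons in 20 synonymous families. The table id is an
argument everywhere.

`count_codons()` reads codons in frame from position 0, drops a trailing
1–2 nt partial codon, excludes a terminal stop, and tallies internal stops
and N-containing codons separately as quality flags. Stops never enter
RSCU, ENC or positional-GC denominators — standard codon-bias practice.
`positional_gc()` derives GC1/GC2/GC3 from exactly the retained codons, so
all statistics share one denominator; GC12 = (GC1+GC2)/2 is exact by
construction.

RSCU is observed count over synonymous-family mean; values are never
rounded in computation (only at presentation). An entirely unused family
gets RSCU 0 for all members and is flagged via the `empty_families`
attribute.

ENC uses Wright's generalized estimator: per family of size k with n
codons and frequencies p, F̂ = (nΣp²−1)/(n−1); families are grouped by
size and ENC = Σ_k N_k / mean(F̂_k), clipped to (0, 62]. Families with
n < 2 are imputed from their size-class mean; an empty size-3 class is
interpolated from the size-2 and size-4 classes, and any other empty class
falls back to the uniform value 1/k. Mitochondrial gene sets are small, so
sparse families are routine and the imputation rule matters in practice.
Note one numerical subtlety: because F̂ carries the small-sample −1
correction, ENC is only asymptotically invariant to rescaling all counts;
doubling counts shifts ENC by O(1/n) (about one unit at ~1,400 codons,
under 0.1 by ~20,000). The null curve `enc_expected()` is
ENC\*(s) = 2 + s + 29/(s²+(1−s)²).

`neutrality_regression()` fits GC12 on GC3 by ordinary least squares. Two
open choices were resolved as follows. First, the "95% confidence
interval" drawn on such plots is taken to be the confidence band of the
mean response (the most common reading); a prediction band is available
via `band = "prediction"`. Second, points are per-taxon over the 13
concatenated PCGs — one point per species — matching species-level
regressions; a per-gene analysis is possible by passing per-gene values,
but is not the default. Whether outgroup taxa belong in the regression is
left to the caller: any subset of points can be fitted. A slope below 1 is
labelled "mutation-bias dominant" — third positions respond to mutation
pressure while first/second positions are shielded by selection.

`cluster_rscu_matrix()` clusters rows (taxa) and columns (codons) by
average-linkage agglomeration on Euclidean distance, the standard choice
for RSCU heatmaps; on bias-polarised matrices the unfavoured (RSCU < 1)
and favoured (RSCU > 1) codons separate into the two top-level column
clusters. `hclust` merging is deterministic for distinct distances; ties
resolve by input index.

# Intergenic gaps and cloverleaf tRNA discovery

`find_intergenic_gaps()` projects all annotated features to forward-strand
intervals, merges overlaps (overlapping genes are common; gaps are never
computed inside annotated features), and reports spacers **strictly
longer** than `min_length` (default 20 nt — the "exceeding 20 bp" rule for
the anomalous tRNA-Ser/nad1 spacer), including the wrap-around spacer on
circular records. The sum of merged feature spans and all spacers equals
the genome length.

`predict_trna()` attempts cloverleaf assembly at every offset of both
strands. Geometry bounds are standard tRNA architecture (no bounds are
dictated by the study system itself, so all are configuration with stated
defaults in `trna_fold_params()`): acceptor stem 7 bp, 2-nt spacer, D-stem
3–4 bp with a 4–12 nt loop, 1-nt spacer, anticodon stem 4–5 bp with a
fixed 7-nt loop, variable region 3–23 nt, T-stem 4–5 bp with a 5–9 nt
loop. The anticodon occupies loop positions 3–5, read 5'→3' on the tRNA
sense strand, and is decoded by reverse-complement lookup in the genetic
code (so anticodon AAT is tRNA-Ile). Scoring is +1 per Watson–Crick pair,
+0.5 per GU wobble pair, −1 per mismatch (at most one per stem), and −0.5
per nucleotide of deviation from canonical geometry; the acceptance
threshold of 18 against a canonical maximum of 21 was calibrated so that
shuffled AT-rich spacers fold below the threshold in far fewer than 5% of
cases while perfectly paired canonical tRNAs score 21. Reported candidate
length is the paired span plus a 3-nt 3' extension (discriminator plus two
bases), the same convention under which the synthetic emitter's canonical
gene totals 74 nt; annotated tRNA gene lengths vary by ±3 nt depending on
whether a discriminator/tail is included, and the length bounds (60–95 nt)
tolerate that. Candidates are strand-symmetric by construction: scanning
the reverse complement yields the same candidate, mirrored, with an
identical score.

`cross_species_gap_survey()` takes the flanking pair as arguments (nothing
about the tRNA-Ser/nad1 pair is hard-coded — annotation naming of the two
serine tRNAs is inconsistent enough that callers must be able to ask for
either), reports per-record status ("hit", "no candidate", "below
threshold", "gap absent"), and attaches the pairwise ungapped identity of
the recovered candidate sequences trimmed to the shortest.

# Supermatrix construction and the NJ stage

`extract_pcg_set()` pulls the 13 canonical PCGs in coding orientation.
Alignment is deliberately delegated to external tools (MAFFT et al.):
multiple sequence alignment is not this package's contribution, and
`as_aligned_gene_set()` simply verifies equal within-gene lengths.
`concatenate()` records partitions 1-based inclusive (the RAxML/NEXUS
convention, although internal coordinates are 0-based half-open), with a
`gapfill` policy for missing taxa available but off by default. Writers
emit aligned FASTA, relaxed sequential PHYLIP, NEXUS with a sets block,
and RAxML-style partition lines; taxon names are sanitised per dialect
with the mapping returned to the caller.

The distance/NJ stage (`pairwise_distance`, `nj_tree`) exists for
desk-scale sanity checks only — it is exact on additive matrices and
recovers simulated topologies, but is explicitly not equivalent to the
ML/Bayesian inference used for publication-grade phylogenies, which this
package does not attempt. K2P distances error on saturated pairs (log of
a non-positive argument) rather than returning NaN; NJ clamps negative
branch lengths to zero with a warning.

# The synthetic generator: what it emulates, and what it does not

`simulate_mitogenome()` builds a circular genome along a 37-gene template
in the ancestral insect mitochondrial gene order (the study clade's order
is archetypal but not printed anywhere authoritative, so the template is
data, not code, and user-replaceable). Defaults are the study conditions:
~15.4 kb target length, base probabilities (A 0.40, C 0.16, G 0.11,
T 0.33) giving ~73–75% AT with A modal and G rarest, GC3 = 15%,
GC12 = 0.23·GC3 + 27.73 (the published neutrality line as the programmed
scenario), a 30-nt trnS2/nad1 spacer, and a control region of at least
200 nt sized to hit the length target.

Design choices worth noting:

- **Codon-resolved PCG emission.** Bases are not i.i.d.: per-position GC
  counts are allocated exactly (to rounding) across a pooled codon set, so
  realized GC3/GC12 sit within 0.5 percentage points of target — required
  for programming the neutrality relationship. Accidental stop codons are
  repaired by an A→T flip at position 2, which preserves GC at every
  position.
- **Strand-aware composition.** The A>T / C>G asymmetry is a property of
  the major strand, as in real mitogenomes; genes transcribed from the
  minor strand are emitted with mirrored within-class identities, so their
  coding-orientation skew is reversed while the genome-wide bias holds.
- **tRNA emission.** Cloverleaves use fixed canonical geometry with
  perfectly Watson–Crick stems, guaranteeing detectability by design; the
  implant shared across a `simulate_taxa()` panel models the conserved
  cross-species tRNA.
- **One seeded generator per call.** Every simulation function seeds and
  restores RNG state locally; identical parameters give byte-identical
  output.

The generator deliberately does **not** model indels, rate heterogeneity
across sites, selection on codon usage beyond the programmed positional GC
targets, sequence homology between independently simulated taxa (panel
genomes are mutually unrelated except for the shared implant; use
`simulate_alignment_on_tree()` when relatedness matters), tRNA wobble/GU
stems, or realistic control-region repeat structure. Passing tests on
synthetic data therefore demonstrate correctness of the statistics and the
detector on data satisfying the model's assumptions — not robustness to
annotation errors, heteroplasmy, or alignment ambiguity in real records.

Note also that a panel spanning the default GC3 range (8–30%) includes
high-GC3 taxa whose AT% can dip just below 70; the >70% AT property is a
statement about the default single-genome conditions (GC3 = 15%).

# Numerical choices and problem sizes

Tolerances: exact identities (RSCU family sums, GC12 midpoint, OLS vs
normal equations) are tested to 1e−9 or tighter; recovery tests use the
emission tolerance (0.5 percentage points) or Monte-Carlo bounds. The test
suite and acceptance script use desk-scale sizes chosen to make the
checks statistically meaningful while keeping a full run in minutes:
200 implant/shuffle replicates for the tRNA detector, 10-taxon zero-noise
panels for neutrality recovery (slope within ±0.02), 30 replicates of
40-taxon noisy panels for CI coverage, and 50 replicates of 8-taxon /
5,000-column alignments for NJ topology recovery (≥95%).

# Known limitations

GenBank parsing supports the location forms that occur in mitogenome
records (single spans, complement, and two-span origin joins); arbitrary
multi-segment joins are rejected rather than mis-read. The ENC
small-sample behaviour discussed above means ENC values from very short
gene sets (hundreds of codons) carry an upward-bias correction that makes
cross-study comparison sensitive to sequence length. The cloverleaf
detector is a geometric scorer, not a covariance-model homology search: it
asserts foldability, not homology, and candidates should be confirmed with
a CM-based tool before annotation. Real-record reproduction
(`reproduce_published_metrics()`) requires the user to fetch the cited
GenBank records; they are not redistributed with the package.
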