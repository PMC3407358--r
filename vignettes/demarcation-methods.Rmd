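---
title: "Genetics-based species demarcation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetics-based species demarcation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidotax)
library(dplyr)
```

## The problem

When a new RNA virus is sequenced, the question "is this the same species
as its closest known relative, or something new?" often has to be answered
from genome sequences alone. For nidoviruses — and for the mosquito-borne
mesoniviruses that motivated this package — biological data are typically
too sparse to support a phenotype-based decision, so classification leans
on comparative sequence analysis: how divergent is the new genome from its
relatives, and where does that divergence sit relative to the divergence
*within* established species?

`nidotax` implements that workflow end to end:

1. **Genome comparison** — annotate ORFs, reading frames, the −1
   ribosomal-frameshift slippery site (`GGAUUUU` in mesoniviruses) and
   candidate TRS motifs; build a per-ORF nucleotide/amino-acid identity
   table between two genomes (`find_orfs()`, `scan_motif()`,
   `orf_table()`).
2. **Distance computation** — concatenate conserved replicase-domain
   alignments (3CLpro, RdRp, HEL1, optionally ExoN and OMT) and compute
   pairwise evolutionary distances, PEDs (`concat_domains()`,
   `ped_matrix()`).
3. **Demarcation** — compile the divergence distribution, derive distance
   thresholds that separate taxonomic levels by minimising a clustering
   cost, and classify query pairs against intra-species divergence
   (`ped_histogram()`, `find_thresholds()`, `intra_group_max()`,
   `classify_pair()`).
4. **Simulation** — generate hierarchical taxonomies with known ground
   truth, so every stage of the pipeline can be validated without any
   external data (`simulate_taxonomy()`).

## Distance models

For two aligned amino-acid rows, columns that are gapped (`-`) or
ambiguous (`X`) in *either* row are excluded (pairwise deletion), and the
proportion of differing residues over the remaining columns is the
p-distance $p$. Pairwise deletion — rather than dropping every column any
taxon gaps — keeps distances between close taxa unaffected by unrelated
taxa's gaps. Three estimators of the evolutionary distance (substitutions
per site) are available:

| model | formula | default |
|---|---|---|
| `p` | $p$ | |
| `poisson` | $-\ln(1-p)$ | yes |
| `gamma_poisson` | $a\,\big((1-p)^{-1/a}-1\big)$, shape $a$ (default 1) | |

For any $p>0$ the three are strictly ordered
$p < -\ln(1-p) < a((1-p)^{-1/a}-1)$, and as $a \to \infty$ the Gamma
correction approaches the Poisson one. The published intra-species
distances that demarcation decisions hinge on are small (roughly
0.016–0.037 substitutions/site), a regime where all three estimators
nearly coincide — the classification outcome is therefore robust to the
model choice, which is nevertheless recorded in every output. Poisson is
the default because it is the simplest multiple-hit correction; the exact
estimator behind published PED compilations is configuration, not
something this package guesses.

A $p$-distance of 1 cannot be corrected (the logarithm diverges) and
raises an error, as does a pair with no comparable columns.

## Clustering cost and threshold search

A candidate threshold $t$ induces a single-linkage partition: clusters are
the connected components of the graph joining every pair with
$\mathrm{PED} \le t$. This is computed by cutting a single-linkage
dendrogram (`stats::hclust`/`cutree`), which yields exactly those
components, deterministically and independent of input order. The quality
of $t$ is the **clustering cost**

$$ C(t) \;=\; \sum_{\substack{\text{intra pairs}}} \max(0,\, d - t)
  \;+\; \sum_{\substack{\text{inter pairs}}} \max(0,\, t - d), $$

the total magnitude of violations: intra-cluster pairs more distant than
$t$ and inter-cluster pairs closer than $t$. (Under single linkage the
second sum is always zero — any pair closer than $t$ is by construction in
one component — but the functional is stated and implemented in full so it
remains meaningful for externally supplied partitions.) $C(t) = 0$ exactly
when $t$ cleanly separates intra- from inter-cluster distances.

`find_thresholds()` scores every candidate threshold — the midpoints
between consecutive sorted unique distances, a finite and complete search
space — and extracts local minima of the cost profile:

* Candidates are collapsed into runs of equal cost; a run lying strictly
  below its neighbours is a **basin**. Runs at the edges of the candidate
  range qualify: when every species has only a couple of isolates the cost
  can be zero from the smallest distances all the way up to the species
  gap, and that flat region is a legitimate basin.
* Candidate $k$ is the midpoint of unique distances $(v_k, v_{k+1})$, so a
  run spanning candidates $i..j$ holds its cost over the whole interval
  $(v_i, v_{j+1})$ of the threshold continuum. That interval is the
  basin's **support**; its width is the size of the distance gap the basin
  sits in, and the reported threshold is its midpoint.
* Basins are ranked by cost (zero-cost basins first), then support width
  (a wide, empty distance gap is the stronger demarcation signal than a
  narrow dip), then topographic prominence of the cost profile; remaining
  ties go to the smaller threshold — when two cutoffs are otherwise
  equivalent the method refuses the coarser lumping.

Ranking by width before prominence is a deliberate choice: in dense
distance clouds the cost is large simply because many pairs contribute,
so absolute prominence can favour meaningless dips inside a cloud over the
genuinely empty gap between clouds. Width measures the gap itself and is
insensitive to how many pairs surround it.

Degenerate inputs take a warning path rather than inventing structure: a
matrix with fewer than two distinct distances (including the 2-taxon
case) yields no threshold, and a request for more levels than there are
basins returns what exists.

Partitions at increasing thresholds are always nested (single linkage
guarantees it), so per-level partitions form a proper hierarchy.

## Classifying a candidate pair

Given reference species labels, `classify_pair()` declares two taxa
conspecific when their PED does not exceed the *largest intra-species
divergence observed among the labelled reference species* — the direct
formalisation of "their distance is within the range of intra-species
divergence". This criterion needs no threshold search and is the one used
for the mesonivirus-type decision. Alternatively (or additionally), the
pair can be judged against explicit thresholds, one verdict per taxonomic
level. `intra_group_max()` drops singleton groups with a notice — a group
of one carries no intra-group divergence — and returns an empty table if
no group has two members; `classify_pair()` then refuses to classify,
since there is no reference range to compare against.

## The simulator and what it does (not) emulate

`simulate_taxonomy()` generates the bimodal distance structure that
threshold demarcation assumes:

* **Topology** — a star-of-stars: species nodes hang off the root at depth
  `inter_species_depth / 2`, isolates off their species node at
  `intra_species_depth / 2`. Every intra-species pair is then separated by
  exactly `intra_species_depth` and every inter-species pair by
  `inter_species_depth`. A birth–death tree would smear both modes; the
  two-depth design concentrates them, mirroring the intra/inter divergence
  separation the method relies on.
* **Substitution model** — uniform over 20 amino acids: events are a
  Poisson process at rate 1 per site per unit branch length, each
  replacing the residue with one of the other 19 uniformly. This model is
  chosen *because* it has a closed-form expected p-distance at divergence
  $t$,
  $\bar p(t) = \tfrac{19}{20}\big(1 - e^{-20t/19}\big)$
  (`expected_p_distance()`), which the test suite uses as an independent
  oracle for calibration. Real protein evolution (empirical exchange
  matrices, site-rate heterogeneity) is deliberately out of scope.
* **Indels** — off by default; when enabled, single-residue deletions are
  a Poisson process per site and are irreversible, so the true alignment
  is known by construction and is emitted directly, never re-estimated.
* **Determinism** — the whole simulation is a pure function of its
  `sim_config()`, including the seed; identical configs give byte-identical
  FASTA output.

Defaults (5 species × 4 isolates, intra depth 0.03, inter depth 0.6,
three domains of 300/500/250 aa) put the expected intra-species p-distance
near 0.03 — the scale of published intra-species nidovirus divergence —
against a widely separated inter-species mode, over a concatenation length
(1,050 aa) comparable to a three-domain replicase dataset. Four isolates
per species matter: with only two, the cost profile below the species gap
is identically zero (pairs either merge cleanly or stay singletons, so no
violations arise) and the basin support extends to the smallest distances;
with three or more, partial linkage inside a species produces cost humps
that delimit the gap basin sharply.

Passing the simulation-based tests shows the machinery recovers a planted
two-mode structure; it does **not** show that real virus families present
such clean gaps, that alignment or domain-delineation error is tolerated
(alignments are inputs here), or that the uniform substitution model's
distances transfer quantitatively to empirical data.

## Genome-comparison conventions

* Coordinates are 1-based inclusive throughout (GenBank convention); an
  ORF spans start codon through stop codon inclusive, and `length_nt`
  counts the stop.
* Only forward-strand ORFs are scanned: positive-sense RNA virus genomes
  are translated genome-sense.
* Relative reading frames map the start-offset difference
  $d = (\text{start}_q - \text{start}_{ref}) \bmod 3$ as $0 \to 0$,
  $1 \to +1$, $2 \to -1$, so the ORF downstream of a −1 programmed
  ribosomal frameshift is labelled −1.
* Nested same-frame starts are suppressed by default (longest ORF per
  stop codon), overridable with `all_starts = TRUE`.
* `U` and `T` are equivalent everywhere internally; output restores the
  input alphabet. RNA motifs such as `GGAUUUU` can be scanned directly
  against DNA-stored genomes.
* Global alignment uses Needleman–Wunsch with affine gaps
  (BLOSUM62, open 11 / extend 1 for proteins; match +2 / mismatch −3,
  open 5 / extend 2 for nucleotides). A gap of length $L$ costs
  $\text{open} + L \cdot \text{extend}$. Percent identity defaults to the
  `excl_gaps` denominator (columns with residues in both rows); for
  near-length-matched ORFs the two conventions differ negligibly, but the
  choice is fixed and surfaced. Terminal stop codons are stripped before
  amino-acid identity is computed. No default TRS motif ships with the
  package: published TRS assignments disagree between closely related
  genomes, so motif scanning is always user-driven.

## A worked simulated example

```{r example}
sim <- simulate_taxonomy(sim_config(seed = 1))
sim

m <- ped_matrix(concat_domains(sim$alignments, name = "sim-3dom"))
m

dem <- find_thresholds(m)
tidy(dem)

classify_pair(m, "sp01_iso01", "sp01_iso02", labels = sim$labels)
classify_pair(m, "sp01_iso01", "sp02_iso01", labels = sim$labels)
```

```{r plots, fig.width = 6, fig.height = 3.5}
autoplot(m, bin_width = 0.02)
autoplot(dem)
```

## Problem sizes and test design

The test suite validates the core operations against independent oracles:
a quadratic-space affine-gap DP for alignment scores (random pairs up to
50 residues), exhaustive ORF enumeration (random genomes up to 2 kb),
brute-force graph components and violation sums for partitions and costs
(1,000 random matrices of up to 8 taxa), and the closed-form p-distance
expectation (50 replicates at 10,000 sites). Parameter recovery runs 100
seeded simulations at the default conditions and requires the species
threshold to land inside the true distance gap, with fully correct
same-species classification, in at least 95 of them. These sizes keep the
whole suite under a minute while leaving each property no room to pass by
accident.

## Known limitations

* Distances are computed from user-supplied alignments; alignment and
  domain-boundary error propagate directly into PEDs.
* The cost functional counts violation magnitudes, not probabilities; it
  provides no uncertainty measure on thresholds (no bootstrap).
* With two isolates per species the region below the species gap is
  cost-flat and the reported threshold is the midpoint of a wide support
  interval rather than of the gap proper; three or more isolates per
  species sharpen the basin.
* Maximum-likelihood distances under empirical amino-acid models, tree
  inference, and de novo TRS discovery are out of scope.
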