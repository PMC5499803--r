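---
title: "Finding restorer-of-fertility-like gene hotspots with rflscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding restorer-of-fertility-like gene hotspots with rflscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflscout)
library(dplyr)
```

## The problem

Cytoplasmic male sterility (CMS) — maternally inherited pollen failure
caused by aberrant mitochondrial open reading frames — is the workhorse of
commercial hybrid seed production. Fertility is restored by nuclear
*restorer of fertility* (*Rf*) genes, and in most characterised systems the
restorer is a P-class pentatricopeptide repeat (PPR) protein. The
*restorer-of-fertility-like* (RFL) subgroup of the PPR family is small
(roughly 10–30 genes per plant genome), fast-evolving, and physically
clustered: new RFLs arise by tandem duplication inside compact genomic
regions. Locating those regions — "RFL generation hotspots" — in a newly
sequenced genome shortlists the places where a functional *Rf* gene is
likely to sit, long before any mapping population exists.

`rflscout` implements that screen as a chain of small, testable stages:

1. **Motif scan** — find PPR repeat motifs in a proteome with
   position-specific scoring matrices (PSSMs), or import HMMER3 hits.
2. **Classification** — split PPRs into the P and PLS subfamilies and the
   E / E+ / DYW editing subclasses from the motif architecture.
3. **RFL screen** — call RFL candidates from the P subfamily by combining
   greedy identity clustering with similarity to known restorer proteins.
4. **Orthologous clustering** — build an all-vs-all similarity graph over
   several proteomes, call ortholog/in-paralog/co-ortholog pairs, cluster
   with Markov clustering (MCL), and detect the outlying cross-species RFL
   supercluster.
5. **Phylogeny and hotspots** — build a distance tree of the supercluster,
   extract maximal single-species clades, and map them to genomic regions.

A seeded synthetic-data generator with complete ground truth makes every
stage testable end to end.

## Motif model and scanning

PPR repeats are degenerate helical motifs: the canonical P motif is 35
amino acids, with a long (L, ~36 aa) and a short (S, ~31 aa) variant, and
the PLS subfamily carries up to three C-terminal domains (E, E+, DYW — the
last named for its terminal Asp-Tyr-Trp). The scanner models each motif
class as a position-specific log-odds matrix built from an aligned block:

$$\mathrm{logodds}[c, a] = \log_2 \frac{(n_{c,a} + w\,b_a)/(N + w)}{b_a}$$

with pseudocount weight $w$ (default 1) and background frequencies $b_a$
(default uniform 0.05). Scanning slides an ungapped, fixed-length window
over the protein; every window scoring at least a threshold is reported.
The default threshold is **0.35 × the maximum attainable window score** —
a score cutoff is unavoidable and no canonical value exists for these
simplified profiles, so it is exposed as `threshold_frac`. Unknown
residues (`X`) and stops (`*`) score 0 bits per column, i.e. as background.

Overlapping candidate hits are resolved per protein by weighted interval
scheduling (dynamic programming): the non-overlapping subset with maximal
total score wins, with ties broken towards more hits, then leftmost start,
then profile order P < L < S < E < E+ < DYW. A global optimum rather than a
greedy sweep makes the track unique and directly testable against subset
enumeration.

Deliberately **not** implemented: a full profile HMM with insert/delete
states. The discrimination task here is motif class and position, which
ungapped windows handle at desk scale; users with true HMM hits can import
them via `read_domtblout()` with an alias table mapping their profile names
onto the six classes.

## Classification rules

A protein is a PPR when its track has at least `min_motifs` (default 2)
P/L/S hits; it is PLS when at least one L **and** one S hit are present,
else P. PLS proteins are subclassified by their C-terminal domains with
precedence DYW > E+ > E; a qualifying domain hit must lie C-terminal to the
last repeat (a domain profile match upstream of the repeat array is not a
terminal domain and is ignored with a warning). Motif class comes from
which profile scored the hit, never from the measured hit length — repeat
lengths are only "usually" 36/31 and length rules would be fragile.

Pseudogene flagging is heuristic by necessity: a record is flagged when it
lacks an initial Met, contains a stop before the end of its last motif hit,
or its last motif runs into the final 5 residues (truncated mid-motif).

Summary percentages are rounded **half-up** to integers: with 207 P-class
genes out of 373 PPRs this prints 55%, matching how such surveys round
their headline shares.

## The RFL screen

Two deliberately different identity definitions coexist:

* **Clustering identity** (CD-HIT convention): identities in the local
  alignment divided by the length of the *shorter* sequence. Used by
  `greedy_cluster()`, which sorts by length (descending, ties by id) and
  joins each sequence to the first representative meeting the threshold.
* **Search identity** (BLAST convention): identities divided by aligned
  columns, paired with query coverage. Used by `reference_hit_list()`
  with inclusive gates (default ≥50% identity **and** ≥50% coverage,
  the candidate PPR being the query).

`consensus_rfl()` builds four membership lists — membership in a 60%
identity cluster of at least 4 sequences, plus similarity to each of three
known restorer references — and calls a candidate when a protein sits on at
least 3 of the 4. The identity ladder (90/80/70/60/50%) is available via
`cluster_ladder()` for diagnostics, but only the 60% level feeds the call:
in practice the higher levels yield only tiny clusters, while 60% is where
RFL families coalesce. All alignments are Smith–Waterman with affine gaps
(gap of length $L$ costs `gap_open + (L-1) * gap_extend`), BLOSUM62 by
default.

## Orthologous clustering

After a QC filter (keep length > 30 aa and stop fraction ≤ 10%), an
all-vs-all similarity graph is built. A shared-4-mer prefilter skips pairs
without any exact common word; surviving pairs are scored by a compiled
Smith–Waterman kernel and converted to an approximate E-value
$E = K m n\, 2^{-\text{bits}}$ with fixed $K = 0.1$ and
$\text{bits} = \lambda S / \ln 2$, $\lambda = 0.267$ (the gapped BLOSUM62
constant). Only the rank/threshold behaviour of these weights matters for
graph construction, so the constants are documented rather than calibrated.
Edges require $-\log_{10} E \ge 5$ (the conventional 1e-5 cutoff); weights
are capped at 300.

Pair calling follows the standard orthology heuristics: orthologs are
reciprocal best cross-species edges (ties kept), in-paralogs are
within-species edges at least as heavy as the lighter member's best
cross-species edge, co-orthologs are cross-species edges joined to an
ortholog pair through in-paralog components. Weights are normalised by the
mean of their pair type per species pair — a simplification of the cited
tools' normalisation, which is not fully specified in the literature we
re-implement from.

MCL runs on the column-stochastic matrix with self-loops set to each
node's maximum incident weight, inflation 1.5 (the default of the
canonical implementation), pruning at 1e-5, convergence when the largest
entry change drops below 1e-6. Clusters are connected components of the
limit matrix's non-zero structure; the iteration is fully deterministic.

**Supercluster detection.** Among clusters containing at least one
focal-species PPR, cluster size grows roughly linearly with species count
on a log2 scale; the RFL supercluster sits far above that trend. The
detector fits `log2(proteins) ~ species` by least squares and flags the
largest positive residual only if (a) it exceeds 3 standard deviations of
the *remaining* clusters' residuals and (b) the cluster is more than 3×
the second largest. The spread is estimated leaving the candidate out
because an extreme point otherwise masks itself: with $n$ points the
largest attainable z-score is $(n-1)/\sqrt{n}$, so an all-inclusive 3-sd
rule can never fire on fewer than ~12 clusters, however extreme the
outlier. Requiring both criteria keeps false flags off small cluster sets.

## Phylogeny and hotspot mapping

Distances are p-distances (mismatched fraction of aligned non-gap columns)
from global alignments. Trees are built by neighbor joining with a
deterministic tie-break (lexicographically smallest label pair among
Q-minimisers) and negative branch lengths clamped to zero. The distance
reduction is **variance-weighted** (BIONJ-style) by default: on exactly
additive matrices every reduction weight recovers the true topology, but on
noisy distance estimates the classic equal-weight reduction occasionally
misplaces a single leaf of a tight cluster — we observed exactly that on
synthetic arrays — while the variance-weighted reduction does not.
`method = "nj"` restores the classic behaviour. Distance trees stand in
for maximum-likelihood inference, which is out of scope; externally built
ML trees can be supplied as newick (`read_newick_tree()`, quoted
`species:protein_id` leaf labels).

Species-specific clades are extracted as **bipartitions** for unrooted
trees: a clade is a single-species side of an edge, i.e. monophyletic under
every rooting outside itself, reported at maximal extent. This avoids a
rooting artifact: a midpoint root can land *inside* a species cluster that
spans the tree diameter and split it in two. Rooted input trees are read
as given.

Clade members are mapped to loci and grouped by chromosome; groups of at
least `min_size` (default 3 — configurable, since real surveys report
regions down to 2 genes) become regions spanning min start to max end.
Region sizes print in kb rounded half-up, which reproduces the published
spans of, e.g., the rice chromosome 10 region (319.911 kb → 320) and the
barley chromosome 1 region (3,086.749 kb → 3,087) simultaneously.
`genome_fraction()` reports the summed span over the combined genome sizes
of contributing species, to 2 decimals.

Strand is carried through all locus tables but ignored by every
computation; coordinates are 1-based inclusive everywhere (GFF3
convention), with BED converted at the boundary.

## The synthetic-data generator

`simulate_multispecies()` emulates the two signals the pipeline exploits:

* **Background PPR families**: one ortholog per species, descended from a
  family ancestor. Family ancestors diverge from the bundled motif
  templates at `family_divergence`; species copies at `species_divergence`
  (default 0.05). Families span varying subsets of species (6 up to all),
  giving the cluster-size trend genuine spread for the outlier regression.
* **The RFL family**: present in all but one species (one lineage loses
  the family, as happens in real surveys), with one internal lineage per
  planted array. The focal species carries tandem arrays — by default 7, 8
  and 5 genes at fixed coordinates with 30 kb gaps — at low divergence
  (`array_divergence` 0.03) from their lineage ancestor, while other
  species carry a few older members per lineage (0.12). Three synthetic
  "known restorer" references are drawn from non-focal lineages.

Divergence is i.i.d. residue substitution only; an indel mode exists
(`indel_rate`) but is off by default so that oracle alignments stay
unambiguous. All randomness flows from one integer seed; a fixed seed
gives byte-identical output.

**What the defaults mean.** The default `family_divergence = 0.6` makes
different families effectively unrelated in sequence (~18% pairwise
identity), which is what lets the similarity graph separate them — at the
cost that the bundled PSSMs (built from near-template samples) no longer
detect their motifs. That is a real tension the generator cannot dissolve:
real PPR repeats are degenerate yet detectable by sensitive profile HMMs,
while paralogous families still diverge freely in sequence; a simple
consensus PSSM cannot model both at once. The validation suite therefore
uses two regimes: a *clean* regime (`family_divergence = 0`,
`species_divergence = 0`) for scan/classification recovery (100% subclass
accuracy noise-free, ≥95% at 5% residue noise), and the *diverged* default
regime for the RFL screen, orthologous clustering, supercluster detection
and hotspot mapping. Passing both says the stages are individually sound;
it does not say the bundled PSSMs would detect deeply diverged PPRs in
real proteomes — for real data, import HMMER hits built from curated
alignments.

Problem sizes used throughout the validation suite (14 species, 10
background families, a 56-member RFL family, 10 seeded replicates for the
supercluster and hotspot recoveries) were chosen so the complete suite
runs comfortably on a laptop-class single core.

## Numerical and design notes

* Alignment scores: the compiled score kernel and the full aligner agree
  exactly; both are checked against an exhaustive Gotoh DP oracle in the
  tests.
* The `X` residue scores 0 against everything in simple match/mismatch
  matrices; `*` scores as a mismatch everywhere (so stop-riddled
  translations never align well).
* `min_motifs = 2` for PPR status: a single repeat is not a tandem array;
  published surveys do not state their minimum.
* Percentages and kb spans round half-up; means report to 1 decimal.
* MCL non-convergence at `max_iter` returns the current clustering with a
  warning flag rather than failing.
* Empty summaries print `.` for undefined percentages, matching the `.`
  missing-value convention of all TSV reports.
* The pipeline's `focal_species` defaults to the species of the first
  input record; stages re-run on identical inputs and configuration are
  byte-identical (manifests record parameters and input checksums, never
  timestamps).

## Known limitations

* PSSM scanning under-detects diverged repeats (see above); the domtblout
  import path is the recommended route for real proteomes.
* The E-value approximation uses fixed Karlin–Altschul constants; weights
  are meaningful for ranking and thresholding, not as calibrated E-values.
* Pseudogene detection is a documented heuristic; real surveys rely on
  annotation evidence the package does not see.
* The generator does not plant pseudogenes, does not model codon-level
  evolution, and with default settings contains no indels — planted-order
  motif recovery and exact alignment oracles depend on that simplicity.
* Synteny analysis across species is out of scope.
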