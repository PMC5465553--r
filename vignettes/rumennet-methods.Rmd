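---
title: "Methods: host-microbiome metabolic network analysis with rumennet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-microbiome metabolic network analysis with rumennet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumennet)
```

## The problem

Shotgun metagenomes of the rumen describe a microbial community by the
enzymes it encodes rather than by the taxa it contains. `rumennet`
implements a reaction-centric view of such data: enzyme-catalyzed
reactions become nodes of a graph, two nodes are joined when their
reactions share a metabolite, and the microbial graph is coupled to the
host animal's metabolic network through *interface metabolites* —
compounds such as the volatile fatty acids (VFAs) that microbes
demonstrably hand over to their host. Translated sequencing reads are
assigned to nodes, and a set of statistical contrasts asks how a dietary
intervention (a forage-based versus a concentrate-based ration, `FORG` /
`CONC`) reshapes where in this network the community invests its coding
capacity.

## Reaction graphs and currency metabolites

A reaction database consists of metabolites (with carbon counts),
reactions (sets of metabolite ids) and enzyme sequences cross-referenced
to reactions. `build_graph()` merges reactions with identical metabolite
sets into a single node, connects nodes through shared metabolites and
drops nodes left without any edge. Ubiquitous compounds (water, ATP, ...)
would otherwise connect unrelated chemistry, so metabolites taking part in
at least `cutoff` reactions are classified as *currency* and form no
edges. Because there is no universal currency definition, analyses are run
at cutoffs of 25, 50 and 100 (`N25`, `N50`, `N100`); edges are nested
across these graphs, which the test suite asserts.

The host network is an input in the same schema. One pseudo-reaction,
butyrate to butyryl-CoA, is added programmatically
(`add_butyrate_pseudoreaction()`), representing the host's uptake of
microbially produced butyrate; its metabolites take part in currency
counting like any others, a choice we fixed once since the desk-scale
databases are nowhere near the cutoffs for those two compounds.

## The interface and network layers

Three interface sets are supported: `VFA` (acetate, propionate,
butyrate), `VFA_AA` (the VFAs plus the twenty universal amino acids,
23 compounds) and `ALL` (a caller-supplied list; the published 204-compound
absorbed-metabolite list is an input, not package data). An interface edge
joins every host/microbial node pair that both use a common interface
metabolite, evaluated on the full metabolite sets so that currency
exclusion never severs the interface.

Each node's *layer* is its hop count, through within-subnetwork edges, from
the interface frontier: interface-using nodes sit at layer 0 and distances
grow outward (`assign_layers()`). This frontier convention — rather than
counting the cross-network edge itself — is what makes read-weighted mean
layers below 1 possible for the broad interface sets, matching how the
study system is described. Nodes with no path to the frontier keep their
mapped reads for count statistics but are excluded from all layer
statistics. Layering is computed with unit-weight shortest paths and is
tested against an independent breadth-first flood on random merged
networks.

## Mapping translated reads to nodes

Paired 100 bp reads pass a quality gate: each mate is truncated at the
first run of three bases under phred 15 (the run itself is removed — the
conservative reading of "truncated after"), and the pair is dropped when
either mate has mean quality below 25 or fewer than 85 bases. Both mates
are translated in all six frames; maximal stop-free runs of at least 30
residues are the alignment candidates, and both mates must provide one.

Candidate ORFs are aligned to the enzyme database by seeded
Smith-Waterman: a hit requires two identical seven-residue words, more
than 80% amino-acid identity and an aligned span covering more than 80% of
the ORF. The substitution model is BLOSUM62 with affine gaps (open 11,
extend 1) — standard protein-search defaults, since only
identity/coverage, not raw score, feed the thresholds. Identity counts
gap columns as mismatches. The `>` thresholds are strict; `strict = FALSE`
switches to `>=`. The aligner is compiled code with a fixed, documented
traceback (first maximal cell scanning rows then columns; diagonal before
gap-in-subject before gap-in-query) so that an independent plain-R dynamic
program reproduces identity and coverage exactly in the tests.

Hits are resolved to nodes by reaction-set algebra: if all hit enzymes'
reaction sets are equal or totally ordered by inclusion the pair is
assigned to the minimal set (one node: `UNIQUE`; several: `MULTI`,
tallied separately and excluded from per-node counts); mates with no
common reaction are `discordant_pair`; incomparable sets are
`unrelated_multi`. All hits from all qualifying ORFs of a mate enter the
resolution. Per-sample summaries report node-hit pairs as a percentage of
valid-ORF pairs, to two decimals.

The mapper is validated with database-derived pseudo-reads: pairs of
30-residue windows separated by a 70-residue unsequenced insert, aligned
with their source enzyme excluded (`validate_mapping()`). The sweep over
identity thresholds records, besides mapped fractions and the
unique:multi ratio, both the count and the fraction of pairs assigned to
nodes sharing no reaction with the source. In a database with a
near-identical wrong-reaction twin and a more distant same-reaction family
member, raising the threshold silences the family member first, so
ambiguity stops being detected and the count of incorrect assignments
rises — the behavior that motivates the 80% operating point.

## Diet statistics

Counts are normalized to reads per node per 10^6 mapped reads
(`normalize_counts()`).

**Three-state read density.** Per diet, node read counts follow a mixture:
a point mass at zero (`p0`), a point mass at one read (`p1`), and a
log-normal truncated to (1, Inf) for nodes above one read.
`p0`/`p1` are empirical fractions; `meanlog`/`sdlog` come from numerical
maximum likelihood (Nelder-Mead on `(meanlog, log sdlog)`). The state
boundaries are `x == 0`, `0 < x <= 1` and `x > 1`, which coincides with
the integer reading (0, 1, >= 2 reads) while keeping the truncation point
and the fitted support consistent; parameter recovery across 50
simulations of 5000 nodes is part of the acceptance suite. Diets are
compared with `lrt_diets()`, twice the log-likelihood gain of separate
fits over a pooled fit. The default degrees of freedom are 4 — the free
parameters gained by splitting — with `df = 5` available to mirror the
published reporting convention, which we could not reconstruct from the
parameter count and therefore did not silently adopt.

**Per-node tests.** A two-sample Wilcoxon rank-sum test per node on
normalized counts with Benjamini-Hochberg correction at 5% FDR; with 8
vs 8 animals and no ties the smallest attainable two-sided P is 2/12870,
which the tests assert exactly.

**Randomization contrasts.** The read-weighted mean layer difference
between diets (`mean_layer_test()`) and read-weighted mean differences of
four node statistics — carbon sum, shortest-path-count betweenness,
degree, local clustering coefficient (`network_stat_contrast()`) — are
tested against a pooled-read null: every pooled read is independently
reassigned to a pseudo-FORG group with probability equal to the FORG share
of reads (a binomial split per node), 1000 times by default, with the
add-one P-value `(#{|null| >= |obs|} + 1) / (n + 1)`. Betweenness is the
raw count of all-pairs shortest paths through a node (the definition used
for the study's statistic), not the fractional Brandes variant. The
"weighted mean" is the read-weighted mean `sum(w s) / sum(w)` — the
average statistic experienced by a mapped read; `weighted_mean = FALSE`
selects the unnormalized mean of products for sensitivity.

This null models sampling noise only. Under animal-level overdispersion
the test is anti-conservative by construction; the calibration tests
therefore generate data with no diet effect, no inter-animal dispersion
and identical per-diet densities, and assert a 5% rejection rate within
binomial error at 200 datasets x 1000 randomizations.

**Presence/absence.** Nodes observed in either diet are classified as
shared or diet-exclusive; each exclusive node's reads are randomly
reassigned to animals in proportion to their mapped totals, and
exclusivity is scored at P < 0.01. A single pooled read can never be
significant under a balanced design.

**Variance contrast.** Per-node across-animal variances of normalized
counts are compared between diets with a paired Wilcoxon test, and the
comparison is repeated on depth-equalized datasets (100,000 reads drawn
per animal without replacement; animals with fewer reads are resampled
with replacement and flagged).

**VFA correlation.** Per animal, the fraction of uniquely mapped reads on
nodes using a given VFA is correlated with its measured ruminal
concentration (one-sided Spearman, the reporting convention for these
quantities); animals without measurements are dropped, and fewer than
five pairs is an error.

## Profile distances

Each animal's node (or OTU) counts are scaled to a Euclidean unit vector
(`profile_vector()`), so pairwise Euclidean distances lie in
[0, sqrt(2)] and reflect composition only. `reassignment_null()` pools
each diet's reads per node and multinomially redistributes them to the
diet's animals in proportion to their original mapped totals — conserving
per-diet reads exactly and per-animal totals in expectation (an exact
partition would fix the margins; the expected-conservation form is the
simpler model of "proportional" reassignment and is the default). The
per-replicate min/max within-diet distances bound what sampling noise can
produce; real distances exceeding every null max at 1000 replicates give
the add-one minimum P of about 0.001. `node_otu_correlation()` compares
the Pearson correlation of node and OTU distances over within-diet pairs
(all pairs optionally) with the same correlation in the jointly
reassigned nulls.

## Simulating a diet shift

For node counts `r_j`, the *compound vector* assigns each metabolite the
total reads on nodes whose reaction uses it; vectors are rescaled to sum
to 100,000. The pooled CONC vector is the *target*; each FORG animal's
counts are a start state. Simulated annealing searches for read-to-node
distributions whose scaled compound vector approaches the target under
two move rules: `swap1` moves one read from a count-proportional source
node to a uniform destination; `swap2` draws a source edge whose
endpoints both hold reads and an independent destination edge, moving one
read across each endpoint pair — a proxy for the genomic linkage of
enzymes. Destination nodes must themselves form an edge; requiring
source-destination adjacency has no support in the construction and was
rejected.

The objective is the Euclidean distance between scaled compound vectors
(cosine distance would be the natural alternative; Euclidean was fixed
once as the plain reading of "near in vector space"). Acceptance is
Metropolis, `exp(-delta/T)`, under geometric cooling `T_k = T0 *
alpha^k` (defaults `T0 = 1`, `alpha = 0.9995`; the published procedure
does not state a schedule). Ten restarts per start state use sub-seeds
derived deterministically from one master seed, and the chain whose
best-ever state is closest to the target is retained — "best-ever" rather
than "final" so that late uphill wandering cannot discard a solution.
Reads are indivisible tokens; totals are conserved exactly along every
chain.

The chain maintains its objective through the sufficient statistics
`sum(v^2)`, `sum(v t)` and `sum(v)`, making a move O(metabolites
touched). These large near-cancelling sums carry ~1e-3 absolute error on
the 1e5 scale — harmless for move decisions — so all reported distances
are recomputed exactly from the final state. On three-node instances with
up to eight reads, `swap1` annealing attains the brute-force optimum over
all distributions, for every start state.

## The synthetic study

`scenario_config()` fixes the conditions the analyses are exercised
under: 8 + 8 animals, 50,000 mapped reads each (20,000 in the compact
test scenario), a 300-metabolite / 400-reaction microbial database with a
graded currency tier so all three cutoffs bite, a 60-reaction host
network, and interface metabolites used by both sides. Node read
densities follow the three-state mixture with diet-specific parameters
(`meanlog` 3.7 vs 3.99, `sdlog` 1.70 vs 1.64 — the concentrate diet
denser per node with less spread, matching the study's direction); the
CONC diet's intensities are additionally tilted toward low-layer nodes by
`exp(-layer_bias * layer)` with `layer_bias = 0.5`, its animals get
larger log-normal dispersion (0.6 vs 0.2), and three CONC animals share a
degenerate profile in which five spike nodes absorb 70% of the intensity —
the "high-RFI-like" animals. Reads for the mapper are drawn from
back-translated enzyme sequences (uniform synonymous codons) as 100 bp
mates on fragments of length ~Normal(309, 30), with a configurable
substitution rate (default 0) and constant phred-40 qualities.

What passing tests show: the implementation detects effects it plants, at
the directions and significance the published analysis reports, and its
numerical components agree with independent oracles. What they do not
show: real rumen data have correlated enzyme families, uneven codon
usage, sequencing error structure, and animal-level covariance that the
generator does not emulate; absolute published quantities (mean layers,
reads per node, node counts) derive from the real sequencing project and
are not reproducible at desk scale.

## Problem sizes and determinism

The test suite runs the statistics on 400-node networks with 16 animals
at 20,000 reads per animal, read mapping on databases of 50-70 enzymes
with a few hundred read pairs, calibration on 200 datasets of 120
reactions at 3,000 reads per animal, and annealing oracles on 3-node
instances — sizes chosen so the whole suite is a desk-scale experiment.
Every stochastic operation takes an explicit seed; nested steps derive
31-bit sub-seeds deterministically, so a scenario plus one integer
regenerates identical datasets, and `run_pipeline()` writes a manifest
with checksums of everything it produced.

## Known limitations

- The randomization nulls model read-sampling noise only (see above);
  they answer "could sampling alone do this", not "do animals differ".
- Host-genome contamination screening is a pass-through count from sample
  metadata; nucleotide-space alignment is out of scope.
- `MULTI` pairs are tallied but not used downstream, mirroring the
  separate reporting column; no fractional assignment is attempted.
- The aligner's tie-breaks among co-optimal alignments are fixed by
  convention; a different convention could report slightly different
  identities for the same optimal score.
- OTU calling, orthology inference of the host network, flux modeling and
  ordination graphics are outside the package's scope.
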