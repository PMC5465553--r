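# rumennet

Reaction-centric metabolic network analysis of rumen shotgun metagenomes.

Microbial communities can look very different taxonomically while doing
nearly the same chemistry. `rumennet` analyzes a metagenome at the level
of the reactions its enzymes catalyze: reactions are graph nodes, edges
are shared metabolites (with ubiquitous "currency" metabolites excluded at
configurable occurrence cutoffs N<sub>25</sub>/N<sub>50</sub>/N<sub>100</sub>),
and the microbial graph is joined to the host animal's metabolic network
through *interface metabolites* — the volatile fatty acids (VFAs), the
amino acids, or a broader absorbed-compound list. Every node gets a
*layer*: its hop distance from the host-microbe interface (interface users
= layer 0). Translated paired-end reads are mapped onto nodes, and the
package asks how a diet contrast (forage `FORG` vs concentrate `CONC`)
moves the community's coding investment around this layered network.

The package is aimed at microbiome researchers who want a tested,
end-to-end reimplementation of this analysis style that runs at desk
scale on synthetic data with the same statistical structure as a two-diet
feeding trial.

## What it implements

- **Reaction database** (`load_database`, `currency_metabolites`,
  `add_butyrate_pseudoreaction`): TSV/FASTA dialect with full referential
  validation; the host network receives a butyrate → butyryl-CoA
  pseudo-reaction.
- **Network construction** (`build_graph`, `make_interface_set`,
  `merge_networks`, `assign_layers`): identical-metabolite-set reactions
  merged, currency-filtered edges, interface edges that bypass currency
  exclusion, multi-source shortest-path layering.
- **Read mapping** (`map_sample`, `align_orf`, `generate_pseudo_reads`,
  `validate_mapping`): quality truncation, six-frame ORFs (≥ 30
  residues, both mates), seeded Smith–Waterman (two shared 7-mers,
  > 80% identity, > 80% ORF coverage; BLOSUM62, affine gaps 11/1, Rcpp),
  reaction-set multi-hit resolution, and pseudo-read validation with the
  source sequence held out.
- **Diet statistics** (`fit_three_state`, `lrt_diets`, `per_node_tests`,
  `mean_layer_test`, `network_stat_contrast`, `layer_correlation`,
  `presence_absence`, `variance_contrast`, `vfa_correlation`): the
  zero/one/log-normal read-density mixture with a likelihood-ratio diet
  test, per-node Wilcoxon tests at 5% FDR, and read-randomization nulls
  for layer and network-statistic contrasts (carbon sum, path-count
  betweenness, degree, clustering).
- **Profile distances** (`profile_vector`, `pairwise_distances`,
  `reassignment_null`, `node_otu_correlation`): unit-vector profiles
  `v_i = r_i / sqrt(sum_j r_j^2)`, Euclidean distances, a proportional
  read-reassignment null, and the node-vs-OTU distance correlation.
- **Diet-shift simulation** (`compound_vector`, `scale_vector`,
  `make_target`, `anneal`, `diet_shift_experiment`): metabolite-indexed
  compound vectors scaled to 100,000; simulated annealing over
  read-to-node assignments (unconstrained `swap1` or edge-paired `swap2`
  moves, Metropolis acceptance, geometric cooling, best of ten restarts).
- **Synthetic data** (`scenario_config`, `gen_reaction_db`,
  `gen_count_matrix`, `gen_reads`): a fully seeded generator for the
  database pair, two-diet count matrices (diet-specific densities, a
  configurable shift of concentrate reads toward low layers, higher
  concentrate dispersion, three degenerate animals), an OTU table and
  paired FASTQ with a truth table.
- **Pipeline** (`run_pipeline`): the cutoff × interface grid end to end,
  with a checksum manifest.

## Worked example

```r
library(rumennet)

cfg <- scenario_config(reads_per_animal = 20000, seed = 7)
dbs <- gen_reaction_db(cfg)
gm  <- build_graph(dbs$microbial, cutoff = 50)
gh  <- build_graph(dbs$host, cutoff = 50)
net <- merge_networks(gh, gm,
                      make_interface_set("VFA_AA", dbs$host, dbs$microbial))
gm
#> <metabolic_graph: microbial> 400 nodes, 3207 edges (currency cutoff 50, 14 currency metabolites)
net
#> <merged_network: VFA_AA> 60 host + 400 microbial nodes, 210 interface edges; layers 0-2 (0 unreachable)

gen <- gen_count_matrix(dbs$microbial, net, cfg)
res <- mean_layer_test(gen$cm, net$layer, n_rand = 1000, seed = 1)
res
#> <randomization_result> observed=0.2923 max|null|=0.008242 P=0.000999 (n_rand=1000)
```

The observed statistic is the read-weighted mean layer of the forage
animals minus that of the concentrate animals: +0.29 means the average
forage read sits about a third of a layer further from the host interface
than the average concentrate read — the direction the configured
concentrate low-layer bias plants. The largest difference any of the 1000
read randomizations produced is 0.008, some 35× smaller, so the add-one
P-value is at its floor of 1/1001: sampling noise cannot explain the
shift.

```r
nc    <- normalize_counts(gen$cm)
tests <- per_node_tests(nc)
sum(tests$significant)
#> 11                     # nodes differentially abundant at 5% FDR (of 275 tested)

fit_three_state(rowSums(gen$cm$counts[, gen$cm$diet == "FORG"]))
#> <three_state_fit> p0=0.315 p1=0.000 meanlog=4.861 sdlog=1.925 loglik=-2150.87 (n=400)
```

The mixture fit says 31.5% of nodes drew no forage reads and the read
mass on the remaining nodes is log-normal with `meanlog` 4.86 on the
pooled-count scale.

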