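# otunet

Microbial communities along strong environmental gradients reorganise: some
taxa persist and keep their interaction partners, others are replaced by
ecologically equivalent taxa. `otunet` provides the full analysis chain for
asking that question with 16S OTU tables from a replicated transect design:

1. **Co-occurrence network inference** per gradient section — a
   four-measure ensemble (Pearson, Spearman, Bray–Curtis, symmetrised
   Kullback–Leibler) over OTU and abiotic-variable profiles, candidate
   edges consistent across all four measures, and a ReBoot-style edge test:
   permutation nulls with per-sample compositional renormalisation plus a
   bootstrap stability interval, merged by Brown's method and BH-corrected
   (q < 0.05).
2. **Topological network alignment** — per-node graphlet degree vectors
   (automorphism orbit counts of connected induced subgraphs on 2–4 nodes,
   counted in C++), node scores
   `alpha * seqsim + (1 - alpha) * toposim` (alpha = 1: 16S identity only;
   alpha = 0: topology only), a deterministic greedy seed-and-extend
   optimiser with a conserved-edge bonus, and alignment quality as edge
   correctness `EC = 100·C/|E_source|` and symmetric substructure
   `SS = 100·C/(|E_source| + |E_image| − C)`, scanned over alpha.
3. **Core community analysis** — core/noncore decomposition of the two
   networks, aligned-to-self core OTUs, hub/abundance/environment flags,
   and FAPROTAX-style rule-based functional profiles with ANOVA/t-test
   group comparisons (e.g. nitrogen fixation in core vs noncore OTUs).
4. **A synthetic transect generator** with planted ground truth (true
   signed edges, core set, role-swap map, function labels) so every stage
   is validated by recovery experiments — no external downloads needed.

## Worked example

```r
library(otunet)

# simulate a transect community with planted truth (8 sites x 3 replicates)
dat <- simulate_dataset(simulation_config(n_otus = 150, seed = 7))

# infer the section-1 network
s1  <- filter_min_samples(section_slice(dat$otu, 1), 5)
ab  <- abiotic_table(dat$abiotic$values[, colnames(s1$counts)])
net <- build_network(s1, ab, n_perm = 200, seed = 11)
network_stats(net)$n_edges
#> [1] 440
edge_recovery(net, dat$truth, 1)$f1
#> [1] 0.7362146

# align the two planted section networks on topology alone
aln <- align_networks(truth_network(dat$truth, 1),
                      truth_network(dat$truth, 2), alpha = 0)
aln
#> alignment_result: alpha 0.00, 104 pairs, EC 100.00%, SS 100.00%
swap_recovery(aln, dat$truth)$fraction
#> [1] 1
```

`network_stats(net)$n_edges` is the number of signed edges surviving the
ensemble test; `edge_recovery(...)$f1` compares them with the planted truth
(0.74 here: most planted associations are recovered with few false
positives at 12 samples per section). The alignment maps every node of the
smaller planted network onto the larger one conserving 100% of its edges,
and `swap_recovery` confirms that all section-exclusive role-swap pairs are
matched from topology alone.

The full pipeline (simulate → filter → two networks → alpha scan → core and
function report) is one call:

```r
report <- run_pipeline(list(seed = 42, out_dir = "run1", simulate = TRUE,
                            sim = list(n_otus = 100), n_perm = 200))
```

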