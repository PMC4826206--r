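# SNFmods

Integrative multi-omics patient subtyping and altered-network module
detection for cancer cohorts.

Tumour cohorts are heterogeneous: patients that look alike in one data type
(say, mRNA expression) may differ in another (miRNA expression or copy
number), and clinically meaningful subtypes only emerge when the data types
are analysed together. `SNFmods` implements, as a tested and reusable R
pipeline, an integrative analysis for this problem:

1. **Similarity network fusion (SNF).** Each omics view is turned into a
   patient similarity network with a scaled exponential kernel,
   `W(i,j) = exp(-d(i,j)^2 / (mu * eps_ij))`, where `eps_ij` averages the
   local k-nearest-neighbour distance scales of both patients. Each view's
   full transition kernel `P` (rows sum to 1, diagonal 1/2) and sparse
   k-nearest-neighbour kernel `S` then drive the cross-diffusion
   `P^(v) <- S^(v) (mean of the other views' P) S^(v)T`, iterated with
   re-symmetrisation and renormalisation; the fused network is the mean of
   the final status matrices.
2. **Subtype discovery.** Spectral clustering of the fused network via the
   normalized Laplacian `L = I - D^{-1/2} W D^{-1/2}` (bottom-`C`
   eigenvectors, row-normalised, k-means with restarts). The number of
   subtypes is chosen from a candidate range by the minimal log-rank
   p-value across the induced survival groups.
3. **Alteration scoring.** GISTIC-style gene-level copy-number calls are
   binarized (only homozygous deletions and high amplifications count) and
   scored per subtype with sample-weighted frequencies
   `C_i = sum_j x_ij / (sum_i x_ij)`, normalised to `p0_i = C_i / sum C_i`;
   genes with `p0 >= tau` form the subtype's altered set.
4. **Module detection.** On a curated gene-gene interaction network, the
   altered genes plus statistically enriched *linker* genes (hypergeometric
   test, Benjamini-Hochberg) form a subtype network that is partitioned by
   greedy Newman-modularity agglomeration with deterministic refinement.
   Significance comes from two null models: degree-preserving edge
   rewiring (reported as *scaled modularity*, a null z-score) and random
   gene sets of equal size (global connectivity null).
5. **Downstream characterisation.** Between-subtype differential features
   by Wilcoxon rank-sum with fold-change filtering, miRNA target lookup
   against an evidence-tier table, and per-gene copy-number-vs-expression
   ANOVA.

A synthetic-cohort module (`simulate_cohort`, `simulate_survival`,
`simulate_network_alterations`) generates data with planted subtypes,
subtype-dependent exponential survival and planted network modules, so
every stage has a ground-truth recovery test.

## Worked example

```r
library(SNFmods)

co   <- simulate_cohort(n_patients = 200, n_subtypes = 2, effect_size = 2, seed = 1)
surv <- simulate_survival(co$truth$labels, hazards = c(0.003, 0.001),
                          censor_rate = 0.2, seed = 2)
fit  <- snf_subtype(co$views, surv, c_range = 2:5, seed = 1)
summary(fit)
#> Integrative subtype model (similarity network fusion)
#>   patients: 200   views: 2   subtypes: 2
#>   log-rank: chi-square 38.092 on 1 df, p = 6.75e-10
#>
#> Subtype sizes:
#> subtype
#>   1   2
#> 100 100
#>
#> Survival-guided selection (log-rank per candidate count):
#>  n_clusters    chisq      p_value
#>           2 38.09207 6.748388e-10
#>           3 39.59122 2.528579e-09
#>           4 39.62019 1.282500e-08
#>           5 40.62167 3.218973e-08
```

The fit recovered the two planted 100-patient subtypes; `C = 2` wins the
survival-guided selection (its log-rank p-value, 6.7e-10, is the smallest).
`plot(fit)` draws the two Kaplan-Meier curves. Continuing to the network
stage with the planted alteration data:

```r
na      <- simulate_network_alterations(co$truth$labels, seed = 3)
labels  <- subtype_labels(fit)
scores  <- gene_alteration_scores(na$alterations, names(labels)[labels == 1])
altered <- filter_altered_genes(scores, tau = 0.01)
sn      <- build_subtype_network(na$network, altered, alpha = 0.05)
dm      <- detect_modules(sn)
dm
#> Module partition: 2 modules over 28 genes, Q = 0.4818
null <- local_null_modularity(sn, n_iter = 1000, seed = 4)
scaled_modularity(dm$q, null)
#> [1] 11.8
```

The 24 genes passing the score threshold (the two planted 12-gene modules)
plus their admitted linkers split into 2 modules whose modularity sits
about 12 null standard deviations above degree-preserving rewirings — the
planted modules are recovered and are far more cohesive than chance.

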