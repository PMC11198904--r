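# lncregnet

Quantifying how much gene-expression variation long non-coding RNAs (lncRNAs)
can explain, and inferring a conservative, multi-evidence lncRNA→gene
regulatory network from cohort-scale RNA-seq counts.

Co-expression between a lncRNA and an mRNA is weak evidence of regulation —
most of it reflects shared transcription-factor (TF) regulators. This package
implements a pipeline for researchers in regulatory genomics that:

1. preprocesses raw counts (CPM > 1 in ≥ 41% of samples, TMM normalization,
   log2(CPM+1), per-gene standardization, covariate residualization);
2. models each target gene's expression as a sparse linear combination of
   **~10 ElasticNet-selected regulators refit by OLS**, scored by 5-fold
   cross-validated test R² (selection re-run inside every training fold);
3. treats TFs as confounders: each target is first modeled with TFs, the
   TF-model prediction is subtracted, and lncRNA models are fit to the
   residual, so lncRNA-attributable R² excludes TF-explainable variance;
4. converts R² into **empirical p-values** against nulls built from random
   control regulator sets (enzyme-encoding mRNAs; 100 replicates, resolution
   0.01) and from target permutations;
5. restricts candidate regulators by genomic mechanism — overlapping,
   same-TAD, proximal (< 1 Mbp), same-chromosome — and by a competing
   endogenous RNA (ceRNA) criterion (shared miRNA in the same cell line);
6. detects lncRNA×TF and lncRNA×RBP **statistical interactions** by forward
   Step-AIC selection of product terms, Bonferroni correction, and a
   median-split HH/HL/LH/LL contrast filter;
7. assembles an evidence-gated network: edges require a significant OLS
   coefficient (p ≤ 0.01) *and* at least one mechanism flag, with targets
   retained only when the joint refit reaches R² ≥ 0.2; summaries include
   degrees, activating/inhibitory sign bias and a co-expression baseline.

A seeded synthetic-data generator (`sim_config()` / `simulate_bundle()`)
produces genomes, planted regulatory ground truth (including the TF-driven
confounding the pipeline must remove) and negative-binomial counts, so the
entire pipeline is testable end to end without any external download.

## Worked example

```r
library(lncregnet)

# 320-gene synthetic cohort; lncRNAs keep one TF parent at 0.5 SD so the
# planted 1-SD direct effects sit above the published retention gates
cfg <- sim_config(n_samples = 300, n_tf_per_lnc = 1, beta_tf_lnc = 0.5, seed = 1)
bundle <- simulate_bundle(cfg)
bundle <- c(bundle, list(mirna_gene = bundle$truth$mirna_gene,
                         mirna_lnc = bundle$truth$mirna_lnc))
res <- run_pipeline(bundle, analysis_config(seed = 1))
s <- network_summary(res$network)
cat(sprintf("%d edges, %d lncRNAs, %d targets; %.1f targets/lncRNA\n",
            s$n_edges, s$n_lncrnas, s$n_targets, s$mean_out_degree_1dp))
truth <- paste(bundle$truth$lnc_edges$lncrna_id, bundle$truth$lnc_edges$gene_id)
got <- paste(res$network$edges$lncrna_id, res$network$edges$target_id)
cat(sprintf("precision %.2f, recall %.2f vs planted truth\n",
            mean(got %in% truth), mean(truth %in% got)))
```

prints

```
16 edges, 16 lncRNAs, 16 targets; 1.0 targets/lncRNA
precision 1.00, recall 0.67 vs planted truth
```

i.e. on this synthetic cohort the evidence-gated network recovers 16 of the
24 planted lncRNA→gene edges with no false edges (the misses are trans edges
that carry no mechanism evidence, plus targets below the R² ≥ 0.2 retention
gate).

The numbered scripts under `analysis/` run the same pipeline as a narrative
workflow (simulate → preprocess → models and nulls → categories and
interactions → network → benchmarks), printing what each stage found and
writing tables under `results/`.

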