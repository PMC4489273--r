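# mirtfnet

Construction and analysis of disease-specific transcription-factor (TF) /
microRNA (miRNA) co-regulatory networks in R.

Transcription factors and miRNAs jointly control gene expression through
four typed interactions — TF→gene, TF→miRNA, miRNA→gene, miRNA→miRNA —
and their interplay is frequently organized in feed-forward loops (FFLs).
Given user-supplied interaction tables (with `validated` / `predicted`
evidence tags) and lists of deregulated genes and miRNAs from a disease
study, `mirtfnet`:

1. **builds the combined co-regulatory network** of the deregulated
   molecules (an edge is kept iff both endpoints are deregulated), or, when
   only genes are available, first **infers the deregulated miRNAs** —
   miRNAs whose target genes *and* regulator TFs are both hypergeometrically
   enriched in the gene list (BH-adjusted, cutoff 0.001);
2. **extracts the disease-specific subnetwork** (edges with ≥ 1
   disease-associated endpoint) and reports node/edge coverage ratios
   *C<sub>R</sub> = N<sub>d</sub> / N<sub>t</sub>*;
3. **identifies key network players** by the top 10% of degree, closeness,
   betweenness and eigenvector centrality (union and intersection sets) and
   by an exact **minimum dominating set**:
   min Σ X(i) s.t. ∀i Σ<sub>j</sub> adj(i,j)·X(j) ≥ 1;
4. **detects TF–miRNA–gene FFL motifs**: significant co-regulating pairs by
   the hypergeometric tail on shared-target counts
   (P = P(X ≥ x) with k = miRNA targets, N = TF targets, M = target-gene
   universe; BH < 0.05), each shared target classified exclusively as
   co-regulation / TF-FFL / miRNA-FFL / composite FFL, with significance
   from 100 degree-preserving edge-swap randomizations
   (Z = (N<sub>o</sub> − N<sub>m</sub>)/σ, empirical
   P = N<sub>h</sub>/N<sub>r</sub>);
5. **tests functional homogeneity** of a pair's co-regulated genes against
   a 1000-fold permutation null with a one-sided Kolmogorov–Smirnov test,
   using Jaccard or information-content-weighted Jaccard similarity over
   annotation term sets (or any plug-in measure);
6. ships a **synthetic-data generator** with planted motifs, planted
   enriched miRNAs and planted functional modules, so the whole pipeline is
   testable without any external database.

See `vignettes/coregulatory-network-analysis.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(mirtfnet)

st  <- generate_study(synth_config(seed = 1))   # synthetic disease study
res <- coreg_analysis(st$db, st$dereg$genes, st$dereg$mirnas,
                      assoc = st$assoc, n_random_motifs = 100, seed = 1)
summary(res)
```

```
TF-miRNA co-regulatory network analysis
  input: 180 deregulated genes/TFs, 16 deregulated miRNAs
  combined network: 172 nodes, 372 edges
  disease network: 151 nodes, 258 edges (node CR 87.8%, edge CR 69.4%)
  motifs: 80 instances ( coreg_FFL=20, TF_FFL=20, miRNA_FFL=20, composite_FFL=20 )
  key nodes: union 28, common 8, dominating set 23

Motif significance (100 random networks)
    motif_type N_o  N_m sigma zscore N_h N_r empirical_p empirical_p_smoothed
     coreg_FFL  20 9.31 2.970    3.6   0 100           0               0.0099
        TF_FFL  20 0.07 0.293   68.0   0 100           0               0.0099
     miRNA_FFL  20 0.40 0.888   22.1   0 100           0               0.0099
 composite_FFL  20 0.01 0.100  199.9   0 100           0               0.0099
```

Reading this: of the 372 interactions among the deregulated molecules, 258
touch a disease-associated node (edge coverage 69.4%); each planted motif
class is recovered with 20 instances (2 pairs × 10 shared targets), far
above its degree-preserving random expectation N_m, hence the large
positive Z-scores and empirical P = 0/100; and 28 nodes make up the union
of the four centrality top-10% sets, while 23 nodes suffice to dominate
the disease network.  `write_reports(res, "out/")` emits all tables, the
networks (edge TSV + GraphML) and a run manifest.

A file-based front end with the same capabilities is installed at
`inst/cli/mirtfnet` (subcommands `simulate`, `build`, `keynodes`,
`motifs`, `homogeneity`, `run-all`).

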