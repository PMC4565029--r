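# licornr

Cooperative transcription-factor network inference from gene expression
data, in R.

Mammalian gene regulation is combinatorial: target genes are driven by
coordinated sets of transcription factors (TFs) rather than single
regulators. `licornr` reconstructs, from a genes-by-samples expression
matrix and a list of TF identifiers, a network of **regulatory programs** —
for each target gene a set of co-activators A(g) and a disjoint set of
co-repressors R(g) — and then analyzes the network at three levels:

- **h-Licorn inference.** Expression is ternarized per gene
  (−1 / 0 / +1 by z-score at ±1 population sd).  Candidate co-regulator
  sets are mined as frequent itemsets over two transaction encodings of
  the TF codes (samples where all members are +1, and where all are −1,
  the unanimity *collective state*).  Candidate programs (A, R) are scored
  by the mean absolute error between the observed target code and the
  ternary truth-table prediction

  |            | r = −1 | r = 0 | r = +1 |
  |------------|--------|-------|--------|
  | **a = +1** | +1     | +1    | 0      |
  | **a = 0**  | +1     | 0     | −1     |
  | **a = −1** | 0      | −1    | −1     |

  and the best candidates are re-scored continuously ("hybrid" step) by
  OLS of the centered target on ā (mean activator expression) and r̄
  (mean repressor expression); programs need coef(ā) ≥ 0 and coef(r̄) ≤ 0,
  and the sign-valid candidate with maximal adjusted R² is chosen.
- **Evidence refinement.** External TF→gene evidence (ChIP, binding
  sites) and TF–TF evidence (protein interactions) re-select, per gene,
  the candidate maximizing `w_fit · normalized-fit-rank + Σ_d w_d ·
  support_d` — evidence selects among inferred candidates, never adds
  edges.
- **TF influence.** Per sample, a Welch statistic comparing the centered
  expression of a TF's activated vs repressed targets,
  `(m_a − m_r) / sqrt(v_a/n_a + v_r/n_r)` — a proxy for the TF's
  protein-level activity in that sample.
- **Co-regulation network.** TF pairs sharing same-set targets are tested
  with a one-sided hypergeometric (Fisher) test and
  Benjamini–Hochberg-adjusted; `q ≤ alpha` pairs form the cooperative
  network, exportable as SIF for Cytoscape-class viewers.

A synthetic benchmark generator (linear-Gaussian gene model over i.i.d.
normal TF profiles, with a pair-reuse mechanism that plants cooperative
TF pairs) plus precision–recall scoring make every stage verifiable
without external data.

## Worked example

Simulate a benchmark dataset (20 TFs, 200 genes, 100 samples, effect
size 1, Gaussian noise sd 0.25), infer the network and analyze it
(about 20 s):

```r
library(licornr)
ds  <- generate_synthetic(synthetic_spec())
net <- hlicorn(ds$expr, ds$tfs, targets = setdiff(rownames(ds$expr), ds$tfs),
               min_coreg_support = 0.02, max_coreg = 2)
net
#> tf_network: 200 target programs, 20 regulators, 568 signed edges
#>   candidate lists retained (19869 candidates )
head(net$programs[, 1:5], 3)
#>   target activators repressors  mae    r2_adj
#> 1   G001  TF06;TF14       TF15 0.21 0.9687965
#> 2   G002  TF05;TF15  TF04;TF13 0.25 0.8971057
#> 3   G003       TF10  TF08;TF13 0.09 0.9394106
```

Each program reads: G001 is activated by the cooperative pair
TF06+TF14 and repressed by TF15; its truth-table prediction misses the
observed ternary code by 0.21 on average and the linear model explains
97% of its variance. Sample-specific TF activity and the cooperative
pair ranking:

```r
infl <- influence_matrix(net, ds$expr)
round(infl[1:3, 1:4], 3)
#>        S001   S002   S003   S004
#> TF01 -3.263  3.470 -0.723  7.962
#> TF02  0.271  3.331 -2.670 -0.538
#> TF03 -2.706 -0.849  0.969  0.585
coop <- build_coregulation_network(net)
head(coop$tested[order(coop$tested$p),
                 c("tf1", "tf2", "n_shared", "n1", "n2", "p")], 4)
#>     tf1  tf2 n_shared n1 n2     p
#> 56 TF05 TF15        6 25 35 0.255
#> 87 TF17 TF19        4 22 27 0.343
#> 47 TF06 TF14        4 26 27 0.479
#> 93 TF09 TF20        6 40 28 0.505
```

Positive influence means the TF's activated targets sit above its
repressed targets in that sample (TF01 is strongly active in S004).
The four best-ranked TF pairs are all planted cooperative pairs of the
simulation; note that with only 200 targets and dense regulons the
conservative hypergeometric test ranks pairs well but rarely reaches
FDR significance — on transcriptome-scale data the same counts become
strongly significant.  Recovery against the ground truth:

```r
rec <- score_recovery(net, ds$truth, ds$coop_pairs)
#> signed-edge AUPR 0.618 (prevalence 0.049)
#> cooperative-pair AUPR 0.505 (prevalence 0.132)
influence_robustness(ds$truth, ds$expr, seed = 1)$summary
#>     level mean_cor
#> 0     0.0    1.000
#> 0.1   0.1    0.952
#> 0.2   0.2    0.917
#> 0.3   0.3    0.877
#> 0.5   0.5    0.753
```

The influence statistic stays highly correlated with its value on the
unperturbed network (92% at 20% edge rewiring) and degrades gracefully.

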