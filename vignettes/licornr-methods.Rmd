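---
title: "Methods: cooperative TF network inference with licornr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperative TF network inference with licornr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`licornr` reconstructs cooperative transcription-factor (TF) networks
from expression data and derives sample-specific regulator activities
and a statistically supported co-regulation network from them. This
vignette documents the model, the tunable parameters, the numerical
choices, and what the synthetic benchmark does and does not establish.

## The regulatory program model

For each target gene $g$ the model is a *regulatory program*: a set of
co-activators $A(g)$ and a disjoint set of co-repressors $R(g)$ acting
jointly. Inference is hybrid (hence "h-Licorn"): a discrete,
combinatorial search proposes candidate programs, and a continuous
linear re-scoring ranks and selects them.

### Ternary discretization

Each gene row is z-scored with the population standard deviation
(normalized by $n$) around a per-gene center (mean by default; median
and no centering are available) and coded $+1$ (over-expressed) when
$z \ge$ `threshold_sd`, $-1$ when $z \le -$`threshold_sd`, else $0$.
The default `threshold_sd = 1` is symmetric, keeping the $+1$ and $-1$
classes balanced (about 16% of samples each under normality), which the
downstream search assumes. Zero-variance rows code to all zeros. Genes
with fewer than `ceiling(min_gene_support * n_samples)` non-zero codes
(default `min_gene_support = 0.1`) are uninformative for a discrete
search and are excluded from inference. The scheme is intentionally a
small, replaceable policy: anything producing a genes-by-samples matrix
over $\{-1, 0, +1\}$ can be substituted.

### Collective states and the truth table

A TF set is *collectively* $+1$ in a sample only if **all** members are
$+1$ (unanimity), collectively $-1$ only if all are $-1$, else $0$; the
empty set is neutral. Given collective activator state $a$ and
repressor state $r$, the predicted target code is $\mathrm{sign}(a-r)$,
i.e. the table printed in the README: antisymmetric
($f(a,r) = -f(-a,-r)$), monotone non-decreasing in $a$ and
non-increasing in $r$, and reducing to "follow the activators" /
"oppose the repressors" when the other set is neutral. The discrete fit
of a program is the mean absolute error (MAE) between prediction and
observed code over samples, which lives in $[0, 2]$.

### Mining candidate co-regulator sets

Candidate sets come from level-wise (Apriori) frequent-itemset mining
over two transaction encodings of the discretized TF matrix: samples as
transactions with items "TF coded $+1$" (joint over-expression) and
separately "TF coded $-1$". Sets up to `max_coreg` TFs (default 3) with
support at least `min_coreg_support` (default 0.1) in either context are
retained, together with their supporting samples in both contexts.
Support is monotone under subsets, so the stored family is
subset-closed per context. Setting `min_coreg_support = 0` disables the
filter and enumerates every set up to `max_coreg` — the package's
exhaustive-search mode, used to validate the optimizer against brute
force (below); for the same reason `search_thresh = 0` disables the
coherence filter. The default support of 0.1 is calibrated to real
transcriptomes, where co-regulating TFs are themselves co-expressed;
for data with independent TF profiles a lower support (a floor of a few
samples) is appropriate, because two independent TFs are jointly beyond
$\pm 1$ sd in only a few percent of samples.

### The coherence rule

A mined set qualifies as a candidate *activator* set for gene $g$ when,
among the samples where the set is collectively $+1$, at least a
fraction `search_thresh` (default 1/3) show $g$ at $+1$, and among the
samples where it is collectively $-1$ at least `search_thresh` show $g$
at $-1$; candidate *repressor* sets satisfy the mirrored rule. A
condition over an empty support holds vacuously. The inclusion is
deliberately measured on the **set side** ("when the set is on, the
gene responds"): under unanimity, the joint $\pm 1$ support of a set
shrinks geometrically with its size, so requiring the set to *cover* a
fixed fraction of the gene's $\pm 1$ samples would make multi-TF
candidates unreachable on weakly co-expressed regulators, defeating the
cooperative search; the set-side direction also discriminates better,
since an unrelated TF's $+1$ samples show the gene at $+1$ at only the
base rate. The gene itself is excluded from all its candidate sets, as
are (A, R) pairs with overlapping sets — TFs may regulate TFs, but
never themselves.

### Continuous re-scoring and selection

Per gene, all admissible (A, R) pairs are ranked by discrete MAE (ties:
smaller $|A|+|R|$, then lexicographic on the sorted regulator
identifiers) and the best `n_grn` (default 100) are re-scored by
ordinary least squares of the row-centered target on
$\bar a$ (mean centered expression of $A$) and $\bar r$ (mean of $R$),
with intercept. A program is rejected when the activator coefficient is
negative, the repressor coefficient positive, the two regressors nearly
collinear ($|\rho| > 0.999$), or a regressor is constant. The chosen
program maximizes the adjusted $R^2$ among sign-valid candidates (ties:
MAE, size, lexicographic key); genes with no valid program are dropped
with a message. Candidate lists are retained on the network object for
evidence-based refinement. The whole pipeline is deterministic:
identical inputs and parameters give identical networks.

Numerical choices: scores are compared after rounding to $10^{-12}$, so
tie-breaking does not depend on the order of floating-point operations;
the $[0,2]$ MAE values are exact multiples of $1/n$ and compare
exactly. On instances small enough to enumerate (a handful of TFs,
`max_coreg` 2), running `hlicorn()` with both filters disabled
reproduces, gene by gene, the program found by exhaustive enumeration
under the same scoring and tie-breaks — the test suite and the
acceptance script both verify this against an independently written
enumerator.

A known limitation worth stating: maximizing adjusted $R^2$ over many
candidates is a greedy model-selection rule; at moderate sample sizes a
sign-valid spurious regressor can raise adjusted $R^2$ slightly and be
retained, so inferred programs tend to contain a minority of extra
regulators beside the true ones. Evidence refinement exists precisely
to counteract this with external knowledge.

## Evidence refinement

External evidence never creates edges: it re-selects among the stored
candidates. For each candidate, per regulatory source the support is
the fraction of its (TF, target) edges present in the source; per
co-regulatory source, the fraction of unordered TF pairs within $A$ and
within $R$ present (0 when the program has fewer than two regulators or
no within-set pair). The integrative score is
$w_{fit} \cdot \text{normalized fit rank} + \sum_d w_d \cdot s_d$, with
the normalized fit rank mapping the best candidate (by adjusted $R^2$)
to 1 and the worst to 0. All weights default to 1 and are exposed. With
no usable evidence the selection reduces to the fit ranking, i.e.
refinement is the identity on chosen programs; adding a pair that
supports only the currently chosen candidate can never move the choice
away from it (monotonicity). Selection is per gene: given the candidate
lists, programs are independent, so a global optimization would
decompose gene-wise anyway.

## Sample-specific TF influence

Expression rows are gene-centered; for TF $t$ and sample $s$, with
centered values of the activated targets (count $n_a$, mean $m_a$,
sample variance $v_a$) and of the repressed targets ($n_r, m_r, v_r$),

$$ I(t, s) = \frac{m_a - m_r}{\sqrt{v_a / n_a + v_r / n_r}} , $$

a Welch two-sample statistic: positive when the activated targets sit
above the repressed ones, i.e. when the TF is active in that sample. A
pure activator (or repressor) falls back to the one-sample form
$m/\sqrt{v/n}$ (negated for repressors). TFs with fewer than
`min_targets` scored targets (default 10, minimum 2) are excluded — the
statistic is a noisy summary below that; a non-empty target set with a
single member has undefined sample variance and is treated as empty.
A zero denominator yields 0 when the means agree and a flagged signed
sentinel ($\pm 10^6$) otherwise. Because both means shift equally, the
two-sample form is invariant to adding a constant to every gene in a
sample; the one-sample fallback is not, which is another reason the
minimum-target rule matters.

Robustness protocol: a fraction of the network's signed edges is
rewired to uniformly chosen different targets (sign preserved, no
self-loops, no duplicate edges, no activator/repressor overlap), and
each TF's influence profile on the perturbed network is correlated with
its original profile. At noise 0 the correlation is exactly 1; on data
generated under the model the mean correlation decreases with the
noise level — the package's desk-scale analogue of validating an
activity statistic against network misspecification.

## The co-regulation network

Two TFs *cooperate* on a target when they occur in the **same**
regulator set of its chosen program (both activators or both
repressors); opposite-sign co-targeting is not cooperation. With
$k$ shared same-set targets, $n_1, n_2$ per-TF target counts (either
sign) and $N$ retained targets as the universe, the pair is tested with
the one-sided hypergeometric upper tail
$P(X \ge k), X \sim \mathrm{Hypergeom}(N, n_1, n_2)$ — a one-sided
Fisher exact test — and Benjamini–Hochberg adjusted across tested pairs
(those with at least `min_shared` shared targets, default 1); edges
with $q \le$ `alpha` (default 0.05) form the co-regulation network.
Using either-sign margins with a same-set overlap makes the test
conservative under sign mixing; under a same-sign null (random
activator-only assignment) the raw p-values are calibrated, which the
test suite checks (fraction of $p \le 0.05$ within [0.03, 0.07] over
1225 null pairs). The universe is the set of retained targets, not all
genes: untestable genes carry no information about co-targeting. On
small dense benchmarks (tens of TFs each regulating ~10% of a few
hundred targets) the expected chance overlap is large and FDR
significance is rarely reached even for planted pairs — the *ranking*
by p-value is still informative, which is what the benchmark measures;
on transcriptome-scale data with sparse regulons the same counts become
strongly significant.

## The synthetic benchmark

`synthetic_spec()` defaults encode the package's reference study
conditions: 20 TFs, 200 genes, 100 samples, effect size 1, noise sd
0.25. TF rows are i.i.d. standard normal; gene $g$ is
`effect_size` $\cdot$ mean(TF expression of $A(g)$) $-$ `effect_size`
$\cdot$ mean($R(g)$) $+$ $\mathcal N(0,$ `noise_sd`$)$. Activator set
sizes are drawn uniformly from 1–2 and repressor sizes from 0–1
(programs stay small enough that their discrete signal is observable at
$n = 100$); with probability `coactivation_bias` = 0.5 a gene with two
or more activators reuses an existing cooperative pair instead of
drawing fresh TFs — cooperative programs in tumor transcriptomes
heavily reuse the same TF combinations, and 0.5 plants each pair in
roughly 2–6 programs. The ground-truth cooperative pairs are defined on
the *realized* network: unordered pairs co-occurring in the same
regulator set of at least two programs (a pair that co-occurs twice by
chance is exactly as cooperative as a reused one). Datasets are
bit-for-bit reproducible from the spec and seed.

Recovery scoring: signed TF$\to$gene edges are ranked by the best
adjusted $R^2$ of any sign-valid candidate containing them (edges
absent from all candidates rank last and unranked; a sign-flipped edge
is a miss), cooperative pairs by the cooperativity p-value of the
inferred network, and both rankings are summarized by average precision
— the step-wise (trapezoid-free) integral of the precision–recall
curve, whose expectation under a random ranking is the prevalence.
Precision and recall of the chosen programs are exact signed-edge
counts.

What the generator emulates: the linear-Gaussian regulatory model the
hybrid scoring assumes, cooperative pair structure, pure activators and
repressors. What it deliberately does not: TF–TF co-expression (real
co-regulators are correlated, which *helps* the discrete search; the
i.i.d. choice is the harder case), nonlinearity and saturation,
heavy-tailed or batch-confounded noise, and realistic marginal
distributions of any particular cancer cohort. Passing the benchmark
therefore shows the machinery is correct and recovers structure under
its own model assumptions — not that it will match any particular
biological gold standard.

Benchmark protocol (also used by `scripts/acceptance.R`): inference on
the non-TF genes with `min_coreg_support = 0.02` (a floor of 2 samples
out of 100 — under independent TF profiles a true pair is jointly
beyond $\pm1$ sd in ~2.5 samples, so the co-expression-calibrated
default of 0.1 would discard every true pair), `max_coreg = 2` matching
the generated set sizes, and the remaining defaults. Problem sizes used
by the test suite: the full 20/200/100 benchmark for recovery and
robustness (10 rewiring seeds across noise levels 0–0.5), 25 instances
of 3–5 TFs, 5–8 genes and 15–30 samples for the exhaustive-search
equivalence, 1225 pairs for the null calibration, and 100 random cases
for the Welch cross-check.

## Degenerate inputs and edge cases

Duplicate gene rows are collapsed by mean at load (with a warning);
rows with missing values are dropped (with a count). TFs absent from
the matrix are ignored with a warning; fewer than two present TFs is an
error. Zero-variance genes discretize to all zeros and are excluded by
the support filter. In `perturb_network()`, a regulator already
connected to every possible target simply keeps its edge (there is
nowhere legal to rewire it). Provenance files written by
`run_pipeline()` contain no timestamps, so identical configurations
produce byte-identical artifact directories.
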