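---
title: "Detecting transcriptional network rewiring with rewirekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptional network rewiring with rewirekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewirekit)
```

## The problem

Two groups of tumours or cell lines can have indistinguishable mean
expression for every gene in a pathway and still differ profoundly in how
those genes move together. That change in the correlation (co-expression)
structure — *network rewiring* — matters for drug targeting: a gene that is
a highly connected hub in one disease state may be peripheral in another,
so inferences carried over from wild-type networks can point at the wrong
node. rewirekit implements a suite of rewiring analyses around a single
data substrate, a genes × samples matrix of normalized expression values:

* **unsupervised**: a Gaussian mixture over samples proposes latent groups,
  and a parametric bootstrap asks whether the groups differ in mean
  structure, correlation structure, or model fit;
* **supervised**: for groups fixed in advance (e.g. BRAF+ vs BRAF−),
  correlation-matrix equivalence tests with label-permutation nulls;
* **architecture**: thresholded correlation networks per group, four node
  centralities, consensus hub calling, and drug–gene interaction lookup;
* **modules**: topological-overlap co-expression modules, matched across
  groups by maximal overlap, with permutation overlap nulls and per-module
  rewiring tests.

A synthetic-data generator plants rewiring, hubs and mutation labels so
every stage is testable end to end without external data.

## Models and statistics

### Mixture clustering of samples

Samples are clustered on their full expression profiles with a
k-component Gaussian mixture with **per-component diagonal covariance**.
Diagonal covariance is a deliberate restriction: at the cohort shapes this
pipeline targets (tens of samples on hundreds of genes) a full covariance
is singular and not estimable. The practical consequence is that the
mixture detects groups through per-gene means and variances; correlation
differences enter the omnibus test through the dedicated
correlation-equality statistic, not through the mixture likelihood.

Fitting is EM from `n_restarts = 10` seeded random-responsibility starts,
convergence when the log-likelihood gain drops below `1e-8` (cap 500
iterations), variance floor `1e-6`. Components that collapse (weight below
1/n, or all variances at the floor) are flagged in the fit rather than
silently accepted. Hard labels take the maximum posterior, ties toward the
lower component index.

### Model-selection statistics and the parameter-count question

The k-group and 1-group fits are compared through the likelihood-ratio
statistic LLR = 2(l_k − l_1) and the information-criterion differences

* ΔAIC = 2Δq − LLR,
* ΔBIC = Δq·ln(n) − LLR,

negative values favouring the k-group model, with the exact identity
ΔBIC − ΔAIC = Δq(ln n − 2). Two conventions for Δq are exposed by
`mixture_param_count()`:

* `diagonal_multivariate` — the model actually fitted: q = (k−1) + 2kG;
* `per_component_scalar` — q = 3k − 1, i.e. Δq = 3 per added component.

Published information-criterion tables for this style of analysis are
internally consistent only with Δq = 3 per added component (an effectively
univariate count), which contradicts a multivariate fit over hundreds of
genes. The package does not resolve that discrepancy: both counts are
available, the scalar convention is the default where the printed
arithmetic is reproduced, and the multivariate count is what
`fit_mixture()` itself reports in `n_params`.

### Simulation-based significance (the omnibus test)

`omnibus_rewiring_test()` computes five statistics between the two largest
mixture groups — the paired mean-equality t across genes (df = G − 1), the
Steiger correlation-equality χ², LLR, ΔAIC and ΔBIC — and calibrates each
by simulation: S = 1000 cohorts are drawn from a homogeneity null, the
identical pipeline (mixture fit included) is re-run on each, and the
p-value is (count + 1)/(S + 1). The +1 convention means p is never zero
and the attainable floor is 1/(S+1) — with 1,000 simulations, 9.99e-4.
For the information criteria "more extreme" is "more negative"; with n
fixed all three model-selection p-values then coincide, because each is a
monotone transform of the LLR. (Published tables that print different
bootstrap p-values for ΔBIC than for the LLR at fixed n are internally
inconsistent with their own statistic definitions; we report all three
anyway, for table compatibility.)

**Choice of homogeneity null.** Two nulls are implemented:

* `null_cov = "fitted"` (default): simulate from the fitted one-component
  model, N(pooled mean, diagonal ML variances). This is the standard
  parametric bootstrap for mixture model selection and calibrates all
  five statistics.
* `null_cov = "empirical"`: simulate at the pooled mean and the full
  empirical covariance, rank-truncated through its eigendecomposition
  when samples do not exceed genes. This preserves the observed gene–gene
  correlation structure in the null cohorts, but is *conservative* for
  the LLR family: the covariance estimate's sampling noise becomes real
  correlation structure in the simulated cohorts, which a diagonal
  mixture partially absorbs by splitting samples, inflating the null LLR.
  The effect is easy to reproduce:

```{r null-choice, eval = FALSE}
llr_of <- function(X, seed) {
  fk <- fit_mixture(X, 2, n_restarts = 3, seed = seed)
  2 * (fk$log_likelihood - fit_mixture(X, 1)$log_likelihood)
}
G <- 20; n <- 60
true_llr <- sapply(1:100, function(i) {
  set.seed(i); llr_of(matrix(rnorm(G * n), G, n), seed = i)
})
x0 <- matrix(rnorm(G * n), G, n)
emp <- rewirekit:::null_cohort_sampler(t(x0))
boot_llr <- sapply(1:100, function(i) llr_of(emp(i), seed = i))
quantile(true_llr, c(.1, .5, .9)); quantile(boot_llr, c(.1, .5, .9))
```

Under the fitted null the two distributions agree (the LLR is invariant
to per-gene affine maps, so estimating the diagonal parameters costs
nothing); under the empirical null the bootstrap distribution is shifted
upward. Because the package's type-I acceptance checks require calibrated
p-values, `"fitted"` is the default and `"empirical"` remains available
for users who want the correlation-preserving null and accept its
conservatism.

Inside the bootstrap, replicates whose mixture split is unusable (a top-2
component below 4 samples, or a perfect within-component rank correlation
that makes the Fisher z diverge) are redrawn from a fresh RNG substream,
capped at 2S attempts and counted in the result. Bootstrap refits use
`boot_restarts = 3` rather than 10: restart count affects the LLR
distribution, so what matters for calibration is that the observed and
null fits get comparable optimisation effort, and 3 restarts keeps
S × EM affordable; for strict exchangeability set `n_restarts = 3` too.

### Correlation-matrix equivalence tests

`spearman_corr()` computes the gene-by-gene Spearman correlation matrix
(average ranks for ties) with two-sided p-values from
t = r√((n−2)/(1−r²)) on n − 2 df. Spearman is the default everywhere —
microarray intensities are not bivariate normal — with Pearson behind a
flag for Gaussian calibration work, where the Fisher-z variance 1/(n−3)
is exact.

Two equivalence statistics compare correlation matrices R1 (n1 samples)
and R2 (n2 samples) over the same G genes, both on G(G−1)/2 df:

* **Steiger**: χ² = Σ_{i<j} (z1_ij − z2_ij)² / (1/(n1−3) + 1/(n2−3)),
  z = atanh(r). Aggregate magnitude of entrywise differences.
* **Jennrich**: with R̄ the sample-size-weighted average,
  c = n1n2/(n1+n2) and Z = √c·R̄⁻¹(R1 − R2):
  χ² = tr(Z²)/2 − diag(Z)ᵀS⁻¹diag(Z), S = I + R̄ ∘ R̄⁻¹. Differences
  standardised against the pooled structure.

Degrees of freedom are counted in *gene pairs*. (Published tables for
this analysis print df values matching sample-pair counts n(n−1)/2, which
cannot be the degrees of freedom of a gene-pair matrix test; the package
implements the statistic's own convention.) When the pooled matrix is
singular — unavoidable when samples do not exceed genes — the Jennrich
test refuses unless shrinkage R̄ ← (1−λ)R̄ + λI is enabled (default
λ = 0.1 when the pipeline enables it), and the result is flagged
approximate.

`permutation_equivalence_test()` gives both statistics an exact
finite-sample null: N = 10,000 label permutations preserving class sizes,
p = (count + 1)/(N + 1). For tiny cohorts (`exact = TRUE`) the full
assignment distribution is enumerated instead, and the p-value is the
proportion of assignments at least as extreme, the observed assignment
included.

### Network architecture

`build_network()` applies the edge rule: the pair (i, j) is connected iff
the two-sided p-value of its correlation is ≤ α = 0.05, with edge weight
r². Edge retention uses *raw* p-values — the rule is a per-network sparsity
device, not an inference; Bonferroni control appears only in the
genome-scale pair counting (`count_significant_pairs()`), where it is the
stated convention. Four centralities are computed per gene: weighted
degree (strength); closeness with the Wasserman–Faust within-component
correction, on shortest-path distances over edge lengths 1/w; unnormalized
Brandes betweenness on the same lengths (ties split fractionally);
eigenvector centrality as the principal eigenvector of the weight matrix
on the largest component, max-normalized. The 1/w length transform and
weighted (not binarized) degree are conventions the source analysis left
unstated; they are logged in output headers and the binarized variant is a
one-liner on the returned weight matrix. The *consensus hub* is the modal
gene among the four per-metric winners, all modal genes reported on ties.
`strong_edges()` extracts |r| strictly above 0.7, and `tail_quantile()`
reports the upper-5% point of the coefficient distribution by linear
interpolation (R's type-7 quantile).

### Modules

`detect_modules()` is a fixed-k variant of weighted co-expression module
detection: adjacency |r|^β with β = 6 (the customary soft-threshold
default; the source analysis is silent), unsigned, topological overlap
similarity, average-linkage clustering on 1 − TOM, cut into exactly k
modules (k = 10 and 20 in the pipeline defaults, which parameterizes by
module count rather than dynamic tree cutting). Cross-group module
correspondence is by maximal gene overlap with ties to the lower label;
the permutation null permutes gene labels of the other partition and
records per-reference-module *max* overlap, so its mean sits at or above
the fixed-pair hypergeometric mean. Per-module rewiring tests run the
Steiger permutation test on the intersection genes; intersections below 3
genes are reported NA, mirroring how such cells appear in module tables.

## The synthetic-data generator

`generate_rewired_cohort()` draws each group from the *same* mean vector
(zero by default) and its own correlation matrix, so the only group signal
is rewiring — the headline structure in which mean-equality tests stay
null while correlation-equality tests do not. Defaults state the world the
analyses are tested in: unit variances (a per-gene sd vector mimics
intensity heterogeneity when wanted), Gaussian marginals (`noise_df`
switches to unit-variance scaled-t to stress the rank-based stages), group
shapes taken from the published cohorts (27/7, 39/19, 401/72) in tests.
Correlation recipes cover planted blocks, hub-and-spoke structure and
random PSD matrices via orthogonal mixing; slightly indefinite user
matrices are repaired by eigenvalue clipping with a warning.

One recipe deserves a note: a pure star — hub correlated r with s spokes,
spokes mutually uncorrelated — is only a valid correlation matrix for
r ≤ 1/√s, so the stated hub-recovery setting (10 spokes at r = 0.7) is
infeasible as a star. `corr_hub_spoke()` therefore uses the one-factor
construction: spokes correlate r² among themselves, which is positive
semi-definite for any |r| < 1 and is what "a hub mediating its spokes"
means generatively.

What the generator does **not** emulate: probe-level microarray artifacts,
batch effects, RNA-seq count noise, outlying samples, or mean shifts
confounded with rewiring. A green test therefore establishes that a method
detects planted correlation differences at the stated shapes under clean
Gaussian (or t) sampling — not that it is robust to the full mess of real
cohorts.

`generate_mutation_labels()` attaches binary labels whose prevalence
differs between clusters by exactly a stated odds ratio on the logit
scale; odds ratio 1 gives the null world in which mutation status does not
explain cluster membership, used to calibrate the association stage.

## Numerical conventions

* Empirical p-values are (count + 1)/(S + 1) throughout; "greater than"
  counts use strict inequality, so the floor 1/(S+1) is attainable and
  p never exceeds 1.
* Seeds: every stochastic function takes a seed; the pipeline derives
  named per-stage substreams from one master seed with large multipliers,
  so different master seeds never share bootstrap streams. Seeds are
  reduced mod 2³¹ − 1 before use. The RNG is R's default
  (Mersenne-Twister); the EM core draws its initial responsibilities
  through R's RNG from C++, so fits are bit-reproducible under set.seed.
* Probe collapse keeps the probeset with maximal across-sample mean;
  exact ties go to the lexicographically smallest probeset id and are
  logged. Probesets annotated to several genes keep their composite label
  verbatim as a single node name, and the drug mapper splits such names
  on commas at lookup time.
* Degenerate inputs fail loudly: missing cells on read, constant genes in
  correlation stages (flagged, correlation set to 0), |r| = 1 off the
  diagonal in Fisher-z statistics (error naming the pair), complete
  separation in logistic fits (flagged with a diverging-estimate
  sentinel).

## Limitations

The mixture's diagonal covariance cannot itself see correlation
differences; rewiring detection rests on the correlation statistics. The
Jennrich shrinkage variant is approximate and its null is only exact by
permutation. Type-I calibration of the omnibus test is demonstrated for
the fitted null at the tested shapes; the empirical-covariance null is
offered with documented conservatism. Module detection with a fixed k
inherits k's arbitrariness — matching and rewiring results should be read
per k, not across k. Drug mapping is a lookup against whatever interaction
table is supplied; the packaged table is a small synthetic fixture for
tests and examples, not a clinical resource.
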