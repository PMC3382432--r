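---
title: "Correlation Set Analysis: model, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation Set Analysis: model, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csar)
```

## The problem and the model

Expression surveys of disease populations pose a recurring question: which
upstream regulators are *active* — causally driving the observed
transcriptional state? Purely data-driven network reconstruction needs very
large cohorts and still struggles with regulators whose activity is not
visible in their own transcript (protein-level regulation, phosphorylation,
ligand binding). Correlation Set Analysis (CSA) sidesteps regulator
co-expression entirely. It starts from a *causal network*: a curated
collection of regulator → regulatee edges, each derived from a published
perturbation experiment that establishes a direction of causality, with a
sign for up- or down-regulation. The hypothesis is simple: if a regulator
is active across a population, its regulatees should respond in a
coordinated way, so their transcripts should be mutually correlated.

Given an expression matrix with $m$ samples, write
$\rho_{ij} = |\mathrm{cor}(x_i, x_j)|$ for the absolute Pearson correlation
of regulatees $i$ and $j$. Two scores summarize the coherence of a
regulator $R$ with regulatee set of size $n$:

$$\mu_R = \frac{2}{n(n-1)} \sum_{i<j} \rho_{ij}, \qquad
  F_R = \frac{2c}{n(n-1)},$$

where $c$ counts pairs with $\rho_{ij}$ strictly above a dataset-global
cutoff. The mean score detects a broad shift in coherence; the ratio score
detects a small, strongly co-expressed subset that barely moves the mean —
a pattern that does occur in real cohorts. Absolute correlations are used
because empirically the correlation structure of coherently responding
regulatees does not separate by regulation sign; the sign only labels the
up/down partitions in the report.

Coherent regulatees (counted by $n_c$) are those participating in at least
one supra-cutoff pair. This is the weakest membership notion consistent
with "participates in the coherent signal"; it is monotone in the cutoff
and exact to enumerate. The regulator's own co-expression with its
regulatees, $\mu_{RR}$, is reported for interpretation only — it is often
low for genuinely active regulators, which is the method's starting
premise — and is `NA` when the regulator has no measured transcript.

## The coherence cutoff

The ratio score's cutoff is fixed at the **95th percentile of all pairwise
absolute correlations in the dataset** (after restricting to genes covered
by the causal network, which is also the universe used everywhere else).
This makes the cutoff self-calibrating: datasets with heavier global
correlation (larger cohorts, stronger batch structure) get a
proportionally higher bar. Percentiles interpolate linearly between order
statistics (R's default type 7); the choice is immaterial at these pair
counts but is fixed for reproducibility. Up to $5\times10^6$ gene pairs the
percentile is exhaustive; beyond that it is estimated from $10^6$
uniformly sampled distinct pairs with a fixed seed — at that sample size
the 95th percentile is stable to well below the third decimal.

## Permutation nulls

Both nulls answer "how coherent would this regulatee set look by chance?",
conditioning on different aspects of the observed structure:

- **Gene permutation** draws, for a regulator with $n$ regulatees,
  random sets of $n$ measured genes. The null depends on the data only
  through $n$, so draws are shared across regulators of equal degree — a
  large speedup with no change in distribution.
- **Graph permutation** randomizes the causal network itself by edge
  switching: two edges $(a,b)$ and $(c,d)$ are replaced by $(a,d)$ and
  $(c,b)$, which preserves every node's in- and out-degree. Proposals that
  would create a self-loop or a parallel edge are rejected, keeping the
  graph simple. Following the usual mixing rule of thumb, randomization
  performs an average of 3 accepted switches per edge. Weak connectivity
  is checked between adaptive batches of $K$ switches (initial
  $K = |E|/10$, doubled after a passed check, halved after a failure, with
  the failed batch rolled back); for inputs that are already disconnected
  the requirement relaxes to "the number of weak components does not
  increase", since the strict precondition cannot hold. Each switched edge
  keeps the sign of the edge that contributed its regulator endpoint.

Graph permutation conditions on the full bipartite degree structure — a
regulatee controlled by many regulators stays that way — which makes it
the stricter and slightly more specific null; it is the default.

Empirical p-values use the add-one estimator
$p = (1 + \#\{s_{\text{null}} \ge s_{\text{obs}}\})/(1 + N)$, which is
never zero and counts ties as exceedances (conservative for the discrete
ratio score). Sample-label permutation is *not* offered: with a single
population and correlation-based scores it does not destroy the quantity
under test. Multiple testing across the regulator list is handled by
Benjamini–Hochberg step-up adjustment (`stats::p.adjust`), reported as an
estimated FDR; 0.05 is the reporting threshold.

With $N$ permutations the smallest attainable p-value is $1/(N+1)$, so $N$
bounds the resolution of the BH adjustment: with hundreds of regulators,
$N = 100$ cannot push any adjusted value below typical thresholds. The
package default is $N = 1000$ for analyses; the bundled benchmark uses
$N = 500$, which leaves the smallest adjusted values an order of magnitude
below 0.05 at the benchmark's scale.

## The simulation framework

The simulated benchmark answers "can CSA recover regulators whose activity
we embedded ourselves?" and consists of three generators:

- **Baseline.** Real cohorts are emulated either by per-gene
  label permutation of a user-supplied matrix (`permute_baseline`), which
  preserves each gene's value multiset exactly while destroying
  correlations, or — the self-contained default — by `synthesize_baseline`:
  independent Gaussian gene vectors with per-gene means uniform on
  $[6, 12]$ (a log2 intensity scale) and per-gene standard deviations
  log-normal with median 0.7. These ranges give the marginal heterogeneity
  of a typical normalized microarray cohort without requiring any
  download.
- **Spike-in.** To embed an active regulator, selected regulatee rows are
  standardized, premultiplied by the Cholesky factor $L$ of the
  equicorrelation matrix $\Sigma = (1-\rho)I + \rho J$ (the
  Iman–Conover construction), and rescaled to each row's original mean
  and standard deviation. Row-wise affine rescaling does not change
  correlations, so the marginals are restored exactly while pairwise
  sample correlations concentrate around $\rho$ with the usual
  $O(1/\sqrt{m})$ sampling spread.
- **Coverage.** "A fraction $p$ of regulatee pairs correlated" is
  implemented by spiking a random subset of size
  $k = \min\{k : k(k-1)/2 \ge p\,n(n-1)/2\}$, i.e. pair-fraction
  semantics. When embedded regulators share regulatees, spikes apply in
  regulator-id order and later spikes overwrite earlier rows (reported via
  a message); with heavy-tailed networks this touches a minority of rows
  and slightly *weakens* the embedded signal, so it biases the benchmark
  against the method rather than for it.
- **Synthetic network.** `synthesize_network` draws out-degrees from a
  truncated discrete power law $P(k) \propto k^{-\gamma}$ on
  $[d_{\min}, d_{\max}]$, samples regulatee sets uniformly, lets a
  configurable fraction of regulators also appear as regulatees (genes
  that are both targets and drivers), and re-wires until weakly
  connected. Generated networks pass `filter_network` unchanged.

The bundled benchmark uses 500 regulators over 2000 regulatee nodes with
$\gamma = 1.2$ and degrees 2–100 (about 9000–10000 edges, mean out-degree
≈ 19), 391 samples, and 100 embedded regulators at $\rho = 0.5$ covering
at least 50% of each one's regulatee pairs. Two considerations fixed the
density: curated causal networks have mean regulatee counts well above
their regulator counts' tree threshold (hub regulators control hundreds of
targets), and an edge-switching null needs a graph whose connectivity
survives switching — a near-tree graph (mean total degree ≈ 2) rejects
almost every batch. At mean node degree ≈ 8 the randomizer accepts
essentially every batch, and 500 permutations of the full network run in
well under a minute.

What the simulations do *not* emulate: correlated null structure (real
cohorts have pervasive background co-expression from shared pathways and
batch effects, which raises the global cutoff and the nulls together, but
can also create coherent regulatee sets for inactive regulators — the
known overlapping-regulon failure mode), probe-level noise, missing
values beyond what the row-mean policy covers, and regulatee sets whose
coverage by the spike is degree-dependent. Passing the benchmark therefore
demonstrates correctness of the machinery and calibration of the nulls
under realistic marginals, not biological validity on any particular
cohort.

## Evaluation utilities

ROC curves are computed over regulator rankings; the ranking statistic is
$1 - p$ when permutations were run (so significance, not raw coherence,
drives the ordering) and the raw score otherwise. Tied scores collapse to
a single threshold and AUC uses the trapezoid rule. The quoted operating
point maximizes Youden's $J = \mathrm{TPR} - \mathrm{FPR}$, and
$\min(\mathrm{TPR}, \mathrm{TNR})$ at that point is the balanced-recovery
summary. On the representative benchmark it clears the 0.8 mark with a
wide margin (the acceptance script recomputes the exact value end to end),
and the realized false-discovery proportion at estimated FDR < 0.05 stays
below the nominal level.

Two controls guard against self-deception: on pure-noise data (no spikes)
CSA reports essentially no regulators at FDR < 0.05, and scoring spiked
data against an edge-switched network collapses the AUC to chance,
confirming that the signal enters only through the true network structure.
The out-degree baseline (`degree_rank_baseline`) ranks regulators by their
number of targets: in raw form it ignores the data and performs at chance
when signal is embedded independently of degree; counting only
*coherently* regulated targets ($n_c$) makes it data-aware and better than
random, yet still clearly below CSA, which normalizes by the regulatee
count and calibrates against a null.

Fisher's exact test (one-sided, over-representation) reports the
enrichment of regulatee sets for user-supplied gene signatures over the
measured universe.

## Degenerate inputs, tie-breaks, tolerances

- Regulators with fewer than 2 regulatees after filtering are dropped —
  pairwise coherence is undefined for them. Self-loops are removed before
  degree counting.
- Duplicate (regulator, regulatee) assertions collapse to one edge; a pair
  asserted with both signs keeps a single `up` edge with a warning (the
  sign never enters the scores).
- Zero-variance gene rows are dropped (no defined correlation); missing
  cells impute to the gene's row mean; duplicate gene ids average.
- Ties at the coherence cutoff are non-coherent (strict inequality).
- Degree-rank and ROC tie-breaks are deterministic (regulator id; tied
  scores form one ROC threshold).
- Pairwise correlations from the cached matrix agree with direct
  recomputation to 1e-12; spike-in marginal restoration is exact up to
  floating point.
- A star network (one regulator owning every regulatee) admits no
  alternative degree-preserving simple graph: edge switching stalls by
  construction, is capped by a proposal budget, and returns the input with
  a warning — its graph-permutation null is then degenerate at the
  observed score, which is the correct limit.

## Problem sizes used in the bundled checks

The test suite exercises the representative benchmark once (500
regulators, 391 samples, 500 graph permutations, about half a minute), ten
small pure-noise runs for null specificity, and small fixtures elsewhere;
the acceptance script repeats the representative run over 5 seeds. These
sizes were chosen as the smallest at which the benchmark's Monte-Carlo
variability is negligible relative to its margins.

## Known limitations

- Regulators with heavily overlapping regulatee sets are not
  distinguishable: a single active regulator can render its overlapping
  neighbours significant. Clustering regulators by regulatee-set
  similarity would be the natural extension.
- Results are bounded by the causal network's coverage and quality; the
  package treats identifiers as opaque strings and does no id mapping or
  curation.
- The gene-permutation null ignores the degree structure of regulatees;
  prefer graph permutation when the network is available in full.
- The spike-in induces equicorrelation only; block or hierarchical
  correlation structures are not modelled.
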