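---
title: "Regressing ChIP-Seq peak scores on motif features: models and methods"
author: "peakreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regressing ChIP-Seq peak scores on motif features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakreg)
```

## The problem and the model

A ChIP-Seq experiment yields a set of peaks, each with an enrichment score
that acts as a surrogate for the binding affinity of the assayed protein at
that locus. Given a collection of candidate binding-motif models (PSSMs,
typically produced by a motif-discovery program run on the peak sequences),
`peakreg` asks: which motifs explain the variation in the peak scores, and
in which direction?

The model is a penalized linear regression. Peak $i$ is represented by a
feature vector $v_i \in \mathbb{R}^m$ over the $m$ candidate motifs (next
section), and the response is $y_i = \log(\text{score}_i)$. The default
estimator solves

$$\min_{w, b}\; \sum_i \big(y_i - b - v_i^\top w\big)^2 + \lambda \lVert w \rVert_1 ,$$

the lasso. The L1 penalty drives coefficients of redundant or
uninformative motifs to exactly zero, which matters here because
motif-discovery output is large and highly redundant: many candidate PSSMs
are noisy variants of the same underlying element. A motif with a positive
fitted coefficient is *strengthening* (its presence predicts a higher
binding signal), a negative one *weakening*. Four comparison estimators —
ordinary least squares, ridge, partial least squares (PLS) and principal
component regression (PCR) — share the same interface and coefficient
reporting, so their rankings are directly comparable; PLS/PCR coefficients
are back-projected from the latent space into motif space for that
purpose. In practice the unpenalized and projection-based methods reach
similar predictive correlations but produce rankings that are hard to read
biologically (e.g. near-duplicate columns with large opposite-signed
weights under OLS); the lasso's sparse ranking is the package's default
for that reason.

## From sequences to features

Each peak is first *uniformized* to a fixed width $W$ (default 200 bp,
configurable over the 100–800 bp range that is worth sweeping): either a
window centered on the annotated peak summit, or the peak interval
symmetrically enlarged/trimmed, with an odd leftover base going to the
right and boundary windows shifted inward. A fixed width keeps downstream
motif discovery fast and tolerates summit misplacement in noisy data.

For motif $j$ with letter probabilities $M_j$ (length $L_j$), the log-odds
matrix is

$$\mathrm{lom}_j[p, a] = \log_2 \frac{(M_j[p, a] + c)/(1 + 4c)}{\pi_a},$$

with background $\pi$ and pseudocount $c$ (default 0.01; it prevents
$-\infty$ entries without materially reordering matches). The raw feature
is the best sliding-window sum over all offsets, and over both strands by
default (binding is strand-agnostic; the reverse strand scores the
reverse-complemented matrix), minus the maximum achievable score
$\max_j = \sum_p \max_a \mathrm{lom}_j[p, a]$:

$$\tilde v_{ij} = \max_{\text{offsets, strands}} \;\text{window score} \;-\; \max\nolimits_j \;\le\; 0,$$

with equality exactly when the peak contains a perfect-consensus match.
Each row is then shifted by its minimum (making entries nonnegative, the
peak's best-matching motif carrying the row maximum) and divided by its
Euclidean norm. The normalization is deliberately per peak, not per
column: features arrive on a shared, interpretable scale and the penalized
objective is solved on them exactly as produced (no column
standardization, which would silently change the solution).

Two degenerate cases are rejected rather than patched: a single motif
(every shifted row is identically zero) and a peak in which *all* motifs
tie exactly (same all-zero row). Bases outside `{A, C, G, T}` other than
`N` are errors; `N` scores as background (log-odds contribution 0).

## Hyperparameter selection

The penalty weight is chosen by Monte-Carlo cross-validation: 30 repeated
random train/test splits (test fraction 1/3), a 25-point log-spaced
$\lambda$ grid on $[10^{-4}, 10^{2}]$ spanning near-OLS to full shrinkage,
and Pearson correlation between predicted and observed log scores on the
held-out set as the criterion. Two aggregations are reported: the
per-grid-value mean correlation (whose argmax selects $\lambda$) and the
mean of per-iteration best correlations, an optimistic summary that upper
bounds the former by construction. Reported coefficients are averaged over
the 30 training fits at the selected $\lambda$, so the ranking is not
hostage to a single split; the per-split fits are also retained in the
returned object. All splits derive from one seed (default 17) and are
reproducible.

Splits whose test half has zero response variance are resampled (with a
message); fully shrunk fits predict a constant, whose correlation is
reported as 0 with a warning rather than `NA`.

## Composite motifs

Peaks bound through a combination of elements show joint presence of
several motifs. After fitting, motifs with normalized coefficient above
`tau` (default 0.4, a mid-range cut on the 0–1 normalized scale;
configurable) are selected, each peak is encoded as a binary
presence vector (present = best match at least `alpha` of the achievable
maximum, default `alpha = 0.8`, strict but attainable), and the vectors
are clustered with K-means (Euclidean metric, 10 restarts, best inertia
kept, fixed seed). When `k` is not supplied it is chosen by mean
silhouette width over 2–10. Clusters are summarized by presence-frequency
signatures, and motif pairs whose joint presence frequency within a
cluster reaches `min_pair_freq` are reported as composite candidates. A
binary vector cannot encode multiplicity, so homotypic composites (the
same motif twice in one peak) are detected separately from per-peak match
counts (at least two qualifying offsets).

## Regulatory-SNP candidates

If motif matches inside peaks mark true binding sites, those bases should
tolerate polymorphism poorly, so known SNPs should be *depleted* there.
The mapped positions of the selected motifs (all matches scoring at least
`alpha` of the maximum; overlapping matches cover each base once) are
intersected with a SNP set, and the count $k$ of SNP bases among the $n$
motif-covered bases is tested against the $K$ SNP bases among all $N$ peak
bases with the lower-tail hypergeometric probability, computed in log
space (`phyper`), which is stable for $N$ in the millions. By default $N$
counts distinct genomic bases across (possibly overlapping) windows; a
total-length mode is available since published reports often quote summed
sequence length. The mapping stringency reuses the presence threshold
`alpha` — one knob, consistently interpreted.

## The synthetic benchmark

The generator builds data whose ground truth is known by construction: a
synthetic chromosome of adjacent peak windows with i.i.d. background
bases; informative random PSSMs (consensus probability 0.85); motif
instances planted per (peak, motif) with probability 0.3 at uniform
offsets, instance letters sampled from the PSSM; and the latent log score

$$y_i = b + v_i^\top w + \varepsilon_i, \qquad \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

where $v_i$ is the *same* feature vector the pipeline computes on the
generated sequence. The default conditions are 500 peaks × 50 motifs with
planted weights $(+3, +2, +1, -1, -2)$ among 45 zero-weight decoys and
$\sigma = 0.1$ — a desk-scale rendition of the thousands-of-peaks ×
~800-motif datasets the method targets. SNPs are dropped per base at rate
0.005, optionally multiplied by a depletion factor inside planted
footprints. Peaks in which every motif ties exactly (e.g. all planted
instances hit consensus) would violate the vectorization contract and are
redrawn; this rejection is rare under the default conditions and is part
of the generator's definition.

Because the generating model operates on the pipeline's own features,
recovery tests are well-posed: they validate the estimation machinery, not
the biology. Passing them says nothing about model misspecification on
real ChIP-Seq data — unmodeled background structure, mappability and
nucleosome biases, motif-discovery noise, or non-linear score/affinity
relationships. That gap is intentional and documented rather than papered
over with a more elaborate simulator.

Null calibration of the depletion test exploits an exact property of the
generative model: with SNPs dropped i.i.d. and independently of motif
positions, the SNP count among motif-covered bases is hypergeometric given
the totals, so redrawing only the SNP set (200 replicates over a fixed
2,000-peak landscape — large enough that the discrete p-value support is
fine-grained) must yield uniform p-values, checked by a
Kolmogorov–Smirnov test.

## Numerical choices and edge cases

* The lasso is solved by coordinate descent (`glmnet`) with
  `standardize = FALSE`, convergence threshold $10^{-12}$, and the exact
  objective mapping $\lambda_{\text{glmnet}} = \lambda / (2n)$; fits are
  cross-checked in the test suite against a closed-form single-feature
  soft threshold and an independent coordinate-descent implementation.
* Ridge and OLS use SVD closed forms (exact penalty semantics;
  minimum-norm OLS on rank-deficient designs, so duplicated columns split
  weight equally instead of exploding with opposite signs). PLS is NIPALS
  PLS1 with nested components; PCR regresses on leading SVD components.
  Full-rank, full-component PLS/PCR reproduce OLS — a test invariant.
* Ties in the sliding scan break toward the smallest offset, forward
  strand first; score-sorted peak clustering breaks score ties by peak id.
  Both make outputs deterministic.
* Score-sorted clustering for motif discovery uses groups of 200 peaks; a
  trailing remainder smaller than half a group is merged into the previous
  cluster so no degenerately small sequence set is exported.
* Q-value filtering defaults to 0.05 (conventional FDR level) and
  promoter filtering to TSS ± 2000 bp; both are parameters, not
  constants, since reasonable choices vary by study.
* Coordinates are 0-based half-open throughout; peak-table dialects
  declare 1-based inputs and are converted on read (and back on write).

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at the sizes stated above (500 × 50 recovery; 2,000-peak null
calibration; 1,000-peak uniformization sweeps; 100-instance scanning
oracles), chosen as the smallest scales at which the statistical claims
are meaningful rather than as stress tests. The pipeline itself is linear
in peaks × motifs × width and handles the full-scale datasets the method
is aimed at.

## Known limitations

* Motif discovery itself is out of scope: the package exports per-cluster
  FASTA inputs for an external tool (e.g. MEME in ZOOPS mode) and parses
  its minimal motif format back in.
* Zero-order background only; no dinucleotide or gapped PSSMs.
* Composite reporting is combinatorial presence counting; it imposes no
  spacing or orientation constraints between partners.
* The hypergeometric test treats bases as exchangeable; local mutation-
  rate variation is not modeled.
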