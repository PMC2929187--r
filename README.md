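# peakreg

`peakreg` identifies transcription factor binding motifs (TFBMs) that
explain ChIP-Seq peak enrichment scores. It is aimed at regulatory
genomicists who have a set of called peaks with scores, candidate motif
models (PSSMs) from a motif-discovery run, and want to know *which* motifs
drive the binding signal, *in which direction*, which motifs act *in
combination*, and whether the implied binding sites are depleted of known
SNPs (candidate regulatory SNPs).

## The model

Each peak is uniformized to a fixed-width sequence (default 200 bp) and
scored against every candidate motif: the raw feature is the best sliding
log-odds match minus the maximum achievable score (≤ 0, with 0 exactly at
a perfect-consensus match), then each per-peak vector is shifted by its
minimum and divided by its Euclidean norm. Writing `v_i` for peak *i*'s
feature vector and `y_i = log(score_i)`, the core estimator is the lasso

    min over (w, b) of:  Σ_i (y_i − b − v_iᵀ w)²  +  λ ‖w‖₁

with λ chosen by 30 repeated random train/test splits (test fraction 1/3)
over a 25-point log-spaced grid, scored by held-out Pearson correlation.
The L1 penalty removes redundant or uninformative motifs; positive
coefficients mark *strengthening* motifs, negative ones *weakening*.
Ordinary least squares, ridge, partial least squares and principal
component regression are available behind the same interface for
comparison (PLS/PCR coefficients are back-projected into motif space).
Downstream, binary motif-presence vectors are clustered with K-means to
propose composite motifs, and motif-mapped base positions are tested for
SNP depletion with a lower-tail hypergeometric test.

## Worked example

The package ships a synthetic-data generator whose ground truth is known
by construction: motifs planted at controlled frequencies, and log scores
generated as a linear function of the pipeline's own features plus noise
(see the methods vignette in `vignettes/`).

```r
library(peakreg)

d  <- generate_synthetic(synthetic_spec(n_peaks = 300, n_motifs = 30,
                                        snp_rate = 0.01,
                                        snp_depletion = 0.2, seed = 8))
cv <- cv_peak_regression(d$features, method = "l1", n_iter = 30, seed = 17)
cv
#> Cross-validated peak-score regression (method: l1)
#>   30 random splits, test fraction 0.333, seed 17
#>   selected hyperparameter: 0.3162278 (grid of 25 values)
#>   mean held-out correlation at selection: 0.971
#>   mean best-per-iteration correlation: 0.971
#>   nonzero coefficients: 27 of 30
```

The held-out correlation (0.971) says the selected sparse model predicts
unseen peaks' log scores almost perfectly here — expected, since the data
were generated from the model. The ranked coefficients recover the five
planted motifs (true weights +3, +2, +1, −1, −2) on top, with their signs:

```r
normalize_and_rank(cv)
#> Motif ranking (30 motifs; top 6 shown)
#>  motif_id coefficient normalized_coefficient    sign_label
#>       M01      2.9866                 1.0000 strengthening
#>       M05     -1.9132                -0.6406     weakening
#>       M02      1.8017                 0.6033 strengthening
#>       M04     -0.8801                -0.2947     weakening
#>       M03      0.8193                 0.2743 strengthening
#>       M18     -0.0342                -0.0115     weakening
```

The top-ranked motif's normalized coefficient is 1 by construction; the
steep drop after rank 5 separates planted motifs from decoys. SNPs were
planted at a fivefold lower rate inside motif footprints, and the
depletion report shows the motif-mapped bases carrying fewer SNPs (0.30%)
than peak bases at large (0.73%):

```r
rk  <- normalize_and_rank(cv)
pos <- motif_positions(d$peak_seqs, d$motifs,
                       motif_ids = select_motifs(rk, 0.2), alpha = 0.8)
enrichment_report(pos, d$snps, d$peak_seqs)
#> SNP depletion in motif-mapped positions
#>   motif-mapped: 0.30% (1 SNP bases of 332 bp)
#>   all peaks:    0.73% (439 SNP bases of 60000 bp)
#>   hypergeometric p-value: 0.3002
```

(With only 332 mapped bases the depletion is visible but not significant;
power comes with realistic peak counts.) On real data the same calls are
fed from files instead of the generator — `read_peak_table()`,
`read_fasta()`, `read_meme_motifs()`, `read_snps()` — or the whole chain
is run at once with `run_pipeline(pipeline_config(...))`, which writes
rankings, cluster FASTAs for external motif discovery, composite reports
and a checksummed run manifest.

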