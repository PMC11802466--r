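# hmpattern

Predicting a gene's expression class from the *shape* of histone-modification
ChIP-seq signal around its transcription start site (TSS), and explaining
every prediction down to individual promoter bins.

## Who this is for

Computational epigenomics groups who have per-gene binned ChIP-seq profiles
(or bedGraph tracks plus a TSS annotation) and matched RNA-seq expression,
and who want an *interpretable* classifier of high-vs-low expression: which
histone marks, which signal shapes, and which promoter sub-regions drive
each call.

## The method

The input per gene is a 5 × 200 matrix: five histone marks (H3K4me3,
H3K4me1, H3K36me3, H3K9me3, H3K27me3), 200 bins of 50 bp covering
TSS ± 5000 bp, orientation-normalized so bin −1 is always immediately
upstream.  Expression is binarized at the per-sample median.

A **pattern** is a template `v ∈ [0,1]^L` (L = 2…8) over consecutive bins
of one mark plus a correlation cutoff τ ∈ [0.5, 0.99].  Its feature value
for gene *g* is the match count

```
f(g) = #{ p : corr(x[p : p+L−1], v) > τ }
```

where `corr` is Pearson correlation over the window — invariant under
positive affine transforms of the signal, so only shape matters, never
scale.  Patterns are found by a standard SPSO2007 particle swarm over the
11-dimensional encoding (mark, L, τ, shape values), scored each round by
the training AUC of a gradient-boosted tree classifier (50 rounds,
shrinkage 0.2) on a fresh 3000-gene stratified subset; the round's best
pattern is accepted only if it strictly improves the accepted AUC, until a
0.999 training-AUC target or stagnation.  Backward elimination then drops
every pattern whose removal does not lower validation AUC; swarm-based
tuning picks the final booster's hyperparameters on the same validation
set; the tuned model is evaluated by test-set AUC (tie-aware Mann–Whitney).

Each prediction decomposes exactly into an intercept plus per-pattern
log-odds contributions (cover-weighted expected values along every tree
path), which aggregate into per-bin promoter importance maps and per-mark
frequency–contribution correlations.  Models transfer across samples:
pattern counts are recomputed on the target sample and scored with the
unchanged model.

A synthetic-data module generates gamma-background profiles with a planted
promoter motif (Poisson(5) copies in high-expression genes, Poisson(1) in
low), amplitude-jittered to exercise scale invariance, with a ledger of
every planted occurrence — so the whole pipeline is testable offline.

## Worked example

```r
library(hmpattern)

# a fully synthetic sample: 2000 genes, 5 marks, one planted motif
ds  <- generate_dataset(sim_config(seed = 42))
fit <- run_pipeline(ds$profiles, ds$labels,
                    config = extraction_config(seed = 7), seed = 7)
fit
#> <hm_fit> 5 extracted -> 1 surviving patterns; test AUC 0.9197

fit$model$patterns[[1]]
#> <hm_pattern> mark 1 (H3K4me3), L = 4, cutoff = 0.972
#>   shape: 0.99 0.00 1.00 0.00

pattern_recovery(fit$model$patterns[[1]], ds$config$motif_shape)
#> [1] 0.9980155
```

Extraction accepted five patterns; backward elimination pruned the four
that only memorized the training subset and kept a single detector.  It
sits on the mark carrying the planted motif and its shape — a sharp
high/low alternation — correlates 0.998 with the planted template (at a
one-bin lag: for an alternating template the detector may lock onto
either phase).  The test AUC of 0.92 is close to the ceiling set by the
Poisson(5)-vs-Poisson(1) overlap of planted copy numbers (≈ 0.95).

Explaining one prediction and mapping importance back onto the promoter:

```r
fm  <- build_feature_matrix(ds$profiles, fit$model$patterns)
ex  <- decompose_prediction(fit$model, fm["gene_0007", ],
                            gene_id = "gene_0007")
ex
#> <hm_explanation> gene gene_0007
#>   intercept 0.07098, logit -0.7495, prob 0.3209

imp <- bin_importance(fit$model, subset_profiles(ds$profiles,
                                                 fit$split$test))
signed_bin(which.max(colSums(imp)))
#> [1] -60
```

The importance argmax (bin −60, i.e. 3000 bp upstream of the TSS) falls
inside the window where the generator planted the motif (bins −80 … −15).

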