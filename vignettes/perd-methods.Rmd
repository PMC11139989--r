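---
title: "Predicting drug-responsive enhancers from perturbed expression: models and methods"
author: "perd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perd: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Perturbed chromatin accessibility data are scarce: large drug-perturbation
compendia measure transcriptomes, not open chromatin. `perd` bridges that
gap by learning, for each enhancer, how its DNase I hypersensitivity
("openness") co-varies with the expression of the genes it regulates and the
transcription factors (TFs) that bind it, using paired expression/openness
training data across many cellular contexts. The fitted models are then
applied to control and drug-treated expression profiles; enhancers whose
*predicted* openness changes significantly are called drug-responsive
("diffEnhancers"), and those calls are annotated with motif sites,
drug-perturbed target genes, and regulatory variants that fall inside the
enhancer.

## The per-enhancer openness model

Each enhancer `e` carries two prior sets: its associated target genes
`E_G` (from a curated enhancer-gene resource) and its binding TFs `E_T`
(TFs with at least one binding-site interval overlapping the enhancer).
Openness of one enhancer across `N` samples is modeled as

    O  ≈  a0  +  γ_T · Σ_{p ∈ E_T} α_p TF_p  +  γ_G · Σ_{q ∈ E_G} β_q TG_q

fitted by penalized least squares with an equal-mix L1/L2 (elastic-net)
penalty on `(α, β)`, or by random-forest / support-vector regression on the
same design matrix. One independent model is fitted per enhancer; there is
no parameter sharing across enhancers, matching the per-enhancer cross-cell
evaluation the method is judged by. The two nominal intercepts of the
TF and TG blocks are not separately identifiable and are merged into a
single `a0`.

Openness itself is defined as the maximum DH signal over the genome bins
spanning the enhancer (`compute_openness()`), which is how the training
matrices are expected to have been summarized.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma_T`, `gamma_G` | 1, 1 | fixed group weights multiplying the TF and TG columns; equal weights make the penalized problem a standard elastic net |
| `lambda` | `"cv"` | penalty weight; selected per enhancer by internal 5-fold cross-validation, or fixed by the user (0 = ordinary least squares) |
| `feature_mode` | `"TFandTG"` | `"TGonly"` drops the TF block — the target-gene-only baseline the full model is compared against |
| `preprocess` | `"auto"` | `log2(x+1)` when the expression matrix looks linear-scale (any value > 50), then per-feature z-scoring with training statistics |
| `min_genes`, `min_tfs` | 2, 2 | degree filter: an enhancer is modeled only with at least two associated genes *and* two binding TFs |

On the λ scale we follow the glmnet convention (penalty applied on the
`1/(2N)` squared-error scale with mixing fixed at 0.5). A single penalty
weight multiplying both the L1 and L2 norms cannot be mapped exactly onto
glmnet's `(λ, α)` parametrization for any fixed mixing, so λ here is
glmnet-scale by definition; the limiting contracts that matter — λ = 0 is
exactly least squares, and the aggregate coefficient L1 norm is
non-increasing in λ — are tested.

### Numerical choices

* Fixed-λ fits run glmnet down a decreasing warm-start path that terminates
  at the requested λ (convergence threshold 1e-12), so zero-penalty fits
  agree with the normal equations to better than 1e-6 without an OLS
  special case.
* Constant training targets yield an intercept-only model flagged
  `degenerate`; constant feature columns pass through unscaled.
* Negative predictions are clipped to 0 (openness is nonnegative by
  construction); clipping happens before everything downstream, including
  evaluation, and can be disabled per call.
* Missing values are never imputed: matrices keep explicit `NA`s and model
  fitting refuses them with an error.
* Random-forest models use 100 trees and `mtry = ceiling(sqrt(p))`; the SVM
  backend uses a radial kernel with library defaults; both are fitted under
  a caller-supplied seed so collections are reproducible.

## Evaluation

Three statistics summarize a predicted openness matrix against the measured
one: per-enhancer Pearson correlation across samples (cross-cell, τ_C),
per-sample correlation across enhancers (cross-enhancer, τ_E), and the
normalized squared prediction error
`τ = ΣΣ(O − Ô)² / ΣΣ(O − mean(O))²`, which is 0 for a perfect prediction
and 1 for the constant grand-mean predictor. Correlations of constant
vectors are undefined; they are reported as `NA` and *excluded* from
summaries (zero-filling would bias medians), with the count of defined
entries reported alongside.

Per-enhancer predictability covariates are computed from the measured DH
signal: *spread* (samples with DH > 0), *variation* (sample sd), and
*specificity* (cell types with DH > 2). The working set of well-predictable
enhancers keeps those with spread > 100, variation above the cohort's lower
quartile, and specificity > 10 — all strict inequalities, all configurable,
with the quantile computed on the unfiltered cohort. A leave-one-out driver
(`evaluate_loo()`) refits all models per held-out sample and pools
predictions; it is O(N·M) model fits and intended for moderate sizes.

## Differential calling

Predicted openness for control and treated samples is transformed to
`log2(x + 1)` (configurable to raw), so mean differences are log fold
changes. Two tests are provided:

* **Moderated t** — the empirical-Bayes two-group test: per-feature pooled
  variance `s²` with `d = n_t + n_c − 2` df is shrunk toward a prior
  `(d0, s0²)` estimated from all features by moment matching on `log s²`
  (mean and variance of `log s²` corrected by digamma/trigamma terms;
  the trigamma inversion uses Newton iteration). The statistic
  `logFC / (s̃ √(1/n_t + 1/n_c))` with `s̃² = (d0·s0² + d·s²)/(d0 + d)` is
  referred to a t distribution on `d + d0` df. `prior_df = 0` reproduces the
  textbook pooled t-test exactly; fewer than 10 usable variances also falls
  back to `prior_df = 0` with a warning. When every `s²` is identical the
  prior is taken as `(∞, s²)`, so moderation changes nothing — the natural
  limit for that degenerate input.
* **Wilcoxon rank-sum** — midranks for ties; exact two-sided p by full
  enumeration of group assignments when both groups have ≤ 8 samples,
  otherwise a normal approximation with tie and continuity correction.

Calling thresholds follow the method's defaults: diffEnhancers need
`|logFC| > 0.5` and `p < 0.001` (both strict, raw p-values; BH adjustment
is available but off by default), drug-perturbed genes need `p < 0.05` and
`|logFC| > 0.8`. A condition with fewer than two samples skips the block
with a recorded reason rather than producing unstable statistics.

## The evidence chain

For each called diffEnhancer, `build_evidence_chain()` composes three
primitives: motif-site interval overlap, intersection of the enhancer's
target genes with the drug-perturbed gene set ("concordant genes"), and
variants with `q < 0.05` whose 1-based position lies inside the enhancer's
printed inclusive range. A variant is **consistent** when its associated
gene is both a target gene of the enhancer and drug-perturbed — the full
regulatory story: variant in enhancer → enhancer responds to drug → target
gene responds to drug. Significant variants associated with perturbed genes
that fall outside every called enhancer are reported in a separate
gene-linked tier (gene-body pharmacogenomic variants).

All intervals are stored 0-based half-open (BED-native); coordinates
printed as text are treated as 1-based inclusive and converted on parse, so
the printed form round-trips. Abutting intervals do not overlap; any ≥ 1 bp
overlap links a TF site or motif to an enhancer (full containment is
available as a mode switch).

## What the synthetic data emulates — and what it does not

The generators produce every input with known ground truth:

* `generate_network()` — non-overlapping enhancer intervals on a toy
  chromosome, target-gene and TF sets per enhancer (disjoint across
  enhancers when the universes allow, so perturbations don't leak between
  enhancers by accident), and binding-site intervals that reproduce the TF
  sets when the network is rebuilt from them.
* `generate_paired_training()` — expression from a cell-type block model
  (per-gene baseline ~ U(2, 10) on a log2-like scale, cell-type effects
  sd 0.7, within-type noise sd 1) and openness from the planted linear
  model with coefficients ±U(0.5, 1.5), additive Gaussian noise (by default
  10% of each enhancer's signal sd), truncated at zero. The per-enhancer
  intercept is set to 2.5× the planted signal sd: large enough that
  truncation distorts < ~1% of values, small enough that a shift of twice
  the sampling noise still clears a 0.5 log2-fold-change gate — both
  properties were chosen by power analysis when the generator was designed,
  and they are what make the default conditions a fair test of the caller.
* `generate_perturbation()` — a single-cell-line context whose control
  means sit at each gene's training mean plus a fixed context offset;
  treated samples shift the target genes of designated responsive enhancers
  by `effect_size · sign(β_q)` expression units (`effect_size` is therefore
  in units of the expression noise sd). The ground truth recomputes the
  realized responsive set from the final per-gene shifts.
* `generate_variant_table()` — one consistent variant planted inside each
  responsive enhancer plus decoys of three kinds: outside any enhancer,
  inside with an unperturbed gene, and non-significant (q ≥ 0.05).

What this does **not** emulate: empirical DH signal distributions (heavy
tails, zero inflation beyond truncation), dosage series, batch structure,
correlated TF programs, assembly-specific coordinates, or measurement error
in the priors themselves (wrong target-gene assignments). Passing the
recovery tests therefore demonstrates correctness of the machinery under
the planted model — not calibrated performance on real compendia, where
prior quality and tissue matching dominate.

## Problem sizes

The packaged checks run the pipeline at 100 enhancers × 120 paired training
samples, a 20-vs-20 perturbation block with 30% responsive enhancers, and a
10,000-feature null calibration of the moderated t — sizes at which every
planted property is measurable with comfortable Monte Carlo margins while
the whole suite stays interactive.

## Known limitations

* Random-forest and SVM models are not serialized to text; collections
  using them are reproduced by refitting from data under the recorded seed
  and config (the JSON manifest stores everything needed).
* The leave-one-out driver refits every model per sample; use fixed λ or
  smaller cohorts for quick iteration.
* Cross-enhancer correlation is reported per sample but enhancers are
  modeled independently, so it inherits whatever between-enhancer structure
  the priors induce; it is a descriptive summary, not a fitted quantity.
* The moderated t assumes approximately normal (log-scale) openness within
  groups; the Wilcoxon path is the distribution-free cross-check.
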