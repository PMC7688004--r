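# seqaffinity

Sequence-only prediction of protein–protein binding affinity in R.

Experimentally measuring the binding free energy ΔG (kcal/mol) of a
protein–protein complex — equivalently its dissociation constant
K<sub>d</sub> = exp(ΔG / RT) — is slow and expensive, and most structure-based
predictors cannot be applied because most complexes have no solved structure.
`seqaffinity` implements a regression pipeline that predicts ΔG from the
amino-acid sequences of the ligand and receptor chains alone, for
computational biologists benchmarking affinity predictors or building
sequence-only baselines.

## What it computes

A complex *c* = ((*l*, *r*), *y*) is a set of ligand chains *l*, a set of
receptor chains *r* and an affinity label *y* = ΔG. The pipeline has two
interchangeable representations:

* **Explicit features.** Each chain *s* is encoded by one of five
  descriptors: amino-acid composition φ_AAC(s); averaged BLOSUM62 columns
  φ_Blosum(s) = (1/|s|) Σᵢ B_i; averaged PSI-BLAST PSSM columns
  φ_PSSM(s) = (1/|s|) Σᵢ Fᵢˢ; seven ProtParam-style physicochemical
  indices; or a ~1000-dimensional composite of autocorrelation, CTD,
  sequence-order and pseudo-amino-acid-composition families. The complex
  representation concatenates chain-averaged ligand and receptor blocks,
  ψ(c) = [ψ_Avg(l); ψ_Avg(r)].
* **String kernels.** Chain similarity k(a, b) is the Smith–Waterman
  optimal local-alignment score (BLOSUM62, affine gaps 11/1), the
  local-alignment kernel k_LA(a, b) = Σ_π exp(β·p(a, b, π)) summing over all
  local alignments (β = 0.1), or the (k, m)-mismatch kernel counting shared
  k-mers up to m mismatches (k = 5, m = 3). Complex-level kernels average
  k over chain pairs; indefinite Gram matrices are made positive
  semidefinite by subtracting the most negative eigenvalue from the
  diagonal.

Regression is by ordinary least squares, ε-insensitive support vector
regression f(c) = wᵀψ(c) + b (linear, RBF, or precomputed Gram) or random
forests, with hyperparameters chosen by seeded grid search. Evaluation is
leave-one-complex-out (LOCO) cross-validation reporting RMSE and Pearson r
with a two-sided p-value, against a sequence-homology nearest-neighbour
baseline that returns the ΔG of the most similar training complex. A seeded
synthetic-complex generator with known ground truth makes the whole pipeline
testable without external databases.

## Worked example

Simulate 30 complexes whose affinities are a smooth function of sequence
identity, then evaluate a local-alignment-kernel SVR and the homology
baseline by LOCO cross-validation:

```r
library(seqaffinity)

spec <- synthetic_spec(n_complexes = 30, affinity = "similarity",
                       noise_sd = 0.3, seed = 42)
sim <- simulate_affinity_dataset(spec)
sim$dataset
#> <complex_dataset> 30 complexes, 75 chains, 30 with affinity labels

res <- loco_cv(sim$dataset, "kernel", kernel = "la",
               grid = list(C = c(1, 10, 100), epsilon = 0.1))
res
#> <loco_result> kernel/la/svr_precomputed | n = 30, RMSE = 2.764, Pearson r = 0.8316 (p = 1.25e-08)

glance(loco_cv(sim$dataset, "baseline"))
#> representation kernel model        n  rmse pearson_r  p_value
#> baseline       sw     homology    30 0.882     0.983 3.47e-22
```

`res` is a tidy result: `tidy(res)` gives per-complex observed/predicted ΔG
and absolute error, `glance(res)` the one-row summary, `autoplot(res)` the
observed-versus-predicted scatter. The RMSE is in kcal/mol; Pearson r
measures rank-free linear agreement, and its p-value comes from the t
transform with n − 2 degrees of freedom. Here the homology baseline wins
because the simulated affinities are by construction a function of sequence
identity — the regime the `similarity` generator is designed to produce.
Predicted ΔG converts to a dissociation constant with
`delta_g_to_kd(-9.2)` → `1.8e-07` M.

The same operations are scriptable from a shell through the installed
`exec/seqaffinity` dispatcher (`featurize`, `gram`, `train`, `predict`,
`loco`, `sweep`, `simulate`), driven by a YAML config.

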