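---
title: "Methods: sequence-only binding-affinity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-only binding-affinity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqaffinity)
```

## The problem and the model

`seqaffinity` estimates the binding free energy ΔG (kcal/mol) of a
protein–protein complex from chain sequences alone. A complex is the tuple
*c* = ((*l*, *r*), *y*): an ordered set of ligand chains, an ordered set of
receptor chains, and the label *y* = ΔG. The package treats prediction as
regression, *f*(*c*) ≈ *y*, with two families of complex representations
and three learner families behind one train/predict contract. The central
modelling assumptions are that (i) binding affinity carries enough signal
in global sequence properties or pairwise sequence similarity to be
learnable without structures, and (ii) a chain-level representation can be
lifted to complex level by simple averaging — features are averaged within
each side and concatenated ligand-first, kernels are averaged over chain
pairs.

ΔG and the dissociation constant interconvert as K_d = exp(ΔG/(R·T)) with
R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹ and T defaulting to 298.15 K (the standard
convention; the temperature of each measurement is not modelled). The
affinity range the package treats as plausible, −19 to −4 kcal/mol,
mirrors the span reported for the standard affinity benchmark; the unit is
taken to be kcal/mol, which that benchmark implies even where a table omits
the unit text.

## Chain descriptors

Five explicit descriptors are implemented:

* `aac` — raw residue counts (20 dims). Counts, not frequencies, are kept
  at chain level; the downstream per-sample unit-norm scaling makes the two
  equivalent up to a factor.
* `blosum` — mean over residues of the corresponding BLOSUM62 column
  (20 dims). The matrix comes from `Biostrings`.
* `pssm` — columnwise mean of a PSI-BLAST position-specific scoring matrix
  (20 dims). Profiles are consumed, never computed: the parser reads the
  `-out_ascii_pssm` layout. When no profile is supplied the BLOSUM62 column
  of each residue stands in for the profile row (flagged in metadata); this
  keeps the module testable offline at the cost of discarding
  evolutionary information.
* `protparam` — seven global physicochemical indices: average molecular
  weight (Da), aromaticity (fraction of F/W/Y), the Guruprasad dipeptide
  instability index, the isoelectric point (bisection on the
  Henderson–Hasselbalch net-charge function with Bjellqvist/ExPASy pKa
  values), and helix/turn/sheet residue fractions over the conventional
  VIYFWL / NPGS / EMAL sets. These are the standard published definitions;
  small numerical differences from other implementations (e.g. per-residue
  N-terminal pKa refinements) are expected and bounded by the published
  tables themselves.
* `composite` — the concatenation, in registry order, of amino-acid
  composition, normalized Moreau-Broto, Moran and Geary autocorrelations
  (eight AAindex scales, standardized to zero mean and unit population SD;
  max lag 30), CTD composition/transition/distribution descriptors over the
  seven standard three-class groupings, sequence-order-coupling numbers
  (max lag 30), quasi-sequence-order descriptors (weight 0.1) and type-I
  pseudo-amino-acid composition (λ = 30, w = 0.05). The total dimension is
  exposed by `composite_dimensions()` rather than hard-coded: behaviour,
  not a magic number, is the contract.

Two composite-set choices were genuinely open. First, the distance matrix
behind the sequence-order descriptors: published implementations use the
Schneider–Wrede and Grantham matrices, which are not available from any
package this build depends on and are too error-prone to transcribe by
hand; the package instead derives a physicochemical distance
d(i, j) = RMS difference of the eight standardized autocorrelation scales.
This preserves the construction (squared physicochemical distances summed
over lagged residue pairs) with a transparent, reproducible matrix. Second,
chains shorter than lag + 1 truncate their lag terms to length − 1 and
zero-pad, with a warning, so the descriptor dimension stays constant across
chains — short chains occur in synthetic fixtures even though curated
benchmarks exclude them.

Non-canonical residues are resolved before any featurization: B→D, Z→E,
U→C, O→K, and anything else (including X) becomes alanine with a warning.
Every featurizer and kernel requires the 20-letter alphabet, so the policy
is applied at parse time.

## String kernels

* **Smith–Waterman kernel** — the optimal affine-gap local-alignment score
  with BLOSUM62 and gap penalties 11 (opening) and 1 (extension); a gap of
  length L costs 11 + (L − 1). The empty alignment scores 0, so the kernel
  is non-negative.
* **Local-alignment kernel** — Σ_π exp(β·score(π)) over *all* local
  alignments, including the empty one (+1 term), computed by the standard
  five-state dynamic program entirely in log space (log-sum-exp), with the
  result returned in linear space and a documented overflow error beyond
  double range (`log = TRUE` avoids it). β defaults to 0.1; as β grows,
  (1/β)·log k_LA approaches the Smith–Waterman score, which the tests
  check at β = 20. Note that k_LA is *not* monotone in β in general — at
  small β the many negative-scoring alignments dominate the derivative —
  so monotonicity is only asserted in the β-range where the best positive
  alignment dominates.
* **(k, m)-mismatch kernel** — Σ_u N_a(u)·N_b(u) over the 20^k k-mer space,
  where N_x(u) counts k-mer positions of x within Hamming distance m of u.
  The 20^k space is never materialized: a k-mer pair at Hamming distance d
  contributes a fixed combinatorial count of shared neighbours, computed
  once per (k, m) by a small dynamic program, so the kernel is a sum over
  position pairs. Defaults k = 5, m = 3. The brute-force neighbourhood
  count is kept in the test suite as the oracle; with m = 0 the kernel
  reduces exactly to the spectrum kernel.

Alignment-score kernels need not satisfy Mercer's condition. Whenever a
training Gram matrix has a negative smallest eigenvalue λ_min, the package
replaces G by G − λ_min·I. The shift is applied uniformly to any kernel's
Gram (it is a no-op on an already-PSD matrix), computed on the training
fold only; test-complex cross rows are used as-is, since a diagonal shift
does not alter off-diagonal entries and test diagonal entries are never
consumed by prediction. The operation is idempotent by construction.

At complex level, K(c, c′) averages the chain kernel over all chain pairs
of the two complexes, reading the chain sets literally as ligand ∪ receptor
(|c| counts all chains). A `pairing = "matched"` option restricts averaging
to ligand–ligand and receptor–receptor pairs for users who want the sides
kept separate. Cosine normalization k(a,b)/√(k(a,a)k(b,b)) is available but
off by default.

## Regression and scaling

Feature representations are scaled per training fold: each sample (row) is
scaled to unit L2 norm, then each feature (column) standardized to zero
mean and unit SD using training statistics only; held-out rows are
transformed with the stored statistics, so no test information leaks.
Zero-norm rows skip the unit-norm division and constant columns get a unit
divisor. Two variants exist: `scaling = "standardize"` omits the unit-norm
step and `"none"` disables scaling. The variants matter for verification:
the unit-norm step is a sample-dependent (projective) transform, so a
response that is exactly affine in the raw features is no longer exactly
representable after it. The parameter-recovery checks therefore run the
affine `"standardize"` pipeline, in which noise-free linear ground truth is
recovered to numerical precision; the default pipeline keeps the unit-norm
step for real use.

The learners are ordinary least squares (minimum-norm solution via the SVD
pseudoinverse, well-defined on wide designs where descriptors outnumber
complexes), ε-insensitive SVR (`kernlab`; linear, RBF, or precomputed
complex Gram — the kernel representations are restricted to SVR, as
tree/OLS learners have no kernel form), and random-forest regression
(`ranger`, single-threaded with a fixed seed for reproducibility). An
eps-SVR whose training targets all fall inside the ε tube has no support
vectors; the package then returns the constant centre of the tube rather
than failing, which is the correct limit of the optimization.

Hyperparameters are selected by exhaustive grid search with seeded 5-fold
cross-validation inside the training fold, minimizing mean inner RMSE with
ties broken in grid order; the scaler is refit inside every inner split.
Default grids are standard log grids — C ∈ {0.01…1000},
ε ∈ {0.001…1}, γ ∈ {10⁻⁴…1} plus 1/d, 100–500 trees, minimum split sizes
{2, 5, 10} — and are configurable everywhere; singleton grids skip the
inner CV entirely.

## Evaluation

Leave-one-complex-out cross-validation fits scaler, grid search and model
on N − 1 complexes and predicts the held-out one, for every complex.
Chain features and Gram matrices are computed once up front — they involve
no affinity information — while everything that learns from labels is
refit per fold. Reported metrics are RMSE (kcal/mol) and Pearson r with a
two-sided p-value from the t transform with N − 2 degrees of freedom.
Zero-variance cases report r as `NA`, never 0, so degenerate runs cannot
masquerade as "no correlation" in comparison tables.

The sequence-homology baseline predicts a query's ΔG as the label of its
most similar training complex, with similarity the chain-pair-averaged
Smith–Waterman score (BLOSUM62, gaps 11/1) and ties broken in dataset
order. Averaging over chain pairs (rather than concatenating chains into
one super-sequence) keeps the baseline consistent with the kernel lifting
and avoids an arbitrary chain-order dependence.

## The synthetic generator

`simulate_affinity_dataset()` defines the study conditions for every test:

* **Chains** are uniform random 20-letter sequences (uniform residue usage
  maximizes k-mer coverage for kernel tests; a `natural` composition option
  uses average background frequencies). The default chain length is a fixed
  60 residues and complexes carry 1–2 chains per side. Fixing the length
  keeps composition features inside a fixed affine subspace, which makes
  the noise-free linear recovery regime exactly identified at the default
  n = 40; it is also long enough for every composite-descriptor lag.
* **Linear affinities** draw a random weight vector over the chosen complex
  descriptor and rescale it so the clean labels have mean −11.5 and SD
  2 kcal/mol while staying strictly inside the plausible range
  [−19, −4] — rescaling rather than clipping preserves exact linearity in
  the noise-free case. Gaussian noise of `noise_sd` kcal/mol (default 0)
  is then added and the final labels clipped as a guard.
* **Similarity affinities** mutate one of four anchor complexes per
  complex at a rate drawn from [0.05, 0.3] and set
  y = y_anchor + 8·rate, making affinity a smooth function of sequence
  identity — the regime in which a homology baseline must outperform the
  mean predictor, which the tests assert.

What the generator does *not* emulate: real secondary/tertiary structure,
interface-driven signal (affinity depends on all residues equally),
benchmark-scale label noise heterogeneity, homologous families with
conserved domains, or chain-length variation within a benchmark. Passing
tests therefore demonstrate that the machinery is correct and leakage-free,
not that any descriptor predicts real affinities well; real-data accuracy
must be established on a curated affinity benchmark, which is deliberately
not bundled.

Test problem sizes (n = 40 complexes for recovery, 120 for the noise
floor, 30 for baseline behaviour, 10 for the descriptor-by-model sweep)
were chosen as the smallest sizes at which each property is identified and
stable under the fixed seeds.

## Numerical choices and edge cases

* Log-sum-exp accumulation for the LA kernel; linear-space return values
  overflow-checked.
* Gap convention fixed as open + (L − 1)·extend and verified against an
  exhaustive alignment-enumeration oracle (all monotone sequences of
  aligned residue pairs), which also pins down the alignment set the LA
  kernel sums over.
* PSD correction threshold: any λ_min < 0 triggers the shift; corrected
  matrices are flagged so the operation short-circuits on repeat.
* Minimum-norm OLS tolerance: singular values below
  max(dim)·eps·σ_max are treated as zero.
* Grid-search ties break deterministically in grid order; fold assignment
  and forests are seeded; all commands honour a single `seed`.
* Inner fold counts exceeding the training size are reduced with a
  warning.

## Known limitations

PSSM profiles must be produced externally (running PSI-BLAST is out of
scope), the webserver-style deployment of the original method is replaced
by a local CLI, and the package ships no real benchmark data — the
acceptance script reports quantities computed on the synthetic study
conditions above, not reproductions of published benchmark tables.
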