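---
title: "Metric-learned brain fingerprints: model, simulator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-learned brain fingerprints: model, simulator and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A brain fingerprint is a feature vector derived from a person's
resting-state fMRI that is stable across that person's scans and distinct
from everyone else's, so that a scan can be attributed to its owner by a
nearest-neighbour search. Classical fingerprints use the functional
connectome (the region-by-region Pearson correlation matrix) and match
scans by correlating connectome vectors. `brainfp` implements a deep
metric-learning alternative: a windowed transformer encodes a parcellated
BOLD matrix (R regions × T time points) directly into an embedding vector,
and the encoder is trained so that same-subject embeddings are close and
different-subject embeddings are far under cosine distance.

## The encoder

Each time point's R-vector is linearly projected to an `embed_dim`-vector
(a *BOLD token*). The token sequence is divided into temporally
overlapping windows (`window_length` points, stride `window_stride`, plus
one right-aligned tail window whenever the strided windows leave trailing
time points uncovered, so the windows always tile `[0, T)`). Each window
carries a dedicated CLS token, initialised from a single shared learned
vector. Within a transformer block, the window's CLS token and its BOLD
tokens attend to the window's tokens plus `fringe_length` tokens of
context on each side; a learned positional encoding indexed by
within-window offset is added to token states when they are gathered into
a window (a token's offset differs between the overlapping windows it
belongs to, which is why the encoding cannot be applied once globally).
BOLD-token updates from overlapping windows are averaged (*token fusion*)
before a token-wise two-layer ReLU MLP. Both sub-layers are residual. We
deliberately omit layer normalisation: at the scales this package targets,
Adam training is stable without it, and the simplification keeps the
hand-derived backward pass compact enough to verify exhaustively against
finite differences (see `test-gradients.R`). After `n_blocks` blocks the
fingerprint is the arithmetic mean of the final CLS states, so its
dimension is independent of T — a scan of any length `T ≥ window_length`
(e.g. 1200 time points) can be encoded by the same parameters.

Fingerprints are *not* length-normalised at encode time; all comparisons
use cosine distance `d(u, v) = 1 − cos(u, v)`, which is scale-invariant,
so normalisation belongs to the distance, not the representation.
Per-region z-scoring of the input series is on by default and removes
amplitude nuisance.

Default desk-scale architecture: `embed_dim = 32`, `window_length = 20`,
`window_stride = 10`, `fringe_length = 10`, `n_blocks = 2`, `n_heads = 4`,
dropout 0.1. All are configuration fields; a full-scale configuration
(R = 219, `embed_dim = 200`, `n_blocks = 4`) is reachable by configuration
alone. The forward and backward passes are implemented in compiled code
(RcppArmadillo); everything else is plain R.

## Metric training

Training minimises the triplet margin loss
`L(a, p, n) = max{d(a,p) − d(a,n) + margin, 0}` with cosine distance,
where the anchor and positive are two runs of one subject and negatives
are all runs of the other subjects in the batch; both orderings of the run
pair serve as (anchor, positive). Batch loss is the mean over triplets
(the alternative, summing, only rescales the learning rate). The margin
defaults to 0.7 with a candidate grid `{0.3, 0.5, 0.7, 0.8, 0.9, 1.0}`
for validation-based selection (`select_margin()`). The optimizer is Adam
(default learning rate 1e-3 at desk scale, weight decay 0); parameters,
batching, and dropout all draw from one seeded stream, so a fit is exactly
reproducible. Checkpoints are retained per epoch. Subject-level hold-out
and group-conserved k-fold splits (`holdout_split()`,
`grouped_kfold_split()`) never split a group (site, family) across folds.

A model is trained per scan pairing: within-session models train on a
session's two runs, longitudinal models on run pairs spanning the
interval. This mirrors how identification is evaluated per interval.

## Identification and its metrics

`identify_subjects()` matches each target fingerprint to the
minimal-cosine-distance database entry, with replacement; exact ties break
to the lowest database index and are reported. Metrics:

- **SR** — fraction of targets assigned to their true subject;
- **CR** — mean same-subject distance over mean different-subject distance
  (lower is better);
- **SC** — mean silhouette over the pooled fingerprints of both runs with
  subjects as labels, under cosine distance; degenerate 0/0 cases score 0.

Both database/target directions are evaluated and reported separately.
Significance uses a permutation test: target identities are randomly
relabelled (10,000 times by default) with predictions held fixed, and the
p-value is the add-one estimator `(1 + #{null ≥ observed})/(1 + n)`,
which never returns 0. The connectome baseline implements the classical
protocol: vectorised upper-triangle FC correlated between runs, maximal
Pearson correlation wins.

## Interpretation

Token importance is the CLS-attention mass a token receives, summed over
blocks, heads and windows whose receptive field contains it and divided by
the number of covering windows. This is one of several defensible
attribution rules (rollout and gradient-weighted variants exist); it is
the package's canonical definition and is isolated behind
`token_importance()`. Per participant, the five most and five least
important tokens are labelled 1 and 0 and their z-scored R-vectors, pooled
across participants, train a 500-tree random forest; the normalised
impurity importances are the region weights `W` (non-negative, summing
to 1). Pooling across participants (rather than per-participant forests
averaged afterwards) is the implemented choice; with a common set of
variability-carrying regions the two agree in expectation and pooling uses
the data more efficiently.

Network structure is tested with pooled-variance two-sample t-tests on
`W`: each network against all other regions (df = n1 + n2 − 2, e.g. 217
for one network against the rest of a 219-region atlas) and the
higher-order association networks (default-mode, frontoparietal, ventral
attention) against the primary visual and somatomotor networks.

Annotation-map and gene-expression associations are Pearson correlations
with `W`, with significance from spatial-autocorrelation-preserving
surrogates: a random permutation of the map is smoothed with a Gaussian
kernel of the distance matrix, rank-remapped to the original value
multiset (so every surrogate has exactly the original values), and the
kernel scale plus a white-noise admixture are chosen per surrogate to
minimise the worst-bin relative discrepancy of the empirical variogram
(10 equal-count distance bins up to the 75th percentile of pairwise
distances — coarse enough for stable bin means at R = 60, fine enough to
resolve the autocorrelation decay). A zero-smoothing candidate is always
in the grid, so white-noise maps degrade gracefully to plain permutations
and the test stays calibrated. Annotation maps use two-sided surrogate
p-values with BH correction at q = 0.05; the gene screen is one-sided
(positive correlations only) at the lenient q = 0.1, reflecting the
strong dependence among expression profiles. True spherical "spin" tests
require surface geometry this package does not model; variogram matching
on centroid distances serves all map tests.

## Behavioural and genetic association

`fingerprint_regression()` fits ordinary least squares of a score on the
fingerprint coordinates and reports the overall F-test of the null that
all coefficients are zero, with (df1, df2) stated explicitly; collinear
columns are dropped with a warning. It requires more subjects than
fingerprint dimensions, so behavioural analyses are run at association
scale (n = 150, 16 dimensions in the bundled tests) rather than on the
30-subject identification cohort.

`kinship_distance_test()` compares cosine distances of genetically
related pairs (kinship coefficient > 0.5, first-degree) against
unrelated pairs with a pooled-variance two-sample t-test
(df = n1 + n2 − 2; 80 + 6,240 pairs give df 6,318). A negative t means
related pairs have the more similar fingerprints. The recommended
ordering, implemented in `run_pipeline()`, trains the encoder on
genomically unrelated subjects only and then tests the pairs — metric
training actively pushes the embeddings of subjects it has seen apart, so
including the related pairs in training would bias the contrast toward
zero or even positive t.

## The synthetic cohort simulator

No public generative description of individual fMRI variability exists,
so the simulator is a deliberately minimal model with controllable,
recoverable structure; every distributional choice below is a stand-in,
and passing tests demonstrate the machinery recovers *planted* structure,
not that real data behave this way. Each run is

`X = s_g · A S + s_f · v g' + s_t · B Z + E`

- **Group component** `A S`: a mixing matrix `A` (R × 5) shared by the
  whole cohort, times sinusoid-plus-noise temporal sources drawn fresh
  per run — common spatial covariance, not common time courses.
- **Subject signature** `v g'`: a rank-1 component. The spatial loading
  `v` lives on a cohort-level *signature mask* (fraction
  `signature_region_fraction`, default 0.4, of regions, drawn once with
  3:1 preference for the higher-order association networks, emulating
  where individual variability concentrates in vivo); each subject's
  loading values on the mask are Gaussian. The private temporal source
  `g` is *event-like*: sparse activations smoothed with an AR(1) kernel
  and scaled to unit variance. Burstiness matters: it makes the moments
  that carry identity information identifiable at the token level, which
  is what attention-based attribution quantifies.
- **State component** `B Z`: rank-3 per-run loadings times temporally
  smooth (AR(1), lag coefficient 0.95) sources. This models day-to-day
  state variability (arousal, drift): it reshapes run-to-run covariance —
  keeping connectome-based identification high but imperfect, as observed
  in developmental cohorts — without adding token-level energy spikes
  that would masquerade as signature events.
- **Noise** `E`: independent AR(1) series per region with lag-1
  autocorrelation `noise_ar1` (default 0.3) and unit marginal variance.

Default amplitudes `s_g = 1, s_f = 1.5, s_t = 2` were fixed at design
time so that the connectome baseline identifies roughly half to
three-quarters of 30 subjects within session — high but clearly below
ceiling, leaving headroom the trained encoder must earn.

**Longitudinal drift.** `drift_rate` is defined as the per-year
attenuation of signature *correlation*: at `y` years the loading is
`ρ v + sqrt(1 − ρ²) u` with `ρ = drift_rate^y` and a fresh masked
perturbation `u` per session. Signature energy is constant; only its
orientation decays, which yields the observed ordering of identification
quality (within-session ≥ 2-year ≥ 4-year) without confounding it with
signal strength.

**Kinship.** `kinship_pairs` disjoint pairs share a fraction
`kinship_share` of signature variance (`v = sqrt(share)·common +
sqrt(1−share)·private`) and a kinship coefficient drawn uniformly in
[0.5, 1]; all other pairs are unrelated with coefficient 0.

**Cognitive scores.** Scores load on the leading principal modes of
across-subject variation in the *expected* functional connectome, plus
unit Gaussian noise scaled by `cognitive_weight`. Two identifiability
facts force this design. First, the sign of `v` is unobservable (`v g'`
and `(−v)(−g)'` generate identical data), so any score linear in `v`
would be provably unrecoverable by any method; scores must load on even
functionals of `v`. Second, a random projection of the ~R²/2-dimensional
connectome pattern overlaps any fixed low-dimensional fingerprint only in
proportion to the dimension ratio, making it unrecoverable in practice;
loading the scores on the dominant connectome variation modes — as
empirical cognition-connectome associations do — makes the planted
association recoverable by a representation that captures how subjects
differ. `connectome_modes()` exposes these ground-truth mode coordinates
as the ideal noise-free fingerprint for calibration studies.

All draws flow from one seeded stream in fixed order: identical
configuration and seed reproduce the identical cohort byte for byte.

## Validation design and problem sizes

The bundled tests run at desk scale, chosen to exercise every code path
in minutes on one CPU core: identification cohorts of 30 subjects ×
60 regions × 375 time points × 3 sessions × 2 runs, ten training epochs,
five seeds; association analyses at n = 150 subjects with 16-dimensional
representations; 100–1,000 spatial surrogates; 10,000-draw permutation
nulls. Within-session identification by the trained encoder reaches
SR ≥ 0.9 and beats both its untrained initialisation and the connectome
baseline; a model trained on within-session pairs degrades monotonically
across 2- and 4-year analogue intervals (SR falls, CR rises, SC falls),
while per-interval models recover high SR at their own interval;
region-contribution weights rank the planted signature regions near the
top (ROC-AUC ≈ 1 at these settings, ≈ 0.5 under label shuffling).

What these numbers do *not* show: desk-scale training memorises the
training subjects rather than learning subject-generic features — true
zero-shot transfer to unseen individuals, which the full-scale method
achieves with cohorts three orders of magnitude larger, is out of reach
at these sizes. Validation checks therefore evaluate unseen *scans*
(later sessions) of known subjects, and the kinship analysis follows the
recommended filter-related → train → test ordering rather than relying on
zero-shot embeddings.

## Numerical choices and degenerate inputs

- Time indices are 0-based half-open `[start, stop)` in window slices;
  1-based inclusive indices appear only at R interfaces.
- Constant region series z-score to zero rows; in connectome features
  their correlations are set to 0 with a warning.
- Cosine distance errors on zero vectors rather than guessing.
- Exact distance ties in identification break to the lowest database
  index, deterministically, and are counted in the report.
- `stride = window_length` (zero overlap) is allowed with a warning;
  `stride > window_length` is an error (coverage would break).
- A silhouette sample whose subject has no second sample contributes 0
  with a warning; 0/0 silhouettes are 0.
- The permutation and surrogate p-values use add-one estimators and so
  are never exactly 0.
- TSV round-trips write 17 significant digits; the cohort container
  validates shape, region order and finiteness on read and reports all
  problems at once.

## Known limitations

- No hemodynamic forward model, motion artifacts, or site effects in the
  simulator; no NIfTI/CIFTI ingestion (parcellated matrices only).
- The encoder is a faithful-in-mechanism, reduced-scale windowed
  transformer; exact correspondence to any published architecture's
  internals is not claimed, and the attention-based importance rule is
  one defensible choice among several.
- Surrogate maps preserve isotropic autocorrelation summarised by the
  variogram; orientation-specific (anisotropic) structure of a map on the
  deterministic centroid lattice is not reproduced.
- Open-set identification (rejecting unknown subjects) and
  without-replacement assignment are out of scope.
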