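# brainfp — brain fingerprinting from parcellated fMRI by deep metric learning

Resting-state fMRI carries individual-specific functional architecture: a
scan can be attributed to its owner by comparing compact "brain
fingerprints" across sessions, even years apart. `brainfp` implements a
deep metric-learning fingerprinting framework for longitudinal,
parcellated BOLD data, together with the evaluation and interpretation
toolkit around it, and a fully seeded synthetic cohort simulator so that
every stage is testable without access-controlled imaging data.

The core is a windowed transformer encoder trained with a triplet
cosine-margin loss. Each R × T BOLD matrix (R parcellated regions,
T time points) is projected to a token sequence, divided into temporally
overlapping windows each carrying a dedicated CLS token, passed through
transformer blocks with windowed attention and token fusion, and averaged
over the final CLS states to give a fingerprint vector f(X). Training
minimises

    L(a, p, n) = max{ d(a, p) − d(a, n) + margin, 0 },
    d(u, v)    = 1 − cos(u, v),

where the anchor `a` and positive `p` are two runs of one subject and the
negatives `n` are all other subjects' runs in the batch. Identification
assigns each target fingerprint to the nearest database fingerprint
(with replacement) and is summarised by the success rate (SR), the
intra/inter-class distance ratio (CR, lower is better), and the
silhouette coefficient (SC), with significance from a 10,000-draw
permutation null and a classical connectome-correlation baseline for
comparison. Interpretation attributes fingerprints to time points via
CLS attention, converts token importance to region weights W with a
random-forest classifier, contrasts W across the seven canonical
resting-state networks, and tests annotation or gene-expression maps
against W under variogram-matching spatial surrogates with FDR control.
Association tools relate fingerprints to behaviour (overall regression
F-test) and to kinship (two-sample t-test on pairwise fingerprint
distances, related vs unrelated pairs).

## Worked example

```r
library(brainfp)

# a seeded longitudinal cohort: 30 subjects, 60 regions, 375 time points,
# 3 sessions (baseline, +2y, +4y) x 2 runs, planted subject signatures
cohort <- simulate_cohort(sim_config(seed = 1))

# train the metric encoder on the two baseline runs
model <- fit_fingerprint_model(cohort,
                               training = training_config(epochs = 10,
                                                          seed = 1))

# within-session identification: database = run 1, targets = run 2
db  <- fingerprints(model, cohort, "baseline", 1)
tgt <- fingerprints(model, cohort, "baseline", 2)
evaluate_identification(db, tgt, n_permutations = 10000, seed = 1)
#> Identification report (A->B, N = 30)
#>   SR = 0.967   CR = 0.086   SC = 0.721
#>   permutation null: max SR = 0.233, p = 9.999e-05 (10000 permutations)

# the classical connectome baseline on the same runs
connectome_baseline(session_runs(cohort, "baseline", 1),
                    session_runs(cohort, "baseline", 2))$SR
#> [1] 0.7333333
```

The trained encoder identifies 29 of 30 subjects within session
(SR 0.967), far beyond the permutation ceiling (best of 10,000 shuffled
nulls: 0.233, p ≈ 1e-4) and above the connectome baseline (0.733).
CR ≈ 0.09 says same-subject fingerprints are about ten times closer than
different-subject ones; SC ≈ 0.72 indicates tight, well-separated
subject clusters. Region attribution then recovers the planted
signature-carrying regions:

```r
runs <- session_runs(cohort, "baseline", 1)
imp  <- lapply(runs, function(x) token_importance(model, x))
W    <- region_contribution(runs, imp, seed = 1)
roc_auc(W, cohort$truth$signature_mask)
#> [1] 0.9976852
```

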