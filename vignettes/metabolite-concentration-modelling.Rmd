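---
title: "Modelling intracellular metabolite concentrations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intracellular metabolite concentrations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metaconc` predicts the negative base-10 logarithm of intracellular
metabolite concentration (−logC, concentration in mol/L) in micro-organisms
from molecular, metabolic-network and pathway descriptors. This vignette
explains the model, its assumptions, the tunable parameters, the
synthetic-data generator used for testing, and the design decisions taken
where the procedure admitted more than one reasonable reading.

## The response and the data model

The modelled response is Y = −log₁₀C with C a positive molar concentration;
a 1 mM metabolite has Y = 3. The unit of every RMSE and ε parameter below is
therefore a log₁₀-fold change: an RMSE of 0.7 means typical predictions are
off by a factor ≈ 5 in concentration. One record is a metabolite × organism
pair; a compound measured in two organisms contributes two records that share
molecular and pathway descriptors but carry organism-specific network
topology. `metabolite_dataset()` enforces positivity, the consistency of C
and −logC (tolerance 1e−9), and uniqueness of metabolite × organism keys.

Two train/test split strategies exist. `split_random()` draws the training
records uniformly; it is deliberately unstratified by organism, since nothing
in the modelling procedure conditions on organism beyond the topology
columns. `split_non_overlap()` forces all records of the same metabolite onto
one side, killing train/test leakage through cross-organism duplicates; whole
id-groups are assigned greedily in descending size order to whichever side
has the larger remaining deficit, with the seed shuffling equal-sized groups.
The greedy rule is our choice — any assignment satisfying the grouping
constraint is admissible — and it reaches the target train size exactly
whenever group sizes permit.

## Network topology descriptors

The metabolic network is metabolite-centric: nodes are metabolites, and an
undirected edge links a substrate–product reactant pair. Reconstruction
applies two screening criteria: pairs whose pathway annotation does not
intersect the organism's pathway set are removed, and pairs involving a
compound with an unspecified residue (a generic "R" group in the formula)
are removed. The surviving graph is simple — parallel reactions collapse to
one edge, self-pairs yield none. Reaction directionality and stoichiometry
are deliberately out of scope; the descriptors derived are purely
topological.

Per node we compute *Degree* (neighbour count n) and the
*Clustering-Coefficient*, 2·e/(n(n−1)) with e the number of edges among the
n neighbours — a proxy for the density of biochemical reactions around the
metabolite. For degree 0 or 1 the formula is undefined; we define CC = 0
there, the NetworkAnalyzer convention. Metabolites present in the dataset
but absent from the network get Degree 0 and CC 0 with a warning: treating
missing as "no observed reaction neighbourhood" keeps the feature matrix
complete without imputation magic.

No currency-metabolite filtering (ATP, H₂O, …) is applied beyond what the
reactant-pair convention already encodes; if the pair table follows that
convention, currency-mediated shortcuts are already absent.

## Pathway variables and the MPF descriptor

Each pathway contributes a 0/1 membership column. Binary columns that are
near-constant carry almost no contrast, so besides the global variance
filters the preprocessing drops pathway columns whose minority class holds
fewer than `pathway_min_minority` records (default 2 — "at least two
metabolites must differ").

After variable selection, all surviving pathway columns are collapsed into a
single binary **MPF** descriptor — their element-wise OR — and the model is
refit on the collapsed set. Defining MPF only after selection resolves the
chicken-and-egg ordering (MPF is defined by the selected pathway variables,
but selection needs the candidate variables to exist): selection sees the
individual pathway columns, the final model sees one aggregate membership
flag.

## Preprocessing

Descriptors that are constant over the dataset are dropped (typically atom-
or fragment-count descriptors for atom types absent from every molecule), as
are descriptors with sample standard deviation (n−1 denominator) below
0.001. Missing molecular-descriptor cells are a hard error by default;
`missing = "impute"` mean-imputes with a warning carrying the count. Features
enter the SVR unscaled by default; an optional z-scoring switch exists and
its use is recorded in the run manifest, because RBF-kernel distances are
scale-sensitive and the choice must be reproducible.

## Variable selection

The selection objective is the leave-one-out RMSE of a regressor restricted
to the candidate subset. Two fitness engines are available via
`fitness_regressor()`:

* `"ridge"` (default): linear ridge regression (penalty 1e−6, intercept
  unpenalized) with the exact closed-form LOO residuals eᵢ/(1−hᵢᵢ). One
  evaluation costs a single k×k solve, which is what makes a
  population×generations×rounds GA affordable; with an effectively
  unregularized linear fit, LOO-RMSE ranks subsets by out-of-sample linear
  signal, which is the quantity the selection stage needs.
* `"svr"`: the same ε-SVR used downstream, evaluated by an explicit n-refit
  LOO loop — exact but roughly n× the cost per evaluation; available when
  fitness and final model must share one engine.

Because the default fitness engine (ridge) differs from the evaluation engine
(SVR) used in the reported trace, the hill-climb stage can improve its own
objective while the SVR-evaluated trace metrics move slightly the other way;
the trace makes both visible rather than hiding the disagreement.

The **GA** uses fixed-length bit-vector chromosomes over the current pool.
Defaults follow the published protocol of this model family: population 100,
100 generations, bit-flip mutation 0.01, three chained rounds (each round's
pool is the previous round's selected subset). The remaining operators are
standard generational-GA equivalents, all config-exposed: tournament
selection of size 2, uniform crossover at rate 0.8, single-elite carryover,
and initial bits drawn Bernoulli(0.4) so initial subsets average ~40% of the
pool. Pool shrinkage across rounds emerges from fitness alone — no quota
forces a particular size. With elitism, the best-so-far fitness is provably
non-increasing per generation, which the tests assert.

The **add/remove optimization** is steepest-descent hill climbing: each
iteration evaluates every single-descriptor deletion and every addition from
the full preprocessed pool, and accepts the best move only if it *strictly*
lowers the LOO RMSE, stopping at a local minimum. Steepest descent is chosen
over first-improvement because it is deterministic given the data. Ties on
equal RMSE prefer the smaller subset, then the lexicographically earlier
descriptor name. The tests verify local optimality against exhaustive
one-move neighbourhoods, and against full 2ᵏ−1 subset enumeration on small
pools.

## The regression model

The final model is ε-SVR with Gaussian RBF kernel exp{−γ|μ−ν|²}, fit with
`kernlab` (`ksvm`, `type = "eps-svr"`); γ maps directly onto kernlab's
`sigma`. Reference parameter values for this model family are γ = 0.01,
ε = 0.20 (in −logC units), C = 11; the default grid brackets them
(γ ∈ {0.001, 0.01, 0.1, 1}, ε ∈ {0.05, 0.1, 0.2, 0.4}, C ∈ {1, 11, 100})
and is fully overridable, since the "default ranges" of any particular
grid-search tool are not canonical. Grid search minimizes LOO or seeded
10-fold RMSE; ties break toward smaller cost, then smaller γ, then smaller
ε (preferring the smoother, less complex model). When every training
residual fits inside the ε tube the SVR optimum has no support vectors;
`svr_fit()` represents this degenerate solution explicitly as the flat model
predicting the training mean.

Validation metrics: R² is the squared Pearson correlation of observed vs
predicted (the standard QSAR reading, distinct from Q²);
Q² = 1 − Σ(Y−Ŷ)²/Σ(Y−Ȳ)² on the assembled out-of-fold prediction vector,
computed once per scheme, and may be negative. For the external test set the
denominator uses the test-set mean by default (`q2_test_reference =
"train"` switches to the training-mean convention; the choice is recorded).
10-fold folds are a seeded random permutation, sizes as equal as
divisibility allows. `repeated_trials()` reports mean ± sd of every metric
over re-splits (default 20 trials).

## Applicability domain

Leverage hᵢ = xᵢᵀ(XᵀX)⁻¹xᵢ is computed against the raw selected-descriptor
training matrix, with no appended intercept column (the hat-matrix formula
as used here has none); test-sample leverage is computed against the
training X, the standard practice. The control threshold is h\* = 3k/n. The
standardized residual is the raw residual divided by the RMSE of the
training residuals — a definition chosen so the ±3 band has its usual
reading — and a sample is in-domain iff h ≤ h\* and |standardized residual|
≤ 3. A singular XᵀX is a hard error naming the collinear columns, because
leverages under rank deficiency are not interpretable; a pseudo-inverse
diagnostic mode exists but is never the default. Full-rank training
leverages sum to k, which the tests assert to 1e−8.

## The synthetic-data generator

`generate_synthetic()` creates a complete, self-consistent study:

* 130 records by default — 93 in one organism, 37 in another, 15 metabolites
  shared — matching the scale of the experimental datasets this model family
  is built on;
* 50 molecular descriptor columns (one named `ClogP`), jointly Gaussian with
  a random correlation structure (Cholesky of a random SPD matrix, mixing
  weight 0.3) so that collinearity stresses variable selection realistically;
* per-organism Erdős–Rényi (default) or Barabási–Albert networks at mean
  degree 4, typical of metabolite-centric reaction graphs;
* Bernoulli pathway memberships over 20 pathways, with 3 designated
  MPF-like pathways at low membership rate carrying a −0.8 offset on −logC:
  members sit almost an order of magnitude above the baseline concentration,
  mirroring the deviation story that motivates the MPF descriptor;
* the generative link −logC = 3.57 + Xβ + t·CC + o·MPFtrue + N(0, 0.2),
  with a sparse β over 5 named informative descriptors (ClogP carrying a
  positive coefficient: polarity correlates with concentration), topology
  effect t = −0.5, and intercept 3.57 (the overall mean −logC of the
  experimental datasets). Noise sd 0.2 makes the planted signal strong but
  not trivial for a 50-descriptor pool.

The generator exposes the exact per-record linear predictor, so its
"analytic" mean and R² (= var(signal)/(var(signal)+σ²), conditional on the
drawn descriptors) are exact quantities the tests can compare against
empirical estimates.

What the generator does **not** emulate: real descriptor physics (no
molecular structures), heavy-tailed concentration distributions, measurement
error correlated across organisms, and directed or stoichiometric network
structure. Passing tests therefore demonstrate that the pipeline's machinery
is correct and recovers known sparse signals under realistic collinearity —
not that any particular predictive accuracy will transfer to experimental
data.

## Problem sizes and determinism

The examples, tests and the acceptance script run at desk scale chosen to
exercise every code path comfortably on a single CPU: selection studies use
n = 120 records with a 50-descriptor pool and a reduced GA budget
(population 40, 40 generations, 3 rounds — the full default budget is
population 100 × 100 generations), oracle comparisons use 12–30 row
fixtures where exhaustive enumeration is feasible, and the end-to-end
pipeline examples use the generator's default 130-record study. Every source
of randomness flows from explicit integer seeds; the pipeline derives
per-stage seeds from the master seed, restores the caller's RNG state, and
writes reports with fixed 15-significant-digit formatting so identical
configurations reproduce identical bytes. The run manifest records seeds,
input-file hashes and counts.

## Known limitations

* The GA explores a 2ᵖ space stochastically; different seeds can select
  different, similarly-fitting subsets when descriptors are strongly
  correlated. The selection trace makes the path auditable but not unique.
* LOO-RMSE fitness with the ridge engine measures *linear* out-of-sample
  signal; a descriptor whose effect is purely non-linear could be
  under-selected relative to the SVR fitness engine.
* The leverage-based domain assumes the selected-descriptor cloud is roughly
  ellipsoidal; it cannot flag interpolation gaps inside the cloud.
* When both split strategies are requested, the strategy comparison refits
  and revalidates on each split but reuses the variable subset selected
  under the primary strategy, so it isolates the split effect on model
  performance rather than re-running the full selection per strategy.
* Network reconstruction depends entirely on the supplied reactant-pair
  annotation; no attempt is made to reproduce any particular reaction
  database snapshot.
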