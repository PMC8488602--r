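---
title: "Methods: transcriptome-constrained regularized FBA and multi-omic feature extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-constrained regularized FBA and multi-omic feature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicflux)
```

# The modeling problem

Flux balance analysis predicts steady-state reaction rates *v* of a
genome-scale metabolic model by solving a linear program over
S·v = 0, lb ≤ v ≤ ub, maximizing an objective reaction. Two difficulties
motivate this package's design. First, plain FBA solutions are rarely unique:
alternate optima make downstream statistics irreproducible across solvers.
Second, a single stoichiometric model cannot distinguish growth conditions;
condition specificity has to come from data — here, transcriptomic fold
changes and per-condition exchange bounds.

`omicflux` addresses both: a lexicographic three-level solve (primary
objective, then secondary objective, then minimal squared 2-norm) whose last
level is strictly convex and therefore has a unique optimizer, and a
valve-style expression integration that rescales each reaction's bounds by a
logarithmic function of its expression level.

# Expression integration

## From RPKM to gene values

Transcript abundance enters as RPKM tables with three standard-control
replicate columns. Fold changes are condition ÷ mean(controls), centered
around 1 so transcript and flux features live on a common dimensionless scale
after fusion. Gene identifiers in models often carry a transcript suffix
(".1"); matching to dataset identifiers strips exactly one terminal
`.<digit>` — multi-digit suffixes are left intact because they fall outside
the stated pattern. Genes without a measurement keep the neutral value 1, and
the gene value vector is rebuilt from scratch for every condition, so values
can never leak from one condition into the next.

## GPR evaluation

Reaction expression levels θ are computed from boolean gene–protein–reaction
rules with AND → min (a complex is limited by its scarcest subunit) and
OR → max (isozymes substitute). AND binds tighter than OR, and source
parentheses are honored. The implementation uses a real tokenizer and
recursive-descent parser rather than the string-substitution approach of
older pipelines (which must substitute gene names longest-first to avoid
prefix corruption); the parser eliminates that class of bugs while keeping
identical semantics, and `genes_by_length` is retained only as a
compatibility field. Empty rules evaluate to the constant 1.

## The valve function

Bounds are rescaled by

$$\phi(\theta) = (1 + \gamma\,|\log\theta|)^{\operatorname{sgn}(\theta-1)}$$

with the natural logarithm (the printed formula leaves the base unstated;
natural log makes φ(e) = 1 + γ exactly and is the convention of the valve
family this map belongs to). Properties that the test suite pins down:
φ(1) = 1 (identity configuration changes nothing), φ(θ)·φ(1/θ) = 1
(symmetric up/down regulation), monotone in θ. At θ = 0 the printed formula
diverges; we define φ = 0 below a floor (`theta_floor`, default 1e−12),
silencing the reaction — the continuous limit. γ (default 1) is exposed
everywhere; negative lower bounds scale in magnitude with their sign
preserved, since φ multiplies both limits.

# Condition bounds and the photon budget

Each growth condition overrides a small set of exchange-reaction bounds
(carbon source, nitrogen source, sulfate, iron, O2, photons). The packaged
table (`inst/extdata/condition_bounds.csv`) carries 24 conditions — 23
experimental plus the standard control — with the published magnitudes:
photon lower bound −0.065 in the standard control, −0.003 in darkness,
−0.234 under high light; glycerol −10 under mixotrophy; nitrate −12 when the
medium is supplemented with 12 mM nitrate; O2 capped at −0.01 (forced
residual uptake) under anoxia. One rendering ambiguity deserves note: the
low-CO2 row parses cleanly as CO2 lb = −0.01 with glycerol 0 once one
observes that the glycerol column is 0 in every non-mixotrophic row, so the
packaged table carries the full row. Photon bounds can also be derived from
first principles as P_U = LC·SA/DCW (light consumption × illuminated surface
area ÷ dry cell weight), exposed as `photon_uptake_rate()` and as the
`photon` field of a condition spec.

# The optimization stack

## Lexicographic regularized FBA

Level 1 maximizes the primary objective flux (biomass). Level 2 maximizes
the secondary objective (ATP maintenance or a photosystem reaction) with the
primary held at its optimum. Level 3 minimizes Σv² with both held. Fixing is
implemented as a one-sided cut v ≥ opt − 1e−9·max(1, |opt|) rather than a
hard equality: the optimal value is attained only on a boundary face that
generally has no strict interior inside the bound box (the photon exchange
sits exactly at its lower bound at the growth optimum), which breaks
active-set and interior-point methods alike, while by optimality the flux
cannot exceed `opt`, so the cut is effectively two-sided at tolerance 1e−9.

## Solvers

No linear-programming package is available in the supported environment, so
linear subproblems are solved by a dense Mehrotra predictor–corrector
primal–dual interior-point method implemented in the package. The Newton
system is solved in augmented (quasi-definite) form with pivoted LU — the
normal-equation form loses the primal residual when degenerate bound
intervals spread the scaling diagonal over ~18 orders of magnitude.
Infeasibility is certified by an elastic phase-1 solve (minimal total
constraint violation over slack variables); bound reversals (lb > ub) are
rejected directly; formerly infinite bounds are capped at ±1e6, and an LP
optimum parked at such a cap is reported as unbounded. The strictly convex
norm-2 level goes through `quadprog` (Goldfarb–Idnani) on an orthonormal
null-space parametrization of the equality constraints, with the
interior-point method (unit diagonal Hessian) as fallback. The test suite
checks both routes against `scipy.optimize.linprog` (HiGHS) and a SLSQP
minimum-norm solve as independent oracles, to 1e−5 per flux.

## FVA

Flux variability analysis constrains only the primary objective (at
`opt_fraction` of its optimum, an equality-strength cut at 1.0), mirroring
the single-objective signature of the reference variability routine; whether
the secondary objective should also constrain the polytope is unstated in the
protocol and we resolve it by excluding it. Reported min/max values are the
per-reaction LP optima (unique), so the 2-norm resolution affects only which
vector attains them; `mean_flux` is their midpoint.

## Post-processing

Fluxes are recorded as absolute values and entries ≤ 1e−4 (inclusive, the
solver-tolerance convention) are zeroed. The threshold is exposed because the
right cutoff is model-dependent — users are advised to scan thresholds
upward from the solver tolerance until results stabilize.

# Multi-omic fusion

Flux fold changes divide each condition row by the standard-control row.
Order matters and is frozen as: record the largest finite fold change
(treating Inf as 0, ignoring NaN); recompute ratios; zero entries ≤ 1e−4;
NaN (0/0: a reaction off everywhere) → 1 (interpreted as "unchanged"); Inf
(flux appearing where the control had none) → the recorded maximum. The
fused matrix appends an all-ones row for the standard control. Transcript
fold changes are deliberately *not* thresholded — the asymmetry is part of
the protocol and is preserved. A zero control mean in transcripts (not
addressed by the protocol) adopts the same NaN/Inf policy for consistency.
The transcript-only PCA matrix excludes the control row by default (matching
the 23-row reference layout) with a flag to include it.

# Statistical and machine-learning stages

**PCA** is pinned to the conventions of the reference multivariate stack:
population-variance standardization, eigenvalues of the correlation matrix
(summing to the number of retained variables), contributions
100·coord²/eigenvalue summing to 100 per component, cos² summing to 1 per
individual. Constant columns (a flux identical across conditions) carry no
direction and are dropped with a warning — the spec leaves this open and
erroring would make real flux matrices unusable. Pathway aggregation sums
and averages the first two components' contributions over subsystem members,
counting multi-membership reactions once per subsystem.

**Clustering** keeps the protocol's deliberate asymmetry: the silhouette scan
(k = 2…30 by default) uses correlation distance on z-scored profiles, while
the final k-means uses city-block distance. City-block centroids are updated
with per-coordinate medians — the actual minimizer of within-cluster L1
distance — with the reference tool's mean update available as a
compatibility mode. Five random restarts, explicit seeds. The 2-D embedding
minimizes squared stress by gradient descent from a seeded random start;
degenerate configurations (co-located points) trigger the scalar-retry
(×1.01, up to 10 times) robustness device.

**LASSO** fits the α = 1 path over 100 penalties from λ_max down to
λ_max·1e−4 (the reference tool's defaults; the grid is passed to `glmnet`
explicitly so the all-zero head of the path is guaranteed). The mean
predictor coefficient averages each predictor's coefficients across the whole
path, zeros included, matching the reference code; averaging only nonzero
coefficients (the prose reading) is available as `nonzero_only = TRUE`.
Retention keeps |MPC| > 0.01, sorted descending. Zero-variance predictors
are excluded from the fit and reported as 0: a constant column carries no
information, and standardizing it is numerically undefined.

**Correlation** reports per-feature Pearson r, a two-sided p from the t
statistic with n−2 degrees of freedom, and a 95% CI via Fisher z ± 1.96/√(n−3).
Pathway-level aggregation zeroes NaN coefficients, averages |r| per
subsystem, and counts signed r in seven half-open bins [−0.7,−0.5) …
[0.5,0.7); values outside that range land in an explicit overflow count
rather than disappearing.

# The synthetic world

`make_toy_model()` builds a 14-metabolite, 22-reaction photoautotroph-like
network: photon exchange feeding photosystem II (ATP + O2) and photosystem I
(NADPH), carbon fixation, glycerol assimilation (for the mixotrophic
condition), urease (for the urea condition), nitrogen assimilation, two
parallel identical glycolytic steps (so the L2 tie-break is observable), a
respiratory oxidase that can absorb forced O2 uptake under anoxia, biomass,
and ATP maintenance. GPR rules include one parenthesized rule and one
unparenthesized AND-before-OR rule; subsystem annotations include raw
synonyms and one multi-subsystem name so the curation steps operate on
realistic input. Baseline exchange bounds equal the standard-control row of
the packaged table.

`make_synthetic_transcriptome()` emulates the two-study layout: dataset 1
with 16 conditions, dataset 2 with 7, each with 3 control replicates. Values
are baseline × condition effect × lognormal noise with coefficient of
variation 0.1 (lognormal for RPKM-like positivity). Default effects are
fixed once from the biology of each condition: photosystem genes ×0.25 in
darkness and ×2 under high light, glycerol kinase ×4 under mixotrophy,
nitrate assimilation ×3 under N limitation and ×0.5 with reduced nitrogen.
What a green test on this world establishes is pipeline correctness —
recovery of planted effects, policy fidelity, solver agreement with oracles —
not biological validity on any real organism; real data add batch effects,
dispersion heterogeneity and model-curation error that the generator
deliberately omits.

The LASSO recovery suite deserves its own note. With 50 *independent*
standard-normal noise predictors and n = 12 observations, the noise columns
span the entire sample space and exact support recovery fails in roughly a
third of random seeds for any LASSO implementation — the property is not
identifiable in that world. The packaged fixture therefore draws the noise
predictors from 5 latent co-expression-like modules plus idiosyncratic noise
(sd 0.2), the regime actual omics features occupy, under which the three
planted predictors are recovered with correct signs in ≥95 of 100 seeds.

# Numerical choices and degenerate inputs

* Solver feasibility/optimality tolerances: 1e−10 relative inside the
  interior-point iteration, 1e−6 on the returned solution; objective fixing
  tolerance 1e−9 relative.
* Flux and flux-fold-change zeroing threshold: 1e−4, inclusive, exposed.
* θ floor 1e−12 (silencing); γ default 1.
* Subsystem splitting uses a case-insensitive word-boundary match on "and",
  so names like "Island" are never cut; protected multi-word names are
  rewritten with "&" first; empty fragments are dropped (generalizing the
  reference's manual deletion of two blank cells).
* Ties in top-k correlation selection break by feature identifier;
  clustering, MDS and the transcriptome generator take explicit seeds and
  restore the caller's RNG state.
* Reactions with lb = ub are handled by widening the interval by 1e−10 for
  the interior-point iterates only.

# Known limitations

The solver stack is dense and sized for networks of up to a few hundred
reactions; genome-scale models (thousands of reactions) would need a sparse
LP backend. Batch correction between transcriptome studies is out of scope
(fold changes are computed within-study against each study's own controls).
Loopless FBA, thermodynamic and resource-allocation constraints are not
implemented. The SBML reader covers Level 3 core plus flux bounds and gene
associations as used here; exotic SBML constructs (species references with
math, external parameter rules) are not supported — the toy-table format is
the tested interchange for fixtures.
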