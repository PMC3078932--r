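---
title: "Divergence dating with divtime: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence dating with divtime: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtime)
```

`divtime` estimates node ages on a fixed, rooted, strictly bifurcating
topology. This vignette is the package's own account of the model it fits,
the priors and their parameterizations, the numerical decisions underneath,
and what the synthetic-data tests do and do not establish about real data.

## The model

Time is measured in Ma before present; tips are contemporaneous at age 0 and
every internal node is strictly older than its children. The data are a
partitioned nucleotide alignment; `-` and `?` are treated as fully missing,
IUPAC ambiguity codes as partial information (a conditional-likelihood vector
with ones for every compatible state), which extracts more signal than
discarding ambiguous cells.

**Likelihood.** Felsenstein pruning per partition, with site-pattern
compression keyed on (pattern, partition) and per-node rescaling when the
largest partial drops below 1e-100, so deep trees stay in floating-point
range. The expected substitutions on the branch above node `b` in partition
`p` are `r_b (t_parent − t_b) c_p`: the per-branch clock rate times the time
span times the partition's relative rate. Substitution models are K80, HKY,
TVM and GTR (exchangeabilities in AC, AG, AT, CG, CT, GT order, GT = 1 as
reference; TVM ties AG = CT), optionally with discrete-gamma rate
heterogeneity and a proportion of invariant sites. Transition probabilities
come from the spectral decomposition of the reversible generator via the
`diag(√π) Q diag(1/√π)` symmetrization; rows are clipped at zero and
renormalized, which bounds round-off at ~1e-15 and avoids a separate
series-expansion path for near-degenerate eigenvalues. The generator is
normalized so one unit of branch length is one expected substitution per site
*after* averaging over the gamma categories and the invariant class — i.e.
division by `(1 − p_inv)` times the base rate — so branch lengths keep their
meaning as models change.

**Gamma discretization** uses k = 4 equal-probability categories with the
category rate equal to the conditional mean of its band (computed from the
incomplete-gamma identity, then renormalized to mean exactly 1). Four
categories is the conventional accuracy/cost point; k is a model argument.

**Partition scheme.** Loci are declared as (range, genome, codon phase); the
`paper_scheme` rule pools codon positions 1+2 and separates position 3 within
each genome, giving up to four model-bearing groups with defaults HKY+I+Γ
(mt 1+2), TVM+Γ (mt 3), K80+I+Γ (nuc 1+2), GTR+Γ (nuc 3). The BIC selection
this mirrors named models for nuclear positions 1 and 3 but not 2; we pool
nuclear 1+2 under the position-1 model, mirroring the stated mitochondrial
pooling. The assignment is a configurable default, not a claim about the
original selection. Per-partition relative rates are constrained to mean 1
weighted by partition length, which keeps the clock mean identifiable.

## Priors

**Relaxed clock.** Branch rates are iid lognormal, parameterized by the
real-space mean `M` (substitutions/site/Myr) and log-space sd `S`
(`meanlog = log M − S²/2`). The real-space-mean convention matches how rate
magnitudes are reported and makes `M` directly comparable across `S` values.
Rates are continuous per branch (no rate-category discretization). `S = 0`
is the strict clock; a floor of 1e-6 on `S` keeps the density finite in that
degenerate limit.

**Tree prior.** The conditioned reconstructed birth-death process with
complete sampling and a uniform prior on the origin, parameterized by net
diversification `r = λ − μ > 0` and relative extinction `a = μ/λ ∈ [0, 1)`.
Under this process the `n − 1` node ages are iid with density
`g(t) = r(1−a)e^{−rt}/(1−a e^{−rt})²` and CDF `(1−e^{−rt})/(1−a e^{−rt})`;
the package evaluates the joint log density over the ranked age vector,
`log((n−1)!) + Σ log g(t_i)`, which reduces to the Yule closed form at
`a = 0` and integrates to 1 (verified by quadrature at n = 3). The same
`g` drives the tree simulator — inverse-CDF draws for the ages, a uniformly
chosen extant lineage split for the ranked topology — so the generative and
inferential measures coincide by construction. Hyperpriors default to
`r ~ Lognormal(log 0.1, 1)` and `a ~ U(0, 1)`; the source analysis states no
hyperpriors, so these are deliberately diffuse and exposed in the
configuration.

**Calibrations.** Three density kinds on MRCA ages: uniform (hard bounds),
lognormal with offset (hard lower bound at the fossil age, soft upper tail),
normal (soft both sides, for geological/vicariance constraints). `-Inf` is a
value, not an error. Calibration clades must be monophyletic in the input
topology; a violation is reported by name. Calibrations multiply the
birth-death prior without a conditioning correction — the common practical
choice, and an approximation worth stating: the product is not exactly the
conditional birth-death density given the calibrated ages.

The packaged A–J constraint set carries the published hard bounds exactly
(e.g. B ≥ 55.8 Ma, J uniform 32.25–56.0 Ma, E normal with central 95%
interval 98.2–121.8 Ma). The lognormal *shape* parameters of the fossil
calibrations were not published in the text we model; the fixture defaults to
`sdlog = 0.75` with the 95% quantile placed 50% above each hard bound. Both
are flagged as defaults in the fixture and configurable; they do not affect
the hard bounds.

## The sampler

Metropolis–Hastings with fixed (non-adaptive) proposal tuning. Operators:

- uniform slide of an internal node age within (oldest child, parent) —
  bounds depend only on other nodes, so the move is symmetric;
- root-age scale (multiplier `f^U(−1,1)`, Hastings `+log u`);
- likelihood-invariant *exchange* moves: slide an internal node age (or
  scale the root age) and counter-adjust the three (two) adjacent branch
  rates so every branch's expected substitutions stay fixed; the Hastings
  term is the Jacobian of the rate map. These walk along the age–rate
  ridge that otherwise dominates the posterior autocorrelation, at the
  cost of a prior evaluation only;
- log-space slide on a single branch rate (Hastings `log(r'/r)`);
- multiplicative scales on `M`, `S`, `r` (and, when substitution parameters
  are sampled, on `α`, `κ`/exchangeabilities, with a logit slide on `p_inv`);
- uniform slide on `a` with rejection outside [0, 1);
- whole-tree age scale with matching branch-rate counter-scale (Jacobian
  `u^{(n−1)−(2n−2)}`, i.e. Hastings `(1−n) log u`), which moves the time
  scale without touching the likelihood;
- a pairwise exchange on relative rates that preserves the weighted mean.

Default weights are proportional to the number of parameters each operator
touches. The published analysis "optimized operators according to preliminary
runs" without stating the mix; ours makes no claim to match. Likelihood
recomputation is skipped for moves that only touch priors, and restricted to
the affected partition for substitution-parameter moves.

Substitution-model parameters are *fixed* at their configured values by
default (`estimate_substitution = FALSE`): at desk scale the focus is the
clock and the calibrations, fixing the nuisance parameters roughly halves
runtime, and every test that checks ages is then conditionally exact. One
flag turns sampling on.

Starting ages come from interval constraint propagation: hard calibration
bounds flow root-ward (lower) and tip-ward (upper) along the topology, the
joint window is checked for emptiness (an empty window means the calibration
set admits no tree at all and is reported as such), and nodes are placed
bottom-up at their preferred age clamped into the window. Replicate `i` is
seeded with `seed + i`; identical seeds give byte-identical traces.

**Convergence reporting.** ESS uses the truncated autocorrelation sum with
Geyer's initial-positive-sequence rule, capped at N; a constant series is
reported as N with a warning. The burn-in default is 10%, matching the
published 2M-of-20M discard. The ESS gate *warns* (never fails) below a
threshold of 200 — the published gate of >1200 came from ~400M combined
generations; 200 is a floor that desk-scale chains can meet, and the
threshold is configurable. HPD intervals are the shortest window of sorted
samples whose endpoints enclose `ceiling(level·N)` samples (the convention
that makes samples 1..100 at level 0.95 give the 96-value window).

## Cross-validation of calibrations

Round 1 relaxes each calibration in turn and estimates its node's age from
all others; the relaxed constraint is scored by *concordance* — the fraction
of posterior samples inside its central 95% prior interval (hard bounds
as-is for uniform; 2.5/97.5% quantiles otherwise). The published analysis
judged prior–posterior fit visually; a numeric score needed a threshold, and
we use 0.5: a constraint is kept when at least half the posterior mass is
compatible with it. The midpoint is transparent, symmetric between the "fits"
and "does not fit" readings, and configurable. Calibrations below threshold
are excluded; excluded ones are re-scored against a run under the reduced set
and re-included when they now fit — necessary because one genuinely bad
constraint can drag a neighbouring node's estimate far enough to make a good
constraint look bad (the re-inclusion in the worked README example is
exactly this). When nothing at all survives round 1 — a single gross
violation can drag every node — only the single worst scorer is excluded, so
the re-inclusion rounds have an anchored run to re-score against. Rounds
iterate to a fixed point or `max_rounds`; decisions are monotone within a
round, so the procedure terminates.

## The synthetic-data generator

`simulate_scenario()` mirrors the shape of the motivating dataset at reduced
size: 12 taxa (against 83), six loci — two fast "mitochondrial", four slow
"nuclear", relative rates 3:1 normalized to weighted mean 1 — of 300 bp each
(against 4599 bp total), 6.5% missing data matching the reported fraction,
clock mean 0.02 substitutions/site/Myr with log-sd 0.3 (a plausible fish
mitochondrial/nuclear blend), birth-death `r = 0.08`, `a = 0.2`, and 4–6
calibrations, optionally one deliberately biased: its hard lower bound is
placed 50% *above* the true node age, emulating a misassigned fossil. When a
hard-capped ancestor would leave no room above a planted bad bound, the
ancestor's cap is widened so the joint support stays non-empty — the planted
scenario must remain runnable to be diagnosable. Calibration nodes are drawn
from reasonably deep nodes (at least 15% of the root age by default):
fossil and biogeographic constraints bound major divergences, and sequence
data carry essentially no information about very recent splits, so
calibrating a near-present node would be both unrealistic and untestable.
Truth tables (ages, rates, parameters) are written alongside the data.

What passing these tests shows: the sampler targets the exact posterior of
the model (prior-only Kolmogorov–Smirnov keystone), the estimator is
well-calibrated when the model is true (HPD coverage), and the
cross-validation detects gross calibration violations (planted-outlier
exclusion at ≥90%). What they do not show: robustness to model violations
real data carry — alignment error, among-site rate correlation, saturated
third positions, non-lognormal rate variation, incomplete taxon sampling
(the birth-death prior here assumes complete sampling) — nor anything about
topology, which is an input.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are chosen to keep the
whole battery in the tens of minutes on one CPU: prior-only keystone chains
of 2×100k generations on two-taxon trees, 50 coverage replicates of 8 taxa ×
500 bp with 4k-generation chains, and 20 cross-validation replicates of the
default 12-taxon × 1800 bp scenario with 5k-generation inner chains. These
are stated as the package's test conditions; production analyses should
scale chain lengths up until replicate traces agree and ESS values are
comfortably above the warning threshold.

One property of the cross-validation deserves a direct statement. The
planted grossly-misdated constraint is excluded essentially always — that
detection is the procedure's purpose and it is robust. Retaining *every*
truth-consistent constraint in a replicate is harder at this data scale:
the concordance score of a consistent calibration is the posterior mass
inside its central 95% prior interval, and when 1800 bp leave the relaxed
node's posterior wider than (or displaced from) a tight prior interval, a
perfectly consistent constraint can score near or below the midpoint
threshold. In our replicates individual consistent calibrations survive at
roughly 90–95%, while the all-five-survive-per-replicate rate sits nearer
60–75%. This is a sensitivity limit of desk-scale data, not of the
procedure: the score definition and threshold are kept as specified rather
than widened to mask it, and the corresponding acceptance expectation is
allowed to fail visibly at this scale.

The harmonic-mean marginal-likelihood estimator is shipped because it is the
classic trace-based route to Bayes factors, with a bootstrap SE attached —
and with the standard caveat that it is upward-biased and high-variance;
treat the SE as a lower bound and prefer path-sampling methods where the
comparison matters. Bayes factors are reported on the log10 scale with the
conventional bands ("very strong" above 2).

## Known limitations

Fixed topology (no tree search, no topology moves); contemporaneous tips
only; complete-sampling birth-death (no ρ < 1 variant); no exponential
calibration kind; no adaptive operator tuning; harmonic-mean-only marginal
likelihoods. The node-age prior multiplies calibrations without a
conditioning correction, as noted above.
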