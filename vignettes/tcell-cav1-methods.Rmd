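---
title: "Modeling CAV1 signaling in CD4+ T-cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CAV1 signaling in CD4+ T-cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellsim)
```

This vignette documents the modeling choices behind `tcellsim`: the update
semantics, the environment and genotype machinery, the curated reference
model, the exact verification oracle, the downstream expression pipeline,
and the places where the design was genuinely open and a choice had to be
made.

## The simulation semantics

Each node of a logical network is binary. The update step is
*semi-synchronous*:

1. every **external** node is resampled independently, ON with probability
   `level/100` — its *activity level* in `[0, 100]` is the only continuous
   quantity in the model;
2. every **internal** node evaluates its Boolean rule on the *current*
   state (synchronous update);
3. perturbations override the result: knocked-out nodes are clamped to 0,
   *forced* nodes are resampled ON with probability `forced_level/100`,
   bypassing their rule entirely.

A simulation runs 800 iterations from a drawn initial state and reports
each node's activity as its %-ON over the final 300 iterations; an
experiment aggregates 1,000 such simulations, redrawing the environment
each time. These defaults are the study protocol this package implements
and are what `sim_config()` and `run_experiment()` use unless told
otherwise.

Why this scheme? Per-iteration Bernoulli resampling of the inputs is what
turns a Boolean model into a dose–response machine: downstream activities
become smooth, monotone functions of the input levels, which is exactly
the behaviour the validation sweeps probe. Two points were genuinely open:

* **Synchronous vs asynchronous internal update.** We use synchronous
  update. It is deterministic given the stochastic input layer, cheap, and
  sufficient for activity-level (time-average) readouts; asynchronous
  schemes matter mostly when attractor identity, not occupancy frequency,
  is the question.
* **Resampling vs holding the environment within a simulation.** Default
  is per-iteration resampling; `sim_config(env_resample = "fixed")` holds
  each input at its initial draw for the whole simulation. Every result in
  this package uses the default.
* **Forced activation semantics.** A forced node ignores its upstream rule
  completely (it does *not* OR with it): the activator construct exists
  precisely to control the node independently of its regulators. The
  heterozygote is forcing at level 50; "random activation" redraws the
  forced level uniformly in `[0, 100]` per simulation.
* **Initial states.** Internal nodes start ON with probability 1/2
  (`random_uniform`), biasing toward no attractor; `all_off` and `fixed`
  are available. The trailing-window readout makes results insensitive to
  this choice for ergodic-ish networks, which stochastic input resampling
  strongly encourages.

Determinism: all randomness flows through R's RNG (the C++ stepper uses
the same stream), so a seed fixes the full trajectory bit-for-bit.
Experiments derive simulation `i`'s seed as `base_seed + i`.

## The exact oracle

Under these semantics the successor state factorises: internal non-forced
nodes are deterministic functions of the current state; external and
forced nodes are independent Bernoulli draws. `stationary_oracle()`
exploits this to propagate the exact state distribution in `O(2^n)` per
iteration (pooling probability mass by the deterministic-bit signature,
then multiplying by the stochastic-bit product measure), and returns the
exact expectation of the activity profile. It is the independent
correctness anchor for the engine: on 20 seeded random networks of 5–8
nodes, 1,000-simulation Monte-Carlo means agree with it to well under 1
activity point (the suite enforces ±2).

For these equivalence checks we fix one interior environment per network
and start from the all-OFF state. With a deterministic initial state both
sides share the initial distribution trivially and across-simulation
variance comes only from the stochastic environment; under random initial
states a multi-attractor network can have across-simulation SD near 50
points, which no 1,000-simulation mean matches to ±2. Both policies are
exercised elsewhere in the suite.

## Environments and genotypes

`build_environment()` returns the per-stimulus activity categories of
three tissue conditions — wild type and two immunosuppressive disease
milieus (disease A: broadly elevated suppressive stimuli; disease B:
IL-10 varied over its full range) — over 29 stimuli. Categories map to
levels two ways:

* **randomized** (default for experiments): uniform draw per simulation
  from the category subrange — `Zero = {0}`, `Low = [0, 33.3]`,
  `Med = [33.3, 66.7]`, `MedHigh = [50, 83.3]`, `High = [66.7, 100]`,
  `FullRange = [0, 100]`;
* **fixed** (used as the dose–response background):
  `Zero = 0, Low = 25, Med = 50, MedHigh = 75, High = 90,
  FullRange = 50`.

The category subranges are a design choice: they reconcile qualitative
condition tables with a protocol of levels drawn randomly between 0
and 100. Both modes are first-class; whether the random draws should
respect the categories or range freely is not decidable from qualitative
descriptions alone, so neither mode claims to be *the* original
procedure. Inputs a network has that the table does not cover (the GalphaQ
ligand, the CAV1 activator) default to 0. The Gα12/13 ligand is called
`Alpha_13L` in the condition table and `Galpha12_13_L` in the network; the
environment spec carries that mapping.

Ranking (`rank_most_affected()`) uses the signed difference of mean
activities against the same-environment WT baseline, top-k by absolute
shift, lexicographic tie-break. A ratio-based ranking was rejected because
exact-zero baselines (clamped nodes) occur by construction.

Dose–response sweeps hold all non-swept inputs at the wild-type fixed-mode
background — single-variable sweeps need a reproducible, non-saturating
background, and the wild-type condition is the natural one.

## The reference model

`build_reference_model()` returns a 70-node network (39 internal, 31
environment inputs) encoding, one edge per established qualitative
relationship: CAV1-dependent TCR-proximal signaling (LCK, FYN, and the
ZAP70–LAT–GRB2/SHC1–SOS chain it gates), the KSR1-scaffolded RAF/MEK/ERK
cascade with integrin co-dependence, the CARMA1–BCL10–MALT1–NF-κB branch
(IL-10-suppressed, with NOS2A as a CAV1-requiring target), CAV1 restraint
of CD26, BCL10, RAC1 and GATA3 (so knockout de-represses them), and a
CAV1-independent CD28→PI3K→AKT axis. Stimuli that do not gate any of
these phenotypes enter two aggregate milieu readouts so that every input
is referenced and validation is clean.

This is a deliberately small, fully quotable model, *not* a
reconstruction of any larger unpublished rule set; its purpose is to make
the pipeline's qualitative claims testable:

* all six validation sweeps (APC→ERK, ECM→F-actin, GalphaQ→PI3K,
  ECM→MAPK, IL2→MAPK, Gα12/13→Cdc42) are monotone with Spearman ρ ≥ 0.9
  (in practice ρ = 1);
* knockout shifts each of CD26, CARMA1, FYN, SHC1, SOS, SHP2, NOS2A,
  BCL10, GRB2 by ≥ 10 activity points in *all three* tissue conditions,
  while CD28 moves < 5;
* the heterozygote holds CAV1 at 50 ± 1 over an experiment.

One modeling tension worth recording: in knockout settings BCL10 behaves
as CAV1-restrained (up on knockout), while in leukemic expression cohorts
BCL10 co-varies *positively* with CAV1. The logical model encodes the
knockout direction; the expression pipeline (below) handles cohort
correlations separately and plants the positive value there. The two
claims live at different biological levels and are not forced to agree.

The model is frozen: `reference_model_digest()` must equal the stored
constant, and the shipped rule file and SBML-qual copy under
`inst/extdata/` are digest-checked in the suite. SBML-qual export uses the
Boolean dialect (`maxLevel = 1`, MathML `and/or/not/eq` function terms,
default term 0, externals as transition-less species).

## Expression pipeline

`compute_fold_change()` takes log2 ratios of group means against the
control group (log2 because it is symmetric around 0 and standard for
clustering microarray-style data; the control is the denominator, not a
column). Clustering is agglomerative average linkage (UPGMA over original
items) on `1 − uncentered correlation` — cosine similarity, the Cluster
3.0 metric — with a deterministic lowest-item-index tie-break, and
`.cdt`/`.gtr` export loadable in Java TreeView. "Pearson regression" is
implemented as the product-moment correlation of each gene's fold-change
profile against the reference gene (CAV1) across subtype columns, with
slope/intercept emitted for completeness; per-subtype-mean profiles
without a healthy column are the correlation columns.

`generate_synthetic_foldchange()` stands in for a patient cohort: gene
`g` is `r_g·z + sqrt(1 − r_g²)·ε` against a standard-normal reference
profile `z`, so the population correlation is exactly the planted `r_g`.
With 100 columns, 20-seed mean recoveries land within ±0.1 of every
planted value and per-seed rank agreement with the planted ordering
exceeds 0.9. With only 4 subtype columns — the width of a realistic
cohort design — the per-seed sampling SD of a correlation is ~0.3–0.5, so
the pipeline runs and reports values at that width but the package makes
*no accuracy claim there*; that caveat is printed by the analysis script
itself.

What the generator does not emulate: within-subtype patient replicates,
gene–gene correlation beyond the single planted factor, heavy-tailed
intensity noise, and normalisation artefacts. Passing recovery tests
therefore shows the estimator and ranking machinery are correct, not that
4-column cohort correlations are reliable.

## Problem sizes and numerical notes

The shipped analyses use: 20 random networks × 1,000 simulations for
oracle equivalence; 1,000-simulation experiments for the genotype screens;
11-point grids × 30 replicates for the six sweeps; 20 seeds × 100 columns
for recovery — a few minutes total on one CPU, with the stepping loop in
C++ (rules precompiled to per-node truth tables, capped at 16 regulators).
Degenerate inputs are handled explicitly: constant truth tables are
representable in the rule grammar via tautology/contradiction forms;
zero-norm rows are rejected by the cosine metric; clamped nodes yield
exact zeros (no tolerance); Spearman scores use average ranks on ties.

## Known limitations

* Boolean-only semantics: no multi-valued levels, no kinetics; "50%
  activity" means 50% occupancy of the ON state, not half-maximal
  concentration.
* The reference model is a curated miniature; rankings beyond its curated
  scope (e.g. exact top-15 orderings of a much larger model) are out of
  reach by design.
* The exact oracle is limited to 12 nodes (4,096 states); above that only
  Monte-Carlo estimates are available.
* Blood-tissue conditions are not modelled, and the expression module
  performs no normalisation or differential-expression testing — it
  consumes already-normalised matrices.
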