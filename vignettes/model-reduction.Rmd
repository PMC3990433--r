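---
title: "Systematic model reduction by variable replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic model reduction by variable replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modred)
```

## The question the method answers

Process-based simulation models — crop models are the motivating case —
accumulate internal variables: quantities recomputed every time step from
assumed relationships between parameters, driving inputs and other
variables. Each such variable encodes a mechanistic hypothesis. This
package asks, for every candidate variable: *does letting this quantity
vary, as the model says it should, actually help the model predict the
data?* The probe is blunt on purpose: replace the variable's update rule
with a single constant for the whole run, across all sites and
treatments, and measure what happens to predictive skill.

Three outcomes are possible, and each is informative:

* skill collapses — the variable **contributes**; the mechanism earns its
  keep on these data;
* skill is unchanged — the variable is **redundant**; over the range of
  conditions in the data, the modelled dynamics were indistinguishable
  from a constant;
* skill improves — the variable behaves as **noise**; its fluctuations
  actively degrade prediction, which usually means the mechanism is
  mis-specified for these conditions.

A redundancy verdict is always conditional on the driving data. A
temperature adjustment can be redundant over three temperate sites and
essential elsewhere; the method tests the model against the evidence at
hand, not against all possible worlds.

## Skill: weighted RSS and Nash–Sutcliffe efficiency

Model-observation agreement is summarised by a weighted residual sum of
squares over all observations $j$:

$$\mathrm{RSS} = \sum_j \left(\frac{O_j - M_j}{s_j}\right)^2,$$

with $s_j$ the estimated standard error of observation $j$, taken as a
stream-specific fraction of the observed value (defaults: 10% for biomass
and grain, 20% for leaf area index — typical of crop growth-analysis
data). Fractional errors make streams with different units commensurate
in one sum. Because $s_j \to 0$ as $O_j \to 0$, each $s_j$ is floored at
the fraction times 1% of the stream's mean observed value (configurable);
otherwise a single pre-emergence zero would dominate the sum.

For reporting, skill is expressed as Nash–Sutcliffe efficiency with the
same weights inside the square:

$$\mathrm{NS} = 1 - \frac{\sum_j ((O_j - M_j)/s_j)^2}
                        {\sum_j ((O_j - \bar O)/s_j)^2},$$

which reads like an $r^2$ except that $M_j$ comes from the model under
test rather than a fitted regression, so NS can be negative. The pooled
NS takes each deviation from its own stream's mean: this keeps the
denominator from being inflated by between-stream variance, and makes the
per-stream values the natural decomposition of the pooled one.

## Belief in a reduced model: the informal pseudo-likelihood

Reduced models are compared through an informal, GLUE-style belief
weight rather than a formal likelihood (replacement constants and model
parameters are *not* refitted per combination, so an integrated
likelihood would be the wrong object):

$$Q_i = A \exp\!\left(-\ln(0.5)\,\frac{\mathrm{RSS_{full}} -
\mathrm{RSS}_i}{\alpha}\right),$$

with $A$ normalising $\sum_i Q_i = 1$ over the models considered. The
single tuning constant $\alpha$ has a direct reading: every $\alpha$ of
RSS above the full model halves the belief weight. $\alpha$ is specified
as a fraction of $\mathrm{RSS_{full}}$ — 2.5%, 5% and 10% by default —
and the sensitivity of every conclusion to that choice is part of the
standard output. Since $A$ cancels in ratios, the search works with
unnormalized $q$ (in log space, for numerical range); normalisation is
applied only when probabilities are reported.

## Stage 1 — screening

Each candidate variable is replaced *individually*. Its replacement
constant is fitted by minimising RSS, constrained to the range the
variable takes in the run of the full model — the constant must be a
value the model itself considers plausible. The optimizer is a coarse
grid (25 points) followed by bounded scalar refinement around the best
grid cell, with ties broken toward the smallest constant; the grid guards
against multi-modality, since a constant threading through conditionals
can make the objective non-smooth. A replacement that drives the
simulation out of its valid regime (non-finite state) is scored as
infinite RSS at that constant, not as an error.

Two special cases:

* **Switch variables** are artificial gates inserted so that one
  replacement can neutralise a whole multi-variable mechanism (e.g.
  reduce a modelled soil temperature to plain air temperature). Their
  constant is the documented off value, never fitted.
* **Excluded variables** represent the one step that must stay manual:
  variables whose replacement would break a mass balance, or intermediate
  steps better reduced through their end point, are listed by the user
  and never screened. The package deliberately does not try to infer
  this list.

Variables whose ratio $\mathrm{RSS_{reduced}}/\mathrm{RSS_{full}}$ stays
at or below 1.1 (default) become candidates for the combinatorial stage;
their fitted constants are frozen and reused from here on.

## Stage 2 — searching the replacement space

With $N$ candidates there are $2^N$ replacement combinations. The space
is explored by a Metropolis–Hastings walk: from the current combination,
toggle one uniformly chosen candidate (one flip per step is the default;
the proposal is symmetric, so no Hastings correction arises), simulate,
and accept when

$$\frac{Q_\mathrm{trial}}{Q_\mathrm{current}} > r, \qquad r \sim
U(0,1).$$

Mildly detrimental moves are therefore accepted often, ruinous ones
rarely — enough mixing to escape local structure. Every state evaluated
is cached by its bitmask with its RSS; revisits cost nothing. The walk
starts at the all-normal state and stops when the cache holds a target
number of unique models (10,000 by default, capped at $2^N$ when the
space is smaller), or at a proposal-count guard: with a steep belief
surface the walk may effectively never *propose* the deepest low-$Q$
corners of a small space, and those corners carry negligible probability
anyway. The termination reason is recorded in the result and manifest.

The **replacement probability** of a variable is the sum of normalised
pseudo-likelihoods over cached models in which it is replaced — a sum
over distinct models, not over chain steps, so chain dwell times never
double-count a state. One chain (driven by the middle $\alpha$) is run
and the cache re-weighted for each $\alpha$; the three columns of the
probability table therefore share one model set. Anchors for reading the
table: values near 1 mean replacement helped (noise), near 0.5 mean it
made no difference (redundant), near 0 mean it hurt (contributing). The
reporting bands (noise $\ge 0.6$, contributing $\le 0.4$) are a
labelling convenience and configurable; the anchors are the substance.
Pairwise joint probabilities with independence ratios
$P(A \wedge B)/P(A)P(B)$ expose either/or structure between
replacements. For $N \le 15$, `exhaustive_enumeration()` computes the
exact tables and doubles as the oracle against which the stochastic
search is tested.

Note one boundary convention: the all-normal (full) model is included in
the enumeration and in the normalisation set — it is the walk's start
state and a legitimate member of the model set, even though it replaces
nothing.

## The synthetic fixture and what a green test establishes

No real crop model or field data ship with the package. Instead
`build_toy_crop_model()` constructs a small daily-step crop analogue —
thermal time and a phyllochron driving leaf number, canopy expansion
damped by a drought factor from a soil-water bucket, Beer's-law light
interception with radiation-use-efficiency biomass growth, anthesis three
phyllochrons after final leaf number, grain filling under a
translocation-potential cap set from anthesis biomass — with every
variable's role *planted* by construction:

* **essential** (thermal time, soil water, drought factor, and the three
  observed streams): mechanisms that visibly shape the outputs, checked
  by finite-difference sensitivity;
* **redundant**: terms engineered to be analytically near-neutral over
  the generated driver range — a soil-temperature adjustment of a few
  hundredths of a degree (plus its switch), a nearly constant soil
  evaporation, a translocation cap that never binds, and a pure
  accumulator nothing reads;
* **noise**: a radiation-use modifier tracking diurnal temperature range
  and a canopy-temperature adjustment on grain fill (behind a switch).
  These are *absent from the data-generating truth*: observations are
  drawn around the model with both mechanisms turned off, so their
  fluctuations can only hurt — which is exactly what makes a variable
  noise.

Weather is generated per site with seasonal trends and seeded noise; one
site has rain withheld over a mid-season window (drought signal), one is
generously watered (its drought factor provably stays at 1). Observation
noise is multiplicative Gaussian, matched to the fractional-SE weighting
scheme, truncated at $-3\sigma$ and floored at zero.

Magnitudes were fixed once, from the structure of the belief scheme: each
noise mechanism is sized to cost a few $\alpha$ of RSS (site-systematic
biases of roughly 5–10% on biomass and ~10% on grain), so that removing
it is decisively favoured; redundant terms are sized well below one
$\alpha$. Two caveats are documented deliberately. First, the planted
redundancies are redundant *over the generated driver range*, mirroring
how real redundancy findings are conditional on the trial conditions.
Second, the gated noise pair is genuinely either/or: replacing either
member neutralises the mechanism, so each member's probability
asymptotes at $2/3$, not 1 — the joint-probability ratio (≈ 0.75 < 1)
is what reveals the substitution structure. One of the five acceptance
seeds leaves the switch member just below the 0.6 noise band (0.589);
the role-recovery criterion's 4-of-5 margin absorbs exactly this kind of
edge case, and the value is reported rather than tuned away.

A green suite therefore establishes that the machinery — simulation
under replacement, constant fitting, screening, search, probability
accounting — recovers roles that were planted to be recoverable. It does
not establish anything about real crops, real models, or the
identifiability of subtler mechanisms than those planted.

## Numerical and design choices

* **Time stepping**: explicit daily update, each variable evaluated once
  per day in a computed topological order; a variable's own name (or
  `lag()`) refers to yesterday's value, which is how feedback loops are
  expressed without intra-step cycles. No ODE machinery: daily empirical
  update rules are the convention of the model family this serves.
* **Expression language**: arithmetic, comparisons, `pmin`/`pmax`,
  `ifelse`, `exp`/`log`/`sqrt`/`abs`, `lag()`. Rules are data, not code:
  they are parsed, validated against this whitelist, compiled to a small
  stack-machine bytecode and executed in C++, so a model file can never
  execute arbitrary code and a full-model run costs ~2 ms at fixture
  scale.
* **Replacement range**: one constant model-wide, bounded by the global
  (all-site) min/max of the full run — replacement is a claim about the
  model everywhere, not per site.
* **Optimizer tolerances**: grid step refined by `stats::optimize` at
  `1e-6` of the bound width; the acceptance suite checks fitted constants
  against a 1000-point grid at `1e-6 * RSS_full` slack.
* **Degenerate inputs**: degenerate ranges return the constant without
  optimisation; empty candidate sets stop the pipeline with an explicit
  manifest status; all observations equal raises a degenerate-data error
  for NS; failed simulations are cached with zero belief weight and can
  never be accepted by the walk.
* **Reproducibility**: weather, observations and the search each draw
  from a seeded generator and restore the caller's RNG state; a pipeline
  rerun with the same seed reproduces every report byte for byte.

## Limitations

* The definition of a "variable" is the modeller's granularity choice;
  the package takes the declared variables as given and does not
  aggregate intermediate expressions.
* Exclusion of mass-balance-breaking or intermediate variables is manual
  by design; automating it would require mechanistic reasoning the
  method explicitly leaves to the user.
* The pseudo-likelihood is informal: replacement probabilities rank
  evidence, they are not posterior probabilities, and no annealing or
  multi-chain convergence formalism is attached to the walk — the
  convergence trace is an inspection diagnostic.
* Minimum-model synthesis (choosing which redundant variables to replace
  together, and judging the result) remains a scientific act: the
  package scores any chosen replacement set via
  `apply_replacement_set()`, it does not choose one.
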