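---
title: "Fuzzy hierarchical screening of anti-cancer metabolic targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy hierarchical screening of anti-cancer metabolic targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

A good metabolic drug target should do three things at once: kill the cancer
cell, spare the healthy cell, and perturb healthy metabolism as little as
possible. `actd` scores candidate interventions — enzyme knockouts or
modulations, and antimetabolites that block a metabolite's synthesis — against
all three goals simultaneously, on a *pair* of constraint-based metabolic
models: a cancer model (CA) whose phenotype is growth, and a healthy
counterpart (HT) whose phenotype is ATP regeneration.

Four fuzzy goals are evaluated for every candidate:

1. **Mortality** — the treated CA cell's growth rate and ATP production should
   both approach zero.
2. **Viability** — the perturbed HT cell should not proliferate, but its ATP
   production should stay near its unperturbed maximum.
3. **Dissimilarity from the cancer template** — the perturbed HT flux pattern
   should not look like cancer metabolism.
4. **Similarity to the healthy template** — it should still look like healthy
   metabolism.

Goals 3 and 4 together are the *metabolic deviation* score: a proxy for side
effects that most synthetic-lethality screens ignore.

## Inner problems: FBA then a uniform flux distribution

Each model is flux-split: every reaction `j` contributes nonnegative forward
and backward variables with `v_j = v_f,j − v_b,j`, so regulation can address
the two directions separately. For a given intervention the package solves,
per model:

* an **FBA linear program** — maximize biomass (CA) or ATP (HT) subject to
  steady state `N(v_f − v_b) = 0` and the (regulated) bounds; and
* a **UFD quadratic program** — minimize
  `Σ_k c_k (v_f,k² + v_b,k²)` over internal (non-exchange) reactions subject
  to the same constraints plus a floor pinning the FBA objective at its
  optimum.

The UFD stage makes the reported flux pattern unique and biased toward
low-confidence reactions carrying little flux: the weights `c_k ∈
{1/4, 1/2, 3/4, 1}` come from expression data (high, medium, negative, other
confidence; reactions without gene association get 1). The floor uses the
exact FBA optimum by default (`floor_fraction = 1`, configurable).

Whether exchange fluxes belong inside the quadratic penalty is genuinely open;
this implementation excludes them (internal reactions only), because
penalizing exchanges would distort uptake/secretion scaling rather than
resolve alternate internal optima. They still satisfy all constraints.

## Regulation semantics

A target table (`regulation_targets()`) holds `(target, mode, δ)` with
`δ ∈ [0,1]`. For an enzyme target, every reaction it catalyzes gets new
bounds; `δ` interpolates between the basal template flux (`δ = 0`) and the
hard bound (`δ = 1`):

* **down**: `v_f ∈ [LB, (1−δ)·basal + δ·LB]`, with the backward direction
  opened symmetrically;
* **up**: `v_f ∈ [(1−δ)·basal + δ·UB, UB]`, backward capped at basal;
* **knockout**: both directions fixed at zero —

*unless* the reaction remains covered by another isozyme after the targeted
enzymes are removed, in which case its flux is pinned to the basal window
`[(1−ε)·basal, (1+ε)·basal]` in both directions, with `ε = 0.03` by default.
The window also applies to buffered down-regulation. Metabolite-centric
regulation rescales or zeroes every *producing* direction of the target
species (forward for positive stoichiometric coefficients, backward for
reversible consumers) — a knockout is the antimetabolite model of synthesis
inhibition.

Two semantic points deserve emphasis because they interact:

* **Redundant enzymes** (identical reaction sets) are collapsed to one
  representative after rule expansion; regulating the representative regulates
  the whole group. Consequently a reaction is *isozyme-buffered* only when an
  enzyme with a *different* reaction set still covers it — two isozymes that
  are everywhere interchangeable are one regulation unit, not a buffer.
* Overlapping targets compose by interval intersection. An empty intersection
  (or a knockout on a reaction with a forced minimum flux) marks the scheme
  infeasible; the candidate is kept and ranked, not dropped.

Infeasible inner problems — lethal or incoherent perturbations — map to the
all-zero flux state with status recorded. Zero flux means full mortality
credit on the CA side and zero ATP credit on the HT side, which is exactly the
ranking a screen needs for lethal candidates.

## Membership grades and aggregation

All memberships are linear ramps clamped to `[0, 1]`. Minimization goals use a
descending ramp from `LB` to `UB`; maximization goals the ascending mirror;
template comparisons use a two-sided tent that peaks at the standard level
`ST` taken from a template flux and falls to zero at `ST ± w`. Dissimilarity
is the exact complement of similarity per element.

Grade vectors are pooled with the **mean–min operator** `(mean + min)/2`,
which separates vectors with equal means but different spreads; the final
hierarchical objective is

```
η_D = (η_TR + min{η_TR, η_CV, η_MD}) / 2,
```

so mortality is the first priority and the worst remaining grade the second;
`η_D ≤ η_TR` always.

Defaults that the source method leaves to the user, chosen here once:

* **Ramp bounds for mortality/viability.** `LB = 0` and `UB =` the
  *unperturbed FBA maximum* of the relevant objective (biomass and ATP maxima
  are both recorded in each template). Using the UFD template value instead
  would be degenerate: the UFD stage pins the ATP demand at its maintenance
  floor, so treated and template values would coincide and the ATP ramp would
  collapse to a step.
* **Two-sided specs.** `ST` is the template value; the half-width is
  `w = max(α·|ST|, w_min)` with `α = 1` and `w_min = 0.1 ×` the median
  nonzero template magnitude, so ramps are scale-aware and never degenerate.
  `LB` is clamped at zero for quantities that cannot go negative.
* **Comparison universe.** Internal reactions present in both models (net
  fluxes) and base metabolites present in both models (compartment-pooled
  flow rates), keeping elements with a nonzero value in at least one
  template; all-zero elements carry no signal. Per-element grades are pooled
  by the arithmetic mean within each of the four classes.
* **Flow rates.** Production of metabolite `m` pools, across compartments,
  positive coefficients times forward fluxes *minus* negative coefficients
  times backward fluxes — the literal algebra, under which reverse flux
  through a consumer counts as production (`|N|·v_b`). Flow rates are
  therefore nonnegative.
* **Gene groups to confidence classes.** Expression quantiles (25/50/75th of
  detected genes, configurable) split genes into not-detected/low/medium/high;
  rules propagate AND = least-confident gene, OR = most-confident branch; the
  reaction class maps high→high, medium→medium, low→negative,
  not-detected→other. The mapping is monotone and matches the spirit of
  confidence-based model extraction, but the exact published rule is not
  printed anywhere; this one is the package's own.

## Outer search

The mixed-integer outer problem — choose target identities and `δ` to
maximize `η_D` — is solved by nested hybrid differential evolution:
DE/rand/1 mutation (rounded for the integer slots, with uniform resampling on
range violations and duplicate collisions), binomial crossover, greedy
one-to-one selection on the lexicographic key `(η_D, η_TR, η_MD)`, and a
migration phase that re-randomizes 80% of the population around the incumbent
when the fraction of distinct individuals falls below `10⁻³`. Defaults
(population 20, `F = 0.5`, `CR = 0.8`, 200 generations, `δ` memoized at
`10⁻³` resolution) follow standard hybrid-DE practice; the original method's
exact hyperparameters live only in its supplementary deposit, so these are
explicitly this package's defaults, all configurable. Every distinct
evaluated target set is archived with its grades, so the result is a ranked
table, matching how screening studies report top-k lists. Fitness evaluations
are memoized on `(targets, modes, quantized δ)`; with fixed seeds runs are
bit-reproducible.

Two-target screens use the two-group strategy: one slot per group, searching
only the `|G1|·|G2|` cross pairs. Spaces up to 2 000 pairs (default) are
enumerated exhaustively instead — the same threshold logic that makes the
source study switch from enumeration to the evolutionary search.

## Numerical choices

All LPs and QPs go through the Goldfarb–Idnani dual active-set solver
(`quadprog`). The UFD program is its native territory (strictly convex after
a `10⁻⁹` ridge on unpenalized variables). The FBA LP is solved in net-flux
space as a Tikhonov-regularized QP: for a small enough ridge the regularized
solution is exactly the least-norm LP optimum, so the optimal value is exact
rather than approximate. Because active-set methods are brittle on the heavy
degeneracy of LPs, the implementation (a) rescales variables so the feasible
box is order one, (b) eliminates fixed variables and rank-reduces the
equality rows, and (c) walks a deterministic ladder of ridge values
(`10⁻⁸ … 10⁻³`), accepting a value once two independent ridges agree to
`10⁻⁷` relative. If every rung reports inconsistency, an L-BFGS-B
least-violation probe distinguishes genuine infeasibility from solver
failure. The UFD floor is relaxed by `10⁻⁹ + 10⁻¹⁰·|floor|` so the QP never
sits exactly on the LP optimum's facet; optimal states are verified to
satisfy steady state within `10⁻⁸`. Reported ranking ties break by target id,
so screens are order-independent.

## What the toy generator does and does not emulate

`make_toy_pair()` builds a seeded cancer/healthy pair (about 16 metabolites
and 23 reactions by default) sharing a core of glucose/glutamine uptake, an
isozyme-buffered hexokinase-like step, a glycolysis complex, a
respiration-like high-yield ATP branch, a growth-limiting
nucleotide-precursor pathway, and two parallel lipid routes. The cancer model
adds a glycolytic bypass and caps respiration (an aerobic-glycolysis
phenotype, uptake 10 vs 8 mmol/gDW/h); the ATP demand carries a maintenance
floor of 1 mmol/gDW/h so treated cells cannot trivially report zero ATP
turnover. Planted ground truth: a cancer-lethal/healthy-sparing enzyme, a
shared-essential transporter, a buffered isozyme, a synthetic-lethal reaction
pair, a redundant enzyme group and an enzyme complex, plus seeded log-normal
expression. Decoration counts add further isozyme/complex/redundancy motifs.

The generator emulates the *structure* the method manipulates — GPR motifs,
confidence weights, competing objectives — not human metabolism: stoichiometry
is not elementally balanced, there are no cofactor pools or compartmental
transport costs, and expression is synthetic. Passing tests therefore
demonstrate that the machinery ranks planted structure correctly under known
conditions; they say nothing about recovering the published patient-derived
target lists, which require the deposited genome-scale models and their
membership bounds (see limitations).

## Limitations

* The published cohort-level grade tables are not reproducible from this
  package alone: the tissue-specific models and the study's membership bounds
  exist only in an external data deposit. The package reproduces the
  method, its worked numeric examples, and its combinatorics.
* Membership shapes are linear only; no sigmoidal variants.
* No loopless-FBA/FVA/thermodynamic constraints; futile two-sided flux is
  discouraged by the quadratic penalty, not forbidden.
* The SBML reader/writer covers the Level 3 FBC subset this package emits
  (species, bounds as parameters, gene associations, one active objective);
  it is not a general-purpose SBML library.
* Problem sizes in the test suite and reproduction script (tens of reactions,
  populations of 10–20, 20–30 generations) were chosen so that brute-force
  oracles — dense grids, exhaustive enumeration — remain exact references.
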