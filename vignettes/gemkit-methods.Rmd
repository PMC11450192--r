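---
title: "Methods: constraint-based modelling and omics integration in gemkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based modelling and omics integration in gemkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemkit)
```

## The model and its assumptions

A genome-scale metabolic model is a stoichiometric matrix $S$ (metabolites
$\times$ reactions), flux bounds $lb \le v \le ub$ in mmol/gDW/h (the
growth pseudo-reaction in 1/h), and per-reaction gene–protein–reaction
(GPR) rules in which `and` joins the subunits of a complex and `or` joins
isoenzymes. Steady state ($Sv = 0$) is assumed throughout: intracellular
metabolites neither accumulate nor deplete on the timescale of growth.
Flux balance analysis (FBA) maximises an objective flux over that
polytope; parsimonious FBA (pFBA) then minimises $\sum_i |v_i|$ with the
objective pinned at its optimum (to within $10^{-9}$ relative), on the
rationale that efficient proteome use favours minimal total flux.
Reactions are split into irreversible forward/reverse parts for every
$|v|$-based objective.

Thermodynamic annotations are standard transformed Gibbs energies
(ΔG°′, kJ/mol; pH 7, 298 K, unit concentrations). An absent annotation is
a distinct state (`NA`), never zero. In vivo driving forces follow
$\Delta G = \Delta G^{\circ\prime} + RT \ln Q$ with
$R = 8.314\times10^{-3}$ kJ/(mol·K); water and protons take activity 1 by
the biochemical convention, so they are also excluded when a reaction
ΔG°′ is reconstructed from metabolite formation energies.

The mass/charge audit counts a reaction as balanced only when every
element and the net charge cancel exactly. Pseudo-reactions (exchanges,
biomass, maintenance, lumped assemblies) are excluded from the summary
denominator — they are unbalanced by construction. Metabolites with
generic `R`/`X` residues make their reactions unauditable, which the
summary counts as unbalanced rather than silently skipping.

## Linear programming

No LP solver package is available to depend on, so `gemkit` ships a dense
bounded-variable two-phase simplex: nonbasic variables rest on a bound,
phase 1 drives signed artificial variables to zero (infeasibility is
declared when their mass exceeds $10^{-7}$, scaled by the right-hand
side), the ratio test admits bound flips, and Bland's rule engages after
60 consecutive degenerate pivots to preclude cycling. The basis is
refactorised by a dense solve at every iteration — numerically transparent
and entirely adequate at the problem sizes used here (tens to a few
hundred variables). Bounds must be finite; reactions with free bounds are
capped at ±1000 mmol/gDW/h before any analysis, following the common
convention. No property anywhere in the package depends on which optimal
vertex the solver returns, only on objective values — except for pFBA,
whose secondary objective makes the relevant part of the solution unique.

Feasibility tolerances: $Sv = 0$ is asserted to
$10^{-6}\max(1, \max|v|)$, bounds to $10^{-9}$, and the GIMME kept-set
flux cutoff is $10^{-9}$.

## GIMME context extraction

Given gene expression mapped to reactions (minimum over `and`, maximum
over `or`; genes without values are skipped, and a reaction whose genes
are all missing carries no evidence), GIMME solves

$$\min \textstyle\sum_i \max(0,\, t - x_i)\,|v_i| \quad \text{s.t.}\quad
  Sv = 0,\; lb \le v \le ub,\; v_{obj} \ge f\, v_{obj}^{max}$$

and keeps reactions that are expressed at or above $t$, carry no
evidence, or carry flux at the optimum. The objective fraction defaults
to $f = 0.9$. The threshold $t$ defaults to the 25th percentile of
nonzero expression — but `batch_contexts()` derives **one pooled
threshold per dataset** rather than one per cell. A per-cell quantile has
two failure modes we consider disqualifying: it penalises a fixed 25% of
genes in every cell regardless of their absolute expression, and a
strongly induced regulon inflates the cell's own quantile so that
unshifted core genes fall below it. With a pooled threshold, "low
expression" means the same expression level in every cell. A single-cell
zero is treated as expression 0 (maximal penalty), not as missing:
dropout and true silence cannot be distinguished in the data.

Condition comparison runs a two-sided two-sample t-test per active
reaction (nonzero in at least one sample); reactions constant in both
groups get $p = 1$ by convention. Raw p-values drive the divergent
fraction at $\alpha = 0.05$; Benjamini–Hochberg q-values are reported
alongside.

## Strain-specific bound scaling

Non-log expression fold-changes versus wildtype are winsorized per strain
to that strain's 1st–99th percentiles (rank-linear-interpolation
percentiles; the knockout genes are exempt), mapped to reactions through
the GPR (min/max as above), and multiplied into both wildtype bounds.
Scaling always starts from the wildtype parent — strain effects never
compound. Knocked-out genes that are in the model are additionally closed
through the GPR logic; knockouts of genes outside the model are legal
no-ops, since many deleted genes are regulatory rather than metabolic.
Winsorization is applied per strain (each microarray experiment defines
its own extreme-value distribution); the alternative dataset-wide pool
would let one aberrant strain cap every other strain's values.

Predicted growth is correlated against measured *relative doubling
times*. Growth rate and doubling time are inversely related, so the
default transform is the reciprocal, and |r| is reported; `raw = TRUE`
disables the transform.

## Nitrogen preference and nitrogen-limited conditions

The preference protocol fixes growth at 0.1 1/h, opens one nitrogen
source at a time (all other nitrogen-carrying exchanges closed to uptake,
secretion left open so surplus nitrogen may overflow), minimises the
source's uptake, then fixes the uptake — **as an equality** — at five
evenly spaced levels from 100% to 150% of that minimum, re-minimising
glucose uptake each time. The equality matters: the protocol measures how
glucose compensates when nitrogen absorption actually changes; a mere
upper bound would leave the extra allowance unused and every slope zero.
The score is the absolute OLS slope of glucose on nitrogen uptake
(endpoint slope available as an option), and scores are scaled to sum to
1 over exactly the set of sources compared in one call.

Condition-specific models under nitrogen limitation follow a staged
pipeline: measured exchange fluxes enter at 0.8× their magnitude (uptake
capped at, secretion forced to at least, 80% of the measurement — the
relaxation absorbs experimental error) with growth fixed at the measured
rate; nitrogen uptake is minimised and then capped at 1.5× that minimum;
finally growth is released and all fluxes recomputed by pFBA maximising
growth. Biomass macro-composition (protein/carbohydrate/RNA, g/gDW) is
rescaled per condition beforehand: each class's coefficients are
multiplied to the target mass and the classified components renormalised
so total biomass is exactly 1 g/gDW.

## Protein regulation coefficients

For each GPR-bearing reaction, ρ is the OLS slope of $\log|v|$ on
$\log p$ across conditions, using only conditions where flux and protein
are **jointly** nonzero (the log is undefined otherwise; an entity-wise
variant of the filter is available), and requiring at least 5 of the 12
conditions. Complexes collapse to the per-condition minimum subunit
concentration before one slope is fitted; isoenzymes get one slope per
protein, combined by the arithmetic mean; an `or` of `and` complexes
collapses each branch first and then averages across branches — the
natural composition of the two rules. Reactions whose flux changes sign
across conditions are excluded and logged rather than forced through a
signed logarithm. ρ is invariant to rescaling protein units, since a
multiplicative constant shifts only the intercept in log space.

## The classification harness

The harness owns the protocol; the learners come from the standard R
packages (e1071, randomForest, nnet, class, kernlab). Features are
standardised, optionally projected by kernel PCA, split 70/30 with
stratification (unequal class sizes would otherwise starve folds), and
hyperparameters are chosen by exhaustive grid search under 5-fold
cross-validation on the training portion only; all reported metrics come
from the untouched 30%. ROC curves are one-vs-rest per class with
trapezoid-rule AUC, macro-averaged. Every stochastic step (split, folds,
stochastic learners) derives from one integer seed, and no gemkit
function mutates the caller's RNG state.

## The synthetic study system

`make_toy_gem()` builds TOY-CORE: 46 metabolites, 56 reactions, 28 genes
across two compartments, with real elemental formulas and charges so that
every non-planted reaction balances exactly. Lumped central carbon
metabolism gives 20 ATP per glucose fully respired (2 substrate-level +
12 NADH at 1.5 ATP each); fermentation and an NADH-consuming glycerol
branch from DHAP provide overflow routes. Three planted defects (two
mis-balanced reactions and one generic-residue lipid reaction, all closed
so they can never carry flux) exercise the audit. Upper glycolysis and
the glycerol branch carry isoenzyme pairs and lower glycolysis a paralog
pair, mirroring the redundancy of the real pathways; the lumped TCA step
is a two-subunit complex.

The four nitrogen sources have planted marginal economics, in ATP per mol
of forced surplus uptake: glutamine +7.5 (its glutamate skeleton yields 9
NADH, minus urea excretion costs), ammonium −3 (urea synthesis only),
isoleucine −1.5 and phenylalanine −1 (transamination NADH gains minus
transport and excretion costs; their carbon skeletons leave as keto/aryl
acids). Dividing by 20 ATP/glucose gives the exact preference slopes the
LP must reproduce, strictly ordered glutamine ≻ ammonium ≻ isoleucine ≻
phenylalanine — the qualitative order reported for *S. cerevisiae*.
Planted gene truths (5 essential genes, 3 synthetic-lethal pairs) are
re-verified by a brute-force deletion oracle at generation time.

The omics generators are pure functions of their seed. Single-cell
profiles place core carbon/energy enzymes at high basal abundance (as
their real transcripts are) and shift the stress regulon tenfold — the
order of the osmotic induction of the glycerol-branch genes — with
Bernoulli dropout (default 0.1) zeroing entries. The single-cell pipeline
runs on an oxygen-limited, glucose-forced (chemostat-style) condition:
with respiration capped and glucose consumption mandatory, cells that
exclude fermentation must reoxidise surplus NADH through the glycerol
branch, which is what makes the planted condition difference expressible
in fluxes at all. Knockout-strain profiles drive a planted growth effect
through the glucose-transporter fold (the transporter capacity equals the
medium supply, so growth scales linearly with folds below 1) and plant
extreme outliers beyond the winsorization percentiles on non-metabolic
regulator genes. Flux/protein series set flux $= c\,p^{\rho}e^{\varepsilon}$
with log-normal protein and $\varepsilon \sim N(0, \sigma^2)$; complex
subunit series are constructed so the planted limiting subunit is the
per-condition minimum, and isoenzyme pairs get distinct slopes whose mean
is the planted reaction ρ.

What the generators do **not** emulate: genome-scale size (56 reactions,
not thousands), realistic yeast identifiers, sequencing-depth variation,
compositional count noise, batch effects, or growth-condition-dependent
biomass composition beyond the three macro classes. Passing tests
therefore demonstrate that the algorithms recover what was planted under
controlled conditions, not that they would resolve the far weaker signals
of real single-cell or proteomic data. At the default dropout the
single-cell condition signal is deliberately imperfect — a dropped-out
fermentation transcript genuinely rewires a cell's context model — so
condition classification sits below perfect accuracy there, while the
recovery invariant is tested without dropout.

## Known limitations

- The simplex refactorises densely each iteration; genome-scale models
  (thousands of reactions) would need a sparse LU and a real LP package.
- The SBML layer covers the constraint-based subset (species
  formula/charge, FBC bounds/GPRs/objective, groups-as-subsystems) and
  stores ΔG°′ in a package annotation namespace; it is not a general SBML
  round-tripper.
- Hit-and-run sampling uses a maximum-slack interior start and fixed
  thinning (100); convergence diagnostics are the user's responsibility.
- GIMME and pFBA inherit FBA's steady-state and optimality assumptions;
  thermodynamic annotations are descriptive and never constrain fluxes.
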