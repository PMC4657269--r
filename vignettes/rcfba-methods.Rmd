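---
title: "Resource-constrained flux balance analysis in fluctuating environments: model and methods"
author: "rcfba package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rcfba model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Classical flux balance analysis (FBA) maximises a biomass flux subject to
steady-state mass balance $S\nu = 0$ and flux bounds. `rcfba` extends this
picture in two directions that matter for organisms living in *fluctuating*
environments.

First, fluxes cost protein. Every enzymatic reaction $i$ (the biomass
reaction included — its "enzyme" is the ribosome pool) carries a
per-condition investment $\varphi_i^k \ge 0$ coupled to its flux by the
catalytic rates:

$$-\beta_i \varphi_i^k \le \nu_i^k \le \alpha_i \varphi_i^k.$$

Separating investment from flux is essential: an enzyme can be expressed
(costly) while carrying no flux because its substrate is absent.
Pseudo-exchange reactions, which only encode nutrient availability through
their upper bounds $u_i^k$, carry no investment; nutrients absent from a
condition have $u_i^k = 0$, available nutrients are unbounded (implemented
by *omitting* the bound row, never by a big-M constant), and secretion is
never bounded.

Second, re-regulating enzymes between environments costs resources too
(ribosome capacity, transcription-factor and signalling overhead). With $P$
conditions visited with equal probability, the switching investment of
condition $k$ is linear in the investment differences,

$$\varphi'^k = \frac{r}{P-1} \sum_{l \ne k} \sum_i
  \lvert \varphi_i^k - \varphi_i^l \rvert,$$

with the dimensionless switching parameter $r \ge 0$ weighting how much
fast adaptation matters relative to growth. Both investments share one
capacity,

$$\sum_i \varphi_i^k + \varphi'^k \le \varphi_0,$$

and the objective is the mean biomass flux across conditions. The optimal
metabolic network is read off the solution as the support of the
investments: reactions with $\max_k \varphi_i^k$ above a threshold are
present. Reactions with identical binary on/off patterns across conditions
form one *regulon*; the regulon count summarises the regulation strategy
(one regulon = fully constitutive expression).

### Linearisation, tie-breaking and numerics

The absolute values enter a $\le$ capacity constraint, so each pair
$\{k,l\}$ gets an auxiliary variable $d_i^{kl} \ge \pm(\varphi_i^k -
\varphi_i^l)$. Slack in $d$ only tightens the capacity, and maximisation
presses $d$ down to the true absolute value whenever the capacity binds; in
the non-binding case (for example, zero growth) the reported switching
investments are *always recomputed exactly* from the optimal $\varphi$, so
solver slack never leaks into results.

With equal catalytic rates the LP optimum can be degenerate in which
reactions carry the investment. After maximising growth, a second
lexicographic stage fixes the objective at its optimum (within $10^{-9}$
relative) and minimises total investment $\sum_{k,i}\varphi_i^k$, which
makes the selected set deterministic; remaining ties fall back to reaction
order. The support threshold defaults to $10^{-6}\varphi_0$ (relative,
because LP solvers return roughly $10^{-9}$ absolute noise on unit-scale
problems) and the feasibility tolerance to $10^{-8}$; both are
configurable in `rcfbaParams()`. The LP itself is assembled sparsely in R
and solved by HiGHS (`scipy.optimize.linprog` through a bundled helper
script), a deterministic simplex/dual method, so identical inputs give
identical solutions.

Degenerate inputs behave conservatively: a condition with every exchange
closed is feasible with zero flux, zero growth and an empty selected
network; a universe without a biomass reaction is rejected; $P=1$ makes the
switching sum empty, so any $r$ reproduces the $r=0$ solution.

## The canonical two-substrate fixture

`buildToyUniverse()` constructs a 12-metabolite universe with 14 enzymatic
reactions (biomass included) and two costless exchanges supplying the
alternative substrates S1 and S2. Two *direct* 5-reaction routes
(S1→A→C→D→E→P, S2→B→F→G→E→P) compete with two 6-reaction routes that share
a hub H (S1→A→H→I→D→E→P and the S2 analogue). Uptake reactions are
enzymatic (they cost transporter protein); exogenous supply is modelled by
the separate costless pseudo-exchanges.

At growth $g$ with unit rates, each expressed enzyme needs investment $g$,
so the three relevant pure strategies cost per condition:

| strategy | investments | switching | capacity coefficient |
|---|---|---|---|
| direct routes, regulated | $6g$ | $8rg$ | $6+8r$ |
| hub routes, regulated | $7g$ | $4rg$ | $7+4r$ |
| hub routes, constitutive | $9g$ | $0$ | $9$ |

The growth envelope $\varphi_0\max\{\frac{1}{6+8r},\frac{1}{7+4r},
\frac{1}{9}\}$ has breakpoints at exactly $r=1/4$ (structural transition:
the selected set shrinks from 10 to 9 reactions and the average shortest
path to biomass grows from 5 to 6) and $r=1/2$ (regulatory transition: three
regulons collapse to one with the set unchanged). The test suite verifies
the LP against this enumeration, recomputed independently in the test
helpers, to $10^{-8}$ across a 200-point grid — the fixture's behaviour is
measured, not assumed.

## Sweeps, transitions, Monte-Carlo averaging

`sweepR()` re-solves the full lexicographic problem at every grid value of
$r$ and records a structural profile: mean growth, selected reaction count,
and node count, input-node count and average shortest path of the selected
subnetwork's metabolite graph, plus the regulon count.

`detectTransitions()` compares the *state* of adjacent grid points — the
selected set and the full activity-pattern map (pattern maps, not regulon
counts, because a count can be conserved across a pattern change). A
differing set brackets a structural transition, a differing pattern map
with equal sets a regulatory one; brackets are refined by bisection to a
default width of $10^{-3}$ and reported at the midpoint. Because exact
crossing points sit anywhere inside the final bracket, reported transitions
carry an uncertainty of half the resolution.

`growthBreakpoints()` detects kinks in the growth curve from second
differences. A smooth strictly-convex growth curve sampled on a fine grid
has nonzero second differences everywhere, so a bare threshold would flag
every point; the detector therefore also requires a slope change to
dominate (3× by default) the changes at its *next-nearest* neighbours —
immediate neighbours are excluded because a kink falling between grid
points splits its jump over two adjacent intervals, which are then merged
into one report.

`monteCarloSweep()` perturbs all catalytic rates by $U(-\sigma, \sigma)$
around their means (`randomizeRates()`, $\sigma < 1$ keeps unit-mean rates
positive), sweeps each realization, and averages profiles. Replicate $i$
is seeded `seed + i - 1`; failed solves are skipped and counted rather than
resampled, so seeds stay aligned with replicate indices.

## The *E. coli* core experiments

The package bundles the published core network (72 metabolites, 95
reactions including pseudo-reactions) as plain COBRA JSON.
`buildCoreEnvironments()` builds five single-carbon-source conditions
(acetate, pyruvate, L-malate, L-glutamate, D-glucose), ammonium, phosphate
and CO₂ saturating everywhere, oxygen open except in the D-glucose
(anaerobic) condition. Water and proton exchange are open in every
condition: the published model exchanges both freely by default, and
closing their uptake would render the acetate and L-malate conditions
infeasible for reasons unrelated to the trade-off under study. Default
rates follow the core-network convention: mean $\alpha = 1$, mean $\beta$
1 for reversible and 0 for irreversible reactions, capacity
$\varphi_0 = 100$ (transition points are invariant to the exact value; the
objective scales linearly in $\varphi_0$, which the tests check).

With equal rates at $r = 2$ the optimal network is a single regulon and
produces no biomass on D-glucose — the organism abandons its only
anaerobic niche rather than pay the switching cost. The acceptance tests
re-run the rate-randomized sweep at reduced replication (20 realizations,
$\sigma = 0.9$, six grid points over $[0, 2.5]$; chosen to keep the default
suite complete on one CPU while leaving the trend directions
unambiguous) and check the qualitative trends: growth decreases, average
shortest path increases, input/node/reaction counts of the selected
network decrease, and the regulon count falls to one.

## Graph representation and structural metrics

`buildGraph()` converts a universe (or a selected subnetwork) into a
directed metabolite graph: an edge from every substrate to every product
of each enzymatic reaction, both directions if reversible, parallel edges
collapsed with reaction provenance retained. Currency and energy carriers
(ATP, NAD(P)H, water, protons, …) are removed *as graph nodes only* —
they stay in the LP — because they would create biologically meaningless
shortcuts; the exact list is a configurable default
(`defaultCarriers()`) since published analyses state the principle rather
than an exhaustive list. External metabolite copies are *input* nodes;
non-carrier substrates of the biomass reaction are *biomass components*;
the biomass and pseudo-exchange reactions contribute no edges.

Metrics (`structuralMetrics()`): path lengths count edges (a transport
step counts as 1); $l_{\min}$ of a biomass component is the shortest
directed path from any input, and the ASP averages $l_{\min}$ over
reachable components (unreachable ones are excluded and counted).
Distances *between* input pairs and between biomass-component pairs use
the underlying undirected graph by default: input nodes are pure sources,
so directed input-to-input distances are undefined by construction, while
the undirected distance captures how quickly routes converge on shared
hubs (a `pairMode` flag restores directed behaviour). The overall
closeness centralization index is Freeman centralization
$\sum_v (C_{\max} - C(v)) / \frac{(n-1)(n-2)}{2n-3}$ over closeness scores
computed on reachable distances only (nodes reaching nothing score 0); it
serves as a whole-graph bow-tie proxy and the exact closeness variant is
recorded here since more than one convention exists in the literature.

## Essentiality and group comparison

The deletion screen uses *standard* FBA (no resource constraint): rich
medium opens every exchange, fluxes are capped at ±1000 arbitrary units
(the common constraint-based convention), each non-pseudo reaction is
deleted in turn, and a knockout is essential when growth falls below
$10^{-6}$ of wild type (a relative threshold, since no absolute viability
cutoff is canonical). Deletion is at reaction level; gene–protein–reaction
logic is out of scope.

`compareGroups()` profiles a panel of models, joins a user-supplied
lifestyle table (facultative vs non-facultative as a proxy for fluctuating
vs stable habitats, one model per organism, first listed wins), and tests
each metric with the two-group Kruskal–Wallis rank test (tie-corrected H,
chi-square approximation with 1 degree of freedom). The test suite
validates the statistic against a hand-computed rank example and the
chi-square p against a permutation null.

## What the synthetic generators do and do not emulate

`generateRandomUniverse()` builds layered, irreversible, unit-rate,
unimolecular universes that are viable by construction — ideal for
property tests (graph oracles, essentiality monotonicity, chain growth
closed forms) because every expected value can be derived independently.
Real metabolic networks differ in every respect that these fixtures hold
fixed: multi-substrate reactions, reversibility, cofactor coupling, broad
rate distributions and gaps. Passing tests on these fixtures therefore
validates the *machinery* (LP assembly, graph construction, screens), not
biological predictions; the core-network experiments are the closest the
suite comes to real data, and the 143-organism panel of reconstructed
models is explicitly out of scope (database-version dependent).

## Known limitations

* The LP grows as $O(NP + N P^2)$ variables with the pair-wise
  linearisation; many conditions on genome-scale universes will be slow.
  No parametric-LP basis tracking is attempted — numeric sweeps plus
  bisection suffice at the sizes studied here.
* Network selection is read off LP support; there are no integer design
  variables, no dynamic FBA, no thermodynamic constraints.
* SBML support targets Level 3 with FBC objectives (the dialect the
  package writes and BiGG-style files); it is not a general SBML
  implementation.
* Transition detection assumes transitions are separated by more than the
  initial grid spacing; two transitions inside one bracket would be
  reported as one.
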