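---
title: "The metabolic niche: projecting flux polytopes onto the environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metabolic niche: projecting flux polytopes onto the environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheflux)
```

## The model and its assumptions

A constraint-based metabolic model describes a cell at quasi-steady state:
every internal metabolite is produced as fast as it is consumed, so the
admissible flux vectors form the polytope `F = {v : S v = 0, lb ≤ v ≤ ub}`.
The biomass reaction aggregates the stoichiometric requirements of growth;
its flux is the growth rate (h⁻¹) and is constrained non-negative. Exchange
reactions connect the network to the environment, each touching exactly one
boundary metabolite. Flux balance analysis (FBA) estimates growth as the LP
maximum of the biomass flux over `F`.

Three assumptions matter downstream. First, environmental forcing enters
*only* through bounds: a nutrient's bioavailability is an upper limit on its
uptake flux, never a forced uptake — the organism may always take up less,
which guarantees the growth LP is feasible whenever the unforced model is.
Second, temperature has no metabolic representation here; thermal limits are
applied, optionally, as a post-hoc mask on results (boundary-inclusive: a
point exactly at the threshold is viable). Third, fixed carbon is treated
like a nutrient: an upper bound on the carbon-fixation reaction (the
organism may fix less), not an equality. An equality reading would make
strongly lit, nutrient-poor environments infeasible, which contradicts the
bioavailability semantics; the choice is recorded per run in the results
metadata.

## The niche projection

Most of a genome-scale network is irrelevant to a biogeochemical model that
tracks a handful of nutrients. The metabolic niche `N` is the projection of
`F` onto the `p` *reactions of interest* — nutrient uptake exchanges, carbon
fixation, biomass. Growth extraction under an environment `x_env^b` is then
`max x_bio` subject to `x ∈ N`, `0 ≤ x_env ≤ x_env^b`: a `p`-dimensional LP
answered thousands of times against a polytope computed once.

`project_niche()` builds both a vertex and a halfspace representation by
support-function refinement:

1. seed with support points of `F`'s projection along `±e_j` for each
   coordinate;
2. build the convex hull of the collected points;
3. for each hull facet normal `u`, solve the support LP
   `max u·x over F`; if the support value exceeds the facet offset by more
   than the tolerance, insert the support point and go to 2.

Every support LP optimum is *purified lexicographically* (re-maximising each
coordinate in turn at the pinned optimum), which makes it an extreme point
of the projection and makes the whole construction deterministic. Since each
refinement round either certifies all facets or adds a genuinely new vertex,
and a polytope has finitely many vertices, the loop reaches the exact
projection in finitely many rounds. At the fixpoint the hull is sandwiched:
its vertices lie in the projection (they are support points), and every
facet is certified by a support LP, so projection and hull coincide up to
the tolerance. Tests verify this against independently computed support
functions of the full polytope (the Hausdorff distance between convex
bodies is the largest support-function gap over unit directions) and by
lifting every vertex back to a feasible full flux vector.

Degenerate geometry is first-class rather than joggled away. Quota-like
models tie uptakes stoichiometrically to biomass, so a niche over four
reactions is often a 2-dimensional polytope: the construction detects the
affine rank and stores an explicit affine-hull basis plus equality
constraints next to the facets. The hull itself is computed by exhaustive
facet enumeration — every affinely independent `d`-subset of points whose
hyperplane supports the whole set is a facet — which is `O(C(n,d)·n)` but
immune to the coplanar-vertex degeneracies of box-like flux polytopes, and
entirely adequate for the tens of vertices a niche has. Projections are
supported for `p ≤ 6` and routinely exercised up to `p = 4`.

## The LP core

All of this rests on many small LPs, so the package carries its own dense
bounded-variable two-phase simplex (`lp_solve()`). The design goals are
exactness at vertex solutions, explicit infeasible/unbounded verdicts
(an infeasible environment is a "no growth state", distinct from an optimal
growth of zero), and bit-level determinism: Dantzig pricing with a Bland
anti-cycling fallback, smallest-index tie-breaks, refactorisation at every
iteration. Solver tolerances are 1e-9; every fixing of a flux at its
optimum first tries the exact pin and relaxes by a relative 1e-6 only if
floating-point rounding makes the exact pin infeasible. Infinite model
bounds are encoded as ±1e6 so every projection is bounded. Degenerate
alternative optima are canonicalised parsimoniously (minimum total absolute
flux at fixed objective), so reported flux vectors are reproducible.

## Diagnostics

**Auxiliary fluxes.** The production capacity of a component at optimal
growth is a bi-level question: maximise biomass, pin it, then min/maximise
the component's flux. Components without an export get a secretion-only
exchange (lower bound 0: the model may produce, never consume, the
component), which cannot alter the growth optimum. Candidates are handled
sequentially and independently; the summed per-metabolite maxima are
therefore an upper envelope of simultaneous secretion, and are labelled as
such in the output metadata. Energetic costs of storing or mobilising the
exported compounds are not modelled.

**Slacks and resource constraints.** The slack `d_n` is bioavailability
minus the *minimum* feasible uptake of `n` at pinned optimal growth — a
per-nutrient LP, so slacks do not depend on which optimal flux vector a
solver happened to return (the slack at the canonical parsimonious optimum
is available as an option). Across an ensemble `E` of environments each
nutrient's slack distribution is min–max normalised and inverted,
`RC_n = (max d − d)/(max d − min d)·100`, so 100% marks the environment
where the nutrient is limiting. The orientation (small slack → high
constraint) follows the semantics of limitation; the normalisation
statistics are stored with the results so values remain comparable. A
nutrient with identical slack everywhere is flagged uninformative rather
than normalised. The ensemble defaults to the whole grid across months
(per-month scope is an explicit option, since pooling choice changes the
normalisation and must be a deliberate decision).

**Composition ratios and the storage index.** Component production is
converted to carbon equivalents as `c_M (x_M + a_M x_bio)/x_bio`, with
`c_M` the component's carbon stoichiometry and `a_M` its share in the
biomass reaction; the carbon coefficient multiplies the *total* component
flux, biomass-bound share included. At zero growth the ratio is undefined
(`NA`), never infinite. The storage ratio `r_stor` divides carbon-scaled
glycogen production by the bioavailable fixed carbon (using realised
fixation instead is a documented toggle); min–max normalisation over the
ensemble gives the storage index in `[0, 1]`, split at the ensemble mean
into storage and consumption regimes. For consumption entries the implied
glycogen consumption is `v̄ − v`, where `v̄` is the production that would
correspond to the mean index under the entry's own carbon fixation.
Min–max was chosen for the normalisation (over, say, rank or z-scoring)
because it preserves the ratio's zero and keeps the index interpretable as
a fraction of the ensemble's observed range; the choice is recorded in the
output attributes.

**DOC diversity.** A metabolite counts toward diversity if its production
strictly exceeds 5% of the maximal per-metabolite production, the maximum
taken over the candidate set *including* the metabolite itself (excluding
it would make the top producer's own inclusion ill-defined). Diversity is
computed on carbon-scaled fluxes; an unscaled toggle exists.

## Synthetic study conditions

The package tests itself without external data. The quota-chain generator
produces the smallest models with Liebig behaviour: nutrient uptakes with
biomass stoichiometries (`TOY1`: N at 1, P at 0.2, 5 fixed carbons per
biomass unit, glycogen at 7 carbons costing 7 fixed carbons, absent from
biomass), with uptake capacities of 10 mmol gDW⁻¹ h⁻¹ and a fixation
capacity of 50 — transporter-scale ceilings that keep the niche at a
physical scale. Their optimum has the closed form
`min_n(x_n/a_n, c_fix/c_per_biomass)`, the analytic oracle recovered by the
LP to 1e-8 across a thousand random environments. Random feasible networks
for fuzzing are built as acyclic conversion chains from uptakes to biomass:
feasibility and a positive optimum hold by construction, and acyclicity
plus irreversibility excludes futile cycles, keeping projections bounded
without loop-law machinery.

The environment generator emulates the fields an ocean model would supply:
smooth latitudinal nutrient gradients, carbon fixation decaying
exponentially with depth (e-folding 60 m) and modulated seasonally,
a latitude/depth-dependent temperature field, an abundance field, and
multiplicative lognormal noise (5%). Designed starvation boxes force a
chosen nutrient's availability-to-requirement ratio below half the minimum
of the other resources and store the ground-truth label, so the pipeline's
limitation calls can be scored; the default grid is 12×12×2 depths×2
months (576 points), sized so the full sweep takes seconds. What the
synthetic grid does *not* emulate — circulation, Eppley-type temperature
kinetics, realistic co-limitation textures — bounds what passing tests
show: they demonstrate the machinery recovers designed structure exactly,
not that any particular ocean is well predicted.

## Numerical choices and degenerate inputs

- Geometric tolerance: 1e-6 of the projection diameter (membership,
  refinement stopping, lift pinning); hull tolerances derive from it.
- An environment incompatible with the niche (possible only for models
  with obligatory fluxes, e.g. a growth floor) reports growth 0 with an
  `outside_niche` flag — the flag, not the zero, carries the information.
- Ties everywhere (entering variable, leaving variable, facet order,
  vertex order) break by smallest index; two runs of any pipeline under
  the same seed are byte-identical, which the test-suite and the
  acceptance script verify end to end through the CLI.
- Iron-like nutrient columns a model cannot utilise are skipped with a
  warning rather than an error, so multi-tracer environment tables can be
  reused across organisms.

## Limitations

The niche is exact for the *linear* questions asked of it; diagnostics that
would require interior sampling of `F` (flux distributions, loop analysis)
are out of scope. Simultaneous multi-metabolite secretion is not modelled —
per-metabolite maxima are upper envelopes. The facet-enumeration hull is
exponential in `p` and is the practical reason projections are capped at
`p = 6`. The SBML reader covers flux-bounds/objective-annotated FBC v2
(sufficient for round-tripping and plain exports), not the full breadth of
curated model annotations.
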