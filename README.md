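# nicheflux

Constraint-based metabolic models predict how a phytoplankton cell grows
from what its environment offers, but solving a genome-scale model at every
grid point of an ocean biogeochemical simulation is computationally out of
reach. `nicheflux` implements the *metabolic niche* approach to this
coupling problem: project the model's steady-state flux polytope once onto
the handful of environmentally relevant reactions, then answer every
per-grid-point question with a tiny linear program on the projection.

## The model

A metabolic model is the polytope

```
F = { v ∈ R^m : S v = 0,  lb ≤ v ≤ ub }
```

with `S` the stoichiometric matrix (n metabolites × m reactions) and the
biomass reaction's flux `v_bio` the growth rate (h⁻¹). Writing
`v = (x, y)` where `x` collects the *reactions of interest* — nutrient
uptake exchanges, the carbon-fixation reaction, biomass — the metabolic
niche `N` is the projection of `F` onto the `x` coordinates. Growth under
an environment is then the small LP

```
max x_bio   s.t.   x ∈ N,   0 ≤ x_env ≤ x_env^b
```

where `x_env^b` is the nutrient *bioavailability* (an upper limit of
uptake, not a forced uptake) supplied per grid point by the environment
model. On top of growth the package derives, per grid point:

- **auxiliary flux ranges** — min/max flux of any reaction with biomass
  pinned at its maximum (bi-level flux variability), used to quantify the
  (over)production of storage compounds and secreted metabolites;
- **resource constraints** — per-nutrient slack `d_n` (bioavailable minus
  minimally required uptake at optimal growth), min–max normalised over an
  ensemble of environments so that `RC_n = 100%` marks the limiting
  nutrient;
- **variable biomass composition** — carbon-equivalent component ratios
  `c_M (x_M + a_M x_bio) / x_bio`;
- **glycogen storage index** — fixed carbon routed to glycogen over carbon
  fixed, normalised over the ensemble; entries below the ensemble mean are
  read as glycogen consumption supporting growth;
- **DOC scoring** — carbon-scaled maximal secretion per candidate
  metabolite, abundance-scaled intensity (mmol C h⁻¹), and a diversity
  count of metabolites exceeding 5% of the maximal production.

The projection itself is computed by support-function refinement with an
exact, deterministic bounded-variable simplex written for this package
(the niche LPs are small and must be bit-reproducible), and is validated
against brute-force support functions of the full polytope.

## Worked example

```r
library(nicheflux)

toy <- toy1_model()   # quota chain: growth = min(N, P/0.2, C/5)
niche <- project_niche(toy, c("EX_N", "EX_P", "CFIX", "BIO"))
niche
#> <niche_projection> over (EX_N, EX_P, CFIX, BIO)
#>   3 vertices, 3 facets, rank 2/4

env <- c(EX_N = 2, EX_P = 0.2, CFIX = 12)
max_biomass_on_niche(niche, env)
#> $growth
#> [1] 1
#> $realized_uptake
#>  EX_N  EX_P  CFIX
#>   1.0   0.2   5.0
#> $outside_niche
#> [1] FALSE

auxiliary_flux_range(toy, env, "SYN_glycogen")
#> min max
#>   0   1
#> attr(,"growth")
#> [1] 1
#> attr(,"outside_niche")
#> [1] FALSE
round(nutrient_slack(toy, env), 10)
#>  EX_N  EX_P  CFIX
#>     1     0     7
#> attr(,"growth")
#> [1] 1
```

Growth is 1 h⁻¹: phosphate (0.2 available, 0.2 needed) and fixed carbon
(12 available, but see the slack) co-limit before nitrogen does. At that
optimum the cell holds 7 mmol of surplus fixed carbon — exactly enough to
build one flux unit of glycogen (7 C each), which is the auxiliary range
`[0, 1]` — while 1 flux unit of nitrogen is divertible.

A full sweep over a gridded environment, from the shell:

```sh
Rscript inst/cli/nicheflux.R gen-synthetic --preset toy1 --seed 42 --out demo/
Rscript inst/cli/nicheflux.R run-grid --model demo/toy1.json \
    --env demo/environment.csv --map demo/nutrient_map.csv \
    --doc-list demo/doc_candidates.csv --thermal-min 10 --out demo/run/
```

which writes `demo/run/results.csv` with per-point growth, uptakes,
slacks, resource constraints, production ratios, storage-index and DOC
columns, plus the serialized niche.

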