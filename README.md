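# raftsim

Agent-based lattice simulation of lipid raft formation in brain cell
membranes, driven purely by lipid-class composition.

## The scientific problem

Lipid rafts — liquid-ordered membrane microdomains enriched in
cholesterol, sphingolipids and saturated lipids — reorganize during
Alzheimer's disease: human frontal-cortex studies across Braak stages
report altered raft lipid composition well before clinical symptoms.
`raftsim` is for membrane biophysicists and computational
neurobiologists who want to ask: *given only the lipid-class
composition of a membrane, what domain structure does physics
predict?* The package simulates domain formation for Control, ADI/II,
ADIII/IV and ADV/VI frontal-cortex compositions (bundled), estimates
raft size, number and area, maps membrane peroxidability, and tests
predictions against experimental raft compositions with a
random-composition reference ensemble.

## The model in brief

A membrane monolayer is a 200 × 200 periodic lattice over seven lipid
classes. Each class is a cylinder (radius *R*, length *L*); neighbors
attract through the non-retarded additive London–Van der Waals energy

    LVW_ij = A·L / (12·√2·D^{3/2}) · √(R_i R_j / (R_i + R_j))

with Hamaker constant *A* and intermolecular distance *D* = 1.50 Å.
Stochastic neighbor exchanges follow a kinetic-arrest rule: the
probability that a pair of elements switches decays exponentially with
their current binding, `p = exp(-(B - B_min)/θ)` — the higher the
force between neighbors, the lower the probability to switch. Sites
that rarely move define the rafts: per-site mobility is the fraction
of sweeps in which the element changed position, and sites below a
fixed mobility threshold (0.07) are segmented into domains. Raft size
is estimated by row-by-row run-length screening, raft number from the
occupied area assuming circular domains (with a 4/π chord-to-diameter
correction), and membrane peroxidability by the linear index

    PI = 0.025·%monoenes + 5·%n-6 LCPUFA + 6·%DHA.

Validation compares squared compositional distances (Δ²) against an
ensemble of membranes with symmetric-Dirichlet random compositions
(95% percentile intervals).

## Worked example

```r
library(raftsim)
sc  <- scenario_set()                       # bundled frontal-cortex tables
ff  <- build_force_field(sc$cylinders)      # 7x7 LVW interaction matrix
res <- run_simulation(sc$membrane$Control, ff, sim_config(seed = 1))
res
#> Membrane simulation result
#>   lattice: 200 x 200, 1000 iterations, rule = binding
#>   theta = 1.855e-20 J, mean mobility = 0.121
raft_stats(res)
#> Raft stats: tau = 0.0700, mean size = 2.60 cells (SD 1.95),
#>   count = 750 (labeled: 738), area fraction = 0.162
```

The Control membrane (27.5% saturates, 13.7% DHA) segregates into
~750 low-mobility domains covering 16% of the lattice, with a mean
row-scan size of 2.6 cells; the chord-corrected circular-count
estimate (750) agrees closely with exact connected-component labeling
(738). Domain peroxidability separates cleanly:

```r
dp <- domain_pi(res$lattice, raft_stats(res)$mask)
#> PI whole 143.7 inside 114.5 outside 149.4
```

— rafts are enriched in saturates/sphingolipids and depleted in DHA,
so their PI (114.5) is far below the non-raft regions (149.4). Running
all four conditions at reduced scale:

```r
reproduce(preset = "desk", seed = 1, validate = FALSE)
#> Scenario report (preset 'desk', seed 1)
#>   Control   size   2.57  count  310.7  area 0.261  PI whole  143.7  in  102.1  out  158.4
#>   ADI/II    size   3.09  count  290.7  area 0.354  PI whole  121.5  in   90.8  out  138.2
#>   ADIII/IV  size   3.12  count  293.3  area 0.364  PI whole  124.8  in   93.2  out  142.9
#>   ADV/VI    size   4.05  count  235.3  area 0.492  PI whole  105.9  in   82.6  out  128.5
```

Raft size grows with disease stage (2.57 → 4.05 cells) while raft
number falls (311 → 235) — the reciprocal size/number relationship —
raft area climbs from 26% to 49%, and membrane peroxidability drops
from 143.7 to 105.9, with the non-raft regions carrying most of the
decline. A thin CLI wraps the same functions:

```sh
exec/raftsim reproduce --preset desk --seed 1 --outdir out/
exec/raftsim rafts --composition inst/extdata/frontal_cortex_cell_membrane.csv \
    --condition Control --preset paper --seed 1
```

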