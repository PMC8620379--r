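---
title: "Modeling lipid raft formation from membrane composition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lipid raft formation from membrane composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftsim)
```

## The model

`raftsim` simulates the lateral organization of a cell-membrane
monolayer as a coarse-grain agent-based (cellular-automata) system. A
piece of membrane is a 200 x 200 lattice whose cells hold one of seven
lipid classes — cholesterol, sterol esters, DHA (n-3 LCPUFA), n-6
LCPUFA, monoenes, saturates, sphingolipids — aggregated by structural
similarity. Each class is represented by the cylinder that best fits
its molecular volume (radius $R$, length $L$, in Angstrom), and two
neighboring lipids attract through the non-retarded, additive
London–Van der Waals energy

$$LVW_{ij} = \frac{A\,L}{12\sqrt{2}\,D^{3/2}}\sqrt{\frac{R_i R_j}{R_i+R_j}},$$

with Hamaker constant $A$ and intermolecular distance $D$ (1.50 A, the
value fitted together with the cylinder geometry on mouse
frontal-cortex membranes). Water is not modeled at this scale, there
is no electrostatics, no Lifshitz/retardation correction, and only one
leaflet is simulated. The seven-class geometry table and the human
frontal-cortex composition tables for Control and the three Braak
stages (ADI/II, ADIII/IV, ADV/VI) are bundled, so all four scenarios
run with no external data.

Two conventions are worth making explicit:

* **Length convention.** The energy formula carries a single $L$. For a
  heterogeneous pair we use the arithmetic mean of the two class
  lengths. This makes the force field symmetric by construction (the
  swap rule requires symmetry) and reduces to the plain formula for a
  within-class pair.
* **Hamaker constant.** Vacuum Hamaker constants are of order
  $10^{-20}$–$10^{-19}$ J; the default is $A = 10^{-19}$ J and it is
  configurable. Because the swap-rule scale $\theta$ is calibrated from
  the force field itself, the dynamics depend only on energy *ratios*:
  rescaling $A$ changes nothing downstream.

## Swap dynamics

One iteration (sweep) visits every lattice site once in a fresh random
permutation, so each element gets the opportunity to switch once per
iteration; a site may additionally be moved passively when a later
site selects it. The visited site proposes to exchange with one of its
four von Neumann neighbors chosen uniformly; the lattice is periodic.
Acceptance follows one of two rules:

* **`binding` (default, kinetic arrest).** The probability to switch
  decreases exponentially with the *current* binding of the two
  participating elements:
  $p = \exp\!\big(-(B - B_{\min})/\theta\big)$, where $B$ sums the two
  sites' four-neighbor binding energies (the shared bond counted in
  both, consistently) and $B_{\min} = 8\min_{ij} LVW_{ij}$ is the
  weakest realizable two-site binding. The higher the force between
  neighbors, the lower the probability to switch: strongly bound
  saturate/sphingolipid-rich neighborhoods freeze, weakly bound
  PUFA-rich neighborhoods keep diffusing. With a zero force field
  every proposal is accepted (free diffusion).
* **`metropolis` (sensitivity alternative).**
  $p = \min\{1, \exp((B_{swap}-B_{cur})/\theta)\}$, the standard
  binding-seeking exchange rule.

The Metropolis rule is kept because it is the textbook choice, but it
cannot be the default here: under the mean-length convention the mixing
coupling $J_{ij} = (E_{ii}+E_{jj}-2E_{ij})/4$ is of order $10^{-22}$ J
— the length terms cancel exactly and the radius terms nearly so — which
puts any workable $\theta$ orders of magnitude above the demixing
temperature. Equilibrium exchange dynamics on this force field mixes
ideally and never forms domains. Domain formation in this model is a
*kinetic* phenomenon: regions that happen to assemble a strongly bound
neighborhood stop moving, and low mobility is precisely the observable
that defines a raft.

**Scale $\theta$.** For the binding rule the default is
$\theta = \max_{ij} LVW_{ij} - \min_{ij} LVW_{ij}$, the spread of the
pairwise energies. A two-site neighborhood holds eight bonds, so
acceptance spans $e^{-8}$ to $1$ between the weakest- and
strongest-bound configurations. This was calibrated once, against the
default force field, as the quench depth at which membranes segregate
into persistent low-mobility domains within 1000 iterations — shallower
quenches never nucleate, much deeper quenches freeze the background
indiscriminately — and is configurable (`swap_scale_theta`). For the
Metropolis rule the default is the median off-diagonal energy.

**Mobility.** The per-site mobility is the fraction of iterations in
which the element at that site changed position at least once. The
binary per-iteration flag (rather than a raw event count) keeps the
value in $[0,1]$ even though a site can be exchanged several times in
one sweep. Whether a same-class exchange counts as a move is a config
switch (`count_same_class`, default on: any exchange is a change of
position).

**Noise series.** As an indirect noise estimate the simulation records
the root-mean-square deviation of the per-site binding-energy field
relative to the initial configuration, evaluated before each sweep (so
the first entry is exactly zero and the series has one entry per
iteration).

## Initialization and steady state

The initial lattice allocates sites to classes by largest-remainder
rounding of the composition percentages (ties broken by class order;
percentages are first rescaled to sum exactly to 100, absorbing the
±0.01 rounding of published tables) and arranges the resulting multiset
uniformly at random. Class counts are an invariant of the dynamics and
are asserted on every run. 1000 iterations suffice for the distribution
of low-mobility regions to stabilize at the default scale; the bundled
`paper` preset uses 200 x 200, 1000 iterations, 10 replicates, while
the `desk` preset (100 x 100, 300 iterations, 3 replicates, validation
ensemble 20) is used for interactive work and the test suite.

## Raft segmentation and the fixed threshold

Rafts are contiguous regions of low mobility. The package uses a single
fixed threshold `raft_mobility_threshold()` = 0.07 shared by all
conditions — the analogue of carrying one fitted threshold across
scenarios. It was calibrated once against the default force field and
rule: at 0.07 the segmented domains are strongly enriched in
saturates, sphingolipids and cholesterol and the per-condition
statistics are insensitive to small changes of the value. A per-map
alternative (`auto_tau()`) places the threshold at the antimode of the
mobility histogram when it is clearly bimodal and falls back to the
10th percentile otherwise; it is exported as a diagnostic, but because
a data-driven threshold moves with each map (and in particular a
percentile pins every condition's raft area to the same fraction), it
erases cross-condition area/size/count contrasts and must not be used
for scenario comparisons.

## Size and number estimators

Raft size is estimated by row-by-row screening: the lengths of maximal
horizontal runs of raft cells (merged across the periodic boundary)
are collected, and their mean ± SD is the size estimate. The run
length is a *chord*, not a diameter: for a disc of radius $r$ the mean
chord over rows is $\pi r/2$. The raft count is the raft area divided
by the area of a circle of the estimated size; by default the mean
chord is converted to an effective diameter with the factor $4/\pi$
first, which makes the count estimator agree (±1) with exact
connected-component labeling on synthetic discs — the package also
ships a periodic-wrap 4-connectivity labeler as the direct
cross-check. Runs of length 1 are kept (no minimum-size filter by
default). Sizes are reported in lattice cells; the lattice has no
calibrated physical pitch, so no absolute nm scale is claimed.

## Peroxidability

The peroxidability index of a composition is the linear score

$$PI = 0.025\,\%\text{monoenes} + 5\,\%\text{n-6 LCPUFA} + 6\,\%\text{DHA},$$

restricted to the unsaturated classes present in the model; the other
four classes contribute zero, and $0 \le PI \le 600$ (pure DHA). PI
maps tile the lattice into non-overlapping 5 x 5 patches (a 200 x 200
lattice gives a 40 x 40 map); each patch's class census is converted
to percentages and scored. Region scores (`domain_pi()`) apply the
same formula to the composition inside rafts, outside rafts, and of
the whole lattice; PI is linear, so the whole-membrane value equals
the area-weighted combination of the two regions, which is asserted
exactly in the tests. Scenario summaries report the mean patch PI
(the patch total is a trivial multiple).

## Validation against random compositions

The significance check simulates an ensemble (default 100) of
membranes with *random* lipid compositions and computes, per draw, two
squared distances on the percent scale:
$\Delta^2(a, b) = \sum_{c} (a_c - b_c)^2$ between (i) the random
membrane and its own simulated raft composition and (ii) the simulated
raft composition and a fixed experimental raft reference. Random
compositions are symmetric-Dirichlet($\alpha = 1$) draws on the
seven-class simplex — uniform over compositions, the least informative
reading of "random proportions"; $\alpha$ is configurable. The 95%
interval is the empirical 2.5/97.5 percentile band (no normality
assumption). A data-driven solution passes when its statistic (ii)
falls below the random upper bound; `validate_solution()` also reports
whether statistic (i) falls outside the random interval. Draws whose
raft region comes out empty (possible for extreme random compositions)
are flagged, counted, and resampled.

This ensemble doubles as the package's synthetic-data generator. It
emulates compositional variability only: real membranes are not
Dirichlet-distributed, have correlated class abundances, undergo
homeoviscous remodeling, and contain proteins — none of which the
generator (or the model) represents. Passing the validation therefore
shows that the experimental compositions carry real signal relative to
arbitrary ones, not that the model captures membrane biology at large.

## Numerical and reproducibility choices

* All randomness flows through R's RNG; one integer seed fully
  determines a trajectory (initial arrangement, sweep permutations,
  neighbor choices, acceptance draws), and scenario runs derive
  per-replicate seeds from a single master seed, so reruns are
  bit-identical.
* Periodic boundaries everywhere (dynamics, binding, run merging,
  labeling) to avoid edge artifacts in domain statistics.
* Empty-region compositions raise explicit errors rather than
  returning silent zeros; an empty mask yields size 0, count 0.
* The `desk` preset sizes (100 x 100, 300 iterations; validation
  ensembles of 20; the interval-calibration check at 64 x 64, 200
  iterations with 100 + 200 draws) were chosen as the smallest scales
  at which the segregation statistics are stable across seeds.

## Known limitations

* The acceptance rule and $\theta$ are a model *choice*; only the
  qualitative monotonicity ("higher force, lower switching
  probability") is anchored, and both the rule and its scale are
  exposed as configuration for sensitivity analysis.
* Raft sizes are in lattice cells; no physical length scale is fitted.
* Sphingolipid enrichment in simulated rafts falls well short of
  experimental raft fractions (the hardest class for this force
  field), which inflates the simulated-vs-experimental $\Delta^2$ —
  visible in the validation reports.
* The model conserves composition and simulates a single leaflet: no
  flip-flop, no exchange with the environment, no proteins, no
  peroxidation chemistry (PI is a static susceptibility score).
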