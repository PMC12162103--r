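---
title: "Modeling the HNSCC tumor microenvironment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the HNSCC tumor microenvironment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmedyn)
```

## The model

`tmedyn` simulates the cellular and molecular ecology of the head and neck
squamous cell carcinoma (HNSCC) tumor microenvironment (TME) as a
deterministic, spatially homogeneous ODE system over 24 state variables:
15 cell-state populations and 9 secreted molecular species.

The cell states are three tumor phenotypes — stem-like (`C0`), PDL1−
(`Cneg`), and PDL1+ (`Cpos`), each split into a killer-T-*exposed* and a
CAF-*protected* compartment — plus PD1+ and PD1− killer T cells, helper,
regulatory and exhausted T cells, M1/M2 macrophages, and wild-type versus
cancer-associated fibroblasts (CAF). The molecular species are IL-2, IL-8,
IL-10, LIF, IFN-γ, IRF8, OPN, ICAM1 and lactate.

Every equation is assembled from six reusable rate laws
(see `?flux_proliferation` and friends):

* **logistic proliferation** `Kprol·x·(1 − occupancy)`, where the
  occupancy is the total of a *capacity pool* (cells of one type, or all
  six tumor compartments) over its carrying capacity;
* **first-order conversion** between states of one cell type, optionally
  gated by saturating occupancy factors `m/(V + m)` of mediating species
  (IL-8 gates stem→PDL1−, IFN-γ gates PDL1−→PDL1+, LIF gates
  fibroblast→CAF, IL-10 gates M1→M2, and PD1+ killer-T exhaustion
  requires both exposed PDL1+ tumor cells and M2 macrophages);
* a **paracrine multiplier** `1 + Kpara·α·x/(V + a·x)` on the target's
  proliferation flux (CAF and exhausted T cells promote tumor growth; OPN
  drives CAF autocrine renewal; CAF promotes Treg and M2 growth; helper T
  cells, IFN-γ and IL-2 promote killer-T growth; exposed PDL1− tumor
  cells and IFN-γ activate helper T cells);
* a **regulatory inhibition factor** `1/(Vreg + α·x)` (Treg ⊣ helper-T
  proliferation, IRF8 ⊣ OPN secretion, lactate ⊣ killer-T cytotoxicity);
* **mass-action elimination** `Kkill·α_ac·x_target·x_killer` (killer T
  cells destroy exposed stem and PDL1− tumor cells; after anti-PD1, PD1−
  killer T cells also destroy exposed PDL1+ cells);
* **first-order death / degradation** for every state.

Molecular species obey
`d[m]/dt = Σ_cells Ksec·x_cell·(regulatory factor) − KD·[m]`.
With no constant source terms the all-zero state is an exact fixed point.

## Immune accessibility

CAF remodel the extracellular matrix and exclude killer T cells. The
package represents this with the **immune accessibility index**

\[ I_a = 1 - \tanh(\alpha \cdot \mathrm{CAF} \cdot K_{br}) \in (0, 1], \]

recomputed at every right-hand-side evaluation from the instantaneous CAF
population (`accessibility_index()`). It acts in three places:

1. **Compartment split.** Each tumor phenotype migrates between its
   exposed and protected compartments by a conserving first-order exchange
   whose equilibrium is the accessibility partition
   `exposed/protected → I_a` (the `partition_capacities()` split of the
   common capacity). The exchange rate `Kmig` is a registry parameter.
2. **Barrier penetration.** Elimination edges never target protected
   compartments directly; every exposed-compartment kill flux is mirrored
   onto the protected twin scaled by `exp(-α²·δ·CAF²)`
   (`barrier_penetration()`), the probability that a killer T cell
   penetrates a CAF barrier of width δ.
3. **Frozen scans.** `freeze_Ia` holds the index at a constant for
   dose-response scans across accessibility levels.

All six tumor compartments compete for a single fixed resource capacity
`xmax_tumor`: their logistic terms share one occupancy
`Σ tumor / xmax_tumor`. This resource coupling is load-bearing: when
checkpoint therapy eliminates exposed tumor cells in a poorly accessible
TME, protected cells reclaim the freed resources, leaving the total tumor
burden nearly unchanged — the hallmark of the fibro-dominated
non-response. A variant with separate per-compartment capacities
partitioned by \(I_a\) was tried during development and discarded because
it cannot produce this compensation.

The two fibroblast phenotypes occupy separate niches (quiescent stroma
vs remodeled matrix), each with the full fibroblast capacity: CAF is
sustained jointly by OPN-driven autocrine renewal
(`Kprol_CAF · (1 + paracrine) > KD_CAF` only when OPN is present) and by
LIF-gated conversion from a standing wild-type pool. Both supports are
individually non-essential but jointly necessary, which is what makes
single (OPN-only or LIF-only) and combined knockouts behave differently.

## The registry

The full model has exactly 91 named parameters (`nominal_parameters()`;
the count is enforced by a self-check): 12 proliferation rates, 7 carrying
capacities, 11 cell death rates, 9 molecular degradation rates, 5
conversion rates with 3 gate constants, 1 migration rate, 9 paracrine
(gain, dissociation) pairs sharing one cell–cell proximity index
`alpha_prox` (molecular mediators act at proximity 1; the saturation
coefficient `a` is fixed at 1), 3 regulatory pairs, 3 elimination rates
with one accessibility factor, 9 secretion rates, 3 accessibility
hyperparameters (`alpha_acc`, `Kbr`, `delta_br`), and the 2 anti-PD1
intervention parameters (`k_bind_pd1`, `dose_pd1`, dose 0 = untreated).

Units: time in days, populations in cells, concentrations in arbitrary
units. Magnitudes follow the conventions of tumor–immune population
models: growth rates of order 0.1–1 per day, capacities of order
10³–10⁴ cells, molecular turnover of order 1 per day. Since no published
value set exists for this network, the nominal registry is the package's
own calibration: it was iterated during development until the baseline
model expresses the qualitative behaviors the network is built to
explain — all five TME compositions reachable by parameter tilts, three
distinguishable immune-desert mechanisms, coexisting macrophage phases,
dual CAF maintenance, and no accidental near-critical balances at nominal
(an early draft left helper-T growth within 1% of its death rate, which
produced 10⁴-day transients). The registry is therefore a reference
condition, not a fit to data.

## Steady states, classification and sweeps

`steady_state()` integrates with a stiff variable-step solver
(lsoda; relative tolerance 1e−6, absolute 1e−9) in windows of 100 days
until the scaled residual `max |dx/dt|/(1 + |x|)` drops below `tol`
(default 1e−6 per day; a scaled residual is used because an absolute one
is unattainable at populations of 10⁴ with finite solver tolerances).
Non-convergence yields `converged = FALSE`, never an error; tiny negative
solver overshoots (to −1e−6) are clipped to zero.

`classify_steady_state()` maps converged summaries to the five clinically
recognized compositions with thresholds at 2% of the relevant carrying
capacities: *desert* (killer T and CAF both absent), *immune desert*
("fibrotic only"), *fibro desert* ("immune/non-fibrotic"),
*fibro-dominated* (CAF ≥ killer T with a high tumor burden) and
*immune-dominated* otherwise. Threshold sensitivity is guarded by a test:
±20% threshold shifts relabel under 3% of a 1000-sample sweep.

`run_sweep()` draws Latin-hypercube samples (log₁₀ scale) of the 28
parameters that directly govern proliferation, death and conversion of
the tumor, killer-T and CAF populations plus the accessibility
hyperparameters, over 0.1×–10× nominal (the CAF proximity fraction is
capped at 1). The shipped analyses use 1000 samples with a 1500-day
horizon and a 1e−5 residual tolerance; samples still drifting at the
horizon (about a quarter, mostly near-critical balances) are reported as
unconverged and excluded from group statistics. The balance metric
`zeta()` — the natural-log ratio of a state's maximum proliferation
factor `Kprol·Π(1 + Kpara)` to its summed kill, conversion and death
rates — orders the groups as the mechanism predicts (natural log is used
throughout).

## Interventions

* `apply_anti_pd1()` adds a PD1-removal conversion `k_bind·dose·TKp` into
  the exhaustion-immune PD1− pool and elimination edges from PD1− killer
  T cells onto exposed PDL1+ tumor cells. Dose 0 returns the model object
  unchanged. An optional `exhaustion_block` also scales the residual PD1+
  exhaustion rate.
* `il2_spike()` increments the IL-2 entry of an initial state. IL-2 is
  secreted by killer T cells only, so a depleted TME has near-zero
  ambient IL-2 and the spike-versus-rescue threshold is a genuine
  bistability: `scenario_il2_threshold()` locates it by grid scan plus
  bisection to 1% relative precision, returning `Inf` when the IL-2
  autocrine gain is below the rescue floor.
* `knockout()` in `production_zero` mode scales every secretion rate
  feeding a species by `1 − fraction` (the "reduction rate" style
  intervention used for OPN and LIF); `clamp_zero` adds an absorbing
  first-order sink (10⁴ per day × fraction) for idealized knockouts.
  Knockout scenarios start from the established baseline steady state,
  since the therapeutic question concerns an existing TME.

The ICI protocol used by the scenario runners re-seeds a small killer-T
population (1% of capacity) and IL-2 floor before applying the drug,
reflecting that a checkpoint trial presumes some killer T cells reach the
tumor; the biomarker readouts deliberately omit this re-seeding so that a
true desert shows exactly no post-treatment change.

## Scenario conventions and numerical choices

* Immune-desert mechanisms: *Treg-driven* is read off the steady state
  (regulatory T cells above 30% of capacity); *low-proliferation* from the
  balance `Kprol·(1 + helper support at half saturation) < KD`;
  *exhaustion-driven* from `Kconv_TKp_TEx ≥ KD_TKp`. A flux-balance call
  is needed for exhaustion because a fully collapsed killer pool leaves
  the exhausted pool without influx — its steady state decays even when
  the transient is dominated by exhausted cells.
* Biomarker signs use a 0.05% relative dead band: a state that changes by
  less than the band counts as "unchanged". The shipped fibro-dominated
  exemplar changes IL-8 by about +0.1%, i.e. a factor ≈2 above the band —
  the increase is small because tumor cells dominate the IL-8 source pool,
  matching the "slight increase" character of the observation it encodes.
* Exemplar registries (`subtype_exemplars()`) are multiplicative tilts of
  the nominal registry, documented in their help page; they are curated
  entry points, not outputs of the sweep (use
  `representative_parameters()` for sweep medoids).
* Threshold locations (IL-2 spike, OPN fraction) are found by scanning
  plus bisection; no continuation methods are used.
* Problem sizes in the shipped tests: 1000-sample sweeps, 100-state
  oracle comparisons, scenario grids of 8–12 steady states — sizes chosen
  so the full suite documents the model's behavior while remaining
  routinely runnable.

## What the synthetic inputs do and do not show

All inputs are synthetic: the network is a literature-derived atlas and
the registry a calibrated reference condition. Passing tests demonstrate
that the *mechanistic logic* of the network — compartmental protection,
resource compensation, exhaustion balances, dual CAF maintenance,
IL-2 bistability — produces the qualitative subtype phenomenology and
intervention responses it was built to explain. They do not validate
rate constants against patients, nor calibrate dose units; trajectories
are in model days and arbitrary concentration units.

## Known limitations

* Lactate in the fibro-dominated exemplar *decreases* marginally after
  checkpoint therapy (lactate tracks total tumor burden), whereas reports
  of poorly accessible tumors suggest a slight increase; the IL-8
  contrast between subtypes, which the biomarker analysis rests on, is
  reproduced.
* Exhausted-T steady states require killer-T influx; purely
  exhaustion-driven deserts carry their exhausted signature in the
  transient, not the terminal state.
* The model is deterministic and spatially homogeneous: no Gillespie
  semantics, no spatial heterogeneity, no HPV-status mechanism (low
  accessibility serves as a proxy), no B-cell states, and no parameter
  estimation from patient data.
* ICAM1 is a read-out species only; its downstream wiring is not modeled.
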