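---
title: "Modeling contact-dependent growth inhibition in expanding colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling contact-dependent growth inhibition in expanding colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`cdicolony` simulates competition between two bacterial strains growing as a
mixed colony on a surface, where one strain (the *inhibitor*) carries a
contact-dependent growth inhibition (CDI) system — a Type Vb secretion
apparatus that delivers a growth-arresting toxin into touching *target*
cells. The questions the package is built to ask are ecological: when does
carrying a CDI system pay off in a spatially structured population, and how
do the system's kinetic parameters and the initial population structure
(inoculation density) shape the outcome?

## Cells and mechanics

Cells are rigid capsules (spherocylinders) confined to the plane, described
by center, axis angle, cylinder length $L$ (between cap centers) and cap
radius $r$. Three types exist: targets, inhibitors, and inhibited
(intoxicated) targets.

Growth is exponential elongation of the pole-to-pole length $E = L + 2r$:

$$\frac{dE}{dt} = \alpha_{\mathrm{eff}}\,E, \qquad
\alpha_{\mathrm{eff}} = \begin{cases}
\alpha & \text{target}\\
\alpha(1-\beta) & \text{inhibitor (cost } \beta)\\
\alpha(1-\delta) & \text{inhibited target (toxicity } \delta)
\end{cases}$$

Two readings of the discrete update exist. The literal per-step increment
$\Delta L = \alpha L \Delta t$ (exposed as
`unconstrained_elongation(method = "euler")`) compounds to
$L(1+\alpha\Delta t)^n$, whose doubling time at $\Delta t = 0.05$ h and
$\alpha = \ln 2 / 0.5\,\mathrm{h^{-1}}$ is ~3.5% longer than $\ln 2/\alpha$.
The engine default (`"exact"`) integrates the law exactly over the step,
$\Delta L = E\,(e^{\alpha \Delta t} - 1)$, so that macroscopic doubling times
equal $\ln 2/\alpha$ independent of the step size. We consider $\alpha$ the
biologically meaningful exponential rate and treat the first-order product as
a discretization of it, not as the model itself.

Growth acts on the pole-to-pole length because division — at a stochastic
target length drawn from $\mathcal N(3.5, 0.35^2)$ µm (truncated at $2r$) —
splits the parent into two daughters whose capsules exactly tile the parent:
each daughter cylinder is $(L - 2r)/2$, so summed pole-to-pole extents are
conserved at the division instant. Under this pairing a free lineage's total
extent is *exactly* exponential, which is what the growth-law acceptance
test asserts. Daughter axes are the parent axis perturbed by independent
Uniform(±0.1 rad) angles — a small default that preserves cell files while
still letting them buckle — and each daughter draws a fresh division target.

Crowding is handled by damped sequential pairwise projection: for each
touching pair, both cells are displaced apart along the line joining the
closest core points by half the overlap times a damping factor (0.7), plus a
small torque-like axis correction, swept over all near-contact pairs up to
50 times per step or until the worst overlap falls below 0.01 µm. Dense
colony interiors do not converge within the sweep budget — deliberately so:
the persistent overlap is the pressure signal that suppresses interior
growth. Each cell's realized elongation is

$$\Delta L_{\mathrm{real}} = \Delta L \cdot
\max\!\big(0,\ 1 - \kappa \textstyle\sum_c \max(0,\ o_c - o_{\mathrm{tol}})\big)$$

where $o_c$ are the overlap depths of its contacts at the start of the step
and $o_{\mathrm{tol}} = 0.01$ µm is the solver residual (subtracted so that
fully relaxed configurations feel no pressure). $\kappa = 50\ \mathrm{µm^{-1}}$
makes deeply jammed cells (several contacts at the persistent ~0.1–0.3 µm
interior overlap) realize essentially none of their unconstrained
elongation, while edge cells elongate freely. $\kappa$ was calibrated
against the emergent radial expansion speed: the full-scale experiment grows
from a 200 µm inoculum to a ~4×10^5 µm² colony in 35 h (~4.5 µm/h); the
attenuation saturates near ~6 µm/h in this solver, and $\kappa = 50$ sits at
that plateau. The emergent behavior — growth
confined to the expanding rim, near-linear radius growth, sector formation
by drift — is the contract; the specific attenuation law and its constants
are package design choices.

Contact is defined as surface separation ≤ 0.05 µm (a small positive skin
that keeps touching pairs from flickering in and out of contact between
steps). Contacts are found with a uniform grid hash whose bucket edge equals
the largest capsule extent, making queries near-linear while provably
reproducing the all-pairs computation (tested against an $O(n^2)$ oracle).

## CDI kinetics

Inhibition is stochastic and contact-gated. A susceptible target touching
$k \ge 1$ inhibitor cells is intoxicated with propensity $\eta k$ — $\eta$
is per hour *per contacting inhibitor cell*; with the two-inhibitor contact
neighborhood used as the reference configuration, $\eta = 1\,\mathrm{h^{-1}}$
corresponds to a 30-minute mean contact time and $\eta = 0.1\,\mathrm{h^{-1}}$
to 300 minutes. Waiting times are managed by a next-reaction (Gibson–Bruck)
scheduler: an indexed binary min-heap holds one putative firing time per
cell, drawn as $\tau = t + \mathrm{Exp}(1)/a$. When a pending reaction's
propensity changes from $a$ to $a'$ (the contact count changed), the
remaining wait is rescaled, $\tau' = t + (a/a')(\tau - t)$; at $a' = 0$
(contact lost) the reaction is removed, and a fresh exponential is drawn if
contact is later re-established — exact by memorylessness, and verified
distributionally against direct Gillespie oracles (including a mid-wait rate
change and an on/off toggling contact).

An inhibited target that has lost *all* inhibitor contact recovers at rate
$\mu = 0.01\,\mathrm{h^{-1}}$ — recovery is kept constant and low; in dense
colonies contact loss is rare, so the choice has little effect, and it is
exposed as a parameter. Inhibitors never change type; inhibition state is
inherited at division (the parsimonious choice for a cytoplasmic toxin), and
pending reactions of a divided parent are discarded and re-derived from the
daughters' contacts at the next step.

The scheduler is coupled to the mechanics at one contact rebuild per
timestep ($\Delta t = 0.05$ h, 700 steps = 35 h at full scale): each step
(1) rebuilds contacts, (2) synchronizes pending reactions, (3) fires
reactions due in the step window, (4) grows and relaxes with type-dependent
rates, (5) divides. A reaction fired within a window affects the growth update of
that same step; at $\Delta t = 0.05$ h the alternative (deferring the new
growth rate by one step) differs by less than any quantity measured.

## Inoculation

$N = \mathrm{round}(\rho \cdot \pi R^2 / 1000)$ cells ($\rho$ in cells per
1000 µm²) are placed uniformly at random (position and orientation) in a
central disc of radius $R$ (200 µm at full scale), with exactly
$\mathrm{round}(N f)$ inhibitors assigned by draw without replacement and
initial lengths uniform between birth length and division target (uniform
over the cell cycle's length range approximates an unsynchronized
population). Residual
placement overlaps are relaxed before $t = 0$; an inoculum too dense to
relax is an error with advice rather than a silent jam.

# Analyses

All composition statistics treat inhibited targets as targets (the ratios of
interest are strain ratios; intoxication is a state, not a strain).

* **Radial profile** — cells are binned into annuli of width 20 µm around
  the cell centroid; each annulus reports counts and the inhibitor ratio
  $I/(I+T)$.
* **Sector strips** — within an annulus, cells are discretized by polar
  angle into bins of roughly one mean cell diameter of arc (minimum 16
  bins), the per-bin mean type code (inhibitor = 1) is smoothed with a
  circular Gaussian kernel ($\sigma$ = 3 bins) and thresholded at 0.5 (ties
  to inhibitor), repeatedly until the binary strip is a fixed point — this
  removes all single-bin runs, mirroring "smooth until no effect and all
  singletons removed". The discretization bin rule and threshold are package
  choices (unprinted in the source); annuli with fewer than 3 occupied bins
  are flagged too sparse. Strips live on a circle: sectors never split at
  angle 0.
* **Sector count** — transitions from inhibitor (1) to target (0) around
  the circle; on a circle this equals the number of target sectors and of
  inhibitor sectors, and is rotation- and relabeling-invariant.
* **Sector sizes** — maximal circular runs × $2\pi/n_{\mathrm{bins}}$
  radians; per annulus the largest target and inhibitor sectors are
  reported, with the strip length notionally normalized to the largest
  annulus radius (the normalization factor is recorded; angular sizes are
  unaffected).
* **Neighbor index** —
  $\log_2(I_{t_\mathrm{end}}/T_{t_\mathrm{end}}) -
  \log_2(I_{t_0}/T_{t_0})$ over cells at the inter-strain contact interface
  (inhibitors touching ≥ 1 target; targets touching ≥ 1 inhibitor).
* **Relative fitness** —
  $\ln(S1_\mathrm{end}/S1_0) / \ln(S2_\mathrm{end}/S2_0)$.

# What the synthetic colonies do and do not establish

The simulations reproduce the qualitative regime the model was built for:
well-mixed growth inside the inoculum disc, radial expansion with strain
demixing into sectors, contact-frequency-dependent CDI benefit. They do not
emulate: three-dimensional colony structure, nutrient gradients,
motility/aggregation, mutual (bidirectional) inhibition, or any feature of
the wet-lab imaging pipeline. A green colony-scale test therefore
establishes that the implemented mechanism produces the expected *ordering*
of outcomes (rate dominance over toxicity, density dependence, cost
effects), not the quantitative endpoint ratios of the full-scale experiment,
which depend on colony size.

## Scale of the test suite

The full experiment (inoculum radius 200 µm, 700 steps, ~150,000 cells) and
even the "desk" CLI profile (50 µm, 350 steps) exceed a reasonable test-time
budget, so the colony-level acceptance tests run at radius 33.5 µm for 120
steps (6 h) with 10 replicate seeds per condition. 33.5 µm is chosen so
that the inoculum size is even at all three densities (6, 56 and 564 cells
at 1.6, 16 and 160 cells/1000 µm²), making the 50:50 inoculum exact —
important because the neutral-control criterion is a ±0.05 band around 0.5
and integer rounding at small N would bias it. Consequences of the reduced
scale: the low-density condition has only 6 founders, so neutral drift noise
is near the band's resolution, and effect sizes (e.g. the CDI benefit at
high density) are smaller than at full scale, though their ordering is
preserved.

# Numerical choices and degenerate inputs

* Relaxation: damping 0.7 per sweep, torque gain 0.5 with per-sweep rotation
  capped at 0.05 rad, residual tolerance 0.01 µm, 50-sweep budget, neighbor
  lists rebuilt every 10 sweeps with a 0.3 µm skin; convergence is only
  accepted when verified against a freshly rebuilt neighbor list (a stale
  active set can hide overlaps created by force chains). Failure to converge
  sets a jam flag and is counted, never thrown.
* Capsules with coincident cores are separated along the first cell's
  perpendicular (an arbitrary but deterministic tie-break).
* Exactly one pending reaction can exist per cell (a cell is either awaiting
  inhibition or awaiting recovery); scheduling a duplicate is a contract
  violation, firing for a divided (absent) cell id is dropped as stale.
* Snapshots are plain TSV with a `#` header carrying time, seed and a
  64-bit FNV-1a parameter hash; identical parameters and seed reproduce
  byte-identical tables.
* Empty colonies, zero-density inocula and `n_steps = 0` are all valid and
  covered by tests.

# Known limitations

* The mechanical solver is a projection scheme, not the energy-minimization
  machinery of established capsule-cell frameworks such as CellModeller;
  only the emergent contracts (edge
  growth, center jamming, linear radius growth, neutral sector coarsening)
  are matched, and quantities like the expansion speed are not calibrated to
  the original.
* Strictly 2D; no periodic boundaries; no cell death or lysis.
* The per-annulus discretization constants (bin width, threshold, tie rule)
  are package choices; sector counts on experimental images may differ in
  absolute terms while preserving trends.
* Downstream inferential statistics (robust two-way ANOVA, GLMs, Tukey
  tests) are out of scope; the package emits tidy
  per-run and per-annulus tables for use with standard R tools.
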