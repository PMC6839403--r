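# cdicolony

Individual-based simulation of **contact-dependent growth inhibition (CDI)**
in two-dimensional expanding bacterial colonies, with the analysis suite used
to quantify the outcome of CDI-mediated competition.

Many bacteria carry CDI systems (Type Vb secretion): on cell–cell contact an
inhibitor cell delivers a toxin that slows or arrests the growth of a
susceptible target cell. Whether carrying such a system pays off in a colony
is not obvious — colonies demix into single-strain sectors during range
expansion, so most contacts are with kin. This package is for researchers in
microbial ecology and sociobiology who want to dissect that question in
silico: it simulates mixed inhibitor/target colonies growing from a random
inoculum and measures how the CDI parameters and the inoculation density
shape the final population structure.

## Model

Cells are rigid capsules in the plane that elongate exponentially,

    dE/dt = alpha_eff * E,     E = pole-to-pole length

with `alpha_eff = alpha` for targets, `alpha (1 - beta)` for inhibitors
(cost of carrying the system), and `alpha (1 - delta)` for intoxicated
targets (toxicity). Cells divide in half at a stochastic target length;
crowding is resolved by damped pairwise overlap projection, and contact
pressure suppresses elongation, so growth concentrates at the expanding
colony edge — sectors emerge from genetic drift at the front.

Inhibition is contact-gated and stochastic: a target touching `k` inhibitor
cells is intoxicated with propensity `eta * k` (h^-1 per contacting
inhibitor; waiting times are exact next-reaction / Gibson–Bruck draws on a
dynamic contact graph, with rescaling when contacts change, removal on
contact loss, and recovery at rate `mu` once all inhibitor contact is lost).

Analyses: radial annulus composition `I/(I+T)`, sector counts and sector
sizes (radians) from circular-Gaussian-smoothed binary strips, the neighbor
index `log2(I_end/T_end) - log2(I_0/T_0)` over interface cells, and relative
fitness `ln(S1_end/S1_0) / ln(S2_end/S2_0)`.

## Worked example

A high-density competition with fast, low-toxicity CDI (`eta = 1` h^-1 per
contact, `delta = 0.2`) at reduced scale:

```r
library(cdicolony)
p <- sim_params(inoculum_radius = 20, inoculum_density = 160, n_steps = 120,
                eta = 1, delta = 0.2, seed = 1)
run <- run_colony(p)
print(run)
#> colony_run: 4 snapshots, final t = 6.00 h, 3010 cells, 7.0 s wall
#>   inhibitor proportion 0.669; jammed steps 112; seed 1

radial_profile(run$final, annulus_width = 10)[, c("r_in_um", "r_out_um",
                                                  "ratio", "n_sectors")]
#>   r_in_um r_out_um ratio n_sectors
#> 1       0       10  0.51         2
#> 2      10       20  0.53         2
#> 3      20       30  0.56         6
#> 4      30       40  0.67         6
#> 5      40       50  0.77         4
#> 6      50       60  0.82         6

c0 <- interface_counts(run$snapshots[[1]])
c1 <- interface_counts(run$final)
neighbor_index(c0["I"], c0["T"], c1["I"], c1["T"])
#> 0.158
```

Reading the output: the colony started 50:50 and ended 67% inhibitor. Inside
the inoculum disc (first two annuli, up to the ~20 µm inoculum radius) the
ratio stays near 0.5 — the population there filled before much inhibition
could act. The inhibitor advantage grows with radius (0.56 → 0.82) as
intoxicated target sectors lose the race for the expanding front, and the
largest surviving target sectors shrink outward. The positive neighbor index
says inhibitors outnumber targets at the inter-strain interface at the end —
the contact boundary advances into target territory.

## Command line

```sh
Rscript inst/cli/cdicolony run --config inst/extdata/example.cfg \
    --profile desk --seed 1 --out-dir out/
Rscript inst/cli/cdicolony sweep --eta 0.1,1 --delta 0.2,1 \
    --inoculum_density 1.6,16,160 --replicates 10 --profile desk --out-dir sweep/
Rscript inst/cli/cdicolony analyze out/snapshot_t0.tsv out/snapshot_final.tsv \
    --out-dir analysis/
Rscript inst/cli/cdicolony plot out/snapshot_final.tsv --out-dir plots/
```

`--profile desk` is a reduced-scale profile (inoculum radius 50 µm, 350
steps); `--profile paper` is the full-scale experiment (200 µm, 700 steps =
35 h, ~150,000 cells — hours of CPU). Every `sim_params()` key is accepted
as a `--key value` override; outputs embed the RNG seed and a parameter hash
so runs replay bit-identically.

## Further reading

`vignettes/cdicolony-methods.Rmd` documents the model assumptions, the
numerical choices (solver constants, discretization, tie-breaks), what the
reduced-scale tests do and do not establish, and known limitations.
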