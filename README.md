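# macpol

Continuous fuzzy-logic modelling of macrophage polarization networks.

Macrophages polarize along a spectrum of phenotypes — pro-inflammatory
M1-types and regulatory/wound-healing M2 subtypes (M2a–M2d) — steered by the
cytokines and metabolic byproducts of their microenvironment. Boolean models
of the underlying transcriptional regulatory network capture the attractor
structure of this decision but not the *continuous* dependence on cytokine
concentration: at what dose does a monocyte commit, how wide is the zone
where no phenotype can be assigned, and which hybrid states appear in
between. `macpol` answers those questions for any Boolean regulatory network
by transforming it into an ODE system and scanning its steady states. It is
aimed at systems immunologists and logical-modelling practitioners who want
dose–response and phenotype-landscape readouts from rule-based networks.

## The model

Each node *i* carries a normalized expression level *qᵢ(t) ∈ [0,1]*. Its
Boolean update rule is made continuous by the probabilistic fuzzy-logic
composition

    q AND p  ->  q·p
    q OR  p  ->  q + p − q·p
    NOT   p  ->  1 − p

giving a fuzzy truth value ωᵢ(q) ∈ [0,1] that coincides with the Boolean
rule on 0/1 states. The activation drive is the sigmoid characteristic
function

    φ[ω] = 1 / (1 + exp(−b (ω − ω_thr))),     ω_thr = 0.5

with steepness *b* (package default 25), and the dynamics are

    dqᵢ/dt = φ[ωᵢ(q)] − αᵢ qᵢ,     αᵢ = 1,

so at steady state each node's expression equals the degree of truth of its
rule passed through φ. Extracellular nodes are pure inputs carried as
zero-derivative state components, clamped to microenvironment
concentrations. A steady state is labeled by thresholding marker
transcription factors — active at ≥ 0.75, inactive at ≤ 0.25, any marker
strictly in between puts the state into the *range of uncertainty*
(`NoLabel`) — with markers NFkB → M1, STAT1 → M1a, STAT6 → M2a, ERK → M2b,
STAT3 → M2c, HIF1a → M2d and hybrid labels concatenated in canonical order.

The package ships a 29-node, 60-interaction macrophage network
(14 transcription factors, 15 extracellular components) whose rule set is a
documented reconstruction (see `inst/extdata/macrophage_trn.txt` and the
vignette), plus a random-network generator and an exhaustive synchronous
Boolean attractor oracle so every pipeline stage is testable on networks
with known ground truth.

## Worked example: interferon dose scan

```r
library(macpol)

net <- macrophage_network()   # 29 nodes, 60 interactions
sys <- build_ode_system(net)  # 29 ODEs, b = 25

res <- dose_scan_1d(sys, scan_spec_1d("IFNG", step = 0.025))
res
#> dose_scan_1d over {IFNG}: 41 grid points
#>   labels: M0 x19 | NoLabel x3 | M1a x19
#>   transitions at: 0.475 (M0 -> NoLabel); 0.55 (NoLabel -> M1a)

find_transition_threshold(res, "M0", "M1a")
#> $value
#> [1] 0.55
#> $band
#> [1] 0.475 0.525
```

Reading: below an interferon-gamma concentration of 0.475 the monocyte stays
unpolarized (M0); between 0.475 and 0.525 the STAT1 marker sits strictly
between the inactivation and activation thresholds, so no phenotype can be
assigned (the range of uncertainty); from 0.55 upward the cell commits to
the STAT1-driven M1-type phenotype M1a. The steady state at the transition:

```r
st <- integrate_to_steady_state(sys, clamps = clamp_set(IFNG = 0.55))
round(st$q[c("STAT1", "NFkB", "STAT6", "ERK", "STAT3", "HIF1a")], 4)
#>  STAT1   NFkB  STAT6    ERK  STAT3  HIF1a
#> 0.7773 0.0000 0.0000 0.0000 0.0000 0.0000
label_state(st)$label
#> [1] "M1a"
```

Only STAT1 is above 0.75: an interferon-specific M1-type macrophage. By
contrast, an IL-6 scan (`dose_scan_1d(sys, scan_spec_1d("IL6e"))`) shows an
*abrupt* M0 → M1 jump at 0.45 with no uncertainty band — the signature of a
bistable NFkB/AP1 positive feedback loop igniting.

Other experiment families: `microenvironment_scan()` (robustness of a
polarized state under joint cytokine presets, `microenvironment_presets()`),
`tgem_scan()` (constant genetic perturbations, NFkB clamped on / HIF1a
clamped off), and `phenotype_map_2d()` (transcription-factor competition
maps over initial conditions and clamps).

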