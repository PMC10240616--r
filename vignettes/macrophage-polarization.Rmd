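---
title: "Continuous fuzzy-logic modelling of macrophage polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous fuzzy-logic modelling of macrophage polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macpol)
```

## The model and its assumptions

`macpol` turns a Boolean transcriptional regulatory network (TRN) into a
continuous dynamical system. A TRN here is a directed signed graph over two
node classes: *extracellular* components (cytokines, immune complexes,
metabolic byproducts) that are pure inputs, and *transcription factors*
(TFs), each governed by one AND/OR/NOT update rule over other nodes. The
Boolean picture gives attractors — candidate cell fates — but treats every
signal as on/off. The continuous extension asks how those fates depend on
*graded* signal concentrations.

Three ingredients define the transformation:

1. **Fuzzy composition.** Each rule's connectives are replaced by their
   probabilistic counterparts: `q AND p → q·p`, `q OR p → q + p − q·p`,
   `NOT p → 1 − p`. The resulting fuzzy truth value $\omega_i(q) \in [0,1]$
   agrees exactly with the Boolean rule on 0/1 states (tested exhaustively
   over every rule's $2^k$ literal combinations), and both fuzzy AND and OR
   are associative and commutative, so the left-associative parse of an
   n-ary connective is immaterial.

2. **Characteristic function.**
   $\varphi[\omega] = 1/(1+e^{-b(\omega-\omega_{thr})})$ maps the fuzzy
   truth value to an activation drive. $\omega_{thr}=0.5$ is the
   inactivation/activation midpoint ($\varphi = 1/2$ there for every $b$);
   $b$ sets how sharply a node saturates.

3. **Dynamics.** $\dot q_i = \varphi[\omega_i(q)] - \alpha_i q_i$ with
   $\alpha_i = 1$, so the steady-state expression of a node is exactly the
   characteristic value of its rule. Extracellular nodes are carried as
   state components with zero derivative — for the macrophage network this
   yields a 29-dimensional system — and are clamped to their
   microenvironment concentration.

Because $\varphi \in (0,1)$ and $\alpha = 1$, the flow points inward at both
faces of the unit box ($\dot q_i > 0$ at $q_i = 0$, $< 0$ at $q_i = 1$):
trajectories never leave $[0,1]^n$. At any Boolean fixed point the residual
obeys $\lVert \dot q \rVert_\infty \le e^{-b/2}$, which is how the
continuous system provably inherits the Boolean attractor skeleton at large
$b$. (One numerical caveat: at $b = 50$ this bound, $\approx 1.4\times
10^{-11}$, has an analytic margin of order $e^{-b} \approx 2\times10^{-22}$,
far below the double-precision spacing at 1.0; the test suite therefore
allows a $10^{-15}$ machine-precision slack on it.)

## Phenotype labeling

A steady state is labeled from marker TFs: NFkB → M1, STAT1 → M1a,
STAT6 → M2a, ERK → M2b, STAT3 → M2c, HIF1a → M2d. A marker is *active* at
$q \ge 0.75$ and *inactive* at $q \le 0.25$ (both inclusive — boundary
values commit, they do not fall into the gap). If any marker lies strictly
between, the state is in the *range of uncertainty* and labeled `NoLabel`.
With no active and no uncertain marker the cell is an unpolarized monocyte,
`M0`. Hybrid states concatenate their active tags in the fixed canonical
order M1 < M1a < M2a < M2b < M2c < M2d, which makes labels independent of
marker-table row order. When NFkB and STAT1 are simultaneously active the
pair collapses to the single tag `M1`: both are M1-type markers, and the
literature uses "M1" for NFkB-driven, STAT1-driven, and doubly active cells
alike. The collapse and the marker set are configurable
(`marker_table()`); in particular ERK was chosen over AP-1 as the M2b
marker, matching how the dose-scan results are phrased, with AP1 retained
as an ordinary network node.

The scalar summary for dose–response plots is the Euclidean distance
between the initial state and the steady state *over TF nodes only* —
clamped inputs would otherwise contribute a trivial offset. The figure
convention this mirrors does not pin down a formal metric, so the per-node
difference vector is attached to every distance for users who prefer
another norm.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `b` | 25 | — | sigmoid steepness of $\varphi$ |
| `omega_thr` | 0.5 | fuzzy truth | activation midpoint of $\varphi$ |
| `alpha` | 1 | 1/time | decay rate, sets the relaxation timescale |
| activation / inactivation | 0.75 / 0.25 | expression | labeling thresholds |
| grid step | 0.025 | concentration | dose-scan resolution |
| `t_max` | 500 | 1/`alpha` | integration horizon |
| `convergence_tol` | 1e-6 | d*q*/d*t* | steady-state criterion |

**Why b = 25.** The steepness is the one free parameter of the
transformation. Small $b$ smears every transition; very large $b$ recovers
hard Boolean switching and erases the graded transitions and uncertainty
bands that motivate the continuous model. With the vendored network's
direct interferon→STAT1 route, $b=25$ places the monocyte→M1a commitment at
an interferon concentration of 0.55 with the uncertainty band spanning
0.475–0.525, and makes the IL-6–driven NFkB/AP1 positive loop ignite
abruptly at 0.45 — the calibration targets for the reconstruction (below).
At $b=25$ the Boolean-limit residual $e^{-b/2} \approx 3.7\times10^{-6}$ is
already negligible. Every scan result records `b` via
`run_metadata_json()`.

**Grid step 0.025.** All reported transition thresholds (0.45, 0.475,
0.525, 0.55, 0.6) are multiples of 0.025; a finer grid may only narrow a
detected threshold by less than one coarse step (asserted as a property).

## The vendored macrophage network is a reconstruction

The shipped 29-node rule file (`inst/extdata/macrophage_trn.txt`) is *data*,
not code: every analysis accepts any conforming network. Its structure —
29 nodes, 60 signed interactions, 14 TFs, 15 extracellular components — and
its mechanisms were rebuilt from the published description of the network
rather than copied from a machine-readable source, and the file is flagged
accordingly. The audit trail for each encoded mechanism:

* STAT6 inactivates NFkB and STAT1 through SOCS1 (`STAT6 → SOCS1`,
  `SOCS1 ⊣ {NFkB, STAT1}`);
* TGFB activates HIF1a by inactivating STAT1 (`TGFB ⊣ STAT1`,
  `STAT1 ⊣ HIF1a`, `TGFB → HIF1a`);
* M2b activation requires immune complexes with IL-1R / glucocorticoid
  co-signals (`ERK` rule over IgG, GCGCR, AP1·IL1B);
* M2c stems from IL-10 via STAT3; MCSF supports it; IL-6's STAT3 arm needs
  co-stimulation and is otherwise diverted to NFkB;
* M2d is driven by hypoxia, TGFB, and adenosine with TLR4 co-stimulation
  (`LPS AND A2a`), opposed by STAT1;
* a self-sustaining NFkB/AP1 loop (with SOCS3) gives the committed M1 state
  its stability at zero input — it is one of the two synchronous Boolean
  fixed points of the fixture under an all-zero environment, the other
  being the monocyte.

Two extracellular nodes beyond the thirteen named in the source description
were needed to reach the stated count of fifteen: LPS (the TLR4 ligand
required by the M2d co-stimulation mechanism) and IL13e (the canonical
second STAT6-activating interleukin). Both are marked reconstructed.

Where the published prose overconstrains a memoryless rule set, the
reconstruction makes a documented choice. Monocyte + TGFB reaching an
M2a-containing hybrid and a committed M1 in an IL-4/TGFB milieu reaching a
*pure* M2d state cannot both hold: once the NFkB loop collapses the two
conditions see identical environments, and the second is a superset of the
first. The fixture follows the monocyte behavior (TGFB → STAT6), so the M1
+ pro-M2a scan settles in M2aM2d. Similarly, under a constant NFkB = 1
perturbation any steady state necessarily carries the M1 tag, so
descriptions of such cells reaching a bare M2a label are unreachable under
clamp semantics; the perturbation scans report what the clamps imply.
Joint interferon scans from the committed M1 state pass STAT1 through the
uncertainty band at intermediate doses, so "invariance" there means: the
label is M1 at every grid value outside the band and no other phenotype
ever appears.

## Numerical choices

* **Integration.** `deSolve::lsodar` with `rtol = 1e-8`, `atol = 1e-10`;
  steady state is detected by the solver's root-finding on
  $\lVert \dot q\rVert_\infty - \text{tol}$ over unclamped TFs, so
  convergence is located by the integrator rather than on a coarse grid. A
  state already at a fixed point returns immediately (idempotence).
* **Horizon.** `t_max = 500` relaxation times. Near a saddle-node ghost
  (e.g. the IL-6 ignition just past 0.45) passage can take on the order of
  50–100 time units; the generous horizon keeps every grid point of the
  shipped scans convergent.
* **Clamps.** A clamped node's derivative is identically zero and its value
  is re-imposed on output, so clamped coordinates are bit-identical to
  their clamp values.
* **Oscillation detection.** If the horizon is reached unconverged, a dense
  terminal window (40 time units, dt = 0.01) is integrated and searched for
  a recurrence of the final state at lag ≥ 0.5 within an infinity-norm
  tolerance of $10^{-2}$, with an amplitude guard so a slow monotone drift
  is classified `undetermined`, not `cyclic`. A coarse-grid recurrence test
  at much tighter tolerance would never fire on a limit cycle with
  non-integer period — unit-spaced samples simply do not revisit the same
  phase — which is why detection happens on the dense window. The
  three-node repressor ring at $b=50$ is the positive control.
* **Degenerate inputs.** Scanning a node with no outgoing edges changes
  nothing downstream (labels constant, no transitions); a 2D map with one
  degenerate axis reproduces the corresponding 1D scan exactly. Both are
  asserted as properties.
* **Independent grid points.** Every scan integrates each grid value from
  the same initial state; there is no continuation between neighboring
  points and hence no artificial hysteresis. Abrupt transitions in the
  results therefore reflect bistability of the dynamics, not protocol
  memory.

## What the synthetic generator emulates — and what it does not

`random_boolean_network()` draws networks from the same structural class as
the macrophage fixture: clamp-only inputs, one AND/OR/NOT rule per TF, up
to `k` regulators, literals negated with probability `p_not`, rule trees
shallow enough that exhaustive truth-table checks stay cheap. Together with
`boolean_attractors_synchronous()` — an exhaustive $2^n$ enumeration of the
synchronous Boolean state space ($n \le 20$; fixed points are
update-scheme-independent, which is all the continuous bridge needs) — it
provides ground truth for every pipeline stage without any external data.

What passing these tests shows: the transformation, integration, labeling
and scanning machinery are correct on networks of this class. What it does
not show: that any particular rule set is a faithful model of macrophage
biology. The generator produces neither realistic degree distributions nor
biologically calibrated cytokine kinetics; real signalling networks also
contain mechanisms (post-translational modification, spatial gradients,
secretion feedback onto the *same* cell's inputs) that the model class
excludes by construction.

## Test and scan problem sizes

The shipped suite exercises: 50 seeded random networks (≤ 10 TFs) plus the
fixture for the Boolean-limit bound at $b \in \{10, 20, 50\}$; 100 random
trajectories for unit-box invariance and fixed-point consistency; full
41-point dose scans of interferon-gamma and IL-6 on the fixture; and
refinement, order-invariance and degenerate-map properties on reduced
windows. These sizes were chosen so the whole suite re-derives every
published quantity it asserts while remaining comfortable to run
interactively.

## Known limitations

* The model is qualitative: time courses are relaxation dynamics toward
  attractors, not calibrated kinetics; only steady-state structure should
  be interpreted.
* No stochasticity, no delays, no spatial diffusion, no extracellular
  matrix — single-cell, well-mixed signalling only.
* Basin volumes over all continuous initial conditions are not computed
  (the initial-condition space is a continuum; the 2D maps slice it along
  chosen axes instead).
* The vendored rule set is a calibrated reconstruction; conclusions that
  depend on fine rule details rather than on the encoded mechanisms should
  be re-checked against a user-supplied rule file (any conforming network
  drops in via `load_network()` or `read_boolnet()`).
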