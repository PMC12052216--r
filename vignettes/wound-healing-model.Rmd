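---
title: "A Cellular Potts model of dermal wound healing with senescent-cell dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Cellular Potts model of dermal wound healing with senescent-cell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`dermalCPM` simulates a 600 µm × 600 µm dermal section (200 × 200 pixels,
3 µm per pixel) from the end of the inflammatory phase of wound healing
through the proliferative and remodelling phases. Six generalised cell types
live on the lattice: quiescent/activated **fibroblasts**, contractile
**myofibroblasts**, M1/M2-polarised **macrophages**, **senescent
myofibroblasts**, **pre-existing inflammatory senescent cells**, and
one-pixel, immobile **ECM** elements. Four diffusible fields couple them:
PDGF, CSF1, MMP (proteinase) and a single aggregated inflammatory-SASP
field.

### Lattice mechanics

Cells are sets of pixels evolving by Metropolis pixel-copy attempts. One
Monte-Carlo step (MCS) is width × height attempts and corresponds to 27 s
(0.3 µm/MCS reference displacement against a 40 µm/h peak fibroblast
migration speed), so one simulated day is 3200 MCS. The effective energy is

$$H = \sum_{\text{pairs}} J(\tau,\tau')\,(1-\delta_{\sigma\sigma'})
 + \sum_\sigma \lambda_V (v_\sigma - V_\sigma)^2
 + \sum_\sigma \lambda_S (s_\sigma - S_\sigma)^2,$$

with contact energies over the 2nd-order (Moore) neighbourhood, copy
adjacency over the 1st-order (von Neumann) neighbourhood, and closed
(non-periodic) borders. A candidate copy is accepted with probability 1 if
$\Delta H \le 0$ and $e^{-\Delta H/T}$ otherwise. Chemotaxis adds
$-\lambda\,(c_{\text{target}} - c_{\text{source}})$ for copies that extend a
chemotacting cell; fibroblasts and myofibroblasts climb PDGF (with
$\lambda$ raised to `lambda_pdgf_ecm` while the cell touches ECM,
representing haptokinetic guidance along fibres), macrophages climb the
inflammatory field. The ECM-contact flag is refreshed at behaviour-sweep
granularity (every 50 MCS ≈ 22 min), not per attempt.

The Metropolis temperature (T = 3) and the contact/constraint coefficients
were calibrated so that a single unconstrained 8 × 8 cell travels ~0.1
pixel/MCS, the reference free-cell speed; `scripts/acceptance.R` recomputes
this quantity.

Plain CPM copies can fragment a cell. Connectivity is repaired lazily once
per behaviour sweep: detached fragments smaller than 2 pixels are culled to
Medium; cells whose volume reaches zero are removed.

### Fields

Each field obeys
$\partial_t c = D\nabla^2 c - \delta c + S$
integrated per MCS by forward-Euler with a 5-point Laplacian, reflecting
(no-flux) boundaries and multiplicative decay, sub-stepped so that
$D\,\Delta t \le 0.2$ (the 1/4 stability limit leaves the highest lattice
mode undamped, which visibly contaminates point-source profiles). Secretion
is deposited every MCS over all pixels of the secreting cell, with the
per-cell rate split per pixel so cell size does not multiply output. Fields
diffuse across cells. Concentrations are arbitrary model units; only their
ratios to thresholds matter. The baseline D = 1 px²/MCS ≈ 0.33 µm²/s with
decay constants of 0.0005–0.002 /MCS gives signalling ranges of ~20–45
pixels (60–135 µm), enough for wound-edge crosstalk on this domain.

### Cell behaviour

Behaviour rules run every `sweep_period_mcs` = 50 MCS from a consistent
census snapshot, in a fixed order: senescence clocks/SASP phases;
macrophage polarisation (M1 iff INF at COM > `inf_thr`); persistent
fibroblast activation (PDGF at COM > `pdgf_f`); TIMP (each myofibroblast
subtracts `mmp_thr` from MMP at its COM, clamped at 0); ECM degradation
(ECM cells with MMP at COM > `mmp_thr` are removed); myofibroblast
differentiation (activated fibroblast, inside the t = 0 wound mask, PDGF
gate, ECM contact > `ecm_thr`, probability `p_mf` per check); ECM
deposition (activated fibroblasts deposit `ecm_fib_per_day` one-pixel ECM
cells on adjacent Medium, myofibroblasts exactly double that, fibrogenic
senescent cells deposit constitutively); myofibroblast fate (apoptosis on
ECM contact < `ecm_thr` or INF > `inf_thr`, else primary/CCN1 senescence
with probability `p_snc` per check while the `t_sen` gate is open);
juxtacrine then paracrine secondary senescence; senescent clearance;
background removal (rate `mu` for activated fibroblasts and macrophages,
plus CSF1-withdrawal death for macrophages below `csf1_thr`); Monod growth
with contact inhibition; mitosis; fragment culling. All threshold
comparisons are strict as printed; boundary cases (Rs = `t_ci` grows,
clock = `t_nis_days` is fibrolytic, contact = `ecm_thr` survives) are noted
per rule in the reference pages.

Growth raises the target volume by $G_{max}\, c/(c + c_0)$ per MCS (PDGF
for fibroblasts/myofibroblasts, CSF1 for macrophages) only while the
medium-surface ratio $R_s = s_{\text{medium}}/s$ is at least `t_ci`;
otherwise the target volume freezes at the current volume. Mitosis occurs
at twice the type's original target volume, splitting along a random line
through the COM; daughters inherit state flags and the original target
volume.

### Senescence programme

A senescent myofibroblast runs a two-phase secretory programme: fibrogenic
(PDGF secretion + ECM deposition) for `t_nis_days` = 3 days, then
fibrolytic (CSF1 + inflammation + MMP) permanently. Pre-existing
inflammatory senescent cells are always fibrolytic. Three induction routes
are tracked separately for the time series: primary (CCN1; probabilistic,
gated by time and ECM contact), juxtacrine (contact with a fibrogenic-phase
senescent cell while PDGF at COM > `snc_thr`), and paracrine (contact with
a fibrolytic-phase or pre-existing senescent cell while INF at COM >
`inf_thr`). Clearance has two equal-chance triggers (probability `p_clear`
per sweep each): macrophage contact (phagocytosis) and INF at the cell's
COM above `inf_thr`.

## Time-base and gate decisions

Three places in the rule system need a time base the source material leaves
open; the package resolves them as follows and exposes each choice in the
configuration:

* **`t_sen` unit.** The senescence-induction gate value 12 is kept verbatim
  in the baseline configuration with a configurable unit
  (`steps500`, `steps1000`, `hours`, `days`). The baseline unit is
  1000-MCS blocks, i.e. a gate at 3.75 days: with this package's
  parameterisation that reproduces the observed succession (senescence
  rising from ~day 4 and peaking near day 7, one fibrogenic-phase duration
  later), whereas a 1.875-day gate makes the senescent population peak
  around day 5. The delayed-induction scenario uses 15 *days*, which the
  narrative states explicitly. The alternative printed reading ("induction
  only while t < T_SEN") is available via `t_sen_gate = "closed_after"`.
* **`p_snc`, `p_mf` cadence.** The binomial fate draws are per 500-MCS
  model step (the model's reporting cadence) and are compounded to the
  sweep period as $1-(1-p)^{K/500}$. Per-step 0.15 corresponds to an
  effective primary-senescence hazard of ~0.65/day once the gate opens,
  which ends the myofibroblast era on the observed schedule. A per-day
  reading leaves myofibroblast termination to a juxtacrine threshold
  crossing that is knife-edge sensitive to the stochastic PDGF field.
* **`mu`** is a per-day rate converted as $1-e^{-\mu\,\Delta t}$;
  `p_clear` is per sweep by definition.

## Baseline parameterisation

No complete published parameter table accompanies the model narrative, so
the packaged baseline (`inst/extdata/baseline_params.yaml`) was calibrated,
mirroring the original calibration-against-curves approach, to the
headline healthy-healing landmarks: free-cell speed ~0.1 px/MCS;
myofibroblast count peaking near day 4; senescent-myofibroblast count
peaking near day 7; macrophages roughly doubling before plateauing from
~day 3.5. The landmark check in the test suite measures peaks on the
5-sample rolling mean of the three-replicate mean trajectory over a
12-day full-scale run (all landmarks fall before day 12; three replicates
is the study's own design). Parameters of note:

* Contact energies make cell–Medium contact (7) cheaper than cell–cell
  contact (11), so the wound is invaded rather than the dermis compacted.
  ECM–ECM contact is cheap (2) while ECM–Medium is expensive (12) with a
  strong one-pixel volume constraint (λ = 150), making ECM elements inert:
  they neither crawl nor dissolve, and only the MMP rule removes them.
* The dermis is tiled with 8 × 8 fibroblasts (45% of blocks) in an
  interstitial ECM bed (70% fill); the wound-facing ring of blocks is
  always fibroblasts — the invasion front advances by chemotaxis plus
  front proliferation.
* An initial uniform CSF1 pool (0.5) represents inflammatory-phase
  growth-factor carry-over; without it, wound macrophages starve before
  fibroblast-derived, contact-gated CSF1 can reach them.
* `p_clear` = 0.03 per sweep per trigger. Larger values clear
  macrophage-contacted senescent cells within an hour and truncate the
  senescent population days before its observed peak.

## What the synthetic pieces do and do not show

`generate_calibration_curves()` produces smooth log-normal/logistic curves
carrying the qualitative landmarks (myofibroblast peak day 4, senescent
peak day 7, macrophage doubling, double-plateau ECM). They are synthetic
stand-ins for digitised literature data and are labelled as such; fitting
against them exercises the estimation machinery but says nothing about
real wounds. Likewise, passing landmark tests shows the model reproduces
the published qualitative dynamics under this parameterisation — not that
the parameters are biologically identified; several (notably secretion
rates and thresholds, which only appear as ratios) are degenerate by
construction.

## Scenarios, sweep and fitting

The five classifications differ only in senescent-cell dynamics
(`p_snc` 0.15 → 0.75 or 0; `t_sen` → 15 days; or pre-existing inflammatory
senescent cells seeded at t = 0 with an inflammatory bolus):

```{r}
library(dermalCPM)
cfg <- scenario_config("healthy")
res <- run_scenario(cfg)
```

End states at day 18 are labelled against the healthy baseline by
`classify_outcome()`: fibrotic when wound ECM exceeds the baseline by
`fibrosis_factor`, chronic when wound ECM falls below `deficit_factor`
times baseline or the inflammatory load (INF total, macrophage count)
exceeds `inflammation_factor` times baseline. The factors are
package-defined defaults chosen so the five canonical scenarios map to
their expected labels; the original classification was by inspection.

`run_sweep()` executes the 5 × 5 (`p_snc` × `t_sen`) grid — 25 simulations
— with a "preexisting" pseudo-level standing for induction before the
simulated window. `pso_fit()` implements canonical global-best PSO
(inertia 0.7, cognitive = social = 1.5 by default) and
`fit_thresholds()` wraps it around reduced-scale simulations with the
mean-relative-error objective over the six calibration observables
(fibroblasts, myofibroblasts, senescent myofibroblasts, macrophages, ECM,
closure rate; denominator floored at 1% of each curve's maximum).
Objective evaluations reuse one fixed seed so the objective is a
deterministic function of the parameters.

## Numerical and degenerate-case conventions

* COM field sampling uses the round-half-up nearest pixel, matching
  lattice-native behaviour; bilinear interpolation was rejected.
* Division retries up to 24 random axes before skipping a cell that cannot
  be split into two non-empty daughters this sweep.
* ECM deposition with no adjacent Medium pixel produces nothing that sweep.
* A zero-surface cell is a degenerate input for Rs and raises an error.
* Same-sweep rule chaining is deliberately absent: decisions are made on
  the entry census, so e.g. a cell senescing this sweep induces juxtacrine
  senescence in neighbours from the next sweep onward.
* Reproducibility: one seed drives the engine RNG (C++, Metropolis and
  structural randomness) and the rule RNG (R session RNG); identical seeds
  give bit-identical runs.

## Problem sizes used by the checks

The test suite runs the landmark check at the full 200 × 200 scale for 12
simulated days × 3 replicates, scenario-logic checks on a 60 × 60 domain
for 6 days, the sweep-cardinality check on a 40 × 40 domain for 0.1 day
per cell, and threshold-recovery on a 40 × 40 domain for 1.5 days per
objective evaluation. These sizes are the package's own trade-off between
statistical stability of stochastic landmarks and a test suite that stays
pleasant to run.

## Known limitations

* The wound does not reach complete (closure ≈ 1) healing under the
  baseline: late remodelling keeps a churning equilibrium of fibroblasts,
  matrix and surviving senescent cells at ~50–65% closure. The landmark
  dynamics up to the remodelling phase are unaffected, but closure-rate
  comparisons against saturating curves should use the early phase only.
* A single aggregated inflammation field stands in for the inflammatory
  SASP mixture; there are no immune cell types beyond macrophages, no
  keratinocytes/epidermis, and no explicit TIMP or CCN1 species.
* Myofibroblast de-differentiation has no published rule; it ships off by
  default (`p_dediff = 0`).
* ECM is one-pixel and unoriented: fibre alignment, tension and
  plasticity are outside scope.
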